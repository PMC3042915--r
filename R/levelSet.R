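#' Connected components of a density level set
#'
#' Retains the observations with fitted density strictly above the cut
#' \code{c} and splits them into connected components of the induced
#' neighbour subgraph.
#'
#' @param graph a \code{\linkS4class{NeighborGraph}}.
#' @param densities fitted density at each vertex.
#' @param c cut level; strict inequality \code{densities > c} is used, so
#'   at a cut equal to a fitted value that observation is excluded.
#' @return list of integer vectors (sorted vertex indices), one per
#'   component; an empty list when no vertex is retained.
#' @examples
#' g <- buildNeighborGraph(c(1, 2, 3))
#' levelSetComponents(g, c(3, 1, 3), 2)
#' @export
levelSetComponents <- function(graph, densities, c) {
    stopifnot(is(graph, "NeighborGraph"),
              length(densities) == graph@nVertices,
              all(is.finite(densities)))
    keep <- which(densities > c)
    if (!length(keep)) return(list())
    sub <- igraph::induced_subgraph(.asIgraph(graph), keep)
    comp <- igraph::components(sub)
    out <- split(keep, comp$membership)
    names(out) <- NULL
    lapply(out, sort)
}

# Adjacency list of a NeighborGraph.
.adjList <- function(graph) {
    n <- graph@nVertices
    adj <- rep(list(integer(0)), n)
    if (nrow(graph@edges)) {
        e <- graph@edges
        adj <- unname(split(c(e[, 2], e[, 1]),
                            factor(c(e[, 1], e[, 2]), levels = seq_len(n))))
    }
    adj
}

# Level-scan by incremental union-find: activate vertices in decreasing
# density order, merging with already-active neighbours.  Records, for
# each cut level (the next lower unique density value, 0 last), the
# number of components and the number of components reaching minCoreSize.
.levelScan <- function(graph, densities, minCoreSize) {
    n <- graph@nVertices
    adj <- .adjList(graph)
    parent <- seq_len(n)
    csize <- integer(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    active <- logical(n)
    ord <- order(densities, decreasing = TRUE)
    dOrd <- densities[ord]
    newLevel <- c(TRUE, dOrd[-1] != dOrd[-n])
    levelEnds <- c(which(newLevel[-1]), n)  # last position of each level
    nComp <- 0L; nBig <- 0L
    levels <- numeric(0); compCounts <- integer(0); bigCounts <- integer(0)
    pos <- 1L
    for (le in levelEnds) {
        while (pos <= le) {
            i <- ord[pos]
            active[i] <- TRUE
            csize[i] <- 1L
            nComp <- nComp + 1L
            if (minCoreSize <= 1L) nBig <- nBig + 1L
            for (j in adj[[i]]) {
                if (!active[j]) next
                ri <- find(i); rj <- find(j)
                if (ri == rj) next
                bi <- csize[ri] >= minCoreSize
                bj <- csize[rj] >= minCoreSize
                parent[ri] <- rj
                csize[rj] <- csize[rj] + csize[ri]
                nComp <- nComp - 1L
                nBig <- nBig - bi - bj + (csize[rj] >= minCoreSize)
            }
            pos <- pos + 1L
        }
        levels <- c(levels, if (le < n) dOrd[le + 1L] else 0)
        compCounts <- c(compCounts, nComp)
        bigCounts <- c(bigCounts, nBig)
    }
    list(levels = levels, nComponents = compCounts, nCores = bigCounts)
}

# Cluster-tree leaves by the same incremental sweep.  A component
# "matures" into a leaf when it first reaches minCoreSize members; its
# core keeps growing until its component meets another matured leaf (or
# a region already containing frozen leaves), at which point the core is
# frozen.  Returns the leaf count and per-point core membership.
.leafScan <- function(graph, densities, minCoreSize) {
    n <- graph@nVertices
    adj <- .adjList(graph)
    parent <- seq_len(n)
    csize <- integer(n)
    lab <- integer(n)            # per root: 0 immature, >0 leaf, -1 dead
    members <- vector("list", n) # per root, while immature (< minCoreSize)
    leafOf <- rep(NA_integer_, n)
    frozen <- logical(0)
    nLeaf <- 0L
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    mature <- function(r) {
        nLeaf <<- nLeaf + 1L
        frozen[nLeaf] <<- FALSE
        leafOf[members[[r]]] <<- nLeaf
        lab[r] <<- nLeaf
        members[r] <<- list(NULL)
    }
    active <- logical(n)
    # Activating a point merges it with ALL adjacent active components at
    # once (they become one component at this level); maturation and
    # freezing are judged on the combined component, never on phantom
    # pairwise intermediates.
    for (i in order(densities, decreasing = TRUE)) {
        active[i] <- TRUE
        roots <- unique(vapply(adj[[i]][active[adj[[i]]]], find, 1L))
        labs <- lab[roots]
        leaves <- labs[labs > 0L]
        anyDead <- any(labs == -1L)
        newMembers <- c(i, unlist(members[roots[labs == 0L]]))
        r <- i
        csize[i] <- 1L
        for (rt in roots) {
            parent[rt] <- r
            csize[r] <- csize[r] + csize[rt]
            members[rt] <- list(NULL)
        }
        if (length(leaves) >= 2L || (length(leaves) >= 1L && anyDead)) {
            frozen[leaves] <- TRUE      # distinct modes meet: freeze cores
            lab[r] <- -1L
        } else if (anyDead) {
            lab[r] <- -1L
        } else if (length(leaves) == 1L) {
            lab[r] <- leaves            # component continues as this leaf
            leafOf[newMembers] <- leaves
        } else {
            lab[r] <- 0L
            members[[r]] <- newMembers
            if (csize[r] >= minCoreSize) mature(r)
        }
    }
    list(nLeaves = nLeaf, leafOf = leafOf)
}

# Cluster-tree leaves examined only at a fixed grid of cut levels
# (decreasing, ending at 0).  Components are merged incrementally
# between checkpoints; maturation (a component reaching minCoreSize
# becomes a leaf) and freezing (distinct leaves meeting) are judged at
# the checkpoints, so modes that exist only between two consecutive
# levels are never seen.  Tracks full member sets so the frozen cores
# can be returned.
.gridLeafScan <- function(graph, densities, minCoreSize, cuts) {
    n <- graph@nVertices
    adj <- .adjList(graph)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    members <- vector("list", n)  # per root: all member points
    leaves <- vector("list", n)   # per root: unfrozen leaf ids inside
    dead <- logical(n)            # per root: contains frozen leaves
    active <- logical(n)
    snapshot <- list()            # per leaf: core member set
    nLeaf <- 0L
    ord <- order(densities, decreasing = TRUE)
    pos <- 1L
    for (cut in cuts) {
        while (pos <= n && densities[ord[pos]] > cut) {
            i <- ord[pos]
            active[i] <- TRUE
            members[[i]] <- i
            leaves[[i]] <- integer(0)
            roots <- unique(vapply(adj[[i]][active[adj[[i]]]], find, 1L))
            for (rt in roots) {
                parent[rt] <- i
                members[[i]] <- c(members[[i]], members[[rt]])
                leaves[[i]] <- c(leaves[[i]], leaves[[rt]])
                dead[i] <- dead[i] || dead[rt]
                members[rt] <- list(NULL)
            }
            pos <- pos + 1L
        }
        for (r in unique(vapply(which(active), find, 1L))) {
            lf <- leaves[[r]]
            if (length(lf) >= 2L || (length(lf) == 1L && dead[r])) {
                leaves[[r]] <- integer(0)   # modes meet: freeze cores
                dead[r] <- TRUE
            } else if (length(lf) == 1L) {
                snapshot[[lf]] <- members[[r]]   # core grows
            } else if (!dead[r] && length(members[[r]]) >= minCoreSize) {
                nLeaf <- nLeaf + 1L              # new mode matures
                leaves[[r]] <- nLeaf
                snapshot[[nLeaf]] <- members[[r]]
            }
        }
    }
    leafOf <- rep(NA_integer_, n)
    for (L in seq_len(nLeaf)) leafOf[snapshot[[L]]] <- L
    list(nLeaves = nLeaf, leafOf = leafOf)
}

# equispaced cut grid over [0, max density], decreasing, ending at 0
.gridCuts <- function(densities, nGrid) {
    c(max(densities) * ((nGrid - 1):1) / nGrid, 0)
}

#' Detect the number of clusters and the cluster cores
#'
#' Scans the cut level c downward and tracks the connected components of
#' \{i : f(x_i) > c\} in the neighbour graph.  By default the scan
#' examines every unique fitted density value (every level at which the
#' component structure can change); with \code{levelGrid =
#' "equispaced"} it examines only \code{nGrid} equispaced levels over
#' [0, max f], a coarser scan that is markedly more robust to transient
#' spurious modes (the per-gene filter defaults to it).  Two extraction
#' rules are available:
#'
#' \describe{
#' \item{\code{"tree-leaves"} (default)}{every density mode that matures
#'   — whose component reaches \code{minCoreSize} members while still
#'   separate — is a cluster; its core keeps growing until its component
#'   meets another matured mode, at which point the core is frozen.
#'   This is the branch count of the cluster tree.}
#' \item{\code{"max-count"}}{the number of clusters is the maximum, over
#'   the scan, of the number of simultaneous components with at least
#'   \code{minCoreSize} members; the cores are those components at the
#'   smallest cut attaining the maximum (ties toward the smaller cut,
#'   giving larger cores).}
#' }
#'
#' Observations outside every core are left unallocated.  Cores are
#' labelled 1..m by decreasing peak density (ties by smallest member
#' index), which makes labels deterministic.
#'
#' @inheritParams levelSetComponents
#' @param points the observations the densities were fitted on (n x p).
#' @param minCoreSize smallest component size that counts as a cluster
#'   core (default 2, suppressing singleton spurious modes).
#' @param mRule cluster-count extraction rule, see Details.
#' @param levelGrid \code{"equispaced"} (default) or \code{"exact"}.
#' @param nGrid number of equispaced cut levels (default 20).
#' @param keepTree also record the full partition at every level in the
#'   returned tree (needed only for inspection/diagnostics).
#' @return list with elements \code{tree}
#'   (\code{\linkS4class{ClusterTree}}), \code{nClusters} and
#'   \code{coreLabels} (integer, \code{NA} = unallocated).
#' @export
detectClusters <- function(points, densities, graph, minCoreSize = 2L,
                           mRule = c("tree-leaves", "max-count"),
                           levelGrid = c("exact", "equispaced"),
                           nGrid = 20L, keepTree = FALSE) {
    mRule <- match.arg(mRule)
    levelGrid <- match.arg(levelGrid)
    points <- .asPoints(points)
    stopifnot(length(densities) == nrow(points),
              graph@nVertices == nrow(points))
    n <- nrow(points)
    minCoreSize <- as.integer(minCoreSize)
    sc <- .levelScan(graph, densities, minCoreSize)
    if (levelGrid == "equispaced") {
        cuts <- .gridCuts(densities, as.integer(nGrid))
        # recorded state with the largest level <= cut is the state at cut
        idx <- vapply(cuts, function(cc) {
            w <- which(sc$levels <= cc)
            w[1]
        }, 1L)
        scanLevels <- cuts
        scanCores <- sc$nCores[idx]
        scanComps <- sc$nComponents[idx]
    } else {
        scanLevels <- sc$levels
        scanCores <- sc$nCores
        scanComps <- sc$nComponents
    }
    coreCut <- NA_real_
    if (mRule == "max-count") {
        best <- max(scanCores)
        if (best < 1L) {          # no component ever reaches core size
            m <- 1L
            coreLabels <- rep(1L, n)
            coreCut <- 0
        } else {
            m <- best
            at <- which(scanCores == best)
            coreCut <- scanLevels[at[length(at)]] # smallest qualifying cut
            comps <- levelSetComponents(graph, densities, coreCut)
            cores <- comps[vapply(comps, length, 1L) >= minCoreSize]
            stopifnot(length(cores) == m)
            coreLabels <- .labelCores(cores, densities, n)
        }
    } else {
        lf <- if (levelGrid == "equispaced")
            .gridLeafScan(graph, densities, minCoreSize,
                          .gridCuts(densities, as.integer(nGrid)))
        else .leafScan(graph, densities, minCoreSize)
        if (lf$nLeaves < 1L) {
            m <- 1L
            coreLabels <- rep(1L, n)
        } else {
            m <- lf$nLeaves
            cores <- unname(split(seq_len(n)[!is.na(lf$leafOf)],
                                  lf$leafOf[!is.na(lf$leafOf)]))
            coreLabels <- .labelCores(cores, densities, n)
        }
    }
    tree <- new("ClusterTree", levels = scanLevels,
                nComponents = as.integer(scanComps),
                nCores = as.integer(scanCores),
                componentsPerLevel = if (keepTree)
                    lapply(scanLevels, function(l)
                        levelSetComponents(graph, densities, l))
                else list(),
                minCoreSize = minCoreSize)
    list(tree = tree, nClusters = m, coreLabels = coreLabels,
         coreCut = coreCut, mRule = mRule)
}

# order cores by decreasing peak density (ties by smallest index) and
# return the per-point label vector
.labelCores <- function(cores, densities, n) {
    peak <- vapply(cores, function(ix) max(densities[ix]), 1)
    cores <- cores[order(-peak, vapply(cores, min, 1L))]
    lab <- rep(NA_integer_, n)
    for (k in seq_along(cores)) lab[cores[[k]]] <- k
    lab
}

#' Allocate low-density observations to the cluster cores
#'
#' Unallocated observations are processed in decreasing order of their
#' (global) fitted density.  For each observation x0 a kernel density
#' estimate \eqn{\hat f_k} is fitted on the observations currently
#' assigned to group k, and x0 is assigned to the group maximizing the
#' ratio \eqn{\hat f_k(x_0) / \max_{l \neq k} \hat f_l(x_0)} (computed
#' in log space; ties broken to the lowest group index).  The assignment
#' immediately enlarges group k for the subsequent allocations.
#'
#' Three bandwidth policies are available for the per-group estimates:
#' \describe{
#' \item{\code{"scaled-global"} (default)}{the pooled normal-reference
#'   bandwidths rescaled for the group size,
#'   \eqn{h_k = h \cdot (n/n_k)^{1/(p+4)}} — the normal-reference sample
#'   size dependence with a pooled scale estimate, so that small cores
#'   keep a reach comparable to their competitors.}
#' \item{\code{"refit"}}{bandwidths recomputed from the group members;
#'   groups too small for a bandwidth (fewer than 2 members, or a
#'   degenerate dimension) fall back to the global vector.}
#' \item{\code{"global"}}{the pooled bandwidths, unscaled.}
#' }
#'
#' @param points n x p matrix of observations.
#' @param coreLabels integer labels in 1..m with \code{NA} for
#'   unallocated observations.
#' @param shrinkage bandwidth shrinkage used for the fits.
#' @param densities global fitted density per observation (recomputed
#'   from \code{points} when omitted); fixes the allocation order.
#' @param groupBandwidths bandwidth policy, see Details.
#' @return integer vector of final labels in 1..m.
#' @export
allocateRemaining <- function(points, coreLabels, shrinkage = 0.75,
                              densities = NULL,
                              groupBandwidths = c("scaled-global",
                                                  "refit", "global")) {
    groupBandwidths <- match.arg(groupBandwidths)
    points <- .asPoints(points)
    n <- nrow(points); p <- ncol(points)
    stopifnot(length(coreLabels) == n)
    m <- suppressWarnings(max(coreLabels, na.rm = TRUE))
    if (!is.finite(m) || m < 1L) stop("at least one core must be non-empty")
    labels <- as.integer(coreLabels)
    if (m == 1L) {
        labels[] <- 1L
        return(labels)
    }
    if (is.null(densities))
        densities <- kdeEvaluate(kdeFit(points, shrinkage), points)
    globalH <- normalReferenceBandwidth(points, shrinkage)
    groupH <- function(pts) {
        nk <- nrow(pts)
        switch(groupBandwidths,
               "scaled-global" = globalH * (n / nk)^(1 / (p + 4)),
               "refit" = tryCatch(
                   normalReferenceBandwidth(pts, shrinkage),
                   error = function(e) globalH),
               "global" = globalH)
    }
    todo <- which(is.na(labels))
    todo <- todo[order(densities[todo], decreasing = TRUE)]
    for (i in todo) {
        x0 <- points[i, , drop = FALSE]
        lf <- vapply(seq_len(m), function(k) {
            pts <- points[which(labels == k), , drop = FALSE]
            mod <- new("DensityModel", points = pts + 0,
                       bandwidths = groupH(pts), shrinkage = shrinkage)
            kdeEvaluate(mod, x0, log = TRUE)
        }, 1)
        # log ratio log f_k - max_{l != k} log f_l; which.max takes the
        # lowest index on ties
        r <- vapply(seq_len(m), function(k) lf[k] - max(lf[-k]), 1)
        labels[i] <- which.max(r)
    }
    labels
}

#' Nonparametric density-based clustering
#'
#' Clusters the rows of \code{points} as the connected components of
#' high-density regions of a Gaussian product-kernel density estimate:
#' fit the KDE with shrunk normal-reference bandwidths, link the
#' observations through the Delaunay neighbour graph, scan the density
#' cut level to detect the number of clusters and the cluster cores
#' (\code{\link{detectClusters}}), then allocate the remaining
#' observations by the density-ratio rule
#' (\code{\link{allocateRemaining}}).  The number of clusters is
#' detected from the data, not pre-specified.  The procedure is
#' deterministic given its inputs; the only randomness is the seeded
#' jitter used to escape degenerate triangulations.
#'
#' @param points numeric matrix (n x p, p <= \code{pMax}) or vector.
#' @param shrinkage bandwidth shrinkage factor (default 3/4).
#' @param minCoreSize smallest component size accepted as a cluster core.
#' @param mRule cluster-count extraction rule, see
#'   \code{\link{detectClusters}}.
#' @param levelGrid,nGrid cut-level grid, see
#'   \code{\link{detectClusters}}.
#' @param groupBandwidths allocation bandwidth policy, see
#'   \code{\link{allocateRemaining}}.
#' @param pMax largest allowed dimension (default 3: triangulation cost
#'   grows steeply beyond that); override with a warning.
#' @param keepTree record full per-level partitions in the result's tree.
#' @param jitter,jitterSeed degenerate-triangulation fallback, see
#'   \code{\link{buildNeighborGraph}}.
#' @return a \code{\linkS4class{ClusteringResult}}.
#' @examples
#' x <- c(rnorm(50), rnorm(50, 8))
#' res <- pdfCluster(x)
#' nClusters(res)
#' @export
pdfCluster <- function(points, shrinkage = 0.75, minCoreSize = 2L,
                       mRule = c("tree-leaves", "max-count"),
                       levelGrid = c("exact", "equispaced"), nGrid = 20L,
                       groupBandwidths = c("scaled-global", "refit",
                                           "global"),
                       pMax = 3L, keepTree = FALSE, jitter = TRUE,
                       jitterSeed = 1L) {
    mRule <- match.arg(mRule)
    levelGrid <- match.arg(levelGrid)
    groupBandwidths <- match.arg(groupBandwidths)
    points <- .asPoints(points)
    n <- nrow(points)
    if (n < 2) stop("need at least 2 observations")
    model <- kdeFit(points, shrinkage)
    dens <- kdeEvaluate(model, points)
    graph <- buildNeighborGraph(points, jitter = jitter,
                                jitterSeed = jitterSeed, pMax = pMax)
    det <- detectClusters(points, dens, graph, minCoreSize = minCoreSize,
                          mRule = mRule, levelGrid = levelGrid,
                          nGrid = nGrid, keepTree = keepTree)
    final <- allocateRemaining(points, det$coreLabels,
                               shrinkage = shrinkage, densities = dens,
                               groupBandwidths = groupBandwidths)
    new("ClusteringResult",
        nClusters = as.integer(det$nClusters),
        coreLabels = as.integer(det$coreLabels),
        finalLabels = as.integer(final),
        densities = dens, tree = det$tree,
        metadata = list(shrinkage = shrinkage,
                        minCoreSize = as.integer(minCoreSize),
                        mRule = mRule, levelGrid = levelGrid,
                        nGrid = as.integer(nGrid),
                        groupBandwidths = groupBandwidths,
                        bandwidths = model@bandwidths,
                        coreCut = det$coreCut,
                        graph = graph@metadata))
}

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusteringResult", function(x) x@nClusters)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusteringResult", function(x) x@finalLabels)

#' @rdname accessors
#' @export
setMethod("coreLabels", "ClusteringResult", function(x) x@coreLabels)

#' @rdname accessors
#' @export
setMethod("pointDensities", "ClusteringResult", function(x) x@densities)

setMethod("show", "ClusteringResult", function(object) {
    cat("ClusteringResult:", length(object@finalLabels),
        "observations in", object@nClusters, "cluster(s)\n")
    cat("  core sizes:",
        paste(tabulate(object@coreLabels, object@nClusters),
              collapse = ", "),
        "| unallocated:", sum(is.na(object@coreLabels)), "\n")
    cat("  final sizes:",
        paste(tabulate(object@finalLabels, object@nClusters),
              collapse = ", "), "\n")
})

#' Export a clustering result as delimited text
#'
#' Writes one row per observation: id, fitted density, core label (empty
#' if the observation was unallocated before the ratio stage) and final
#' label.
#'
#' @param result a \code{\linkS4class{ClusteringResult}}.
#' @param path output file.
#' @param ids optional observation identifiers.
#' @return the path, invisibly.
#' @export
writeClusteringResult <- function(result, path, ids = NULL) {
    n <- length(result@finalLabels)
    if (is.null(ids)) ids <- seq_len(n)
    df <- data.frame(id = ids,
                     density = sprintf("%.17g", result@densities),
                     core_label = ifelse(is.na(result@coreLabels), "",
                                         result@coreLabels),
                     final_label = result@finalLabels)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a level-set scan record as delimited text
#'
#' One row per cut level: level, number of components, number of
#' core-sized components.
#'
#' @param tree a \code{\linkS4class{ClusterTree}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClusterTree <- function(tree, path) {
    df <- data.frame(level = sprintf("%.17g", tree@levels),
                     n_components = tree@nComponents,
                     n_cores = tree@nCores)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

setMethod("show", "ClusterTree", function(object) {
    cat("ClusterTree:", length(object@levels), "cut levels, up to",
        max(object@nCores), "core-sized component(s) (minCoreSize ",
        object@minCoreSize, ")\n", sep = " ")
})
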