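#' Detected number of clusters for each gene
#'
#' Runs the univariate level-set clustering scan on every gene's
#' expression profile across the samples and reports the detected number
#' of clusters per gene.  Genes with zero variance across samples report
#' one cluster.  The default engine is a compiled implementation of the
#' univariate case (where the Delaunay neighbour graph reduces to the
#' chain over the sort order); \code{engine = "reference"} runs the
#' general-dimension code path gene by gene and is used to validate the
#' fast path.
#'
#' @param expr genes x samples matrix, data.frame or
#'   SummarizedExperiment.
#' @param shrinkage bandwidth shrinkage factor (default 3/4).
#' @param minCoreSize smallest component size accepted as a cluster core.
#' @param mRule cluster-count extraction rule, see
#'   \code{\link{detectClusters}}.
#' @param engine \code{"fast"} (compiled) or \code{"reference"}.
#' @return integer vector, one detected cluster count per gene.
#' @export
geneClusterCounts <- function(expr, shrinkage = 0.75, minCoreSize = 2L,
                              mRule = c("tree-leaves", "max-count"),
                              levelGrid = c("equispaced", "exact"),
                              nGrid = 20L,
                              engine = c("fast", "reference")) {
    engine <- match.arg(engine)
    mRule <- match.arg(mRule)
    levelGrid <- match.arg(levelGrid)
    m <- .asExprMatrix(expr)
    if (ncol(m) < 4)
        stop("univariate clustering needs at least 4 samples")
    if (engine == "fast") {
        out <- .geneClusterCountsCpp(m, shrinkage, as.integer(minCoreSize),
                                     if (mRule == "max-count") 1L else 0L,
                                     if (levelGrid == "equispaced")
                                         as.integer(nGrid) else 0L)
    } else {
        out <- vapply(seq_len(nrow(m)), function(g) {
            x <- m[g, ]
            if (sd(x) <= 0) return(1L)
            dens <- kdeEvaluate(kdeFit(x, shrinkage), x)
            graph <- buildNeighborGraph(x)
            detectClusters(matrix(x, ncol = 1), dens, graph,
                           minCoreSize = minCoreSize,
                           mRule = mRule, levelGrid = levelGrid,
                           nGrid = nGrid)$nClusters
        }, 1L)
    }
    names(out) <- rownames(m)
    out
}

#' Univariate density-based gene filtering
#'
#' First step of the pipeline: each gene is clustered on its own
#' univariate distribution across the samples, and only the genes for
#' which the method detects two or more clusters are retained.  A gene
#' is thereby considered relevant when its values split the samples into
#' distinct groups, rather than when its overall variance is large —
#' high variance need not imply grouping, nor low variance exclude it.
#' Constant genes are never selected.
#'
#' @inheritParams geneClusterCounts
#' @return integer vector of selected gene indices, named by gene id.
#'   An empty selection is legal and reported with a warning.
#' @examples
#' m <- rbind(bimodal = c(rnorm(30), rnorm(30, 10)), flat = rnorm(60))
#' filterGenes(m)
#' @export
filterGenes <- function(expr, shrinkage = 0.75, minCoreSize = 2L,
                        mRule = c("tree-leaves", "max-count"),
                        levelGrid = c("equispaced", "exact"),
                        nGrid = 20L,
                        engine = c("fast", "reference")) {
    counts <- geneClusterCounts(expr, shrinkage, minCoreSize,
                                match.arg(mRule), match.arg(levelGrid),
                                nGrid, match.arg(engine))
    sel <- which(counts >= 2L)
    if (!length(sel))
        warning("no gene passed the density-based filter")
    sel
}

#' Principal-component reduction of the selected genes
#'
#' Treats the samples as observations and the (selected) genes as
#' variables, centers each gene (no scaling: genes are assumed to share
#' a common, typically log, scale) and returns the first
#' \code{nComponents} principal-component scores, ordered by decreasing
#' explained variance.  The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making scores
#' reproducible across platforms.
#'
#' @param expr genes x samples input, already restricted to the selected
#'   genes.
#' @param nComponents number of components to keep (default 3); when the
#'   input supports fewer, the feasible maximum is used with a warning.
#' @return n x nComponents numeric score matrix (samples in rows).
#' @export
reduceDimension <- function(expr, nComponents = 3L) {
    m <- .asExprMatrix(expr)
    x <- t(m)                                    # samples x genes
    kmax <- min(nrow(x) - 1L, ncol(x))
    if (nComponents > kmax) {
        warning("only ", kmax, " principal component(s) available; ",
                "reducing nComponents")
        nComponents <- kmax
    }
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- seq_len(nComponents)
    rot <- pc$rotation[, k, drop = FALSE]
    flip <- vapply(seq_along(k), function(j) {
        l <- rot[, j]
        if (l[which.max(abs(l))] < 0) -1 else 1
    }, 1)
    scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, "*")
    rownames(scores) <- colnames(m)
    scores
}

#' Three-step density-based clustering of expression samples
#'
#' The full pipeline: (i) univariate density-based gene filtering
#' (\code{\link{filterGenes}}), (ii) PCA reduction of the selected genes
#' to \code{nComponents} dimensions (\code{\link{reduceDimension}}),
#' (iii) level-set clustering of the sample scores
#' (\code{\link{pdfCluster}}).  Deterministic given the inputs and the
#' jitter seed.
#'
#' If no gene passes the filter, the pipeline falls back to clustering
#' the first principal components of the full (unfiltered) matrix; this
#' is flagged prominently with a warning and recorded in the result
#' metadata, so results are never silently unfiltered.
#'
#' @inheritParams filterGenes
#' @param filterLevelGrid,filterNGrid cut-level grid for the per-gene
#'   filtering stage (default: 20 equispaced levels, which is robust to
#'   spurious tail modes in the univariate profiles).
#' @param levelGrid,nGrid cut-level grid for the clustering stage on the
#'   scores (default: the exact scan over every unique fitted value).
#' @param groupBandwidths allocation bandwidth policy, see
#'   \code{\link{allocateRemaining}}.
#' @param nComponents number of principal components retained (default
#'   3: with around a hundred samples the clustering degrades beyond 3-4
#'   dimensions while triangulation cost rises steeply).
#' @param jitter,jitterSeed degenerate-triangulation fallback, see
#'   \code{\link{buildNeighborGraph}}.
#' @return a \code{\linkS4class{PipelineResult}}.
#' @examples
#' sim <- simulateNU(nuParams(clusterSizes = c(10, 10, 5), p = 60,
#'                            upGenes = list(1:10, integer(0), integer(0)),
#'                            downGenes = list(11:15, 11:15, integer(0))),
#'                   seed = 1)
#' res <- clusterSamples(exprValues(sim))
#' nClusters(res)
#' @export
clusterSamples <- function(expr, nComponents = 3L, shrinkage = 0.75,
                           minCoreSize = 2L,
                           mRule = c("tree-leaves", "max-count"),
                           filterLevelGrid = c("equispaced", "exact"),
                           filterNGrid = 20L,
                           levelGrid = c("exact", "equispaced"),
                           nGrid = 20L,
                           groupBandwidths = c("scaled-global", "refit",
                                               "global"),
                           jitter = TRUE, jitterSeed = 1L,
                           engine = c("fast", "reference")) {
    mRule <- match.arg(mRule)
    filterLevelGrid <- match.arg(filterLevelGrid)
    levelGrid <- match.arg(levelGrid)
    groupBandwidths <- match.arg(groupBandwidths)
    m <- .asExprMatrix(expr)
    sel <- withCallingHandlers(
        filterGenes(m, shrinkage, minCoreSize, mRule, filterLevelGrid,
                    filterNGrid, match.arg(engine)),
        warning = function(w) invokeRestart("muffleWarning"))
    fallback <- length(sel) == 0L
    if (fallback) {
        warning("no gene passed the filter; clustering the first ",
                "principal components of the FULL matrix instead")
        sub <- m
    } else {
        sub <- m[sel, , drop = FALSE]
    }
    scores <- reduceDimension(sub, nComponents)
    clus <- pdfCluster(scores, shrinkage = shrinkage,
                       minCoreSize = minCoreSize, mRule = mRule,
                       levelGrid = levelGrid, nGrid = nGrid,
                       groupBandwidths = groupBandwidths,
                       jitter = jitter, jitterSeed = jitterSeed)
    new("PipelineResult",
        selectedGenes = rownames(m)[sel],
        selectedIndex = as.integer(sel),
        scores = scores, clustering = clus,
        config = list(nComponents = as.integer(nComponents),
                      shrinkage = shrinkage,
                      minCoreSize = as.integer(minCoreSize),
                      mRule = mRule,
                      filterLevelGrid = filterLevelGrid,
                      filterNGrid = as.integer(filterNGrid),
                      levelGrid = levelGrid,
                      nGrid = as.integer(nGrid),
                      groupBandwidths = groupBandwidths,
                      jitterSeed = as.integer(jitterSeed)),
        metadata = list(fallbackUnfiltered = fallback,
                        nGenes = nrow(m), nSamples = ncol(m)))
}

#' @rdname accessors
#' @export
setMethod("nClusters", "PipelineResult",
          function(x) x@clustering@nClusters)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "PipelineResult",
          function(x) x@clustering@finalLabels)

#' @rdname accessors
#' @export
setMethod("selectedGenes", "PipelineResult", function(x) x@selectedGenes)

#' @rdname accessors
#' @export
setMethod("sampleScores", "PipelineResult", function(x) x@scores)

setMethod("show", "PipelineResult", function(object) {
    cat("PipelineResult:", object@metadata$nSamples, "samples,",
        length(object@selectedGenes), "of", object@metadata$nGenes,
        "genes selected,", ncol(object@scores), "component(s)\n")
    if (isTRUE(object@metadata$fallbackUnfiltered))
        cat("  NOTE: empty gene selection; full matrix used\n")
    cat("  clusters found:", object@clustering@nClusters, "\n")
})
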