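#' @import methods
NULL

#' Fitted product-Gaussian kernel density estimate
#'
#' A \code{DensityModel} stores the training points together with one
#' normal-reference bandwidth per dimension (shrunk by a common factor,
#' 3/4 by default).  It can be evaluated at arbitrary query points with
#' \code{\link{kdeEvaluate}}.
#'
#' @slot points numeric matrix, n observations by p dimensions.
#' @slot bandwidths numeric vector of length p, strictly positive.
#' @slot shrinkage positive scalar multiplying every bandwidth.
#'
#' @seealso \code{\link{kdeFit}}, \code{\link{normalReferenceBandwidth}}
#' @exportClass DensityModel
setClass("DensityModel",
    representation(points = "matrix", bandwidths = "numeric",
                   shrinkage = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@points) < 2)
            msg <- c(msg, "need at least 2 training points")
        if (length(object@bandwidths) != ncol(object@points))
            msg <- c(msg, "one bandwidth per dimension required")
        if (any(!is.finite(object@bandwidths)) || any(object@bandwidths <= 0))
            msg <- c(msg, "bandwidths must be strictly positive")
        if (length(object@shrinkage) != 1L || object@shrinkage <= 0)
            msg <- c(msg, "shrinkage must be a positive scalar")
        if (is.null(msg)) TRUE else msg
    })

#' Delaunay neighbour graph of a point set
#'
#' Adjacency structure used to connect high-density observations: the
#' Delaunay triangulation edges for p >= 2, the chain over the sort order
#' for p = 1, and the complete graph when n <= p + 1.
#'
#' @slot nVertices number of points.
#' @slot edges two-column integer matrix of unordered vertex pairs
#'   (1-based, no self loops).
#' @slot metadata list; records jitter applied to escape degenerate
#'   (collinear/coplanar) configurations, if any.
#'
#' @seealso \code{\link{buildNeighborGraph}}
#' @exportClass NeighborGraph
setClass("NeighborGraph",
    representation(nVertices = "integer", edges = "matrix",
                   metadata = "list"),
    validity = function(object) {
        e <- object@edges
        n <- object@nVertices
        msg <- NULL
        if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
        if (nrow(e) > 0) {
            if (any(e < 1L) || any(e > n))
                msg <- c(msg, "edge indices out of range")
            if (any(e[, 1] == e[, 2])) msg <- c(msg, "self loops not allowed")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Level-set scan record
#'
#' For a decreasing sequence of cut levels c the scan records how many
#' connected components the retained set \{i : f(x_i) > c\} splits into,
#' and how many of those reach the minimum core size.  Full per-level
#' partitions are kept only when requested (\code{keepTree = TRUE}), as
#' they are not needed to detect the number of clusters.
#'
#' @slot levels numeric, decreasing cut values (last one is 0).
#' @slot nComponents integer, components per level.
#' @slot nCores integer, components with >= minCoreSize members per level.
#' @slot componentsPerLevel list of partitions (possibly empty).
#' @slot minCoreSize integer.
#'
#' @exportClass ClusterTree
setClass("ClusterTree",
    representation(levels = "numeric", nComponents = "integer",
                   nCores = "integer", componentsPerLevel = "list",
                   minCoreSize = "integer"),
    validity = function(object) {
        msg <- NULL
        if (is.unsorted(rev(object@levels), strictly = FALSE))
            msg <- c(msg, "levels must be decreasing")
        if (length(object@nComponents) != length(object@levels) ||
            length(object@nCores) != length(object@levels))
            msg <- c(msg, "one component count per level required")
        if (is.null(msg)) TRUE else msg
    })

#' Result of density-based level-set clustering
#'
#' @slot nClusters detected number of clusters m.
#' @slot coreLabels integer labels in 1..m for cluster-core members,
#'   \code{NA} for observations left unallocated by the level-set stage.
#' @slot finalLabels integer labels in 1..m for every observation, after
#'   density-ratio allocation; extends \code{coreLabels}.
#' @slot densities fitted density at each observation.
#' @slot tree the \code{\linkS4class{ClusterTree}} scan record.
#' @slot metadata list (bandwidths, shrinkage, jitter record, ...).
#'
#' @seealso \code{\link{pdfCluster}}
#' @exportClass ClusteringResult
setClass("ClusteringResult",
    representation(nClusters = "integer", coreLabels = "integer",
                   finalLabels = "integer", densities = "numeric",
                   tree = "ClusterTree", metadata = "list"),
    validity = function(object) {
        msg <- NULL
        n <- length(object@finalLabels)
        if (length(object@coreLabels) != n || length(object@densities) != n)
            msg <- c(msg, "label and density vectors must share length")
        if (any(is.na(object@finalLabels)))
            msg <- c(msg, "every observation must receive a final label")
        core <- !is.na(object@coreLabels)
        if (any(object@finalLabels[core] != object@coreLabels[core]))
            msg <- c(msg, "final labels must extend core labels")
        if (is.null(msg)) TRUE else msg
    })

#' Parameters of the Gamma-Gamma expression simulator
#'
#' Observations are Gamma(shape \code{alpha}, scale \code{lambda}) with a
#' gene-specific random scale \code{lambda ~ Gamma(alpha0, scale nu)}.
#' Each gene is differentially expressed between the two sample groups
#' with probability \code{pDE} (an independent lambda per group);
#' otherwise a single lambda is shared.  All Gamma distributions use the
#' (shape, scale) parameterization.
#'
#' @exportClass GGParams
setClass("GGParams",
    representation(alpha = "numeric", alpha0 = "numeric", nu = "numeric",
                   pDE = "numeric", n = "integer", p = "integer"),
    validity = function(object) {
        msg <- NULL
        if (any(c(object@alpha, object@alpha0, object@nu) <= 0))
            msg <- c(msg, "alpha, alpha0 and nu must be positive")
        if (object@pDE < 0 || object@pDE > 1)
            msg <- c(msg, "pDE must lie in [0, 1]")
        if (object@n < 2 || object@p < 1)
            msg <- c(msg, "need n >= 2 samples and p >= 1 genes")
        if (is.null(msg)) TRUE else msg
    })

#' Parameters of the Normal-Uniform expression simulator
#'
#' Normally expressed values are Gaussian around a gene effect plus a
#' sample effect; up-/down-regulated values are Uniform tails of width
#' \code{kappa_j} above/below that level.  The regulation design fixes,
#' per cluster, which genes are up- and which are down-regulated.
#'
#' @exportClass NUParams
setClass("NUParams",
    representation(clusterSizes = "integer", p = "integer",
                   upGenes = "list", downGenes = "list",
                   muMean = "numeric", muSd = "numeric",
                   sigmaShape = "numeric", sigmaScale = "numeric",
                   alphaSd = "numeric", kappaRate = "numeric",
                   kappaShift = "numeric"),
    validity = function(object) {
        msg <- NULL
        k <- length(object@clusterSizes)
        if (k < 1 || any(object@clusterSizes < 1))
            msg <- c(msg, "cluster sizes must be positive")
        if (length(object@upGenes) != k || length(object@downGenes) != k)
            msg <- c(msg, "one up- and one down-gene set per cluster required")
        for (cl in seq_len(k)) {
            up <- object@upGenes[[cl]]; dn <- object@downGenes[[cl]]
            if (length(intersect(up, dn)))
                msg <- c(msg, sprintf(
                    "cluster %d: up- and down-regulated gene sets overlap", cl))
            if (length(c(up, dn)) && (max(c(up, dn)) > object@p ||
                                      min(c(up, dn)) < 1))
                msg <- c(msg, sprintf("cluster %d: gene index out of range", cl))
        }
        if (any(c(object@muSd, object@sigmaShape, object@sigmaScale,
                  object@alphaSd, object@kappaRate) <= 0))
            msg <- c(msg, "hyperprior parameters must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' Simulated expression dataset with ground truth
#'
#' @slot expr \code{SummarizedExperiment}, genes by samples.
#' @slot trueLabels integer cluster label per sample.
#' @slot relevantGenes logical mask: gene generated to differ across
#'   clusters (regulated in at least one but not all clusters, or
#'   differentially expressed).
#' @slot params parameter echo plus the seed used.
#'
#' @exportClass SimulatedDataset
setClass("SimulatedDataset",
    representation(expr = "ANY", trueLabels = "integer",
                   relevantGenes = "logical", params = "list"),
    validity = function(object) {
        msg <- NULL
        d <- dim(object@expr)
        if (length(object@trueLabels) != d[2])
            msg <- c(msg, "one true label per sample required")
        if (length(object@relevantGenes) != d[1])
            msg <- c(msg, "one relevance flag per gene required")
        if (is.null(msg)) TRUE else msg
    })

#' Result of the three-step clustering pipeline
#'
#' @slot selectedGenes character ids of genes passing the univariate
#'   density-based filter.
#' @slot selectedIndex integer indices of the same genes.
#' @slot scores n x p'' principal-component score matrix fed to the
#'   clustering stage.
#' @slot clustering \code{\linkS4class{ClusteringResult}} on the scores.
#' @slot config echo of nComponents, shrinkage, minCoreSize, jitterSeed.
#' @slot metadata list; \code{fallbackUnfiltered} flags the case where no
#'   gene passed the filter and the full matrix was used instead.
#'
#' @seealso \code{\link{clusterSamples}}
#' @exportClass PipelineResult
setClass("PipelineResult",
    representation(selectedGenes = "character", selectedIndex = "integer",
                   scores = "matrix", clustering = "ClusteringResult",
                   config = "list", metadata = "list"))

#' Replicated-simulation metrics report
#'
#' @slot model "gg" or "nu".
#' @slot perReplicate data.frame with one row per replicate: seed,
#'   detected m, ER, RG, SE, SP, nSelected, fallback flag.
#' @slot aggregates data.frame (metric, mean, se) with se = sd/sqrt(B).
#' @slot counts list: CC, and CC2/CC3 plus the m distribution for
#'   three-cluster designs; number of failed replicates.
#' @slot config parameter echo.
#'
#' @seealso \code{\link{replicateStudy}}
#' @exportClass MetricsReport
setClass("MetricsReport",
    representation(model = "character", perReplicate = "data.frame",
                   aggregates = "data.frame", counts = "list",
                   config = "list"))
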