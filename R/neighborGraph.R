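#' Build the Delaunay neighbour graph of a point set
#'
#' For p >= 2 the edges are exactly the edges of the Delaunay
#' triangulation (computed by an incremental Bowyer-Watson insertion with
#' a final empty-circumsphere validation pass); for p = 1 consecutive
#' order statistics are joined into a chain; for n <= p + 1 all pairs are
#' Delaunay neighbours and the complete graph is returned.
#'
#' Degenerate configurations (all points collinear in p = 2, coplanar in
#' p = 3, or near-cospherical subsets) have no unique triangulation; they
#' are escaped by adding a seeded uniform jitter of magnitude
#' \code{1e-8} times the per-coordinate range and retrying.  The jitter
#' seed and attempt count are recorded in the graph metadata.
#'
#' @param points numeric matrix (n x p), p <= 3 by default.
#' @param jitter allow the seeded jitter fallback (default TRUE); with
#'   \code{jitter = FALSE} a degenerate configuration is an error.
#' @param jitterSeed integer seed for the jitter stream.
#' @param pMax largest supported dimension; raising it past 3 is allowed
#'   but warns, as triangulation cost grows steeply with p.
#' @return a \code{\linkS4class{NeighborGraph}}.
#' @examples
#' g <- buildNeighborGraph(cbind(runif(20), runif(20)))
#' g
#' @export
buildNeighborGraph <- function(points, jitter = TRUE, jitterSeed = 1L,
                               pMax = 3L) {
    points <- .asPoints(points)
    n <- nrow(points); p <- ncol(points)
    if (n < 2) stop("need at least 2 points")
    if (pMax > 3L)
        warning("triangulation in p > 3 dimensions can be very slow")
    if (p > pMax)
        stop("p = ", p, " exceeds pMax = ", pMax,
             "; raise pMax explicitly to override")

    if (p == 1L) {
        o <- order(points[, 1])
        edges <- cbind(o[-n], o[-1])
        return(new("NeighborGraph", nVertices = n,
                   edges = matrix(as.integer(edges), ncol = 2),
                   metadata = list(type = "chain")))
    }
    if (n <= p + 1L) {
        idx <- utils::combn(n, 2)
        return(new("NeighborGraph", nVertices = n,
                   edges = matrix(as.integer(t(idx)), ncol = 2),
                   metadata = list(type = "complete")))
    }

    res <- .delaunayEdges(points)
    meta <- list(type = "delaunay", jittered = FALSE)
    attempt <- 0L
    while (res$degenerate && jitter && attempt < 5L) {
        attempt <- attempt + 1L
        rng <- apply(points, 2, function(v) diff(range(v)))
        rng[rng <= 0] <- 1
        jit <- .withSeed(.deriveSeed(jitterSeed, attempt), {
            matrix(runif(n * p, -1, 1), n, p)
        })
        mag <- 1e-8 * 10^(attempt - 1) * rng  # escalate on retries
        res <- .delaunayEdges(points + sweep(jit, 2, mag, "*"))
        meta <- list(type = "delaunay", jittered = TRUE,
                     jitterSeed = jitterSeed, jitterAttempts = attempt,
                     jitterMagnitude = mag)
    }
    if (res$degenerate)
        stop("degenerate point configuration: no valid Delaunay ",
             "triangulation", if (!jitter) " (jitter disabled)")
    new("NeighborGraph", nVertices = n,
        edges = matrix(as.integer(res$edges), ncol = 2), metadata = meta)
}

#' @rdname accessors
#' @export
setMethod("graphEdges", "NeighborGraph", function(x) x@edges)

setMethod("show", "NeighborGraph", function(object) {
    cat("NeighborGraph:", object@nVertices, "vertices,",
        nrow(object@edges), "edges (", object@metadata$type, ")\n")
    if (isTRUE(object@metadata$jittered))
        cat("  degenerate input escaped by seeded jitter (seed ",
            object@metadata$jitterSeed, ")\n", sep = "")
})

# igraph view of a NeighborGraph, used for component extraction.
.asIgraph <- function(graph) {
    igraph::make_graph(edges = as.vector(t(graph@edges)),
                       n = graph@nVertices, directed = FALSE)
}
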