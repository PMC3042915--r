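#' @useDynLib kdeCluster, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats prcomp rnorm runif rexp rgamma sd dnorm quantile
#' @importFrom utils read.table write.table head
NULL

# Coerce matrix / data.frame / SummarizedExperiment input to a plain
# genes x samples numeric matrix with dimnames.
.asExprMatrix <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, 1)
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression input must be a numeric matrix, data.frame or ",
             "SummarizedExperiment")
    if (anyNA(x)) stop("expression matrix contains missing values")
    if (is.null(rownames(x)))
        rownames(x) <- paste0("gene", seq_len(nrow(x)))
    if (is.null(colnames(x)))
        colnames(x) <- paste0("sample", seq_len(ncol(x)))
    if (anyDuplicated(rownames(x)))
        stop("duplicate gene id: ",
             rownames(x)[anyDuplicated(rownames(x))])
    if (anyDuplicated(colnames(x)))
        stop("duplicate sample id: ",
             colnames(x)[anyDuplicated(colnames(x))])
    x
}

# Wrap a genes x samples matrix into a SummarizedExperiment.
.asSE <- function(m) {
    SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
}

# Counter-based per-replicate seed derivation: independent, individually
# reproducible streams that stay inside the 32-bit integer range.
.deriveSeed <- function(seed, k) {
    s <- (as.double(seed) + 1664525 * as.double(k)) %% 2147483646
    as.integer(s) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (NULL = use the current stream); the caller's state is restored.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

# Points argument: accept a numeric vector (univariate) or matrix.
.asPoints <- function(points) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
    points <- as.matrix(points)
    storage.mode(points) <- "double"
    if (anyNA(points) || any(!is.finite(points)))
        stop("points must be finite and free of missing values")
    points
}
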