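#' Read an expression matrix from delimited text
#'
#' Expects a rectangular table whose first column holds gene identifiers
#' and whose header row holds sample identifiers (use
#' \code{orientation = "samples-rows"} for the transposed dialect).  The
#' delimiter is auto-detected from the header line (tab versus comma)
#' unless given.
#'
#' @param path file to read.
#' @param delimiter \code{"auto"} (default), \code{"\t"} or \code{","}.
#' @param orientation \code{"genes-rows"} (default) or
#'   \code{"samples-rows"}.
#' @return a \code{SummarizedExperiment}, genes in rows.
#' @export
readExpression <- function(path, delimiter = "auto",
                           orientation = c("genes-rows", "samples-rows")) {
    orientation <- match.arg(orientation)
    if (delimiter == "auto") {
        header <- readLines(path, n = 1L)
        delimiter <- if (lengths(regmatches(header,
                gregexpr("\t", header))) >=
            lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
    }
    df <- read.table(path, sep = delimiter, header = TRUE,
                     check.names = FALSE, stringsAsFactors = FALSE,
                     comment.char = "")
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate id in first column: ", ids[anyDuplicated(ids)])
    body <- df[, -1, drop = FALSE]
    for (j in seq_along(body)) {
        if (!is.numeric(body[[j]])) {
            bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))) &
                         !is.na(body[[j]]))[1]
            stop("non-numeric value at row ", bad, ", column ",
                 colnames(body)[j])
        }
    }
    m <- as.matrix(body)
    rownames(m) <- ids
    if (orientation == "samples-rows") m <- t(m)
    .asSE(.asExprMatrix(m))
}

#' Write an expression matrix as delimited text
#'
#' Writes genes in rows, a header of sample ids and a leading gene-id
#' column, at full double precision so that a write/read round trip is
#' bit-exact.
#'
#' @param expr matrix, data.frame or SummarizedExperiment.
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @return the path, invisibly.
#' @export
writeExpression <- function(expr, path, delimiter = "\t") {
    m <- .asExprMatrix(expr)
    body <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
    lines <- c(paste(c("gene_id", colnames(m)), collapse = delimiter),
               paste(rownames(m), apply(body, 1, paste,
                                        collapse = delimiter),
                     sep = delimiter))
    writeLines(lines, path)
    invisible(path)
}

#' Quantile normalization across samples
#'
#' Forces every sample column to share one common distribution: each
#' value is replaced by the cross-sample mean of the order statistics at
#' its rank, ties receiving the mean of the tied reference values.
#' After normalization all columns have identical sorted values, and the
#' operation is idempotent.
#'
#' @param expr genes x samples input.
#' @return object of the input kind with normalized values.
#' @examples
#' quantileNormalize(cbind(a = c(1, 3), b = c(2, 4)))
#' @export
quantileNormalize <- function(expr) {
    m <- .asExprMatrix(expr)
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    if (is(expr, "SummarizedExperiment")) .asSE(out) else out
}

#' Elementwise log transform
#'
#' @param expr genes x samples input; all values must be positive.
#' @param base logarithm base (2, 10 or \code{exp(1)}).
#' @return object of the input kind with log-transformed values.
#' @export
logTransform <- function(expr, base = 2) {
    m <- .asExprMatrix(expr)
    if (any(m <= 0)) {
        bad <- which(m <= 0, arr.ind = TRUE)
        show <- head(bad, 5)
        stop("non-positive values cannot be log-transformed: ",
             paste(sprintf("%s/%s", rownames(m)[show[, 1]],
                           colnames(m)[show[, 2]]), collapse = ", "),
             if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5))
    }
    out <- log(m, base = base)
    if (is(expr, "SummarizedExperiment")) .asSE(out) else out
}

#' Raw-intensity preprocessing: threshold, filter, log10
#'
#' The standard recipe for raw oligonucleotide-array intensities:
#' (a) thresholding, clamping every value to
#' [\code{floor}, \code{ceiling}]; (b) filtering, retaining only the
#' genes with max/min > \code{minRatio} AND max - min > \code{minRange}
#' computed after clamping (i.e., excluding genes with max/min <= 5 or
#' max - min <= 500 at the defaults); (c) log transformation in base
#' \code{logBase}.
#'
#' @param expr genes x samples raw-intensity input.
#' @param floor,ceiling clamping bounds.
#' @param minRatio,minRange retention thresholds (strict inequalities).
#' @param logBase base of the final log transform (default 10).
#' @return object of the input kind with fewer genes.
#' @export
golubPreprocess <- function(expr, floor = 100, ceiling = 16000,
                            minRatio = 5, minRange = 500, logBase = 10) {
    if (floor >= ceiling) stop("floor must be below ceiling")
    m <- .asExprMatrix(expr)
    m <- pmin(pmax(m, floor), ceiling)
    mx <- apply(m, 1, max)
    mn <- apply(m, 1, min)
    keep <- (mx / mn > minRatio) & (mx - mn > minRange)
    out <- log(m[keep, , drop = FALSE], base = logBase)
    if (is(expr, "SummarizedExperiment")) .asSE(out) else out
}

#' Single-channel preprocessing: log then quantile normalization
#'
#' The usual recipe for single-channel intensity matrices before
#' clustering: log transform (base 2 by convention) followed by quantile
#' normalization; the order is configurable.
#'
#' @param expr genes x samples raw-intensity input.
#' @param logBase log base (default 2).
#' @param normalizeFirst quantile-normalize before taking logs.
#' @return object of the input kind.
#' @export
colonPreprocess <- function(expr, logBase = 2, normalizeFirst = FALSE) {
    if (normalizeFirst)
        logTransform(quantileNormalize(expr), base = logBase)
    else
        quantileNormalize(logTransform(expr, base = logBase))
}

#' Write a density evaluation grid as two-column delimited text
#'
#' Evaluates a univariate fitted density on a regular grid spanning the
#' data plus six bandwidths on each side and writes (x, density) rows,
#' for diagnostics.
#'
#' @param model a univariate \code{\linkS4class{DensityModel}}.
#' @param path output file.
#' @param gridSize number of grid points.
#' @return the grid as a data.frame, invisibly.
#' @export
writeDensityGrid <- function(model, path, gridSize = 512L) {
    stopifnot(is(model, "DensityModel"), ncol(model@points) == 1L)
    h <- model@bandwidths
    x <- seq(min(model@points) - 6 * h, max(model@points) + 6 * h,
             length.out = gridSize)
    df <- data.frame(x = x, density = kdeEvaluate(model, x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Generate small deterministic fixture datasets
#'
#' Writes the small synthetic matrices used throughout the test suite:
#' \code{"bimodal-gene"} (one clearly bimodal gene among unimodal ones),
#' \code{"noise-matrix"} (pure N(0,1) noise, no structure) and
#' \code{"nu-small"} (a reduced Normal-Uniform dataset with truth labels
#' and relevance mask).  Regeneration with the same seed is
#' file-identical.
#'
#' @param kind fixture flavour.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named character vector of written paths, invisibly.
#' @export
makeFixture <- function(kind = c("bimodal-gene", "noise-matrix",
                                 "nu-small"),
                        dir, seed = 1L) {
    kind <- match.arg(kind)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(expression = file.path(dir,
                                      paste0(kind, "-expression.tsv")))
    if (kind == "bimodal-gene") {
        m <- .withSeed(seed, {
            rbind(bimodal = c(rnorm(30, 0), rnorm(30, 10)),
                  flat1 = rnorm(60), flat2 = rnorm(60))
        })
        colnames(m) <- paste0("sample", seq_len(ncol(m)))
        writeExpression(m, paths[["expression"]])
    } else if (kind == "noise-matrix") {
        m <- .withSeed(seed, matrix(rnorm(50 * 40), 50, 40))
        writeExpression(m, paths[["expression"]])
    } else {
        params <- nuParams(clusterSizes = c(8L, 8L, 4L), p = 50L,
                           upGenes = list(1:8, integer(0), integer(0)),
                           downGenes = list(9:12, 9:12, integer(0)))
        sim <- simulateNU(params, seed = seed)
        writeExpression(exprValues(sim), paths[["expression"]])
        paths[["labels"]] <- file.path(dir, paste0(kind, "-labels.tsv"))
        write.table(data.frame(sample_id = colnames(exprValues(sim)),
                               label = trueLabels(sim)),
                    paths[["labels"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
        paths[["mask"]] <- file.path(dir, paste0(kind, "-mask.tsv"))
        write.table(data.frame(gene_id = rownames(exprValues(sim)),
                               relevant = relevantGenes(sim)),
                    paths[["mask"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(paths)
}
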