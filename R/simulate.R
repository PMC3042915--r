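#' Gamma-Gamma simulator parameters
#'
#' Constructor for \code{\linkS4class{GGParams}}.  Every sample is
#' assigned to one of two groups with equal probability; each gene is
#' differentially expressed (DE) with probability \code{pDE}.  An
#' equally-expressed gene draws a single scale
#' \eqn{\lambda \sim \Gamma(\alpha_0, \mathrm{scale}\ \nu)} shared by all
#' samples; a DE gene draws an independent scale per group.
#' Observations are \eqn{x \sim \Gamma(\alpha, \mathrm{scale}\ \lambda)}.
#' All Gamma distributions are parameterized by (shape, scale).
#'
#' The default numeric values are placeholders in the range customary
#' for Gamma-Gamma expression models (shape \eqn{\alpha = 10},
#' \eqn{\alpha_0 = 0.9}, \eqn{\nu = 0.5}); they produce two
#' well-separated groups and are fully configurable.
#'
#' @param alpha Gamma shape of the observations.
#' @param alpha0,nu Gamma shape and scale hyperparameters of the
#'   gene-specific scale lambda.
#' @param pDE probability that a gene is differentially expressed.
#' @param n,p numbers of samples and genes.
#' @return a \code{\linkS4class{GGParams}} object.
#' @export
ggParams <- function(alpha = 10, alpha0 = 0.9, nu = 0.5, pDE = 0.05,
                     n = 100L, p = 2000L) {
    new("GGParams", alpha = alpha, alpha0 = alpha0, nu = nu, pDE = pDE,
        n = as.integer(n), p = as.integer(p))
}

#' Normal-Uniform simulator parameters
#'
#' Constructor for \code{\linkS4class{NUParams}}.  The measured
#' intensity of gene j in sample i depends on its regulation state
#' \eqn{e_{ji} \in \{-1, 0, 1\}}:
#' \deqn{f_{-1,j} = U(\alpha_i + \mu_j - \kappa_j,\ \alpha_i + \mu_j),
#'   \quad f_{0,j} = N(\alpha_i + \mu_j,\ \sigma_j), \quad
#'   f_{1,j} = U(\alpha_i + \mu_j,\ \alpha_i + \mu_j + \kappa_j),}
#' with gene effect \eqn{\mu_j \sim N(7.5, 1.5)} (1.5 read as a standard
#' deviation; set \code{muSdIsVariance = TRUE} for the variance reading),
#' precision \eqn{\sigma_j^{-1} \sim \Gamma(2, \mathrm{scale}\ 1)},
#' sample effect \eqn{\alpha_i \sim N(0, 1)} and tail width
#' \eqn{\kappa_j \sim \mathrm{Exp}(1) + 7\sigma_j}.
#'
#' The default design is the three-cluster layout mimicking two disease
#' subtypes versus a control: cluster 1 (40 samples) has genes 1-150
#' up-regulated and genes 151-200 down-regulated; cluster 2 (40 samples)
#' has the same 50 genes down-regulated (making clusters 2 and 3 closer
#' to each other than to cluster 1); cluster 3 (20 samples) has neither.
#' The 200 regulated genes are the relevant genes.
#'
#' @param clusterSizes integer sample counts per cluster.
#' @param p number of genes.
#' @param upGenes,downGenes per-cluster lists of up-/down-regulated gene
#'   indices (disjoint within each cluster).
#' @param muMean,muSd gene-effect hyperprior N(muMean, muSd).
#' @param muSdIsVariance interpret \code{muSd} as a variance.
#' @param sigmaShape,sigmaScale hyperprior of the precision 1/sigma_j,
#'   Gamma(shape, scale).
#' @param alphaSd standard deviation of the sample effect.
#' @param kappaRate rate of the Exponential part of kappa_j.
#' @param kappaShift multiplier of sigma_j added to kappa_j (default 7).
#' @return a \code{\linkS4class{NUParams}} object.
#' @export
nuParams <- function(clusterSizes = c(40L, 40L, 20L), p = 1000L,
                     upGenes = list(1:150, integer(0), integer(0)),
                     downGenes = list(151:200, 151:200, integer(0)),
                     muMean = 7.5, muSd = 1.5, muSdIsVariance = FALSE,
                     sigmaShape = 2, sigmaScale = 1, alphaSd = 1,
                     kappaRate = 1, kappaShift = 7) {
    if (muSdIsVariance) muSd <- sqrt(muSd)
    obj <- new("NUParams", clusterSizes = as.integer(clusterSizes),
               p = as.integer(p),
               upGenes = lapply(upGenes, as.integer),
               downGenes = lapply(downGenes, as.integer),
               muMean = muMean, muSd = muSd, sigmaShape = sigmaShape,
               sigmaScale = sigmaScale, alphaSd = alphaSd,
               kappaRate = kappaRate, kappaShift = kappaShift)
    obj
}

# per-gene, per-cluster regulation states (p x k matrix in {-1, 0, 1})
.nuStates <- function(params) {
    k <- length(params@clusterSizes)
    st <- matrix(0L, params@p, k)
    for (cl in seq_len(k)) {
        st[params@upGenes[[cl]], cl] <- 1L
        st[params@downGenes[[cl]], cl] <- -1L
    }
    st
}

#' Simulate a Gamma-Gamma expression dataset
#'
#' @param params a \code{\linkS4class{GGParams}} object.
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-identically and the caller's RNG state is left untouched.
#' @return a \code{\linkS4class{SimulatedDataset}}; the relevant-gene
#'   mask flags the differentially expressed genes.
#' @examples
#' sim <- simulateGG(ggParams(n = 20, p = 50), seed = 7)
#' sum(relevantGenes(sim))
#' @export
simulateGG <- function(params, seed = NULL) {
    stopifnot(is(params, "GGParams"))
    n <- params@n; p <- params@p
    .withSeed(seed, {
        groups <- sample.int(2L, n, replace = TRUE)
        de <- runif(p) < params@pDE
        lambda1 <- rgamma(p, shape = params@alpha0, scale = params@nu)
        lambda2 <- ifelse(de,
                          rgamma(p, shape = params@alpha0,
                                 scale = params@nu),
                          lambda1)
        scaleMat <- cbind(lambda1, lambda2)[, groups, drop = FALSE]
        x <- matrix(rgamma(p * n, shape = params@alpha, scale = scaleMat),
                    p, n)
        dimnames(x) <- list(paste0("gene", seq_len(p)),
                            paste0("sample", seq_len(n)))
        new("SimulatedDataset", expr = .asSE(x),
            trueLabels = as.integer(groups), relevantGenes = de,
            params = list(model = "gg", alpha = params@alpha,
                          alpha0 = params@alpha0, nu = params@nu,
                          pDE = params@pDE, n = n, p = p, seed = seed,
                          lambda = cbind(lambda1, lambda2)))
    })
}

#' Simulate a Normal-Uniform expression dataset
#'
#' Hierarchical draw: first the gene effects, precisions, sample effects
#' and tail widths from their hyperpriors, then every measured intensity
#' from the Normal or Uniform distribution dictated by the cluster
#' design (see \code{\link{nuParams}}).
#'
#' @param params a \code{\linkS4class{NUParams}} object.
#' @param seed integer seed; same seed, bit-identical dataset.
#' @return a \code{\linkS4class{SimulatedDataset}}; relevant genes are
#'   those whose regulation state differs between clusters.
#' @examples
#' sim <- simulateNU(nuParams(), seed = 1)
#' table(trueLabels(sim))
#' @export
simulateNU <- function(params, seed = NULL) {
    stopifnot(is(params, "NUParams"))
    sizes <- params@clusterSizes
    n <- sum(sizes); p <- params@p; k <- length(sizes)
    states <- .nuStates(params)
    relevant <- apply(states, 1, function(r) length(unique(r)) > 1L)
    labels <- rep(seq_len(k), sizes)
    E <- states[, labels, drop = FALSE]          # p x n regulation matrix
    .withSeed(seed, {
        mu <- rnorm(p, params@muMean, params@muSd)
        sigma <- 1 / rgamma(p, shape = params@sigmaShape,
                            scale = params@sigmaScale)
        alpha <- rnorm(n, 0, params@alphaSd)
        kappa <- rexp(p, rate = params@kappaRate) +
            params@kappaShift * sigma
        M <- outer(mu, rep(1, n)) +
            matrix(alpha, p, n, byrow = TRUE)    # alpha_i + mu_j
        x <- M + sigma * matrix(rnorm(p * n), p, n)
        tail <- kappa * matrix(runif(p * n), p, n)
        up <- E == 1L; dn <- E == -1L
        x[up] <- M[up] + tail[up]
        x[dn] <- M[dn] - tail[dn]
        dimnames(x) <- list(paste0("gene", seq_len(p)),
                            paste0("sample", seq_len(n)))
        new("SimulatedDataset", expr = .asSE(x),
            trueLabels = as.integer(labels), relevantGenes = relevant,
            params = list(model = "nu", clusterSizes = sizes, p = p,
                          states = states, seed = seed, mu = mu,
                          sigma = sigma, alpha = alpha, kappa = kappa))
    })
}

#' @rdname accessors
#' @export
setMethod("trueLabels", "SimulatedDataset", function(x) x@trueLabels)

#' @rdname accessors
#' @export
setMethod("relevantGenes", "SimulatedDataset", function(x) x@relevantGenes)

#' @rdname accessors
#' @export
setMethod("exprValues", "SimulatedDataset",
          function(x) SummarizedExperiment::assay(x@expr, 1))

#' @rdname accessors
#' @export
setMethod("exprValues", "ANY", function(x) .asExprMatrix(x))

setMethod("show", "SimulatedDataset", function(object) {
    d <- dim(object@expr)
    cat("SimulatedDataset (", object@params$model, " model): ",
        d[1], " genes x ", d[2], " samples, ",
        length(unique(object@trueLabels)), " clusters, ",
        sum(object@relevantGenes), " relevant genes\n", sep = "")
})

#' Replicated simulation study of the clustering pipeline
#'
#' Repeatedly simulates a dataset, runs the three-step pipeline and
#' scores it against the ground truth; replicate b uses a seed derived
#' from the master seed by a counter scheme, so replicates are
#' independent and individually reproducible.  Per-replicate failures
#' are recorded and excluded from the aggregates, which report the mean
#' and Monte-Carlo standard error (sd/sqrt(B)) of each metric together
#' with the cluster-count frequencies.
#'
#' @param model \code{"nu"} or \code{"gg"}.
#' @param B number of replicates.
#' @param params simulator parameters (\code{\link{nuParams}} or
#'   \code{\link{ggParams}}); defaults to the model's standard design.
#' @param nComponents,shrinkage,minCoreSize pipeline configuration.
#' @param seed master seed.
#' @param verbose print a progress line every 10 replicates.
#' @return a \code{\linkS4class{MetricsReport}}.
#' @examples
#' rep <- replicateStudy("nu", B = 2,
#'     params = nuParams(clusterSizes = c(10, 10, 5), p = 60,
#'                       upGenes = list(1:10, integer(0), integer(0)),
#'                       downGenes = list(11:15, 11:15, integer(0))),
#'     seed = 1)
#' metricAggregates(rep)
#' @export
replicateStudy <- function(model = c("nu", "gg"), B, params = NULL,
                           nComponents = 3L, shrinkage = 0.75,
                           minCoreSize = 2L, seed = 1L,
                           verbose = FALSE) {
    model <- match.arg(model)
    stopifnot(B >= 1)
    if (is.null(params))
        params <- if (model == "nu") nuParams() else ggParams()
    trueM <- if (model == "nu") length(params@clusterSizes) else 2L
    rows <- vector("list", B)
    nFailed <- 0L
    for (b in seq_len(B)) {
        sb <- .deriveSeed(seed, b)
        row <- tryCatch({
            sim <- if (model == "nu") simulateNU(params, seed = sb)
                   else simulateGG(params, seed = sb)
            m <- exprValues(sim)
            res <- withCallingHandlers(
                clusterSamples(m, nComponents = nComponents,
                               shrinkage = shrinkage,
                               minCoreSize = minCoreSize,
                               jitterSeed = sb),
                warning = function(w) invokeRestart("muffleWarning"))
            truth <- trueLabels(sim)
            pred <- clusterLabels(res)
            selMask <- logical(nrow(m))
            selMask[res@selectedIndex] <- TRUE
            sesp <- if (length(unique(truth)) == 2L)
                sensitivitySpecificity(pred, truth) else c(SE = NA, SP = NA)
            data.frame(seed = sb, m = nClusters(res),
                       ER = errorRate(pred, truth),
                       RG = geneSelectionError(selMask,
                                               relevantGenes(sim)),
                       SE = sesp[["SE"]], SP = sesp[["SP"]],
                       nSelected = length(res@selectedIndex),
                       fallback = res@metadata$fallbackUnfiltered)
        }, error = function(e) NULL)
        if (is.null(row)) nFailed <- nFailed + 1L else rows[[b]] <- row
        if (verbose && b %% 10 == 0)
            message("replicate ", b, "/", B)
    }
    per <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    agg <- do.call(rbind, lapply(c("ER", "RG", "SE", "SP"), function(met) {
        v <- per[[met]]
        v <- v[!is.na(v)]
        data.frame(metric = met,
                   mean = if (length(v)) mean(v) else NA_real_,
                   se = if (length(v) > 1) sd(v) / sqrt(length(v))
                        else NA_real_)
    }))
    cc <- clusterCountFrequencies(per$m, trueM)
    cc$nFailed <- nFailed
    cc$nFallback <- sum(per$fallback)
    new("MetricsReport", model = model, perReplicate = per,
        aggregates = agg, counts = cc,
        config = list(B = B, seed = seed, nComponents = nComponents,
                      shrinkage = shrinkage, minCoreSize = minCoreSize,
                      trueM = trueM))
}

#' @rdname accessors
#' @export
setMethod("metricAggregates", "MetricsReport", function(x) x@aggregates)

setMethod("show", "MetricsReport", function(object) {
    cat("MetricsReport (", object@model, " model, B = ",
        object@config$B, "):\n", sep = "")
    a <- object@aggregates
    for (i in seq_len(nrow(a)))
        if (!is.na(a$mean[i]))
            cat(sprintf("  %-3s mean %.4f  se %.4f\n", a$metric[i],
                        a$mean[i], a$se[i]))
    cc <- object@counts
    cat("  CC", sprintf("%.2f", cc$CC))
    if (!is.null(cc$CC2)) cat("  CC2", sprintf("%.2f", cc$CC2))
    if (!is.null(cc$CC3)) cat("  CC3", sprintf("%.2f", cc$CC3))
    cat("\n")
    if (cc$nFailed > 0) cat("  failed replicates:", cc$nFailed, "\n")
})

#' Export a metrics report as delimited text
#'
#' Writes the aggregate table (metric, mean, se) followed by the
#' cluster-count frequencies, mirroring the usual simulation-table
#' layout.
#'
#' @param report a \code{\linkS4class{MetricsReport}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
    a <- report@aggregates
    cc <- report@counts
    extra <- data.frame(metric = c("CC",
                                   if (!is.null(cc$CC2)) "CC2",
                                   if (!is.null(cc$CC3)) "CC3"),
                        mean = c(cc$CC, cc$CC2, cc$CC3),
                        se = NA_real_)
    write.table(rbind(a, extra), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
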