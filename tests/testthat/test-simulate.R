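test_that("the default three-cluster design marks 200 relevant genes", {
    sim <- simulateNU(nuParams(), seed = 1)
    expect_identical(sum(relevantGenes(sim)), 200L)
    expect_identical(which(relevantGenes(sim)), 1:200)
    expect_identical(as.integer(table(trueLabels(sim))), c(40L, 40L, 20L))
    expect_identical(dim(exprValues(sim)), c(1000L, 100L))
})

test_that("regulated intensities respect the Uniform support bounds", {
    p <- nuParams()
    sim <- simulateNU(p, seed = 2)
    x <- exprValues(sim)
    pe <- sim@params
    M <- outer(pe$mu, rep(1, ncol(x))) +
        matrix(pe$alpha, nrow(x), ncol(x), byrow = TRUE)
    E <- kdeCluster:::.nuStates(p)[, trueLabels(sim)]
    up <- E == 1L; dn <- E == -1L
    K <- matrix(pe$kappa, nrow(x), ncol(x))
    expect_true(all(x[up] >= M[up]))
    expect_true(all(x[up] <= M[up] + K[up]))
    expect_true(all(x[dn] <= M[dn]))
    expect_true(all(x[dn] >= M[dn] - K[dn]))
    # normally expressed entries standardize to N(0, 1)
    z <- (x - M)[E == 0L] / matrix(pe$sigma, nrow(x), ncol(x))[E == 0L]
    expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
    expect_equal(sd(z), 1, tolerance = 0.02)
})

test_that("overlapping regulation sets are rejected", {
    expect_error(nuParams(upGenes = list(1:10, integer(0), integer(0)),
                          downGenes = list(5:15, integer(0), integer(0))),
                 "overlap")
    expect_error(nuParams(p = 20L), "out of range")
})

test_that("simulators are seed-reproducible and RNG-clean", {
    s1 <- simulateNU(nuSmallParams(), seed = 5)
    s2 <- simulateNU(nuSmallParams(), seed = 5)
    expect_identical(exprValues(s1), exprValues(s2))
    set.seed(123); before <- runif(3)
    set.seed(123); invisible(simulateGG(ggParams(n = 10, p = 20), seed = 1))
    expect_identical(runif(3), before)
    g1 <- simulateGG(ggParams(n = 10, p = 20), seed = 7)
    g2 <- simulateGG(ggParams(n = 10, p = 20), seed = 7)
    expect_identical(exprValues(g1), exprValues(g2))
})

test_that("the Gamma-Gamma hierarchy has the documented moments", {
    # no differential expression: no relevant genes
    sim0 <- simulateGG(ggParams(pDE = 0, n = 20, p = 50), seed = 1)
    expect_identical(sum(relevantGenes(sim0)), 0L)
    # DE count is Binomial(p, pDE)
    counts <- vapply(1:10, function(s)
        sum(relevantGenes(simulateGG(ggParams(), seed = s))), 1L)
    expect_true(all(counts >= 60 & counts <= 140))   # 100 +- >3 SD band
    # equally-expressed gene mean is alpha * lambda
    simBig <- simulateGG(ggParams(n = 10000L, p = 3L, pDE = 0), seed = 2)
    x <- exprValues(simBig)
    lam <- simBig@params$lambda[, 1]
    for (g in 1:3) {
        se <- sd(x[g, ]) / sqrt(ncol(x))
        expect_lt(abs(mean(x[g, ]) - 10 * lam[g]), 3 * se)
    }
})

test_that("gene marginals match their conditional Gamma distribution", {
    sim <- simulateGG(ggParams(n = 200L, p = 200L, pDE = 0), seed = 4)
    x <- exprValues(sim)
    lam <- sim@params$lambda[, 1]
    pvals <- vapply(seq_len(nrow(x)), function(g)
        suppressWarnings(
            ks.test(x[g, ], pgamma, shape = 10, scale = lam[g]))$p.value,
        1)
    expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("replicated studies aggregate reproducibly", {
    p <- nuSmallParams()
    r1 <- replicateStudy("nu", B = 2, params = p, seed = 3)
    r2 <- replicateStudy("nu", B = 2, params = p, seed = 3)
    expect_identical(r1@perReplicate, r2@perReplicate)
    expect_identical(metricAggregates(r1), metricAggregates(r2))
    expect_identical(r1@counts$nFailed, 0L)
    # reported standard errors are sd/sqrt(B) of the replicate values
    r3 <- replicateStudy("nu", B = 4, params = p, seed = 6)
    a <- metricAggregates(r3)
    er <- r3@perReplicate$ER
    expect_equal(a$se[a$metric == "ER"], sd(er) / sqrt(length(er)))
    expect_equal(a$mean[a$metric == "ER"], mean(er))
    f <- tempfile(fileext = ".tsv")
    writeMetricsReport(r3, f)
    tab <- read.table(f, header = TRUE, sep = "\t")
    expect_true(all(c("ER", "RG", "CC", "CC2", "CC3") %in% tab$metric))
})
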