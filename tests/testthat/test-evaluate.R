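test_that("error rate maps clusters to classes by majority overlap", {
    expect_identical(errorRate(c(2, 2, 1, 1), c(1, 1, 2, 2)), 0)
    expect_identical(errorRate(c(1, 1, 1, 2), c(1, 1, 2, 2)), 0.25)
    # many-to-one: two predicted clusters jointly covering one class,
    # the benchmark colon-tissue confusion (8 of 62 misclassified)
    truth <- rep(c("tumor", "normal"), c(40, 22))
    pred <- c(rep(1, 35), rep(2, 3), rep(3, 2),      # tumor samples
              rep(1, 3), rep(2, 12), rep(3, 7))      # normal samples
    expect_equal(errorRate(pred, truth), 8 / 62)
})

test_that("metrics are invariant under predicted-label permutation", {
    set.seed(1)
    for (rep in 1:20) {
        n <- sample(10:40, 1)
        truth <- sample(1:2, n, replace = TRUE)
        pred <- sample(1:4, n, replace = TRUE)
        relab <- sample(4)[pred]
        expect_identical(errorRate(pred, truth), errorRate(relab, truth))
        if (length(unique(truth)) == 2)
            expect_identical(sensitivitySpecificity(pred, truth),
                             sensitivitySpecificity(relab, truth))
    }
    set.seed(2)
    sel <- runif(50) < 0.3; rel <- runif(50) < 0.2
    expect_identical(geneSelectionError(sel, rel),
                     geneSelectionError(sel, rel))
})

test_that("error rate is zero iff a zero-mismatch mapping exists", {
    expect_identical(errorRate(c(1, 1, 2, 2, 3, 3),
                               c(2, 2, 3, 3, 1, 1)), 0)
    expect_gt(errorRate(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0)
})

test_that("sensitivity and specificity follow the mapped confusion", {
    truth <- rep(1:2, each = 10)
    expect_identical(sensitivitySpecificity(truth, truth),
                     c(SE = 1, SP = 1))
    # everything in one cluster: maps to the majority class
    one <- rep(1, 30)
    truth2 <- rep(1:2, c(20, 10))
    expect_identical(sensitivitySpecificity(one, truth2),
                     c(SE = 1, SP = 0))
    expect_error(sensitivitySpecificity(one, rep(1:3, 10)),
                 "exactly two")
})

test_that("one-to-one mapping can disagree with majority mapping", {
    # cluster 1 overlaps class 1 most, but the injective optimum
    # assigns cluster 2 there
    pred <- c(1, 1, 1, 1, 2, 2, 2, 1, 1)
    true <- c(1, 1, 1, 2, 1, 1, 1, 2, 2)
    mj <- mapClustersToClasses(pred, true, "majority")
    oo <- mapClustersToClasses(pred, true, "one-to-one")
    expect_identical(unname(mj), c("1", "1"))
    expect_identical(sort(unname(oo)), c("1", "2"))
    expect_lte(errorRate(pred, true, "one-to-one"), 1)
})

test_that("gene-selection error decomposes as (FP + FN) / p", {
    expect_identical(geneSelectionError(c(TRUE, FALSE), c(TRUE, FALSE)), 0)
    sel <- logical(10); sel[c(1, 3)] <- TRUE
    rel <- logical(10); rel[c(1, 2)] <- TRUE
    expect_identical(geneSelectionError(sel, rel), 0.2)
    expect_identical(geneSelectionError(sel, rel, denominator = "relevant"),
                     1)
    expect_error(geneSelectionError(sel, rel[1:5]), "equal length")
    # cross-check against confusion-matrix construction
    set.seed(3)
    s <- runif(200) < 0.4; r <- runif(200) < 0.1
    cm <- table(factor(s, c(FALSE, TRUE)), factor(r, c(FALSE, TRUE)))
    expect_identical(geneSelectionError(s, r),
                     (cm["TRUE", "FALSE"] + cm["FALSE", "TRUE"]) / 200)
})

test_that("cluster-count frequencies summarize the m distribution", {
    cc <- clusterCountFrequencies(c(2, 3, 3, 2), 3)
    expect_identical(cc$CC, 0.5)
    expect_identical(cc$CC2, 0.5)
    expect_identical(cc$CC3, 0.5)
    expect_identical(clusterCountFrequencies(rep(3, 5), 3)$CC3, 1)
    expect_null(clusterCountFrequencies(c(2, 2), 2)$CC2)
    expect_error(clusterCountFrequencies(integer(0), 2), "non-empty")
})
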