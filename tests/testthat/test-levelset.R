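chain3 <- buildNeighborGraph(c(1, 2, 3))   # chain 1 - 2 - 3

test_that("level-set components follow the strict density cut", {
    expect_identical(canonPartition(levelSetComponents(chain3, c(3, 1, 3), 2)),
                     list(1L, 3L))
    expect_identical(canonPartition(levelSetComponents(chain3, c(3, 1, 3), 0.5)),
                     list(1:3))
    # cut exactly at a fitted value excludes that observation
    expect_identical(canonPartition(levelSetComponents(chain3, c(3, 1, 3), 1)),
                     list(1L, 3L))
    expect_identical(levelSetComponents(chain3, c(1, 1, 1), 5), list())
})

test_that("component extraction agrees with a union-find oracle", {
    set.seed(11)
    for (rep in 1:100) {
        n <- sample(5:25, 1)
        nEdge <- sample(0:(2 * n), 1)
        edges <- matrix(sample(n, 2 * nEdge, replace = TRUE), ncol = 2)
        edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
        g <- new("NeighborGraph", nVertices = as.integer(n),
                 edges = matrix(as.integer(edges), ncol = 2),
                 metadata = list())
        dens <- runif(n)
        cut <- runif(1)
        expect_identical(canonPartition(levelSetComponents(g, dens, cut)),
                         canonPartition(ufComponents(n, edges,
                                                     which(dens > cut))))
    }
})

test_that("detection handles the textbook chain examples", {
    det <- detectClusters(matrix(1:3, ncol = 1), c(3, 1, 3), chain3,
                          minCoreSize = 1)
    expect_identical(det$nClusters, 2L)
    expect_identical(sort(unique(det$coreLabels[c(1, 3)])), 1:2)
    expect_true(is.na(det$coreLabels[2]))
    # unimodal profile on a chain: every level set is an interval
    chain5 <- buildNeighborGraph(1:5)
    for (rule in c("tree-leaves", "max-count")) {
        det <- detectClusters(matrix(1:5, ncol = 1), c(1, 2, 3, 2, 1),
                              chain5, minCoreSize = 2, mRule = rule)
        expect_identical(det$nClusters, 1L)
        expect_identical(det$coreLabels, rep(1L, 5))
    }
})

test_that("well-separated univariate mixtures are detected reliably", {
    hits <- vapply(1:200, function(s) {
        set.seed(s)
        x <- c(rnorm(50, 0, 0.5), rnorm(50, 10, 0.5))
        nClusters(pdfCluster(x)) == 2L
    }, TRUE)
    expect_gte(mean(hits), 0.95)
})

test_that("cluster count depends only on density ranks (exact scan)", {
    set.seed(21)
    pts <- matrix(rnorm(80), 40, 2)
    g <- buildNeighborGraph(pts)
    dens <- kdeEvaluate(kdeFit(pts), pts)
    for (rule in c("tree-leaves", "max-count")) {
        d1 <- detectClusters(pts, dens, g, mRule = rule,
                             levelGrid = "exact")
        d2 <- detectClusters(pts, exp(3 * dens) - 1, g, mRule = rule,
                             levelGrid = "exact")
        expect_identical(d1$nClusters, d2$nClusters)
        expect_identical(d1$coreLabels, d2$coreLabels)
    }
})

test_that("level-set components are nested along the scan", {
    set.seed(31)
    pts <- matrix(rnorm(60), 30, 2)
    g <- buildNeighborGraph(pts)
    dens <- kdeEvaluate(kdeFit(pts), pts)
    det <- detectClusters(pts, dens, g, keepTree = TRUE)
    parts <- det$tree@componentsPerLevel
    for (t in seq_len(length(parts) - 1)) {
        for (comp in parts[[t]]) {   # higher cut: contained in exactly
            holders <- sum(vapply(parts[[t + 1]],   # one lower component
                                  function(C) all(comp %in% C), TRUE))
            expect_identical(holders, 1L)
        }
    }
})

test_that("cores are disjoint, core-sized, and labelled by peak density", {
    set.seed(41)
    pts <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(40, 6), 20, 2))
    dens <- kdeEvaluate(kdeFit(pts), pts)
    g <- buildNeighborGraph(pts)
    for (grid in c("exact", "equispaced")) {
        det <- detectClusters(pts, dens, g, levelGrid = grid)
        sizes <- tabulate(det$coreLabels, det$nClusters)
        expect_true(all(sizes >= 2))
        peaks <- vapply(seq_len(det$nClusters), function(k)
            max(dens[which(det$coreLabels == k)]), 1)
        expect_true(all(diff(peaks) <= 0))
    }
})

test_that("allocation follows the density-ratio rule", {
    pts <- matrix(c(-10, -9, 9, 10, 8), ncol = 1)
    lab <- c(1L, 1L, 2L, 2L, NA)
    out <- allocateRemaining(pts, lab)
    expect_identical(out[5], 2L)           # overwhelmingly nearer core
    expect_identical(out[1:4], lab[1:4])   # cores never relabelled
    # exact midpoint between equal symmetric cores: tie to label 1
    ptsMid <- matrix(c(-2, -1, 1, 2, 0), ncol = 1)
    out <- allocateRemaining(ptsMid, c(1L, 1L, 2L, 2L, NA))
    expect_identical(out[5], 1L)
})

test_that("refit allocation matches an independent ratio computation", {
    pts <- rbind(c(0, 0), c(0.5, 0), c(10, 0), c(10.5, 0),
                 c(5, 5), c(5.5, 5), c(3, 1))
    lab <- c(1L, 1L, 2L, 2L, 3L, 3L, NA)
    out <- allocateRemaining(pts, lab, groupBandwidths = "refit")
    # oracle: explicit per-group KDE ratios for the single point
    globalH <- normalReferenceBandwidth(pts)
    lf <- vapply(1:3, function(k) {
        grp <- pts[which(lab == k), , drop = FALSE]
        h <- tryCatch(normalReferenceBandwidth(grp),
                      error = function(e) globalH)
        log(bruteKde(grp, h, pts[7, , drop = FALSE]))
    }, 1)
    ratios <- vapply(1:3, function(k) lf[k] - max(lf[-k]), 1)
    expect_identical(out[7], which.max(ratios))
})

test_that("pdfCluster is deterministic and stable under duplication", {
    set.seed(51)
    x <- c(rnorm(40), rnorm(40, 8))
    r1 <- pdfCluster(x)
    r2 <- pdfCluster(x)
    expect_identical(clusterLabels(r1), clusterLabels(r2))
    expect_identical(pointDensities(r1), pointDensities(r2))
    # duplicating every observation preserves m and per-point labels
    rd <- pdfCluster(c(x, x))
    expect_identical(nClusters(rd), nClusters(r1))
    expect_identical(clusterLabels(rd)[seq_along(x)],
                     clusterLabels(rd)[seq_along(x) + length(x)])
})

test_that("a standard normal sample is usually one cluster", {
    m1 <- vapply(1:100, function(s) {
        set.seed(s)
        nClusters(pdfCluster(rnorm(100))) == 1L
    }, TRUE)
    expect_gte(mean(m1), 0.6)
})

test_that("separated mixtures are recovered without misallocations", {
    set.seed(61)
    x <- c(rnorm(50, 0, 0.5), rnorm(50, 10, 0.5))
    r <- pdfCluster(x)
    expect_identical(nClusters(r), 2L)
    expect_identical(errorRate(clusterLabels(r), rep(1:2, each = 50)), 0)
    # final labels extend core labels
    core <- coreLabels(r)
    expect_identical(clusterLabels(r)[!is.na(core)], core[!is.na(core)])
})

test_that("clustering results export to delimited text", {
    set.seed(71)
    r <- pdfCluster(c(rnorm(20), rnorm(20, 6)))
    f <- tempfile(fileext = ".tsv")
    writeClusteringResult(r, f, ids = paste0("s", 1:40))
    tab <- read.table(f, header = TRUE, sep = "\t")
    expect_identical(nrow(tab), 40L)
    expect_identical(tab$final_label, clusterLabels(r))
    f2 <- tempfile(fileext = ".tsv")
    writeClusterTree(r@tree, f2)
    expect_identical(nrow(read.table(f2, header = TRUE, sep = "\t")),
                     length(r@tree@levels))
})
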