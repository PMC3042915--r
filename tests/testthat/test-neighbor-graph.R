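test_that("the univariate graph is the chain over the sort order", {
    g <- buildNeighborGraph(c(3, 1, 2))
    expect_identical(g@nVertices, 3L)
    # sorted order is 2, 3, 1: consecutive order statistics are joined
    expect_setequal(edgeKey(graphEdges(g)), c("2-3", "1-3"))
})

test_that("tiny point sets give the complete graph", {
    g <- buildNeighborGraph(matrix(rnorm(6), 3, 2))
    expect_identical(nrow(graphEdges(g)), 3L)
    g <- buildNeighborGraph(matrix(rnorm(12), 4, 3))
    expect_identical(nrow(graphEdges(g)), 6L)
})

test_that("the unit square yields four hull edges plus one diagonal", {
    # the four corners are cocircular: exactly one of the two diagonals
    # completes the four hull edges
    sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    g <- buildNeighborGraph(sq, jitterSeed = 5)
    e <- edgeKey(graphEdges(g))
    expect_length(e, 5)
    expect_true(all(c("1-2", "2-3", "3-4", "1-4") %in% e))
})

test_that("2-D triangulations match the empty-circumcircle oracle", {
    for (s in 1:5) {
        set.seed(s)
        pts <- matrix(runif(24), 12, 2)
        g <- buildNeighborGraph(pts)
        expect_identical(edgeKey(graphEdges(g)),
                         edgeKey(bruteDelaunay2D(pts)))
    }
})

test_that("3-D triangulations match the empty-circumsphere oracle", {
    for (s in 1:4) {
        set.seed(s)
        pts <- matrix(rnorm(30), 10, 3)
        g <- buildNeighborGraph(pts)
        expect_identical(edgeKey(graphEdges(g)),
                         edgeKey(bruteDelaunay3D(pts)))
    }
})

test_that("degenerate configurations jitter or fail as requested", {
    coll <- cbind(1:8, 2 * (1:8))             # collinear in 2-D
    expect_error(buildNeighborGraph(coll, jitter = FALSE), "degenerate")
    g <- buildNeighborGraph(coll, jitterSeed = 2)
    expect_true(isTRUE(g@metadata$jittered))
    expect_gte(nrow(graphEdges(g)), 7L)       # connected
})

test_that("dimension guard respects pMax", {
    pts <- matrix(rnorm(40), 10, 4)
    expect_error(buildNeighborGraph(pts), "pMax")
    expect_warning(
        expect_error(buildNeighborGraph(pts, pMax = 4L), NA),
        "slow")
})
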