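test_that("normal-reference bandwidths match independent arithmetic", {
    set.seed(1)
    # univariate, sample sd forced to exactly 2
    x <- as.numeric(scale(rnorm(100))) * 2
    expect_equal(normalReferenceBandwidth(x, shrinkage = 0.75),
                 0.75 * 2 * (4 / 300)^(1 / 5))
    expect_equal(normalReferenceBandwidth(x, shrinkage = 0.75), 0.6326,
                 tolerance = 1e-3)
    # shrinkage scales h linearly
    expect_equal(normalReferenceBandwidth(x, shrinkage = 1),
                 normalReferenceBandwidth(x, shrinkage = 0.75) / 0.75)
    # p = 3, unit-variance columns
    m <- apply(matrix(rnorm(300), 100, 3), 2, function(v) as.numeric(scale(v)))
    expect_equal(unname(normalReferenceBandwidth(m)), rep(0.3763, 3),
                 tolerance = 1e-4)
})

test_that("degenerate inputs are rejected with informative errors", {
    m <- cbind(rnorm(10), rep(1, 10))
    expect_error(normalReferenceBandwidth(m), "column 2")
    expect_error(normalReferenceBandwidth(matrix(1, 1, 1)), "insufficient")
    expect_error(normalReferenceBandwidth(rnorm(10), shrinkage = -1),
                 "positive")
    fit <- kdeFit(matrix(rnorm(20), 10, 2))
    expect_error(kdeEvaluate(fit, matrix(0, 1, 3)), "dimension mismatch")
})

test_that("kdeEvaluate reproduces the hand-computed two-point value", {
    fit <- kdeFit(matrix(c(-1, 1), ncol = 1))
    expect_equal(kdeEvaluate(fit, 0), 0.2418, tolerance = 1e-3)
    # symmetry of the Gaussian kernel
    q <- seq(0.3, 3, by = 0.3)
    expect_equal(kdeEvaluate(fit, q), kdeEvaluate(fit, -q))
})

test_that("kdeEvaluate agrees with a brute-force double loop", {
    set.seed(42)
    train <- matrix(rnorm(60), 20, 3)
    fit <- kdeFit(train)
    query <- matrix(rnorm(30), 10, 3)
    expect_equal(kdeEvaluate(fit, query),
                 bruteKde(train, bandwidths(fit), query),
                 tolerance = 1e-12)
    expect_equal(exp(kdeEvaluate(fit, query, log = TRUE)),
                 kdeEvaluate(fit, query))
})

test_that("a univariate density integrates to one", {
    set.seed(7)
    x <- rgamma(80, 3)
    fit <- kdeFit(x)
    h <- bandwidths(fit)
    grid <- seq(min(x) - 6 * h, max(x) + 6 * h, length.out = 4096)
    f <- kdeEvaluate(fit, grid)
    integral <- sum((f[-1] + f[-length(f)]) / 2 * diff(grid))
    expect_equal(integral, 1, tolerance = 1e-3)
})

test_that("the estimate is affine equivariant and finite at the data", {
    set.seed(3)
    x <- rnorm(50)
    a <- 2.5
    fx <- kdeFit(x); fy <- kdeFit(a * x)
    expect_equal(bandwidths(fy), a * bandwidths(fx))
    q <- c(-1, 0, 1.3)
    expect_equal(kdeEvaluate(fy, a * q), kdeEvaluate(fx, q) / a,
                 tolerance = 1e-12)
    expect_true(all(is.finite(kdeEvaluate(fx, x))))
    expect_true(all(kdeEvaluate(fx, x) > 0))
})

test_that("the fitted model is isolated from the caller's matrix", {
    m <- matrix(rnorm(40), 20, 2)
    fit <- kdeFit(m)
    q <- matrix(0, 1, 2)
    before <- kdeEvaluate(fit, q)
    m[1, 1] <- 100
    expect_identical(kdeEvaluate(fit, q), before)
})
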