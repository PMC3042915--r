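# Independent oracles and small data generators used across the suite.

# Brute-force product-Gaussian KDE: explicit double loop over query and
# training points, no shared code with kdeEvaluate.
bruteKde <- function(train, h, query) {
    train <- as.matrix(train); query <- as.matrix(query)
    n <- nrow(train); p <- ncol(train)
    out <- numeric(nrow(query))
    for (q in seq_len(nrow(query))) {
        acc <- 0
        for (i in seq_len(n)) {
            prod <- 1
            for (j in seq_len(p))
                prod <- prod * dnorm((query[q, j] - train[i, j]) / h[j]) / h[j]
            acc <- acc + prod
        }
        out[q] <- acc / n
    }
    out
}

# Brute-force Delaunay edges in 2-D: enumerate all triangles and keep
# those whose circumcircle contains no other point (empty-circumcircle
# test via the lifted determinant).
bruteDelaunay2D <- function(pts) {
    n <- nrow(pts)
    inCircle <- function(a, b, c, d) {
        # > 0 iff d inside circumcircle of counter-clockwise (a, b, c)
        m <- cbind(rbind(a, b, c) - rep(d, each = 3),
                   rowSums((rbind(a, b, c) - rep(d, each = 3))^2))
        det(m)
    }
    orient <- function(a, b, c)
        (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    edges <- matrix(integer(0), 0, 2)
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
        a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
        if (abs(orient(a, b, c)) < 1e-12) next
        if (orient(a, b, c) < 0) { tmp <- b; b <- c; c <- tmp
                                   tri <- tri[c(1, 3, 2)] }
        empty <- TRUE
        for (q in setdiff(seq_len(n), tri)) {
            if (inCircle(a, b, c, pts[q, ]) > 1e-10) { empty <- FALSE; break }
        }
        if (empty)
            edges <- rbind(edges, t(utils::combn(sort(tri), 2)))
    }
    unique(edges)
}

# Brute-force Delaunay edges in 3-D for tiny point sets: enumerate
# tetrahedra with empty circumspheres.
bruteDelaunay3D <- function(pts) {
    n <- nrow(pts)
    circum <- function(ix) {
        A <- 2 * (pts[ix[-1], , drop = FALSE] -
                  matrix(pts[ix[1], ], 3, 3, byrow = TRUE))
        b <- rowSums(pts[ix[-1], , drop = FALSE]^2) - sum(pts[ix[1], ]^2)
        centre <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(centre)) return(NULL)
        list(centre = centre, r2 = sum((pts[ix[1], ] - centre)^2))
    }
    edges <- matrix(integer(0), 0, 2)
    for (tet in utils::combn(n, 4, simplify = FALSE)) {
        cs <- circum(tet)
        if (is.null(cs)) next
        others <- setdiff(seq_len(n), tet)
        d2 <- colSums((t(pts[others, , drop = FALSE]) - cs$centre)^2)
        if (all(d2 > cs$r2 * (1 - 1e-9)))
            edges <- rbind(edges, t(utils::combn(sort(tet), 2)))
    }
    unique(edges)
}

edgeKey <- function(e) {
    if (!nrow(e)) return(character(0))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
}

# Union-find connected components oracle over an induced vertex subset.
ufComponents <- function(nVertices, edges, keep) {
    parent <- seq_len(nVertices)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    inKeep <- logical(nVertices); inKeep[keep] <- TRUE
    if (nrow(edges)) for (r in seq_len(nrow(edges))) {
        a <- edges[r, 1]; b <- edges[r, 2]
        if (inKeep[a] && inKeep[b]) parent[find(a)] <- find(b)
    }
    if (!length(keep)) return(list())
    roots <- vapply(keep, find, 1L)
    unname(lapply(split(keep, roots), sort))
}

canonPartition <- function(parts) {
    parts <- lapply(parts, sort)
    parts[order(vapply(parts, min, 1L))]
}

# reduced Normal-Uniform design used in several tests: full sample size
# (the level-set method needs on the order of a hundred observations)
# but far fewer genes, so a pipeline run takes a fraction of a second
nuSmallParams <- function() {
    nuParams(clusterSizes = c(40L, 40L, 20L), p = 200L,
             upGenes = list(1:30, integer(0), integer(0)),
             downGenes = list(31:40, 31:40, integer(0)))
}
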