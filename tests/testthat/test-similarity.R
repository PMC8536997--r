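test_that("the binary matrix indexes the allele union per sample", {
  m <- build_binary_matrix(list(S1 = c("A", "B"), S2 = c("B", "C")))
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m), rbind(c(1L, 1L, 0L), c(0L, 1L, 1L)))
  expect_equal(colnames(m), c("A", "B", "C"))

  same <- build_binary_matrix(list(S1 = c("A", "B"), S2 = c("A", "B")))
  expect_equal(same["S1", ], same["S2", ])
  expect_error(build_binary_matrix(list(S1 = "A")), "at least 2")
  expect_error(build_binary_matrix(list(S1 = "A", S2 = character())),
               "zero alleles")
})

test_that("Jaccard similarity matches set arithmetic and vegan", {
  m <- build_binary_matrix(list(S1 = c("A", "B", "C"), S2 = c("B", "C", "D")))
  j <- jaccard_matrix(m)
  expect_equal(j["S1", "S2"], 0.5)  # 2 / 4
  expect_equal(diag(j), c(S1 = 1, S2 = 1))

  disj <- build_binary_matrix(list(S1 = c("A", "B"), S2 = c("C", "D")))
  expect_equal(jaccard_matrix(disj)["S1", "S2"], 0)

  skip_if_not_installed("vegan")
  set.seed(41)
  for (rep in 1:5) {
    x <- matrix(rbinom(8 * 15, 1, 0.4), nrow = 8)
    x[rowSums(x) == 0, 1] <- 1L
    j <- jaccard_matrix(x)
    expect_true(isSymmetric(j))
    expect_true(all(j >= 0 & j <= 1))
    vd <- as.matrix(vegan::vegdist(x, method = "jaccard", binary = TRUE))
    expect_equal(unname(1 - j), unname(vd), tolerance = 1e-12)
  }
})

test_that("1 - J satisfies the triangle inequality on random triples", {
  set.seed(43)
  for (rep in 1:40) {
    x <- matrix(rbinom(3 * 12, 1, 0.5), nrow = 3)
    x[rowSums(x) == 0, 1] <- 1L
    d <- 1 - jaccard_matrix(x)
    expect_lte(d[1, 2], d[1, 3] + d[3, 2] + 1e-12)
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-12)
    expect_lte(d[2, 3], d[2, 1] + d[1, 3] + 1e-12)
  }
})

test_that("single and complete linkage agree with hand-worked merges", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  for (m in c("single", "complete")) {
    hc <- linkage_cluster(d2, m)
    expect_equal(hc$height, 0.3)
  }

  d3 <- matrix(c(0, 1, 2,
                 1, 0, 3,
                 2, 3, 0), 3, byrow = TRUE,
               dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  s <- linkage_cluster(d3, "single")
  expect_equal(s$height, c(1, 2))
  expect_equal(s$merge[1, ], c(-2L, -1L))
  co <- linkage_cluster(d3, "complete")
  expect_equal(co$height, c(1, 3))
  expect_error(linkage_cluster(matrix(c(0, 1, 2, 0), 2), "single"),
               "symmetric")
})

test_that("linkage reproduces hclust and respects the single <= complete bound", {
  set.seed(47)
  for (rep in 1:5) {
    n <- 7
    d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
    dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
    for (m in c("single", "complete")) {
      mine <- linkage_cluster(d, m)
      ref <- hclust(as.dist(d), method = m)
      expect_equal(mine$height, ref$height, tolerance = 1e-12)
    }
    s <- linkage_cluster(d, "single")
    co <- linkage_cluster(d, "complete")
    expect_true(all(sort(s$height) <= sort(co$height) + 1e-12))
  }
})

test_that("ultrametric input yields identical trees under both linkages", {
  # three leaves at mutual heights 1,1,2 plus an outlier at 4
  d <- matrix(4, 4, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- d[2, 3] <- d[3, 2] <- 2
  diag(d) <- 0
  s <- linkage_cluster(d, "single")
  co <- linkage_cluster(d, "complete")
  expect_equal(s$merge, co$merge)
  expect_equal(s$height, co$height)
})

test_that("classical MDS recovers embeddable configurations", {
  # three collinear points
  x <- c(0, 1, 3)
  d <- as.matrix(dist(x))
  co <- classical_mds(d, k = 1)
  expect_equal(as.matrix(dist(co)), d, tolerance = 1e-9,
               ignore_attr = TRUE)

  z <- matrix(0, 3, 3)
  expect_equal(classical_mds(z, k = 2), matrix(0, 3, 2),
               ignore_attr = TRUE)

  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  dsq <- as.matrix(dist(sq))
  co2 <- classical_mds(dsq, k = 2)
  expect_equal(as.matrix(dist(co2)), dsq, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("MDS recovers planar configurations up to rigid motion", {
  set.seed(53)
  pts <- matrix(rnorm(12 * 2), 12)
  d <- as.matrix(dist(pts))
  co <- classical_mds(d, k = 2)
  # Procrustes: center, optimal rotation via SVD
  a <- scale(co, scale = FALSE)
  b <- scale(pts, scale = FALSE)
  sv <- svd(crossprod(a, b))
  rot <- sv$u %*% t(sv$v)
  rms <- sqrt(mean((a %*% rot - b)^2))
  expect_lt(rms, 1e-6)
})

test_that("logistic PCA deviance is non-increasing and fits separable structure", {
  set.seed(59)
  for (rep in 1:3) {
    x <- matrix(rbinom(10 * 18, 1, 0.4), nrow = 10)
    fit <- logistic_pca(x, k = 2, m = 4)
    expect_true(all(diff(fit$deviance) <= 1e-8))
    expect_equal(dim(fit$scores), c(10L, 2L))
    expect_equal(unname(crossprod(fit$loadings)), diag(2), tolerance = 1e-9)
  }

  # rank-1 separable block matrix: two duplicated row patterns
  patt <- rbind(c(1, 1, 1, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 1, 1, 1, 1))
  x <- patt[rep(1:2, each = 5), ]
  fit <- logistic_pca(x, k = 1, m = 10)
  expect_true(all(fit$fitted_prob[x == 1] >= 0.9))
  expect_true(all(fit$fitted_prob[x == 0] <= 0.1))

  # constant all-ones column stays finite
  x2 <- cbind(1, matrix(rbinom(8 * 6, 1, 0.5), nrow = 8))
  fit2 <- logistic_pca(x2, k = 2, m = 4)
  expect_true(all(is.finite(fit2$scores)))
  expect_true(all(is.finite(fit2$fitted_prob)))
  expect_error(logistic_pca(matrix(0.5, 4, 4), k = 1), "0/1")
  expect_error(logistic_pca(matrix(rbinom(16, 1, 0.5), 4), k = 4), "k <")
})

test_that("sample_similarity bundles all components consistently", {
  sets <- list(S1 = c("A", "B", "C"), S2 = c("B", "C", "D"),
               S3 = c("A", "E"), S4 = c("E", "F"))
  ss <- sample_similarity(sets, k = 2, m = 4)
  expect_equal(dim(ss$matrix), c(4L, 6L))
  expect_equal(ss$dissimilarity, 1 - ss$jaccard)
  expect_s3_class(ss$single, "hclust")
  expect_equal(dim(ss$mds), c(4L, 2L))
  expect_equal(nrow(ss$lpca$scores), 4L)
  skip_if_not_installed("ape")
  nw <- linkage_newick(ss$complete)
  expect_match(nw, "^\\(.*\\);$")
  expect_setequal(ape::read.tree(text = nw)$tip.label, names(sets))
})
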