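test_that("mixed encoding: population z-scores for quantitative columns
          and sqrt(p)-weighted centered indicators for levels", {
  m <- encode_mixed(data.frame(x = c(1, 2, 3)))
  expect_equal(unname(m[, 1]), c(-sqrt(3 / 2), 0, sqrt(3 / 2)))

  m2 <- encode_mixed(data.frame(g = c("a", "b", "a", "b")))
  expect_equal(dim(m2), c(4L, 2L))
  expect_equal(sort(unique(as.vector(m2))),
               c(-0.5 / sqrt(0.5), 0.5 / sqrt(0.5)))
  expect_equal(colSums(m2), c(g.a = 0, g.b = 0))

  # all-quantitative encoding equals PCA standardization
  X <- data.frame(a = rnorm(10), b = runif(10))
  m3 <- encode_mixed(X)
  expect_equal(unname(m3[, 1]),
               (X$a - mean(X$a)) / sqrt(mean((X$a - mean(X$a))^2)))

  expect_error(encode_mixed(data.frame(x = rep(1, 5))), "zero variance")
  expect_error(encode_mixed(data.frame(g = rep("a", 5))),
               "fewer than 2 observed levels")
})

test_that("all-quantitative FAMD eigenvalues equal correlation-matrix
          PCA eigenvalues to 1e-8", {
  set.seed(21)
  X <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40),
                  d = runif(40))
  f <- famd(X, n_dims = 4)
  ev <- eigen(cor(X), only.values = TRUE)$values
  expect_lt(max(abs(f$eigenvalues - ev)), 1e-8)
  expect_equal(sum(f$percent_inertia), 100)
})

test_that("categorical-only FAMD recovers MCA: inertia sum(L - 1) and
          row coordinates matching a from-scratch correspondence
          analysis", {
  set.seed(22)
  g <- factor(sample(letters[1:4], 30, replace = TRUE))
  f <- famd(data.frame(g = g), n_dims = 3)
  expect_equal(f$total_inertia, 3, tolerance = 1e-10)

  # two associated variables give a non-degenerate spectrum whose row
  # coordinates must match the CA-of-indicator oracle up to column sign
  set.seed(26)
  g1 <- factor(sample(letters[1:3], 40, replace = TRUE,
                      prob = c(0.5, 0.3, 0.2)))
  g2 <- factor(ifelse(g1 == "a", sample(c("x", "y"), 40, TRUE,
                                        prob = c(0.8, 0.2)),
                      sample(c("x", "y"), 40, TRUE)))
  f2 <- famd(data.frame(g1 = g1, g2 = g2), n_dims = 3)
  expect_equal(f2$total_inertia, 3, tolerance = 1e-10)
  ora <- oracle_mca_rowcoords(list(g1, g2), 3)
  # compare only dimensions separated from their neighbors (distinct
  # singular values; degenerate subspaces are rotation-arbitrary)
  gaps <- abs(diff(ora$sv[1:4]))
  for (k in 1:3) {
    sep <- (k == 1 || gaps[k - 1] > 1e-6) && gaps[k] > 1e-6
    if (!sep) next
    d_same <- max(abs(f2$row_coords[, k] - ora$coords[, k]))
    d_flip <- max(abs(f2$row_coords[, k] + ora$coords[, k]))
    expect_lt(min(d_same, d_flip), 1e-8)
  }
})

test_that("total inertia is conserved at K + sum(levels - 1) on random
          mixed tables", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(10:25, 1)
    kq <- sample(1:4, 1)
    tab <- as.data.frame(matrix(rnorm(n * kq), n))
    lv <- sample(2:4, 1)
    tab$g <- factor(sample(letters[1:lv], n, replace = TRUE))
    if (nlevels(droplevels(tab$g)) < 2) next
    lv_obs <- nlevels(droplevels(tab$g))
    f <- famd(tab, n_dims = 2)
    expect_lt(abs(f$total_inertia - (kq + lv_obs - 1)), 1e-10)
  }
  # the worked three-quantitative + four-level example: inertia 6
  set.seed(24)
  tab <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20),
                    g = factor(rep(letters[1:4], 5)))
  expect_equal(famd(tab, n_dims = 2)$total_inertia, 6, tolerance = 1e-10)
})

test_that("incomplete rows are dropped with a count and the sign
          convention fixes reproducible loadings", {
  set.seed(25)
  tab <- data.frame(a = rnorm(12), b = rnorm(12))
  tab$a[3] <- NA
  f <- famd(tab, n_dims = 2)
  expect_equal(f$n_rows, 11)
  expect_equal(f$dropped, 1L)
  # largest-magnitude loading entry positive in every dimension
  for (k in 1:2) {
    expect_gt(f$loadings[which.max(abs(f$loadings[, k])), k], 0)
  }
})

test_that("the 50% cumulative-inertia support rule", {
  f <- famd(data.frame(a = rnorm(30), b = rnorm(30)), n_dims = 2)
  # two dims of a two-column table carry all inertia
  expect_true(support_check(f, 2)$supported)
  expect_true(support_check(f, 2, threshold = 0)$supported)
  fake <- f
  fake$cumulative_inertia <- c(20, 35)
  expect_false(support_check(fake, 2)$supported)
  expect_true(support_check(fake, 2, threshold = 0.30)$supported)
  expect_match(support_check(fake, 2)$report, "below the 50%")
  expect_error(famd(data.frame(a = rnorm(5), b = rnorm(5)), n_dims = 5),
               "n_dims")
})
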