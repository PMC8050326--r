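test_that("region delineation follows the emission bands", {
  r <- raster_grid(c(0, 0), 1, matrix(2.0, 3, 3))
  ra <- delineate_regions(r)
  expect_true(all(ra$labels == "R2"))
  r2 <- raster_grid(c(0, 0), 1, matrix(c(2.8, 3.0, 1.5, NA), 2, 2))
  ra2 <- delineate_regions(r2)
  expect_equal(ra2$counts[["R1"]], 1)      # 3.0
  expect_equal(ra2$counts[["unassigned"]], 3)  # gap value, below band, NA
  expect_error(delineate_regions(r, low_band = c(1, 3), high_band = c(2, 4)),
               "overlap")
})

test_that("regions constructed from two field patches are recovered", {
  g <- paper_grid()
  m <- variogram_model("spherical", 0.01, 0.04, 27)
  z_low <- simulate_grf(g, m, mean = 2.3, seed = 51)   # inside 1.9-2.7
  z_high <- simulate_grf(g, m, mean = 3.5, seed = 52)  # inside 2.9-4.2
  vals <- ifelse(g$y > 40, z_high, z_low)              # top = high patch
  truth <- ifelse(g$y > 40, "R1", "R2")
  r <- raster_grid(c(-5, -5), 10,
                   matrix(vals[order(-g$y, g$x)], 10, 10, byrow = TRUE))
  ra <- delineate_regions(r)
  lab <- as.vector(t(ra$labels))
  truth_r <- truth[order(-g$y, g$x)]
  in_band <- !is.na(lab)
  expect_gte(mean(lab[in_band] == truth_r[in_band]), 0.95)
})

test_that("pooled t statistic matches the textbook formula and t.test", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  r <- students_t(a, b)
  sp2 <- ((2) * var(a) + (2) * var(b)) / 4
  expect_equal(r$statistic, (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3)))
  expect_equal(r$df, 4)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic))
  expect_equal(r$p_value, tt$p.value)
  w <- students_t(a, b, var_equal = FALSE)
  tw <- t.test(a, b)
  expect_equal(w$statistic, unname(tw$statistic))
  expect_equal(w$df, unname(tw$parameter))
})

test_that("t handles identical and degenerate groups per contract", {
  r <- students_t(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$statistic, 0); expect_equal(r$p_value, 1)
  expect_false(r$significant)
  z <- students_t(c(2, 2), c(2, 2))
  expect_equal(z$statistic, 0); expect_equal(z$p_value, 1)
  d <- students_t(c(3, 3), c(1, 1))
  expect_equal(d$p_value, 0); expect_true(d$significant)
  shift <- students_t(c(1, 2, 3) + 100, c(2, 4, 6) + 100)
  expect_equal(shift$statistic - students_t(c(1, 2, 3), c(2, 4, 6))$statistic,
               0, tolerance = 1e-12)
})

test_that("Hotelling T2 reduces to t-squared for one variable", {
  set.seed(13)
  for (i in 1:5) {
    a <- rnorm(9, 0); b <- rnorm(9, 1)
    ht <- hotelling_t2(matrix(a), matrix(b))
    tt <- students_t(a, b)
    expect_lt(abs(ht$t2 - tt$statistic^2), 1e-8)
  }
})

test_that("Hotelling T2 is affine invariant and zero for identical groups", {
  set.seed(14)
  x1 <- matrix(rnorm(27), 9); x2 <- matrix(rnorm(27, 0.8), 9)
  base <- hotelling_t2(x1, x2)
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 3), 3)
  shift <- c(5, -2, 100)
  tr <- function(x) sweep(x %*% A, 2, shift, "+")
  expect_equal(hotelling_t2(tr(x1), tr(x2))$t2, base$t2, tolerance = 1e-8)
  same <- hotelling_t2(x1, x1)
  expect_equal(same$t2, 0, tolerance = 1e-10)
  expect_equal(same$p_value, 1)
  expect_gte(base$t2, 0); expect_gte(base$f, 0)
  expect_error(hotelling_t2(x1[1:2, ], x2[1:2, ]), "too few")
})

test_that("the per-variable battery flags and corrects as configured", {
  tab <- simulate_microbiology(microbiology_config(seed = 8))
  cmp <- compare_groups(tab, "region", alpha = 0.01)
  expect_equal(nrow(cmp), 9)
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  cmp_bonf <- compare_groups(tab, "region", alpha = 0.01,
                             p_adjust = "bonferroni")
  expect_true(all(cmp_bonf$p_value >= cmp$p_value - 1e-15))
})

test_that("two items merge at their Euclidean distance", {
  x <- rbind(c(0, 0), c(3, 4))
  wc <- ward_cluster(x, n_groups = 2)
  expect_equal(wc$hclust$height, 5)
  expect_equal(unname(wc$labels), c(1L, 2L))
})

test_that("well-separated clouds are cut exactly into their groups", {
  set.seed(15)
  cloud1 <- matrix(rnorm(20, 0, 0.2), 10)
  cloud2 <- matrix(rnorm(20, 50, 0.2), 10)
  wc <- ward_cluster(rbind(cloud1, cloud2), n_groups = 2)
  lab <- wc$labels
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_true(lab[1] != lab[11])
})

test_that("merge heights match the brute-force Ward oracle for n <= 6", {
  set.seed(16)
  for (n in c(4, 5, 6)) {
    x <- matrix(rnorm(n * 3), n)
    wc <- ward_cluster(x, n_groups = 2)
    expect_equal(sort(wc$hclust$height), brute_ward_heights(x),
                 tolerance = 1e-9)
    expect_true(all(diff(wc$hclust$height) >= -1e-12))  # monotone dendrogram
  }
  expect_error(ward_cluster(matrix(rnorm(4), 2), n_groups = 3), "n_groups")
})

test_that("perfectly correlated variables collapse onto one component", {
  x <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  p <- pca(x)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(p$explained_variance[1], 100, tolerance = 1e-10)
})

test_that("correlation-matrix eigenvalues sum to p and variances decrease", {
  set.seed(17)
  x <- matrix(rnorm(120), 20, 6)
  p <- pca(x)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-10)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  expect_equal(sum(p$explained_variance), 100, tolerance = 1e-10)
  # reconstruction of the correlation matrix from all loadings
  expect_equal(p$loadings %*% t(p$loadings), cor(x), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("loadings agree with an SVD-based computation up to sign", {
  set.seed(18)
  x <- matrix(rnorm(100), 20, 5)
  p <- pca(x)
  sv <- svd(scale(x) / sqrt(19))
  oracle <- sv$v %*% diag(sv$d)      # loadings up to column signs
  for (j in 1:5) {
    expect_equal(abs(p$loadings[, j]), abs(oracle[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # sign convention: dominant loading positive
  expect_true(all(apply(p$loadings, 2, function(l) l[which.max(abs(l))] > 0)))
  expect_error(pca(cbind(x, const = 1)), "constant")
})

test_that("Kaiser retention and the 0.70 interpretation rule apply", {
  set.seed(19)
  f <- rnorm(30)
  x <- cbind(v1 = f + rnorm(30, 0, 0.3), v2 = -f + rnorm(30, 0, 0.3),
             v3 = f + rnorm(30, 0, 0.3), noise = rnorm(30))
  p <- pca(x)
  expect_true(1 %in% p$retained)
  expect_true(all(p$eigenvalues[p$retained] > 1))
  expect_true(all(c("v1", "v2", "v3") %in% p$interpreted[["PC1"]]))
})
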