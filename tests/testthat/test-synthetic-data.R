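test_that("zero-variance model yields a constant field at the mean", {
  g <- paper_grid()
  m <- variogram_model("spherical", 0, 0, 27)
  z <- simulate_grf(g, m, mean = 2.91, seed = 1)
  expect_equal(z, rep(2.91, nrow(g)))
})

test_that("fixed seed gives bit-identical output and spares the caller's RNG", {
  cfg <- survey_config(seed = 11)
  d1 <- simulate_survey(cfg)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  d2 <- simulate_survey(cfg)
  after <- rnorm(1)
  expect_identical(d1, d2)
  expect_identical(before, after)  # generator did not consume caller's stream

  mc <- microbiology_config(seed = 3)
  expect_identical(simulate_microbiology(mc), simulate_microbiology(mc))
})

test_that("pure-nugget fields match the i.i.d. limit", {
  g <- paper_grid()  # 10 x 10 grid
  m <- variogram_model("spherical", 1, 0, 10)
  z <- simulate_grf(g, m, mean = 0, seed = 42, n = 200)
  expect_equal(dim(z), c(100L, 200L))
  pooled_var <- mean(apply(z, 2, var))
  expect_lt(abs(pooled_var - 1), 0.1)
  # lag-1 (10 m) correlation pooled over east-neighbor pairs
  left <- which(g$x < max(g$x))
  right <- match(paste(g$x[left] + 10, g$y[left]), paste(g$x, g$y))
  r <- cor(as.vector(z[left, ]), as.vector(z[right, ]))
  expect_lt(abs(r), 0.1)
})

test_that("simulated fields reproduce the generating variogram", {
  g <- paper_grid()
  m <- variogram_model("spherical", 0.15, 0.10, 27)
  gam <- sapply(1:30, function(i) {
    z <- simulate_grf(g, m, mean = 0, seed = 200 + i)
    empirical_variogram(point_dataset(cbind(g, z = z), spacing = 10),
                        "z")$gamma
  })
  ev <- empirical_variogram(point_dataset(cbind(g, z = simulate_grf(g, m, 0, seed = 1)),
                                          spacing = 10), "z")
  pooled <- rowMeans(gam)
  model_curve <- semivariance(m, ev$dist)
  expect_lt(max(abs(pooled - model_curve) / model_curve), 0.1)
})

test_that("non-positive-definite covariance is reported with its parameters", {
  # gaussian model with zero nugget on a dense collinear layout is the
  # classic ill-conditioned case
  g <- data.frame(x = seq(0, 1, length.out = 40), y = 0)
  m <- variogram_model("gaussian", 0, 1, 500)
  expect_error(simulate_grf(g, m, seed = 1), "positive definite")
})

test_that("covariance assembly is invariant to 90-degree grid rotation", {
  g <- paper_grid()
  rot <- data.frame(x = g$y, y = max(g$x) - g$x)
  perm <- match(paste(rot$x, rot$y), paste(g$x, g$y))
  expect_true(all(!is.na(perm)))   # rotation maps the grid onto itself
  d1 <- as.matrix(dist(g))
  d2 <- as.matrix(dist(rot))[order(perm), order(perm)]
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("default survey lies on the 10 m lattice with 100 points", {
  d <- simulate_survey(survey_config(seed = 5))
  expect_s3_class(d, "point_dataset")
  expect_equal(nrow(d), 100)
  expect_true(all(d$x %% 10 == 0) && all(d$y %% 10 == 0))
  expect_true(all(c("FCO2", "SOM") %in% attribute_names(d)))
})

test_that("generator means converge to the configured targets", {
  atts <- default_survey_attributes(c("FCO2", "SOM"))
  cfg <- survey_config(attributes = atts, seed = 1)
  means <- t(sapply(1:50, function(i) {
    d <- simulate_survey(cfg, seed = 3000 + i)
    c(FCO2 = mean(d$FCO2), SOM = mean(d$SOM))
  }))
  targets <- c(FCO2 = 2.91, SOM = 32.17)
  for (nm in names(targets)) {
    se <- sd(means[, nm]) / sqrt(nrow(means))
    expect_lt(abs(mean(means[, nm]) - targets[[nm]]), 3 * se + 1e-12)
  }
})

test_that("a configured positive correlation shows up in the samples", {
  atts <- default_survey_attributes(c("FCO2", "SOM"),
                                    driver_correlations = c(SOM = 0.7))
  cfg <- survey_config(attributes = atts, seed = 1)
  pos <- sapply(1:100, function(i) {
    d <- simulate_survey(cfg, seed = 4000 + i)
    cor(d$FCO2, d$SOM) > 0
  })
  expect_gte(mean(pos), 0.95)
})

test_that("survey config validation rejects bad specifications", {
  expect_error(survey_config(spacing = 0), "spacing")
  expect_error(survey_config(extent = 95), "integer multiple")
  atts <- default_survey_attributes(c("FCO2", "SOM"))
  atts$SOM$cor <- 1.5; atts$SOM$cor_with <- "FCO2"
  expect_error(survey_config(attributes = atts), "magnitude")
  dup <- default_survey_attributes("FCO2")
  expect_error(survey_config(attributes = c(dup, dup)), "duplicate")
})

test_that("microbiology table bookkeeping and error contracts hold", {
  mc <- microbiology_config(n_per_group = 9, seed = 2)
  tab <- simulate_microbiology(mc)
  expect_equal(nrow(tab), 18)
  expect_equal(unname(table(tab$region)), c(9L, 9L), ignore_attr = TRUE)
  expect_equal(ncol(tab) - 1, nrow(microbiology_reference()))

  bad <- microbiology_reference()
  bad$r1_mean[bad$family == "lognormal"][1] <- -1
  expect_error(microbiology_config(variables = bad), "positive means")
  expect_error(microbiology_config(n_per_group = 1), "at least 2")
})

test_that("identical groups reject at about the nominal 1% rate", {
  vars <- data.frame(variable = "v", family = "normal",
                     r1_mean = 10, r1_se = 1, r2_mean = 10, r2_se = 1)
  mc <- microbiology_config(variables = vars, n_per_group = 9, seed = 1)
  rej <- vapply(1:1000, function(i) {
    tab <- simulate_microbiology(mc, seed = i)
    students_t(tab$v[tab$region == "R1"], tab$v[tab$region == "R2"],
               alpha = 0.01)$significant
  }, logical(1))
  # binomial(1000, 0.01) central 99.9% interval
  expect_gte(sum(rej), qbinom(0.0005, 1000, 0.01))
  expect_lte(sum(rej), qbinom(0.9995, 1000, 0.01))
})

test_that("the dehydrogenase contrast is detected in most replicates", {
  ref <- microbiology_reference()
  mc <- microbiology_config(ref[ref$variable == "dehydrogenase", ], seed = 1)
  hits <- vapply(1:100, function(i) {
    tab <- simulate_microbiology(mc, seed = 6000 + i)
    students_t(tab$dehydrogenase[tab$region == "R1"],
               tab$dehydrogenase[tab$region == "R2"],
               alpha = 0.01)$significant
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
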