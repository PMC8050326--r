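# Independent oracles and small fixtures shared across the suite.
# These deliberately re-derive results by brute force (explicit loops,
# alternative formulations) so they never share code with the package
# internals they check.

paper_grid <- function(extent = 90, spacing = 10) {
  expand.grid(x = seq(0, extent, by = spacing),
              y = seq(0, extent, by = spacing))
}

# brute-force pair-enumeration variogram with the same binning rule
# (half-open bins centered at multiples of the width)
brute_variogram <- function(dataset, attribute, bin_width, max_lag) {
  z <- dataset[[attribute]]
  n <- nrow(dataset)
  acc <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((dataset$x[i] - dataset$x[j])^2 +
                (dataset$y[i] - dataset$y[j])^2)
      if (d <= 0 || d > max_lag) next
      k <- max(1, floor(d / bin_width + 0.5))
      key <- as.character(k)
      acc[[key]] <- c(acc[[key]], (z[i] - z[j])^2)
    }
  }
  ks <- sort(as.integer(names(acc)))
  data.frame(center = ks * bin_width,
             gamma = vapply(as.character(ks),
                            function(k) sum(acc[[k]]) / (2 * length(acc[[k]])),
                            numeric(1)),
             npairs = vapply(as.character(ks), function(k) length(acc[[k]]),
                             numeric(1)))
}

# independent dense ordinary-kriging solve: system assembled entry by
# entry in explicit loops, solved by qr.solve
brute_ok <- function(dataset, attribute, model, x0, y0) {
  n <- nrow(dataset)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        h <- sqrt((dataset$x[i] - dataset$x[j])^2 +
                  (dataset$y[i] - dataset$y[j])^2)
        A[i, j] <- semivariance(model, h)
      }
    }
    A[i, n + 1] <- 1
    A[n + 1, i] <- 1
  }
  b <- numeric(n + 1)
  for (i in seq_len(n)) {
    h <- sqrt((dataset$x[i] - x0)^2 + (dataset$y[i] - y0)^2)
    b[i] <- semivariance(model, h)
  }
  b[n + 1] <- 1
  sol <- qr.solve(A, b)
  list(weights = sol[seq_len(n)], mu = sol[n + 1],
       pred = sum(sol[seq_len(n)] * dataset[[attribute]]))
}

# exhaustive Ward agglomeration from the merge-cost definition
# Delta(A, B) = |A||B| / (|A| + |B|) * ||mean_A - mean_B||^2,
# heights on the distance scale: sqrt(2 * Delta)
brute_ward_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) x[i, , drop = FALSE])
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        na <- nrow(clusters[[i]]); nb <- nrow(clusters[[j]])
        dm <- colMeans(clusters[[i]]) - colMeans(clusters[[j]])
        cost <- na * nb / (na + nb) * sum(dm^2)
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    heights <- c(heights, sqrt(2 * best[1]))
    merged <- rbind(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  sort(heights)
}

random_dataset <- function(n, extent = 90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_dataset(data.frame(x = runif(n, 0, extent),
                           y = runif(n, 0, extent),
                           z = rnorm(n)))
}

# direct construction of a fitted_variogram for select_model tests
fake_fit <- function(ssr, r2, rmse = NA_real_, kind = "spherical") {
  m <- variogram_model(kind, 0.1, 1, 20)
  m$diagnostics <- list(ssr = ssr, r2 = r2, rmse_cv = rmse, n_bins = 6,
                        weighting = "npairs", converged = TRUE)
  class(m) <- c("fitted_variogram", "variogram_model")
  m
}
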