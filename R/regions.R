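#' Delineate contrasting-emission regions on a kriged map
#'
#' Labels raster cells by FCO2 value band: cells inside `high_band` are
#' assigned to region R1 (high emission), cells inside `low_band` to R2
#' (low emission), all others (including nodata) are left unassigned.
#' Defaults are the emission bands used to contrast post-reform survey
#' regions: R1 2.9-4.2 and R2 1.9-2.7 umol m-2 s-1. Band edges are
#' inclusive; bands must not overlap.
#'
#' @param raster a [raster_grid()] of predicted FCO2.
#' @param low_band numeric `(min, max)` for region R2.
#' @param high_band numeric `(min, max)` for region R1.
#' @return A `region_assignment`: list with `labels` (character matrix
#'   `"R1"`/`"R2"`/`NA`), `low_band`, `high_band` and per-region cell
#'   counts.
#' @examples
#' r <- raster_grid(c(0, 0), 1, matrix(c(2, 2.5, 3, 3.5), 2, 2))
#' delineate_regions(r)$counts
#' @export
delineate_regions <- function(raster, low_band = c(1.9, 2.7),
                              high_band = c(2.9, 4.2)) {
  stopifnot(inherits(raster, "raster_grid"),
            length(low_band) == 2, length(high_band) == 2,
            low_band[1] <= low_band[2], high_band[1] <= high_band[2])
  if (low_band[2] >= high_band[1] && high_band[2] >= low_band[1]) {
    stop("low_band and high_band overlap")
  }
  v <- raster$values
  lab <- matrix(NA_character_, nrow(v), ncol(v))
  lab[!is.na(v) & v >= high_band[1] & v <= high_band[2]] <- "R1"
  lab[!is.na(v) & v >= low_band[1] & v <= low_band[2]] <- "R2"
  structure(list(labels = lab, low_band = low_band, high_band = high_band,
                 counts = c(R1 = sum(lab == "R1", na.rm = TRUE),
                            R2 = sum(lab == "R2", na.rm = TRUE),
                            unassigned = sum(is.na(lab)))),
            class = "region_assignment")
}

#' @export
print.region_assignment <- function(x, ...) {
  cat(sprintf("region assignment: R1 (%.4g-%.4g) %d cells, R2 (%.4g-%.4g) %d cells, %d unassigned\n",
              x$high_band[1], x$high_band[2], x$counts[["R1"]],
              x$low_band[1], x$low_band[2], x$counts[["R2"]],
              x$counts[["unassigned"]]))
  invisible(x)
}

#' Two-sample Student's t test (pooled variance)
#'
#' Classical equal-variance two-sided t with
#' `df = n1 + n2 - 2`. Degenerate contract: when the pooled variance is
#' zero and the means are equal, `t = 0`, `p = 1`; when the pooled
#' variance is zero and the means differ, the difference is certain under
#' the model (`t = Inf`, `p = 0`). A Welch option is available.
#'
#' @param a,b numeric samples, `n >= 2` each.
#' @param alpha significance level for the `significant` flag.
#' @param var_equal pooled (default `TRUE`) or Welch.
#' @return List with `statistic`, `df`, `p_value`, `significant`,
#'   `mean_a`, `mean_b`, `alpha`.
#' @examples
#' students_t(c(1, 2, 3), c(2, 4, 6))
#' @export
students_t <- function(a, b, alpha = 0.01, var_equal = TRUE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- if (se == 0) n1 + n2 - 2 else
      (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) { tt <- 0; p <- 1 } else { tt <- Inf * sign(m1 - m2); p <- 0 }
  } else {
    tt <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(statistic = tt, df = df, p_value = p, significant = p < alpha,
       mean_a = m1, mean_b = m2, alpha = alpha)
}

#' Per-variable group comparison of a two-region table
#'
#' Applies [students_t()] to every numeric variable of a table split by
#' a two-level group factor. No multiple-testing correction is applied by
#' default (matching univariate reporting practice in two-region survey
#' comparisons); set `p_adjust` to a [stats::p.adjust()] method to
#' correct.
#'
#' @param data data frame with a group column plus numeric variables.
#' @param group name of the group column (two levels).
#' @param alpha significance level.
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @param var_equal pooled (default) or Welch t.
#' @return Data frame, one row per variable: means, `t`, `df`, `p_value`
#'   (adjusted when requested) and `significant`.
#' @export
compare_groups <- function(data, group = "region", alpha = 0.01,
                           p_adjust = "none", var_equal = TRUE) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group column must have exactly two levels")
  vars <- setdiff(names(data), group)
  vars <- vars[vapply(data[vars], is.numeric, logical(1))]
  rows <- lapply(vars, function(v) {
    r <- students_t(data[[v]][g == levels(g)[1]],
                    data[[v]][g == levels(g)[2]],
                    alpha = alpha, var_equal = var_equal)
    data.frame(variable = v, mean_1 = r$mean_a, mean_2 = r$mean_b,
               t = r$statistic, df = r$df, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  attr(out, "groups") <- levels(g)
  out
}

#' Two-sample Hotelling's T-squared test
#'
#' Multivariate mean comparison from the pooled covariance:
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2} (\bar x_1 - \bar x_2)' S^{-1}
#'   (\bar x_1 - \bar x_2)}
#' with \eqn{F = T^2 (n_1 + n_2 - p - 1) / ((n_1 + n_2 - 2) p)} on
#' \eqn{(p, n_1 + n_2 - p - 1)} degrees of freedom.
#'
#' @param x1,x2 numeric matrices (or data frames), samples in rows, the
#'   same `p` variables in columns.
#' @return List with `t2`, `f`, `df1`, `df2`, `p_value`, `n1`, `n2`, `p`.
#' @examples
#' set.seed(1)
#' hotelling_t2(matrix(rnorm(27), 9), matrix(rnorm(27, 1), 9))
#' @export
hotelling_t2 <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("groups must share the same variables")
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  if (n1 + n2 - p - 1 < 1) {
    stop("too few samples for ", p, " variables (need n1 + n2 >= p + 2)")
  }
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  d <- colMeans(x1) - colMeans(x2)
  Sinv_d <- tryCatch(solve(S, d), error = function(e)
    stop("pooled covariance is singular; reduce or decorrelate variables (",
         conditionMessage(e), ")"))
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * Sinv_d)
  df1 <- p; df2 <- n1 + n2 - p - 1
  f <- t2 * df2 / ((n1 + n2 - 2) * p)
  list(t2 = t2, f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       n1 = n1, n2 = n2, p = p)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering on the Euclidean distance with the classic
#' Ward minimum-variance objective; merge heights are reported on the
#' distance scale (the first merge of two singletons sits at their
#' Euclidean distance). Delegates the Lance-Williams recurrence to
#' [stats::hclust()] with `method = "ward.D2"`; `variant = "ward.D"`
#' gives the squared-scale heights instead.
#'
#' @param x numeric matrix or data frame, items in rows.
#' @param n_groups number of groups for the dendrogram cut.
#' @param variant `"ward.D2"` (default, distance-scale heights) or
#'   `"ward.D"`.
#' @return A `ward_cluster`: list with `hclust` (merge sequence and
#'   heights), `labels` (cut into `n_groups`), and `cophenetic_cor`.
#' @examples
#' wc <- ward_cluster(rbind(matrix(0:3, 2), matrix(10 + 0:3, 2)), 2)
#' wc$labels
#' @export
ward_cluster <- function(x, n_groups = 2, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 items")
  if (any(!is.finite(x))) stop("non-finite entries")
  if (n_groups > nrow(x)) stop("n_groups exceeds the number of items")
  d <- stats::dist(x)
  hc <- stats::hclust(if (variant == "ward.D") d^2 else d, method = variant)
  structure(list(hclust = hc,
                 labels = stats::cutree(hc, k = n_groups),
                 n_groups = n_groups,
                 cophenetic_cor = suppressWarnings(
                   stats::cor(d, stats::cophenetic(hc))),
                 variant = variant),
            class = "ward_cluster")
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat(sprintf("Ward clustering (%s): %d items cut into %d group(s)\n",
              x$variant, length(x$labels), x$n_groups))
  cat(sprintf("cophenetic correlation: %.3f\n", x$cophenetic_cor))
  print(table(x$labels))
  invisible(x)
}

#' @export
plot.ward_cluster <- function(x, ...) {
  plot(x$hclust, ylab = "Euclidean merge height", ...)
  invisible(x)
}

#' Principal component analysis with Kaiser retention
#'
#' Eigen-decomposition of the correlation matrix (default) or covariance
#' matrix. Loadings are reported as variable-component correlations;
#' components with eigenvalue above 1 are retained (Kaiser criterion) and
#' variables with `|loading| >= loading_cutoff` on a retained component
#' are flagged for interpretation. Component signs are fixed so the
#' largest-magnitude loading in each column is positive.
#'
#' @param x numeric matrix or data frame, samples in rows.
#' @param standardize correlation-matrix PCA when `TRUE` (default).
#' @param loading_cutoff absolute-loading interpretation threshold
#'   (default 0.70).
#' @return A `pca_result`: list with `eigenvalues`,
#'   `explained_variance` (percent, summing to 100), `loadings`,
#'   `scores`, `retained` (Kaiser indices) and `interpreted` (named list
#'   of flagged variables per retained component).
#' @examples
#' set.seed(1)
#' pca(matrix(rnorm(100), 20, 5))
#' @export
pca <- function(x, standardize = TRUE, loading_cutoff = 0.70) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop("need n >= 2 and p >= 2")
  sds <- apply(x, 2, stats::sd)
  if (standardize && any(sds == 0)) {
    stop("constant column(s) under standardization: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  C <- if (standardize) stats::cor(x) else stats::cov(x)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors %*% diag(sqrt(ev), length(ev))
  # sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      eig$vectors[, j] <- -eig$vectors[, j]
    }
  }
  vn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  dimnames(load) <- list(vn, paste0("PC", seq_along(ev)))
  xc <- scale(x, center = TRUE, scale = standardize)
  scores <- xc %*% eig$vectors
  colnames(scores) <- colnames(load)
  retained <- which(ev > 1)
  interpreted <- lapply(retained, function(j) {
    vn[abs(load[, j]) >= loading_cutoff]
  })
  names(interpreted) <- colnames(load)[retained]
  structure(list(eigenvalues = ev,
                 explained_variance = 100 * ev / sum(ev),
                 loadings = load, scores = scores,
                 retained = retained, interpreted = interpreted,
                 standardize = standardize,
                 loading_cutoff = loading_cutoff),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, digits = 3, ...) {
  cat(sprintf("PCA on the %s matrix: %d components\n",
              if (x$standardize) "correlation" else "covariance",
              length(x$eigenvalues)))
  tab <- rbind(eigenvalue = x$eigenvalues,
               `explained %` = x$explained_variance)
  colnames(tab) <- colnames(x$loadings)
  print(round(tab, digits))
  cat(sprintf("retained (eigenvalue > 1): %s\n",
              paste(names(x$interpreted), collapse = ", ")))
  for (nm in names(x$interpreted)) {
    cat(sprintf("  %s interprets: %s\n", nm,
                paste(x$interpreted[[nm]], collapse = ", ")))
  }
  invisible(x)
}
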