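#' Variogram model
#'
#' Constructs an isotropic variogram model of kind `spherical`,
#' `exponential` or `gaussian`, parameterized by nugget \eqn{C_0},
#' partial sill \eqn{C_1} and range \eqn{a} (meters). The sill is
#' \eqn{C_0 + C_1}. Exponential and gaussian kinds use the practical
#' range: \eqn{\gamma(a) = C_0 + 0.95 C_1} exactly, so a fitted `a` is
#' comparable across kinds.
#'
#' Model curves (for \eqn{h > 0}; \eqn{\gamma(0) = 0} always):
#' \describe{
#'   \item{spherical}{\eqn{C_0 + C_1[1.5 (h/a) - 0.5 (h/a)^3]} for
#'     \eqn{h \le a}, \eqn{C_0 + C_1} beyond.}
#'   \item{exponential}{\eqn{C_0 + C_1[1 - e^{-\log(20) h / a}]}.}
#'   \item{gaussian}{\eqn{C_0 + C_1[1 - e^{-\log(20) h^2 / a^2}]}.}
#' }
#'
#' @param kind one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget nugget variance \eqn{C_0 \ge 0} (attribute units squared).
#' @param psill partial sill \eqn{C_1 \ge 0} (attribute units squared).
#' @param range_m range \eqn{a > 0} in meters.
#' @param attribute optional attribute name the model belongs to.
#' @param log_transformed logical; `TRUE` when the model was fitted on
#'   natural-log transformed values.
#' @return A `variogram_model` object.
#' @seealso [fit_variogram()], [semivariance()], [krige()]
#' @examples
#' m <- variogram_model("spherical", nugget = 0.2, psill = 1, range_m = 10)
#' semivariance(m, c(0, 5, 10, 20))
#' @export
variogram_model <- function(kind = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range_m,
                            attribute = NULL, log_transformed = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(nugget), is.numeric(psill), is.numeric(range_m))
  if (nugget < 0) stop("nugget must be >= 0, got ", nugget)
  if (psill < 0) stop("partial sill must be >= 0, got ", psill)
  if (range_m <= 0) stop("range must be > 0, got ", range_m)
  structure(
    list(kind = kind, nugget = nugget, psill = psill, range_m = range_m,
         attribute = attribute, log_transformed = isTRUE(log_transformed)),
    class = "variogram_model")
}

#' Model semivariance at given separations
#'
#' Evaluates the variogram model curve \eqn{\gamma(h)}. `predict()` on a
#' `variogram_model` is an alias.
#'
#' @param model a [variogram_model()].
#' @param h numeric vector of separation distances (meters, `>= 0`).
#' @return Numeric vector of semivariances (attribute units squared).
#' @export
semivariance <- function(model, h) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("negative separation distance")
  c0 <- model$nugget; c1 <- model$psill; a <- model$range_m
  g <- switch(model$kind,
    spherical = {
      r <- pmin(h / a, 1)
      c0 + c1 * (1.5 * r - 0.5 * r^3)
    },
    exponential = c0 + c1 * (1 - exp(-log(20) * h / a)),
    gaussian    = c0 + c1 * (1 - exp(-log(20) * h^2 / a^2)))
  g[h == 0] <- 0   # gamma(0) = 0 by convention; nugget is a jump at 0+
  g
}

#' @rdname semivariance
#' @param object a `variogram_model`.
#' @param ... ignored.
#' @export
predict.variogram_model <- function(object, h, ...) semivariance(object, h)

#' @export
coef.variogram_model <- function(object, ...) {
  c(nugget = object$nugget, psill = object$psill, range_m = object$range_m)
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram model%s\n", x$kind,
              if (!is.null(x$attribute)) paste0(" [", x$attribute, "]") else ""))
  cat(sprintf("  nugget C0      = %.6g\n", x$nugget))
  cat(sprintf("  partial sill C1 = %.6g  (sill C0+C1 = %.6g)\n",
              x$psill, x$nugget + x$psill))
  cat(sprintf("  range a        = %.6g m\n", x$range_m))
  if (x$log_transformed) cat("  fitted on natural-log scale\n")
  invisible(x)
}

#' Empirical (experimental) semivariogram
#'
#' Matheron's classical estimator under the intrinsic hypothesis:
#' \deqn{\hat\gamma(h) = \frac{1}{2 N(h)} \sum_{i=1}^{N(h)}
#'   [z(x_i + h) - z(x_i)]^2}
#' computed over point pairs whose separation falls in half-open lag bins
#' of width `bin_width` centered at multiples of `bin_width`. Empty bins
#' are omitted. The reported `dist` is the mean pair separation within
#' the bin (used for model fitting); `center` is the nominal bin center.
#'
#' @param dataset a [point_dataset()].
#' @param attribute attribute column name.
#' @param bin_width lag bin width in meters. Default: the declared grid
#'   spacing, or the minimum pairwise distance.
#' @param max_lag maximum lag in meters. Default: half the maximum
#'   pairwise distance.
#' @return An `empirical_variogram`: a data frame with columns `center`,
#'   `dist`, `gamma`, `npairs`, carrying the attribute name, bin width,
#'   max lag and sample variance as attributes.
#' @examples
#' d <- point_dataset(data.frame(x = c(0, 10), y = c(0, 0), z = c(1, 3)))
#' empirical_variogram(d, "z", bin_width = 10)
#' @export
empirical_variogram <- function(dataset, attribute, bin_width = NULL,
                                max_lag = NULL) {
  z <- get_attribute(dataset, attribute)
  n <- nrow(dataset)
  if (n < 2) stop("need at least 2 points")
  dx <- outer(dataset$x, dataset$x, "-")
  dy <- outer(dataset$y, dataset$y, "-")
  dmat <- sqrt(dx^2 + dy^2)
  up <- upper.tri(dmat)
  d <- dmat[up]
  sqdiff <- (outer(z, z, "-")^2)[up]
  maxd <- max(d)
  if (is.null(bin_width)) {
    bin_width <- attr(dataset, "spacing") %||% min(d[d > 0])
  }
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(max_lag)) max_lag <- maxd / 2
  if (max_lag > maxd) max_lag <- maxd
  keep <- d > 0 & d <= max_lag
  if (!any(keep)) stop("no point pair within max_lag = ", max_lag, " m")
  d <- d[keep]; sqdiff <- sqdiff[keep]
  # half-open bins [k*w - w/2, k*w + w/2) centered at k*w, k = 1, 2, ...
  k <- floor(d / bin_width + 0.5)
  k[k < 1] <- 1
  ks <- sort(unique(k))
  gamma <- vapply(ks, function(j) sum(sqdiff[k == j]) / (2 * sum(k == j)),
                  numeric(1))
  npairs <- vapply(ks, function(j) sum(k == j), integer(1))
  dist <- vapply(ks, function(j) mean(d[k == j]), numeric(1))
  out <- data.frame(center = ks * bin_width, dist = dist,
                    gamma = gamma, npairs = npairs)
  structure(out,
            attribute = attribute, bin_width = bin_width, max_lag = max_lag,
            sample_variance = stats::var(z), n_points = n,
            max_pair_distance = maxd,
            class = c("empirical_variogram", "data.frame"))
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat(sprintf("empirical variogram of '%s': %d bins (width %g m, max lag %g m), %d pairs\n",
              attr(x, "attribute"), nrow(x), attr(x, "bin_width"),
              attr(x, "max_lag"), sum(x$npairs)))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  plot(x$dist, x$gamma, xlab = "lag h (m)",
       ylab = expression(hat(gamma)(h)), ylim = c(0, max(x$gamma) * 1.1),
       xlim = c(0, max(x$dist)), pch = 19,
       main = paste("Variogram:", attr(x, "attribute")), ...)
  if (!is.null(model)) {
    hh <- seq(0, max(x$dist), length.out = 200)
    lines(hh, semivariance(model, hh), col = "steelblue", lwd = 2)
  }
  invisible(x)
}

#' @export
plot.variogram_model <- function(x, max_lag = 2 * x$range_m, ...) {
  hh <- seq(0, max_lag, length.out = 200)
  plot(hh, semivariance(x, hh), type = "l", col = "steelblue", lwd = 2,
       xlab = "lag h (m)", ylab = expression(gamma(h)),
       main = paste(x$kind, "variogram model"), ...)
  invisible(x)
}
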