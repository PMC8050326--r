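#' Ordinary kriging prediction
#'
#' Best linear unbiased prediction \eqn{\hat z(x_0) = \sum_i \lambda_i
#' z(x_i)} with weights solving the ordinary kriging system in its
#' semivariance form: the sample-to-sample semivariance matrix (zero on
#' the diagonal, so data are honored exactly even with a nugget),
#' bordered by the unbiasedness row of ones, with a Lagrange multiplier.
#' Kriging variance is \eqn{\sum_i \lambda_i \gamma(x_i, x_0) + \mu},
#' clamped at zero against roundoff.
#'
#' The neighborhood is global (all samples), appropriate for surveys of
#' around a hundred points.
#'
#' @param dataset a [point_dataset()].
#' @param attribute attribute column to predict.
#' @param model a [variogram_model()].
#' @param targets data frame (or matrix) of target locations with
#'   columns/components `x` and `y` in meters.
#' @param keep_weights logical; retain the weight matrix and Lagrange
#'   multipliers.
#' @return A `kriging` object: list with `x`, `y`, `pred`, `var`, and —
#'   when `keep_weights` — `weights` (targets in rows) and `lagrange`.
#' @examples
#' d <- point_dataset(data.frame(x = c(0, 10), y = c(0, 0), z = c(1, 3)))
#' m <- variogram_model("spherical", 0, 1, 15)
#' krige(d, "z", m, data.frame(x = 5, y = 0))
#' @export
krige <- function(dataset, attribute, model, targets, keep_weights = FALSE) {
  z <- get_attribute(dataset, attribute)
  stopifnot(inherits(model, "variogram_model"))
  targets <- as.data.frame(targets)
  if (!all(c("x", "y") %in% names(targets))) {
    stop("targets must have x and y columns")
  }
  n <- nrow(dataset)
  dup <- duplicated(dataset[c("x", "y")])
  if (any(dup)) {
    stop("duplicate sample coordinates (singular kriging system) at row(s): ",
         paste(which(dup), collapse = ", "))
  }
  xs <- dataset$x; ys <- dataset$y
  if (n == 1) {
    # unbiasedness forces lambda = 1
    g0 <- semivariance(model, sqrt((targets$x - xs)^2 + (targets$y - ys)^2))
    out <- list(x = targets$x, y = targets$y,
                pred = rep(z, nrow(targets)), var = pmax(g0, 0))
    if (keep_weights) {
      out$weights <- matrix(1, nrow(targets), 1)
      out$lagrange <- rep(0, nrow(targets))
    }
    class(out) <- "kriging"
    return(out)
  }
  dmat <- sqrt(outer(xs, xs, "-")^2 + outer(ys, ys, "-")^2)
  A <- rbind(cbind(semivariance(model, dmat), 1), c(rep(1, n), 0))
  diag(A)[seq_len(n)] <- 0
  d0 <- sqrt(outer(xs, targets$x, "-")^2 + outer(ys, targets$y, "-")^2)
  B <- rbind(semivariance(model, d0), 1)
  sol <- tryCatch(solve(A, B), error = function(e)
    stop("singular ordinary kriging system: ", conditionMessage(e)))
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- drop(crossprod(lambda, z))
  kv <- colSums(lambda * B[seq_len(n), , drop = FALSE]) + mu
  kv[kv < 0] <- 0   # numerical floor
  out <- list(x = targets$x, y = targets$y, pred = pred, var = kv)
  if (keep_weights) {
    out$weights <- t(lambda)
    out$lagrange <- mu
  }
  class(out) <- "kriging"
  out
}

#' @export
print.kriging <- function(x, ...) {
  cat(sprintf("ordinary kriging: %d target(s)\n", length(x$pred)))
  print(head(data.frame(x = x$x, y = x$y, pred = x$pred, var = x$var), 10))
  if (length(x$pred) > 10) cat("...\n")
  invisible(x)
}

#' Raster grid container
#'
#' Regular raster with origin at the lower-left cell *corner*, square or
#' rectangular cells, values stored as a matrix with rows running north
#' to south (row 1 = top), the ESRI ASCII grid convention.
#'
#' @param origin numeric length-2, lower-left corner `(x0, y0)` (meters).
#' @param cell_size cell edge length (meters), `> 0`.
#' @param values numeric matrix (`n_rows` x `n_cols`), `NA` = nodata.
#' @return A `raster_grid` object.
#' @export
raster_grid <- function(origin, cell_size, values) {
  stopifnot(length(origin) == 2, is.matrix(values))
  if (cell_size <= 0) stop("cell_size must be > 0")
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_rows = nrow(values), n_cols = ncol(values),
                 values = values),
            class = "raster_grid")
}

#' Cell-center coordinates of a raster grid
#'
#' @param raster a [raster_grid()].
#' @return Data frame of `x`, `y` cell centers, one row per cell, in
#'   row-major north-to-south order matching `as.vector(t(values))`.
#' @export
raster_cell_centers <- function(raster) {
  stopifnot(inherits(raster, "raster_grid"))
  cs <- raster$cell_size
  xc <- raster$origin[1] + (seq_len(raster$n_cols) - 0.5) * cs
  # row 1 is the northernmost row
  yc <- raster$origin[2] + (raster$n_rows - seq_len(raster$n_rows) + 0.5) * cs
  data.frame(x = rep(xc, times = raster$n_rows),
             y = rep(yc, each = raster$n_cols))
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells of %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("values: [%.4g, %.4g], %d nodata cell(s)\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, main = "kriged map", ...) {
  cs <- x$cell_size
  xc <- x$origin[1] + (seq_len(x$n_cols) - 0.5) * cs
  yc <- x$origin[2] + (seq_len(x$n_rows) - 0.5) * cs
  image(xc, yc, t(x$values[x$n_rows:1, , drop = FALSE]),
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "x (m)", ylab = "y (m)", main = main, asp = 1, ...)
  invisible(x)
}

#' Ordinary kriging map on a raster
#'
#' Predicts each raster cell center by [krige()].
#'
#' @inheritParams krige
#' @param cell_size raster resolution in meters (default 1 m).
#' @param origin lower-left corner; defaults to half a cell below the
#'   data extent minimum, so that sample locations on a whole-meter
#'   lattice fall on cell centers.
#' @param extent numeric length-2 `(width, height)` in meters; defaults
#'   to the data span plus one cell.
#' @return List with `prediction` and `variance`, both [raster_grid()]s.
#' @export
krige_map <- function(dataset, attribute, model, cell_size = 1,
                      origin = NULL, extent = NULL) {
  if (is.null(origin)) {
    origin <- c(min(dataset$x) - cell_size / 2, min(dataset$y) - cell_size / 2)
  }
  if (is.null(extent)) {
    extent <- c(max(dataset$x) + cell_size / 2 - origin[1],
                max(dataset$y) + cell_size / 2 - origin[2])
  }
  n_cols <- max(1L, as.integer(ceiling(extent[1] / cell_size)))
  n_rows <- max(1L, as.integer(ceiling(extent[2] / cell_size)))
  template <- raster_grid(origin, cell_size,
                          matrix(NA_real_, n_rows, n_cols))
  centers <- raster_cell_centers(template)
  kr <- krige(dataset, attribute, model, centers)
  pred <- matrix(kr$pred, n_rows, n_cols, byrow = TRUE)
  kvar <- matrix(kr$var, n_rows, n_cols, byrow = TRUE)
  list(prediction = raster_grid(origin, cell_size, pred),
       variance = raster_grid(origin, cell_size, kvar))
}

#' Leave-one-out cross-validation RMSE of a kriging model
#'
#' Each sample is held out in turn and predicted by ordinary kriging from
#' the remaining samples; RMSE of observed minus predicted is returned in
#' attribute units.
#'
#' @inheritParams krige
#' @return Scalar RMSE.
#' @export
loo_rmse <- function(dataset, attribute, model) {
  z <- get_attribute(dataset, attribute)
  n <- nrow(dataset)
  if (n < 3) stop("need at least 3 samples for cross-validation")
  err <- vapply(seq_len(n), function(i) {
    kr <- krige(point_dataset(as.data.frame(dataset)[-i, , drop = FALSE]),
                attribute, model, dataset[i, c("x", "y")])
    z[i] - kr$pred
  }, numeric(1))
  sqrt(mean(err^2))
}
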