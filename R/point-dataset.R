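#' Georeferenced point survey table
#'
#' A `point_dataset` is a data frame with planar coordinates `x`, `y`
#' (meters, origin at the survey's southwest corner) and one numeric
#' column per soil attribute. Coordinates must be unique: duplicate
#' sampling locations make kriging systems singular.
#'
#' @param data data frame containing numeric `x` and `y` columns plus
#'   attribute columns.
#' @param spacing optional declared minimum grid spacing in meters.
#' @return A `point_dataset` (also a `data.frame`).
#' @examples
#' d <- point_dataset(data.frame(x = c(0, 10), y = c(0, 0), z = c(1, 3)))
#' attribute_names(d)
#' @export
point_dataset <- function(data, spacing = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame")
  miss <- setdiff(c("x", "y"), names(data))
  if (length(miss)) {
    stop("missing coordinate column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(data$x) || !is.numeric(data$y)) {
    stop("coordinates `x` and `y` must be numeric")
  }
  dup <- duplicated(data[c("x", "y")])
  if (any(dup)) {
    stop("duplicate coordinates at row(s): ",
         paste(which(dup), collapse = ", "))
  }
  attr_cols <- setdiff(names(data), c("x", "y"))
  bad <- attr_cols[!vapply(data[attr_cols], is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric attribute column(s): ",
                        paste(bad, collapse = ", "))
  out <- as.data.frame(data)
  attr(out, "spacing") <- spacing
  class(out) <- c("point_dataset", "data.frame")
  out
}

#' @export
print.point_dataset <- function(x, ...) {
  cat(sprintf("point_dataset: %d points, %d attribute(s)\n",
              nrow(x), length(attribute_names(x))))
  sp <- attr(x, "spacing")
  if (!is.null(sp)) cat(sprintf("declared grid spacing: %g m\n", sp))
  cat(sprintf("extent: x [%g, %g] m, y [%g, %g] m\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  cat("attributes:", paste(attribute_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' Attribute columns of a point dataset
#'
#' @param dataset a [point_dataset()] (or plain data frame with x/y).
#' @return Character vector of attribute column names (everything except
#'   the coordinates).
#' @export
attribute_names <- function(dataset) {
  setdiff(names(dataset), c("x", "y"))
}

get_attribute <- function(dataset, attribute) {
  if (!attribute %in% names(dataset)) {
    stop("unknown attribute: ", attribute)
  }
  v <- dataset[[attribute]]
  if (anyNA(v) || any(!is.finite(v))) {
    stop("attribute '", attribute, "' contains missing or non-finite values")
  }
  v
}
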