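#' Read and write point survey CSVs
#'
#' Comma-separated, period decimal (locale-fixed), header row with `x`,
#' `y` plus attribute names. Values are written with 10 significant
#' digits so a write-read round trip is an identity for survey-scale
#' magnitudes.
#'
#' @param path file path.
#' @param strict error on duplicate coordinates (default `TRUE`); when
#'   `FALSE` duplicates only warn and the dataset is returned as a plain
#'   data frame.
#' @return `read_point_csv()` returns a [point_dataset()];
#'   `write_point_csv()` returns `path` invisibly.
#' @export
read_point_csv <- function(path, strict = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("x", "y"), names(tab))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- names(tab)[!vapply(tab, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric cells in column(s): ", paste(bad, collapse = ", "))
  }
  dup <- duplicated(tab[c("x", "y")])
  if (any(dup) && !strict) {
    warning("duplicate coordinates at row(s): ",
            paste(which(dup), collapse = ", "))
    return(tab)
  }
  point_dataset(tab)
}

#' @rdname read_point_csv
#' @param dataset a [point_dataset()] (or plain data frame with x/y).
#' @export
write_point_csv <- function(dataset, path) {
  out <- as.data.frame(dataset)
  out[] <- lapply(out, function(v) signif(v, 10))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ESRI ASCII grids
#'
#' The 6-line-header ASCII raster dialect (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) with row-major values north
#' to south, matching the [raster_grid()] storage order.
#'
#' @param raster a [raster_grid()].
#' @param path file path.
#' @param nodata nodata marker written for `NA` cells.
#' @return `read_ascii_grid()` returns a [raster_grid()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "raster_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", raster$n_cols),
               sprintf("nrows %d", raster$n_rows),
               sprintf("xllcorner %.10g", raster$origin[1]),
               sprintf("yllcorner %.10g", raster$origin[2]),
               sprintf("cellsize %.10g", raster$cell_size),
               sprintf("NODATA_value %.10g", nodata)), con)
  v <- raster$values
  v[is.na(v)] <- nodata
  writeLines(apply(v, 1, function(r) paste(sprintf("%.10g", r),
                                           collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed ASCII grid: fewer than 7 lines")
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2])))) {
      stop("malformed ASCII grid header at line ", i, ": '", lines[i], "'")
    }
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) stop("ASCII grid header lacks: ",
                         paste(miss, collapse = ", "))
  if (hdr$cellsize <= 0) stop("invalid cellsize ", hdr$cellsize,
                              " at line ", which(need == "cellsize"))
  vals <- lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  vals <- vals[lengths(vals) > 0]
  if (length(vals) != hdr$nrows ||
      any(lengths(vals) != hdr$ncols)) {
    stop("ASCII grid body does not match nrows x ncols = ",
         hdr$nrows, " x ", hdr$ncols)
  }
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA_real_
  raster_grid(c(hdr$xllcorner, hdr$yllcorner), hdr$cellsize, m)
}
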