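#' Spatial dependence index (SDI)
#'
#' Classifies the strength of spatial dependence of a fitted variogram as
#' weak, moderate or strong. The index combines the structured-variance
#' share, the range relative to half the maximum sampling distance, and a
#' model-specific factor:
#' \deqn{SDI\% = MF \cdot \frac{C_1}{C_0 + C_1} \cdot
#'   \frac{\min(a, 0.5 MD)}{0.5 MD} \cdot 100}
#' with default model factors 0.375 (spherical), 0.317 (exponential),
#' 0.504 (gaussian) and default class thresholds: weak when
#' \eqn{SDI \le 7}, moderate when \eqn{7 < SDI \le 15}, strong above.
#' A pure-nugget model (or \eqn{C_0 + C_1 = 0}) has SDI 0 and class weak.
#'
#' @param model a [variogram_model()].
#' @param max_distance maximum distance MD between sampling points
#'   (meters); for a regular grid this is the grid diagonal.
#' @param model_factors named numeric vector of model factors.
#' @param thresholds numeric length-2 vector `c(weak_max, moderate_max)`
#'   in percent.
#' @return An `sdi` object: list with `sdi_percent`, `class`
#'   (`"weak"`/`"moderate"`/`"strong"`), `model_factor`, `max_distance`
#'   and `thresholds`.
#' @examples
#' m <- variogram_model("spherical", 0.156, 0.257 - 0.156, 26.74)
#' spatial_dependence_index(m, max_distance = 127.28)
#' @export
spatial_dependence_index <- function(model, max_distance,
                                     model_factors = c(spherical = 0.375,
                                                       exponential = 0.317,
                                                       gaussian = 0.504),
                                     thresholds = c(7, 15)) {
  stopifnot(inherits(model, "variogram_model"), max_distance > 0,
            length(thresholds) == 2, thresholds[1] < thresholds[2])
  mf <- model_factors[[model$kind]]
  if (is.null(mf)) stop("no model factor for kind ", model$kind)
  sill <- model$nugget + model$psill
  half_md <- max_distance / 2
  sdi <- if (sill == 0) 0 else {
    mf * (model$psill / sill) * (min(model$range_m, half_md) / half_md) * 100
  }
  cls <- if (sdi <= thresholds[1]) "weak"
         else if (sdi <= thresholds[2]) "moderate" else "strong"
  structure(list(sdi_percent = sdi, class = cls, model_factor = mf,
                 max_distance = max_distance, thresholds = thresholds,
                 attribute = model$attribute),
            class = "sdi")
}

#' @export
print.sdi <- function(x, ...) {
  cat(sprintf("SDI%s = %.2f%% -> %s spatial dependence (MD = %g m)\n",
              if (!is.null(x$attribute)) paste0(" [", x$attribute, "]") else "",
              x$sdi_percent, x$class, x$max_distance))
  invisible(x)
}
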