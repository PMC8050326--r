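#' Derived soil-carbon and pore-space quantities
#'
#' Computes, vectorized over records:
#' * `TOC` (g kg-1) = `SOM / 1.724` (Van Bemmelen factor);
#' * `Cstock` (Mg ha-1) = `TOC * Ds * depth / 10` with `Ds` in g cm-3 and
#'   `depth` in cm;
#' * `C_CO2` (Mg C ha-1 d-1), the daily carbon emission: `FCO2` in
#'   umol CO2 m-2 s-1 times 86400 s, times 12 g C mol-1, times 1e-6
#'   (umol to mol), times 0.01 (g m-2 to Mg ha-1) — carbon mass, not CO2
#'   mass, since the decay constant relates emitted carbon to stored
#'   carbon;
#' * `k` (d-1) = `C_CO2 / Cstock`, the soil carbon decay constant;
#' * `Macro` (%) = `TPV - Micro`;
#' * `AFPS` (%) = `TPV - Ms` (air-filled pore space).
#'
#' Only the outputs whose inputs are present are returned, so the
#' function can be applied to partial records.
#'
#' @param SOM soil organic matter (g dm-3).
#' @param Ds soil bulk density (g cm-3), `> 0`.
#' @param FCO2 soil CO2 efflux (umol m-2 s-1).
#' @param TPV total pore volume (%).
#' @param Micro microporosity (%).
#' @param Ms soil moisture / water-filled porosity (%).
#' @param depth soil layer depth (cm), default 20.
#' @return Data frame of the derivable quantities.
#' @examples
#' derive_attributes(SOM = 32.17, Ds = 1.33, FCO2 = 2.91)
#' @export
derive_attributes <- function(SOM = NULL, Ds = NULL, FCO2 = NULL,
                              TPV = NULL, Micro = NULL, Ms = NULL,
                              depth = 20) {
  if (depth <= 0) stop("depth must be > 0")
  out <- list()
  if (!is.null(SOM)) out$TOC <- SOM / 1.724
  if (!is.null(out$TOC) && !is.null(Ds)) {
    if (any(Ds <= 0)) stop("bulk density must be > 0")
    out$Cstock <- out$TOC * Ds * depth / 10
  }
  if (!is.null(FCO2)) {
    out$C_CO2 <- FCO2 * 1e-6 * 12 * 86400 * 0.01
  }
  if (!is.null(out$C_CO2) && !is.null(out$Cstock)) {
    if (any(out$Cstock == 0 & out$C_CO2 != 0)) {
      stop("decay constant undefined: zero carbon stock with nonzero flux")
    }
    out$k <- ifelse(out$Cstock == 0, 0, out$C_CO2 / out$Cstock)
  }
  if (!is.null(TPV) && !is.null(Micro)) {
    if (any(TPV < Micro)) stop("TPV < microporosity: negative macroporosity")
    out$Macro <- TPV - Micro
  }
  if (!is.null(TPV) && !is.null(Ms)) {
    if (any(TPV < Ms)) stop("TPV < soil moisture: negative air-filled pore space")
    out$AFPS <- TPV - Ms
  }
  as.data.frame(out)
}

#' Append derived quantities to a point dataset
#'
#' Column-wise application of [derive_attributes()] over a
#' [point_dataset()]: every derivable quantity whose inputs are present
#' as columns is appended as a new column.
#'
#' Columns already present in the dataset (e.g. measured or simulated
#' macroporosity) are kept, not recomputed, so a survey that records a
#' quantity directly is never overwritten by its arithmetic counterpart.
#'
#' @param dataset a [point_dataset()] with some of the columns `SOM`,
#'   `Ds`, `FCO2`, `TPV`, `Micro`, `Ms`.
#' @param depth soil layer depth (cm).
#' @return The dataset with derived columns appended.
#' @export
add_derived_attributes <- function(dataset, depth = 20) {
  pick <- function(nm) if (nm %in% names(dataset)) dataset[[nm]] else NULL
  want_pore <- function(out_nm) !out_nm %in% names(dataset)
  der <- derive_attributes(SOM = pick("SOM"), Ds = pick("Ds"),
                           FCO2 = pick("FCO2"),
                           TPV = if (want_pore("Macro") || want_pore("AFPS"))
                                   pick("TPV") else NULL,
                           Micro = if (want_pore("Macro")) pick("Micro")
                                   else NULL,
                           Ms = if (want_pore("AFPS")) pick("Ms") else NULL,
                           depth = depth)
  for (nm in setdiff(names(der), names(dataset))) dataset[[nm]] <- der[[nm]]
  dataset
}

#' Descriptive summary with CV classification
#'
#' Mean, standard error, SD, range, coefficient of variation and
#' higher moments of a numeric sample. The CV (%) is classified after
#' Warrick-Nielsen: low below 12%, moderate from 12% to 24% (closed
#' interval), high above 24%. Skewness and kurtosis use the
#' small-sample-adjusted conventions (kurtosis is excess kurtosis,
#' normal = 0):
#' \deqn{G_1 = \frac{\sqrt{n(n-1)}}{n-2} \frac{m_3}{m_2^{3/2}}, \quad
#'   G_2 = \frac{n-1}{(n-2)(n-3)}\left[(n+1)\left(\frac{m_4}{m_2^2} -
#'   3\right) + 6\right]}
#'
#' @param values numeric vector, `n >= 2`, finite.
#' @param cv_thresholds length-2 vector of CV class bounds (percent).
#' @return A one-row data frame with `n`, `mean`, `se`, `sd`, `min`,
#'   `max`, `cv`, `skewness`, `kurtosis`, `cv_class`.
#' @examples
#' describe(c(2.1, 2.9, 3.4, 2.6, 3.1))
#' @export
describe <- function(values, cv_thresholds = c(12, 24)) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("values contain missing or non-finite entries")
  }
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0 && s > 0) stop("CV undefined: zero mean with nonzero SD")
  cv <- if (s == 0) 0 else 100 * s / m
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  if (m2 == 0) {
    skew <- 0; kurt <- 0
  } else {
    skew <- if (n > 2) sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5 else NA_real_
    kurt <- if (n > 3) {
      (n - 1) / ((n - 2) * (n - 3)) * ((n + 1) * (m4 / m2^2 - 3) + 6)
    } else NA_real_
  }
  cls <- if (cv < cv_thresholds[1]) "low"
         else if (cv <= cv_thresholds[2]) "moderate" else "high"
  data.frame(n = n, mean = m, se = s / sqrt(n), sd = s,
             min = min(values), max = max(values), cv = cv,
             skewness = skew, kurtosis = kurt, cv_class = cls,
             stringsAsFactors = FALSE)
}

#' Descriptive summary table for all attributes of a dataset
#'
#' @param dataset a [point_dataset()].
#' @param attributes attribute names (default: all).
#' @return Data frame, one [describe()] row per attribute.
#' @export
describe_dataset <- function(dataset, attributes = attribute_names(dataset)) {
  rows <- lapply(attributes, function(a) {
    cbind(attribute = a, describe(get_attribute(dataset, a)))
  })
  do.call(rbind, rows)
}
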