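#' Simulate a Gaussian random field on grid points
#'
#' Draws one (or several) stationary Gaussian field(s) whose variogram is
#' the supplied model: the covariance between two points at separation
#' \eqn{h > 0} is \eqn{C(h) = (C_0 + C_1) - \gamma(h)} and the marginal
#' variance (diagonal) is the full sill \eqn{C_0 + C_1}, i.e. the nugget
#' sits on the diagonal. Sampling is by exact Cholesky factorization of
#' the assembled covariance — no spectral truncation — which is cheap for
#' survey-sized grids (around a hundred points).
#'
#' @param grid data frame with `x`, `y` coordinates (meters), or a
#'   [point_dataset()].
#' @param model a [variogram_model()].
#' @param mean field mean (attribute units).
#' @param seed optional integer seed (local RNG; the caller's RNG stream
#'   is untouched when supplied).
#' @param n number of independent replicate fields.
#' @return Numeric vector of length `nrow(grid)` (or a matrix with `n`
#'   columns when `n > 1`).
#' @examples
#' g <- expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10))
#' m <- variogram_model("spherical", 0.15, 0.10, 27)
#' z <- simulate_grf(g, m, mean = 2.91, seed = 1)
#' @export
simulate_grf <- function(grid, model, mean = 0, seed = NULL, n = 1) {
  stopifnot(inherits(model, "variogram_model"))
  npts <- nrow(grid)
  sill <- model$nugget + model$psill
  draw <- function() {
    if (sill == 0) {
      matrix(mean, npts, n)
    } else {
      dmat <- sqrt(outer(grid$x, grid$x, "-")^2 +
                   outer(grid$y, grid$y, "-")^2)
      S <- sill - semivariance(model, dmat)
      diag(S) <- sill
      L <- tryCatch(chol(S), error = function(e)
        stop(sprintf(paste0("covariance from %s(C0=%g, C1=%g, a=%g) is not ",
                            "positive definite: %s"),
                     model$kind, model$nugget, model$psill, model$range_m,
                     conditionMessage(e)), call. = FALSE))
      mean + crossprod(L, matrix(rnorm(npts * n), npts, n))
    }
  }
  z <- if (is.null(seed)) draw() else withr_seed(seed, draw())
  if (n == 1) drop(z) else z
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Survey generator configuration
#'
#' Describes a regular survey grid and the attribute fields to simulate
#' on it. Each attribute carries a target mean, a variogram model on its
#' simulation scale and, optionally, a correlation with a designated
#' driver attribute; attributes flagged `log_transformed` are simulated
#' as log-gaussian fields whose *arithmetic* mean matches the target
#' (moment matching).
#'
#' @param extent grid extent in meters (square), an integer multiple of
#'   `spacing`.
#' @param spacing grid spacing in meters, `> 0`.
#' @param attributes list of attribute specifications; each a list with
#'   `name`, `mean`, `model` (a [variogram_model()]) and optionally
#'   `cor_with` (driver attribute name) and `cor` in `[-1, 1]`.
#'   Default: the soil-survey attribute set of
#'   [default_survey_attributes()].
#' @param seed integer seed.
#' @return A `survey_config` object.
#' @seealso [simulate_survey()]
#' @export
survey_config <- function(extent = 90, spacing = 10,
                          attributes = default_survey_attributes(),
                          seed = 1L) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (abs(extent / spacing - round(extent / spacing)) > 1e-9) {
    stop("extent must be an integer multiple of spacing")
  }
  nm <- vapply(attributes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate attribute names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  for (a in attributes) {
    stopifnot(inherits(a$model, "variogram_model"))
    if (!is.null(a$cor)) {
      if (abs(a$cor) > 1) stop("correlation magnitude > 1 for ", a$name)
      if (is.null(a$cor_with) || !a$cor_with %in% nm) {
        stop("cor_with must name another configured attribute for ", a$name)
      }
    }
  }
  structure(list(extent = extent, spacing = spacing,
                 attributes = attributes, seed = as.integer(seed)),
            class = "survey_config")
}

#' Default survey attribute specifications
#'
#' Attribute set emulating a post-reform sugarcane survey: means from the
#' packaged descriptive-summary table and variogram models from the
#' packaged variogram table (see [soil_summary_table()] and
#' [soil_variogram_table()]). FCO2 acts as the driver field; soil organic
#' matter, macroporosity, air-filled pore space and silt — the attributes
#' whose maps co-vary with FCO2 in this kind of survey — are generated
#' with a positive correlation to it.
#'
#' @param names optional subset of attribute names to keep.
#' @param driver_correlations named numeric vector of correlations with
#'   the FCO2 driver field.
#' @return List of attribute specifications for [survey_config()].
#' @export
default_survey_attributes <- function(names = NULL,
                                      driver_correlations = c(SOM = 0.7,
                                                              Macro = 0.7,
                                                              AFPS = 0.7,
                                                              Silt = 0.6)) {
  vt <- soil_variogram_table()
  st <- soil_summary_table()
  common <- intersect(vt$attribute, st$attribute)
  if (!is.null(names)) common <- intersect(common, names)
  specs <- lapply(common, function(nm) {
    vrow <- vt[vt$attribute == nm, ]
    srow <- st[st$attribute == nm, ]
    spec <- list(
      name = nm, mean = srow$mean,
      model = variogram_model(vrow$model, vrow$nugget,
                              max(vrow$sill - vrow$nugget, 0), vrow$range_m,
                              attribute = nm,
                              log_transformed = vrow$log_transformed))
    if (nm %in% base::names(driver_correlations) && nm != "FCO2" &&
        "FCO2" %in% common) {
      spec$cor_with <- "FCO2"
      spec$cor <- unname(driver_correlations[[nm]])
    }
    spec
  })
  stats::setNames(specs, common)
}

#' Simulate a point survey
#'
#' Generates a [point_dataset()] on the configured regular grid: one
#' gaussian (or log-gaussian) field per attribute with the configured
#' variogram. A correlated attribute is built as a linear mixture of the
#' standardized driver field and an independent field with the
#' attribute's own variogram, so its marginal spatial structure is
#' preserved while the pointwise correlation with the driver equals the
#' requested coefficient in expectation.
#'
#' @param config a [survey_config()].
#' @param seed optional override of the config seed.
#' @return A [point_dataset()] with `extent/spacing + 1` points per side.
#' @examples
#' d <- simulate_survey(survey_config(seed = 42))
#' nrow(d)  # 100 points on the default 90 x 90 m / 10 m grid
#' @export
simulate_survey <- function(config, seed = NULL) {
  stopifnot(inherits(config, "survey_config"))
  seed <- seed %||% config$seed
  coords <- expand.grid(
    x = seq(0, config$extent, by = config$spacing),
    y = seq(0, config$extent, by = config$spacing))
  withr_seed(seed, {
    fields <- list()
    for (a in config$attributes) {
      m <- a$model
      sill <- m$nugget + m$psill
      raw <- simulate_grf(coords, m, mean = 0)   # zero-mean structure field
      if (!is.null(a$cor)) {
        drv <- fields[[a$cor_with]]$raw
        if (is.null(drv)) {
          stop("driver attribute '", a$cor_with,
               "' must be configured before '", a$name, "'")
        }
        zd <- if (stats::sd(drv) > 0) (drv - base::mean(drv)) / stats::sd(drv)
              else drv * 0
        zi <- if (stats::sd(raw) > 0) (raw - base::mean(raw)) / stats::sd(raw)
              else raw * 0
        mixed <- a$cor * zd + sqrt(1 - a$cor^2) * zi
        raw <- mixed * sqrt(sill)
      }
      if (m$log_transformed) {
        # log-gaussian field whose arithmetic mean hits the target
        if (a$mean <= 0) stop("log-transformed attribute '", a$name,
                              "' needs a positive target mean")
        mu <- log(a$mean) - sill / 2
        vals <- exp(mu + raw)
      } else {
        vals <- a$mean + raw
      }
      fields[[a$name]] <- list(raw = raw, vals = vals)
    }
    out <- coords
    for (nm in names(fields)) out[[nm]] <- fields[[nm]]$vals
    point_dataset(out, spacing = config$spacing)
  })
}

#' Two-region microbiology generator configuration
#'
#' Per-variable group means and standard errors of the mean for regions
#' R1 and R2, with a per-variable distribution family (`normal` or
#' `lognormal`; log-normal variables are moment-matched so the arithmetic
#' mean and SE equal the targets).
#'
#' @param variables data frame with columns `variable`, `family`,
#'   `r1_mean`, `r1_se`, `r2_mean`, `r2_se`. Default: the packaged
#'   two-region reference of [microbiology_reference()].
#' @param n_per_group composite samples per region (default 9).
#' @param seed integer seed.
#' @return A `microbiology_config` object.
#' @export
microbiology_config <- function(variables = microbiology_reference(),
                                n_per_group = 9, seed = 1L) {
  need <- c("variable", "family", "r1_mean", "r1_se", "r2_mean", "r2_se")
  miss <- setdiff(need, names(variables))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (n_per_group < 2) stop("need at least 2 samples per group")
  if (any(variables$r1_se < 0 | variables$r2_se < 0)) {
    stop("standard errors must be >= 0")
  }
  if (!all(variables$family %in% c("normal", "lognormal"))) {
    stop("family must be 'normal' or 'lognormal'")
  }
  bad <- variables$family == "lognormal" &
    (variables$r1_mean <= 0 | variables$r2_mean <= 0)
  if (any(bad)) {
    stop("log-normal family needs positive means: ",
         paste(variables$variable[bad], collapse = ", "))
  }
  structure(list(variables = as.data.frame(variables),
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "microbiology_config")
}

#' Simulate a two-region microbiology table
#'
#' Draws `n_per_group` composite samples per region for every configured
#' variable. Normal variables are drawn with SD = SE * sqrt(n);
#' log-normal variables are moment-matched to the target arithmetic mean
#' and SD.
#'
#' @param config a [microbiology_config()].
#' @param seed optional override of the config seed.
#' @return Data frame with a `region` factor (`R1`/`R2`) and one column
#'   per variable; `2 * n_per_group` rows.
#' @examples
#' tab <- simulate_microbiology(microbiology_config(seed = 7))
#' table(tab$region)
#' @export
simulate_microbiology <- function(config, seed = NULL) {
  stopifnot(inherits(config, "microbiology_config"))
  seed <- seed %||% config$seed
  n <- config$n_per_group
  vars <- config$variables
  withr_seed(seed, {
    out <- data.frame(region = factor(rep(c("R1", "R2"), each = n)))
    for (i in seq_len(nrow(vars))) {
      draw_group <- function(m, se) {
        s <- se * sqrt(n)
        if (vars$family[i] == "lognormal") {
          if (s == 0) return(rep(m, n))
          sig2 <- log(1 + (s / m)^2)
          stats::rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
        } else {
          stats::rnorm(n, m, s)
        }
      }
      out[[vars$variable[i]]] <- c(draw_group(vars$r1_mean[i], vars$r1_se[i]),
                                   draw_group(vars$r2_mean[i], vars$r2_se[i]))
    }
    out
  })
}
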