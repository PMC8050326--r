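#' Pipeline configuration
#'
#' Assembles (with defaults) or validates the configuration driving
#' [run_pipeline()]. Every source of randomness flows from the single
#' `seed`. The configuration is a plain nested list, so it can be stored
#' as YAML (see [read_pipeline_config()]).
#'
#' @param seed integer seed for the whole run.
#' @param input optional path to a point CSV ([read_point_csv()]); when
#'   `NULL` a survey is simulated from `survey`.
#' @param survey list: `extent`, `spacing`, `attributes` (names drawn
#'   from the packaged reference tables).
#' @param variography list: `bin_width`, `max_lag` (`NULL` = defaults),
#'   `kinds` (candidate model kinds), `weighting`.
#' @param sdi list: `model_factors`, `thresholds`.
#' @param kriging list: `cell_size` (meters).
#' @param regions list: `attribute`, `low_band`, `high_band`.
#' @param comparison list: `alpha`, `n_per_group`.
#' @param depth_cm soil layer depth for derived quantities.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            input = NULL,
                            survey = list(),
                            variography = list(),
                            sdi = list(),
                            kriging = list(),
                            regions = list(),
                            comparison = list(),
                            depth_cm = 20) {
  cfg <- list(
    seed = as.integer(seed),
    input = input,
    survey = modifyList(list(extent = 90, spacing = 10,
                             attributes = c("FCO2", "SOM", "Macro", "AFPS",
                                            "TPV", "Micro", "Ds", "Ms")),
                        survey),
    variography = modifyList(list(bin_width = NULL, max_lag = NULL,
                                  kinds = c("spherical", "exponential",
                                            "gaussian"),
                                  weighting = "npairs"),
                             variography),
    sdi = modifyList(list(model_factors = c(spherical = 0.375,
                                            exponential = 0.317,
                                            gaussian = 0.504),
                          thresholds = c(7, 15)),
                     sdi),
    kriging = modifyList(list(cell_size = 1), kriging),
    regions = modifyList(list(attribute = "FCO2",
                              low_band = c(1.9, 2.7),
                              high_band = c(2.9, 4.2)),
                         regions),
    comparison = modifyList(list(alpha = 0.01, n_per_group = 9), comparison),
    depth_cm = depth_cm)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the [pipeline_config()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in c("sdi", "survey", "variography", "kriging", "regions",
              "comparison")) {
    if (!is.null(raw[[k]])) raw[[k]] <- lapply(raw[[k]], unlist)
  }
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full geostatistical pipeline
#'
#' Chains every stage from one configuration: survey input (read or
#' simulated), derived soil-carbon quantities, descriptive statistics,
#' variography with model selection and SDI classification per attribute,
#' ordinary-kriging maps with leave-one-out cross-validation, region
#' delineation on the kriged emission map, the simulated two-region
#' microbiology comparison (pooled t per variable and Hotelling's T2),
#' Ward clustering and correlation-matrix PCA of the region samples.
#'
#' Deterministic for a fixed configuration and seed. Every run writes a
#' `MANIFEST.json` with the package version, configuration hash and the
#' stage that produced each file. Attributes flagged as log-transformed
#' in the packaged variogram table are analyzed (variography, kriging)
#' on the natural-log scale and their maps are reported on that scale.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param outdir output directory, created if missing.
#' @return Invisibly, a list with every stage's results and `outdir`.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1), tempfile("run"))
#' res$sdi_table
#' }
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_path <- file.path(outdir, "log.txt")
  cat("", file = log_path)
  note <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  emit <- function(stage, file) {
    manifest[[file]] <<- stage
    file.path(outdir, file)
  }

  # ---- validation --------------------------------------------------------
  atts <- config$survey$attributes
  if (!config$regions$attribute %in% atts) {
    stop_stage("validate", "regions.attribute '", config$regions$attribute,
               "' is not among the survey attributes")
  }
  vt <- soil_variogram_table()
  unknown <- setdiff(atts, vt$attribute)
  if (is.null(config$input) && length(unknown)) {
    stop_stage("validate", "no generator parameters for attribute(s): ",
               paste(unknown, collapse = ", "))
  }

  # ---- input -------------------------------------------------------------
  if (!is.null(config$input)) {
    dataset <- read_point_csv(config$input)
    note("input", "read %d points from %s", nrow(dataset), config$input)
  } else {
    sc <- survey_config(extent = config$survey$extent,
                        spacing = config$survey$spacing,
                        attributes = default_survey_attributes(atts),
                        seed = config$seed)
    dataset <- simulate_survey(sc)
    note("simulate", "simulated %d points, %d attributes (seed %d)",
         nrow(dataset), length(attribute_names(dataset)), config$seed)
  }
  dataset <- add_derived_attributes(dataset, depth = config$depth_cm)
  write_point_csv(dataset, emit("input", "points.csv"))

  # ---- descriptive statistics -------------------------------------------
  summary_tab <- describe_dataset(dataset)
  write.csv(summary_tab, emit("describe", "summary.csv"), row.names = FALSE)
  note("describe", "descriptive statistics for %d attributes",
       nrow(summary_tab))

  # ---- variography -------------------------------------------------------
  md <- max(dist(dataset[c("x", "y")]))
  log_flags <- setNames(vt$log_transformed, vt$attribute)
  dir.create(file.path(outdir, "variograms"), showWarnings = FALSE)
  models <- list(); sdi_rows <- list()
  for (att in atts) {
    work <- dataset
    col <- att
    if (isTRUE(log_flags[[att]])) {
      if (any(work[[att]] <= 0)) {
        stop_stage("variogram", "cannot log-transform '", att,
                   "': non-positive values")
      }
      col <- paste0("log_", att)
      work[[col]] <- log(work[[att]])
    }
    ev <- empirical_variogram(work, col,
                              bin_width = config$variography$bin_width,
                              max_lag = config$variography$max_lag)
    write.csv(as.data.frame(ev),
              emit("variogram", file.path("variograms",
                                          paste0(att, "_bins.csv"))),
              row.names = FALSE)
    cands <- lapply(config$variography$kinds, function(k) {
      fit_variogram(ev, k, weighting = config$variography$weighting,
                    dataset = point_dataset(
                      work[c("x", "y", col)],
                      spacing = attr(dataset, "spacing")))
    })
    sel <- select_model(cands)
    best <- sel$best
    best$attribute <- att
    best$log_transformed <- isTRUE(log_flags[[att]])
    s <- spatial_dependence_index(best, md,
                                  model_factors = config$sdi$model_factors,
                                  thresholds = config$sdi$thresholds)
    models[[att]] <- best
    sdi_rows[[att]] <- data.frame(attribute = att, kind = best$kind,
                                  nugget = best$nugget,
                                  sill = best$nugget + best$psill,
                                  range_m = best$range_m,
                                  ssr = best$diagnostics$ssr,
                                  r2 = best$diagnostics$r2,
                                  rmse_cv = best$diagnostics$rmse_cv,
                                  sdi_percent = s$sdi_percent,
                                  sdi_class = s$class,
                                  log_transformed = best$log_transformed)
    note("variogram", "%s: %s, C0=%.4g, sill=%.4g, a=%.4g m, SDI=%.1f%% (%s)",
         att, best$kind, best$nugget, best$nugget + best$psill,
         best$range_m, s$sdi_percent, s$class)
  }
  sdi_table <- do.call(rbind, sdi_rows)
  rownames(sdi_table) <- NULL
  write.csv(sdi_table, emit("sdi", "sdi.csv"), row.names = FALSE)
  jsonlite::write_json(
    lapply(models, function(m) c(coef(m), m$diagnostics[c("ssr", "r2",
                                                          "rmse_cv")],
                                 kind = m$kind,
                                 log_transformed = m$log_transformed)),
    emit("sdi", "models.json"), auto_unbox = TRUE, digits = NA)

  # ---- kriging maps ------------------------------------------------------
  dir.create(file.path(outdir, "grids"), showWarnings = FALSE)
  maps <- list()
  for (att in atts) {
    work <- dataset
    col <- att
    if (models[[att]]$log_transformed) {
      col <- paste0("log_", att)
      work[[col]] <- log(work[[att]])
    }
    km <- krige_map(point_dataset(work[c("x", "y", col)],
                                  spacing = attr(dataset, "spacing")),
                    col, models[[att]],
                    cell_size = config$kriging$cell_size)
    maps[[att]] <- km
    write_ascii_grid(km$prediction,
                     emit("krige", file.path("grids", paste0(att, ".asc"))))
    write_ascii_grid(km$variance,
                     emit("krige", file.path("grids",
                                             paste0(att, "_var.asc"))))
  }
  note("krige", "kriged %d attribute maps at %g m resolution",
       length(maps), config$kriging$cell_size)

  # ---- regions -----------------------------------------------------------
  ratt <- config$regions$attribute
  rmap <- maps[[ratt]]$prediction
  if (models[[ratt]]$log_transformed) {
    # bands are on the data scale; compare on the data scale
    rmap <- raster_grid(rmap$origin, rmap$cell_size, exp(rmap$values))
  }
  regions <- delineate_regions(rmap,
                               low_band = config$regions$low_band,
                               high_band = config$regions$high_band)
  jsonlite::write_json(
    list(attribute = ratt, low_band = regions$low_band,
         high_band = regions$high_band, counts = as.list(regions$counts)),
    emit("regions", "regions.json"), auto_unbox = TRUE, digits = NA)
  write.csv(cbind(raster_cell_centers(rmap),
                  value = as.vector(t(rmap$values)),
                  region = as.vector(t(regions$labels))),
            emit("regions", "regions.csv"), row.names = FALSE)
  note("regions", "R1: %d cells, R2: %d cells, unassigned: %d",
       regions$counts[["R1"]], regions$counts[["R2"]],
       regions$counts[["unassigned"]])

  # ---- two-region microbiology battery ----------------------------------
  mc <- microbiology_config(n_per_group = config$comparison$n_per_group,
                            seed = config$seed + 1L)
  micro <- simulate_microbiology(mc)
  write.csv(micro, emit("compare", "microbiology.csv"), row.names = FALSE)
  cmp <- compare_groups(micro, "region", alpha = config$comparison$alpha)
  vars <- setdiff(names(micro), "region")
  # T2 on a subset small enough for the pooled covariance to be invertible
  t2_vars <- intersect(c("pmoA", "dehydrogenase", "urease", "amylase",
                         "MBC", "CN_ratio"), vars)
  t2 <- hotelling_t2(micro[micro$region == "R1", t2_vars],
                     micro[micro$region == "R2", t2_vars])
  jsonlite::write_json(list(t_tests = cmp, hotelling = t2),
                       emit("compare", "comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  note("compare", "%d/%d variables differ at alpha = %g; Hotelling F = %.3g (p = %.3g)",
       sum(cmp$significant), nrow(cmp), config$comparison$alpha, t2$f,
       t2$p_value)

  # ---- clustering and PCA ------------------------------------------------
  scaled <- scale(micro[vars])
  wc <- ward_cluster(scaled, n_groups = 2)
  pc <- pca(micro[vars])
  jsonlite::write_json(
    list(merge = wc$hclust$merge, height = wc$hclust$height,
         order = wc$hclust$order, labels = unname(wc$labels),
         cophenetic_cor = wc$cophenetic_cor),
    emit("cluster", "clustering.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(eigenvalues = pc$eigenvalues,
         explained_variance = pc$explained_variance,
         retained = pc$retained, interpreted = pc$interpreted),
    emit("pca", "pca.json"), auto_unbox = TRUE, digits = NA)
  write.csv(cbind(variable = rownames(pc$loadings),
                  as.data.frame(pc$loadings)),
            emit("pca", "pca_loadings.csv"), row.names = FALSE)
  note("pca", "PC1 explains %.1f%%, %d component(s) retained",
       pc$explained_variance[1], length(pc$retained))

  # ---- report ------------------------------------------------------------
  jsonlite::write_json(
    list(package = "soilspatial",
         version = as.character(utils::packageVersion("soilspatial")),
         config_hash = config_hash(config), seed = config$seed,
         files = manifest),
    file.path(outdir, "MANIFEST.json"), auto_unbox = TRUE, digits = NA)
  note("report", "run complete: %d files in %s", length(manifest) + 2,
       outdir)

  invisible(list(outdir = outdir, dataset = dataset,
                 summary = summary_tab, models = models,
                 sdi_table = sdi_table, maps = maps, regions = regions,
                 microbiology = micro, comparison = cmp, hotelling = t2,
                 clustering = wc, pca = pc))
}
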