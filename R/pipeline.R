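#' Assemble a pipeline run configuration
#'
#' @param population_path CSV of the stratified population/case table
#'   (`unit_id, sex, age_band, population, cases`).
#' @param census_path CSV of the four Townsend census components.
#' @param adjacency_path GAL or JSON neighbour-list file.
#' @param outdir output directory.
#' @param cases_path optional CSV of per-case records (`unit_id`, `cause`,
#'   `egfr`, `visits`, `townsend`), enabling the association stage.
#' @param centroids_path optional CSV of unit centroids for GeoJSON export.
#' @param years study duration in years.
#' @param ci_level interval coverage for raw and smoothed SIRs.
#' @param rate_scale reporting scale for crude rates.
#' @param reference_rates_path optional CSV of external reference rates
#'   (`sex, age_band, rate`); default is internal standardization.
#' @param townsend_transform passed to [townsend_score()].
#' @param covariates `"townsend"` (quintile dummies), `"none"`, or a path to
#'   a covariate CSV (`unit_id` + numeric columns).
#' @param bym list of [bym_config()] overrides (e.g. `n_iter`, `n_burnin`).
#' @param seed integer seed for the whole run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(population_path, census_path, adjacency_path,
                       outdir, cases_path = NULL, centroids_path = NULL,
                       years = 7, ci_level = 0.95, rate_scale = 1e6,
                       reference_rates_path = NULL,
                       townsend_transform = "townsend1988",
                       covariates = "townsend",
                       bym = list(), seed = 1L) {
  cfg <- list(population_path = population_path, census_path = census_path,
              adjacency_path = adjacency_path, outdir = outdir,
              cases_path = cases_path, centroids_path = centroids_path,
              years = years, ci_level = ci_level, rate_scale = rate_scale,
              reference_rates_path = reference_rates_path,
              townsend_transform = townsend_transform,
              covariates = covariates, bym = bym, seed = as.integer(seed))
  for (p in c("population_path", "census_path", "adjacency_path",
              "cases_path", "centroids_path", "reference_rates_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input does not exist: ", cfg[[p]], call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @param ... overrides applied on top of the file (CLI > file > defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(run_config, vals)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full small-area mapping pipeline
#'
#' Executes the stages in order -- standardize (expected counts and raw
#' SIRs), townsend (deprivation scores and quintiles), fit (BYM smoothing
#' with optional ecological covariates), associate (eGFR / cause /
#' late-referral correlations, when case records are supplied), report
#' (GeoJSON export and run manifest). Each stage's files are written before
#' the next starts; rerunning with the same inputs, config and seed
#' reproduces byte-identical artifacts and manifest.
#'
#' @param config a [run_config()] (or a path to a YAML file).
#' @return The run manifest (also written as `manifest.json`): files written
#'   with md5 content hashes, the seed, config echo and package version.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  stages <- list()
  written <- character(0)

  run_stage <- function(stage, fn) {
    pipeline_log(stage, "starting")
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      for (f in written[!file.exists(paste0(written, ".partial"))]) NULL
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(stage, sprintf("done (%.1fs)", proc.time()[["elapsed"]] - t0))
    res
  }

  # -- standardize ----------------------------------------------------------
  std <- run_stage("standardize", function() {
    tab <- utils::read.csv(config$population_path, stringsAsFactors = FALSE)
    rates <- if (is.null(config$reference_rates_path))
      internal_reference_rates(tab, config$years)
    else utils::read.csv(config$reference_rates_path,
                         stringsAsFactors = FALSE)
    E <- expected_counts(tab, rates, config$years)
    O <- observed_counts(tab)
    sir <- sir_table(O, E, level = config$ci_level)
    utils::write.csv(sir, out("sir.csv"), row.names = FALSE)
    pipeline_log("standardize",
                 sprintf("total O = %d, total E = %.3f, pooled SIR = %.6f",
                         sum(sir$observed), sum(sir$expected),
                         sum(sir$observed) / sum(sir$expected)))
    list(sir = sir, files = out("sir.csv"))
  })
  written <- c(written, std$files)
  stages$standardize <- basename(std$files)

  # -- townsend -------------------------------------------------------------
  tw <- run_stage("townsend", function() {
    census <- utils::read.csv(config$census_path, stringsAsFactors = FALSE)
    scores <- assign_quintiles(
      townsend_score(census, transform = config$townsend_transform))
    utils::write.csv(scores, out("townsend.csv"), row.names = FALSE)
    list(scores = scores, files = out("townsend.csv"))
  })
  written <- c(written, tw$files)
  stages$townsend <- basename(tw$files)

  # -- fit ------------------------------------------------------------------
  fit <- run_stage("fit", function() {
    adj <- read_neighbor_list(config$adjacency_path)
    sir <- std$sir
    m <- match(adj$unit_ids, sir$unit_id)
    if (anyNA(m))
      stop("adjacency and stratified table cover different units")
    X <- NULL
    if (identical(config$covariates, "townsend")) {
      mt <- match(adj$unit_ids, tw$scores$unit_id)
      X <- quintile_dummies(tw$scores[mt, ])
    } else if (!identical(config$covariates, "none") &&
               !is.null(config$covariates)) {
      cv <- utils::read.csv(config$covariates, stringsAsFactors = FALSE)
      X <- as.matrix(cv[match(adj$unit_ids, cv$unit_id),
                        setdiff(names(cv), "unit_id"), drop = FALSE])
    }
    md <- model_data(sir$observed[m], sir$expected[m], adj, X)
    bc <- do.call(bym_config, c(list(seed = config$seed), config$bym))
    f <- fit_bym(md, bc)
    utils::write.csv(f$summary, out("smoothed_sir.csv"), row.names = FALSE)
    files <- out("smoothed_sir.csv")
    if (!is.null(f$coefficients)) {
      utils::write.csv(f$coefficients, out("coefficients.csv"),
                       row.names = FALSE)
      files <- c(files, out("coefficients.csv"))
    } else {
      pipeline_log("fit", "no covariates: coefficient table omitted")
    }
    pipeline_log("fit", sprintf(
      "smoothed SIR range %.2f-%.2f; mean acceptance u %.2f",
      min(f$summary$smoothed_sir), max(f$summary$smoothed_sir),
      mean(f$diagnostics$accept$u)))
    list(fit = f, files = files)
  })
  written <- c(written, fit$files)
  stages$fit <- basename(fit$files)

  # -- associate ------------------------------------------------------------
  if (!is.null(config$cases_path)) {
    assoc <- run_stage("associate", function() {
      cases <- utils::read.csv(config$cases_path, stringsAsFactors = FALSE)
      units <- fit$fit$summary$unit_id
      res <- list()
      if ("egfr" %in% names(cases)) {
        med <- area_median(cases$unit_id, cases$egfr, units = units)
        res$egfr_pearson <- pearson_log_sir(fit$fit$summary$smoothed_sir,
                                            med$value)
      }
      if ("cause" %in% names(cases)) {
        res$diabetic_mean_pct <- mean(
          cause_proportions(cases$unit_id, cases$cause, "diabetic",
                            units = units)$value, na.rm = TRUE)
        res$vascular_mean_pct <- mean(
          cause_proportions(cases$unit_id, cases$cause, "vascular",
                            units = units)$value, na.rm = TRUE)
      }
      if (all(c("townsend", "visits") %in% names(cases)))
        res$late_referral <- late_referral_association(cases$townsend,
                                                       cases$visits)
      jsonlite::write_json(res, out("associations.json"), auto_unbox = TRUE,
                           digits = NA)
      list(res = res, files = out("associations.json"))
    })
    written <- c(written, assoc$files)
    stages$associate <- basename(assoc$files)
  } else {
    stages$associate <- character(0)
  }

  # -- report ---------------------------------------------------------------
  rep_files <- run_stage("report", function() {
    files <- character(0)
    if (!is.null(config$centroids_path)) {
      cent <- read_centroids(config$centroids_path)
      export_geojson(cent, fit$fit$summary, tw$scores, out("results.geojson"))
      files <- c(files, out("results.geojson"))
    }
    files
  })
  written <- c(written, rep_files)
  stages$report <- basename(rep_files)

  manifest <- list(
    package = "esrdmap",
    version = as.character(utils::packageVersion("esrdmap")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "outdir")],
    stages = stages,
    artifacts = lapply(stats::setNames(written, basename(written)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Export mapping results as GeoJSON
#'
#' Emits one feature per unit with the smoothed-SIR and deprivation
#' properties, using centroid Point geometries (polygon geometry is out of
#' scope). Units without a centroid get a null geometry and are listed in
#' the returned value.
#'
#' @param centroids data frame `unit_id, name, lon, lat` (see
#'   [read_centroids()]).
#' @param results per-unit summary from [fit_bym()] (`summary` component).
#' @param townsend scores/quintiles from [assign_quintiles()].
#' @param path output path.
#' @return Invisibly, the unit ids that lacked geometry.
#' @export
export_geojson <- function(centroids, results, townsend, path) {
  mt <- match(results$unit_id, townsend$unit_id)
  mc <- match(results$unit_id, centroids$unit_id)
  features <- lapply(seq_len(nrow(results)), function(i) {
    geom <- if (is.na(mc[i])) NULL else
      list(type = "Point",
           coordinates = c(centroids$lon[mc[i]], centroids$lat[mc[i]]))
    list(type = "Feature",
         id = results$unit_id[i],
         geometry = geom,
         properties = list(
           unit_id = results$unit_id[i],
           smoothed_sir = results$smoothed_sir[i],
           ci_low = results$ci_low[i],
           ci_high = results$ci_high[i],
           exceed_prob = results$exceed_prob[i],
           significant = results$significant[i],
           townsend_score = if (is.na(mt[i])) NULL else
             townsend$score[mt[i]],
           quintile = if (is.na(mt[i])) NULL else
             townsend$quintile[mt[i]]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(results$unit_id[is.na(mc)])
}
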