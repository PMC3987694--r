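#' Write area values as a GeoJSON choropleth
#'
#' One point feature per area at its centroid, with the supplied values as
#' properties (rounded to 6 decimals). Missing values become null properties
#' with a warning. Output round-trips through standard GeoJSON parsers.
#'
#' @param area_values data.frame with `area_id` and one or more numeric
#'   value columns, or a named numeric vector.
#' @param map an [area_map].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_choropleth <- function(area_values, map, path) {
  stopifnot(inherits(map, "area_map"))
  if (is.numeric(area_values) && !is.data.frame(area_values)) {
    area_values <- data.frame(area_id = names(area_values),
                              value = as.numeric(area_values))
  }
  vcols <- setdiff(names(area_values), "area_id")
  feats <- lapply(seq_along(map$area_ids), function(i) {
    id <- map$area_ids[i]
    row <- area_values[area_values$area_id == id, , drop = FALSE]
    props <- list(area_id = id)
    for (v in vcols) {
      val <- if (nrow(row) == 1) row[[v]] else NA_real_
      if (is.na(val)) {
        warning("no value for area ", id, " (", v, "); writing null")
        props[[v]] <- NULL
        props[v] <- list(NULL)
      } else {
        props[[v]] <- round(val, 6)
      }
    }
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = as.numeric(map$centroids[i, ])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8, null = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Configuration-driven end-to-end run mirroring the study workflow:
#' simulate (or load) survey data, design-weighted description, hierarchical
#' model fits with DIC comparison, posterior prevalence mapping for the best
#' model, and Bernoulli scan cluster detection. Every output lands in
#' `outdir`, together with a `manifest.json` recording seeds, settings and
#' every defaulted assumption; runs are deterministic given the config.
#'
#' @param config a named list or path to a YAML file with blocks:
#'   \describe{
#'     \item{simulation}{`rows`, `cols`, `n` per-psu/psu counts via
#'       `design`, `truth` (beta0, beta, tau_s, tau_u), `factor_spec`,
#'       `seed` — exclusive with `input`.}
#'     \item{input}{`records`, `centroids`, `adjacency` file paths.}
#'     \item{model}{`models` (subset of 1:4), `iterations`, `burn_in`,
#'       `thin`, `seed`, `prior_a`, `prior_b`, `beta_prior_precision`.}
#'     \item{scan}{`directions`, `max_fraction`, `replications`, `alpha`,
#'       `seed`, `use_weights`.}
#'   }
#' @param outdir output directory.
#' @return (invisibly) list with the fits, comparison table, map summary and
#'   cluster reports.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (sum(c("simulation", "input") %in% names(config)) != 1) {
    stop("config must contain exactly one of 'simulation' or 'input'")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("bymscan")))

  ## stage 1: data
  if ("simulation" %in% names(config)) {
    sim <- config$simulation
    if (is.null(sim$seed)) stop("simulation block requires a seed")
    map <- make_lattice_map(sim$rows %||% 5, sim$cols %||% 4)
    tr <- sim$truth %||% list()
    set.seed(sim$seed)
    f_s <- if (!is.null(tr$tau_s)) simulate_icar_field(map, tr$tau_s) else NULL
    f_u <- if (!is.null(tr$tau_u))
      stats::rnorm(length(map$area_ids), 0, 1 / sqrt(tr$tau_u)) else NULL
    truth <- truth_set(beta0 = tr$beta0 %||% 0,
                       beta = unlist(tr$beta %||% list()),
                       f_s = f_s, f_u = f_u,
                       tau_s = tr$tau_s %||% NA_real_,
                       tau_u = tr$tau_u %||% NA_real_)
    fspec <- lapply(sim$factor_spec %||% list(), unlist)
    records <- simulate_survey(map, truth, design = sim$design %||% list(),
                               factor_spec = fspec, seed = sim$seed + 1)
    write_survey_records(records, file.path(outdir, "records.csv"))
    manifest$simulation <- sim
  } else {
    map <- read_area_map(config$input$centroids, config$input$adjacency)
    records <- read_survey_records(config$input$records)
    manifest$input <- config$input
  }
  factors <- attr(records, "factors")

  ## stage 2: design-weighted description
  prev <- weighted_prevalence(records)
  desc <- NULL
  if (length(factors) > 0) {
    desc <- write_descriptive_table(records, "outcome", factors,
                                    file.path(outdir, "descriptive_table.csv"))
  }
  crude <- aggregate_to_areas(records, map)
  write_choropleth(
    data.frame(area_id = crude$area_id,
               prevalence = ifelse(crude$total > 0,
                                   crude$cases / crude$total, NA)),
    map, file.path(outdir, "crude_prevalence.geojson"))

  ## stage 3: hierarchical models + DIC comparison
  mb <- utils::modifyList(
    list(models = 1:4, iterations = 20000, burn_in = 5000, thin = 5,
         seed = NULL, prior_a = 0.5, prior_b = 0.0005,
         beta_prior_precision = 1e-4, reference_levels = list()),
    config$model %||% list())
  if (is.null(mb$seed)) stop("model block requires a seed")
  fits <- list()
  for (mno in mb$models) {
    spec <- model_spec(include_structured = mno %in% c(3, 4),
                       include_unstructured = mno %in% c(2, 4),
                       prior_a = mb$prior_a, prior_b = mb$prior_b,
                       beta_prior_precision = mb$beta_prior_precision,
                       reference_levels = mb$reference_levels)
    fit <- fit_model(records, map, spec,
                     mcmc = list(iterations = mb$iterations,
                                 burn_in = mb$burn_in, thin = mb$thin,
                                 seed = mb$seed + mno))
    fits[[as.character(mno)]] <- fit
    write_fit(fit, file.path(outdir, sprintf("model_%d", mno)))
  }
  comparison <- data.frame(
    model = as.integer(names(fits)),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    pd = vapply(fits, function(f) f$pd, numeric(1)))
  utils::write.csv(comparison, file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  best <- if (length(fits) >= 2) select_best_model(fits) else
    as.integer(names(fits))

  ## stage 4: posterior prevalence map of the best model
  best_fit <- fits[[as.character(best)]]
  pmap <- posterior_prevalence_map(best_fit)
  utils::write.csv(pmap, file.path(outdir, "posterior_prevalence.csv"),
                   row.names = FALSE)
  write_choropleth(pmap[, c("area_id", "mean", "median", "q025", "q975")],
                   map, file.path(outdir, "posterior_prevalence.geojson"))

  ## stage 5: scan
  sb <- utils::modifyList(
    list(directions = c("high", "low"), max_fraction = 0.5,
         replications = 999, alpha = 0.05, seed = NULL, use_weights = FALSE),
    config$scan %||% list())
  if (is.null(sb$seed)) stop("scan block requires a seed")
  case_data <- aggregate_to_areas(records, map, use_weights = sb$use_weights)
  write_case_data(case_data, file.path(outdir, "case_data.csv"))
  clusters <- list()
  for (d in sb$directions) {
    cand <- monte_carlo_pvalues(case_data, map, d, sb$max_fraction,
                                sb$replications, seed = sb$seed +
                                  match(d, c("high", "low")))
    rep_d <- secondary_clusters(cand, sb$alpha)
    clusters[[d]] <- rep_d
    write_cluster_report(
      rep_d, d, file.path(outdir, sprintf("clusters_%s.csv", d)),
      assumptions = list(max_fraction = sb$max_fraction,
                         replications = sb$replications,
                         alpha = sb$alpha,
                         use_weights = sb$use_weights,
                         overlap_rule = "no geographical overlap"))
  }

  manifest$model <- mb[setdiff(names(mb), "reference_levels")]
  manifest$scan <- sb
  manifest$best_model <- best
  manifest$prevalence <- list(point = prev$point, ci_low = prev$ci_low,
                              ci_high = prev$ci_high)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(map = map, records = records, prevalence = prev,
                 descriptive = desc, fits = fits, comparison = comparison,
                 best_model = best, prevalence_map = pmap,
                 clusters = clusters))
}
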