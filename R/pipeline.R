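# End-to-end orchestration: simulate -> connectivity -> graphs -> permutation
# test -> Bayesian networks -> cohort statistics, from a single config, with
# per-stage seeds and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Study-scale defaults: 87 male + 89 female subjects, 174 timepoints, the
#' 8-region a-priori network plus the language control network, density grid
#' 0.05-0.50 by 0.01, 2000 permutations, 10 structure-search restarts,
#' impairment threshold -1.3, Benjamini-Yekutieli FDR.
#'
#' @param seed Global seed; per-stage seeds are derived from it by
#'   [stage_seed()].
#' @param ... Named overrides merged into the top level of the config.
#' @return A nested config list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    cohort = list(n_male = 87, n_female = 89, impairment_prevalence = 0.35,
                  n_timepoints = 174),
    networks = c("ctc", "language"),
    density_grid = seq(0.05, 0.5, by = 0.01),
    n_perm = 2000,
    bayesnet = list(restarts = 10),
    stats = list(threshold = -1.3, fdr_method = "BY"),
    write_panels = FALSE
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields are filled from [default_config()].
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; failures are reported, not thrown.
#'
#' @param config A config list.
#' @return A tibble of failures (`field`, `message`); zero rows when valid.
#' @export
#' @examples
#' validate_config(default_config())
validate_config <- function(config) {
  fails <- list()
  add <- function(field, message) {
    fails[[length(fails) + 1L]] <<- tibble::tibble(field = field,
                                                   message = message)
  }
  co <- config$cohort
  for (f in c("n_male", "n_female", "n_timepoints")) {
    if (is.null(co[[f]]) || !is.numeric(co[[f]]) || co[[f]] < 1) {
      add(paste0("cohort$", f), "must be a positive count")
    }
  }
  prev <- co$impairment_prevalence
  if (is.null(prev) || !is.numeric(prev) || any(prev < 0) || any(prev > 1)) {
    add("cohort$impairment_prevalence", "must lie in [0, 1]")
  }
  g <- config$density_grid
  if (is.null(g) || !is.numeric(g) || length(g) == 0L) {
    add("density_grid", "must be a non-empty numeric vector")
  } else {
    if (any(g <= 0) || any(g > 1)) add("density_grid", "values must lie in (0, 1]")
    if (is.unsorted(g, strictly = TRUE)) add("density_grid", "must be strictly ascending")
  }
  if (!is.numeric(config$n_perm) || config$n_perm < 1) {
    add("n_perm", "must be a positive count")
  }
  if (!all(config$networks %in% c("ctc", "language"))) {
    add("networks", "must be a subset of {ctc, language}")
  }
  if (!is.null(config$partition)) {
    missing <- setdiff(ctc_regions("ctc"), names(config$partition))
    if (length(missing)) {
      add("partition", paste0("does not cover region(s): ",
                              paste(missing, collapse = ", ")))
    }
    unknown <- setdiff(names(config$partition), ctc_regions("ctc"))
    if (length(unknown)) {
      add("partition", paste0("unknown region(s): ",
                              paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(config$stats$fdr_method) &&
      !config$stats$fdr_method %in% c("BY", "BH")) {
    add("stats$fdr_method", "must be BY or BH")
  }
  if (!is.null(config$stats$correlate_measures)) {
    unknown <- setdiff(config$stats$correlate_measures,
                       default_neurocog_model()$measure)
    if (length(unknown)) {
      add("stats$correlate_measures",
          paste0("unknown measure(s): ", paste(unknown, collapse = ", ")))
    }
  }
  if (length(fails)) dplyr::bind_rows(fails) else
    tibble::tibble(field = character(), message = character())
}

#' Write time-series panels as one CSV per subject plus a JSON manifest
#'
#' @param panels Named list of panels.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_timeseries_panels <- function(panels, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(panels), function(s) {
    path <- file.path(dir, paste0(s, ".csv"))
    readr::write_csv(panels[[s]], path, progress = FALSE)
    path
  }, character(1))
  manifest <- file.path(dir, "panels_manifest.json")
  jsonlite::write_json(
    list(subjects = names(panels),
         n_timepoints = nrow(panels[[1L]]),
         regions = setdiff(names(panels[[1L]]), "time"),
         files = basename(paths)),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes every stage in order on a synthetic cohort: data generation,
#' Fisher-z connectivity, minimum-density graphs and metrics, the
#' impaired-vs-unimpaired permutation test on global efficiency, stratified
#' and common Bayesian-network models with the sex-by-impairment interaction
#' ANOVA on the cerebellum-DLPFC edge, and cohort statistics with FDR
#' control. All numeric outputs are written as CSV/JSON under `out_dir`
#' together with a manifest; re-running with the same config reproduces
#' identical numbers.
#'
#' @param config Config list, see [default_config()] / [read_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `results` (all in-memory objects) and
#'   `manifest` (config hash, per-stage seeds, files, warnings).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("ctcnet")) {
  bad <- validate_config(config)
  if (nrow(bad)) {
    abort(paste0("invalid config: ",
                 paste(bad$field, bad$message, collapse = "; ")),
          class = "ctcnet_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  notes <- character(0)
  emit_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path, progress = FALSE)
    files <<- c(files, path)
  }
  emit_json <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <<- c(files, path)
  }
  seeds <- lapply(setNames(nm = c("simulate", "neurocog", "permtest",
                                  "bayesnet")),
                  function(s) stage_seed(config$seed, s))

  # -- stage 1: simulate -----------------------------------------------------
  spec <- cohort_spec(
    n_male = config$cohort$n_male, n_female = config$cohort$n_female,
    impairment_prevalence = config$cohort$impairment_prevalence,
    n_timepoints = config$cohort$n_timepoints, seed = seeds$simulate)
  subjects <- generate_cohort(spec)
  scores <- generate_neurocog(subjects, seed = seeds$neurocog,
                              threshold = config$stats$threshold)
  imp <- classify_impairment(scores, threshold = config$stats$threshold)
  subjects$impaired <-
    imp$any_executive_impaired[match(subjects$subject_id, imp$subject_id)]
  panels <- list(ctc = simulate_cohort_timeseries(subjects, spec, "ctc"))
  if ("language" %in% config$networks) {
    panels$language <- simulate_cohort_timeseries(subjects, spec, "language")
  }
  emit_csv(subjects, "subjects.csv")
  emit_csv(scores, "neurocog.csv")
  emit_csv(imp, "impairment.csv")
  if (isTRUE(config$write_panels)) {
    for (nw in names(panels)) {
      files <- c(files, write_timeseries_panels(
        panels[[nw]], file.path(out_dir, paste0("panels_", nw))))
    }
  }

  # -- stages 2-3: connectivity, density search, metrics ---------------------
  metrics <- list()
  for (nw in names(panels)) {
    res <- lapply(panels[[nw]], function(p) {
      conn <- compute_connectivity(p)
      find_minimum_density(conn, grid = config$density_grid,
                           partition = config$partition)
    })
    m <- dplyr::bind_rows(lapply(res, function(r) graph_metrics(r$graph))) |>
      dplyr::mutate(network = nw,
                    d_min = vapply(res, function(r) r$d_min, numeric(1)),
                    fragmented = vapply(res, function(r) r$fragmented,
                                        logical(1)))
    metrics[[nw]] <- m
  }
  metrics_all <- dplyr::bind_rows(metrics)
  frag <- fragmentation_summary(metrics$ctc, subjects)
  if (any(metrics$ctc$fragmented)) {
    notes <- c(notes, sprintf(
      "%d of %d subjects fragmented at the maximum grid density (ctc network)",
      sum(metrics$ctc$fragmented), nrow(metrics$ctc)))
  }
  wmdz <- dplyr::bind_rows(lapply(seq_len(nrow(metrics$ctc)), function(i) {
    dplyr::mutate(metrics$ctc$wmdz[[i]],
                  subject_id = metrics$ctc$subject_id[i], .before = 1L)
  }))
  emit_csv(dplyr::select(metrics_all, -"wmdz", -"disconnected"), "metrics.csv")
  emit_csv(wmdz, "within_module_degree_z.csv")
  emit_csv(frag, "fragmentation.csv")

  # -- stage 4: permutation test on global efficiency ------------------------
  perm <- efficiency_group_comparison(
    metrics$ctc, subjects, n_perm = config$n_perm, seed = seeds$permtest)
  emit_json(c(as.list(tidy(perm)),
              list(null_diffs = perm$null_diffs)), "permtest.json")

  # -- stage 5: effective connectivity ---------------------------------------
  restarts <- config$bayesnet$restarts
  strat <- learn_stratified(panels$ctc, subjects, restarts = restarts,
                            seed = stage_seed(seeds$bayesnet, "stratified"))
  common <- fit_common_model(panels$ctc, restarts = restarts,
                             seed = stage_seed(seeds$bayesnet, "common"))
  weights <- estimate_edge_weights(common, panels$ctc)
  edge <- match_edge(common, "Cerebellum_L", "DLPFC_L")
  if (!nrow(edge)) edge <- match_edge(common, "Cerebellum_R", "DLPFC_R")
  anova_res <- NULL
  if (nrow(edge)) {
    anova_res <- interaction_anova(weights, subjects,
                                   edge$parent[1L], edge$child[1L])
    emit_json(c(list(edge = as.list(edge[1L, ])),
                list(table = tidy(anova_res))), "anova.json")
  } else {
    notes <- c(notes,
               "no cerebellum-DLPFC edge in the common model; ANOVA skipped")
  }
  for (g in names(strat$models)) {
    emit_json(list(edges = tidy(strat$models[[g]]),
                   score = strat$models[[g]]$score),
              sprintf("dag_%s.json", g))
  }
  emit_json(list(edges = tidy(common), score = common$score),
            "dag_common.json")
  emit_csv(strat$comparison, "dag_comparison.csv")
  emit_csv(weights, "edge_weights.csv")

  # -- stage 6: cohort statistics --------------------------------------------
  model <- default_neurocog_model()
  prop <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
    ids <- subjects$subject_id[subjects$sex == sx]
    dplyr::bind_rows(lapply(model$measure, function(ms) {
      z <- scores$z[scores$subject_id %in% ids & scores$measure == ms]
      k <- sum(z < config$stats$threshold)
      dplyr::mutate(impairment_proportion_ci(k, length(z)),
                    sex = sx, measure = ms, .before = 1L)
    }))
  }))
  ttests <- dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
    ids <- subjects$subject_id[subjects$sex == sx]
    dplyr::bind_rows(lapply(model$measure, function(ms) {
      z <- scores$z[scores$subject_id %in% ids & scores$measure == ms]
      dplyr::mutate(one_sample_vs_reference(z), sex = sx, measure = ms,
                    .before = 1L)
    }))
  }))
  ttests$p.adjusted <- fdr_correct(ttests$p.value,
                                   method = config$stats$fdr_method)
  cors <- dplyr::bind_rows(lapply(names(metrics), function(nw) {
    dplyr::bind_rows(lapply(c("male", "female"), function(sx) {
      ids <- subjects$subject_id[subjects$sex == sx]
      eff <- metrics[[nw]]$global_efficiency[
        match(ids, metrics[[nw]]$subject_id)]
      dplyr::bind_rows(lapply(model$measure, function(ms) {
        z <- scores$z[match(paste(ids, ms),
                            paste(scores$subject_id, scores$measure))]
        dplyr::mutate(correlate_metric(eff, z), network = nw, sex = sx,
                      measure = ms, .before = 1L)
      }))
    }))
  }))
  cors$p.adjusted <- fdr_correct(cors$p.value,
                                 method = config$stats$fdr_method)
  emit_csv(prop, "impairment_proportions.csv")
  emit_csv(ttests, "reference_tests.csv")
  emit_csv(cors, "efficiency_correlations.csv")

  manifest <- list(
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("ctcnet")),
    seed = config$seed,
    stage_seeds = seeds,
    files = basename(files),
    warnings = notes
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  manifest$files <- c(manifest$files, basename(path))

  invisible(list(
    results = list(
      spec = spec, subjects = subjects, scores = scores, impairment = imp,
      panels = panels, metrics = metrics_all, fragmentation = frag,
      wmdz = wmdz, permtest = perm, stratified = strat, common = common,
      weights = weights, anova = anova_res, proportions = prop,
      reference_tests = ttests, correlations = cors),
    manifest = manifest, out_dir = out_dir))
}
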