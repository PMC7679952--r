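# Synthetic cohort generator: subject tables, ground-truth directed networks,
# regional time series, and neurocognitive z-score tables with the statistical
# structure the downstream analyses assume.

#' Region labels of the a-priori cerebello-thalamo-cortical network
#'
#' Bilateral cerebellar Crus I/II, thalamus, dorsolateral prefrontal cortex
#' (DLPFC) and precuneus; or the control language network (bilateral Brodmann
#' areas 40, 44 and 45), which has comparatively low glucocorticoid receptor
#' distribution.
#'
#' @param network `"ctc"` (default) or `"language"`.
#' @return Character vector of region labels.
#' @export
ctc_regions <- function(network = c("ctc", "language")) {
  network <- match.arg(network)
  if (network == "ctc") {
    c("Cerebellum_L", "Cerebellum_R", "Thalamus_L", "Thalamus_R",
      "DLPFC_L", "DLPFC_R", "Precuneus_L", "Precuneus_R")
  } else {
    c("BA40_L", "BA40_R", "BA44_L", "BA44_R", "BA45_L", "BA45_R")
  }
}

#' Default hemispheric module partition
#'
#' The bilateral graph is analysed as one network with left/right hemisphere
#' modules, the default convention for the within-module degree z-score.
#'
#' @param regions Character vector of region labels ending in `_L` / `_R`.
#' @return Named character vector mapping region -> module.
#' @export
hemisphere_partition <- function(regions = ctc_regions()) {
  setNames(ifelse(grepl("_L$", regions), "left", "right"), regions)
}

#' Specify a synthetic cohort
#'
#' Holds the design of a simulated survivor cohort: sample sizes by sex,
#' impairment prevalence, dimensions of the regional time-series panels, and
#' the group-specific network rewiring applied to impaired female survivors.
#' Defaults reproduce the study conditions: 87 male and 89 female survivors,
#' an 8-region a-priori network, and 174 volumes (about 6 minutes of rest at a
#' TR of 2.06 s).
#'
#' @param n_male,n_female Number of subjects per sex.
#' @param impairment_prevalence Probability of executive impairment, recycled
#'   or named per sex (`c(male = , female = )`).
#' @param n_regions Number of regions (8 for the a-priori network).
#' @param n_timepoints Number of time-series volumes per subject.
#' @param seed Integer seed making every generated artefact reproducible.
#' @param effect_config Group-specific rewiring, see [default_effect_config()].
#' @return A `cohort_spec` object (validated list).
#' @export
#' @examples
#' cohort_spec(n_male = 10, n_female = 10, seed = 1)
cohort_spec <- function(n_male = 87, n_female = 89,
                        impairment_prevalence = 0.35,
                        n_regions = 8, n_timepoints = 174,
                        seed = 1L,
                        effect_config = default_effect_config()) {
  spec <- list(
    n_male = check_count(n_male, "n_male"),
    n_female = check_count(n_female, "n_female"),
    impairment_prevalence = check_fraction(impairment_prevalence,
                                           "impairment_prevalence"),
    n_regions = check_count(n_regions, "n_regions", min = 2L),
    n_timepoints = check_count(n_timepoints, "n_timepoints", min = 10L),
    seed = check_count(seed, "seed", min = 0L),
    effect_config = effect_config
  )
  if (spec$n_timepoints <= spec$n_regions) {
    abort("`n_timepoints` must exceed `n_regions`", class = "ctcnet_config_error")
  }
  prev <- spec$impairment_prevalence
  if (is.null(names(prev))) {
    prev <- setNames(rep_len(prev, 2L), c("male", "female"))
  }
  spec$impairment_prevalence <- prev[c("male", "female")]
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d male + %d female subjects, prevalence %.2f/%.2f, %d regions x %d timepoints, seed %d\n",
    x$n_male, x$n_female, x$impairment_prevalence[["male"]],
    x$impairment_prevalence[["female"]], x$n_regions, x$n_timepoints, x$seed))
  invisible(x)
}

#' Default group-specific rewiring of the ground-truth network
#'
#' Impaired female survivors get a qualitatively different effective
#' connectivity structure: the cerebellum-to-DLPFC edges are reversed (DLPFC
#' conditions cerebellar activity) with increased weight, and the
#' precuneus-to-DLPFC edges are removed, in both hemispheres. All other groups
#' share the common structure.
#'
#' @param reversed_weight Weight of the reversed DLPFC -> cerebellum edges.
#' @return Named list of per-group rewiring instructions.
#' @export
default_effect_config <- function(reversed_weight = 0.8) {
  list(
    female_impaired = list(
      drop_edges = data.frame(
        parent = c("Precuneus_L", "Precuneus_R"),
        child = c("DLPFC_L", "DLPFC_R")
      ),
      reverse_edges = data.frame(
        parent = c("Cerebellum_L", "Cerebellum_R"),
        child = c("DLPFC_L", "DLPFC_R"),
        new_weight = reversed_weight
      )
    )
  )
}

#' Construct a ground-truth directed network
#'
#' Builds the directed acyclic generating network for one sex-by-impairment
#' group. The common structure (both unimpaired groups and impaired males) has,
#' per hemisphere, cerebellar and precuneus input to both the thalamus and the
#' DLPFC; impaired females receive the rewiring in `effect_config`.
#'
#' @param group One of `"male_unimpaired"`, `"male_impaired"`,
#'   `"female_unimpaired"`, `"female_impaired"`.
#' @param effect_config See [default_effect_config()].
#' @param network `"ctc"` or `"language"` (the control network is identical in
#'   every group).
#' @param noise_sd Residual standard deviation of each node.
#' @return A `ctc_network` object: node labels, an edge tibble
#'   (`parent`, `child`, `weight`) and per-node noise SDs.
#' @export
#' @examples
#' build_ground_truth("female_impaired")
build_ground_truth <- function(group, effect_config = default_effect_config(),
                               network = c("ctc", "language"), noise_sd = 1) {
  network <- match.arg(network)
  groups <- c("male_unimpaired", "male_impaired",
              "female_unimpaired", "female_impaired")
  if (!is.character(group) || length(group) != 1L || !group %in% groups) {
    abort(paste0("`group` must be one of: ", paste(groups, collapse = ", ")),
          class = "ctcnet_config_error")
  }
  if (network == "language") {
    nodes <- ctc_regions("language")
    edges <- tibble::tibble(
      parent = c("BA44_L", "BA44_R", "BA45_L", "BA45_R"),
      child  = c("BA40_L", "BA40_R", "BA40_L", "BA40_R"),
      weight = 0.25
    )
    return(new_ctc_network(nodes, edges, noise_sd))
  }
  nodes <- ctc_regions("ctc")
  edges <- tibble::tibble(
    parent = c("Cerebellum_L", "Cerebellum_R", "Precuneus_L", "Precuneus_R",
               "Cerebellum_L", "Cerebellum_R", "Precuneus_L", "Precuneus_R"),
    child  = c("Thalamus_L", "Thalamus_R", "Thalamus_L", "Thalamus_R",
               "DLPFC_L", "DLPFC_R", "DLPFC_L", "DLPFC_R"),
    weight = c(0.6, 0.6, 0.4, 0.4, 0.5, 0.5, 0.5, 0.5)
  )
  cfg <- effect_config[[group]]
  if (!is.null(cfg)) {
    drop <- cfg$drop_edges
    if (!is.null(drop)) {
      edges <- dplyr::anti_join(edges, tibble::as_tibble(drop),
                                by = c("parent", "child"))
    }
    rev <- cfg$reverse_edges
    if (!is.null(rev)) {
      rev <- tibble::as_tibble(rev)
      for (k in seq_len(nrow(rev))) {
        hit <- edges$parent == rev$parent[k] & edges$child == rev$child[k]
        if (!any(hit)) {
          abort(sprintf("reverse_edges: %s -> %s is not in the base network",
                        rev$parent[k], rev$child[k]),
                class = "ctcnet_config_error")
        }
        w <- if ("new_weight" %in% names(rev)) rev$new_weight[k] else
          edges$weight[hit]
        edges <- edges[!hit, ]
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          parent = rev$child[k], child = rev$parent[k], weight = w))
      }
    }
  }
  new_ctc_network(nodes, edges, noise_sd)
}

# Constructor + validator for ground-truth networks.
new_ctc_network <- function(nodes, edges, noise_sd = 1) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("parent", "child", "weight") %in% names(edges)))
  bad <- setdiff(unique(c(edges$parent, edges$child)), nodes)
  if (length(bad)) {
    abort(paste0("edge endpoints not in node set: ", paste(bad, collapse = ", ")),
          class = "ctcnet_config_error")
  }
  if (any(!is.finite(edges$weight))) {
    abort("edge weights must be finite", class = "ctcnet_config_error")
  }
  if (is.null(names(noise_sd))) {
    noise_sd <- setNames(rep_len(noise_sd, length(nodes)), nodes)
  }
  if (any(noise_sd <= 0)) {
    abort("noise_sd must be positive", class = "ctcnet_config_error")
  }
  ord <- topological_order(nodes, edges)
  if (is.null(ord)) {
    abort("edge set contains a cycle", class = "ctcnet_config_error")
  }
  structure(list(nodes = nodes, edges = edges, noise_sd = noise_sd[nodes],
                 topo_order = ord),
            class = "ctc_network")
}

# Kahn topological sort; NULL if cyclic.
topological_order <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$child)
  indeg[names(tab)] <- as.integer(tab)
  out <- character(0)
  avail <- nodes[indeg == 0L]
  edges_left <- edges
  while (length(avail)) {
    v <- sort(avail)[1L]
    avail <- setdiff(avail, v)
    out <- c(out, v)
    kids <- edges_left$child[edges_left$parent == v]
    edges_left <- edges_left[edges_left$parent != v, , drop = FALSE]
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) avail <- c(avail, k)
    }
  }
  if (length(out) == length(nodes)) out else NULL
}

#' @export
print.ctc_network <- function(x, ...) {
  cat(sprintf("<ctc_network> %d nodes, %d directed edges\n",
              length(x$nodes), nrow(x$edges)))
  print(x$edges, n = nrow(x$edges))
  invisible(x)
}

#' @method tidy ctc_network
#' @export
tidy.ctc_network <- function(x, ...) x$edges

#' Generate a synthetic subject table
#'
#' Draws demographics, morphometry (with means and dispersions matching the
#' published survivor cohort), chemotherapy exposures and a latent executive
#' impairment indicator for `n_male + n_female` subjects. Deterministic given
#' the seed stored in the cohort specification.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `sex`, `age_dx`,
#'   `age_eval`, `icv`, regional volumes/thicknesses, `dex_auc`, `mtx_auc`,
#'   `it_count`, `impaired`.
#' @export
#' @examples
#' generate_cohort(cohort_spec(n_male = 5, n_female = 5, seed = 1))
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec", class = "ctcnet_config_error")
  }
  withr_seed(spec$seed, {
    n <- spec$n_male + spec$n_female
    sex <- factor(rep(c("male", "female"), c(spec$n_male, spec$n_female)),
                  levels = c("male", "female"))
    male <- sex == "male"
    rtrunc <- function(n, mean, sd, lo, hi) {
      pmin(pmax(rnorm(n, mean, sd), lo), hi)
    }
    age_dx <- rtrunc(n, 6.8, 4.5, 1, 18)
    time_since <- rtrunc(n, 7.7, 1.7, 5, 10)
    icv <- ifelse(male, rnorm(n, 1550000, 120000), rnorm(n, 1400000, 110000))
    icv_z <- (icv - ifelse(male, 1550000, 1400000)) / ifelse(male, 120000, 110000)
    # regional draws share half their SD with ICV (r ~ 0.5 with global volume)
    reg <- function(mean_m, sd_m, mean_f, sd_f) {
      mu <- ifelse(male, mean_m, mean_f)
      s <- ifelse(male, sd_m, sd_f)
      mu + 0.5 * s * icv_z + sqrt(0.75) * s * rnorm(n)
    }
    prev <- spec$impairment_prevalence
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex,
      age_dx = age_dx,
      age_eval = age_dx + time_since,
      icv = icv,
      cerebellum_left = reg(77437, 6030, 70611, 6540),
      cerebellum_right = reg(77232, 6390, 70525, 6390),
      thalamus_left = reg(8001, 829, 7457, 801),
      thalamus_right = reg(8142, 907, 7546, 971),
      precuneus_thickness_left = reg(2.60, 0.18, 2.48, 0.35),
      precuneus_thickness_right = reg(2.57, 0.17, 2.59, 0.17),
      dlpfc_thickness_left = reg(2.86, 0.17, 2.88, 0.19),
      dlpfc_thickness_right = reg(2.85, 0.16, 2.88, 0.20),
      dex_auc = rtrunc(n, 500, 150, 50, 1200),
      mtx_auc = rtrunc(n, 1500, 400, 200, 3200),
      it_count = 13L + rbinom(n, 12, 0.5),
      impaired = rbinom(n, 1, prev[as.character(sex)]) == 1
    )
  })
}

# Evaluate expr with a temporary RNG state seeded at `seed`
# (NULL seed = use the current stream).
withr_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Group label of a subject
#'
#' @param sex `"male"`/`"female"` vector or factor.
#' @param impaired Logical vector.
#' @return Character vector like `"female_impaired"`.
#' @export
group_label <- function(sex, impaired) {
  paste0(as.character(sex), ifelse(impaired, "_impaired", "_unimpaired"))
}

#' Simulate a regional time-series panel from a ground-truth network
#'
#' Each timepoint is drawn from the contemporaneous linear-Gaussian structural
#' model: nodes are evaluated in topological order, a child equals the weighted
#' sum of its parents plus Gaussian noise. Optional AR(1) smoothing of the
#' noise emulates the temporal autocorrelation of haemodynamic signals.
#'
#' @param network A `ctc_network`.
#' @param n_timepoints Number of rows to simulate (>= 10).
#' @param seed Optional integer seed.
#' @param ar AR(1) coefficient in `[0, 1)` applied to each node's innovation
#'   stream (variance-preserving).
#' @param subject_id Optional label stored as an attribute.
#' @return A tibble with a `time` column and one column per region.
#' @export
#' @examples
#' net <- build_ground_truth("male_unimpaired")
#' ts <- simulate_timeseries(net, n_timepoints = 50, seed = 1)
simulate_timeseries <- function(network, n_timepoints = 174, seed = NULL,
                                ar = 0, subject_id = NULL) {
  if (!inherits(network, "ctc_network")) {
    abort("`network` must be a ctc_network", class = "ctcnet_config_error")
  }
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 10L)
  stopifnot(ar >= 0, ar < 1)
  nodes <- network$nodes
  withr_seed(seed, {
    eps <- matrix(rnorm(n_timepoints * length(nodes)), n_timepoints,
                  dimnames = list(NULL, nodes))
    if (ar > 0) {
      eps <- apply(eps, 2L, function(e) {
        as.numeric(stats::filter(e * sqrt(1 - ar^2), ar, method = "recursive"))
      })
      colnames(eps) <- nodes
    }
    x <- matrix(0, n_timepoints, length(nodes), dimnames = list(NULL, nodes))
    for (v in network$topo_order) {
      par <- network$edges[network$edges$child == v, , drop = FALSE]
      x[, v] <- network$noise_sd[[v]] * eps[, v]
      if (nrow(par)) {
        x[, v] <- x[, v] + x[, par$parent, drop = FALSE] %*% par$weight
      }
    }
    out <- tibble::as_tibble(as.data.frame(x))
    out <- dplyr::bind_cols(tibble::tibble(time = seq_len(n_timepoints)), out)
    attr(out, "subject_id") <- subject_id
    out
  })
}

#' Simulate time-series panels for a whole cohort
#'
#' Wraps [build_ground_truth()] and [simulate_timeseries()]: each subject's
#' panel is drawn from their group's network, with small subject-level jitter
#' on the edge weights so inter-individual variation in connectivity strength
#' is present.
#'
#' @param subjects Subject table from [generate_cohort()].
#' @param spec The [cohort_spec()] used to generate `subjects`.
#' @param network `"ctc"` or `"language"`.
#' @param weight_jitter SD of the additive subject-level weight perturbation.
#' @param ar AR(1) smoothing coefficient, see [simulate_timeseries()].
#' @return Named list of panels (one tibble per `subject_id`).
#' @export
simulate_cohort_timeseries <- function(subjects, spec, network = "ctc",
                                       weight_jitter = 0.05, ar = 0) {
  nets <- lapply(
    setNames(nm = c("male_unimpaired", "male_impaired",
                    "female_unimpaired", "female_impaired")),
    build_ground_truth, effect_config = spec$effect_config, network = network)
  withr_seed(stage_seed(spec$seed, paste0("timeseries_", network)), {
    panels <- vector("list", nrow(subjects))
    names(panels) <- subjects$subject_id
    for (i in seq_len(nrow(subjects))) {
      net <- nets[[group_label(subjects$sex[i], subjects$impaired[i])]]
      if (weight_jitter > 0 && nrow(net$edges)) {
        net$edges$weight <- net$edges$weight +
          rnorm(nrow(net$edges), 0, weight_jitter)
      }
      panels[[i]] <- simulate_timeseries(net, spec$n_timepoints, seed = NULL,
                                         ar = ar,
                                         subject_id = subjects$subject_id[i])
    }
    panels
  })
}

#' Default linear effect specification for neurocognitive scores
#'
#' Per-measure baseline means and SDs of the age-adjusted z-scores by sex
#' (matching the published survivor cohort), which measures belong to the
#' executive-function set, the executive deficit shift applied to impaired
#' subjects, and linear slopes on subject covariates (on the z-scored
#' covariate scale).
#'
#' @param impaired_shift Mean shift of executive measures in impaired
#'   subjects (negative = deficit).
#' @param cerebellum_slope Slope of selected measures on mean cerebellar
#'   volume (per within-sex SD of volume).
#' @return A tibble, one row per measure, with a `slopes` list-column.
#' @export
default_neurocog_model <- function(impaired_shift = -1.0,
                                   cerebellum_slope = 0.2) {
  m <- tibble::tribble(
    ~measure, ~executive, ~mean_male, ~sd_male, ~mean_female, ~sd_female,
    "number_letter_switch",  TRUE, -0.74, 1.14, -0.38, 1.23,
    "color_word_switch",     TRUE, -0.34, 0.95, -0.07, 1.03,
    "verbal_fluency",        TRUE, -0.49, 1.03, -0.25, 0.93,
    "categorical_fluency",  FALSE,  0.03, 1.15, -0.01, 0.99,
    "digit_backward",        TRUE, -0.33, 1.03, -0.25, 0.96,
    "spatial_backward",     FALSE, -0.05, 0.98, -0.02, 1.00,
    "rey_osterrieth_copy",   TRUE, -2.44, 2.37, -2.33, 2.45,
    "twenty_questions",      TRUE, -0.12, 1.11, -0.24, 0.94,
    "tower",                FALSE, -0.18, 0.87, -0.05, 0.83,
    "dominant_hand_speed",  FALSE, -1.48, 1.50, -1.16, 1.57,
    "symbol_search",        FALSE, -0.25, 1.06,  0.14, 0.99,
    "digit_symbol",         FALSE, -0.70, 0.90, -0.10, 0.93,
    "number_sequencing",    FALSE, -0.25, 0.99, -0.18, 1.15,
    "letter_sequencing",    FALSE, -0.47, 1.18, -0.23, 1.12
  )
  m$impaired_shift <- ifelse(m$executive, impaired_shift, 0)
  cb_measures <- c("digit_backward", "rey_osterrieth_copy",
                   "dominant_hand_speed", "symbol_search")
  m$slopes <- lapply(m$measure, function(meas) {
    if (meas %in% cb_measures) c(cerebellum_mean = cerebellum_slope) else
      numeric(0)
  })
  m
}

#' The executive-function measure set
#'
#' Measures whose age-adjusted z-score below -1.3 (the 10th percentile of the
#' reference distribution) defines executive impairment: letter/number switch,
#' color/word switch, verbal fluency, digit span backward, Rey-Osterrieth
#' complex figure, and 20 questions.
#'
#' @return Character vector of measure names.
#' @export
executive_measures <- function() {
  c("number_letter_switch", "color_word_switch", "verbal_fluency",
    "digit_backward", "rey_osterrieth_copy", "twenty_questions")
}

#' Generate age-adjusted neurocognitive z-scores
#'
#' Per measure, `z = baseline(sex) + impaired_shift * impaired +
#' sum(beta * covariate_z) + noise`. With `enforce_labels = TRUE` (default)
#' executive scores are drawn conditional on the subject's impairment label
#' (impaired: at least one executive z below `threshold`; unimpaired: none),
#' so the label is exactly rederivable from the generated scores.
#'
#' @param subjects Subject table from [generate_cohort()].
#' @param model Effect specification, see [default_neurocog_model()]. The
#'   names inside each `slopes` entry must be subject-table columns (the
#'   special name `cerebellum_mean` averages the two cerebellar volumes);
#'   a missing covariate is an error naming it.
#' @param seed Integer seed.
#' @param enforce_labels Condition executive draws on the impairment label.
#' @param threshold Impairment threshold on the z scale.
#' @return A tibble in long form: `subject_id`, `measure`, `z`.
#' @export
generate_neurocog <- function(subjects, model = default_neurocog_model(),
                              seed = 1L, enforce_labels = TRUE,
                              threshold = -1.3) {
  stopifnot(is.data.frame(subjects), is.data.frame(model))
  covars <- unique(unlist(lapply(model$slopes, names)))
  for (cv in setdiff(covars, "cerebellum_mean")) {
    if (!cv %in% names(subjects)) {
      abort(sprintf("covariate `%s` referenced by the model is missing from the subject table", cv),
            class = "ctcnet_config_error")
    }
  }
  covtab <- subjects
  if ("cerebellum_mean" %in% covars) {
    covtab$cerebellum_mean <-
      (subjects$cerebellum_left + subjects$cerebellum_right) / 2
  }
  # z-score covariates within sex so slopes are per within-sex SD
  for (cv in covars) {
    covtab[[cv]] <- stats::ave(covtab[[cv]], covtab$sex,
                               FUN = function(x) as.numeric(scale(x)))
  }
  n <- nrow(subjects)
  male <- subjects$sex == "male"
  exec_set <- model$measure[model$executive]
  withr_seed(seed, {
    draw_all <- function() {
      vapply(seq_len(nrow(model)), function(k) {
        mu <- ifelse(male, model$mean_male[k], model$mean_female[k]) +
          model$impaired_shift[k] * subjects$impaired
        sl <- model$slopes[[k]]
        for (cv in names(sl)) mu <- mu + sl[[cv]] * covtab[[cv]]
        s <- ifelse(male, model$sd_male[k], model$sd_female[k])
        rnorm(n, mu, s)
      }, numeric(n))
    }
    z <- draw_all()
    colnames(z) <- model$measure
    if (enforce_labels && length(exec_set)) {
      consistent <- function(zi, imp) {
        if (imp) any(zi < threshold) else all(zi >= threshold)
      }
      exec_idx <- match(exec_set, model$measure)
      for (i in seq_len(n)) {
        tries <- 0L
        while (!consistent(z[i, exec_idx], subjects$impaired[i]) &&
               tries < 1000L) {
          for (k in exec_idx) {
            mu <- (if (male[i]) model$mean_male[k] else model$mean_female[k]) +
              model$impaired_shift[k] * subjects$impaired[i]
            sl <- model$slopes[[k]]
            for (cv in names(sl)) mu <- mu + sl[[cv]] * covtab[[cv]][i]
            s <- if (male[i]) model$sd_male[k] else model$sd_female[k]
            z[i, k] <- rnorm(1L, mu, s)
          }
          tries <- tries + 1L
        }
        if (!consistent(z[i, exec_idx], subjects$impaired[i])) {
          # degenerate configuration: force the worst executive score across
          # the threshold from the matching truncated normal tail
          k <- exec_idx[which.min(z[i, exec_idx])]
          mu <- (if (male[i]) model$mean_male[k] else model$mean_female[k]) +
            model$impaired_shift[k] * subjects$impaired[i]
          s <- if (male[i]) model$sd_male[k] else model$sd_female[k]
          pth <- stats::pnorm(threshold, mu, s)
          u <- runif(1L)
          z[i, k] <- if (subjects$impaired[i]) {
            stats::qnorm(u * pth, mu, s)
          } else {
            stats::qnorm(pth + u * (1 - pth), mu, s)
          }
        }
      }
    }
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble::tibble(subject_id = subjects$subject_id),
                       tibble::as_tibble(as.data.frame(z))),
      -"subject_id", names_to = "measure", values_to = "z")
  })
}
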