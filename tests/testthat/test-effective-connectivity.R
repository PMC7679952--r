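test_that("Gaussian BIC matches the least-squares formula and is decomposable", {
  set.seed(14)
  n <- 400
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  d$C <- 0.8 * d$A + rnorm(n)
  nodes <- c("A", "B", "C")

  # empty graph: per-node score from the stated formula via an explicit lm
  empty <- dag_from_edges(nodes)
  s_empty <- gaussian_bic_score(d, empty)
  oracle <- sum(vapply(nodes, function(j) {
    rss <- sum(residuals(lm(d[[j]] ~ 1))^2)
    -(n / 2) * log(rss / n) - (0 + 2) / 2 * log(n)
  }, numeric(1)))
  expect_equal(as.numeric(s_empty), oracle, tolerance = 1e-10)

  # with a parent set: formula oracle again, through lm
  dag <- dag_from_edges(nodes, data.frame(parent = "A", child = "C"))
  s1 <- gaussian_bic_score(d, dag)
  oracle_c <- {
    rss <- sum(residuals(lm(C ~ A, data = d))^2)
    -(n / 2) * log(rss / n) - (1 + 2) / 2 * log(n)
  }
  expect_equal(as.numeric(s1) - as.numeric(s_empty),
               oracle_c - attr(s_empty, "per_node")[["C"]],
               tolerance = 1e-10)

  # adding a true parent strictly increases the score
  expect_gt(as.numeric(s1), as.numeric(s_empty))

  # invariant to column permutation
  expect_equal(as.numeric(gaussian_bic_score(d[c("C", "B", "A")], dag)),
               as.numeric(s1), tolerance = 1e-12)

  # score decomposability: a single-edge change only moves that child's term
  per0 <- attr(s_empty, "per_node")
  per1 <- attr(s1, "per_node")
  expect_equal(per0[c("A", "B")], per1[c("A", "B")])

  # collinear parents are a named error
  d2 <- d; d2$D <- d2$A
  dag2 <- dag_from_edges(c(nodes, "D"),
                         data.frame(parent = c("A", "D"), child = c("C", "C")))
  expect_error(gaussian_bic_score(d2, dag2), "C",
               class = "ctcnet_input_error")
})

test_that("hill climbing finds the exhaustive-oracle optimum on 3-node problems", {
  nodes <- c("A", "B", "C")
  dags <- enumerate_dags(nodes)
  expect_length(dags, 25)
  for (r in 1:20) {
    set.seed(100 + r)
    n <- 150
    x1 <- rnorm(n); x2 <- rnorm(n)
    d <- data.frame(A = x1, B = x2, C = 0.6 * x1 + 0.4 * x2 + rnorm(n))
    oracle_best <- max(vapply(dags, function(e) {
      as.numeric(gaussian_bic_score(d, e))
    }, numeric(1)))
    learned <- hill_climb_structure(d, restarts = 5, seed = r)
    expect_equal(learned$score, oracle_best, tolerance = 1e-8)
    expect_false(is.null(ctcnet:::topological_order(learned$nodes,
                                                    tidy(learned))))
  }
})

test_that("hill climbing matches the exhaustive oracle on 4-node problems (543 DAGs)", {
  nodes <- c("A", "B", "C", "D")
  dags <- enumerate_dags(nodes)
  expect_length(dags, 543)
  for (r in 1:3) {
    set.seed(200 + r)
    n <- 300
    a <- rnorm(n); b <- rnorm(n)
    d <- data.frame(A = a, B = b, C = 0.7 * a + rnorm(n),
                    D = 0.5 * a + 0.5 * b + rnorm(n))
    oracle_best <- max(vapply(dags, function(e) {
      as.numeric(gaussian_bic_score(d, e))
    }, numeric(1)))
    learned <- hill_climb_structure(d, restarts = 10, seed = r)
    expect_equal(learned$score, oracle_best, tolerance = 1e-8)
  }
})

test_that("hill climbing returns the empty graph on noise and identifies colliders", {
  for (r in 1:5) {
    set.seed(300 + r)
    d <- as.data.frame(matrix(rnorm(1000 * 4), 1000,
                              dimnames = list(NULL, c("A", "B", "C", "D"))))
    learned <- hill_climb_structure(d, restarts = 3, seed = r)
    expect_equal(sum(learned$adjacency), 0)
    # never below the empty-graph score
    expect_gte(learned$score,
               as.numeric(gaussian_bic_score(d, dag_from_edges(colnames(d)))))
  }
  set.seed(77)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = x1 + x2 + rnorm(n))
  learned <- hill_climb_structure(d, restarts = 5, seed = 1)
  e <- tidy(learned)
  expect_true(all(c("x1", "x2") %in% e$parent[e$child == "x3"]))
  expect_false(any((e$parent == "x1" & e$child == "x2") |
                     (e$parent == "x2" & e$child == "x1")))
  # forbidden edges are honoured
  forb <- data.frame(parent = "x1", child = "x3")
  l2 <- hill_climb_structure(d, restarts = 5, seed = 1,
                             forbidden_edges = forb)
  e2 <- tidy(l2)
  expect_false(any(e2$parent == "x1" & e2$child == "x3"))
})

test_that("CPDAG utilities identify equivalence classes correctly", {
  nodes <- c("A", "B", "C")
  chain <- dag_from_edges(nodes, data.frame(parent = c("A", "B"),
                                            child = c("B", "C")))
  fork <- dag_from_edges(nodes, data.frame(parent = c("B", "B"),
                                           child = c("A", "C")))
  collider <- dag_from_edges(nodes, data.frame(parent = c("A", "C"),
                                               child = c("B", "B")))
  expect_true(markov_equivalent(chain, fork))
  expect_false(markov_equivalent(chain, collider))
  # chain/fork CPDAG is fully undirected; collider CPDAG is fully compelled
  m <- cpdag(chain)
  expect_true(all(m[m == 1] == t(m)[m == 1]))
  mc <- cpdag(collider)
  expect_equal(mc["A", "B"], 1); expect_equal(mc["B", "A"], 0)
  expect_equal(mc["C", "B"], 1); expect_equal(mc["B", "C"], 0)

  expect_equal(structural_hamming(chain, collider), 1)
  expect_equal(structural_hamming(chain, fork), 1)
  expect_equal(structural_hamming(chain, fork, equivalence = TRUE), 0)
  d <- compare_structures(chain, collider)
  expect_equal(d$status, "reversed")
})

test_that("stratified learning recovers the planted group rewiring", {
  spec <- cohort_spec(n_male = 10, n_female = 10, impairment_prevalence = 0.5,
                      n_timepoints = 400, seed = 19)
  subjects <- generate_cohort(spec)
  # ensure each stratum is non-empty at this size
  expect_true(all(table(subjects$sex, subjects$impaired) > 0))
  panels <- simulate_cohort_timeseries(subjects, spec, weight_jitter = 0.02)
  strat <- learn_stratified(panels, subjects, restarts = 5, seed = 5)

  truth_common <- build_ground_truth("male_unimpaired")
  truth_fi <- build_ground_truth("female_impaired")
  for (g in c("male_unimpaired", "male_impaired", "female_unimpaired")) {
    expect_true(markov_equivalent(
      strat$models[[g]],
      dag_from_edges(truth_common$nodes, truth_common$edges)))
  }
  # impaired females: equivalence class of the rewired truth, and no
  # DLPFC-precuneus adjacency
  fi <- strat$models$female_impaired
  expect_true(markov_equivalent(
    fi, dag_from_edges(truth_fi$nodes, truth_fi$edges)))
  e <- tidy(fi)
  expect_false(any((grepl("DLPFC", e$parent) & grepl("Precuneus", e$child)) |
                     (grepl("Precuneus", e$parent) & grepl("DLPFC", e$child))))
  # male strata learned identical edge sets (all common edges compelled)
  expect_identical(tidy(strat$models$male_impaired),
                   tidy(strat$models$male_unimpaired))
  expect_true(all(strat$comparison$shd_cpdag[
    strat$comparison$stratum_a == "female_impaired" |
      strat$comparison$stratum_b == "female_impaired"] > 0))

  # identical data in every stratum gives identical models (determinism)
  subj2 <- tibble::tibble(subject_id = letters[1:4],
                          sex = factor(c("male", "male", "female", "female"),
                                       levels = c("male", "female")),
                          impaired = c(FALSE, TRUE, FALSE, TRUE))
  pan2 <- setNames(rep(panels[1], 4), letters[1:4])
  st2 <- learn_stratified(pan2, subj2, restarts = 3, seed = 2)
  edge_sets <- lapply(st2$models, tidy)
  for (k in 2:4) expect_identical(edge_sets[[k]], edge_sets[[1]])
  expect_true(all(st2$comparison$shd == 0))

  # a missing stratum is an identified error
  expect_error(learn_stratified(panels, subjects[subjects$sex == "male", ]),
               "female", class = "ctcnet_input_error")
})

test_that("edge weights are recovered under the common model", {
  net <- build_ground_truth("male_unimpaired")
  common <- dag_from_edges(net$nodes, net$edges)
  panels <- lapply(setNames(nm = sprintf("S%02d", 1:6)), function(s) {
    simulate_timeseries(net, 500, seed = match(s, sprintf("S%02d", 1:6)))
  })
  w <- estimate_edge_weights(common, panels, standardize = FALSE)
  truth <- net$edges
  merged <- dplyr::inner_join(w, truth, by = c("parent", "child"))
  # per-edge estimates (averaged over subjects) recover the generating
  # weights; individual subject estimates stay within sampling error
  per_edge <- dplyr::summarise(
    dplyr::group_by(merged, .data$parent, .data$child),
    est = mean(.data$weight.x), truth = .data$weight.y[1], .groups = "drop")
  expect_true(all(abs(per_edge$est - per_edge$truth) < 0.1))
  expect_true(all(abs(merged$weight.x - merged$weight.y) < 0.2))

  # single-edge network: subject-level recovery of weight 0.8 at 500 tp
  ab <- ctcnet:::new_ctc_network(
    c("A", "B"), data.frame(parent = "A", child = "B", weight = 0.8))
  pab <- list(P1 = simulate_timeseries(ab, 500, seed = 12))
  wab <- estimate_edge_weights(dag_from_edges(c("A", "B"), ab$edges), pab,
                               standardize = FALSE)
  expect_equal(wab$weight, 0.8, tolerance = 0.1 / 0.8)

  # an edge absent from the generating model but present in the fitted DAG
  # gets weight ~ 0
  aug <- dplyr::bind_rows(net$edges[c("parent", "child")],
                          data.frame(parent = "Thalamus_L",
                                     child = "DLPFC_L"))
  w2 <- estimate_edge_weights(dag_from_edges(net$nodes, aug), panels,
                              standardize = FALSE)
  fake <- w2$weight[w2$parent == "Thalamus_L" & w2$child == "DLPFC_L"]
  expect_true(all(abs(fake) < 0.15))

  # parent-free children emit no rows
  expect_false(any(w$child %in% c("Cerebellum_L", "Cerebellum_R",
                                  "Precuneus_L", "Precuneus_R")))

  # subjects with too few timepoints are skipped with a warning
  short <- panels
  short$S01 <- short$S01[1:4, ]
  expect_warning(w3 <- estimate_edge_weights(common, short),
                 class = "ctcnet_skip_warning")
  expect_false("S01" %in% w3$subject_id)
})

test_that("the interaction ANOVA matches a direct sums-of-squares oracle and is calibrated", {
  # balanced 2x2 with a planted pure interaction
  set.seed(99)
  n_cell <- 12
  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:(4 * n_cell)),
    sex = factor(rep(c("male", "female"), each = 2 * n_cell),
                 levels = c("male", "female")),
    impaired = rep(c(FALSE, TRUE, FALSE, TRUE), each = n_cell))
  delta <- ifelse(subjects$sex == "female" & subjects$impaired, 0.5, 0)
  weights <- tibble::tibble(subject_id = subjects$subject_id,
                            parent = "Cerebellum_L", child = "DLPFC_L",
                            weight = delta + rnorm(4 * n_cell, sd = 0.3))
  res <- interaction_anova(weights, subjects, "Cerebellum_L", "DLPFC_L")
  tab <- tidy(res)
  oracle <- balanced_anova_oracle(weights$weight, subjects$sex,
                                  subjects$impaired)
  expect_equal(tab$statistic[tab$term == "sex"], oracle$F1, tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "impaired"], oracle$F2,
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "sex:impaired"], oracle$Fint,
               tolerance = 1e-8)

  # identical cell means: interaction F has null expectation ~ df/(df-2)
  fs <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    w0 <- weights
    w0$weight <- rnorm(4 * n_cell)
    tidy(interaction_anova(w0, subjects, "Cerebellum_L",
                           "DLPFC_L"))$statistic[3]
  }, numeric(1))
  expect_gt(mean(fs), 0.6)
  expect_lt(mean(fs), 1.6)

  # an empty cell is an identified error
  bad <- subjects
  bad$impaired[bad$sex == "female"] <- FALSE
  expect_error(interaction_anova(weights, bad, "Cerebellum_L", "DLPFC_L"),
               "female", class = "ctcnet_input_error")
  expect_error(interaction_anova(weights, subjects, "DLPFC_L", "BOGUS"),
               class = "ctcnet_input_error")
})
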