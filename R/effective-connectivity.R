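# Effective connectivity: score-based Bayesian-network structure learning on
# regional time courses (Gaussian BIC, greedy hill-climbing with restarts),
# CPDAG equivalence-class utilities, stratified comparison, common-model edge
# weights, and the sex-by-impairment interaction ANOVA.

new_ctc_dag <- function(nodes, adj, per_node_scores = NULL, score = NA_real_) {
  dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = adj,
                 per_node_scores = per_node_scores, score = score),
            class = "ctc_dag")
}

#' Build a DAG model from an edge list
#'
#' @param nodes Character vector of node labels.
#' @param edges Data frame with `parent` and `child` columns (may be empty).
#' @return A `ctc_dag` (unscored); an error if the edge set is cyclic.
#' @export
dag_from_edges <- function(nodes, edges = NULL) {
  adj <- matrix(0L, length(nodes), length(nodes))
  dimnames(adj) <- list(nodes, nodes)
  if (!is.null(edges) && nrow(edges)) {
    if (is.null(topological_order(nodes, edges))) {
      abort("edge set contains a cycle", class = "ctcnet_input_error")
    }
    adj[cbind(match(edges$parent, nodes), match(edges$child, nodes))] <- 1L
  }
  new_ctc_dag(nodes, adj)
}

#' @export
print.ctc_dag <- function(x, ...) {
  cat(sprintf("<ctc_dag> %d nodes, %d directed edges", length(x$nodes),
              sum(x$adjacency)))
  if (is.finite(x$score)) cat(sprintf(", score %.3f", x$score))
  cat("\n")
  e <- tidy(x)
  if (nrow(e)) print(e, n = nrow(e))
  invisible(x)
}

#' @method tidy ctc_dag
#' @export
tidy.ctc_dag <- function(x, ...) {
  idx <- which(x$adjacency == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  tibble::tibble(parent = x$nodes[idx[, 1L]], child = x$nodes[idx[, 2L]])
}

#' @method glance ctc_dag
#' @export
glance.ctc_dag <- function(x, ...) {
  tibble::tibble(n_nodes = length(x$nodes), n_edges = sum(x$adjacency),
                 score = x$score)
}

#' @method autoplot ctc_dag
#' @export
autoplot.ctc_dag <- function(object, ...) {
  n <- length(object$nodes)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  pos <- data.frame(node = object$nodes, x = cos(ang), y = sin(ang))
  e <- tidy(object)
  seg <- merge(merge(e, pos, by.x = "parent", by.y = "node"),
               pos, by.x = "child", by.y = "node",
               suffixes = c("", "end"))
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(seg)) {
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "in"), type = "closed"),
      colour = "grey40")
  }
  p + ggplot2::geom_label(ggplot2::aes(label = .data$node), size = 3) +
    ggplot2::coord_equal() + ggplot2::theme_void()
}

# --- scoring ---------------------------------------------------------------

# Internal scoring context: ML covariance + cache so node scores are computed
# once per (node, parent-set).
score_context <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("data must be finite numeric", class = "ctcnet_input_error")
  }
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  list(S = crossprod(xc) / n, n = n, nodes = colnames(x),
       cache = new.env(parent = emptyenv()))
}

score_node <- function(ctx, j, parents) {
  key <- paste0(j, "|", paste(sort(parents), collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- ctx$S; n <- ctx$n
  sigma2 <- if (length(parents) == 0L) S[j, j] else {
    sol <- tryCatch(solve(S[parents, parents, drop = FALSE],
                          S[parents, j, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      abort(sprintf("singular parent design for node `%s`", j),
            class = "ctcnet_input_error")
    }
    S[j, j] - drop(crossprod(S[parents, j, drop = FALSE], sol))
  }
  if (sigma2 <= .Machine$double.eps) {
    abort(sprintf("residual variance of node `%s` is numerically zero", j),
          class = "ctcnet_input_error")
  }
  val <- -(n / 2) * log(sigma2) - (length(parents) + 2) / 2 * log(n)
  ctx$cache[[key]] <- val
  val
}

#' Gaussian BIC score of a DAG
#'
#' Decomposable penalized Gaussian log-likelihood: per node `j` with parent
#' set `P`, least squares of `j` on `P` with intercept gives residual sum of
#' squares `RSS_j`, and the node score is
#' `-(n/2) log(RSS_j / n) - (|P| + 2)/2 log(n)` (parameters: `|P|`
#' coefficients, intercept, residual variance). The total is the sum over
#' nodes; higher is better. Invariant to the column order of the data.
#'
#' @param data Data frame or matrix of samples x nodes (a `time` column is
#'   dropped).
#' @param dag A `ctc_dag` or an edge data frame (`parent`, `child`).
#' @return The total score, with per-node scores in attribute `per_node`.
#' @export
gaussian_bic_score <- function(data, dag) {
  data <- as.data.frame(data)[setdiff(colnames(data), "time")]
  if (is.data.frame(dag) && !inherits(dag, "ctc_dag")) {
    dag <- dag_from_edges(colnames(data), dag)
  }
  ctx <- score_context(data)
  if (ctx$n <= length(ctx$nodes) + max(colSums(dag$adjacency))) {
    abort("too few samples for the largest parent set",
          class = "ctcnet_input_error")
  }
  if (!all(dag$nodes %in% ctx$nodes)) {
    abort("DAG nodes must match data columns", class = "ctcnet_input_error")
  }
  per <- vapply(ctx$nodes, function(j) {
    score_node(ctx, j, dag$nodes[dag$adjacency[, j] == 1L])
  }, numeric(1))
  structure(sum(per), per_node = per)
}

# TRUE if a path child -> ... -> target exists in adj (used to veto cycles).
has_path <- function(adj, from, to) {
  seen <- logical(nrow(adj))
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] == 1L))
  }
  FALSE
}

#' Learn a DAG by greedy hill-climbing over the Gaussian BIC score
#'
#' Greedy search over single-edge add / delete / reverse operators, accepting
#' the best strictly score-improving acyclic move until none exists. The first
#' restart starts from the empty graph; further restarts start from random
#' sparse DAGs. The best-scoring model across restarts is returned, so the
#' result never scores below the empty graph. Deterministic given `seed`
#' (ties between moves are broken in a fixed operator/edge order). Per-node
#' scores are cached; caching cannot change results because the score
#' decomposes over nodes.
#'
#' @param data Samples x nodes data frame/matrix (a `time` column is
#'   dropped).
#' @param restarts Number of search starts (>= 1, default 10).
#' @param max_iter Maximum accepted moves per start.
#' @param seed Optional integer seed for the random restarts.
#' @param forbidden_edges Optional data frame (`parent`, `child`) of directed
#'   edges the search must never contain.
#' @return A scored `ctc_dag`.
#' @export
#' @examples
#' net <- build_ground_truth("male_unimpaired")
#' d <- simulate_timeseries(net, 300, seed = 2)
#' hill_climb_structure(d, restarts = 3, seed = 1)
hill_climb_structure <- function(data, restarts = 10, max_iter = 500,
                                 seed = NULL, forbidden_edges = NULL) {
  restarts <- check_count(restarts, "restarts")
  data <- as.data.frame(data)[setdiff(colnames(data), "time")]
  ctx <- score_context(data)
  nodes <- ctx$nodes
  p <- length(nodes)
  forb <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (!is.null(forbidden_edges) && nrow(forbidden_edges)) {
    forb[cbind(match(forbidden_edges$parent, nodes),
               match(forbidden_edges$child, nodes))] <- TRUE
  }

  # One search run: strictly-improving greedy phase, then a bounded tabu
  # phase that accepts the best non-improving move (never the inverse of a
  # recent move) to escape collider-orientation local optima; the best
  # structure seen is returned.
  climb <- function(adj, tabu_len = 10L, patience = 15L) {
    per <- vapply(seq_len(p), function(j) {
      score_node(ctx, nodes[j], nodes[adj[, j] == 1L])
    }, numeric(1))
    best_adj <- adj; best_per <- per; best_score <- sum(per)
    tabu <- character(0)
    stall <- 0L
    for (iter in seq_len(max_iter)) {
      best <- list(delta = -Inf, move = NULL)
      for (a in seq_len(p)) for (b in seq_len(p)) {
        if (a == b) next
        if (adj[a, b] == 1L) {
          # delete a -> b
          d_del <- score_node(ctx, nodes[b],
                              nodes[adj[, b] == 1L & seq_len(p) != a]) - per[b]
          if (d_del > best$delta && !(paste(1L, a, b) %in% tabu)) {
            best <- list(delta = d_del, move = c(1L, a, b))
          }
          # reverse a -> b  (becomes b -> a)
          if (!forb[b, a] && !(paste(2L, a, b) %in% tabu)) {
            adj2 <- adj; adj2[a, b] <- 0L
            if (!has_path(adj2, a, b)) {
              d_rev <- d_del +
                score_node(ctx, nodes[a],
                           nodes[c(which(adj[, a] == 1L), b)]) - per[a]
              if (d_rev > best$delta) best <- list(delta = d_rev,
                                                   move = c(2L, a, b))
            }
          }
        } else if (adj[b, a] == 0L && !forb[a, b] &&
                   !(paste(0L, a, b) %in% tabu)) {
          # add a -> b
          if (!has_path(adj, b, a)) {
            d_add <- score_node(ctx, nodes[b],
                                nodes[c(which(adj[, b] == 1L), a)]) - per[b]
            if (d_add > best$delta) best <- list(delta = d_add,
                                                 move = c(0L, a, b))
          }
        }
      }
      if (is.null(best$move)) break
      op <- best$move[1L]; a <- best$move[2L]; b <- best$move[3L]
      if (op == 0L) {
        adj[a, b] <- 1L
        inverse <- paste(1L, a, b)
      } else if (op == 1L) {
        adj[a, b] <- 0L
        inverse <- paste(0L, a, b)
      } else {
        adj[a, b] <- 0L; adj[b, a] <- 1L
        per[a] <- score_node(ctx, nodes[a], nodes[adj[, a] == 1L])
        inverse <- paste(2L, b, a)
      }
      per[b] <- score_node(ctx, nodes[b], nodes[adj[, b] == 1L])
      tabu <- c(inverse, head(tabu, tabu_len - 1L))
      if (sum(per) > best_score + 1e-9) {
        best_adj <- adj; best_per <- per; best_score <- sum(per)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    list(adj = best_adj, per = best_per, score = best_score)
  }

  # Iterated local search: the first climb starts from the empty graph; each
  # further restart either perturbs the incumbent (escaping covered-edge
  # orientation traps that single-edge moves cannot leave) or, every third
  # restart, starts from a fresh random sparse DAG.
  perturb <- function(adj, k = 3L) {
    for (m in seq_len(k)) {
      a <- sample.int(p, 1L); b <- sample.int(p, 1L)
      if (a == b) next
      if (adj[a, b] == 1L) {
        adj[a, b] <- 0L
        if (!forb[b, a] && !has_path(adj, a, b) && runif(1) < 0.7) {
          adj[b, a] <- 1L
        }
      } else if (adj[b, a] == 0L && !forb[a, b] && !has_path(adj, b, a)) {
        adj[a, b] <- 1L
      }
    }
    adj
  }
  random_start <- function() {
    adj0 <- matrix(0L, p, p)
    ord <- sample.int(p)
    for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
      if (runif(1) < 0.25 && !forb[ord[i], ord[j]]) adj0[ord[i], ord[j]] <- 1L
    }
    adj0
  }
  withr_seed(seed, {
    best <- climb(matrix(0L, p, p))
    for (r in seq_len(restarts - 1L)) {
      adj0 <- if (r %% 2L == 0L) perturb(best$adj) else random_start()
      res <- climb(adj0)
      if (res$score > best$score + 1e-9) best <- res
    }
    new_ctc_dag(nodes, best$adj, setNames(best$per, nodes), best$score)
  })
}

# --- equivalence classes ---------------------------------------------------

# V-structures of a DAG: tibble(parent1, child, parent2) with parent1 < parent2
# and the two parents non-adjacent.
v_structures <- function(dag) {
  adj <- dag$adjacency
  nodes <- dag$nodes
  sk <- (adj + t(adj)) > 0
  out <- list()
  for (c in seq_along(nodes)) {
    pars <- which(adj[, c] == 1L)
    if (length(pars) >= 2L) {
      for (cmb in utils::combn(pars, 2L, simplify = FALSE)) {
        if (!sk[cmb[1L], cmb[2L]]) {
          out[[length(out) + 1L]] <-
            c(nodes[cmb[1L]], nodes[c], nodes[cmb[2L]])
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(parent1 = character(), child = character(),
                          parent2 = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(parent1 = pmin(m[, 1L], m[, 3L]), child = m[, 2L],
                 parent2 = pmax(m[, 1L], m[, 3L])) |> dplyr::arrange(
                   .data$parent1, .data$child, .data$parent2)
}

#' Completed partially directed graph (CPDAG) of a DAG
#'
#' Returns the Markov-equivalence-class representative: v-structure edges are
#' compelled and Meek's orientation rules are applied to closure; remaining
#' edges stay undirected. Used to compare learned structures without
#' over-claiming directions that Gaussian likelihoods cannot identify.
#'
#' @param dag A `ctc_dag`.
#' @return A matrix `M` with `M[i,j] = 1` for a compelled edge `i -> j` and
#'   `M[i,j] = M[j,i] = 1` for an undirected (reversible) edge.
#' @export
cpdag <- function(dag) {
  adj <- dag$adjacency
  nodes <- dag$nodes
  p <- length(nodes)
  sk <- ((adj + t(adj)) > 0) * 1L
  m <- sk  # start fully undirected
  vs <- v_structures(dag)
  for (k in seq_len(nrow(vs))) {
    i1 <- match(vs$parent1[k], nodes); i2 <- match(vs$parent2[k], nodes)
    cc <- match(vs$child[k], nodes)
    m[cc, i1] <- 0L; m[cc, i2] <- 0L
  }
  directed <- function(i, j) m[i, j] == 1L && m[j, i] == 0L
  undirected <- function(i, j) m[i, j] == 1L && m[j, i] == 1L
  adjacent <- function(i, j) sk[i, j] == 1L
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (a == b || !undirected(a, b)) next
      orient <- FALSE
      for (c in seq_len(p)) {
        if (c == a || c == b) next
        # R1: c -> a, a - b, c not adjacent b  =>  a -> b
        if (directed(c, a) && !adjacent(c, b)) orient <- TRUE
        # R2: a -> c -> b and a - b  =>  a -> b
        if (directed(a, c) && directed(c, b)) orient <- TRUE
        if (!orient) {
          for (d in seq_len(p)) {
            if (d %in% c(a, b, c)) next
            # R3: a - c, a - d, c -> b, d -> b, c,d non-adjacent => a -> b
            if (undirected(a, c) && undirected(a, d) && directed(c, b) &&
                directed(d, b) && !adjacent(c, d)) orient <- TRUE
            # R4: a - d, d -> c, c -> b, a - c or a adjacent c, c,d handled
            if (undirected(a, d) && directed(d, c) && directed(c, b) &&
                adjacent(a, c) && !adjacent(d, b)) orient <- TRUE
            if (orient) break
          }
        }
        if (orient) break
      }
      if (orient) { m[b, a] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  dimnames(m) <- list(nodes, nodes)
  m
}

#' Are two DAGs Markov equivalent?
#'
#' Equivalent iff they share skeleton and v-structures (Verma-Pearl).
#'
#' @param dag_a,dag_b `ctc_dag` objects on the same node set.
#' @return Logical.
#' @export
markov_equivalent <- function(dag_a, dag_b) {
  stopifnot(identical(sort(dag_a$nodes), sort(dag_b$nodes)))
  ord <- dag_a$nodes
  ska <- (dag_a$adjacency + t(dag_a$adjacency)) > 0
  adjb <- dag_b$adjacency[ord, ord]
  skb <- (adjb + t(adjb)) > 0
  identical(ska, skb) &&
    identical(as.data.frame(v_structures(dag_a)),
              as.data.frame(v_structures(new_ctc_dag(ord, adjb))))
}

#' Recovery of the identifiable structure of a generating network
#'
#' Compares a learned DAG with the ground truth at the level the data can
#' identify: does the learned skeleton contain every true skeleton edge, and
#' does the learned model contain every true v-structure? Exact equivalence
#' (`markov_equivalent`) is reported alongside; it additionally requires that
#' no spurious edge was added.
#'
#' @param dag Learned `ctc_dag`.
#' @param truth Generating `ctc_dag` (or `ctc_network` edge tibble via
#'   [dag_from_edges()]).
#' @return One-row tibble: `skeleton_recovered`, `v_structures_recovered`,
#'   `recovered` (both), `markov_equivalent`, `shd_cpdag`.
#' @export
structure_recovery <- function(dag, truth) {
  if (inherits(truth, "ctc_network")) {
    truth <- dag_from_edges(truth$nodes, truth$edges)
  }
  ord <- truth$nodes
  sk_t <- (truth$adjacency + t(truth$adjacency)) > 0
  adj_l <- dag$adjacency[ord, ord]
  sk_l <- (adj_l + t(adj_l)) > 0
  vs_t <- v_structures(truth)
  vs_l <- v_structures(new_ctc_dag(ord, adj_l))
  v_ok <- nrow(vs_t) == 0L ||
    nrow(dplyr::inner_join(vs_t, vs_l,
                           by = c("parent1", "child", "parent2"))) == nrow(vs_t)
  sk_ok <- all(sk_l[sk_t])
  tibble::tibble(
    skeleton_recovered = sk_ok, v_structures_recovered = v_ok,
    recovered = sk_ok && v_ok,
    markov_equivalent = markov_equivalent(dag, truth),
    shd_cpdag = structural_hamming(dag, truth, equivalence = TRUE))
}

#' Structural Hamming distance between two structures
#'
#' Number of unordered node pairs whose edge state (absent, `i -> j`,
#' `j -> i`, or undirected when comparing CPDAGs) differs; a reversal counts
#' as one difference.
#'
#' @param dag_a,dag_b `ctc_dag` objects on the same node set.
#' @param equivalence Compare CPDAGs instead of raw DAGs.
#' @return Integer distance.
#' @export
structural_hamming <- function(dag_a, dag_b, equivalence = FALSE) {
  ord <- dag_a$nodes
  a <- if (equivalence) cpdag(dag_a) else dag_a$adjacency
  b <- if (equivalence) cpdag(dag_b)[ord, ord] else dag_b$adjacency[ord, ord]
  state <- function(m, i, j) paste0(m[i, j], m[j, i])
  pr <- region_pairs(ord)
  sum(vapply(seq_len(nrow(pr)), function(k) {
    state(a, pr$i[k], pr$j[k]) != state(b, pr$i[k], pr$j[k])
  }, logical(1)))
}

#' Edge-level differences between two DAGs
#'
#' @param dag_a,dag_b `ctc_dag` objects on the same node set (`dag_a` is the
#'   reference).
#' @return Tibble of differing pairs: `region_a`, `region_b`, `status`
#'   (`added` = in `dag_b` only, `removed` = in `dag_a` only, `reversed`).
#' @export
compare_structures <- function(dag_a, dag_b) {
  ord <- dag_a$nodes
  a <- dag_a$adjacency; b <- dag_b$adjacency[ord, ord]
  pr <- region_pairs(ord)
  status <- vapply(seq_len(nrow(pr)), function(k) {
    i <- pr$i[k]; j <- pr$j[k]
    ea <- a[i, j] + 2L * a[j, i]; eb <- b[i, j] + 2L * b[j, i]
    if (ea == eb) "" else if (ea == 0L) "added" else if (eb == 0L) "removed"
    else "reversed"
  }, character(1))
  tibble::tibble(region_a = pr$region_a, region_b = pr$region_b,
                 status = status)[status != "", ]
}

# --- stratified learning and weights ---------------------------------------

# Pool panels: per-subject z-standardization of each region, then row-bind.
pool_panels <- function(panels, ids = names(panels)) {
  do.call(rbind, lapply(panels[ids], function(p) {
    x <- as.matrix(p[setdiff(names(p), "time")])
    scale(x)
  }))
}

#' Learn effective connectivity structure per sex-by-impairment stratum
#'
#' Per stratum, subject panels are z-standardized per region, concatenated,
#' and a DAG is learned by [hill_climb_structure()]. The comparison reports
#' pairwise structural Hamming distances at the raw DAG and at the
#' equivalence-class (CPDAG) level, plus edge-level differences against a
#' reference stratum.
#'
#' @param panels Named list of per-subject panels.
#' @param subjects Subject table (`subject_id`, `sex`, `impaired`).
#' @param reference Stratum used for the edge-level difference listing.
#' @param ... Passed to [hill_climb_structure()].
#' @return A list: `models` (named `ctc_dag` list), `comparison` (pairwise
#'   SHD tibble), `edge_diffs` (differences vs the reference stratum).
#' @export
learn_stratified <- function(panels, subjects,
                             reference = "female_unimpaired", ...) {
  groups <- c("male_unimpaired", "male_impaired",
              "female_unimpaired", "female_impaired")
  subjects$group <- factor(group_label(subjects$sex, subjects$impaired),
                           levels = groups)
  strata <- split(subjects$subject_id, subjects$group)
  if (any(lengths(strata) == 0L)) {
    abort(paste0("empty stratum: ",
                 paste(names(strata)[lengths(strata) == 0L], collapse = ", ")),
          class = "ctcnet_input_error")
  }
  models <- lapply(strata, function(ids) {
    hill_climb_structure(pool_panels(panels, ids), ...)
  })
  nm <- names(models)
  pairs <- utils::combn(nm, 2L, simplify = FALSE)
  comparison <- dplyr::bind_rows(lapply(pairs, function(pp) {
    tibble::tibble(
      stratum_a = pp[1L], stratum_b = pp[2L],
      shd = structural_hamming(models[[pp[1L]]], models[[pp[2L]]]),
      shd_cpdag = structural_hamming(models[[pp[1L]]], models[[pp[2L]]],
                                     equivalence = TRUE))
  }))
  ref <- if (reference %in% nm) reference else nm[1L]
  edge_diffs <- dplyr::bind_rows(lapply(setdiff(nm, ref), function(g) {
    d <- compare_structures(models[[ref]], models[[g]])
    if (nrow(d)) dplyr::mutate(d, stratum = g, .before = 1L) else NULL
  }))
  list(models = models, comparison = comparison, edge_diffs = edge_diffs,
       reference = ref)
}

#' Learn the best-fit common model on the entire cohort
#'
#' Pools all subjects' standardized panels and runs the structure search.
#'
#' @param panels Named list of per-subject panels.
#' @param ... Passed to [hill_climb_structure()].
#' @return A scored `ctc_dag`.
#' @export
fit_common_model <- function(panels, ...) {
  hill_climb_structure(pool_panels(panels), ...)
}

#' Estimate per-subject connectivity weights under a common model
#'
#' For each subject, each child node of the common DAG is regressed on its
#' parents; the fitted coefficients are the subject's edge weights. With
#' `standardize = TRUE` (default) variables are z-scored first, giving
#' standardized coefficients; with `FALSE` the coefficients are on the raw
#' generative scale. Subjects with too few timepoints for the largest
#' regression are skipped with a warning. Children with no parents emit no
#' rows.
#'
#' @param dag The common `ctc_dag`.
#' @param panels Named list of per-subject panels.
#' @param standardize Z-score each region before regression.
#' @return Tibble: `subject_id`, `parent`, `child`, `weight`.
#' @export
estimate_edge_weights <- function(dag, panels, standardize = TRUE) {
  kids <- dag$nodes[colSums(dag$adjacency) > 0]
  out <- vector("list", length(panels))
  skipped <- character(0)
  for (s in names(panels)) {
    x <- as.matrix(panels[[s]][setdiff(names(panels[[s]]), "time")])
    if (nrow(x) < max(colSums(dag$adjacency)) + 3L) {
      skipped <- c(skipped, s)
      next
    }
    if (standardize) x <- scale(x)
    rows <- lapply(kids, function(ch) {
      pars <- dag$nodes[dag$adjacency[, ch] == 1L]
      fit <- stats::lm.fit(cbind(1, x[, pars, drop = FALSE]), x[, ch])
      tibble::tibble(subject_id = s, parent = pars, child = ch,
                     weight = unname(fit$coefficients[-1L]))
    })
    out[[s]] <- dplyr::bind_rows(rows)
  }
  if (length(skipped)) {
    warn(paste0("skipped subjects with insufficient timepoints: ",
                paste(skipped, collapse = ", ")),
         class = "ctcnet_skip_warning")
  }
  dplyr::bind_rows(out)
}

#' Find the common-model edge between two regions, in either orientation
#'
#' @param dag A `ctc_dag`.
#' @param region_a,region_b Region labels.
#' @return A one-row tibble (`parent`, `child`) or zero rows if the regions
#'   are not adjacent in the model.
#' @export
match_edge <- function(dag, region_a, region_b) {
  e <- tidy(dag)
  e[(e$parent == region_a & e$child == region_b) |
      (e$parent == region_b & e$child == region_a), ]
}

#' Two-way interaction ANOVA on an edge's connectivity weights
#'
#' Fixed-effects two-way ANOVA of one edge's per-subject weights on sex,
#' impairment, and their interaction, using Type II sums of squares for the
#' unbalanced design. Tests whether the strength (and, through the common
#' model's orientation, direction) of the connection differs by sex and
#' executive dysfunction.
#'
#' @param weights Edge-weight table from [estimate_edge_weights()].
#' @param subjects Subject table (`subject_id`, `sex`, `impaired`).
#' @param parent,child Edge to test (as present in the common model).
#' @return A `ctc_anova` object; `tidy()` gives the per-term F table.
#' @export
interaction_anova <- function(weights, subjects, parent, child) {
  w <- weights[weights$parent == parent & weights$child == child, ]
  if (!nrow(w)) {
    abort(sprintf("edge %s -> %s has no weights", parent, child),
          class = "ctcnet_input_error")
  }
  d <- dplyr::inner_join(w, subjects[c("subject_id", "sex", "impaired")],
                         by = "subject_id")
  d$impaired <- factor(ifelse(d$impaired, "impaired", "unimpaired"),
                       levels = c("unimpaired", "impaired"))
  d$sex <- factor(as.character(d$sex), levels = c("male", "female"))
  cells <- table(d$sex, d$impaired)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)
    abort(sprintf("cell %s x %s has fewer than 2 subjects",
                  rownames(cells)[bad[1L, 1L]], colnames(cells)[bad[1L, 2L]]),
          class = "ctcnet_input_error")
  }
  fit <- lm(weight ~ sex * impaired, data = d)
  a2 <- car::Anova(fit, type = 2)
  tab <- tibble::tibble(
    term = rownames(a2),
    sumsq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    statistic = a2[["F value"]],
    p.value = a2[["Pr(>F)"]]
  )
  structure(list(fit = fit, table = tab, edge = c(parent = parent,
                                                  child = child),
                 data = tibble::as_tibble(d)),
            class = "ctc_anova")
}

#' @export
print.ctc_anova <- function(x, ...) {
  cat(sprintf("<ctc_anova> edge %s -> %s (type II SS)\n",
              x$edge[["parent"]], x$edge[["child"]]))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Tidy an edge-weight ANOVA
#'
#' @param x A `ctc_anova`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `sumsq`, `df`,
#'   `statistic` (F), `p.value`.
#' @method tidy ctc_anova
#' @export
tidy.ctc_anova <- function(x, ...) x$table

#' @rdname tidy.ctc_anova
#' @method glance ctc_anova
#' @export
glance.ctc_anova <- function(x, ...) {
  inter <- x$table[x$table$term == "sex:impaired", ]
  tibble::tibble(f.interaction = inter$statistic,
                 p.interaction = inter$p.value,
                 df.residual = x$table$df[x$table$term == "Residuals"],
                 n = nrow(x$data))
}

#' @method autoplot ctc_anova
#' @export
autoplot.ctc_anova <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$impaired, y = .data$weight,
                               colour = .data$sex, group = .data$sex)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(
      y = sprintf("weight of %s -> %s", object$edge[["parent"]],
                  object$edge[["child"]]),
      x = NULL, colour = NULL,
      title = "Edge weight by sex and executive impairment")
}
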