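# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Floyd-Warshall all-pairs hop counts on a binary adjacency matrix.
fw_distances <- function(adj) {
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(nrow(adj))) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

efficiency_oracle <- function(adj) {
  d <- fw_distances(adj)
  n <- nrow(adj)
  sum(1 / d[row(d) != col(d)]) / (n * (n - 1))
}

# All undirected graphs on n labelled nodes, as adjacency matrices.
all_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  lapply(seq_len(2^m) - 1L, function(mask) {
    adj <- matrix(0L, n, n)
    on <- bitwAnd(mask, 2L^(seq_len(m) - 1L)) > 0
    adj[pairs[on, , drop = FALSE]] <- 1L
    adj <- adj + t(adj)
    dimnames(adj) <- list(paste0("R", 1:n), paste0("R", 1:n))
    adj
  })
}

# All DAGs on the given labelled nodes (each unordered pair: absent, ->, <-),
# filtered for acyclicity by an independent check (R's topo sort via repeated
# leaf removal).
enumerate_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  m <- nrow(pairs)
  states <- as.matrix(expand.grid(rep(list(0:2), m)))
  acyclic <- function(adj) {
    left <- seq_len(nrow(adj))
    repeat {
      if (!length(left)) return(TRUE)
      outdeg <- rowSums(adj[left, left, drop = FALSE])
      leaves <- left[outdeg == 0]
      if (!length(leaves)) return(FALSE)
      left <- setdiff(left, leaves)
    }
  }
  out <- list()
  for (i in seq_len(nrow(states))) {
    adj <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    s <- states[i, ]
    fwd <- s == 1L
    bwd <- s == 2L
    adj[pairs[fwd, , drop = FALSE]] <- 1L
    adj[pairs[bwd, c(2L, 1L), drop = FALSE]] <- 1L
    if (acyclic(adj)) {
      e <- which(adj == 1L, arr.ind = TRUE)
      out[[length(out) + 1L]] <- data.frame(parent = nodes[e[, 1L]],
                                            child = nodes[e[, 2L]])
    }
  }
  out
}

# Wrap a plain symmetric matrix as a connectivity object (bypasses the
# correlation step so hand-built matrices can be thresholded).
as_conn <- function(m, regions = NULL) {
  if (is.null(rownames(m))) {
    regions <- regions %||% paste0("R", seq_len(nrow(m)))
    dimnames(m) <- list(regions, regions)
  }
  structure(m, class = c("ctc_connectivity", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two series with exactly the requested Pearson correlation.
pair_with_cor <- function(r, n = 40) {
  x <- scale(seq_len(n))[, 1]
  set.seed(42)
  e <- stats::residuals(stats::lm(rnorm(n) ~ x))
  e <- scale(e)[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  data.frame(A = x, B = y)
}

# Direct sums-of-squares two-way ANOVA decomposition for a balanced 2x2
# design (classic textbook formulas).
balanced_anova_oracle <- function(y, f1, f2) {
  gm <- mean(y)
  ss <- function(groups) {
    sum(tapply(y, groups, function(v) length(v) * (mean(v) - gm)^2))
  }
  ss1 <- ss(f1); ss2 <- ss(f2)
  cellm <- tapply(y, list(f1, f2), mean)
  ncell <- table(f1, f2)
  sscells <- sum(ncell * (cellm - gm)^2)
  ssint <- sscells - ss1 - ss2
  sse <- sum((y - ave(y, f1, f2))^2)
  dfe <- length(y) - 4L
  list(
    F1 = (ss1 / 1) / (sse / dfe),
    F2 = (ss2 / 1) / (sse / dfe),
    Fint = (ssint / 1) / (sse / dfe)
  )
}

# Small deterministic cohort + panels for integration-style tests.
tiny_cohort <- function(n = 6, seed = 11, n_timepoints = 120) {
  spec <- cohort_spec(n_male = n, n_female = n, impairment_prevalence = 0.5,
                      n_timepoints = n_timepoints, seed = seed)
  subjects <- generate_cohort(spec)
  list(spec = spec, subjects = subjects,
       panels = simulate_cohort_timeseries(subjects, spec))
}
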