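# Functional connectivity: Fisher-z correlation matrices, proportional
# density thresholding, and the minimum-density / fragmentation search.

#' Compute a Fisher-z functional connectivity matrix
#'
#' Pearson-correlates every pair of regional time courses and applies the
#' Fisher z-transform `atanh(r)`, with `r` clipped to `±(1 - clip_tol)` so a
#' duplicated (perfectly correlated) region yields a large finite value rather
#' than infinity. The diagonal is fixed at zero.
#'
#' @param panel Data frame of regional time courses (one column per region; a
#'   `time` column, if present, is ignored). At least 2 regions, no missing
#'   values, and every region must have nonzero variance.
#' @param clip_tol Clipping tolerance applied to `|r|` before `atanh`.
#' @return A `ctc_connectivity` object (symmetric numeric matrix with region
#'   dimnames and a `subject_id` attribute carried over from the panel).
#' @export
#' @examples
#' p <- simulate_timeseries(build_ground_truth("male_unimpaired"), 60, seed = 1)
#' compute_connectivity(p)
compute_connectivity <- function(panel, clip_tol = 1e-7) {
  stopifnot(is.data.frame(panel))
  x <- as.matrix(panel[setdiff(names(panel), "time")])
  if (ncol(x) < 2L) {
    abort("panel must contain at least 2 regions", class = "ctcnet_input_error")
  }
  if (anyNA(x)) abort("panel contains missing values", class = "ctcnet_input_error")
  v <- apply(x, 2L, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance region(s): ",
                 paste(colnames(x)[v == 0], collapse = ", ")),
          class = "ctcnet_input_error")
  }
  r <- cor(x)
  r <- pmin(pmax(r, -(1 - clip_tol)), 1 - clip_tol)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # enforce exact symmetry
  structure(z, class = c("ctc_connectivity", "matrix"),
            subject_id = attr(panel, "subject_id"))
}

#' @export
print.ctc_connectivity <- function(x, ...) {
  cat(sprintf("<ctc_connectivity> %d regions\n", nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @method tidy ctc_connectivity
#' @export
tidy.ctc_connectivity <- function(x, ...) {
  pr <- region_pairs(rownames(x))
  tibble::tibble(region_a = pr$region_a, region_b = pr$region_b,
                 z = x[cbind(pr$i, pr$j)])
}

#' Threshold a connectivity matrix at a proportional density
#'
#' Retains the `ceiling(d * n(n-1)/2)` largest positive Fisher-z entries as
#' binary undirected edges. Negative (anticorrelated) entries are never
#' admitted; ties are broken by the fixed lexicographic region-pair order so
#' results are exactly reproducible. If fewer positive entries exist than
#' requested, all positive entries are kept and a warning records the achieved
#' density.
#'
#' @param conn A `ctc_connectivity` matrix.
#' @param density Target edge density in `(0, 1]`.
#' @param partition Optional named vector mapping regions to modules (defaults
#'   to the hemispheric partition when labels end in `_L`/`_R`).
#' @return A `ctc_graph`: binary symmetric adjacency, region labels, requested
#'   and achieved density, and the module partition.
#' @export
threshold_at_density <- function(conn, density, partition = NULL) {
  stopifnot(inherits(conn, "ctc_connectivity"))
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
      density <= 0 || density > 1) {
    abort("`density` must lie in (0, 1]", class = "ctcnet_input_error")
  }
  regions <- rownames(conn)
  pr <- region_pairs(regions)
  zvals <- unclass(conn)[cbind(pr$i, pr$j)]
  n <- length(regions)
  n_pairs <- n * (n - 1L) / 2L
  m <- as.integer(ceiling(density * n_pairs))
  pos <- which(zvals > 0)
  # order positive entries by decreasing z; ties fall back to pair order
  ord <- pos[order(-zvals[pos], pos)]
  if (length(ord) < m) {
    warn(sprintf(
      "only %d positive connections available for %d requested edges; achieved density %.3f",
      length(ord), m, length(ord) / n_pairs), class = "ctcnet_density_warning")
    keep <- ord
  } else {
    keep <- ord[seq_len(m)]
  }
  adj <- matrix(0L, n, n, dimnames = list(regions, regions))
  adj[cbind(pr$i[keep], pr$j[keep])] <- 1L
  adj <- adj + t(adj)
  new_ctc_graph(adj, density_requested = density, partition = partition,
                subject_id = attr(conn, "subject_id"))
}

#' Construct a brain graph from a binary adjacency matrix
#'
#' Mostly useful for testing metrics on hand-built graphs; [threshold_at_density()]
#' is the usual constructor.
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal and region
#'   dimnames.
#' @param partition Optional named region -> module vector.
#' @return A `ctc_graph`.
#' @export
brain_graph <- function(adjacency, partition = NULL) {
  if (is.null(rownames(adjacency))) {
    rn <- paste0("R", seq_len(nrow(adjacency)))
    dimnames(adjacency) <- list(rn, rn)
  }
  if (is.null(partition)) {
    partition <- setNames(rep("all", nrow(adjacency)), rownames(adjacency))
  }
  new_ctc_graph(adjacency, partition = partition)
}

new_ctc_graph <- function(adj, density_requested = NA_real_, partition = NULL,
                          subject_id = NULL) {
  regions <- rownames(adj)
  stopifnot(isTRUE(all.equal(adj, t(adj))), all(diag(adj) == 0))
  if (is.null(partition) && all(grepl("_[LR]$", regions))) {
    partition <- hemisphere_partition(regions)
  }
  n <- nrow(adj)
  structure(list(
    adjacency = adj,
    regions = regions,
    density_requested = density_requested,
    density = sum(adj) / 2 / (n * (n - 1) / 2),
    partition = partition,
    subject_id = subject_id
  ), class = "ctc_graph")
}

#' @export
print.ctc_graph <- function(x, ...) {
  cat(sprintf("<ctc_graph> %d regions, %d edges (density %.3f)\n",
              length(x$regions), sum(x$adjacency) / 2, x$density))
  invisible(x)
}

#' @method tidy ctc_graph
#' @export
tidy.ctc_graph <- function(x, ...) {
  pr <- region_pairs(x$regions)
  keep <- x$adjacency[cbind(pr$i, pr$j)] == 1L
  tibble::tibble(region_a = pr$region_a[keep], region_b = pr$region_b[keep])
}

#' Find the minimum admissible density of a connectivity matrix
#'
#' Scans an ascending density grid and returns the smallest density at which
#' the thresholded graph has no disconnected (degree-zero) node — the
#' lowest-density threshold that removes weak, likely false-positive
#' connections while keeping every region attached. If no grid density
#' achieves this, the subject's network is flagged as fragmented and the
#' regions that remain disconnected at the grid maximum are reported.
#'
#' @param conn A `ctc_connectivity` matrix.
#' @param grid Ascending density grid in `(0, 1]` (default 0.05 to 0.50 by
#'   0.01).
#' @param partition Optional module partition passed to the graph.
#' @return A list of class `ctc_density_search`: `fragmented` (logical),
#'   `d_min` (NA when fragmented), `graph` (at `d_min`, or at the grid maximum
#'   when fragmented), and `disconnected` (regions isolated at the grid
#'   maximum).
#' @export
find_minimum_density <- function(conn, grid = seq(0.05, 0.5, by = 0.01),
                                 partition = NULL) {
  stopifnot(inherits(conn, "ctc_connectivity"))
  if (length(grid) == 0L) {
    abort("density grid is empty", class = "ctcnet_input_error")
  }
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid > 1)) {
    abort("density grid must be strictly ascending within (0, 1]",
          class = "ctcnet_input_error")
  }
  g <- NULL
  for (d in grid) {
    g <- suppressWarnings(threshold_at_density(conn, d, partition = partition))
    deg <- rowSums(g$adjacency)
    if (all(deg > 0)) {
      return(structure(list(fragmented = FALSE, d_min = d, graph = g,
                            disconnected = character(0)),
                       class = "ctc_density_search"))
    }
  }
  deg <- rowSums(g$adjacency)
  structure(list(fragmented = TRUE, d_min = NA_real_, graph = g,
                 disconnected = g$regions[deg == 0]),
            class = "ctc_density_search")
}

#' @export
print.ctc_density_search <- function(x, ...) {
  if (x$fragmented) {
    cat("<ctc_density_search> fragmented; persistently disconnected:",
        paste(x$disconnected, collapse = ", "), "\n")
  } else {
    cat(sprintf("<ctc_density_search> minimum admissible density %.3f\n",
                x$d_min))
  }
  invisible(x)
}
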