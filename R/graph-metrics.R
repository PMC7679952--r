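# Graph metrics on binary thresholded brain graphs: shortest paths, global
# efficiency, within-module degree z-score, and cohort fragmentation summaries.

#' Hop-count shortest path lengths
#'
#' Matrix of unweighted shortest path lengths between all region pairs, with
#' `Inf` for unreachable pairs and zeros on the diagonal. Computed by
#' breadth-first expansion of boolean walk matrices, which is essentially
#' free at the region counts used here (a-priori networks of 6-8 nodes).
#'
#' @param graph A `ctc_graph`.
#' @return A symmetric numeric matrix with region dimnames.
#' @export
shortest_path_lengths <- function(graph) {
  stopifnot(inherits(graph, "ctc_graph"))
  adj <- graph$adjacency > 0
  n <- nrow(adj)
  d <- ifelse(adj, 1, Inf)
  diag(d) <- 0
  walk <- adj
  for (k in seq_len(max(n - 2L, 0L)) + 1L) {
    if (!any(is.infinite(d[row(d) != col(d)]))) break
    walk <- (walk %*% adj) > 0
    d[walk & is.infinite(d)] <- k
  }
  dimnames(d) <- dimnames(graph$adjacency)
  d
}

#' Global efficiency of a binary graph
#'
#' `E = mean over ordered pairs (i != j) of 1/d_ij`, with `1/Inf = 0` for
#' unreachable pairs: 0 for an edgeless graph, 1 for a complete graph. A
#' measure of total network integration and capacity for parallel information
#' exchange.
#'
#' @param graph A `ctc_graph` with at least 2 regions.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' conn <- compute_connectivity(
#'   simulate_timeseries(build_ground_truth("male_unimpaired"), 60, seed = 1))
#' global_efficiency(threshold_at_density(conn, 0.3))
global_efficiency <- function(graph) {
  d <- shortest_path_lengths(graph)
  n <- nrow(d)
  if (n < 2L) abort("graph must have at least 2 nodes", class = "ctcnet_input_error")
  sum(1 / d[row(d) != col(d)]) / (n * (n - 1))
}

#' Within-module degree z-score
#'
#' Standardizes each node's within-module degree against the other nodes of
#' its module: `z_i = (k_i - mean_m) / sd_m`, using the population
#' (divide-by-n) SD. Nodes in modules whose within-module degrees have zero
#' SD (including singleton modules) get `z = 0`.
#'
#' @param graph A `ctc_graph`.
#' @param partition Named vector mapping every region to a module; defaults to
#'   the partition stored in the graph.
#' @return A tibble: `region`, `module`, `within_degree`, `z`.
#' @export
within_module_degree_z <- function(graph, partition = graph$partition) {
  stopifnot(inherits(graph, "ctc_graph"))
  missing <- setdiff(graph$regions, names(partition))
  if (length(missing)) {
    abort(paste0("regions missing from partition: ",
                 paste(missing, collapse = ", ")),
          class = "ctcnet_input_error")
  }
  part <- partition[graph$regions]
  k_within <- vapply(seq_along(graph$regions), function(i) {
    same <- part == part[i]
    sum(graph$adjacency[i, same])
  }, numeric(1))
  out <- tibble::tibble(region = graph$regions, module = unname(part),
                        within_degree = k_within)
  dplyr::mutate(
    dplyr::group_by(out, .data$module),
    z = {
      s <- sqrt(mean((.data$within_degree - mean(.data$within_degree))^2))
      if (s == 0) rep(0, dplyr::n()) else
        (.data$within_degree - mean(.data$within_degree)) / s
    }) |>
    dplyr::ungroup()
}

#' Per-subject graph metrics
#'
#' Computes global efficiency, the achieved density, the set of disconnected
#' regions, and per-node within-module degree z-scores for one thresholded
#' graph. Efficiency is still computed for fragmented graphs (unreachable
#' pairs contribute zero) and the subject is flagged.
#'
#' @param graph A `ctc_graph`.
#' @param partition Optional module partition (defaults to the graph's).
#' @return A one-row tibble: `subject_id`, `global_efficiency`, `density`,
#'   `n_disconnected`, `disconnected` (list-column), `wmdz` (list-column with
#'   the [within_module_degree_z()] tibble).
#' @export
graph_metrics <- function(graph, partition = graph$partition) {
  deg <- rowSums(graph$adjacency)
  tibble::tibble(
    subject_id = graph$subject_id %||% NA_character_,
    global_efficiency = global_efficiency(graph),
    density = graph$density,
    n_disconnected = sum(deg == 0),
    disconnected = list(graph$regions[deg == 0]),
    wmdz = list(within_module_degree_z(graph, partition))
  )
}

#' Cohort fragmentation summary
#'
#' Counts and proportions of subjects with at least one completely
#' disconnected region, overall and by sex.
#'
#' @param metrics Tibble of per-subject metrics (from [graph_metrics()],
#'   row-bound across subjects) containing `subject_id` and `n_disconnected`.
#' @param subjects Optional subject table with `subject_id` and `sex`; when
#'   given, per-sex rows are added.
#' @param digits Rounding applied to the reported percentage.
#' @return A tibble: `group`, `n_fragmented`, `n_total`, `percent`.
#' @export
fragmentation_summary <- function(metrics, subjects = NULL, digits = 0) {
  stopifnot(nrow(metrics) >= 1L)
  flag <- metrics$n_disconnected > 0
  out <- tibble::tibble(group = "all", n_fragmented = sum(flag),
                        n_total = nrow(metrics))
  if (!is.null(subjects)) {
    m <- dplyr::left_join(
      metrics[c("subject_id", "n_disconnected")],
      subjects[c("subject_id", "sex")], by = "subject_id")
    by_sex <- dplyr::summarise(
      dplyr::group_by(m, group = as.character(.data$sex)),
      n_fragmented = sum(.data$n_disconnected > 0),
      n_total = dplyr::n(), .groups = "drop")
    out <- dplyr::bind_rows(out, by_sex)
  }
  dplyr::mutate(out,
                percent = round(100 * .data$n_fragmented / .data$n_total,
                                digits))
}
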