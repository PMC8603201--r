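# Cross-cell-line comparison of repair kinetics: five-timepoint repair
# vectors of posterior median focus probabilities, pairwise Euclidean
# distances, agglomerative clustering for the heatmap, and residual-damage
# percentages.

#' Five-timepoint repair vector of a foci fit
#'
#' Collects the posterior median focus probability per unit area at the five
#' canonical times 0, 0.5, 2, 6, 24 h into the cell line's repair vector.
#'
#' @param fit A `foci_fit` covering all five canonical times (or `times`).
#' @param times Required time grid (default [foci_times()]).
#' @return Tibble with `cell_line`, `time_h`, `q` (5 rows, fixed time order)
#'   and attribute `valid` inherited from the fit's convergence flag.
#' @export
repair_vector <- function(fit, times = foci_times()) {
  stopifnot(inherits(fit, "foci_fit"))
  missing <- setdiff(times, fit$times)
  if (length(missing)) {
    abort(sprintf("fit lacks time(s) %s; present: %s",
                  paste(missing, collapse = ", "),
                  paste(fit$times, collapse = ", ")))
  }
  p <- pooled_draws(fit, "p")
  q <- vapply(match(times, fit$times), function(t) median(p[, t]), 0)
  out <- tibble(cell_line = fit$cell_line, time_h = times, q = q)
  attr(out, "valid") <- fit$converged
  out
}

#' Pairwise Euclidean distance matrix of repair vectors
#'
#' `d_ij = sqrt(sum_t (q_i,t - q_j,t)^2)` for each pair of cell lines; exact
#' symmetry is guaranteed by computing each pair once.
#'
#' @param vectors Tibble of stacked [repair_vector()] outputs (long format:
#'   `cell_line`, `time_h`, `q`).
#' @return A labelled symmetric matrix of class `repair_dist`.
#' @export
distance_matrix <- function(vectors) {
  wide <- tidyr::pivot_wider(vectors, id_cols = "cell_line",
                             names_from = "time_h", values_from = "q")
  m <- as.matrix(wide[-1])
  if (anyNA(m)) abort("repair vectors have unequal time grids.")
  rownames(m) <- wide$cell_line
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(wide$cell_line, wide$cell_line))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- sqrt(sum((m[i, ] - m[j, ])^2))
      }
    }
  }
  structure(D, class = c("repair_dist", "matrix", "array"))
}

#' Agglomerative clustering of a repair distance matrix
#'
#' Hierarchical clustering on the precomputed distances (default average
#' linkage; the study does not state its criterion). Returns the dendrogram
#' and the leaf ordering used to arrange the heatmap.
#'
#' @param D A `repair_dist` (or plain symmetric) matrix.
#' @param linkage `"average"`, `"single"`, `"complete"` or `"ward.D2"`
#'   (Ward on distances: heights are not cophenetic distances).
#' @return List with `order` (leaf labels in dendrogram order), `heights`
#'   (merge heights) and `hclust` (the stats::hclust object).
#' @export
cluster_order <- function(D, linkage = c("average", "single", "complete",
                                         "ward.D2")) {
  linkage <- match.arg(linkage)
  D <- unclass(as.matrix(D))
  if (anyNA(D)) abort("distance matrix contains NA.")
  hc <- hclust(as.dist(D), method = linkage)
  list(order = rownames(D)[hc$order], heights = hc$height, hclust = hc)
}

#' Residual DNA damage per cell line and replicate
#'
#' Percentage of the mean focus density (foci per unit area) remaining at the
#' final time relative to the reference time: `100 * density(t_final) /
#' density(t_ref)`, the residual-damage readout (24 h normalised to 30 min).
#'
#' @param records Foci tibble (may contain several cell lines).
#' @param t_ref Reference time in hours (default 0.5).
#' @param t_final Final time in hours (default 24).
#' @return Tibble with `cell_line`, `replicate`, `pct_residual`.
#' @export
residual_damage <- function(records, t_ref = 0.5, t_final = 24) {
  records <- validate_foci_records(records)
  for (t in c(t_ref, t_final)) {
    if (!t %in% records$time_h) abort(sprintf("time %g h not present.", t))
  }
  dens <- records |>
    filter(.data$time_h %in% c(t_ref, t_final)) |>
    group_by(.data$cell_line, .data$replicate, .data$time_h) |>
    summarise(dens = sum(.data$foci_count) / sum(.data$area_units),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "time_h", values_from = "dens")
  ref <- dens[[as.character(t_ref)]]
  fin <- dens[[as.character(t_final)]]
  if (any(is.na(ref) | is.na(fin))) {
    abort("some cell line x replicate groups lack one of the two times.")
  }
  if (any(ref == 0)) abort("zero reference focus density: percentage undefined.")
  tibble(cell_line = dens$cell_line, replicate = dens$replicate,
         pct_residual = 100 * fin / ref)
}

#' Clustered heatmap of repair distances
#'
#' ggplot tile heatmap of the pairwise distances with rows and columns
#' reordered by [cluster_order()].
#'
#' @param object A `repair_dist` matrix. @param linkage Linkage criterion.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.repair_dist <- function(object, linkage = "average", ...) {
  ord <- cluster_order(object, linkage)$order
  df <- as_tibble(unclass(as.matrix(object)), rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "d") |>
    mutate(row = factor(.data$row, levels = ord),
           col = factor(.data$col, levels = ord))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "d_ij") +
    ggplot2::labs(x = NULL, y = NULL,
                  subtitle = "Euclidean distances of repair vectors") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
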