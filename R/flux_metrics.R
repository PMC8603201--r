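# Stress-test parameter extraction from OCR/ECAR traces, per-well RFU
# normalisation, and log2 fold changes against matched unirradiated controls.
#
# Kit-standard cycle selection (configurable to per-phase means):
#   Mito Stress Test (OCR): non-mitochondrial = min over rot/AA cycles;
#     basal = last basal cycle - non-mito; ATP production = last basal -
#     min oligo; proton leak = min oligo - non-mito; maximal = max FCCP -
#     non-mito; spare capacity = maximal - basal.
#   Glycolysis Stress Test (ECAR): non-glycolytic = last pre-glucose cycle;
#     glycolysis = max glucose - non-glycolytic; glycolytic capacity =
#     max oligo - non-glycolytic; reserve = capacity - glycolysis.

mito_param_cols <- c("non_mito", "basal", "atp_production", "proton_leak",
                     "maximal", "spare_capacity")
glyco_param_cols <- c("non_glycolytic", "glycolysis", "glycolytic_capacity",
                      "glycolytic_reserve")

phase_stat <- function(values, stat) {
  switch(stat,
         last = values[length(values)],
         min = min(values),
         max = max(values),
         mean = mean(values))
}

params_one_well <- function(rows, assay, cycle_stat) {
  rows <- rows[order(rows$cycle_index), ]
  if (assay == "mito") {
    need <- mito_phases()
    chan <- "ocr"
  } else {
    need <- glyco_phases()
    chan <- "ecar"
  }
  missing <- setdiff(need, unique(rows$phase))
  if (length(missing)) {
    abort(sprintf("well %s: missing phase(s) %s", rows$well[1],
                  paste(missing, collapse = ", ")),
          class = "repairflux_validation_error")
  }
  v <- function(phase, stat) {
    phase_stat(rows[[chan]][rows$phase == phase],
               if (cycle_stat == "mean") "mean" else stat)
  }
  if (assay == "mito") {
    non_mito <- v("rot_aa", "min")
    basal <- v("basal", "last") - non_mito
    atp <- v("basal", "last") - v("oligo", "min")
    leak <- v("oligo", "min") - non_mito
    maximal <- v("fccp", "max") - non_mito
    out <- tibble(non_mito = non_mito, basal = basal, atp_production = atp,
                  proton_leak = leak, maximal = maximal,
                  spare_capacity = maximal - basal)
  } else {
    non_g <- v("baseline", "last")
    glyc <- v("glucose", "max") - non_g
    cap <- v("oligo", "max") - non_g
    out <- tibble(non_glycolytic = non_g, glycolysis = glyc,
                  glycolytic_capacity = cap, glycolytic_reserve = cap - glyc)
  }
  out
}

#' Derive stress-test parameters for every well of a flux plate
#'
#' Splits the plate by well, applies the kit-standard parameter formulas to
#' each trace, and optionally divides every parameter by the well's Hoechst
#' fluorescence (cell-number normalisation, giving pmol/min/RFU or
#' mpH/min/RFU). Negative derived parameters (biologically degenerate but
#' numerically valid) are kept and flagged via a message.
#'
#' @param plate A flux tibble (see [flux_schema()]); may mix cell lines,
#'   treatments and timepoints but must contain a single assay.
#' @param assay `"mito"` or `"glyco"`; defaults to the plate's assay column.
#' @param normalize Divide parameters by per-well RFU (default `TRUE`).
#' @param cycle_stat `"kit"` for the last/min/max selections documented
#'   above, or `"mean"` to use per-phase means throughout.
#' @return A tibble with one row per well: the well metadata columns plus
#'   the derived parameters.
#' @export
flux_params <- function(plate, assay = NULL, normalize = TRUE,
                        cycle_stat = c("kit", "mean")) {
  plate <- validate_flux_plate(plate)
  cycle_stat <- match.arg(cycle_stat)
  assay <- assay %||% unique(plate$assay)
  if (length(assay) != 1 || !assay %in% c("mito", "glyco")) {
    abort("`plate` must contain a single assay ('mito' or 'glyco').")
  }
  plate <- plate[plate$assay == assay, ]
  meta <- distinct(plate, .data$well, .data$cell_line, .data$treatment,
                   .data$timepoint_h, .data$assay, .data$rfu)
  params <- plate |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(~params_one_well(dplyr::mutate(.x, well = .y$well),
                                         assay, cycle_stat)) |>
    dplyr::ungroup()
  out <- left_join(meta, params, by = "well")
  value_cols <- if (assay == "mito") mito_param_cols else glyco_param_cols
  neg <- out$well[rowSums(as.matrix(out[value_cols]) < 0) > 0]
  if (length(neg)) {
    inform(sprintf("negative derived parameter(s) in well(s): %s",
                   paste(neg, collapse = ", ")))
  }
  if (normalize) out <- normalize_params(out)
  out
}

#' @rdname flux_params
#' @export
compute_mito_params <- function(plate, normalize = TRUE,
                                cycle_stat = c("kit", "mean")) {
  flux_params(plate, assay = "mito", normalize = normalize,
              cycle_stat = match.arg(cycle_stat))
}

#' @rdname flux_params
#' @export
compute_glyco_params <- function(plate, normalize = TRUE,
                                 cycle_stat = c("kit", "mean")) {
  flux_params(plate, assay = "glyco", normalize = normalize,
              cycle_stat = match.arg(cycle_stat))
}

#' Normalise derived parameters to cell number (RFU)
#'
#' Divides every parameter column by the per-well fluorescence. Because the
#' operation is linear, the additive invariants (basal = ATP production +
#' proton leak; spare = maximal - basal; reserve = capacity - glycolysis)
#' are preserved.
#'
#' @param params Per-well parameter tibble from [flux_params()].
#' @param rfu Optional positive scalar or per-row vector overriding the
#'   `rfu` column.
#' @return The tibble with parameter columns divided by RFU.
#' @export
normalize_params <- function(params, rfu = NULL) {
  rfu <- rfu %||% params$rfu
  if (is.null(rfu)) abort("no `rfu` column or argument supplied.")
  if (any(rfu <= 0)) abort("rfu must be > 0.")
  cols <- intersect(c(mito_param_cols, glyco_param_cols), names(params))
  params[cols] <- params[cols] / rfu
  params
}

#' Log2 fold change of group-mean parameters versus matched controls
#'
#' For each cell line, timepoint and parameter, computes
#' `log2(mean(treated) / mean(control))` using the ratio of group means
#' (matching the study's presentation of well-group means), with group sizes
#' recorded. Controls are matched within cell line (and within timepoint if
#' control wells exist at that timepoint; otherwise all control wells of the
#' cell line are pooled).
#'
#' @param params Per-well parameter tibble from [flux_params()] containing
#'   both treated and control wells.
#' @param parameters Parameter columns to compare; default all present.
#' @param control Treatment label of the unirradiated controls.
#' @return A tibble with columns `parameter`, `cell_line`, `treatment`,
#'   `timepoint_h`, `log2_fc`, `n_treated`, `n_control`.
#' @export
log2_fold_change <- function(params, parameters = NULL, control = "control") {
  parameters <- parameters %||%
    intersect(c(mito_param_cols, glyco_param_cols), names(params))
  if (!length(parameters)) abort("no parameter columns found.")
  ctrl <- params[params$treatment == control, ]
  trt <- params[params$treatment != control, ]
  if (!nrow(ctrl)) abort("no control wells with label '%s'." |>
                           sprintf(control))
  if (!nrow(trt)) abort("no treated wells present.")
  long <- tidyr::pivot_longer(trt, cols = dplyr::all_of(parameters),
                              names_to = "parameter", values_to = "value")
  ctrl_long <- tidyr::pivot_longer(ctrl, cols = dplyr::all_of(parameters),
                                   names_to = "parameter",
                                   values_to = "value")
  out <- long |>
    group_by(.data$parameter, .data$cell_line, .data$treatment,
             .data$timepoint_h) |>
    summarise(mean_treated = mean(.data$value), n_treated = dplyr::n(),
              .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(ctrl_rows = list({
      cc <- ctrl_long[ctrl_long$cell_line == .data$cell_line &
                        ctrl_long$parameter == .data$parameter, ]
      if (any(cc$timepoint_h == .data$timepoint_h)) {
        cc[cc$timepoint_h == .data$timepoint_h, ]
      } else cc
    })) |>
    dplyr::ungroup()
  out$mean_control <- purrr::map_dbl(out$ctrl_rows, ~mean(.x$value))
  out$n_control <- purrr::map_int(out$ctrl_rows, nrow)
  if (any(out$mean_control <= 0)) {
    bad <- out[out$mean_control <= 0, ]
    abort(sprintf("non-positive control mean for %s (%s): fold change undefined",
                  bad$parameter[1], bad$cell_line[1]),
          class = "repairflux_validation_error")
  }
  tibble(parameter = out$parameter, cell_line = out$cell_line,
         treatment = out$treatment, timepoint_h = out$timepoint_h,
         log2_fc = log2(out$mean_treated / out$mean_control),
         n_treated = out$n_treated, n_control = out$n_control)
}
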