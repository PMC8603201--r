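# Readers/writers for the tabular artifacts, with column contracts and
# row-level validation. TSV is the default on-disk format (CSV accepted on
# read via delimiter sniffing); reals are written with 17 significant digits
# so that write -> read round-trips exactly.

foci_cols <- c("cell_line", "replicate", "time_h", "nucleus_id",
               "area_units", "foci_count")
flux_cols <- c("well", "cell_line", "treatment", "timepoint_h", "assay",
               "cycle_index", "phase", "ocr", "ecar", "rfu")

#' Column contracts of the on-disk tables
#'
#' Returns the schema of the per-nucleus foci table or the per-cycle flux
#' plate table: column names, types and the validated invariants.
#'
#' @return A tibble with columns `column`, `type`, `constraint`.
#' @export
foci_schema <- function() {
  tibble(
    column = foci_cols,
    type = c("character", "integer", "double", "character", "integer",
             "integer"),
    constraint = c("cell-line label", "replicate index >= 1",
                   "hours post-irradiation, >= 0 (0 = baseline)",
                   "unique per nucleus",
                   "nuclear area in 0.1*Pixel^2 units, >= 1",
                   "0 <= foci_count <= area_units")
  )
}

#' @rdname foci_schema
#' @export
flux_schema <- function() {
  tibble(
    column = flux_cols,
    type = c("character", "character", "character", "double", "character",
             "integer", "character", "double", "double", "double"),
    constraint = c("unique well label", "cell-line label",
                   "control / IR / IR+inhibitor label",
                   "hours post-irradiation, >= 0",
                   "mito or glyco",
                   "measurement cycle >= 1, canonical phase order",
                   "mito: basal,oligo,fccp,rot_aa; glyco: baseline,glucose,oligo,2dg",
                   "pmol O2/min, >= 0", "mpH/min, >= 0",
                   "Hoechst RFU, > 0, constant within well")
  )
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

check_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          class = "repairflux_schema_error")
  }
}

#' Read and validate a per-nucleus foci table
#'
#' @param path TSV (or CSV) file with the [foci_schema()] columns.
#' @return A validated tibble of per-nucleus records.
#' @export
read_foci_table <- function(path) {
  df <- read_delim_sniff(path)
  check_columns(df, foci_cols, path)
  df <- df[foci_cols]
  df$replicate <- as.integer(df$replicate)
  df$area_units <- as.integer(df$area_units)
  df$foci_count <- as.integer(df$foci_count)
  validate_foci_records(df)
}

#' @rdname read_foci_table
#' @param records A foci tibble to validate in memory.
#' @export
validate_foci_records <- function(records) {
  check_columns(records, foci_cols, "foci records")
  bad <- which(records$area_units < 1)
  if (length(bad)) {
    abort(sprintf("row %d: area_units = %d must be >= 1", bad[1],
                  records$area_units[bad[1]]),
          class = "repairflux_validation_error")
  }
  bad <- which(records$foci_count < 0 | records$foci_count > records$area_units)
  if (length(bad)) {
    abort(sprintf("row %d: foci_count = %d outside [0, area_units = %d]",
                  bad[1], records$foci_count[bad[1]],
                  records$area_units[bad[1]]),
          class = "repairflux_validation_error")
  }
  if (any(records$time_h < 0) || any(records$replicate < 1)) {
    abort("time_h must be >= 0 and replicate >= 1.",
          class = "repairflux_validation_error")
  }
  as_tibble(records)
}

#' Read and validate a flux plate table
#'
#' Beyond the column contract this checks that each well's phases appear in
#' the canonical injection order (basal, oligo, fccp, rot_aa for the mito
#' assay; baseline, glucose, oligo, 2dg for the glyco assay), that rates are
#' non-negative, and that the normalisation fluorescence is constant and
#' positive within each well.
#'
#' @param path TSV (or CSV) file with the [flux_schema()] columns.
#' @return A validated tibble of per-cycle records.
#' @export
read_flux_plate <- function(path) {
  df <- read_delim_sniff(path)
  check_columns(df, flux_cols, path)
  df <- df[flux_cols]
  df$cycle_index <- as.integer(df$cycle_index)
  validate_flux_plate(df)
}

#' @rdname read_flux_plate
#' @param plate A flux tibble to validate in memory.
#' @export
validate_flux_plate <- function(plate) {
  check_columns(plate, flux_cols, "flux plate")
  if (any(!plate$assay %in% c("mito", "glyco"))) {
    abort(sprintf("unknown assay label '%s'",
                  setdiff(unique(plate$assay), c("mito", "glyco"))[1]),
          class = "repairflux_validation_error")
  }
  if (any(plate$ocr < 0) || any(plate$ecar < 0)) {
    abort("OCR and ECAR must be >= 0.", class = "repairflux_validation_error")
  }
  if (any(plate$rfu <= 0)) {
    abort("rfu must be > 0.", class = "repairflux_validation_error")
  }
  for (w in unique(plate$well)) {
    rows <- plate[plate$well == w, ]
    rows <- rows[order(rows$cycle_index), ]
    canonical <- if (rows$assay[1] == "mito") mito_phases() else glyco_phases()
    seen <- rle(rows$phase)$values
    if (!identical(seen, canonical[canonical %in% seen]) ||
        !all(seen %in% canonical)) {
      abort(sprintf("well %s: phases out of canonical %s order (%s)", w,
                    rows$assay[1], paste(seen, collapse = " -> ")),
            class = "repairflux_validation_error")
    }
    if (length(unique(rows$rfu)) != 1) {
      abort(sprintf("well %s: rfu must be constant within a well", w),
            class = "repairflux_validation_error")
    }
  }
  as_tibble(plate)
}

fmt_real <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                               trim = TRUE),
         format(x, digits = 17, trim = TRUE))
}

write_tsv_17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_real(out[[j]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write tabular artifacts
#'
#' All writers emit UTF-8 TSV with '.' decimal separator and reals at 17
#' significant digits, guaranteeing exact read/write round-trips.
#'
#' @param records,plate,summaries Tibbles to serialise.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_foci_table <- function(records, path) {
  write_tsv_17(validate_foci_records(records), path)
}

#' @rdname write_foci_table
#' @export
write_flux_plate <- function(plate, path) {
  write_tsv_17(validate_flux_plate(plate), path)
}

#' @rdname write_foci_table
#' @export
write_posterior_summary <- function(summaries, path) {
  fixed <- intersect(c("cell_line", "time_h", "parameter", "term", "median",
                       "hdi50_lo", "hdi50_hi", "hdi95_lo", "hdi95_hi",
                       "p_minus", "rhat", "ess"), names(summaries))
  write_tsv_17(as_tibble(summaries)[c(fixed, setdiff(names(summaries),
                                                     fixed))], path)
}

#' @rdname write_foci_table
#' @export
read_posterior_summary <- function(path) read_delim_sniff(path)

#' Write / read a labelled symmetric distance matrix
#'
#' @param D Square symmetric numeric matrix with row/column labels.
#' @param path Output TSV path.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-12))) {
    abort("refusing to write a non-symmetric distance matrix.",
          class = "repairflux_validation_error")
  }
  labels <- rownames(D) %||% paste0("V", seq_len(nrow(D)))
  df <- as_tibble(D, .name_repair = ~labels)
  df <- dplyr::bind_cols(tibble(label = labels), df)
  write_tsv_17(df, path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- read_delim_sniff(path)
  labels <- df[[1]]
  m <- as.matrix(df[-1])
  rownames(m) <- labels
  storage.mode(m) <- "double"
  m
}
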