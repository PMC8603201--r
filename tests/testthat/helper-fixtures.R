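# Fixture builders shared across test files. Everything is generated in code;
# no data files on disk.

tiny_foci <- function() {
  tibble::tibble(
    cell_line = "A",
    replicate = c(1L, 1L, 2L),
    time_h = c(0, 0.5, 0.5),
    nucleus_id = c("n1", "n2", "n3"),
    area_units = c(100L, 120L, 90L),
    foci_count = c(2L, 30L, 25L)
  )
}

# one well's trace with constant per-phase values
flux_well <- function(well = "w1", assay = "mito", values,
                      cell_line = "A", treatment = "control",
                      timepoint_h = 0, rfu = 1000, cycles = 3) {
  phases <- if (assay == "mito") {
    c("basal", "oligo", "fccp", "rot_aa")
  } else {
    c("baseline", "glucose", "oligo", "2dg")
  }
  phase_vec <- rep(phases, each = cycles)
  vals <- unname(values[phase_vec])
  ocr_vals <- if (assay == "mito") vals else rep(10, length(phase_vec))
  ecar_vals <- if (assay == "glyco") vals else rep(5, length(phase_vec))
  tibble::tibble(
    well = well, cell_line = cell_line, treatment = treatment,
    timepoint_h = timepoint_h, assay = assay,
    cycle_index = seq_along(phase_vec), phase = phase_vec,
    ocr = ocr_vals, ecar = ecar_vals, rfu = rfu
  )
}

# a minimal foci_fit-shaped object with point-mass posterior draws, for
# functions that only consume the draws
fake_foci_fit <- function(q, cell_line = "X", times = repairflux::foci_times(),
                          ndraw = 200) {
  structure(
    list(cell_line = cell_line, times = times, model = "hierarchical",
         replicates = 1:3,
         draws = list(list(p = matrix(rep(q, each = ndraw), ndraw))),
         diagnostics = tibble::tibble(parameter = as.character(times),
                                      rhat = 1, ess = ndraw),
         converged = TRUE, seed = 1L),
    class = "foci_fit"
  )
}

# independent brute-force implementation of the stress-test formulas,
# deliberately written in plain base R against raw rows; the derived
# differences (spare capacity, glycolytic reserve) are built from the same
# intermediate quantities the formulas state, so agreement is exact in
# floating point rather than merely algebraic
oracle_mito <- function(rows) {
  ph <- function(p) rows$ocr[rows$phase == p]
  non_mito <- min(ph("rot_aa"))
  basal_last <- ph("basal")[length(ph("basal"))]
  oligo_min <- min(ph("oligo"))
  basal <- basal_last - non_mito
  maximal <- max(ph("fccp")) - non_mito
  c(non_mito = non_mito, basal = basal,
    atp_production = basal_last - oligo_min,
    proton_leak = oligo_min - non_mito,
    maximal = maximal,
    spare_capacity = maximal - basal)
}

oracle_glyco <- function(rows) {
  ph <- function(p) rows$ecar[rows$phase == p]
  non_g <- ph("baseline")[length(ph("baseline"))]
  glycolysis <- max(ph("glucose")) - non_g
  capacity <- max(ph("oligo")) - non_g
  c(non_glycolytic = non_g, glycolysis = glycolysis,
    glycolytic_capacity = capacity,
    glycolytic_reserve = capacity - glycolysis)
}

# random single-well trace with cycle-to-cycle noise
random_trace <- function(assay, seed) {
  set.seed(seed)
  if (assay == "mito") {
    vals <- c(basal = runif(1, 50, 150), oligo = runif(1, 10, 60),
              fccp = runif(1, 100, 250), rot_aa = runif(1, 5, 30))
  } else {
    vals <- c(baseline = runif(1, 5, 15), glucose = runif(1, 20, 60),
              oligo = runif(1, 40, 90), `2dg` = runif(1, 5, 20))
  }
  tr <- flux_well(well = paste0("w", seed), assay = assay, values = vals)
  col <- if (assay == "mito") "ocr" else "ecar"
  tr[[col]] <- tr[[col]] * exp(rnorm(nrow(tr), 0, 0.1))
  tr
}
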