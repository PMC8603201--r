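# Seeded generators emulating the study's data structure: per-nucleus
# gamma-H2A.X focus counts with beta-binomial between-replicate dispersion,
# and extracellular-flux plates for the Mito / Glycolysis Stress Tests with a
# multiplicative irradiation response (1 h shutdown, staged recovery).

#' Configuration for the focus-count generator
#'
#' Describes the "true" world behind a simulated foci table: per-cell-line
#' focus probabilities per unit nuclear area (0.1*Pixel^2) at each scoring
#' time, the number of replicates and nuclei, the nuclear-area distribution,
#' and the between-replicate dispersion.
#'
#' The replicate-level probability `p[r,t]` is drawn from a beta distribution
#' parameterised by mean `p[t]` and concentration `phi`:
#' `alpha = phi * p`, `beta = phi * (1 - p)`, so the replicate-level variance
#' `p(1-p)/(phi + 1)` is always below the binomial bound `p(1-p)`.
#'
#' @param cell_lines Character vector of cell-line labels.
#' @param times Numeric scoring times in hours; default the canonical
#'   `c(0, 0.5, 2, 6, 24)` grid (0 = unirradiated baseline).
#' @param p Matrix of true focus probabilities per unit area with one row per
#'   cell line and one column per time, all in `[0, 1)` (an exact 0 bypasses
#'   the beta level and forces all counts at that time to zero). Rows may be
#'   named by cell line. Default: a fast and a slow repairer peaking at 0.5 h.
#' @param n_replicates Biological replicates per cell line (default 3).
#' @param nuclei_per_replicate Nuclei scored per replicate and time
#'   (default 80; the study scored at least 50).
#' @param phi Beta concentration controlling between-replicate dispersion
#'   (default 1500, i.e. a between-replicate coefficient of variation of
#'   about 16% at p = 0.02, typical of well-controlled triplicate foci
#'   assays; larger = replicates more alike).
#' @param area_meanlog,area_sdlog Log-normal parameters of the nuclear area
#'   in unit-area counts, discretised to integers >= 1. Defaults give a
#'   median of ~400 units. The study does not report area summaries, so these
#'   are configurable placeholders.
#' @param seed Integer random seed (mandatory for reproducibility).
#' @return A `foci_sim_config` list, validated.
#' @export
foci_sim_config <- function(cell_lines = c("CL1", "CL2"),
                            times = foci_times(),
                            p = NULL,
                            n_replicates = 3,
                            nuclei_per_replicate = 80,
                            phi = 1500,
                            area_meanlog = log(400),
                            area_sdlog = 0.35,
                            seed = 1L) {
  if (is.null(p)) {
    stopifnot(identical(times, foci_times()))
    shapes <- rbind(
      fast = c(0.002, 0.030, 0.015, 0.005, 0.002),
      slow = c(0.002, 0.030, 0.024, 0.014, 0.009)
    )
    p <- shapes[rep_len(seq_len(2), length(cell_lines)), , drop = FALSE]
    rownames(p) <- cell_lines
  }
  p <- as.matrix(p)
  if (is.null(rownames(p))) rownames(p) <- cell_lines
  cfg <- structure(
    list(cell_lines = cell_lines, times = times, p = p,
         n_replicates = as.integer(n_replicates),
         nuclei_per_replicate = as.integer(nuclei_per_replicate),
         phi = phi, area_meanlog = area_meanlog, area_sdlog = area_sdlog,
         seed = as.integer(seed)),
    class = "foci_sim_config"
  )
  validate_foci_sim_config(cfg)
}

validate_foci_sim_config <- function(cfg) {
  p <- cfg$p
  if (nrow(p) != length(cfg$cell_lines) || ncol(p) != length(cfg$times)) {
    abort("`p` must be a cell_lines x times matrix.")
  }
  if (any(p < 0 | p >= 1)) {
    bad <- which(p < 0 | p >= 1, arr.ind = TRUE)[1, ]
    abort(sprintf("focus probability p[%s, t=%g] = %g outside [0, 1)",
                  rownames(p)[bad[1]], cfg$times[bad[2]], p[bad[1], bad[2]]))
  }
  if (!is.numeric(cfg$phi) || cfg$phi <= 0) {
    abort(sprintf(paste0(
      "invalid beta mean/dispersion combination: concentration phi = %s ",
      "(with p in [%g, %g]) does not define a valid replicate-level beta; ",
      "phi must be > 0"), format(cfg$phi), min(p), max(p)),
      class = "repairflux_config_error")
  }
  if (cfg$n_replicates < 1 || cfg$nuclei_per_replicate < 1) {
    abort("replicate and nucleus counts must be >= 1.")
  }
  if (cfg$area_sdlog < 0) abort("`area_sdlog` must be >= 0.")
  cfg
}

# deterministic per-group substream so that adding cell lines, replicates or
# times never perturbs draws of existing groups
group_seed <- function(seed, i_cell, i_rep, i_time) {
  as.integer((seed + 7919 * i_cell + 104729 * i_rep + 611953 * i_time) %%
               2147483629)
}

#' Simulate a per-nucleus focus-count table
#'
#' For every cell line, replicate and time, a replicate-level focus
#' probability per unit area is drawn from the configured beta distribution;
#' each nucleus then gets an integer area (trials) and a binomial focus
#' count. Marginally over replicates the counts are beta-binomial, i.e.
#' overdispersed relative to a binomial with the same mean.
#'
#' @param cfg A [foci_sim_config()].
#' @return A tibble of per-nucleus records with columns `cell_line`,
#'   `replicate`, `time_h`, `nucleus_id`, `area_units`, `foci_count`
#'   (the contract enforced by [read_foci_table()]).
#' @seealso [simulate_flux_plate()], [simulate_coupled_study()]
#' @export
simulate_foci_dataset <- function(cfg) {
  cfg <- validate_foci_sim_config(cfg)
  grid <- tidyr::expand_grid(
    i_cell = seq_along(cfg$cell_lines),
    replicate = seq_len(cfg$n_replicates),
    i_time = seq_along(cfg$times)
  )
  out <- purrr::pmap(grid, function(i_cell, replicate, i_time) {
    set.seed(group_seed(cfg$seed, i_cell, replicate, i_time))
    p_t <- cfg$p[i_cell, i_time]
    # boundary bypass: a degenerate truth skips the beta level entirely
    p_rt <- if (p_t == 0) 0 else
      rbeta(1, cfg$phi * p_t, cfg$phi * (1 - p_t))
    n <- cfg$nuclei_per_replicate
    area <- pmax(1L, as.integer(round(rlnorm(n, cfg$area_meanlog,
                                             cfg$area_sdlog))))
    tibble(
      cell_line = cfg$cell_lines[i_cell],
      replicate = as.integer(replicate),
      time_h = cfg$times[i_time],
      nucleus_id = sprintf("%s_r%d_t%g_n%03d", cfg$cell_lines[i_cell],
                           replicate, cfg$times[i_time], seq_len(n)),
      area_units = area,
      foci_count = rbinom(n, area, p_rt)
    )
  })
  dplyr::bind_rows(out)
}

#' Configuration for the extracellular-flux plate generator
#'
#' Describes baseline OCR/ECAR levels per cell line, the injection-phase
#' multipliers of the Mito Stress Test (oligomycin, FCCP,
#' rotenone/antimycin A, applied to OCR) and the Glycolysis Stress Test
#' (glucose, oligomycin, 2-deoxy-glucose, applied to ECAR relative to the
#' non-glycolytic baseline), and the irradiation response: a multiplicative
#' factor per arm, 1 at time 0, the shutdown fraction at 1 h, and staged
#' recovery fractions at 6 and 24 h (linearly interpolated in between).
#' Defaults encode the study's qualitative picture: a pronounced 1 h
#' mitochondrial shutdown with slow, incomplete recovery by 24 h, and a fast,
#' essentially complete glycolytic-capacity recovery by 6 h.
#'
#' @param cell_lines Character labels.
#' @param baseline_ocr,baseline_ecar Named (or recycled) positive baselines:
#'   OCR in pmol O2/min, ECAR (non-glycolytic level) in mpH/min.
#' @param mito_multipliers Named OCR multipliers for phases `oligo`, `fccp`,
#'   `rot_aa` (the basal phase is 1).
#' @param glyco_multipliers Named ECAR multipliers for phases `glucose`,
#'   `oligo`, `2dg` relative to the pre-glucose baseline phase (which is 1).
#' @param mito_response,glyco_response Named factors at hours `"1"`, `"6"`,
#'   `"24"`: trace multiplier under irradiation, each in (0, 1.5].
#' @param cv Multiplicative log-normal noise coefficient of variation
#'   (>= 0; 0 gives exactly noiseless traces).
#' @param wells_per_condition Wells per cell line and condition (default 12,
#'   study range 8-16).
#' @param rfu_mean,rfu_cv Per-well Hoechst fluorescence distribution
#'   (log-normal; RFU used for cell-number normalisation).
#' @param cycles_per_phase Measurement cycles per injection phase (default 3).
#' @param seed Integer random seed.
#' @return A `flux_sim_config` list, validated.
#' @export
flux_sim_config <- function(cell_lines = c("CL1", "CL2"),
                            baseline_ocr = c(120, 90),
                            baseline_ecar = c(8, 12),
                            mito_multipliers = c(oligo = 0.35, fccp = 1.6,
                                                 rot_aa = 0.12),
                            glyco_multipliers = c(glucose = 4, oligo = 7,
                                                  `2dg` = 1.2),
                            mito_response = c(`1` = 0.4, `6` = 0.6,
                                              `24` = 0.8),
                            glyco_response = c(`1` = 0.5, `6` = 0.95,
                                               `24` = 1.05),
                            cv = 0.08,
                            wells_per_condition = 12,
                            rfu_mean = 1000, rfu_cv = 0.1,
                            cycles_per_phase = 3,
                            seed = 1L) {
  cfg <- structure(
    list(cell_lines = cell_lines,
         baseline_ocr = setNames(rep_len(baseline_ocr, length(cell_lines)),
                                 cell_lines),
         baseline_ecar = setNames(rep_len(baseline_ecar, length(cell_lines)),
                                  cell_lines),
         mito_multipliers = mito_multipliers,
         glyco_multipliers = glyco_multipliers,
         mito_response = mito_response, glyco_response = glyco_response,
         cv = cv, wells_per_condition = as.integer(wells_per_condition),
         rfu_mean = rfu_mean, rfu_cv = rfu_cv,
         cycles_per_phase = as.integer(cycles_per_phase),
         seed = as.integer(seed)),
    class = "flux_sim_config"
  )
  validate_flux_sim_config(cfg)
}

validate_flux_sim_config <- function(cfg) {
  if (any(cfg$baseline_ocr <= 0) || any(cfg$baseline_ecar <= 0)) {
    abort("baseline OCR/ECAR levels must be > 0.")
  }
  need_m <- c("oligo", "fccp", "rot_aa")
  need_g <- c("glucose", "oligo", "2dg")
  if (!all(need_m %in% names(cfg$mito_multipliers))) {
    abort("`mito_multipliers` needs names oligo, fccp, rot_aa.")
  }
  if (!all(need_g %in% names(cfg$glyco_multipliers))) {
    abort("`glyco_multipliers` needs names glucose, oligo, 2dg.")
  }
  for (resp in list(cfg$mito_response, cfg$glyco_response)) {
    if (any(resp <= 0 | resp > 1.5)) {
      abort("shutdown/recovery fractions must lie in (0, 1.5].")
    }
  }
  if (cfg$cv < 0 || cfg$rfu_cv < 0) abort("noise CVs must be >= 0.")
  if (cfg$cycles_per_phase < 1) abort("`cycles_per_phase` must be >= 1.")
  if (cfg$wells_per_condition < 1) abort("wells per condition must be >= 1.")
  cfg
}

# irradiation factor at time t: 1 at t = 0, configured factors at the named
# hours, linear interpolation in between, last value carried forward
irradiation_factor <- function(timepoint_h, response) {
  tt <- c(0, as.numeric(names(response)))
  ff <- c(1, unname(response))
  approx(tt, ff, xout = timepoint_h, rule = 2)$y
}

# mean-one multiplicative log-normal noise; exactly 1 when cv = 0
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

#' Simulate one extracellular-flux plate
#'
#' Generates per-well, per-cycle OCR and ECAR traces for either stress-test
#' assay at one post-irradiation timepoint. Every value is
#' `baseline * phase multiplier * irradiation factor * noise`; the
#' irradiation factor is 1 for unirradiated plates. OCR and ECAR are produced
#' in parallel: the assay's primary channel follows the configured phase
#' multipliers, the secondary channel follows fixed nuisance multipliers.
#'
#' @param cfg A [flux_sim_config()].
#' @param assay `"mito"` or `"glyco"`.
#' @param timepoint_h Hours post-irradiation (0 for baseline plates).
#' @param irradiated Logical; `FALSE` gives the matched control plate.
#' @param treatment Treatment label; defaults to `"IR"` when irradiated and
#'   `"control"` otherwise.
#' @return A tibble with columns `well`, `cell_line`, `treatment`,
#'   `timepoint_h`, `assay`, `cycle_index`, `phase`, `ocr`, `ecar`, `rfu`
#'   (the contract enforced by [read_flux_plate()]).
#' @export
simulate_flux_plate <- function(cfg, assay = c("mito", "glyco"),
                                timepoint_h = 1, irradiated = TRUE,
                                treatment = NULL) {
  cfg <- validate_flux_sim_config(cfg)
  if (identical(assay, c("mito", "glyco"))) assay <- "mito"
  if (length(assay) != 1 || !assay %in% c("mito", "glyco")) {
    abort(sprintf("unknown assay label '%s'; use \"mito\" or \"glyco\"",
                  paste(assay, collapse = ",")))
  }
  treatment <- treatment %||% if (irradiated) "IR" else "control"
  if (assay == "mito") {
    phases <- mito_phases()
    ocr_mult <- c(basal = 1, cfg$mito_multipliers[c("oligo", "fccp",
                                                    "rot_aa")])
    ecar_mult <- c(basal = 4, oligo = 5, fccp = 5, rot_aa = 4.5) # nuisance
  } else {
    phases <- glyco_phases()
    ecar_mult <- c(baseline = 1, cfg$glyco_multipliers[c("glucose", "oligo",
                                                         "2dg")])
    ocr_mult <- c(baseline = 1, glucose = 1, oligo = 0.3, `2dg` = 0.3)
  }
  f_mito <- if (irradiated) irradiation_factor(timepoint_h,
                                               cfg$mito_response) else 1
  f_glyco <- if (irradiated) irradiation_factor(timepoint_h,
                                                cfg$glyco_response) else 1
  ncyc <- cfg$cycles_per_phase
  phase_vec <- rep(phases, each = ncyc)
  out <- purrr::imap(cfg$cell_lines, function(cl, i_cell) {
    purrr::map(seq_len(cfg$wells_per_condition), function(w) {
      set.seed(group_seed(cfg$seed + 17 * (assay == "glyco") +
                            31 * irradiated + round(1000 * timepoint_h),
                          i_cell, w, 1L))
      nrows <- length(phase_vec)
      ocr <- cfg$baseline_ocr[[cl]] * unname(ocr_mult[phase_vec]) *
        f_mito * lnoise(nrows, cfg$cv)
      ecar <- cfg$baseline_ecar[[cl]] * unname(ecar_mult[phase_vec]) *
        f_glyco * lnoise(nrows, cfg$cv)
      tibble(
        well = sprintf("%s_%s_t%g_%s_w%02d", assay, treatment, timepoint_h,
                       cl, w),
        cell_line = cl, treatment = treatment, timepoint_h = timepoint_h,
        assay = assay, cycle_index = seq_len(nrows), phase = phase_vec,
        ocr = ocr, ecar = ecar,
        rfu = cfg$rfu_mean * lnoise(1, cfg$rfu_cv)
      )
    })
  })
  dplyr::bind_rows(out)
}

#' Simulate a full flux study (controls and irradiated plates over time)
#'
#' Convenience wrapper producing, for one assay, a control plate and an
#' irradiated plate at each requested post-irradiation timepoint plus the
#' time-0 baseline control.
#'
#' @inheritParams simulate_flux_plate
#' @param timepoints_h Post-irradiation measurement times (default 1, 6, 24).
#' @return One tibble of stacked plates.
#' @export
simulate_flux_study <- function(cfg, assay = "mito",
                                timepoints_h = c(1, 6, 24)) {
  plates <- purrr::map(timepoints_h, function(t) {
    dplyr::bind_rows(
      simulate_flux_plate(cfg, assay, t, irradiated = FALSE),
      simulate_flux_plate(cfg, assay, t, irradiated = TRUE)
    )
  })
  dplyr::bind_rows(simulate_flux_plate(cfg, assay, 0, irradiated = FALSE),
                   plates)
}

#' Simulate a jointly coupled foci + flux study
#'
#' Validation harness for the repair-metabolism coupling analysis. A shared
#' latent recovery trajectory `L(t)` (log of the mitochondrial irradiation
#' factor, piecewise linear on the focus-scoring grid) drives both sides:
#' the focus probability is `p(t) = p0 + coupling_slope * L(t)` and the
#' log-metabolic parameters shift by `L(t)`, so the true linear relation
#' between focus probability per unit area and any log Mito Stress Test
#' parameter has exactly the configured slope. Because `L` is linear in time
#' between 0.5 h and 2 h, interpolating the focus probabilities to 1 h
#' reproduces the latent value there exactly and the four paired points are
#' exactly collinear in truth.
#'
#' @param foci_cfg A [foci_sim_config()]; its time-0 probabilities provide
#'   the per-cell-line intercepts `p0`, the rest of `p` is overridden.
#' @param flux_cfg A [flux_sim_config()]; its `mito_response` provides the
#'   anchor factors of the latent trajectory.
#' @param coupling_slope Finite true slope of focus probability per unit
#'   area on the natural-log metabolic parameter (default -0.05: repair
#'   completes as metabolism recovers).
#' @param seed Integer seed overriding both sub-configs.
#' @return A list with elements `foci` (per-nucleus table), `flux` (stacked
#'   mito plates over the metabolic grid) and `truth` (per cell line: the
#'   four matched timepoints, true focus probability, true log basal
#'   respiration, the configured slope and implied intercept).
#' @export
simulate_coupled_study <- function(foci_cfg, flux_cfg, coupling_slope = -0.05,
                                   seed = 1L) {
  if (!is.finite(coupling_slope)) abort("`coupling_slope` must be finite.")
  stopifnot(identical(foci_cfg$times, foci_times()))
  resp <- flux_cfg$mito_response
  a <- log(resp[["1"]]); b <- log(resp[["6"]]); d <- log(resp[["24"]])
  # latent trajectory nodes on the focus grid {0, 0.5, 2, 6, 24}
  L_foci <- c(0, 0.5 * a, a + (2 - 1) / (6 - 1) * (b - a), b, d)
  L1 <- L_foci[2] + (1 - 0.5) / (2 - 0.5) * (L_foci[3] - L_foci[2])
  L_metab <- c(0, L1, b, d)

  p0 <- foci_cfg$p[, 1]
  p_true <- outer(p0, rep(1, 5)) + coupling_slope * outer(rep(1, nrow(foci_cfg$p)), L_foci)
  if (any(p_true <= 0 | p_true >= 1)) {
    abort("coupled truth pushes focus probabilities outside (0, 1); lower |coupling_slope| or adjust p0.")
  }
  foci_cfg$p <- p_true
  foci_cfg$seed <- as.integer(seed)
  flux_cfg$seed <- as.integer(seed + 10000)
  # realized factors at the metabolic grid follow the latent trajectory
  flux_cfg$mito_response <- c(`1` = exp(L1), `6` = exp(b), `24` = exp(d))

  foci <- simulate_foci_dataset(foci_cfg)
  flux <- simulate_flux_study(flux_cfg, assay = "mito",
                              timepoints_h = c(1, 6, 24))

  rot <- flux_cfg$mito_multipliers[["rot_aa"]]
  truth <- purrr::imap(p0, function(p00, cl) {
    log_basal <- log(flux_cfg$baseline_ocr[[cl]] * (1 - rot)) + L_metab
    tibble(cell_line = cl, time_h = metab_times(),
           latent = L_metab,
           p_true = p00 + coupling_slope * L_metab,
           log_basal_true = log_basal,
           slope_true = coupling_slope,
           intercept_true = p00 - coupling_slope *
             log(flux_cfg$baseline_ocr[[cl]] * (1 - rot)))
  })
  list(foci = foci, flux = flux, truth = dplyr::bind_rows(truth))
}
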