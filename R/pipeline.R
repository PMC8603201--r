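# End-to-end pipeline: simulate (or load) -> flux parameters -> fold changes
# -> multilevel GLM -> foci fits -> repair distances -> coupling models ->
# markdown report. Every stage writes plain-text intermediates so each one is
# independently inspectable and re-runnable; all randomness flows from the
# single config seed, so a fixed seed gives byte-identical outputs.

#' Pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving every stochastic stage (mandatory).
#' @param cell_lines Cell-line labels for the simulated study.
#' @param chains,iter MCMC settings shared by all model fits.
#' @param coupling_slope True repair-metabolism coupling slope of the
#'   simulated study.
#' @param linkage Clustering linkage for the distance heatmap ordering.
#' @param foci_path,flux_path Optional paths to existing input tables; when
#'   given they are loaded instead of simulated and must exist at start.
#' @param verbose Log stage progress to stderr.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cell_lines = c("CL1", "CL2"),
                            chains = 2, iter = 1200,
                            coupling_slope = -0.05,
                            linkage = "average",
                            foci_path = NULL, flux_path = NULL,
                            verbose = TRUE) {
  cfg <- structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         cell_lines = cell_lines, chains = chains, iter = iter,
         coupling_slope = coupling_slope, linkage = linkage,
         foci_path = foci_path, flux_path = flux_path, verbose = verbose),
    class = "pipeline_config"
  )
  if (is.na(cfg$seed)) abort("a seed is mandatory.")
  for (p in c(cfg$foci_path, cfg$flux_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input path not resolvable at start: %s", p))
    }
  }
  cfg
}

stage_msg <- function(cfg, fmt, ...) {
  if (cfg$verbose) message(sprintf(paste0("[repairflux] ", fmt), ...))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order on a simulated (or supplied)
#' study and writes: the input tables, per-well stress-test parameters, log2
#' fold changes, multilevel-GLM effect summaries, per-cell-line foci
#' posterior summaries with PPC and LOO reports, the repair distance matrix
#' with clustering order, the coupling table, and a markdown report stamped
#' with the seed and a config hash. Any stage failure aborts with the stage
#' name; outputs written so far are preserved.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    stage_msg(cfg, "stage %-14s ...", name)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
    stage_msg(cfg, "stage %-14s done (%.1fs)", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  pth <- function(f) file.path(cfg$out_dir, f)

  res$inputs <- stage("simulate", {
    if (!is.null(cfg$foci_path)) {
      foci <- read_foci_table(cfg$foci_path)
      flux <- read_flux_plate(cfg$flux_path)
      truth <- NULL
    } else {
      study <- simulate_coupled_study(
        foci_sim_config(cell_lines = cfg$cell_lines, seed = cfg$seed),
        flux_sim_config(cell_lines = cfg$cell_lines, seed = cfg$seed),
        coupling_slope = cfg$coupling_slope, seed = cfg$seed
      )
      # second simulated experiment for the nested-replicate GLM
      flux2 <- simulate_flux_study(
        flux_sim_config(cell_lines = cfg$cell_lines, seed = cfg$seed + 5000L)
      )
      foci <- study$foci
      flux <- dplyr::bind_rows(mutate(study$flux, replicate = 1L),
                               mutate(flux2, replicate = 2L)) |>
        mutate(well = sprintf("%s_e%d", .data$well, .data$replicate))
      truth <- study$truth
    }
    write_foci_table(foci, pth("foci.tsv"))
    write_flux_plate(select(flux, -dplyr::any_of("replicate")),
                     pth("flux.tsv"))
    if (!is.null(truth)) {
      jsonlite::write_json(
        list(seed = cfg$seed, coupling_slope = cfg$coupling_slope,
             truth = truth),
        pth("simulation_truth.json"), auto_unbox = TRUE, digits = NA)
    }
    list(foci = foci, flux = flux, truth = truth)
  })

  res$flux_params <- stage("flux-params", {
    params <- flux_params(select(res$inputs$flux,
                                 -dplyr::any_of("replicate")),
                          assay = "mito")
    params <- left_join(params,
                        distinct(res$inputs$flux, .data$well,
                                 .data$replicate),
                        by = "well")
    readr::write_tsv(params, pth("mito_params.tsv"), progress = FALSE)
    params
  })

  res$fold_changes <- stage("fold-change", {
    fc <- log2_fold_change(res$flux_params, parameters = c("basal",
                                                           "atp_production",
                                                           "maximal"))
    write_tsv_17(fc, pth("fold_changes.tsv"))
    fc
  })

  res$glm <- stage("glm", {
    vals <- res$flux_params |>
      filter(.data$treatment == "control", .data$timepoint_h == 0,
             .data$basal > 0) |>
      mutate(log_value = log(.data$basal))
    fit <- fit_metabolic_glm(vals, chains = cfg$chains, iter = cfg$iter,
                             seed = cfg$seed + 11L)
    write_posterior_summary(tidy(fit), pth("glm_effects.tsv"))
    fit
  })

  res$foci_fits <- stage("foci-fit", {
    fits <- fit_foci_models(res$inputs$foci, chains = cfg$chains,
                            iter = cfg$iter, seed = cfg$seed + 23L)
    summaries <- purrr::imap(fits, ~mutate(tidy(.x), cell_line = .y)) |>
      dplyr::bind_rows()
    write_posterior_summary(summaries, pth("foci_posteriors.tsv"))
    fits
  })

  res$ppc <- stage("ppc", {
    ppc <- ppc_foci(res$foci_fits[[1]], n_rep = 200, seed = cfg$seed + 31L)
    write_tsv_17(ppc, pth("ppc_foci.tsv"))
    ppc
  })

  res$loo <- stage("loo", {
    cl1 <- cfg$cell_lines[1]
    pooled <- fit_foci_model(
      res$inputs$foci[res$inputs$foci$cell_line == cl1, ],
      model = "pooled", chains = cfg$chains, iter = cfg$iter,
      seed = cfg$seed + 37L)
    cmp <- loo_compare_foci(res$foci_fits[[cl1]], pooled)
    jsonlite::write_json(
      list(models = cmp$models, elpd_diff = cmp$elpd_diff,
           se_diff = cmp$se_diff, preferred = cmp$preferred),
      pth("loo_compare.json"), auto_unbox = TRUE, digits = NA)
    cmp
  })

  res$distances <- stage("distances", {
    vecs <- purrr::map(res$foci_fits, repair_vector) |> dplyr::bind_rows()
    D <- distance_matrix(vecs)
    write_distance_matrix(D, pth("distance_matrix.tsv"))
    ord <- cluster_order(D, cfg$linkage)
    readr::write_tsv(tibble(leaf_order = ord$order), pth("leaf_order.tsv"),
                     progress = FALSE)
    list(vectors = vecs, D = D, order = ord)
  })

  res$coupling <- stage("coupling", {
    params <- res$flux_params
    metab <- params |>
      filter((.data$treatment == "IR" & .data$timepoint_h > 0) |
               (.data$treatment == "control" & .data$timepoint_h == 0),
             .data$replicate == 1L) |>
      group_by(.data$cell_line, .data$timepoint_h) |>
      summarise(log_metab = log(mean(.data$basal)), .groups = "drop")
    fits <- purrr::imap(res$foci_fits, function(fit, cl) {
      q <- setNames(tidy(fit)$median, tidy(fit)$time_h)
      pg <- interpolate_foci_to_metab_grid(q[as.character(foci_times())])
      dd <- left_join(pg, filter(metab, .data$cell_line == cl),
                      by = c("time_h" = "timepoint_h"))
      fit_coupling(dd, seed = cfg$seed + 41L)
    })
    panel <- coupling_panel(tibble(cell_line = names(fits),
                                   parameter = "basal", fit = fits))
    write_tsv_17(panel |> select(-dplyr::any_of("fit")),
                 pth("coupling.tsv"))
    list(fits = fits, panel = panel)
  })

  stage("report", {
    cfg_hash <- rlang::hash(cfg[setdiff(names(cfg),
                                        c("verbose", "out_dir"))])
    lines <- c(
      "# repairflux pipeline report",
      sprintf("seed: %d  |  config hash: %s", cfg$seed, cfg_hash), "",
      "## simulate", sprintf("%d nuclei, %d flux cycles written.",
                             nrow(res$inputs$foci), nrow(res$inputs$flux)),
      "", "## flux-params",
      sprintf("%d wells parameterised (mito assay).", nrow(res$flux_params)),
      "", "## fold-change",
      sprintf("%d log2 fold changes; basal at 1 h: %s.",
              nrow(res$fold_changes),
              paste(sprintf("%s %.2f",
                            res$fold_changes$cell_line[
                              res$fold_changes$parameter == "basal" &
                                res$fold_changes$timepoint_h == 1],
                            res$fold_changes$log2_fc[
                              res$fold_changes$parameter == "basal" &
                                res$fold_changes$timepoint_h == 1]),
                    collapse = ", ")),
      "", "## glm",
      sprintf("converged: %s; effects in glm_effects.tsv.",
              res$glm$converged),
      "", "## foci-fit",
      sprintf("%d cell lines fitted; converged: %s.",
              length(res$foci_fits),
              paste(purrr::map_chr(res$foci_fits,
                                   ~as.character(.x$converged)),
                    collapse = ", ")),
      "", "## ppc",
      sprintf("%d statistics checked; tail probabilities in [%.2f, %.2f].",
              nrow(res$ppc), min(res$ppc$p_tail), max(res$ppc$p_tail)),
      "", "## loo",
      sprintf("elpd difference %.2f (se %.2f); preferred: %s.",
              res$loo$elpd_diff, res$loo$se_diff, res$loo$preferred),
      "", "## distances",
      sprintf("leaf order: %s.",
              paste(res$distances$order$order, collapse = " , ")),
      "", "## coupling",
      sprintf("LS slopes: %s.",
              paste(sprintf("%s %.4f", res$coupling$panel$cell_line,
                            res$coupling$panel$ls_slope), collapse = ", "))
    )
    writeLines(lines, pth("report.md"))
    NULL
  })
  invisible(res)
}
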