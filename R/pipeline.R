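#' Build the dose-table arm list from a study configuration
#'
#' Translates the `dose_table` and `beam` blocks of [study_config()] into
#' the arm structures consumed by [build_dose_table()].
#'
#' @param config A [study_config()] list.
#' @return List of arms for [build_dose_table()].
#' @export
config_dose_arms <- function(config) {
  dt <- config$dose_table
  beam_on <- list(thermal_fluence = config$beam$thermal_fluence,
                  d_h = config$beam$d_h_gy, d_gamma = config$beam$d_gamma_gy)
  beam_off <- list(thermal_fluence = 0, d_h = 0, d_gamma = 0)
  lapply(dt$arms, function(a) {
    tissues <- lapply(a$tissues, function(tis) {
      tis$nitrogen_pct <- dt$nitrogen_pct
      tis
    })
    list(arm = a$arm, tissues = tissues,
         beam = if (isTRUE(a$beam_on)) beam_on else beam_off,
         rbe = dt$rbe, ced_fraction = dt$ced_fraction)
  })
}

#' Bootstrap confidence intervals for the effectiveness chain
#'
#' Nonparametric bootstrap of [estimate_effectiveness()]: resamples rows
#' within each condition, reruns the chain, and reports percentile
#' intervals for the beam RBE and each compound CBE.
#'
#' @param data Clonogenic table (see [estimate_effectiveness()]).
#' @param B Number of bootstrap replicates; default 1000.
#' @param seed Integer seed.
#' @param level Confidence level; default 0.95.
#' @param ... Passed to [estimate_effectiveness()].
#' @return data.frame with columns quantity, estimate, lo, hi.
#' @export
effectiveness_bootstrap <- function(data, B = 1000, seed = 1, level = 0.95,
                                    ...) {
  est <- estimate_effectiveness(data, ...)
  set.seed(seed)
  idx_by_cond <- split(seq_len(nrow(data)), data$condition)
  draws <- matrix(NA_real_, nrow = B, ncol = 1 + length(est$cbe),
                  dimnames = list(NULL, c("rbe_beam",
                                          paste0("cbe_", names(est$cbe)))))
  for (b in seq_len(B)) {
    take <- unlist(lapply(idx_by_cond, function(ix) sample(ix, replace = TRUE)))
    e <- tryCatch(estimate_effectiveness(data[take, ], ...),
                  error = function(err) NULL)
    if (!is.null(e)) draws[b, ] <- c(e$rbe_beam, e$cbe[names(est$cbe)])
  }
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  data.frame(quantity = colnames(draws),
             estimate = c(est$rbe_beam, unname(est$cbe)),
             lo = qs[1, ], hi = qs[2, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Repeated-simulation recovery of beam RBE and compound CBEs
#'
#' Simulates the clonogenic assay with Poisson colony noise `n_rep` times
#' and reruns the full effectiveness chain on each replicate, measuring how
#' well the planted beam RBE and CBEs are recovered.
#'
#' @param config A [study_config()] list.
#' @param n_rep Number of seeded replicates; default 50.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `estimates` (data.frame: rep, rbe_beam, one column per
#'   compound CBE, iso-dose columns) and `truth` (named planted values).
#' @export
cbe_recovery_experiment <- function(config = study_config(), n_rep = 50,
                                    seed = 1) {
  cl <- config$clonogenic
  truth <- c(rbe_beam = cl$rbe_beam, unlist(cl$cbe))
  rows <- lapply(seq_len(n_rep), function(r) {
    dat <- gen_clonogenic(config, seed = seed + r, noise = "poisson")
    est <- estimate_effectiveness(dat)
    c(rep = r, rbe_beam = est$rbe_beam, est$cbe,
      stats::setNames(est$iso_doses, paste0("iso_", names(est$iso_doses))))
  })
  list(estimates = as.data.frame(do.call(rbind, rows)), truth = truth)
}

#' Significance pattern of log-rank tests over simulated cohorts
#'
#' Simulates the five-arm survival experiment `n_rep` times at the
#' configured medians and group sizes, testing each BNCT arm against the
#' untreated reference by log-rank, and reports the fraction of replicates
#' in which each comparison is significant at `alpha`.
#'
#' @param config A [study_config()] list.
#' @param n_rep Number of seeded replicates; default 200.
#' @param seed Base seed.
#' @param alpha Significance threshold; default 0.05.
#' @param reference Reference arm label.
#' @return Named vector: per-arm fraction of replicates with p < alpha.
#' @export
logrank_power_experiment <- function(config = study_config(), n_rep = 200,
                                     seed = 1, alpha = 0.05,
                                     reference = "Untreated") {
  arms <- setdiff(config$survival$arms$arm, reference)
  bnct <- grep("BNCT", arms, value = TRUE)
  hits <- matrix(0L, n_rep, length(bnct), dimnames = list(NULL, bnct))
  for (r in seq_len(n_rep)) {
    dat <- gen_survival(config, seed = seed + r)
    ref <- dat[dat$arm == reference, ]
    for (a in bnct) {
      g <- dat[dat$arm == a, ]
      p <- logrank(g$time_days, g$event, ref$time_days, ref$event)$p
      hits[r, a] <- as.integer(p < alpha)
    }
  }
  colMeans(hits)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates every input (or reads them from `inputs_dir`), runs the five
#' analysis stages — dose table, in vitro effectiveness (beam RBE + CBE),
#' biodistribution summary, expression fold-change, survival/%ILS — and
#' writes their tables plus a consolidated markdown report and a manifest
#' of output hashes. Deterministic for a fixed seed: rerunning with the
#' same seed reproduces every output byte for byte.
#'
#' @param outdir Output directory.
#' @param seed Integer seed used for all simulation.
#' @param config A [study_config()] list.
#' @param simulate Generate inputs under `outdir/inputs` (default). If
#'   FALSE, `inputs_dir` must hold the five input CSVs.
#' @param inputs_dir Directory with pre-existing input CSVs.
#' @param bootstrap_B Bootstrap replicates for the effectiveness CIs;
#'   default 200.
#' @return Invisibly, a list with the per-stage results and output paths.
#' @export
run_all <- function(outdir, seed = 42, config = study_config(),
                    simulate = TRUE, inputs_dir = file.path(outdir, "inputs"),
                    bootstrap_B = 200) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (simulate) {
    paths <- write_study_inputs(inputs_dir, config, seed)
  } else {
    paths <- c(clonogenic = file.path(inputs_dir, "clonogenic.csv"),
               biodistribution = file.path(inputs_dir, "biodistribution.csv"),
               uptake = file.path(inputs_dir, "uptake.csv"),
               expression = file.path(inputs_dir, "expression_ct.csv"),
               survival = file.path(inputs_dir, "survival_events.csv"))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("missing input files: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }

  # stage 1: dosimetry table
  dose_tab <- build_dose_table(config_dose_arms(config))
  dose_path <- file.path(outdir, "dose_table.csv")
  utils::write.csv(dose_tab, dose_path, row.names = FALSE)

  # stage 2: in vitro effectiveness
  clono <- utils::read.csv(paths[["clonogenic"]])
  eff <- estimate_effectiveness(clono)
  ci <- effectiveness_bootstrap(clono, B = bootstrap_B, seed = seed)
  eff_path <- file.path(outdir, "effectiveness.json")
  jsonlite::write_json(
    list(alpha = eff$lq$alpha, beta = eff$lq$beta,
         iso_doses_gy = as.list(eff$iso_doses),
         rbe_beam = eff$rbe_beam, cbe = as.list(eff$cbe),
         bootstrap_ci = ci),
    eff_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage 3: biodistribution + uptake comparison
  biod <- utils::read.csv(paths[["biodistribution"]])
  biod_tab <- biodistribution_table(biod)
  biod_path <- file.path(outdir, "biodistribution_table.csv")
  utils::write.csv(biod_tab, biod_path, row.names = FALSE)
  upt <- utils::read.csv(paths[["uptake"]])
  upt$uptake <- normalize_uptake(upt$boron_ug, upt$n_cells)
  f98 <- upt[upt$cell_line == "F98", ]
  upt_test <- compare_uptake(f98$uptake[f98$compound == "dpa_bstpg"],
                             f98$uptake[f98$compound == "bpa"])

  # stage 4: expression
  cts <- utils::read.csv(paths[["expression"]])
  expr <- cohort_fold_summary(ct_wide(cts))
  expr_path <- file.path(outdir, "expression_summary.json")
  jsonlite::write_json(
    list(folds = expr$folds, mean_fold = expr$mean_fold,
         headline_fold = expr$headline,
         geometric_mean = cohort_fold_summary(expr$folds,
                                              "geometric")$mean_fold),
    expr_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage 5: survival
  surv <- utils::read.csv(paths[["survival"]])
  surv_tab <- survival_report(surv, reference = "Untreated")
  surv_path <- file.path(outdir, "survival_report.csv")
  utils::write.csv(surv_tab, surv_path, row.names = FALSE)

  report_path <- file.path(outdir, "report.md")
  writeLines(render_report(dose_tab, eff, biod_tab, upt_test, expr,
                           surv_tab, seed), report_path)

  outputs <- c(dose_table = dose_path, effectiveness = eff_path,
               biodistribution = biod_path, expression = expr_path,
               survival = surv_path, report = report_path)
  manifest <- list(seed = seed,
                   version = as.character(utils::packageVersion("bnctquant")),
                   inputs = as.list(tools::md5sum(unname(paths))),
                   outputs = as.list(tools::md5sum(unname(outputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dose_table = dose_tab, effectiveness = eff,
                 biodistribution = biod_tab, uptake_test = upt_test,
                 expression = expr, survival = surv_tab,
                 paths = outputs))
}

fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "-", formatC(x, format = "f", digits = digits))
}

md_table <- function(df, digits = 2) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col, digits) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

render_report <- function(dose_tab, eff, biod_tab, upt_test, expr, surv_tab,
                          seed) {
  dose_disp <- dose_tab
  dose_disp$absorbed_gy <- round(dose_disp$absorbed_gy, 1)
  dose_disp$photon_eq_gyeq <- round(dose_disp$photon_eq_gyeq, 1)
  c(
    "# BNCT analysis report", "",
    paste0("Seed: ", seed), "",
    "## Dose table (absorbed Gy and photon-equivalent Gy-Eq)", "",
    md_table(dose_disp[, c("arm", "tissue", "absorbed_gy", "photon_eq_gyeq")], 1), "",
    "## In vitro effectiveness", "",
    paste0("- LQ fit: alpha = ", fmt_num(eff$lq$alpha, 4), " /Gy, beta = ",
           fmt_num(eff$lq$beta, 4), " /Gy^2"),
    paste0("- Iso-effect doses at SF = 0.1 (Gy): ",
           paste(sprintf("%s %.2f", names(eff$iso_doses), eff$iso_doses),
                 collapse = ", ")),
    paste0("- Beam RBE: ", fmt_num(eff$rbe_beam, 2)),
    paste0("- CBE: ", paste(sprintf("%s %.2f", names(eff$cbe), eff$cbe),
                            collapse = ", ")), "",
    "## Biodistribution (tumor / brain / blood, ug B/g)", "",
    md_table(biod_tab, 1), "",
    "## Cellular uptake comparison (F98, highest-uptake vs BPA)", "",
    paste0("- Student's t = ", fmt_num(upt_test$t, 2), ", p = ",
           format(upt_test$p, digits = 3)), "",
    "## Relative expression (2^-ddCt)", "",
    paste0("- Per-subject folds: ",
           paste(fmt_num(expr$folds, 2), collapse = ", ")),
    paste0("- Mean fold: ", fmt_num(expr$mean_fold, 2), " (headline ",
           expr$headline, "-fold)"), "",
    "## Survival", "",
    md_table(surv_tab, 3), ""
  )
}
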