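#' Load the study generator/analysis configuration
#'
#' Reads the JSON configuration that parameterizes the synthetic-data
#' generators and the dose-table fixture. The packaged default transcribes
#' the study conditions this workflow emulates: planted LQ parameters whose
#' photon iso-effect dose at SF = 0.1 is 6.45 Gy, planted beam RBE 3.0 and
#' CBEs 8.43 / 3.80 / 2.41, the published biodistribution means and SDs,
#' the three observed expression fold-changes, and per-arm median survival
#' times 21 / 23 / 28 / 31.5 / 33.5 days.
#'
#' @param path Path to a JSON config; default the packaged
#'   `study_config.json`.
#' @return Nested list. Table-like blocks (`biodistribution`, `uptake`,
#'   `survival$arms`) are data.frames.
#' @export
study_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_config.json", package = "bnctquant")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  # the dose-table arms are heterogeneous nested records, not a table
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg$dose_table$arms <- lapply(raw$dose_table$arms, function(a) {
    a$tissues <- lapply(a$tissues, function(tis) tis)
    a
  })
  cfg
}

# truncated-at-zero normal draws via inverse-CDF (exact, no rejection loop)
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Per-condition clonogenic irradiation design implied by the config
#'
#' Derives, from the planted radiobiology parameters, each condition's
#' component split and iso-effect absorbed dose at SF = 0.1. The
#' boron-to-beam dose-rate ratio of each compound is proportional to its
#' cellular uptake, calibrated so the highest-uptake compound hits the
#' configured target iso dose (default 0.88 Gy).
#'
#' @param cl The `clonogenic` block of [study_config()].
#' @return data.frame with one row per condition (`beam` + compounds):
#'   fractions `f_b`, `f_n`, `f_h`, `f_gamma` of the absorbed dose, the true
#'   iso-effect absorbed dose `iso_gy`, and the absorbed dose rate
#'   `rate_gy_min` (iso dose / 20 min, so 10/20/30-minute exposures bracket
#'   the iso-effect point).
#' @export
clonogenic_design <- function(cl) {
  w_beam <- cl$rbe_beam * (1 - cl$gamma_fraction) + cl$gamma_fraction
  lq_iso <- dose_at_sf(list(alpha = cl$alpha, beta = cl$beta), 0.1)
  upt <- unlist(cl$uptake_ug_per_1e9)
  cbe <- unlist(cl$cbe)[names(upt)]
  ref <- names(which.max(upt))
  iso_ref <- cl$dpa_iso_target_gy
  u_ref <- (lq_iso - iso_ref * w_beam) / (iso_ref * cbe[[ref]] - lq_iso)
  stopifnot(u_ref > 0)
  u <- u_ref * upt / upt[[ref]]
  iso <- lq_iso * (1 + u) / (cbe * u + w_beam)
  conds <- data.frame(
    condition = c("beam", names(upt)),
    f_b = c(0, u / (1 + u)),
    iso_gy = c(lq_iso / w_beam, iso),
    stringsAsFactors = FALSE
  )
  beam_part <- 1 - conds$f_b
  conds$f_gamma <- beam_part * cl$gamma_fraction
  conds$f_n <- beam_part * (1 - cl$gamma_fraction) * cl$nitrogen_share
  conds$f_h <- beam_part * (1 - cl$gamma_fraction) * (1 - cl$nitrogen_share)
  conds$rate_gy_min <- conds$iso_gy / 20
  rownames(conds) <- NULL
  conds
}

#' Generate a synthetic clonogenic-assay table
#'
#' Emulates the in vitro design: an X-ray reference curve plus neutron-beam
#' conditions (beam alone and boron compounds) irradiated for 10, 20 or 30
#' minutes. The expected surviving fraction of every condition follows the
#' planted LQ model evaluated at the CBE/RBE-weighted photon-equivalent
#' dose; treated colony counts are Poisson around `control x SF`
#' (`noise = "none"` keeps the exact expectations, the backbone of the
#' zero-noise recovery tests).
#'
#' @param config A [study_config()] list.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param noise `"poisson"` (default) or `"none"`.
#' @return data.frame with columns condition, duration_min, replicate,
#'   dose_gy, d_b_gy, d_n_gy, d_h_gy, d_gamma_gy, colonies_control,
#'   colonies_treated.
#' @export
gen_clonogenic <- function(config = study_config(), seed = 1,
                           noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  cl <- config$clonogenic
  set.seed(seed)
  des <- clonogenic_design(cl)
  lq <- list(alpha = cl$alpha, beta = cl$beta)
  w <- rbe_weights(cbe = NA, rbe_n = cl$rbe_beam)
  cbe <- unlist(cl$cbe)

  rows <- list()
  # photon reference curve: pure gamma dose
  for (d in cl$xray_doses_gy) {
    sf_true <- lq_sf(lq, d)
    rows[[length(rows) + 1]] <- data.frame(
      condition = "xray", duration_min = NA_real_,
      replicate = seq_len(cl$replicates), dose_gy = d,
      d_b_gy = 0, d_n_gy = 0, d_h_gy = 0, d_gamma_gy = d,
      colonies_control = cl$control_colonies, sf_true = sf_true)
  }
  for (i in seq_len(nrow(des))) {
    cn <- des$condition[i]
    for (t in cl$durations_min) {
      D <- des$rate_gy_min[i] * t
      comp <- c(b = des$f_b[i], n = des$f_n[i], h = des$f_h[i],
                g = des$f_gamma[i]) * D
      deq <- ifelse(cn == "beam", 0, cbe[cn]) * comp[["b"]] +
        cl$rbe_beam * (comp[["n"]] + comp[["h"]]) + comp[["g"]]
      rows[[length(rows) + 1]] <- data.frame(
        condition = cn, duration_min = t,
        replicate = seq_len(cl$replicates), dose_gy = D,
        d_b_gy = comp[["b"]], d_n_gy = comp[["n"]], d_h_gy = comp[["h"]],
        d_gamma_gy = comp[["g"]],
        colonies_control = cl$control_colonies, sf_true = lq_sf(lq, deq))
    }
  }
  out <- do.call(rbind, rows)
  mu <- out$colonies_control * out$sf_true
  out$colonies_treated <- if (noise == "poisson") stats::rpois(nrow(out), mu) else mu
  out$sf_true <- NULL
  rownames(out) <- NULL
  out
}

#' Generate synthetic per-animal organ boron concentrations
#'
#' Per-animal draws from a normal truncated at zero with the configured
#' group mean and SD (concentrations cannot be negative; with mean under
#' two SDs of zero the truncation is active).
#'
#' @inheritParams gen_clonogenic
#' @return Long-format data.frame: subject, compound, route, time_h, organ,
#'   boron_ug_per_g.
#' @export
gen_biodistribution <- function(config = study_config(), seed = 1) {
  set.seed(seed)
  tab <- config$biodistribution
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    data.frame(
      subject = sprintf("%s_%gh_a%d", r$compound, r$time_h, seq_len(r$n)),
      compound = r$compound, route = r$route, time_h = r$time_h,
      organ = r$organ,
      boron_ug_per_g = rtnorm0(r$n, r$mean, r$sd),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic cellular-uptake replicates
#'
#' Truncated-at-zero normal draws of uptake (ug B per 1e9 cells) per cell
#' line and compound, expressed as pellet boron mass over a fixed cell
#' count so [normalize_uptake()] reproduces the draws.
#'
#' @inheritParams gen_clonogenic
#' @param n_cells Cells per pellet; default 1e6.
#' @return data.frame: cell_line, compound, replicate, boron_ug, n_cells.
#' @export
gen_uptake <- function(config = study_config(), seed = 1, n_cells = 1e6) {
  set.seed(seed)
  tab <- config$uptake
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    upt <- rtnorm0(r$n, r$mean, r$sd)
    data.frame(cell_line = r$cell_line, compound = r$compound,
               replicate = seq_len(r$n),
               boron_ug = upt * n_cells / 1e9, n_cells = n_cells,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic qPCR cycle thresholds
#'
#' Constructs target/reference Ct quadruples whose 2^-ddCt fold-change
#' equals each planted fold exactly when the Ct noise SD is 0; independent
#' normal noise on each Ct otherwise.
#'
#' @inheritParams gen_clonogenic
#' @param folds Optional planted per-subject folds overriding the config.
#' @return Long-format data.frame: subject, gene (target|reference), tissue
#'   (tumor|normal), ct.
#' @export
gen_expression <- function(config = study_config(), seed = 1, folds = NULL) {
  set.seed(seed)
  ex <- config$expression
  if (is.null(folds)) folds <- ex$folds
  n <- length(folds)
  ref <- ex$ref_ct
  dct_tumor <- ex$dct_normal - log2(folds)
  wide <- data.frame(
    subject = sprintf("rat%02d", seq_len(n)),
    ct_target_tumor = ref + dct_tumor,
    ct_ref_tumor = ref,
    ct_target_normal = ref + ex$dct_normal,
    ct_ref_normal = ref)
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject = wide$subject[i],
               gene = c("target", "reference", "target", "reference"),
               tissue = c("tumor", "tumor", "normal", "normal"),
               ct = c(wide$ct_target_tumor[i], wide$ct_ref_tumor[i],
                      wide$ct_target_normal[i], wide$ct_ref_normal[i]),
               stringsAsFactors = FALSE)
  }))
  long$ct <- long$ct + stats::rnorm(nrow(long), 0, ex$ct_noise_sd)
  rownames(long) <- NULL
  long
}

#' Generate synthetic per-subject survival times
#'
#' Log-logistic event times per arm, scaled so the distribution median
#' equals the configured median survival time; every subject is an event
#' (the protocol observes until death or euthanasia, with no censoring).
#' The shape parameter controls dispersion; as it grows all subjects
#' concentrate at the arm median.
#'
#' @inheritParams gen_clonogenic
#' @param n_per_arm Optional integer overriding every arm's group size.
#' @param shape Optional shape overriding the config.
#' @return data.frame: subject, arm, time_days, event.
#' @export
gen_survival <- function(config = study_config(), seed = 1,
                         n_per_arm = NULL, shape = NULL) {
  set.seed(seed)
  arms <- config$survival$arms
  if (is.null(shape)) shape <- config$survival$shape
  rows <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    n <- if (is.null(n_per_arm)) a$n else n_per_arm
    u <- stats::runif(n)
    tt <- a$median_days * (u / (1 - u))^(1 / shape)
    data.frame(subject = sprintf("%s_a%d", gsub("[^A-Za-z]+", "_", a$arm),
                                 seq_len(n)),
               arm = a$arm, time_days = tt, event = 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write every synthetic input the pipeline consumes
#'
#' Writes the clonogenic, biodistribution, uptake, expression and survival
#' CSVs plus a copy of the beam/tissue configuration under `outdir`,
#' deterministically for a fixed seed.
#'
#' @inheritParams gen_clonogenic
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_study_inputs <- function(outdir, config = study_config(), seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    clonogenic = file.path(outdir, "clonogenic.csv"),
    biodistribution = file.path(outdir, "biodistribution.csv"),
    uptake = file.path(outdir, "uptake.csv"),
    expression = file.path(outdir, "expression_ct.csv"),
    survival = file.path(outdir, "survival_events.csv")
  )
  utils::write.csv(gen_clonogenic(config, seed), paths["clonogenic"], row.names = FALSE)
  utils::write.csv(gen_biodistribution(config, seed), paths["biodistribution"], row.names = FALSE)
  utils::write.csv(gen_uptake(config, seed), paths["uptake"], row.names = FALSE)
  utils::write.csv(gen_expression(config, seed), paths["expression"], row.names = FALSE)
  utils::write.csv(gen_survival(config, seed), paths["survival"], row.names = FALSE)
  invisible(paths)
}
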