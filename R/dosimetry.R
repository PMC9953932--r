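#' Kerma coefficients for thermal-neutron capture reactions
#'
#' Fluence-to-dose conversion coefficients for the two capture reactions that
#' dominate thermal-neutron dosimetry in tissue: the 10B(n,alpha)7Li reaction
#' and the 14N(n,p)14C reaction. The boron coefficient converts a thermal
#' fluence into absorbed dose per unit boron-10 concentration; the nitrogen
#' coefficient does the same per weight-percent nitrogen.
#'
#' @param boron_coeff Gy cm^2 per (ug 10B/g). Default 7.43e-14.
#' @param nitrogen_coeff Gy cm^2 per weight-percent nitrogen. Default 6.78e-14.
#' @return A list of class `kerma_constants`.
#' @export
#' @examples
#' kerma_constants()
kerma_constants <- function(boron_coeff = 7.43e-14, nitrogen_coeff = 6.78e-14) {
  stopifnot(is.numeric(boron_coeff), is.numeric(nitrogen_coeff))
  if (boron_coeff <= 0 || nitrogen_coeff <= 0) {
    stop("kerma coefficients must be strictly positive", call. = FALSE)
  }
  structure(list(boron_coeff = boron_coeff, nitrogen_coeff = nitrogen_coeff),
            class = "kerma_constants")
}

#' Absorbed-dose components of a mixed neutron field
#'
#' Container for the four absorbed-dose parts of BNCT dosimetry in one tissue
#' under one irradiation: boron capture (`d_b`), nitrogen capture (`d_n`),
#' hydrogen recoil from fast/epithermal elastic scattering (`d_h`) and the
#' gamma-ray dose (`d_gamma`). All in Gy.
#'
#' @param d_b,d_n,d_h,d_gamma Non-negative absorbed doses in Gy.
#' @return A list of class `dose_components`.
#' @export
dose_components <- function(d_b = 0, d_n = 0, d_h = 0, d_gamma = 0) {
  v <- c(d_b = d_b, d_n = d_n, d_h = d_h, d_gamma = d_gamma)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("dose components must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(v), class = "dose_components")
}

#' RBE/CBE weighting factors for photon-equivalent dose
#'
#' @param cbe Compound biological effectiveness applied to the boron dose.
#'   May be `NA` to mark an unmeasured tissue/compound combination (e.g. a
#'   compound whose normal-brain CBE could not be estimated); computations
#'   that need it then fail loudly rather than defaulting.
#' @param rbe_n,rbe_h Relative biological effectiveness of the nitrogen and
#'   hydrogen dose components. In this workflow both default to the beam RBE
#'   estimated in vitro.
#' @return A list of class `rbe_weights`.
#' @export
rbe_weights <- function(cbe, rbe_n, rbe_h = rbe_n) {
  for (w in list(rbe_n, rbe_h)) {
    if (!is.finite(w) || w <= 0) stop("RBE weights must be > 0", call. = FALSE)
  }
  if (!is.na(cbe) && (!is.finite(cbe) || cbe <= 0)) {
    stop("cbe must be > 0 or NA", call. = FALSE)
  }
  structure(list(cbe = cbe, rbe_n = rbe_n, rbe_h = rbe_h),
            class = "rbe_weights")
}

#' Boron absorbed dose from thermal fluence
#'
#' `D_B = k_B x [10B] x phi`, with `k_B` the boron kerma coefficient,
#' `[10B]` the boron-10 concentration in ug/g and `phi` the thermal neutron
#' fluence in 1/cm^2. Linear in both inputs.
#'
#' @param boron_conc Boron-10 concentration, ug 10B per g tissue.
#' @param thermal_fluence Thermal neutron fluence, neutrons/cm^2.
#' @param constants A [kerma_constants()] object.
#' @return Absorbed dose in Gy.
#' @export
#' @examples
#' boron_dose(45, 1e12) # tumor-like concentration at a reactor fluence
boron_dose <- function(boron_conc, thermal_fluence,
                       constants = kerma_constants()) {
  if (any(boron_conc < 0) || any(thermal_fluence < 0)) {
    stop("boron_conc and thermal_fluence must be >= 0", call. = FALSE)
  }
  constants$boron_coeff * boron_conc * thermal_fluence
}

#' Nitrogen absorbed dose from thermal fluence
#'
#' `D_N = k_N x N% x phi`, with `N%` the tissue nitrogen content in
#' weight-percent.
#'
#' @param nitrogen_pct Nitrogen concentration, weight percent (0-100).
#' @inheritParams boron_dose
#' @return Absorbed dose in Gy.
#' @export
nitrogen_dose <- function(nitrogen_pct, thermal_fluence,
                          constants = kerma_constants()) {
  if (any(nitrogen_pct < 0) || any(nitrogen_pct > 100)) {
    stop("nitrogen_pct must be in [0, 100]", call. = FALSE)
  }
  if (any(thermal_fluence < 0)) stop("thermal_fluence must be >= 0", call. = FALSE)
  constants$nitrogen_coeff * nitrogen_pct * thermal_fluence
}

#' Total absorbed dose
#'
#' Sum of the four components, `D_B + D_N + D_H + D_gamma`.
#'
#' @param components A [dose_components()] object.
#' @return Total absorbed dose in Gy.
#' @export
total_absorbed <- function(components) {
  stopifnot(inherits(components, "dose_components"))
  components$d_b + components$d_n + components$d_h + components$d_gamma
}

#' Photon-equivalent (RBE-weighted) dose
#'
#' `D_B x CBE + D_N x RBE_N + D_H x RBE_H + D_gamma`. The gamma component is
#' credited at weight 1. With all weights equal to 1 this reduces to
#' [total_absorbed()].
#'
#' @param components A [dose_components()] object.
#' @param weights An [rbe_weights()] object. A missing (`NA`) CBE is an error
#'   when `d_b > 0`.
#' @return Photon-equivalent dose in Gy-Eq.
#' @export
photon_equivalent <- function(components, weights) {
  stopifnot(inherits(components, "dose_components"),
            inherits(weights, "rbe_weights"))
  if (components$d_b > 0 && is.na(weights$cbe)) {
    stop("CBE is missing but the boron dose is non-zero; cannot weight d_b",
         call. = FALSE)
  }
  cbe <- if (components$d_b == 0) 0 else weights$cbe
  components$d_b * cbe +
    components$d_n * weights$rbe_n +
    components$d_h * weights$rbe_h +
    components$d_gamma
}

#' Effective boron concentration under convection-enhanced delivery
#'
#' With convection-enhanced delivery (CED) only a fraction of the measured
#' tissue boron participates in the capture reaction at the target cells; the
#' dose calculation therefore uses `boron_conc x contribution_fraction`
#' (default 0.268, i.e. a 26.8% contribution).
#'
#' @param boron_conc Measured boron concentration, ug/g.
#' @param contribution_fraction Fraction in (0, 1].
#' @return Effective boron concentration, ug/g.
#' @export
ced_effective_boron <- function(boron_conc, contribution_fraction = 0.268) {
  if (any(boron_conc < 0)) stop("boron_conc must be >= 0", call. = FALSE)
  if (!is.finite(contribution_fraction) ||
      contribution_fraction <= 0 || contribution_fraction > 1) {
    stop("contribution_fraction must be in (0, 1]", call. = FALSE)
  }
  boron_conc * contribution_fraction
}

#' Compute dose components for one tissue under one beam exposure
#'
#' @param tissue List/row with `nitrogen_pct` and `boron_conc` (ug/g).
#' @param beam List with `thermal_fluence` (1/cm^2), `d_h` (Gy), `d_gamma`
#'   (Gy). The hydrogen-recoil and gamma doses are taken as pre-computed
#'   beam properties rather than derived from a spectral model.
#' @param constants A [kerma_constants()] object.
#' @param depth_correction Optional multiplicative correction applied to all
#'   four components (e.g. attenuation with depth); default 1.
#' @return A [dose_components()] object.
#' @export
tissue_dose <- function(tissue, beam, constants = kerma_constants(),
                        depth_correction = 1) {
  stopifnot(depth_correction > 0)
  dose_components(
    d_b = depth_correction * boron_dose(tissue$boron_conc, beam$thermal_fluence, constants),
    d_n = depth_correction * nitrogen_dose(tissue$nitrogen_pct, beam$thermal_fluence, constants),
    d_h = depth_correction * beam$d_h,
    d_gamma = depth_correction * beam$d_gamma
  )
}

#' Build an absorbed / photon-equivalent dose table across treatment arms
#'
#' Produces one row per arm and tissue with the four dose components, their
#' sum (absorbed Gy) and the CBE/RBE-weighted photon-equivalent dose (Gy-Eq).
#' A tissue whose CBE is unknown (`NA`) while it carries boron yields an `NA`
#' photon-equivalent cell, mirroring a "-" entry in a published dose table.
#'
#' @param arms A list of arms. Each arm is a list with fields:
#'   `arm` (label), `tissues` (named list of lists with `nitrogen_pct`,
#'   `boron_conc`, optional `cbe`, optional `depth_correction`),
#'   `beam` (list with `thermal_fluence`, `d_h`, `d_gamma`),
#'   `rbe` (the beam RBE used for the nitrogen and hydrogen components), and
#'   optional `ced_fraction` applied to tissues flagged `ced = TRUE`.
#' @param constants A [kerma_constants()] object.
#' @return A data.frame with columns arm, tissue, d_b, d_n, d_h, d_gamma,
#'   absorbed_gy, photon_eq_gyeq.
#' @export
build_dose_table <- function(arms, constants = kerma_constants()) {
  if (!length(arms)) stop("no arms supplied", call. = FALSE)
  rows <- lapply(arms, function(arm) {
    for (f in c("arm", "tissues", "beam", "rbe")) {
      if (is.null(arm[[f]])) {
        stop("arm definition missing field '", f, "'", call. = FALSE)
      }
    }
    do.call(rbind, lapply(names(arm$tissues), function(tn) {
      tis <- arm$tissues[[tn]]
      conc <- tis$boron_conc
      if (isTRUE(tis$ced)) {
        conc <- ced_effective_boron(conc, arm$ced_fraction %||% 0.268)
      }
      comp <- tissue_dose(
        list(nitrogen_pct = tis$nitrogen_pct, boron_conc = conc),
        arm$beam, constants,
        depth_correction = tis$depth_correction %||% 1
      )
      cbe <- tis$cbe %||% NA_real_
      peq <- if (comp$d_b > 0 && is.na(cbe)) {
        NA_real_
      } else {
        photon_equivalent(comp, rbe_weights(cbe = cbe, rbe_n = arm$rbe))
      }
      data.frame(arm = arm$arm, tissue = tn,
                 d_b = comp$d_b, d_n = comp$d_n, d_h = comp$d_h,
                 d_gamma = comp$d_gamma,
                 absorbed_gy = total_absorbed(comp),
                 photon_eq_gyeq = peq,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
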