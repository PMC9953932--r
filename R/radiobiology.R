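#' Surviving fraction from colony counts
#'
#' Clonogenic surviving fraction: colonies in the treated dish divided by
#' colonies in the unirradiated control. Values above 1 (treated outgrowing
#' control) are clipped to 1 with a warning. A treated count of 0 cannot be
#' log-transformed for LQ fitting; by default it is an error, optionally it
#' is floored at `0.5 / control_colonies`.
#'
#' @param treated_colonies,control_colonies Non-negative counts; the control
#'   must be positive.
#' @param zero_policy `"error"` (default) or `"floor"`.
#' @return Surviving fraction in (0, 1].
#' @export
colony_sf <- function(treated_colonies, control_colonies,
                      zero_policy = c("error", "floor")) {
  zero_policy <- match.arg(zero_policy)
  if (any(control_colonies <= 0)) stop("control_colonies must be > 0", call. = FALSE)
  if (any(treated_colonies < 0)) stop("counts must be >= 0", call. = FALSE)
  sf <- treated_colonies / control_colonies
  if (any(sf > 1)) {
    warning("surviving fraction > 1; clipping to 1")
    sf <- pmin(sf, 1)
  }
  if (any(sf == 0)) {
    if (zero_policy == "error") {
      stop("surviving fraction of 0 cannot be log-transformed; ",
           "use zero_policy = 'floor' to floor at 0.5/control", call. = FALSE)
    }
    sf <- pmax(sf, 0.5 / control_colonies)
  }
  sf
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of `ln SF = -alpha D - beta D^2` on the log-transformed
#' surviving fractions, with `alpha, beta >= 0`. The two-parameter
#' non-negativity constraint is solved exactly by comparing the unconstrained
#' normal-equation solution with the two one-parameter boundary fits.
#'
#' @param dose Doses in Gy (>= 3 distinct values).
#' @param sf Surviving fractions in (0, 1].
#' @param weights Optional non-negative weights (e.g. colony counts).
#' @return A list of class `lq_params` with `alpha` (1/Gy) and `beta`
#'   (1/Gy^2).
#' @export
#' @examples
#' d <- c(0, 2, 4, 6, 8)
#' fit_lq(d, exp(-0.2 * d - 0.02 * d^2))
fit_lq <- function(dose, sf, weights = NULL) {
  if (length(dose) != length(sf)) stop("dose and sf lengths differ", call. = FALSE)
  if (any(sf <= 0) || any(sf > 1)) stop("sf must be in (0, 1]", call. = FALSE)
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  keep <- dose > 0 # SF(0)=1 contributes nothing to the log-linear fit
  if (length(unique(dose[keep])) < 2) {
    stop("need at least 2 distinct positive doses", call. = FALSE)
  }
  if (length(unique(dose)) < 3) stop("need at least 3 distinct doses", call. = FALSE)
  d <- dose[keep]
  y <- -log(sf[keep])
  w <- if (is.null(weights)) rep(1, length(d)) else weights[keep]
  if (any(w < 0)) stop("weights must be >= 0", call. = FALSE)

  X <- cbind(d, d^2)
  rss <- function(cf) sum(w * (y - X %*% cf)^2)
  # unconstrained weighted least squares through the origin
  fit2 <- tryCatch(stats::lm.wfit(X, y, w)$coefficients, error = function(e) c(NA, NA))
  cands <- list()
  if (all(is.finite(fit2)) && all(fit2 >= 0)) cands <- c(cands, list(fit2))
  a1 <- max(0, sum(w * d * y) / sum(w * d^2))      # beta = 0 boundary
  b1 <- max(0, sum(w * d^2 * y) / sum(w * d^4))    # alpha = 0 boundary
  cands <- c(cands, list(c(a1, 0)), list(c(0, b1)))
  best <- cands[[which.min(vapply(cands, rss, numeric(1)))]]
  structure(list(alpha = unname(best[1]), beta = unname(best[2])),
            class = "lq_params")
}

#' Predicted surviving fraction under the LQ model
#'
#' @param params An `lq_params` object (or list with `alpha`, `beta`).
#' @param dose Dose(s) in Gy.
#' @return `exp(-alpha D - beta D^2)`.
#' @export
lq_sf <- function(params, dose) {
  exp(-params$alpha * dose - params$beta * dose^2)
}

#' Dose producing a given surviving fraction under the LQ model
#'
#' Inverts `SF = exp(-alpha D - beta D^2)` at `sf_level`: the positive root
#' of `beta D^2 + alpha D + ln(sf_level) = 0`, or `-ln(sf_level)/alpha` when
#' `beta = 0`.
#'
#' @param params An `lq_params` object.
#' @param sf_level Target surviving fraction in (0, 1); default 0.1.
#' @return Iso-effect dose in Gy.
#' @export
dose_at_sf <- function(params, sf_level = 0.1) {
  if (!is.finite(sf_level) || sf_level <= 0 || sf_level >= 1) {
    stop("sf_level must be in (0, 1)", call. = FALSE)
  }
  a <- params$alpha; b <- params$beta
  if (a < 0 || b < 0 || (a == 0 && b == 0)) {
    stop("need alpha, beta >= 0 and not both zero", call. = FALSE)
  }
  L <- -log(sf_level)
  if (b == 0) return(L / a)
  (-a + sqrt(a^2 + 4 * b * L)) / (2 * b)
}

#' Iso-effect dose of a measured survival curve
#'
#' Absorbed dose at which a measured dose-SF curve crosses `sf_level`.
#' Default strategy fits the LQ model to the curve and inverts it
#' ([dose_at_sf()]); `"loglinear"` interpolates linearly in dose against
#' ln SF between the bracketing observations. Non-monotone curves trigger a
#' warning and, for the interpolation strategy, an isotonic pre-smoothing of
#' -ln SF against dose.
#'
#' @param dose,sf The measured curve.
#' @param sf_level Target surviving fraction; default 0.1.
#' @param strategy `"lq"` (default) or `"loglinear"`.
#' @param extrapolate Allow `sf_level` outside the observed SF range for the
#'   interpolation strategy; default FALSE (error).
#' @return Iso-effect dose in Gy.
#' @export
curve_iso_dose <- function(dose, sf, sf_level = 0.1,
                           strategy = c("lq", "loglinear"),
                           extrapolate = FALSE) {
  strategy <- match.arg(strategy)
  if (strategy == "lq") {
    return(dose_at_sf(fit_lq(dose, sf), sf_level))
  }
  o <- order(dose)
  d <- dose[o]; y <- -log(sf[o])
  if (is.unsorted(y)) {
    warning("SF not monotone decreasing in dose; applying isotonic smoothing")
    y <- stats::isoreg(d, y)$yf
  }
  target <- -log(sf_level)
  if ((target < min(y) || target > max(y)) && !extrapolate) {
    stop("sf_level outside the observed SF range and extrapolation disabled",
         call. = FALSE)
  }
  stats::approx(x = y, y = d, xout = target, ties = mean, rule = 2)$y
}

#' Beam RBE from the beam-only iso-effect dose
#'
#' The beam RBE relates the photon (LQ-model) iso-effect dose to the
#' boron-free neutron-beam dose producing the same effect, with the gamma
#' component credited at weight 1 and excluded:
#' `RBE_beam = (D_photon - D_gamma) / (D_N + D_H)`.
#'
#' @param lq_iso Photon iso-effect dose (Gy) from the X-ray LQ fit.
#' @param beam_iso_components [dose_components()] of the beam-only condition
#'   at its iso-effect dose; `d_b` must be 0.
#' @return Dimensionless beam RBE.
#' @export
estimate_rbe_beam <- function(lq_iso, beam_iso_components) {
  stopifnot(inherits(beam_iso_components, "dose_components"))
  if (beam_iso_components$d_b != 0) {
    stop("beam-only condition must have d_b = 0", call. = FALSE)
  }
  den <- beam_iso_components$d_n + beam_iso_components$d_h
  if (den <= 0) stop("d_n + d_h must be > 0", call. = FALSE)
  (lq_iso - beam_iso_components$d_gamma) / den
}

#' Compound biological effectiveness from a compound iso-effect dose
#'
#' Inverts the photon-equivalent equation at the iso-effect point: the
#' photon-equivalent of the compound condition at SF = `sf_level` must equal
#' the photon iso-effect dose, so
#' `CBE = (D_photon - RBE_beam (D_N + D_H) - D_gamma) / D_B`.
#'
#' @param lq_iso Photon iso-effect dose (Gy).
#' @param compound_iso_components [dose_components()] at the compound
#'   condition's iso-effect dose; `d_b` must be > 0.
#' @param rbe_beam Beam RBE applied to the nitrogen and hydrogen components.
#' @return Dimensionless CBE.
#' @export
estimate_cbe <- function(lq_iso, compound_iso_components, rbe_beam) {
  stopifnot(inherits(compound_iso_components, "dose_components"))
  cc <- compound_iso_components
  if (cc$d_b <= 0) stop("compound condition must have d_b > 0", call. = FALSE)
  num <- lq_iso - rbe_beam * (cc$d_n + cc$d_h) - cc$d_gamma
  if (num < 0) {
    stop("negative numerator: beam components alone exceed the photon ",
         "iso-effect dose; inputs are inconsistent", call. = FALSE)
  }
  num / cc$d_b
}

#' Estimate beam RBE and per-compound CBE from a clonogenic data set
#'
#' Runs the full in vitro effectiveness chain on a long-format clonogenic
#' table: fits the LQ model to the X-ray (photon reference) condition,
#' inverts every condition's curve at `sf_level`, estimates the beam RBE from
#' the boron-free beam condition, and the CBE of each compound condition.
#' Per-condition dose components are taken from the component columns; the
#' component split is assumed proportional along each condition's curve (a
#' fixed beam, varying exposure time), so components at the iso-effect dose
#' are the per-row component fractions times the fitted iso dose.
#'
#' @param data data.frame with columns `condition`, `dose_gy`, `d_b_gy`,
#'   `d_n_gy`, `d_h_gy`, `d_gamma_gy`, `colonies_treated`,
#'   `colonies_control` (or a precomputed `sf` column).
#' @param xray_condition,beam_condition Labels of the photon-reference and
#'   beam-only conditions. All other conditions are treated as compounds.
#' @param sf_level Iso-effect surviving fraction; default 0.1.
#' @return A list with `lq` (the X-ray `lq_params`), `iso_doses` (named Gy
#'   vector, all conditions), `rbe_beam`, and `cbe` (named vector, compound
#'   conditions).
#' @export
estimate_effectiveness <- function(data, xray_condition = "xray",
                                   beam_condition = "beam", sf_level = 0.1) {
  need <- c("condition", "dose_gy")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(data$sf)) {
    data$sf <- colony_sf(data$colonies_treated, data$colonies_control,
                         zero_policy = "floor")
  }
  conds <- unique(data$condition)
  for (cn in c(xray_condition, beam_condition)) {
    if (!cn %in% conds) stop("condition '", cn, "' not present", call. = FALSE)
  }

  fits <- lapply(conds, function(cn) {
    rows <- data[data$condition == cn, ]
    fit_lq(rows$dose_gy, rows$sf)
  })
  names(fits) <- conds
  iso <- vapply(fits, dose_at_sf, numeric(1), sf_level = sf_level)

  frac_at_iso <- function(cn) {
    rows <- data[data$condition == cn & data$dose_gy > 0, ]
    f <- colMeans(rows[, c("d_b_gy", "d_n_gy", "d_h_gy", "d_gamma_gy")] /
                    rows$dose_gy)
    dose_components(d_b = f[[1]] * iso[[cn]], d_n = f[[2]] * iso[[cn]],
                    d_h = f[[3]] * iso[[cn]], d_gamma = f[[4]] * iso[[cn]])
  }

  lq_iso <- iso[[xray_condition]]
  rbe_beam <- estimate_rbe_beam(lq_iso, frac_at_iso(beam_condition))
  compounds <- setdiff(conds, c(xray_condition, beam_condition))
  cbe <- vapply(compounds, function(cn) {
    estimate_cbe(lq_iso, frac_at_iso(cn), rbe_beam)
  }, numeric(1))

  list(lq = fits[[xray_condition]], iso_doses = iso,
       rbe_beam = rbe_beam, cbe = cbe)
}
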