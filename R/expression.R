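#' Relative expression fold-change by the 2^-ddCt method
#'
#' For one subject, with qPCR cycle thresholds of a target and a reference
#' gene in the tumor and in the calibrator (normal) tissue:
#' `dCt_tumor = Ct_target,tumor - Ct_ref,tumor`,
#' `dCt_normal = Ct_target,normal - Ct_ref,normal`,
#' `ddCt = dCt_tumor - dCt_normal`, and fold = `2^(-ddCt)`.
#' Assumes ideal doubling per cycle (no amplification-efficiency correction).
#'
#' @param ct_target_tumor,ct_ref_tumor,ct_target_normal,ct_ref_normal Cycle
#'   thresholds, each in (0, 45].
#' @return Fold-change (> 0).
#' @export
#' @examples
#' fold_change(20, 20, 24, 20) # 16-fold
fold_change <- function(ct_target_tumor, ct_ref_tumor,
                        ct_target_normal, ct_ref_normal) {
  cts <- c(ct_target_tumor, ct_ref_tumor, ct_target_normal, ct_ref_normal)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts > 45)) {
    stop("Ct values must be in (0, 45]", call. = FALSE)
  }
  ddct <- (ct_target_tumor - ct_ref_tumor) -
    (ct_target_normal - ct_ref_normal)
  2^(-ddct)
}

#' Cohort summary of per-subject fold-changes
#'
#' Arithmetic mean of the per-subject 2^-ddCt fold-changes (the headline
#' "x-fold" figure rounds this to the nearest integer); a geometric mean is
#' available since fold-changes are ratios and some workflows average them
#' on the log scale.
#'
#' @param folds Per-subject fold-changes (> 0), or a data.frame with columns
#'   `ct_target_tumor`, `ct_ref_tumor`, `ct_target_normal`, `ct_ref_normal`
#'   (one row per subject).
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return List with `folds` (per subject), `mean_fold`, and `headline`
#'   (mean rounded to nearest integer).
#' @export
cohort_fold_summary <- function(folds, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (is.data.frame(folds)) {
    folds <- mapply(fold_change, folds$ct_target_tumor, folds$ct_ref_tumor,
                    folds$ct_target_normal, folds$ct_ref_normal)
  }
  if (!length(folds)) stop("need at least one subject", call. = FALSE)
  if (any(folds <= 0)) stop("fold-changes must be > 0", call. = FALSE)
  m <- if (method == "arithmetic") mean(folds) else exp(mean(log(folds)))
  list(folds = folds, mean_fold = m, headline = round(m))
}

#' Per-subject fold-changes from a long-format Ct table
#'
#' @param ct_data data.frame with columns `subject`, `gene` ("target" or
#'   "reference"), `tissue` ("tumor" or "normal"), `ct`.
#' @return data.frame with one row per subject and the four Ct columns
#'   expected by [cohort_fold_summary()].
#' @export
ct_wide <- function(ct_data) {
  need <- c("subject", "gene", "tissue", "ct")
  if (!all(need %in% names(ct_data))) {
    stop("ct_data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  subjects <- unique(ct_data$subject)
  pick <- function(s, g, t) {
    v <- ct_data$ct[ct_data$subject == s & ct_data$gene == g &
                      ct_data$tissue == t]
    if (length(v) != 1) {
      stop("subject ", s, " needs exactly one Ct for ", g, "/", t,
           call. = FALSE)
    }
    v
  }
  data.frame(
    subject = subjects,
    ct_target_tumor = vapply(subjects, pick, numeric(1), "target", "tumor"),
    ct_ref_tumor = vapply(subjects, pick, numeric(1), "reference", "tumor"),
    ct_target_normal = vapply(subjects, pick, numeric(1), "target", "normal"),
    ct_ref_normal = vapply(subjects, pick, numeric(1), "reference", "normal"),
    stringsAsFactors = FALSE
  )
}
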