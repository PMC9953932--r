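#' Kaplan-Meier estimate for one cohort
#'
#' Product-limit estimator via [survival::survfit()], with the median
#' reported as the first event time at which the survival function reaches
#' 0.5 or below (a convention that resolves the even-n plateau where the
#' curve sits exactly at 0.5). The 95% CI for the median comes from
#' inverting the survfit confidence band.
#'
#' @param time Times to event, > 0 (days).
#' @param event Event indicator: 1 = death/euthanasia, 0 = censored.
#' @return A list of class `km_estimate`: `time`, `surv` (step function
#'   values after each event time), `n`, `events`, `median`, `median_ci`
#'   (length-2, possibly NA), and the underlying `survfit` object.
#' @export
km_fit <- function(time, event = rep(1, length(time))) {
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  if (sum(event) < 1) {
    stop("need at least one event for a Kaplan-Meier estimate", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  med <- km_median(fit$time, fit$surv)
  q <- stats::quantile(fit, probs = 0.5)
  ci <- c(unname(q$lower[1]), unname(q$upper[1]))
  structure(list(time = fit$time, surv = fit$surv,
                 n = length(time), events = sum(event),
                 median = med, median_ci = ci, survfit = fit),
            class = "km_estimate")
}

# first time at which the step function is <= 0.5 (NA if never reached)
km_median <- function(time, surv) {
  i <- which(surv <= 0.5)
  if (!length(i)) return(NA_real_)
  time[min(i)]
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-group log-rank with simultaneous risk-set
#' accounting of ties, via [survival::survdiff()]; two-sided p from a
#' chi-square with 1 df.
#'
#' @param time_a,event_a,time_b,event_b The two cohorts; each needs >= 2
#'   subjects and the pooled data >= 1 event.
#' @return List with `chisq` and `p`.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) < 2 || length(time_b) < 2) {
    stop("each arm needs >= 2 subjects", call. = FALSE)
  }
  if (sum(event_a) + sum(event_b) < 1) stop("no events", call. = FALSE)
  grp <- c(rep("a", length(time_a)), rep("b", length(time_b)))
  tt <- c(time_a, time_b); ev <- c(event_a, event_b)
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  list(chisq = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Percent increased lifespan
#'
#' `%ILS = (MST_treated - MST_untreated) x 100 / MST_untreated`, reported to
#' 1 decimal.
#'
#' @param mst_treated,mst_untreated Median survival times in days;
#'   `mst_untreated` must be > 0.
#' @return Percent increased lifespan (1 decimal).
#' @export
#' @examples
#' pct_ils(31.5, 21.0) # 50.0
pct_ils <- function(mst_treated, mst_untreated) {
  if (any(mst_untreated <= 0)) stop("mst_untreated must be > 0", call. = FALSE)
  round((mst_treated - mst_untreated) * 100 / mst_untreated, 1)
}

#' Arm-level survival report
#'
#' Per-arm median survival time with 95% CI, percent increased lifespan
#' against a reference arm, and the unadjusted pairwise log-rank p-value of
#' each arm versus the reference.
#'
#' @param data data.frame with columns `arm`, `time_days`, `event`.
#' @param reference Label of the reference arm (default "Untreated").
#' @return data.frame with columns arm, n, events, mst, mst_lo, mst_hi,
#'   pct_ils (NA for the reference), p_vs_reference (NA for the reference),
#'   ordered with the reference first then by arm label.
#' @export
survival_report <- function(data, reference = "Untreated") {
  need <- c("arm", "time_days", "event")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  arms <- unique(data$arm)
  if (!reference %in% arms) {
    stop("reference arm '", reference, "' not present", call. = FALSE)
  }
  fits <- lapply(arms, function(a) {
    rows <- data[data$arm == a, ]
    km_fit(rows$time_days, rows$event)
  })
  names(fits) <- arms
  ref_mst <- fits[[reference]]$median
  rows <- lapply(arms, function(a) {
    f <- fits[[a]]
    is_ref <- identical(a, reference)
    p <- if (is_ref) NA_real_ else {
      ra <- data[data$arm == a, ]; rr <- data[data$arm == reference, ]
      logrank(ra$time_days, ra$event, rr$time_days, rr$event)$p
    }
    data.frame(arm = a, n = f$n, events = f$events, mst = f$median,
               mst_lo = f$median_ci[1], mst_hi = f$median_ci[2],
               pct_ils = if (is_ref) NA_real_ else pct_ils(f$median, ref_mst),
               p_vs_reference = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm != reference, out$arm), , drop = FALSE]
  rownames(out) <- NULL
  out
}
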