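#' Organs recorded in the biodistribution protocol
#' @export
BIODIST_ORGANS <- c("tumor", "brain", "blood", "heart", "lung", "liver",
                    "kidney", "spleen", "skin", "muscle")

#' Summarize per-animal boron concentrations
#'
#' Group-wise sample mean and sample standard deviation (n-1 denominator) of
#' organ boron concentrations, grouped by compound, route, timepoint and
#' organ. Single-animal groups get sd = 0.
#'
#' @param measurements data.frame with columns `subject`, `compound`,
#'   `route`, `time_h`, `organ`, `boron_ug_per_g`.
#' @return data.frame with columns compound, route, time_h, organ, n, mean, sd.
#' @export
summarize_biodistribution <- function(measurements) {
  need <- c("compound", "route", "time_h", "organ", "boron_ug_per_g")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(measurements)) stop("no measurements", call. = FALSE)
  if (any(measurements$boron_ug_per_g < 0)) {
    stop("boron concentrations must be >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(measurements$organ), BIODIST_ORGANS)
  if (length(bad)) stop("unknown organ(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  agg <- stats::aggregate(
    boron_ug_per_g ~ compound + route + time_h + organ,
    data = measurements,
    FUN = function(x) c(n = length(x), mean = mean(x),
                        sd = if (length(x) > 1) stats::sd(x) else 0)
  )
  out <- cbind(agg[, c("compound", "route", "time_h", "organ")],
               as.data.frame(agg$boron_ug_per_g))
  out$n <- as.integer(out$n)
  out[order(out$compound, out$time_h, out$organ), , drop = FALSE]
}

#' Tumor-to-brain and tumor-to-blood ratios
#'
#' Ratios of the group mean tumor concentration to the group mean brain and
#' blood concentrations, computed from unrounded means. Display rounding (1
#' decimal, as in published biodistribution tables) is left to the caller or
#' to `round_ratios = TRUE`.
#'
#' @param summary A summary data.frame from [summarize_biodistribution()]
#'   restricted to one compound/route/timepoint (or with those columns
#'   constant).
#' @param round_ratios Round to 1 decimal for display; default FALSE.
#' @return Named list with `t_over_brain` and `t_over_blood`.
#' @export
tumor_ratios <- function(summary, round_ratios = FALSE) {
  get1 <- function(org) {
    m <- summary$mean[summary$organ == org]
    if (length(m) != 1) stop("need exactly one '", org, "' row", call. = FALSE)
    m
  }
  tum <- get1("tumor"); br <- get1("brain"); bl <- get1("blood")
  if (br <= 0 || bl <= 0) stop("brain and blood means must be > 0", call. = FALSE)
  r <- list(t_over_brain = tum / br, t_over_blood = tum / bl)
  if (round_ratios) r <- lapply(r, round, 1)
  r
}

#' Build a compact biodistribution table (tumor / brain / blood + ratios)
#'
#' One row per compound x route x timepoint with mean tumor, brain and blood
#' concentrations, group size, and the tumor-to-brain / tumor-to-blood
#' ratios from the unrounded means.
#'
#' @param measurements Long-format measurements; see
#'   [summarize_biodistribution()].
#' @return data.frame with columns compound, route, time_h, n, tumor, brain,
#'   blood, t_br, t_bl.
#' @export
biodistribution_table <- function(measurements) {
  s <- summarize_biodistribution(measurements)
  keys <- unique(s[, c("compound", "route", "time_h")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    g <- s[s$compound == k$compound & s$route == k$route &
             s$time_h == k$time_h, ]
    rat <- tumor_ratios(g)
    data.frame(compound = k$compound, route = k$route, time_h = k$time_h,
               n = g$n[g$organ == "tumor"],
               tumor = g$mean[g$organ == "tumor"],
               brain = g$mean[g$organ == "brain"],
               blood = g$mean[g$organ == "blood"],
               t_br = rat$t_over_brain, t_bl = rat$t_over_blood,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$compound, out$time_h), , drop = FALSE]
}

#' Normalize cellular boron uptake to micrograms per 1e9 cells
#'
#' @param boron_ug Boron mass in the digested cell pellet, ug.
#' @param n_cells Number of cells in the pellet (> 0).
#' @return Uptake in ug B per 1e9 cells.
#' @export
#' @examples
#' normalize_uptake(6.03e-2, 1e6) # 60.3 ug B / 1e9 cells
normalize_uptake <- function(boron_ug, n_cells) {
  if (any(n_cells <= 0)) stop("n_cells must be > 0", call. = FALSE)
  if (any(boron_ug < 0)) stop("boron_ug must be >= 0", call. = FALSE)
  boron_ug / n_cells * 1e9
}

#' Two-sample Student's t-test of cellular uptake
#'
#' Pooled-variance (Student's) two-sided t-test comparing boron uptake
#' between two compound groups; Welch's correction available behind a flag.
#'
#' @param group_a,group_b Numeric uptake vectors, each of length >= 2.
#' @param welch Use Welch's unequal-variance t instead; default FALSE.
#' @return List with `t`, `df`, `p`.
#' @export
compare_uptake <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    stop("zero pooled variance with unequal means", call. = FALSE)
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
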