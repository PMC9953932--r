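make_meas <- function(values, organ = "tumor", compound = "x", route = "iv",
                      time_h = 2.5) {
  data.frame(subject = paste0("s", seq_along(values)), compound = compound,
             route = route, time_h = time_h, organ = organ,
             boron_ug_per_g = values)
}

test_that("group summaries give sample mean and sd with n-1 denominator", {
  one <- summarize_biodistribution(make_meas(17.2))
  expect_equal(one$n, 1L)
  expect_equal(one$mean, 17.2)
  expect_equal(one$sd, 0)

  two <- summarize_biodistribution(make_meas(c(44, 46)))
  expect_equal(two$mean, 45.0)
  expect_equal(two$sd, sqrt(2), tolerance = 1e-9)

  # permutation invariance, and sd = 0 iff all equal
  v <- c(3.1, 9.4, 5.5, 7.2)
  a <- summarize_biodistribution(make_meas(v))
  b <- summarize_biodistribution(make_meas(rev(v)))
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_gt(a$sd, 0)
  expect_equal(summarize_biodistribution(make_meas(rep(2.5, 4)))$sd, 0)
  expect_error(summarize_biodistribution(make_meas(1, organ = "tail")),
               "unknown organ")
})

test_that("generator round-trip: summaries sit near configured parameters", {
  cfg <- study_config()
  meas <- gen_biodistribution(cfg, seed = 21)
  s <- summarize_biodistribution(meas)
  tab <- cfg$biodistribution
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    row <- s[s$compound == r$compound & s$time_h == r$time_h &
               s$organ == r$organ, ]
    expect_equal(row$n, r$n)
    # within ~3 standard errors of the generating mean (truncation shifts
    # the near-zero brain/blood groups slightly upward)
    tol <- 3 * r$sd / sqrt(r$n) + 0.3 * r$sd + 1e-9
    expect_lt(abs(row$mean - r$mean), tol + 0.01)
  }
})

test_that("tumor ratios reproduce the published table where consistent", {
  mk <- function(tumor, brain, blood) {
    data.frame(compound = "x", route = "iv", time_h = 2.5,
               organ = c("tumor", "brain", "blood"), n = 4,
               mean = c(tumor, brain, blood), sd = 0)
  }
  # combination row: 61.8 / 5.1 / 7.3 -> 12.1 and 8.5 at 1 decimal
  r <- tumor_ratios(mk(61.8, 5.1, 7.3), round_ratios = TRUE)
  expect_equal(r$t_over_brain, 12.1)
  expect_equal(r$t_over_blood, 8.5)
  # BPA rows arithmetically consistent with their printed means
  expect_equal(tumor_ratios(mk(20.6, 5.5, 7.7), TRUE)$t_over_blood, 2.7)
  r24 <- tumor_ratios(mk(8.2, 2.3, 2.9), TRUE)
  expect_equal(r24$t_over_brain, 3.6)
  expect_equal(r24$t_over_blood, 2.8)
  # high-uptake CED row: printed 55.0 reflects unrounded raw means; the
  # ratio of rounded means (56.25) must sit within 5% of it
  r55 <- tumor_ratios(mk(45.0, 0.8, 0.4))
  expect_lt(abs(r55$t_over_brain - 55.0) / 55.0, 0.05)
  expect_equal(tumor_ratios(mk(3, 3, 3))$t_over_brain, 1.0)
  expect_equal(tumor_ratios(mk(3, 3, 3))$t_over_blood, 1.0)
  expect_error(tumor_ratios(mk(3, 0, 3)), "> 0")
})

test_that("uptake normalization is exact and scale invariant", {
  expect_equal(normalize_uptake(6.03e-2, 1e6), 60.3, tolerance = 1e-9)
  expect_equal(normalize_uptake(0, 5e5), 0)
  expect_equal(normalize_uptake(2 * 6.03e-2, 2e6), 60.3, tolerance = 1e-9)
  expect_error(normalize_uptake(1, 0), "n_cells")
})

test_that("Student's t matches closed-form and permutation oracles", {
  x <- c(60.1, 58.4, 62.3); y <- c(11.4, 12.0, 12.3)
  got <- compare_uptake(x, y)
  want <- oracle_student_t(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)

  x2 <- c(5.1, 6.2, 4.8); y2 <- c(5.6, 6.0, 5.2)
  got2 <- compare_uptake(x2, y2)
  want2 <- oracle_student_t(x2, y2)
  expect_equal(got2$t, want2$t, tolerance = 1e-9)
  expect_equal(got2$p, want2$p, tolerance = 1e-9)
  # the exact permutation p on a clearly-separated 3v3 fixture is 1/10
  # (only the observed split attains the max |mean difference|); Student's p
  # must agree in its significance call at the permutation resolution
  expect_equal(oracle_mean_perm_p(x, y), 0.1, tolerance = 1e-12)
  expect_lt(got$p, 0.1)

  same <- c(4, 5, 6)
  id <- compare_uptake(same, same)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
})

test_that("simulated uptake groups reproduce the reported significance", {
  cfg <- study_config()
  upt <- gen_uptake(cfg, seed = 31)
  upt$uptake <- normalize_uptake(upt$boron_ug, upt$n_cells)
  f98 <- upt[upt$cell_line == "F98", ]
  p <- compare_uptake(f98$uptake[f98$compound == "dpa_bstpg"],
                      f98$uptake[f98$compound == "bpa"])$p
  expect_lt(p, 1e-4)
})
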