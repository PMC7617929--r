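make_4pl_data <- function(b, c, d, e, concs = c(1, 2, 5, 10, 20, 30),
                          reps = 3, noise = 0, seed = NULL) {
  grid <- expand.grid(conc_mM = concs, replicate = seq_len(reps))
  mu <- fourpl(grid$conc_mM, b, c, d, e)
  if (!is.null(seed)) set.seed(seed)
  data.frame(conc_mM = grid$conc_mM,
             diameter_mm = mu + if (noise > 0) rnorm(nrow(grid), 0, noise) else 0)
}

test_that("zero-noise 4PL data are recovered to 1e-4 relative", {
  dat <- make_4pl_data(b = 2, c = 10, d = 40, e = 8)
  fit <- fit_four_pl(dat)
  expect_true(fit$converged)
  expect_equal(fit$b, 2, tolerance = 1e-4)
  expect_equal(fit$c, 10, tolerance = 1e-4)
  expect_equal(fit$d, 40, tolerance = 1e-4)
  expect_equal(fit$e, 8, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-6)
})

test_that("increasing responses fit with a negative slope under the sign convention", {
  dat <- make_4pl_data(b = -1.5, c = 12, d = 35, e = 5)
  fit <- fit_four_pl(dat)
  expect_true(fit$converged)
  expect_equal(fit$b, -1.5, tolerance = 1e-3)
})

test_that("degenerate and underdetermined inputs give flagged, not crashing, fits", {
  flat <- data.frame(conc_mM = rep(c(1, 2, 5, 10, 20), 2), diameter_mm = 6)
  f <- fit_four_pl(flat)
  expect_true(f$degenerate)
  expect_equal(predict(f, c(1, 10, 30)), rep(6, 3))
  few <- data.frame(conc_mM = c(1, 2, 5, 1, 2, 5), diameter_mm = c(4:6, 4:6))
  expect_false(fit_four_pl(few)$converged)
  expect_match(fit_four_pl(few)$message, "distinct")
})

test_that("exact linear data recover intercept and slope with zero residual", {
  dat <- data.frame(conc_mM = rep(c(1, 5, 10, 20), 2))
  dat$diameter_mm <- 30 - 0.5 * dat$conc_mM
  fit <- fit_linear(dat)
  expect_equal(fit$intercept, 30, tolerance = 1e-10)
  expect_equal(fit$slope, -0.5, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)
  two <- data.frame(conc_mM = c(1, 2, 1, 2), diameter_mm = c(5, 6, 5, 6))
  expect_error(fit_linear(two), "distinct")
})

test_that("a 4PL near its linear mid-range is matched closely by the line", {
  # with 21 noisy points the df-adjusted parity of the two models is
  # E[rss_lin]/E[rss_4pl] ~ (n-2)/(n-4) = 1.12; curvature over a narrow
  # log-range around e adds a few percent. The median ratio sits near 1.07.
  set.seed(10)
  concs <- exp(seq(log(5), log(12), length.out = 7))   # around e = 8
  ratios <- replicate(40, {
    dat <- make_4pl_data(b = 1, c = 10, d = 40, e = 8, concs = concs,
                         noise = 1)
    fit_linear(dat)$rss / fit_four_pl(dat)$rss
  })
  expect_lt(median(ratios), 1.15)
})

test_that("model selection prefers sigmoids for sigmoid data and lines for linear data", {
  sig <- make_4pl_data(b = 3, c = 8, d = 40, e = 8)
  sel <- select_model(fit_four_pl(sig), fit_linear(sig))
  expect_equal(sel$choice, "fourpl")
  lin <- data.frame(conc_mM = rep(c(1, 2, 5, 10, 20, 30), 3))
  lin$diameter_mm <- 35 - 0.4 * lin$conc_mM
  sel2 <- select_model(fit_four_pl(lin), fit_linear(lin))
  expect_equal(sel2$choice, "linear")
})

test_that("false sigmoid selections stay below 10% on noisy linear data", {
  set.seed(77)
  wrong <- 0
  n_sim <- 200
  for (r in seq_len(n_sim)) {
    dat <- data.frame(conc_mM = rep(c(1, 2, 5, 10, 20, 30), 3))
    dat$diameter_mm <- 35 - 0.4 * dat$conc_mM + rnorm(nrow(dat), 0, 1)
    sel <- select_model(fit_four_pl(dat), fit_linear(dat))
    if (sel$choice == "fourpl") wrong <- wrong + 1
  }
  expect_lt(wrong / n_sim, 0.10)
})

test_that("inflection estimates are scale-equivariant and fits respect their asymptotes", {
  dat <- make_4pl_data(b = 2, c = 10, d = 40, e = 8, noise = 1, seed = 3)
  f1 <- fit_four_pl(dat)
  dat2 <- dat; dat2$conc_mM <- dat$conc_mM * 3
  f2 <- fit_four_pl(dat2)
  expect_equal(f2$e / f1$e, 3, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
  expect_equal(f2$c, f1$c, tolerance = 1e-6)
  expect_equal(f2$d, f1$d, tolerance = 1e-6)
  grid <- exp(seq(log(0.01), log(1000), length.out = 200))
  pr <- predict(f1, grid)
  expect_true(all(pr >= min(f1$c, f1$d) - 1e-9 & pr <= max(f1$c, f1$d) + 1e-9))
  expect_true(all(diff(pr) <= 1e-9))   # b > 0: monotone non-increasing
})

test_that("inflection recovery on noisy tables has bounded median error", {
  set.seed(11)
  errs <- replicate(60, {
    dat <- make_4pl_data(b = 2, c = 10, d = 40, e = 8,
                         concs = c(1, 2, 4, 8, 12, 20, 30),
                         noise = 1.5)
    f <- fit_four_pl(dat)
    if (f$converged) abs(f$e - 8) / 8 else NA
  })
  expect_lt(median(errs, na.rm = TRUE), 0.25)
})

test_that("the non-motile baseline is mean + 2 SD of the control strain", {
  tab <- data.frame(strain = c("fliG", "fliG", "fliG", "wt"),
                    diameter_mm = c(5, 6, 7, 30))
  expect_equal(non_motile_baseline(tab, "fliG"), 8)
  flat <- data.frame(strain = "fliG", diameter_mm = rep(6, 4))
  expect_equal(non_motile_baseline(flat, "fliG"), 6)
  expect_error(non_motile_baseline(flat, "motA"), "motA")
})

test_that("a motile strain converging to the control level has its lower asymptote near the baseline", {
  set.seed(5)
  curves <- data.frame(strain = c("wildtype", "fliG"),
                       carbon_source = "succinate",
                       b = 2, c = c(6.5, 6), d = c(42, 6), e = 6)
  tab <- generate_halo_table(curves, concentrations = c(1, 2, 5, 10, 20, 30),
                             noise_sd = 0.8, replicates = 4, seed = 19)
  base <- non_motile_baseline(tab, "fliG")
  fit <- fit_four_pl(tab[tab$strain == "wildtype", ])
  ctrl_sd <- sd(tab$diameter_mm[tab$strain == "fliG"])
  expect_lt(abs(fit$c - base), 2 + ctrl_sd)
})

test_that("fit_halo_table reports a model per strain x carbon and the shared baseline", {
  tab <- generate_halo_table(noise_sd = 1, seed = 33)
  res <- fit_halo_table(tab, control_strain = "fliG")
  expect_equal(nrow(res$summary), 9)   # 3 strains x 3 carbons, control excluded
  expect_true(all(res$summary$model %in% c("fourpl", "linear")))
  expect_gt(res$baseline, 5)
})
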