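nat_palm <- natural_pattern("C17H34O2")

test_that("forward model composes binomial, convolution and mixture stages", {
  # degenerate cases collapse to the natural envelope
  nat_norm <- normalise_pattern(nat_palm)$fractions
  expect_equal(predict_observed(0, 0.08, 14, nat_palm)$fractions, nat_norm)
  expect_equal(predict_observed(1, 0, 14, nat_palm)$fractions, nat_norm)
  # hand-composed chain of the three stages
  mp <- deuterium_pattern(0.08, 14)
  mn <- convolve5_oracle(mp$fractions, nat_palm$fractions)
  mix <- 0.25 * mn + 0.75 * nat_palm$fractions
  expect_equal(predict_observed(0.25, 0.08, 14, nat_palm)$fractions,
               mix / sum(mix), tolerance = 1e-12)
  expect_error(predict_observed(1.2, 0.08, 14, nat_palm), "\\[0, 1\\]")
})

test_that("noise-free round trips recover f, p to 1e-5 and N exactly", {
  cfg <- mida_config()
  for (f in c(0.05, 0.25, 0.5, 0.9)) {
    for (p in c(0.04, 0.08)) {
      for (N in c(12, 14, 22)) {
        truth <- predict_observed(f, p, N, nat_palm)$fractions
        ob <- mida_observation("s", "palmitate", "C17H34O2", truth)
        fit <- fit_fp(ob, N, cfg)
        expect_equal(fit$f, f, tolerance = 1e-5)
        expect_equal(fit$p, p, tolerance = 1e-5)
        expect_true(fit$converged)
      }
    }
  }
})

test_that("N-scan selects the generating N by the p-matching rule", {
  cfg <- mida_config()
  for (N_true in c(14, 22)) {
    truth <- predict_observed(0.3, 0.08, N_true, nat_palm)$fractions
    ob <- mida_observation("s", "palmitate", "C17H34O2", truth)
    fit <- determine_N(ob, cfg)
    expect_equal(fit$N, N_true)
    expect_equal(fit$p, 0.08, tolerance = 1e-5)
    trace <- attr(fit, "n_scan")
    expect_equal(trace$N, 8:24)
    expect_equal(trace$p[trace$N == N_true], fit$p)
  }
})

test_that("unlabelled observations are flagged unidentifiable", {
  obs_nat <- normalise_pattern(nat_palm)$fractions
  ob <- mida_observation("s", "palmitate", "C17H34O2", obs_nat)
  fit <- fit_fp(ob, 14)
  expect_true("unidentifiable" %in% fit$flags)
  expect_equal(fit$f, 0, tolerance = 1e-5)
  # N scan still returns (tie rule -> some N in range), flagged the same way
  fitN <- determine_N(ob)
  expect_true("unidentifiable" %in% fitN$flags)
  expect_true(fitN$N %in% 8:24)
})

test_that("fix_p mode pins p and selects N by residual", {
  cfg <- mida_config(mode = "fix_p")
  truth <- predict_observed(0.4, 0.08, 14, nat_palm)$fractions
  ob <- mida_observation("s", "palmitate", "C17H34O2", truth)
  fit <- determine_N(ob, cfg)
  expect_equal(fit$N, 14)
  expect_identical(fit$p, 0.08)
  expect_equal(fit$f, 0.4, tolerance = 1e-6)
})

test_that("optimiser is at least as good as a 101x101 grid search", {
  set.seed(23)
  for (i in 1:3) {
    truth <- predict_observed(runif(1, 0.1, 0.9), runif(1, 0.03, 0.12), 14,
                              nat_palm)$fractions
    noisy <- truth * exp(rnorm(5, 0, 0.02))
    ob <- mida_observation("s", "palmitate", "C17H34O2", noisy)
    fit <- fit_fp(ob, 14)
    expect_lte(fit$sse,
               mida_grid_sse(ob$observed$fractions, nat_palm, 14) + 1e-15)
  }
})

test_that("objective is invariant to raw-intensity rescaling", {
  truth <- predict_observed(0.3, 0.08, 14, nat_palm)$fractions
  f1 <- fit_fp(mida_observation("s", "pa", "C17H34O2", truth * 1e6), 14)
  f2 <- fit_fp(mida_observation("s", "pa", "C17H34O2", truth * 3.7), 14)
  expect_equal(f1$f, f2$f, tolerance = 1e-9)
  expect_equal(f1$p, f2$p, tolerance = 1e-9)
})

test_that("a measured control pattern takes precedence over theory", {
  # distort the control slightly; the fit should follow the control
  ctrl <- isotope_pattern(nat_palm$fractions * c(0.98, 1.05, 1, 1, 1))
  truth <- predict_observed(0.3, 0.08, 14, ctrl)$fractions
  ob <- mida_observation("s", "pa", "C17H34O2", truth, natural = ctrl)
  fit <- fit_fp(ob, 14)
  expect_equal(fit$f, 0.3, tolerance = 1e-5)
  expect_equal(fit$p, 0.08, tolerance = 1e-5)
})

test_that("absolute DNL multiplies fractional synthesis by pool size", {
  expect_equal(absolute_dnl(0.25, 40), 10)
  expect_equal(absolute_dnl(0, 99), 0)
  expect_equal(absolute_dnl(1, 7.5), 7.5)
  fit <- structure(list(f = 0.5), class = "mida_fit")
  expect_equal(absolute_dnl(fit, 10), 5)
  expect_error(absolute_dnl(0.25, NA), "missing")
  expect_error(absolute_dnl(0.25, -1), ">= 0")
})

test_that("batch driver matches single-row fits and survives bad rows", {
  tab <- rbind(
    gen_mida_dataset(f = 0.25, p = 0.08, N = 14, noise_cv = 0, seed = 1,
                     amount_nmol = 40),
    gen_mida_dataset(f = 0.5, p = 0.08, N = 14, formula = "C17H32O2",
                     fatty_acid = "palmitoleate", noise_cv = 0, seed = 2,
                     amount_nmol = 12)
  )
  res <- run_mida_table(tab)
  expect_equal(nrow(res), 2L)
  expect_equal(res$f, c(0.25, 0.5), tolerance = 1e-5)
  expect_equal(res$N, c(14L, 14L))
  expect_equal(res$dnl_nmol, c(0.25 * 40, 0.5 * 12), tolerance = 1e-4)

  # malformed formula: row fails, batch continues
  bad <- tab
  bad$formula[1] <- "C17X2"
  res2 <- run_mida_table(bad)
  expect_match(res2$flags[1], "error")
  expect_equal(res2$f[2], 0.5, tolerance = 1e-5)

  # empty table warns and returns an empty frame
  expect_warning(res3 <- run_mida_table(tab[0, ]), "empty")
  expect_equal(nrow(res3), 0L)
})
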