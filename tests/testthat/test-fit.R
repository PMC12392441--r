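# Fitting tests run at reduced scale (fewer chains and replicates than the
# defaults) to keep the suite fast; the full-scale behavior is exercised in
# the acceptance tests.

small_cfg <- function() fit_config(m = 1000, replicates = 8, base_seed = 21)

test_that("simulated curves behave at the extent grid endpoints", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  c0 <- simulate_curve(0, cfg, curves)
  init <- cumulative_curve(mw_histogram(build_initial_ensemble(cfg$spec)))
  expect_equal(eval_curve(init, c0$mw_da), c0$mean, tolerance = 1e-9)
  # envelope contains the mean pointwise
  c2 <- simulate_curve(2, cfg, curves)
  expect_true(all(c2$lo95 <= c2$mean + 1e-9 & c2$mean <= c2$hi95 + 1e-9))
  # heavier scission shifts mass to lower MW: cumulative curve moves up
  expect_true(all(c2$mean >= c0$mean - 1e-9))
  expect_error(simulate_curve(3.33, cfg, curves), class = "scission_domain_error")
})

test_that("the fit recovers known scission extents from noise-free fixtures", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  for (truth in c(0.5, 2)) {
    tab <- generate_fixture_peak_table(true_sic = truth, seed = 300 + truth,
                                       spec = cfg$spec, model = cfg$model)
    fit <- fit_sic(to_fit_input(tab), cfg, curves)
    expect_lte(abs(fit$sic_hat - truth), 0.2)
    # profile is minimized at the reported estimate
    expect_equal(min(fit$sse_profile$sse), fit$sse)
    expect_equal(fit$sse_profile$sic[which.min(fit$sse_profile$sse)],
                 fit$sic_hat)
  }
})

test_that("the unreacted distribution fits to extent zero", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  init <- cumulative_curve(mw_histogram(build_initial_ensemble(cfg$spec)))
  fit <- fit_sic(init, cfg, curves)
  expect_equal(fit$sic_hat, 0)
  expect_lt(fit$sse, 1e-9)  # deterministic build: simulated extent 0 is exact
})

test_that("fit is invariant to rescaling raw integrals", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  tab <- generate_fixture_peak_table(true_sic = 1.5, seed = 9,
                                     spec = cfg$spec, model = cfg$model)
  scaled <- peak_table(kind = tab$kind, integral = tab$integral * 1234,
                       mw_da = tab$mw_da)
  f1 <- fit_sic(to_fit_input(tab), cfg, curves)
  f2 <- fit_sic(to_fit_input(scaled), cfg, curves)
  expect_equal(f1$sic_hat, f2$sic_hat)
  expect_equal(f1$sse, f2$sse, tolerance = 1e-9)
})

test_that("degenerate and undersized experimental curves are rejected", {
  cfg <- small_cfg()
  flat <- peak_table(kind = c("lump_low", "resolved"),
                     integral = c(0, 10), mw_da = c(NA, 3000))
  # one resolved point + 2 boundary points, but constant cumulative values
  fi <- to_fit_input(flat)
  fi$cum_wt_pct <- 100
  fi$lump_low <- 100  # constant curve
  expect_error(fit_sic(fi, cfg, simulate_sic_curves(cfg)),
               class = "scission_fit_degenerate_error")
})

test_that("sic_fit methods expose the model-object interface", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  tab <- generate_fixture_peak_table(true_sic = 2, seed = 55,
                                     spec = cfg$spec, model = cfg$model)
  fit <- fit_sic(to_fit_input(tab), cfg, curves)
  expect_named(coef(fit), "sic")
  expect_length(residuals(fit), fit$diagnostics$n_points)
  expect_equal(fitted(fit) + residuals(fit), fit$observed)
  expect_equal(predict(fit), fit$fitted, tolerance = 1e-9)
  expect_output(print(fit), "estimated SiC")
  expect_output(summary(fit), "SSE at optimum")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("recovery_report reports bias and rmse per truth", {
  cfg <- small_cfg()
  curves <- simulate_sic_curves(cfg)
  rep <- recovery_report(c(0, 2), cfg, n_trials = 3, curves = curves)
  expect_equal(rep$truth, c(0, 2))
  expect_equal(rep$bias[1], 0)   # unreacted fixtures recover exactly
  expect_lte(abs(rep$bias[2]), 0.15)
  expect_lte(rep$rmse[2], 0.25)
})
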