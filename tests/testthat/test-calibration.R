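test_that("convolution weights are a proper mixture", {
  curve <- synthetic_curve(0:99, CR = 0, PR = seq(0, 0.9, length.out = 100),
                           SD = 0.1, PD = 0.9 - seq(0, 0.9, length.out = 100))
  for (mu in c(-5, 0, 35, 70, 120)) {
    for (sigma in c(4, 15)) {
      out <- convolve_rates(curve, mu, sigma)
      expect_equal(sum(out), 1, tolerance = 1e-12)
    }
  }
  expect_equal(sum(convolve_rates(curve, 50, 0.5)), 1, tolerance = 1e-12)
  # a curve constant in efficacy is invariant under any mixing
  flat <- synthetic_curve(0:99, CR = 0.1, PR = 0.2, SD = 0.3, PD = 0.4)
  expect_equal(convolve_rates(flat, 50, 10),
               c(CR = 0.1, PR = 0.2, SD = 0.3, PD = 0.4))
  expect_equal(convolve_rates(flat, 3, 0.6),
               c(CR = 0.1, PR = 0.2, SD = 0.3, PD = 0.4))
})

test_that("sigma = 0 degenerates to the nearest grid point", {
  curve <- synthetic_curve(0:99, CR = 0, PR = (0:99) / 99, SD = 0,
                           PD = 1 - (0:99) / 99)
  expect_equal(convolve_rates(curve, 35, 0)[["PR"]], 35 / 99)
  expect_equal(convolve_rates(curve, 35.4, 0)[["PR"]], 35 / 99)
  expect_equal(convolve_rates(curve, 35.6, 0)[["PR"]], 36 / 99)
})

test_that("a symmetric distribution mixes a step curve to one half", {
  step <- synthetic_curve(0:99, CR = 0, PR = as.numeric(0:99 >= 35), SD = 0,
                          PD = as.numeric(0:99 < 35))
  out <- convolve_rates(step, 34.5, 4)
  expect_equal(out[["PR"]], 0.5, tolerance = 0.01)
})

test_that("distributions far off the grid are rejected as degenerate", {
  curve <- synthetic_curve(0:99, CR = 0, PR = 0.5, SD = 0.5, PD = 0)
  expect_error(convolve_rates(curve, -500, 0.5), "degenerate")
  expect_error(convolve_rates(curve, 35, -1), "non-negative")
})

test_that("the grid search exactly recovers a self-generated reference", {
  # smooth synthetic curve with all three scored categories varying
  d <- 0:99
  pr <- stats::plogis((d - 50) / 8) * 0.8
  pd <- (1 - stats::plogis((d - 30) / 6)) * 0.9
  sd_ <- 1 - pr - pd
  curve <- synthetic_curve(d, CR = 0, PR = pr, SD = sd_, PD = pd)
  for (truth in list(c(37, 4), c(60, 10), c(12, 2))) {
    ref <- convolve_rates(curve, truth[1], truth[2])
    fit <- fit_delta_distribution(curve, ref, mu_grid = 0:99,
                                  sigma_grid = seq(1, 20, 1))
    expect_equal(c(fit$mu, fit$sigma), truth)
    expect_equal(fit$discrepancy, 0, tolerance = 1e-12)
  }
  # the reported optimum attains the heatmap minimum
  ref <- convolve_rates(curve, 37, 4)
  fit <- fit_delta_distribution(curve, ref, mu_grid = 0:99,
                                sigma_grid = seq(1, 20, 1))
  expect_equal(fit$heatmap[as.character(fit$mu), as.character(fit$sigma)],
               min(fit$heatmap))
})

test_that("a point-mass reference is recovered at sigma = 0", {
  d <- 0:20
  curve <- synthetic_curve(d, CR = 0, PR = d / 20, SD = 1 - d / 20, PD = 0)
  ref <- curve[1, c("CR", "PR", "SD", "PD")]
  fit <- fit_delta_distribution(curve, unlist(ref), mu_grid = 0:20,
                                sigma_grid = c(0, 1, 2))
  expect_equal(fit$sigma, 0)
  expect_equal(fit$mu, 0)
})

test_that("ties break toward the smallest sigma, then the smallest mu", {
  flat <- synthetic_curve(0:10, CR = 0, PR = 0.2, SD = 0.5, PD = 0.3)
  ref <- c(CR = 0, PR = 0.2, SD = 0.5, PD = 0.3)
  fit <- fit_delta_distribution(flat, ref, mu_grid = c(8, 3, 5),
                                sigma_grid = c(2, 1))
  expect_equal(fit$sigma, 1)
  expect_equal(fit$mu, 3)
})

test_that("fit inputs are validated", {
  curve <- synthetic_curve(0:10, CR = 0, PR = 0.2, SD = 0.5, PD = 0.3)
  expect_error(fit_delta_distribution(curve, mu_grid = numeric(0)), "non-empty")
  expect_error(fit_delta_distribution(curve, c(CR = 0.5, PR = 0.2, SD = 0.5,
                                               PD = 0.3)), "sum to 1")
})

test_that("simulated response curves are proper and monotone in efficacy", {
  cfg <- tiny_cfg(n = 60, seed = 14)
  curve <- response_curve(cfg, default_p, ici_pharmacodynamics(),
                          grid = c(0, 25, 45, 70, 99))
  expect_equal(rowSums(curve[, c("CR", "PR", "SD", "PD")]), rep(1, 5))
  # progression becomes rarer as efficacy grows (Monte-Carlo slack one patient)
  expect_true(all(diff(curve$PD) <= 1 / 60 + 1e-12))
  # the zero-efficacy column equals the untreated cohort's rates
  cohort <- sample_cohort(cfg, default_p)
  sim0 <- simulate_cohort(cohort, default_p,
                          treatment_schedule(horizon = 365), delta0 = 0)
  rates0 <- summarize_response(evaluate_cohort(sim0, "sum")$category)$fractions
  expect_equal(unlist(curve[1, c("CR", "PR", "SD", "PD")]), rates0,
               tolerance = 1e-12, ignore_attr = TRUE)
})
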