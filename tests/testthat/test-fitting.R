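test_that("fractional-SD variance model sets sigma = fsd * y", {
  df <- tibble::tibble(patient_id = "P1", time_h = c(2, 24),
                       activity_pct_ia = c(10, 2))
  expect_equal(add_measurement_sd(df, fsd = 0.15)$sigma, c(1.5, 0.3))
  expect_equal(add_measurement_sd(df, fsd = 0.3)$sigma[2], 0.6)
  df$activity_pct_ia[1] <- 0
  expect_error(add_measurement_sd(df), "> 0")
})

test_that("-2lnL is WRSS plus the sigma-dependent constant", {
  tt <- c(1, 24, 48)
  p <- c(A1 = 10, lambda1 = 0.03)
  df <- noise_free_curve("f2b", p, tt)
  df <- add_measurement_sd(df)
  const <- sum(log(2 * pi * df$sigma^2))
  expect_equal(neg2_log_likelihood(df, "f2b", p), const)
  expect_equal(neg2_log_likelihood(df, "f2b", p, include_constant = FALSE), 0)

  # single sample with unit sigma and zero residual -> ln(2*pi)
  one <- tibble::tibble(patient_id = "P1", time_h = 24,
                        activity_pct_ia = evaluate_model("f2b", p, 24),
                        sigma = 1)
  expect_equal(neg2_log_likelihood(one, "f2b", p), log(2 * pi))

  # standardized residuals (1, -1, 2) contribute WRSS = 6
  df2 <- df
  df2$activity_pct_ia <- df$activity_pct_ia + c(1, -1, 2) * df$sigma
  expect_equal(
    neg2_log_likelihood(df2, "f2b", p, include_constant = FALSE), 6)
})

test_that("individual fit recovers noise-free parameters", {
  df <- noise_free_curve("f2b", c(A1 = 12, lambda1 = 0.02), nominal_sessions)
  fit <- fit_individual(df, "f2b")
  est <- tidy(fit)
  expect_true(fit$converged)
  expect_equal(est$estimate[est$parameter == "A1"], 12, tolerance = 1e-6)
  expect_equal(est$estimate[est$parameter == "lambda1"], 0.02, tolerance = 1e-6)
  expect_lt(fit$wrss, 1e-12)
  expect_identical(fit$K, 2L)
})

test_that("fits require enough data points and reject shared models", {
  df3 <- noise_free_curve("f4", c(A1 = 8, lambda1 = 0.05, A2 = 2, lambda2 = 0.005),
                          nominal_sessions[1:3])
  expect_error(fit_individual(df3, "f4"), "only 3 data")
  df5 <- noise_free_curve("f4", c(A1 = 8, lambda1 = 0.05, A2 = 2, lambda2 = 0.005),
                          nominal_sessions)
  expect_s3_class(fit_individual(df5, "f4"), "pbms_fit")
  expect_error(fit_individual(df5, "f3aS4"), "shared")
})

test_that("noisy replicates recover the clearance rate without gross bias", {
  # simulation oracle: median recovered lambda1 over replicates near truth
  truth <- c(A1 = 12, lambda1 = 0.02)
  y0 <- evaluate_model("f2b", truth, nominal_sessions)
  set.seed(314)
  lam <- replicate(60, {
    y <- y0 * (1 + rnorm(5, 0, 0.15))
    while (any(y <= 0)) y <- y0 * (1 + rnorm(5, 0, 0.15))
    df <- tibble::tibble(patient_id = "P1", time_h = nominal_sessions,
                         activity_pct_ia = y)
    f <- fit_individual(df, "f2b", control = fit_control(n_starts = 4))
    p <- tidy(f)
    p$estimate[p$parameter == "lambda1"]
  })
  expect_lt(abs(stats::median(lam) - 0.02) / 0.02, 0.05)
})

test_that("population fit of a non-shared model equals per-patient fits", {
  sim <- simulate_population(seed = 5)
  pop <- fit_population(sim$data, "f2b")
  ids <- unique(sim$data$patient_id)
  for (id in ids[c(1, 7, 13)]) {
    ind <- fit_individual(sim$data[sim$data$patient_id == id, ], "f2b")
    pe <- tidy(pop)
    pe <- pe[pe$patient_id == id, ]
    ie <- tidy(ind)
    expect_equal(pe$estimate, ie$estimate, tolerance = 1e-6)
  }
  expect_identical(pop$K, 26L)
  expect_identical(pop$N, 46L)

  # single-patient population is identical to the individual fit
  one <- sim$data[sim$data$patient_id == ids[1], ]
  expect_equal(tidy(fit_population(one, "f2b"))$estimate,
               tidy(fit_individual(one, "f2b"))$estimate, tolerance = 1e-12)
})

test_that("population fit recovers a noise-free shared fraction exactly", {
  cfg <- synthetic_config(noise_fsd = 0, shared_beta = 0.9)
  sim <- simulate_population(cfg, seed = 3)
  fit <- fit_population(sim$data, "f3aS4")
  est <- tidy(fit)
  expect_equal(est$estimate[est$shared], 0.9, tolerance = 1e-6)
  expect_identical(fit$K, 27L)
  # optimum is at least as good as the generating parameters
  truth_params <- lapply(seq_len(nrow(sim$truth$parameters)), function(i) {
    r <- sim$truth$parameters[i, ]
    c(A1 = r$A1, lambda1 = r$lambda1, beta = 0.9)
  })
  names(truth_params) <- sim$truth$parameters$patient_id
  m2ll_truth <- neg2_log_likelihood(sim$data, "f3aS4", truth_params)
  expect_lte(fit$minus2lnL, m2ll_truth + 1e-8)
})

test_that("population fit is invariant under patient permutation and seed", {
  sim <- simulate_population(seed = 4)
  f1 <- fit_population(sim$data, "f3aS4")
  perm <- sim$data[order(rev(sim$data$patient_id), sim$data$time_h), ]
  f2 <- fit_population(perm, "f3aS4")
  a <- dplyr::arrange(tidy(f1), patient_id, parameter)
  b <- dplyr::arrange(tidy(f2), patient_id, parameter)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-8)

  # bit-reproducible under the same multi-start seed
  f3 <- fit_population(sim$data, "f3aS4")
  expect_identical(tidy(f1)$estimate, tidy(f3)$estimate)

  # different multi-start seeds agree on the optimum for this problem
  f4 <- fit_population(sim$data, "f3aS4",
                       control = fit_control(seed = 42))
  expect_equal(f1$minus2lnL, f4$minus2lnL, tolerance = 1e-6)
})

test_that("reported WRSS matches independently recomputed residuals", {
  sim <- simulate_population(seed = 6)
  fit <- fit_population(sim$data, "f3aS4")
  aug <- augment(fit)
  expect_equal(fit$wrss, sum(aug$std_resid^2), tolerance = 1e-10)
  expect_equal(fit$minus2lnL, fit$wrss + sum(log(2 * pi * aug$sigma^2)),
               tolerance = 1e-10)
})

test_that("fixed-shared fits estimate per-patient parameters only", {
  truth <- c(A1 = 9, lambda1 = 0.025, beta = 0.9632)
  df <- noise_free_curve("f3aS4", truth, nominal_sessions[1:3])
  fit <- fit_fixed_shared(df, "f3aS4", 0.9632)
  est <- tidy(fit)
  expect_identical(fit$K, 2L)
  expect_identical(nrow(est), 2L)
  expect_equal(est$estimate[est$parameter == "A1"], 9, tolerance = 1e-5)
  expect_equal(est$estimate[est$parameter == "lambda1"], 0.025, tolerance = 1e-4)
  expect_error(fit_fixed_shared(df, "f3aS4", 1.2), "bounds")
  expect_error(fit_fixed_shared(df, "f2b", 0.5), "no shared parameter")
})

test_that("uncertainty reporting: 1-parameter case and collinearity", {
  # f1 on one sample: empty correlation, CV from the 1x1 information matrix
  one <- tibble::tibble(patient_id = "P1", time_h = 24,
                        activity_pct_ia = evaluate_model("f1", c(A1 = 50), 24))
  f1fit <- fit_individual(one, "f1")
  expect_identical(length(top_corr <- f1fit$correlation[lower.tri(f1fit$correlation)]), 0L)
  expect_true(is.finite(tidy(f1fit)$cv))

  # f3a on near-mono-exponential data: A1/A2 split is ill-determined,
  # at least one correlation above 0.9
  df <- noise_free_curve("f2b", c(A1 = 10, lambda1 = 0.005), nominal_sessions)
  f3afit <- fit_individual(df, "f3a")
  corrs <- abs(f3afit$correlation[lower.tri(f3afit$correlation)])
  expect_gt(max(corrs), 0.9)

  # exactly determined fit (n = K): zero residual, finite covariance
  df2 <- noise_free_curve("f2b", c(A1 = 10, lambda1 = 0.02), c(2, 40))
  exfit <- fit_individual(df2, "f2b")
  expect_lt(exfit$wrss, 1e-10)
  expect_true(all(is.finite(tidy(exfit)$sd)))
})
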