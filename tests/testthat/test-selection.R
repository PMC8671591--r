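test_that("AICc arithmetic and feasibility bounds", {
  # population dimensions: K = 27, N = 46 -> penalty 54 + 1512/18 = 138
  expect_equal(aicc(10, k = 27, n = 46), 148)
  # per-patient dimensions: K = 2, N = 5 -> penalty 4 + 6 = 10
  expect_equal(aicc(0, k = 2, n = 5), 10)
  expect_equal(aicc(5, k = 0, n = 10), 5)
  expect_error(aicc(0, k = 45, n = 46), "N - K - 1")

  expect_true(is_feasible("f3aS4", n_obs = 46, n_patients = 13))  # K=27
  expect_true(count_parameters("f4", 11) == 44 &&
                is_feasible("f4", n_obs = 46, n_patients = 11))   # K = 44 = N-2
  expect_false(is_feasible("f4", n_obs = 46, n_patients = 13))    # K = 52
  expect_true(is_feasible("f3a", n_obs = 5, n_patients = 1))      # K = 3
  expect_false(is_feasible("f4", n_obs = 5, n_patients = 1))      # K = 4
  expect_true(is_feasible("f1", n_obs = 3, n_patients = 1))
})

test_that("Akaike weights match closed forms and are shift-invariant", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(akaike_weights(42), 1)

  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(6, 150, 30)
    expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(a), akaike_weights(a + 777), tolerance = 1e-12)
  }
  # numerically stable for huge values
  expect_equal(akaike_weights(c(1e8, 1e8 + 2)), akaike_weights(c(0, 2)))
  expect_error(akaike_weights(numeric(0)))
})

test_that("AICc increases in K at fixed -2lnL and data size", {
  ks <- 1:20
  vals <- vapply(ks, function(k) aicc(100, k, 46), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("goodness-of-fit gate reproduces the qualitative pass/fail split", {
  sim <- simulate_population(synthetic_config(noise_fsd = 0), seed = 2)
  fit <- fit_population(sim$data, "f3aS4")

  # crafted uncertainty summaries on a real fit skeleton:
  # max CV 0.37 with top correlations (0.79, 0.81, 0.84) passes
  craft <- function(fit, cvs, r) {
    f <- fit
    f$parameters$cv <- rep_len(cvs, nrow(f$parameters))
    f$parameters$sd <- f$parameters$cv * abs(f$parameters$estimate)
    k <- nrow(f$correlation)
    cm <- diag(k)
    cm[lower.tri(cm)][seq_along(r)] <- r
    cm[upper.tri(cm)] <- t(cm)[upper.tri(cm)]
    f$correlation <- cm
    f
  }
  g_pass <- goodness_of_fit(craft(fit, 0.37, c(0.79, 0.81, 0.84)))
  expect_identical(g_pass$verdict, "pass")
  expect_equal(g_pass$cv_max, 0.37)
  expect_equal(g_pass$top_corr, c(0.84, 0.81, 0.79))

  # a correlation of 0.86 still passes; 0.92 fails
  expect_identical(goodness_of_fit(craft(fit, 0.3, c(0.80, 0.82, 0.86)))$verdict,
                   "pass")
  g_corr <- goodness_of_fit(craft(fit, 0.3, c(0.92, 0.95, 0.99)))
  expect_identical(g_corr$verdict, "fail")
  expect_true("correlation" %in% g_corr$reasons)

  # CV 0.6 violates CV < 0.5
  g_cv <- goodness_of_fit(craft(fit, 0.6, c(0.5, 0.5, 0.5)))
  expect_identical(g_cv$verdict, "fail")
  expect_true("cv" %in% g_cv$reasons)
})

test_that("shape gate rejects curves that go negative", {
  # f2c is negative for all t > 0 by construction
  df <- tibble::tibble(patient_id = "P1", time_h = c(2, 24, 60),
                       activity_pct_ia = c(8, 6, 3))
  fit <- fit_individual(df, "f2c")
  g <- goodness_of_fit(fit)
  expect_identical(g$verdict, "fail")
  expect_true("shape" %in% g$reasons)
})

test_that("IBMS on noise-free mono-exponential data selects f2b", {
  df <- noise_free_curve("f2b", c(A1 = 10, lambda1 = 0.02), nominal_sessions)
  sel <- select_models(df, mode = "IBMS")
  tab <- tidy(sel)
  expect_identical(unname(attr(sel, "best_model")["P1"]), "f2b")
  # shared-parameter models are excluded from individual-based selection
  expect_true(all(tab$excluded_reason[grepl("S", tab$model_id)] ==
                    "shared_parameter_model"))
  # f4 has 4 parameters: feasible on 5 points for fitting but K = 4 > N-2
  expect_identical(tab$excluded_reason[tab$model_id == "f4"],
                   "infeasible_K_exceeds_N_minus_2")
  # per-patient weights over the included subset sum to 1
  expect_equal(sum(tab$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("selection table bookkeeping: weights, deltas, exclusions", {
  sim <- simulate_population(seed = 9)
  sel <- select_models(sim$data, mode = "PBMS",
                       models = c("f2b", "f3a", "f3aS3", "f3aS4", "f4"))
  tab <- tidy(sel)
  expect_identical(tab$excluded_reason[tab$model_id == "f4"],
                   "infeasible_K_exceeds_N_minus_2")
  inc <- !is.na(tab$weight)
  expect_equal(sum(tab$weight[inc]), 1, tolerance = 1e-12)
  expect_equal(min(tab$delta[inc]), 0)
  expect_identical(sum(tab$delta[inc] == 0), 1L)
  expect_true(all(tab$K == count_parameters(tab$model_id[1], 13) |
                    tab$model_id != tab$model_id[1]))
  g <- glance(sel)
  expect_identical(g$mode, "PBMS")
  expect_identical(g$n_models, 5L)
})

test_that("a gate no model passes yields an empty supported set", {
  sim <- simulate_population(seed = 1)
  sel <- select_models(sim$data, mode = "PBMS", models = c("f2b", "f3aS4"),
                       gof = gof_control(cv_max = 1e-6))
  tab <- tidy(sel)
  expect_true(all(is.na(tab$weight)))
  expect_length(attr(sel, "supported_models"), 0)
  expect_true(all(grepl("gof_failed", tab$excluded_reason)))
})

test_that("jackknife reruns selection per left-out patient", {
  sim <- simulate_population(seed = 9)
  models <- c("f2b", "f3a", "f3aS3", "f3aS4", "f3aS6")
  jk <- jackknife_selection(sim$data, models = models)
  expect_identical(jk$n_replicates, 13L)
  expect_identical(nrow(jk$replicates), 13L * length(models))

  # each replicate's included weights sum to 1 (or 0 if nothing passed)
  sums <- tapply(jk$replicates$weight, jk$replicates$left_out, sum)
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))

  # removing a 5-point patient leaves N = 41 and K(f3aS4) = 25
  r <- jk$replicates[jk$replicates$left_out == "P01" &
                       jk$replicates$model_id == "f3aS4", ]
  expect_identical(r$N, 41L)
  expect_identical(r$K, 25L)

  s <- jk$summary
  expect_true(all(s$median >= s$min & s$median <= s$max))
})
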