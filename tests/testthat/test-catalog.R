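test_that("catalog holds the 20 models with their parameterizations", {
  cat20 <- model_catalog()
  expect_length(cat20, 20)
  expect_identical(
    names(cat20),
    c("f2a", "f2b", "f2c", "f2d", "f2e", "f3a", "f3b", "f3c", "f3d",
      "f2a3d", "f2b3d", "f2c3d", "f3aS1", "f3aS2", "f3aS3", "f3aS4",
      "f3aS5", "f3aS6", "f1", "f4"))

  m <- cat20$f3aS4
  expect_identical(m$per_patient_params, c("A1", "lambda1"))
  expect_identical(m$shared_param, "beta")
  expect_identical(cat20$f1$per_patient_params, "A1")
  expect_null(cat20$f1$shared_param)

  # S1-S6 share A1, lambda1, A2, beta, A1, lambda1 in that order
  shared <- vapply(cat20[paste0("f3aS", 1:6)], `[[`, "", "shared_param")
  expect_identical(unname(shared),
                   c("A1", "lambda1", "A2", "beta", "A1", "lambda1"))

  for (m in cat20) {
    expect_identical(m$params_per_patient, length(m$per_patient_params))
    expect_false(isTRUE(m$shared_param %in% m$per_patient_params))
    for (b in m$bounds) expect_gte(b[1], 0)
    if (!is.null(m$shared_param) && m$shared_param == "beta") {
      expect_identical(m$bounds$beta, c(0, 1))
    }
  }
})

test_that("model evaluation matches the functional forms", {
  expect_equal(evaluate_model("f2a", c(lambda1 = 0.05, lambda2 = 0.2), 0), 0)
  expect_equal(evaluate_model("f2e", c(A1 = 40, lambda1 = 0.1), 0), 100)

  # beta = 1 collapses f3aS4 onto the mono-exponential f2b
  expect_equal(
    evaluate_model("f3aS4", c(A1 = 10, lambda1 = 0.1, beta = 1), 5),
    evaluate_model("f2b", c(A1 = 10, lambda1 = 0.1), 5))

  # the f3d family carries the extra factor t on the first term
  d <- lu177()
  t <- 7
  expect_equal(
    evaluate_model("f2b3d", c(A1 = 3, lambda1 = 0.02), t),
    3 * t * exp(-(0.02 + d$lambda_phys) * t))

  expect_error(evaluate_model("f2b", c(A1 = 12), 1), "lambda1")
  expect_error(evaluate_model("f3aS4", c(A1 = 10, lambda1 = 0.1, beta = 1.2), 1),
               "bounds")
  expect_error(evaluate_model("f2b", c(A1 = -1, lambda1 = 0.1), 1), "bounds")
})

test_that("evaluation is continuous in t and parameters at interior points", {
  set.seed(42)
  for (id in c("f2a", "f3aS4", "f3d", "f4")) {
    p <- draw_params(id)
    t0 <- 10
    f0 <- evaluate_model(id, p, t0)
    expect_equal(evaluate_model(id, p, t0 + 1e-7), f0, tolerance = 1e-4)
    p2 <- p
    p2[1] <- p2[1] * (1 + 1e-8)
    expect_equal(evaluate_model(id, p2, t0), f0, tolerance = 1e-5)
  }
})

test_that("parameter counting follows K = p x n (+1 if shared)", {
  expect_identical(count_parameters("f2b", 13), 26L)
  expect_identical(count_parameters("f3aS4", 13), 27L)
  expect_identical(count_parameters("f4", 13), 52L)
  expect_identical(count_parameters("f1", 13), 13L)
  for (m in model_catalog()) {
    expect_identical(count_parameters(m, 1),
                     m$params_per_patient + as.integer(!is.null(m$shared_param)))
    # shared parameter adds exactly 1 regardless of population size
    expect_identical(count_parameters(m, 7) - 7L * m$params_per_patient,
                     as.integer(!is.null(m$shared_param)))
  }
})

test_that("closed-form TIAs match their analytic values", {
  d <- radionuclide(log(2) / 0.01)  # lambda_phys = 0.01 /h
  expect_equal(closed_form_tia("f1", c(A1 = 100), d), 10000)

  # beta = 1 reduces f3aS4 to A1/(lambda1 + lphys)
  d2 <- lu177()
  expect_equal(
    closed_form_tia("f3aS4", c(A1 = 10, lambda1 = 0.1, beta = 1), d2),
    10 / (0.1 + d2$lambda_phys))

  # f3d with A2 = 0 and total rate 0.5: A1/rate^2 = 4; cross-checked by
  # adaptive quadrature in the helper oracle
  d3 <- radionuclide(log(2) / 0.1)
  p3 <- c(A1 = 1, lambda1 = 0.4, A2 = 0)
  expect_equal(closed_form_tia("f3d", p3, d3), 4.0)
  expect_equal(quadrature_tia("f3d", p3, d3), 4.0, tolerance = 1e-8)

  expect_error(closed_form_tia("f2b", c(A1 = 1, lambda1 = 0), radionuclide(Inf)))
})

test_that("closed-form TIA agrees with quadrature across the catalog", {
  set.seed(7)
  for (id in names(model_catalog())) {
    for (r in 1:10) {
      p <- draw_params(id)
      expect_equal(closed_form_tia(id, p), quadrature_tia(id, p),
                   tolerance = 1e-8, label = sprintf("%s draw %d", id, r))
    }
  }
})

test_that("TIA is linear in amplitudes and decreasing in each rate", {
  set.seed(11)
  for (id in c("f2b", "f3a", "f3d", "f4", "f3aS4")) {
    p <- draw_params(id)
    base <- closed_form_tia(id, p)
    p2 <- p
    amps <- grepl("^A", names(p2))
    p2[amps] <- 2 * p2[amps]
    expect_equal(closed_form_tia(id, p2), 2 * base, tolerance = 1e-12)
    for (nm in names(p)[grepl("^lambda", names(p))]) {
      p3 <- p
      p3[nm] <- p3[nm] * 1.01
      expect_lt(closed_form_tia(id, p3), base)
    }
  }
})

test_that("radionuclide decay constant is ln(2)/half-life", {
  d <- radionuclide(159.528)
  expect_identical(d$lambda_phys, log(2) / 159.528)
  expect_error(radionuclide(-1))
})

test_that("catalog JSON dump lists every model with bounds and formulas", {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_catalog_json(path)
  dump <- jsonlite::read_json(path)
  expect_length(dump, 20)
  expect_identical(dump$f3aS4$shared_param, "beta")
  expect_equal(unlist(dump$f3aS4$bounds$beta), c(0, 1))
})
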