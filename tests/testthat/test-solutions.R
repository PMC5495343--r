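# Closed-form solution catalog and the residual verifier.

all_ids <- c("scheme_01", "scheme_02", "scheme_03", "scheme_04",
             "tumor_full", "tumor_reduced")

test_that("structural differentiation matches hand derivatives", {
  sol <- closed_form_solution(
    entries = list(A = list(expr = quote(A0 * exp(-k1 * t)), kind = "value"),
                   K = list(expr = quote(A0 + k1), kind = "value")),
    params = list(A0 = 1, k1 = 2))
  d <- differentiate_solutions(sol, 0)
  expect_equal(d[["A"]], -2)
  expect_equal(d[["K"]], 0)
  d1 <- differentiate_solutions(sol, 1.5)
  expect_equal(d1[["A"]], -2 * exp(-3))
})

test_that("derivative-only entries evaluate at the reconstructed state", {
  p <- as.list(setNames(c(0.9, 0.4, 0.2, 0.5, 0.3, 0.25, 0.15, 0.1), paste0("k", 1:8)))
  sol <- scheme_solution("tumor_full", p)
  d0 <- differentiate_solutions(sol, 0)
  # at t = 0: CSC = 1, P = D = 0, so dM/dt = k6
  expect_equal(d0[["M"]], p$k6)
  expect_error(
    differentiate_solutions(
      closed_form_solution(list(A = list(expr = quote(k_missing * t), kind = "value")),
                           params = list()), 1),
    class = "unbound_parameter")
})

test_that("the scheme-1 closed form takes its textbook values", {
  sol <- scheme_solution("scheme_01", list(A0 = 1, k1 = 1, k2 = 2))
  s0 <- solution_state(sol, 0)
  expect_equal(unname(s0), c(1, 0, 0))
  s1 <- solution_state(sol, 1)
  expect_equal(s1[["A"]], exp(-1))
  expect_equal(s1[["B"]], exp(-1) - exp(-2))
  expect_equal(s1[["C"]], 1 - 2 * exp(-1) + exp(-2))
})

test_that("all cataloged solutions satisfy their rate equations", {
  for (id in all_ids) {
    for (seed in 1:10) {
      p <- random_scheme_params(seed, id)
      rep <- verify_solution(build_scheme(id, p), scheme_solution(id, p))
      expect_true(rep$pass, info = sprintf("%s seed %d", id, seed))
      expect_lte(max(rep$max_abs_residual), 1e-8)
    }
  }
})

test_that("singular parameters are rejected before verification", {
  expect_error(scheme_solution("scheme_01", list(A0 = 1, k1 = 2, k2 = 2)),
               class = "singular_parameters")
  expect_error(scheme_solution("tumor_reduced", list(k1 = 1, k2 = 0.7, k3 = 0.7)),
               class = "singular_parameters")
  # r1, r2 supplied explicitly must satisfy their defining constraints
  p <- random_scheme_params(1, "scheme_03")
  bad <- p; bad$r1 <- bad$r1 * 1.5
  expect_error(scheme_solution("scheme_03", bad), class = "singular_parameters")
  ok <- scheme_solution("scheme_03", p)
  expect_s3_class(ok, "closed_form_solution")
})

test_that("a 1% perturbation of any species is detected by the verifier", {
  for (id in all_ids) {
    p <- random_scheme_params(5, id)
    sol <- scheme_solution(id, p)
    model <- build_scheme(id, p)
    for (sp in names(sol$entries)) {
      rep <- verify_solution(model, perturb_solution(sol, sp, 1.01))
      expect_false(rep$pass, info = sprintf("%s / %s", id, sp))
    }
  }
})

test_that("mass is conserved in the closed forms of all four schemes", {
  for (id in c("scheme_01", "scheme_02", "scheme_03", "scheme_04")) {
    # every reaction converts one molecule into one molecule
    expect_true(all(rowSums(stoich_matrix(
      build_scheme(id, list(k1 = 1, k2 = 2, k3 = 0.5)))) == 0))
    for (seed in 1:5) {
      p <- random_scheme_params(seed, id)
      sol <- scheme_solution(id, p)
      tot <- vapply(default_time_grid(), function(tt)
        sum(solution_state(sol, tt)), numeric(1))
      expect_equal(tot, rep(p$A0, length(tot)), tolerance = 1e-12)
    }
  }
})

test_that("simulation agrees with the closed forms for every model", {
  for (id in all_ids) {
    for (seed in 1:3) {
      p <- random_scheme_params(seed, id)
      sol <- scheme_solution(id, p)
      model <- build_scheme(id, p)
      init <- pmax(solution_state(sol, 0), 0)  # clamp -1e-17 cancellation noise
      times <- c(0, 10^seq(-2, log10(5), length.out = 12))
      tr <- simulate_model(model, init, times = times, rtol = 1e-9, atol = 1e-12)
      living <- names(sol$entries)[vapply(sol$entries, function(e)
        e$kind == "value", logical(1))]
      ref <- t(vapply(times, function(tt) solution_state(sol, tt)[living],
                      numeric(length(living))))
      expect_equal(as.matrix(tr[, living]), ref, tolerance = 1e-6,
                   ignore_attr = TRUE, info = sprintf("%s seed %d", id, seed))
    }
  }
})

test_that("parameter draws are deterministic and respect the assumptions", {
  for (id in all_ids) {
    expect_identical(random_scheme_params(3, id), random_scheme_params(3, id))
    p <- random_scheme_params(3, id)
    sol <- scheme_solution(id, p)
    expect_true(all(check_assumptions(sol)))
  }
  p <- random_scheme_params(0, "scheme_01")
  expect_true(abs(p$k2 - p$k1) > 0)
})
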