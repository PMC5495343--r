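# Mass-action fluxes, stoichiometric matrices and assembly of the rate
# equations.

test_that("the mass-action product follows the law of mass action", {
  expect_identical(mass_action_product(numeric(0), numeric(0)), 1)
  expect_identical(mass_action_product(c(1, 0), c(2, 99)), 2)
  expect_identical(mass_action_product(c(2, 1), c(3, 4)), 36)
  expect_error(mass_action_product(c(1, 1), 1), class = "species_mismatch")
})

test_that("mass-action products are multiplicative over concatenation", {
  set.seed(7)
  for (i in 1:25) {
    n1 <- sample(0:4, 1); n2 <- sample(0:4, 1)
    s1 <- sample(0:3, n1, replace = TRUE); c1 <- runif(n1, 0.1, 3)
    s2 <- sample(0:3, n2, replace = TRUE); c2 <- runif(n2, 0.1, 3)
    expect_equal(mass_action_product(c(s1, s2), c(c1, c2)),
                 mass_action_product(s1, c1) * mass_action_product(s2, c2))
  }
})

test_that("irreversible and reversible fluxes combine rate and product", {
  expect_equal(flux_irreversible(1, 1, conc = 2, kf = 0.5), 1)
  expect_equal(flux_irreversible(c(0, 0), c(1, 0), conc = c(5, 5), kf = 3), 3)
  expect_equal(flux_irreversible(1, 1, conc = 3, kf = 0), 0)
  expect_equal(flux_reversible(c(1, 0), c(0, 1), conc = c(3, 4), kf = 2, kr = 1), 2)
  expect_equal(flux_reversible(c(1, 0), c(0, 1), conc = c(2, 2), kf = 5, kr = 5), 0)
  expect_error(flux_irreversible(1, 1, conc = 1, kf = -1), class = "negative_rate")
})

test_that("single-reaction flux dispatches on the reaction kind", {
  m <- kinetic_model(c("A", "B", "C"), list(
    reaction("irreversible", c(A = 1), c(B = 1), kf = 1),
    reaction("reversible", c(B = 1), c(C = 1), kf = 2, kr = 3)))
  expect_equal(reaction_flux(m$reactions[[1]], c(1, 0, 0)), 1)
  expect_equal(reaction_flux(m$reactions[[2]], c(0, 1, 0)), 2)
  expect_error(reaction("irreversible", c(A = 1), c(B = 1), kf = 1, kr = 2),
               class = "invalid_reaction")
})

test_that("flux vectors follow the scheme reaction lists", {
  s1 <- build_scheme("scheme_01", list(k1 = 0.5, k2 = 2))
  expect_equal(flux_vector(s1, c(A = 3, B = 4, C = 5)), c(0.5 * 3, 2 * 4))
  tr <- build_scheme("tumor_reduced", list(k1 = 1, k2 = 0.5, k3 = 2))
  expect_equal(flux_vector(tr, c(CSC = 2, P = 3, M = 0)),
               c(1 * 2, 0.5 * 2, 2 * 3))
})

test_that("stoichiometry columns are net production s' - s", {
  expect_equal(stoich_column(c(1, 0, 0), c(0, 1, 0)), c(-1, 1, 0))
  expect_equal(stoich_column(c(1, 0, 0, 0), c(2, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(stoich_column(c(1, 2), c(1, 2)), c(0, 0))
  expect_error(stoich_column(c(1, 0), 1), class = "species_mismatch")
})

test_that("stoichiometric matrices are stored reaction-major", {
  s1 <- build_scheme("scheme_01", list(k1 = 1, k2 = 2))
  expect_equal(unname(stoich_matrix(s1)),
               rbind(c(-1, 1, 0), c(0, -1, 1)))
  tr <- build_scheme("tumor_reduced", list(k1 = 1, k2 = 0.5, k3 = 2))
  expect_equal(unname(stoich_matrix(tr)),
               rbind(c(0, 1, 0), c(-1, 0, 1), c(0, -1, 1)))
  loop <- kinetic_model("X", list(reaction("irreversible", c(X = 1), c(X = 1), 1)))
  expect_equal(unname(stoich_matrix(loop)), rbind(0))
})

test_that("the assembled right-hand side is transpose(N storage) times flux", {
  s1 <- build_scheme("scheme_01", list(k1 = 1, k2 = 2))
  st <- c(A = 0.7, B = 0.2, C = 0.1)
  expect_equal(ode_rhs(s1, st),
               c(A = -0.7, B = 0.7 - 2 * 0.2, C = 2 * 0.2))
  tr <- build_scheme("tumor_reduced", list(k1 = 1, k2 = 0.5, k3 = 2))
  st <- c(CSC = 2, P = 3, M = 0)
  expect_equal(ode_rhs(tr, st),
               c(CSC = -0.5 * 2, P = 1 * 2 - 2 * 3, M = 0.5 * 2 + 2 * 3))
  expect_equal(unname(ode_rhs(s1, c(0, 0, 0))), c(0, 0, 0))
  expect_error(ode_rhs(s1, c(1, 0)), class = "species_mismatch")
})

test_that("the rhs is linear in the rate constants for irreversible models", {
  set.seed(3)
  for (i in 1:10) {
    k <- as.list(setNames(runif(8, 0.1, 2), paste0("k", 1:8)))
    st <- runif(4, 0, 2)
    m1 <- build_scheme("tumor_full", k)
    m2 <- build_scheme("tumor_full", lapply(k, `*`, 2.5))
    expect_equal(unname(ode_rhs(m2, st)), 2.5 * unname(ode_rhs(m1, st)))
  }
})

test_that("simulation reproduces the scheme-1 closed forms", {
  p <- list(A0 = 1, k1 = 1, k2 = 2)
  m <- build_scheme("scheme_01", p)
  sol <- scheme_solution("scheme_01", p)
  tr <- simulate_model(m, c(A = 1, B = 0, C = 0), t_max = 8, n_out = 33)
  ref <- t(vapply(tr$t, function(tt) solution_state(sol, tt), numeric(3)))
  expect_equal(as.matrix(tr[, c("A", "B", "C")]), ref,
               tolerance = 1e-6, ignore_attr = TRUE)
  # conservation along the trajectory
  expect_equal(tr$A + tr$B + tr$C, rep(1, nrow(tr)), tolerance = 1e-8)
  # zero initial state stays identically zero
  z <- simulate_model(m, c(A = 0, B = 0, C = 0), t_max = 5, n_out = 6)
  expect_equal(unname(as.matrix(z[, -1])), matrix(0, 6, 3))
})
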