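# Catalog of concrete models: four generic consecutive-reaction schemes with
# their analytic solutions, two cancer-stem-cell (CSC) tumor growth
# compartment models, the TP53 phosphorylation and CSC-death deduction
# fixtures, and the seeded random generators used by the property tests.
#
# Tumor compartments: CSC (cancer stem cells), P (progenitor cells),
# D (terminally differentiated cells), M (dead cells). The full model has
# eight first-order events (symmetric/asymmetric division, differentiation,
# death); the reduced model keeps asymmetric division and death only.

scheme_ids <- c("scheme_01", "scheme_02", "scheme_03", "scheme_04",
                "tumor_full", "tumor_reduced")

#' Species of a cataloged scheme
#'
#' @param id One of `"scheme_01"`..`"scheme_04"` (species A, B, C),
#'   `"tumor_full"` (CSC, P, D, M) or `"tumor_reduced"` (CSC, P, M).
#' @return Character vector of species names in catalog order.
#' @export
scheme_species <- function(id) {
  switch(match_scheme(id),
         scheme_01 = ,
         scheme_02 = ,
         scheme_03 = ,
         scheme_04 = c("A", "B", "C"),
         tumor_full = c("CSC", "P", "D", "M"),
         tumor_reduced = c("CSC", "P", "M"))
}

match_scheme <- function(id) {
  if (!is.character(id) || length(id) != 1L || !id %in% scheme_ids)
    zk_stop("unknown_scheme",
            sprintf("unknown scheme id %s (known: %s)",
                    deparse(id), paste(scheme_ids, collapse = ", ")))
  id
}

#' Build a cataloged kinetic model
#'
#' Returns the exact reaction list of the scheme:
#' * `scheme_01`: A -> B (k1), B -> C (k2), both irreversible.
#' * `scheme_02`: A -> B (k1); B <=> C (k2 forward, k3 reverse).
#' * `scheme_03`: A <=> B (k1, k2); B -> C (k3).
#' * `scheme_04`: A <=> B (k1, k2); A -> C (k3).
#' * `tumor_full`: CSC -> 2 CSC (k1), CSC -> CSC + P (k2), CSC -> 2 P (k3),
#'   P -> 2 P (k4), P -> D (k5), CSC -> M (k6), P -> M (k7), D -> M (k8).
#' * `tumor_reduced`: CSC -> CSC + P (k1), CSC -> M (k2), P -> M (k3).
#'
#' @param id Scheme identifier (see [scheme_species()]).
#' @param params Named list of positive rate constants (`k1`, `k2`, ... as
#'   the scheme requires; `A0` is ignored here — it only scales solutions).
#' @return A [kinetic_model()].
#' @examples
#' build_scheme("tumor_reduced", list(k1 = 1, k2 = 0.5, k3 = 2))
#' @export
build_scheme <- function(id, params) {
  id <- match_scheme(id)
  p <- as.list(params)
  need <- function(...) {
    miss <- setdiff(c(...), names(p))
    if (length(miss))
      zk_stop("unbound_parameter",
              sprintf("missing rate constants for %s: %s", id, paste(miss, collapse = ", ")))
  }
  irr <- function(r, pr, k) reaction("irreversible", r, pr, kf = k)
  rxns <- switch(id,
    scheme_01 = {
      need("k1", "k2")
      list(irr(c(A = 1), c(B = 1), p$k1),
           irr(c(B = 1), c(C = 1), p$k2))
    },
    scheme_02 = {
      need("k1", "k2", "k3")
      list(irr(c(A = 1), c(B = 1), p$k1),
           reaction("reversible", c(B = 1), c(C = 1), kf = p$k2, kr = p$k3))
    },
    scheme_03 = {
      need("k1", "k2", "k3")
      list(reaction("reversible", c(A = 1), c(B = 1), kf = p$k1, kr = p$k2),
           irr(c(B = 1), c(C = 1), p$k3))
    },
    scheme_04 = {
      need("k1", "k2", "k3")
      list(reaction("reversible", c(A = 1), c(B = 1), kf = p$k1, kr = p$k2),
           irr(c(A = 1), c(C = 1), p$k3))
    },
    tumor_full = {
      need(paste0("k", 1:8))
      list(irr(c(CSC = 1), c(CSC = 2), p$k1),
           irr(c(CSC = 1), c(CSC = 1, P = 1), p$k2),
           irr(c(CSC = 1), c(P = 2), p$k3),
           irr(c(P = 1), c(P = 2), p$k4),
           irr(c(P = 1), c(D = 1), p$k5),
           irr(c(CSC = 1), c(M = 1), p$k6),
           irr(c(P = 1), c(M = 1), p$k7),
           irr(c(D = 1), c(M = 1), p$k8))
    },
    tumor_reduced = {
      need("k1", "k2", "k3")
      list(irr(c(CSC = 1), c(CSC = 1, P = 1), p$k1),
           irr(c(CSC = 1), c(M = 1), p$k2),
           irr(c(P = 1), c(M = 1), p$k3))
    })
  kinetic_model(scheme_species(id), rxns)
}

#' Auxiliary exponents r1, r2 of schemes 2-4
#'
#' Scheme 2 uses `r1 = k1`, `r2 = k2 + k3`. Schemes 3 and 4 use the roots of
#' `r^2 - (k1 + k2 + k3) r + q = 0` with `q = k1 k3` (scheme 3) or
#' `q = k2 k3` (scheme 4); the tie-break is `r1 < r2`. For positive rate
#' constants the discriminant `(k1 - k3)^2 + k2^2 + 2 k2 (k1 + k3)` (scheme
#' 3) is strictly positive, so the roots are always real and distinct.
#'
#' @param id Scheme identifier (`scheme_02`, `scheme_03` or `scheme_04`).
#' @param params Named list with the scheme's rate constants.
#' @return Named numeric vector `c(r1, r2)`.
#' @export
rate_roots <- function(id, params) {
  id <- match_scheme(id)
  p <- as.list(params)
  if (id == "scheme_02") return(c(r1 = p$k1, r2 = p$k2 + p$k3))
  if (!id %in% c("scheme_03", "scheme_04"))
    zk_stop("unknown_scheme", sprintf("%s has no auxiliary exponents", id))
  s <- p$k1 + p$k2 + p$k3
  q <- if (id == "scheme_03") p$k1 * p$k3 else p$k2 * p$k3
  disc <- s^2 - 4 * q
  if (disc < 0) zk_stop("singular_parameters", "complex auxiliary exponents")
  r <- sort((s + c(-1, 1) * sqrt(disc)) / 2)
  c(r1 = r[1L], r2 = r[2L])
}

# near-singularity guard: |denominator| must exceed eps times the parameter scale
ns <- 1e-6

scheme_assumption_set <- function(id) {
  pos <- function(ks) {
    a <- lapply(ks, function(k) bquote(.(as.name(k)) > 0))
    names(a) <- paste0(ks, "_positive")
    a
  }
  switch(id,
    scheme_01 = c(pos(c("k1", "k2")),
      list(k2_minus_k1_nonzero = bquote(abs(k2 - k1) > .(ns) * max(k1, k2)))),
    scheme_02 = c(pos(c("k1", "k2", "k3")),
      list(r1_ne_r2 = bquote(abs(r1 - r2) > .(ns) * max(r1, r2)))),
    scheme_03 = ,
    scheme_04 = c(pos(c("k1", "k2", "k3")),
      list(r1_nonzero = bquote(abs(r1) > .(ns)),
           r2_nonzero = bquote(abs(r2) > .(ns)),
           r1_ne_r2 = bquote(abs(r1 - r2) > .(ns) * max(r1, r2)))),
    tumor_full = list(
      growth_exponents_distinct = bquote(
        abs((k1 - k3 - k6) - (k4 - k5 - k7)) > .(ns) * max(k1, k2, k3, k4, k5, k6, k7, k8)),
      csc_death_denominator = bquote(
        abs(k1 - k3 - k6 + k8) > .(ns) * max(k1, k2, k3, k4, k5, k6, k7, k8)),
      progenitor_death_denominator = bquote(
        abs(k4 - k5 - k7 + k8) > .(ns) * max(k1, k2, k3, k4, k5, k6, k7, k8))),
    tumor_reduced = list(
      k3_minus_k2_nonzero = bquote(abs(k3 - k2) > .(ns) * max(k1, k2, k3))))
}

#' Closed-form solution of a cataloged scheme
#'
#' Returns the analytic time courses as expression trees with the given
#' parameters bound, together with the validity assumptions
#' (positive rates, non-singular denominators). For the generic schemes the
#' initial state is `A(0) = A0`, `B(0) = C(0) = 0`. For the tumor models
#' `CSC(0) = 1` (unit normalization) and the dead-cell compartment M is a
#' derivative-only entry, `dM/dt` given directly in terms of the living
#' compartments. Auxiliary exponents `r1`, `r2` (schemes 2-4) are taken from
#' `params` if present — after validation against their defining constraints
#' — and computed with [rate_roots()] otherwise.
#'
#' @param id Scheme identifier.
#' @param params Named list: rate constants, `A0` for the generic schemes,
#'   optionally `r1`/`r2`.
#' @return A [closed_form_solution()]. Errors with class
#'   `singular_parameters` if any validity assumption fails.
#' @examples
#' sol <- scheme_solution("scheme_01", list(A0 = 1, k1 = 1, k2 = 2))
#' solution_state(sol, 1)
#' @export
scheme_solution <- function(id, params) {
  id <- match_scheme(id)
  p <- as.list(params)
  if (id %in% c("scheme_02", "scheme_03", "scheme_04")) {
    rr <- rate_roots(id, p)
    if (!is.null(p$r1) || !is.null(p$r2)) {
      if (is.null(p$r1) || is.null(p$r2))
        zk_stop("singular_parameters", "r1 and r2 must be supplied together")
      given <- c(r1 = p$r1, r2 = p$r2)
      want <- if (id == "scheme_02") rr else {
        s <- p$k1 + p$k2 + p$k3
        q <- if (id == "scheme_03") p$k1 * p$k3 else p$k2 * p$k3
        if (abs(given[["r1"]] * given[["r2"]] - q) > 1e-8 * max(1, q) ||
            abs(given[["r1"]] + given[["r2"]] - s) > 1e-8 * max(1, s))
          zk_stop("singular_parameters",
                  "supplied r1, r2 do not satisfy their defining constraints")
        given
      }
      if (id == "scheme_02" &&
          (abs(given[["r1"]] - rr[["r1"]]) > 1e-8 * max(1, rr[["r1"]]) ||
           abs(given[["r2"]] - rr[["r2"]]) > 1e-8 * max(1, rr[["r2"]])))
        zk_stop("singular_parameters",
                "supplied r1, r2 do not satisfy r1 = k1, r2 = k2 + k3")
      p$r1 <- want[["r1"]]; p$r2 <- want[["r2"]]
    } else {
      p$r1 <- rr[["r1"]]; p$r2 <- rr[["r2"]]
    }
  }
  if (id %in% c("scheme_01", "scheme_02", "scheme_03", "scheme_04") && is.null(p$A0))
    zk_stop("unbound_parameter", "A0 (initial amount of species A) is required")
  val <- function(e) list(expr = e, kind = "value")
  der <- function(e) list(expr = e, kind = "derivative")
  entries <- switch(id,
    scheme_01 = list(
      A = val(quote(A0 * exp(-k1 * t))),
      B = val(quote(A0 * k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t)))),
      C = val(quote(A0 * (1 - k2 / (k2 - k1) * exp(-k1 * t) -
                            k1 / (k1 - k2) * exp(-k2 * t))))),
    scheme_02 = list(
      A = val(quote(A0 * exp(-k1 * t))),
      B = val(quote(k1 * A0 * (k3 / (r1 * r2) +
                               (k3 - r1) / (r1 * (r1 - r2)) * exp(-r1 * t) +
                               (r2 - k3) / (r2 * (r1 - r2)) * exp(-r2 * t)))),
      C = val(quote(k1 * k2 * A0 * (1 / (r1 * r2) +
                                    1 / (r1 * (r1 - r2)) * exp(-r1 * t) -
                                    1 / (r2 * (r1 - r2)) * exp(-r2 * t))))),
    scheme_03 = list(
      A = val(quote(A0 / (r2 - r1) * ((k2 + k3 - r1) * exp(-r1 * t) -
                                      (k2 + k3 - r2) * exp(-r2 * t)))),
      B = val(quote(A0 * k1 / (r2 - r1) * (exp(-r1 * t) - exp(-r2 * t)))),
      C = val(quote(A0 * (1 + k1 * k3 / (r1 * (r1 - r2)) * exp(-r1 * t) +
                              k1 * k3 / (r2 * (r2 - r1)) * exp(-r2 * t))))),
    scheme_04 = list(
      A = val(quote(A0 * ((k2 - r1) / (r2 - r1) * exp(-r1 * t) -
                          (k2 - r2) / (r2 - r1) * exp(-r2 * t)))),
      B = val(quote(k1 * A0 / (r2 - r1) * (exp(-r1 * t) - exp(-r2 * t)))),
      C = val(quote(A0 * (1 + k3 * (k2 - r1) / (r1 * (r1 - r2)) * exp(-r1 * t) +
                              k3 * (k2 - r2) / (r2 * (r2 - r1)) * exp(-r2 * t))))),
    tumor_full = list(
      CSC = val(quote(exp((k1 - k3 - k6) * t))),
      P = val(quote((exp((k1 - k3 - k6) * t) - exp((k4 - k5 - k7) * t)) *
                      (k2 + 2 * k3) / (k1 - k3 - k4 + k5 - k6 + k7))),
      D = val(quote(k5 * (k2 + 2 * k3) / (k1 - k3 - k4 + k5 - k6 + k7) *
                      ((exp((k1 - k3 - k6) * t) - exp(-k8 * t)) / (k1 - k3 - k6 + k8) -
                       (exp((k4 - k5 - k7) * t) - exp(-k8 * t)) / (k4 - k5 - k7 + k8)))),
      M = der(quote(k6 * CSC + k7 * P + k8 * D))),
    tumor_reduced = list(
      CSC = val(quote(exp(-k2 * t))),
      P = val(quote(((k3 - k2 - k1) * exp(-k3 * t) + k1 * exp(-k2 * t)) / (k3 - k2))),
      M = der(quote(k2 * CSC + k3 * P))))
  sol <- closed_form_solution(entries, p, scheme_assumption_set(id))
  checks <- check_assumptions(sol)
  if (!all(checks))
    zk_stop("singular_parameters",
            sprintf("scheme assumptions violated: %s",
                    paste(names(checks)[!checks], collapse = ", ")))
  sol
}

#' Total living tumor cell count N(t)
#'
#' Sums the value entries of a tumor solution at time `t`:
#' `N(t) = CSC(t) + P(t) + D(t)` for the full model,
#' `N(t) = CSC(t) + P(t)` for the reduced model. The dead-cell compartment M
#' (derivative-only) is excluded.
#'
#' @param sol A [closed_form_solution()] for a tumor model.
#' @param t Time (>= 0).
#' @return A number, the total count of living cells.
#' @export
total_cells <- function(sol, t) {
  if (t < 0) zk_stop("invalid_time", "t must be >= 0")
  state <- solution_state(sol, t)
  living <- vapply(sol$entries, function(e) e$kind == "value", logical(1))
  sum(state[living])
}

#' Tumor volume from a cell count
#'
#' Linear scaling by the effective volume of a spherically shaped cell in a
#' spherical tumor, 4.18e-6 mm^3 per cell by default.
#'
#' @param n_cells Non-negative cell count.
#' @param per_cell Per-cell volume in mm^3.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(1e6)  # 4.18 mm^3
#' @export
tumor_volume <- function(n_cells, per_cell = 4.18e-6) {
  if (any(n_cells < 0)) zk_stop("negative_count", "cell counts must be non-negative")
  n_cells * per_cell
}

#' TP53 phosphorylation deduction fixture
#'
#' The pathway from TP53 to phosphorylated TP53: initial aggregate
#' `[[TP53],[ATP],[Kinase]]`, EVFs `[Kinase,ATP] -> [[ATP,Kinase]]` and
#' `[ATP,Kinase,TP53] -> [[Kinase],[pTP53],[ADP]]`, target `[pTP53]`.
#'
#' @return A [zsyntax_problem()].
#' @examples
#' zs_deduce_check(tp53_fixture())
#' @export
tp53_fixture <- function() {
  zsyntax_problem(
    initial = list("TP53", "ATP", "Kinase"),
    evfs = list(
      evf(c("Kinase", "ATP"), list(c("ATP", "Kinase"))),
      evf(c("ATP", "Kinase", "TP53"), list("Kinase", "pTP53", "ADP"))),
    target = "pTP53",
    molecules = c("TP53", "ATP", "Kinase", "ADP", "pTP53"))
}

#' CSC-death deduction fixture
#'
#' The pathway from a cancer stem cell to its death: initial aggregate
#' `[[CSC],[P]]`, EVFs `[CSC] -> [[CSC,P]]` and `[CSC,P] -> [[M]]`, target
#' `[M]`.
#'
#' @return A [zsyntax_problem()].
#' @examples
#' zs_deduce_check(csc_death_fixture())
#' @export
csc_death_fixture <- function() {
  zsyntax_problem(
    initial = list("CSC", "P"),
    evfs = list(
      evf("CSC", list(c("CSC", "P"))),
      evf(c("CSC", "P"), list("M"))),
    target = "M",
    molecules = c("CSC", "P", "M"))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

pair_concats <- function(agg) {
  keys <- character(0)
  for (x in seq_along(agg)) for (y in seq_along(agg))
    keys <- c(keys, paste(c(agg[[x]], agg[[y]]), collapse = "\x1f"))
  unique(keys)
}

#' Seeded random Zsyntax instance generator
#'
#' Generates deterministic small deduction problems for property tests.
#' Modes:
#' * `no_reaction`: no EVF reactant equals any pair-concatenation of the
#'   initial aggregate (including self-pairs), so deduction is the identity.
#' * `single_reaction`: exactly one index pair `(x, y)`, `x != y`, matches
#'   exactly one EVF `z`; all molecules of the aggregate and of that EVF's
#'   products are distinct, so deduction performs exactly that one firing.
#'   The firing coordinates are attached as attribute `"law"`
#'   (`list(x, y, z)`, 0-based).
#' * `free`: unconstrained; EVF reactants are biased toward
#'   pair-concatenations of the initial aggregate so that firings happen.
#'
#' @param seed Integer seed (the generator restores the RNG state on exit).
#' @param n_molecules Alphabet size (<= 8).
#' @param n_initial Initial aggregate length (<= 6; >= 2 for
#'   `single_reaction`).
#' @param n_evfs Number of EVFs (<= 4).
#' @param mode One of `"no_reaction"`, `"single_reaction"`, `"free"`.
#' @return A [zsyntax_problem()].
#' @export
random_zsyntax_instance <- function(seed, n_molecules = 6L, n_initial = 4L,
                                    n_evfs = 3L,
                                    mode = c("no_reaction", "single_reaction", "free")) {
  mode <- match.arg(mode)
  if (n_molecules > 8L || n_initial > 6L || n_evfs > 4L)
    zk_stop("generation_failed", "instance sizes exceed the test scale")
  if (mode == "single_reaction" && n_initial < 2L)
    zk_stop("generation_failed", "single_reaction mode needs at least two initial interactions")
  with_seed(seed, {
    mols <- paste0("m", seq_len(n_molecules))
    if (mode == "single_reaction") {
      if (n_initial + 2L > n_molecules)
        zk_stop("generation_failed",
                "single_reaction mode needs n_molecules >= n_initial + 2 for fresh products")
      picked <- sample(mols, n_initial + 2L)
      initial <- as.list(picked[seq_len(n_initial)])
      fresh <- picked[n_initial + 1:2]
      xy <- sample(seq_len(n_initial) - 1L, 2L)
      z <- sample(seq_len(n_evfs) - 1L, 1L)
      evfs <- vector("list", n_evfs)
      evfs[[z + 1L]] <- evf(c(initial[[xy[1L] + 1L]], initial[[xy[2L] + 1L]]),
                            as.list(fresh[seq_len(sample(2L, 1L))]))
      seen <- character(0)
      for (j in seq_len(n_evfs)) {
        if (j == z + 1L) next
        for (try in seq_len(1000L)) {
          # length-3 reactants can never equal a concatenation of two singletons
          r <- sample(mols, 3L, replace = TRUE)
          key <- paste(r, collapse = "\x1f")
          if (!key %in% seen) { seen <- c(seen, key); break }
          if (try == 1000L) zk_stop("generation_failed", "could not draw distinct EVF reactants")
        }
        evfs[[j]] <- evf(r, list(sample(mols, 1L)))
      }
      prob <- zsyntax_problem(initial, evfs, molecules = mols)
      attr(prob, "law") <- list(x = xy[1L], y = xy[2L], z = z)
      return(prob)
    }
    initial <- replicate(n_initial,
                         sample(mols, sample(2L, 1L), replace = TRUE),
                         simplify = FALSE)
    if (mode == "no_reaction") {
      banned <- pair_concats(initial)
      evfs <- lapply(seq_len(n_evfs), function(j) {
        for (try in seq_len(1000L)) {
          r <- sample(mols, sample(3L, 1L), replace = TRUE)
          if (!paste(r, collapse = "\x1f") %in% banned)
            return(evf(r, replicate(sample(2L, 1L),
                                    sample(mols, sample(2L, 1L), replace = TRUE),
                                    simplify = FALSE)))
        }
        zk_stop("generation_failed", "could not draw a non-matching EVF reactant")
      })
      return(zsyntax_problem(initial, evfs, molecules = mols))
    }
    # free mode: bias reactants toward pair-concatenations so firings occur;
    # single-interaction products keep every firing strictly contracting, so
    # deduction terminates and stays within the oracle's enumeration depth
    evfs <- lapply(seq_len(n_evfs), function(j) {
      r <- if (stats::runif(1) < 0.7) {
        xy <- sample(seq_len(n_initial), 2L, replace = TRUE)
        c(initial[[xy[1L]]], initial[[xy[2L]]])
      } else {
        sample(mols, sample(2L, 1L), replace = TRUE)
      }
      evf(r, list(sample(mols, sample(2L, 1L), replace = TRUE)))
    })
    zsyntax_problem(initial, evfs, molecules = mols)
  })
}

#' Seeded random scheme parameters
#'
#' Draws every rate constant (and `A0` for the generic schemes) log-uniformly
#' from `[1e-2, 1e1]`, rejecting draws that violate the scheme's validity
#' assumptions (up to 1000 resamples). Deterministic in `seed`.
#'
#' @param seed Integer seed.
#' @param id Scheme identifier.
#' @return Named list of parameters (including `r1`, `r2` for schemes 2-4).
#' @export
random_scheme_params <- function(seed, id) {
  id <- match_scheme(id)
  ks <- switch(id,
               scheme_01 = c("k1", "k2"),
               scheme_02 = ,
               scheme_03 = ,
               scheme_04 = c("k1", "k2", "k3"),
               tumor_full = paste0("k", 1:8),
               tumor_reduced = c("k1", "k2", "k3"))
  with_seed(seed, {
    for (try in seq_len(1000L)) {
      p <- as.list(stats::setNames(10 ^ stats::runif(length(ks), -2, 1), ks))
      if (!id %in% c("tumor_full", "tumor_reduced"))
        p$A0 <- 10 ^ stats::runif(1, -2, 1)
      ok <- tryCatch({
        sol <- scheme_solution(id, p)
        TRUE
      }, singular_parameters = function(e) FALSE)
      if (ok) {
        if (id %in% c("scheme_02", "scheme_03", "scheme_04")) {
          rr <- rate_roots(id, p)
          p$r1 <- rr[["r1"]]; p$r2 <- rr[["r2"]]
        }
        return(p)
      }
    }
    zk_stop("generation_failed", "rejection budget exhausted drawing scheme parameters")
  })
}
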