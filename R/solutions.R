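# Closed-form solutions and their verification against the rate equations.
#
# A closed-form solution stores, per species, either a time expression for
# the concentration (an R language object over the bound parameters and the
# time symbol `t`) or a derivative-only expression giving d[X]/dt directly
# (used for terminal compartments such as dead cells, whose concentration
# never feeds back into any flux). Value entries are differentiated
# structurally with stats::D; derivative entries may reference the other
# species by name and are evaluated at the reconstructed state. The verifier
# compares the differentiated solution with the assembled right-hand side
# N v on a time grid and reports the worst scaled residual per species.

#' Construct a closed-form solution
#'
#' @param entries Named list (one entry per species, in model species order).
#'   Each entry is a list with `expr` (a quoted R expression in `t`, the
#'   bound parameters, and — for derivative entries — the species names) and
#'   `kind`, `"value"` (concentration as a function of time) or
#'   `"derivative"` (d[X]/dt given directly).
#' @param params Named list of parameter values binding every parameter
#'   symbol used by the expressions.
#' @param assumptions Named list of quoted predicates over the parameters
#'   (non-negativity, non-singularity); all must hold for the solution to be
#'   valid.
#' @return An object of class `closed_form_solution`.
#' @examples
#' sol <- closed_form_solution(
#'   entries = list(A = list(expr = quote(A0 * exp(-k1 * t)), kind = "value")),
#'   params = list(A0 = 1, k1 = 2),
#'   assumptions = list(k1_positive = quote(k1 > 0))
#' )
#' solution_state(sol, 0)
#' @export
closed_form_solution <- function(entries, params, assumptions = list()) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    zk_stop("invalid_solution", "entries must be named by species")
  entries <- lapply(entries, function(e) {
    if (is.null(e$kind)) e$kind <- "value"
    if (!e$kind %in% c("value", "derivative"))
      zk_stop("invalid_solution", "entry kind must be \"value\" or \"derivative\"")
    if (!is.language(e$expr) && !is.numeric(e$expr))
      zk_stop("invalid_solution", "entry expr must be a quoted expression")
    e
  })
  structure(list(entries = entries, params = as.list(params),
                 assumptions = assumptions),
            class = "closed_form_solution")
}

#' @export
print.closed_form_solution <- function(x, ...) {
  cat("Closed-form solution\n")
  for (nm in names(x$entries)) {
    e <- x$entries[[nm]]
    lhs <- if (e$kind == "derivative") sprintf("d%s/dt", nm) else sprintf("%s(t)", nm)
    cat(sprintf("  %s = %s\n", lhs, paste(deparse(e$expr), collapse = " ")))
  }
  if (length(x$params))
    cat("  parameters:", paste(sprintf("%s = %g", names(x$params),
                                       unlist(x$params)), collapse = ", "), "\n")
  if (length(x$assumptions))
    cat("  assumptions:", paste(names(x$assumptions), collapse = ", "), "\n")
  invisible(x)
}

eval_with <- function(expr, env_list) {
  v <- try(eval(expr, env_list, baseenv()), silent = TRUE)
  if (inherits(v, "try-error")) {
    miss <- setdiff(all.vars(expr), c(names(env_list)))
    if (length(miss))
      zk_stop("unbound_parameter",
              sprintf("unbound symbols in expression: %s", paste(miss, collapse = ", ")))
    zk_stop("invalid_solution", paste("expression evaluation failed:", as.character(v)))
  }
  v
}

#' Check a solution's validity assumptions
#'
#' Evaluates every assumption predicate under the bound parameters.
#'
#' @param sol A [closed_form_solution()].
#' @return Named logical vector, one entry per assumption.
#' @export
check_assumptions <- function(sol) {
  vapply(sol$assumptions, function(a) isTRUE(eval_with(a, sol$params)), logical(1))
}

#' Concentration state of a closed-form solution at a time
#'
#' Evaluates every value entry at `t`. Derivative-only species have no
#' concentration expression; they are reported as 0 (by construction such
#' species never appear as reactants, so the fluxes do not depend on them).
#'
#' @param sol A [closed_form_solution()].
#' @param t Time (scalar, >= 0).
#' @return Named concentration vector in entry order.
#' @export
solution_state <- function(sol, t) {
  env <- c(sol$params, list(t = t))
  vapply(sol$entries, function(e) {
    if (e$kind == "value") eval_with(e$expr, env) else 0
  }, numeric(1))
}

#' Time derivatives of a closed-form solution
#'
#' Value entries are differentiated structurally with respect to `t`
#' (`stats::D`) and evaluated; derivative-only entries are evaluated as
#' given, with the other species' concentrations bound from the value
#' entries (e.g. dM/dt = k6 CSC(t) + k7 P(t) + k8 D(t)).
#'
#' @param sol A [closed_form_solution()].
#' @param t Time (scalar, >= 0).
#' @return Named numeric vector of d[X]/dt in entry order.
#' @examples
#' sol <- scheme_solution("scheme_01", list(A0 = 1, k1 = 1, k2 = 2))
#' differentiate_solutions(sol, 0)
#' @export
differentiate_solutions <- function(sol, t) {
  state <- solution_state(sol, t)
  env <- c(sol$params, list(t = t), as.list(state))
  vapply(sol$entries, function(e) {
    if (e$kind == "value") {
      eval_with(stats::D(e$expr, "t"), env)
    } else {
      eval_with(e$expr, env)
    }
  }, numeric(1))
}

#' Default verification time grid
#'
#' t = 0 plus `n` log-spaced points on `[lo, hi]`.
#'
#' @param n Number of log-spaced points.
#' @param lo,hi Grid limits (time units of the model).
#' @return Numeric vector of length `n + 1`.
#' @export
default_time_grid <- function(n = 50L, lo = 1e-3, hi = 10) {
  c(0, exp(seq(log(lo), log(hi), length.out = n)))
}

#' Verify a closed-form solution against the rate equations
#'
#' For every grid time the solution state is reconstructed, the model's
#' right-hand side N v is assembled at that state ([ode_rhs()]), and the
#' structurally differentiated solution is compared against it. The residual
#' is scaled, `|lhs - rhs| / max(1, |lhs|, |rhs|)`, so the pass criterion is
#' meaningful for both decaying and exponentially growing solutions.
#' Assumptions are checked first: a violated assumption aborts with error
#' class `singular_parameters` naming the predicate.
#'
#' @param model A [kinetic_model()] (the scheme at the solution's
#'   parameters), or a function of no arguments returning one.
#' @param sol A [closed_form_solution()] with parameters bound.
#' @param grid Time grid (default [default_time_grid()]).
#' @param tol Pass tolerance on the maximum scaled residual.
#' @return An object of class `verification_report`: per-species maximum
#'   scaled residual, the grid, per-assumption checks and the overall `pass`.
#' @examples
#' p <- list(A0 = 1, k1 = 1, k2 = 2)
#' verify_solution(build_scheme("scheme_01", p), scheme_solution("scheme_01", p))
#' @export
verify_solution <- function(model, sol, grid = default_time_grid(), tol = 1e-8) {
  if (is.function(model)) model <- model()
  if (!inherits(sol, "closed_form_solution"))
    zk_stop("invalid_solution", "sol must be a closed_form_solution")
  if (length(grid) == 0L) zk_stop("invalid_grid", "the time grid is empty")
  checks <- check_assumptions(sol)
  if (length(checks) && !all(checks))
    zk_stop("singular_parameters",
            sprintf("solution assumptions violated: %s",
                    paste(names(checks)[!checks], collapse = ", ")))
  species <- names(sol$entries)
  if (!identical(species, model$species))
    zk_stop("species_mismatch", "solution entries must match the model species order")
  resid <- matrix(NA_real_, nrow = length(grid), ncol = length(species),
                  dimnames = list(NULL, species))
  for (i in seq_along(grid)) {
    tt <- grid[i]
    state <- solution_state(sol, tt)
    lhs <- differentiate_solutions(sol, tt)
    rhs <- ode_rhs(model, state)
    resid[i, ] <- abs(lhs - rhs) / pmax(1, abs(lhs), abs(rhs))
  }
  max_resid <- apply(resid, 2L, max)
  structure(list(max_abs_residual = max_resid, grid = grid, tol = tol,
                 assumption_checks = checks,
                 pass = all(max_resid <= tol) && (length(checks) == 0L || all(checks))),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("Verification report (%d grid points, tol = %g): %s\n",
              length(x$grid), x$tol, if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$max_abs_residual))
    cat(sprintf("  %-8s max scaled residual %.3e\n", nm, x$max_abs_residual[[nm]]))
  if (length(x$assumption_checks))
    cat("  assumptions:",
        paste(sprintf("%s=%s", names(x$assumption_checks),
                      ifelse(x$assumption_checks, "ok", "VIOLATED")), collapse = ", "), "\n")
  invisible(x)
}

#' Perturb one coefficient of a closed-form solution
#'
#' Multiplies one species' expression by `factor`. Used to confirm that the
#' verifier is sensitive: a 1% perturbation must push the residual above
#' tolerance.
#'
#' @param sol A [closed_form_solution()].
#' @param species Name of the entry to perturb.
#' @param factor Multiplicative perturbation (default 1.01).
#' @return A perturbed `closed_form_solution`.
#' @export
perturb_solution <- function(sol, species, factor = 1.01) {
  if (!species %in% names(sol$entries))
    zk_stop("unknown_species", sprintf("no solution entry for %s", species))
  e <- sol$entries[[species]]
  e$expr <- bquote(.(factor) * (.(e$expr)))
  sol$entries[[species]] <- e
  sol
}
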