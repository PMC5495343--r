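# Mass-action reaction kinetics: fluxes, stoichiometric matrices and the
# assembly of the reaction rate equations d[X]/dt = N v.
#
# A model has m ordered species and n ordered reactions; each reaction
# carries full-length stoichiometry vectors (one entry per species, zero for
# non-participants), a kind (irreversible/reversible) and a rate-constant
# pair (k_r is identically 0 for irreversible reactions). Concentrations are
# not stored in the model: every flux function takes the current state
# vector, so one model serves all time points.

#' Construct a biological reaction
#'
#' Stoichiometries may be given sparsely as named vectors
#' (`c(A = 1)`); [kinetic_model()] expands them to full species order.
#'
#' @param kind `"irreversible"` or `"reversible"`.
#' @param reactants,products Named non-negative integer vectors of
#'   stoichiometries (species absent from the name set get stoichiometry 0).
#' @param kf Forward kinetic rate constant (non-negative).
#' @param kr Reverse kinetic rate constant; must be 0 for irreversible
#'   reactions (a zero reverse constant is the irreversibility convention).
#' @return An object of class `bio_reaction`.
#' @examples
#' reaction("irreversible", c(A = 1), c(B = 1), kf = 0.5)
#' @export
reaction <- function(kind = c("irreversible", "reversible"),
                     reactants, products, kf, kr = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(kf) || length(kf) != 1L || is.na(kf) || kf < 0)
    zk_stop("negative_rate", "kf must be a non-negative number")
  if (!is.numeric(kr) || length(kr) != 1L || is.na(kr) || kr < 0)
    zk_stop("negative_rate", "kr must be a non-negative number")
  if (kind == "irreversible" && kr != 0)
    zk_stop("invalid_reaction", "an irreversible reaction must have kr = 0")
  chk <- function(s, what) {
    if (length(s) && (any(s < 0) || any(s != trunc(s))))
      zk_stop("invalid_reaction", sprintf("%s stoichiometries must be non-negative integers", what))
    s
  }
  structure(list(kind = kind,
                 reactants = chk(reactants, "reactant"),
                 products = chk(products, "product"),
                 kf = kf, kr = kr),
            class = "bio_reaction")
}

expand_stoich <- function(s, species) {
  full <- stats::setNames(numeric(length(species)), species)
  if (length(s)) {
    if (is.null(names(s)) || any(!nzchar(names(s)))) {
      if (length(s) != length(species))
        zk_stop("species_mismatch",
                "unnamed stoichiometry vectors must span the full species list")
      full[] <- s
    } else {
      unknown <- setdiff(names(s), species)
      if (length(unknown))
        zk_stop("unknown_species",
                sprintf("reaction names species not in the model: %s",
                        paste(unknown, collapse = ", ")))
      full[names(s)] <- s
    }
  }
  full
}

#' Construct a kinetic model
#'
#' @param species Ordered character vector of species names (m >= 1).
#' @param reactions List of [reaction()] objects (n >= 1). Their sparse
#'   stoichiometry vectors are expanded to full species order.
#' @return An object of class `kinetic_model`.
#' @examples
#' kinetic_model(c("A", "B"), list(reaction("irreversible", c(A = 1), c(B = 1), 1)))
#' @export
kinetic_model <- function(species, reactions) {
  species <- as.character(species)
  if (length(species) < 1L) zk_stop("empty_model", "at least one species is required")
  if (anyDuplicated(species))
    zk_stop("invalid_model", "duplicate species names")
  if (length(reactions) < 1L) zk_stop("empty_model", "at least one reaction is required")
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "bio_reaction"))
      r <- reaction(r$kind, r$reactants, r$products, r$kf, if (is.null(r$kr)) 0 else r$kr)
    r$reactants <- expand_stoich(r$reactants, species)
    r$products <- expand_stoich(r$products, species)
    r
  })
  structure(list(species = species, reactions = reactions), class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model: %d species (%s), %d reactions\n",
              length(x$species), paste(x$species, collapse = ", "),
              length(x$reactions)))
  side <- function(s) {
    on <- s > 0
    if (!any(on)) return("0")
    paste(ifelse(s[on] > 1, paste0(s[on], " "), ""), names(s)[on],
          sep = "", collapse = " + ")
  }
  for (r in x$reactions) {
    arrow <- if (r$kind == "reversible") sprintf("<=> (kf=%g, kr=%g)", r$kf, r$kr)
             else sprintf("--> (k=%g)", r$kf)
    cat("  ", side(r$reactants), arrow, side(r$products), "\n")
  }
  invisible(x)
}

#' Mass-action product of a reactant list
#'
#' The law of mass action: the product over participating species of the
#' concentration raised to its stoichiometry. Species with stoichiometry 0
#' contribute a factor 1, and the empty product is 1.
#'
#' @param stoich Non-negative integer vector of stoichiometries.
#' @param conc Numeric vector of concentrations, same length.
#' @return A number.
#' @examples
#' mass_action_product(c(2, 1), c(3, 4))  # 3^2 * 4 = 36
#' mass_action_product(numeric(0), numeric(0))  # 1
#' @export
mass_action_product <- function(stoich, conc) {
  if (length(stoich) != length(conc))
    zk_stop("species_mismatch", "stoich and conc must have the same length")
  on <- stoich > 0
  prod(conc[on] ^ stoich[on])
}

#' Flux of an irreversible reaction
#'
#' `kf` times the mass-action product of the reactants. The product
#' stoichiometries are accepted but unused (signature kept symmetric with
#' [flux_reversible()]).
#'
#' @param reactants,products Stoichiometry vectors.
#' @param conc Concentration state vector.
#' @param kf Non-negative rate constant.
#' @return A number.
#' @export
flux_irreversible <- function(reactants, products, conc, kf) {
  if (!is.numeric(kf) || length(kf) != 1L || is.na(kf) || kf < 0)
    zk_stop("negative_rate", "kf must be a non-negative number")
  kf * mass_action_product(reactants, conc)
}

#' Flux of a reversible reaction
#'
#' Forward mass-action flux minus reverse mass-action flux:
#' `kf * prod(conc^reactants) - kr * prod(conc^products)`.
#'
#' @inheritParams flux_irreversible
#' @param kr Non-negative reverse rate constant.
#' @return A number.
#' @export
flux_reversible <- function(reactants, products, conc, kf, kr) {
  if (!is.numeric(kr) || length(kr) != 1L || is.na(kr) || kr < 0)
    zk_stop("negative_rate", "kr must be a non-negative number")
  flux_irreversible(reactants, products, conc, kf) -
    kr * mass_action_product(products, conc)
}

#' Flux of a single reaction at a state
#'
#' Dispatches on the reaction kind.
#'
#' @param rxn A [reaction()] with full-length stoichiometry vectors.
#' @param state Concentration vector in model species order.
#' @return A number.
#' @export
reaction_flux <- function(rxn, state) {
  if (!inherits(rxn, "bio_reaction") ||
      length(rxn$reactants) != length(state) ||
      length(rxn$products) != length(state))
    zk_stop("invalid_reaction", "malformed reaction or state length mismatch")
  if (rxn$kind == "irreversible") {
    if (rxn$kr != 0) zk_stop("invalid_reaction", "irreversible reaction with kr != 0")
    flux_irreversible(rxn$reactants, rxn$products, state, rxn$kf)
  } else {
    flux_reversible(rxn$reactants, rxn$products, state, rxn$kf, rxn$kr)
  }
}

#' Flux vector of a model at a state
#'
#' Component j is the mass-action flux of reaction j, giving the vector v of
#' the rate equations d[X]/dt = N v.
#'
#' @param model A [kinetic_model()].
#' @param state Concentration vector in model species order.
#' @return Numeric vector of length n (number of reactions).
#' @export
flux_vector <- function(model, state) {
  check_model_state(model, state)
  vapply(model$reactions, reaction_flux, numeric(1), state = state)
}

check_model_state <- function(model, state) {
  if (!inherits(model, "kinetic_model")) zk_stop("invalid_model", "not a kinetic_model")
  if (length(model$reactions) == 0L) zk_stop("empty_model", "the model has no reactions")
  if (length(state) != length(model$species))
    zk_stop("species_mismatch",
            sprintf("state has %d entries for %d species", length(state), length(model$species)))
}

#' Net stoichiometry column of one reaction
#'
#' Element i is `products[i] - reactants[i]`, the net production of species i
#' (one column of the stoichiometric matrix N).
#'
#' @param reactants,products Equal-length stoichiometry vectors.
#' @return Numeric vector of length m.
#' @examples
#' stoich_column(c(1, 0, 0), c(0, 1, 0))  # A -> B over (A, B, C)
#' @export
stoich_column <- function(reactants, products) {
  if (length(reactants) != length(products))
    zk_stop("species_mismatch", "reactant and product lists differ in length")
  as.numeric(products) - as.numeric(reactants)
}

#' Stoichiometric matrix, stored reaction-major
#'
#' Row j is the net stoichiometry of reaction j, i.e. this is the transpose
#' of the conventional m-by-n matrix N; [ode_rhs()] applies the transpose, so
#' the rate equations keep the shape d[X]/dt = N v.
#'
#' @param model A [kinetic_model()].
#' @return An n-by-m numeric matrix with species names as column names.
#' @export
stoich_matrix <- function(model) {
  if (!inherits(model, "kinetic_model")) zk_stop("invalid_model", "not a kinetic_model")
  m <- do.call(rbind, lapply(model$reactions, function(r)
    stoich_column(r$reactants, r$products)))
  colnames(m) <- model$species
  m
}

#' Right-hand side of the reaction rate equations
#'
#' Assembles d[X]/dt = N v at the given state: component i is
#' `sum_j n_ij * v_j` with `n_ij = s'_ij - s_ij`.
#'
#' @param model A [kinetic_model()].
#' @param state Concentration vector in model species order.
#' @return Named numeric vector of length m (species derivatives).
#' @examples
#' m <- build_scheme("scheme_01", list(k1 = 1, k2 = 2))
#' ode_rhs(m, c(A = 1, B = 0, C = 0))  # c(-1, 1, 0)
#' @export
ode_rhs <- function(model, state) {
  check_model_state(model, state)
  v <- flux_vector(model, state)
  stats::setNames(as.numeric(crossprod(stoich_matrix(model), v)), model$species)
}

#' Numerically integrate a kinetic model
#'
#' Integrates d[X]/dt = N v from the initial state with `deSolve::ode`
#' (lsoda). Deterministic given solver settings.
#'
#' @param model A [kinetic_model()].
#' @param initial Non-negative initial concentration vector (species order).
#' @param t_max Final time (> 0).
#' @param n_out Number of output points (including t = 0).
#' @param rtol,atol Solver tolerances.
#' @param times Optional explicit output time vector overriding
#'   `t_max`/`n_out`.
#' @return A data.frame with column `t` then one column per species.
#' @examples
#' m <- build_scheme("scheme_01", list(k1 = 1, k2 = 2))
#' tr <- simulate_model(m, c(A = 1, B = 0, C = 0), t_max = 5, n_out = 11)
#' @export
simulate_model <- function(model, initial, t_max, n_out = 101L,
                           rtol = 1e-6, atol = 1e-9, times = NULL) {
  check_model_state(model, initial)
  if (any(!is.finite(initial)) || any(initial < 0))
    zk_stop("invalid_state", "initial concentrations must be finite and non-negative")
  if (is.null(times)) {
    if (!is.numeric(t_max) || t_max <= 0) zk_stop("invalid_time", "t_max must be > 0")
    times <- seq(0, t_max, length.out = n_out)
  }
  deriv <- function(t, y, parms) list(ode_rhs(model, y))
  out <- try(deSolve::ode(y = stats::setNames(as.numeric(initial), model$species),
                          times = times, func = deriv, parms = NULL,
                          rtol = rtol, atol = atol), silent = TRUE)
  if (inherits(out, "try-error") || attr(out, "istate")[1L] < 0)
    zk_stop("integration_failed",
            paste("ODE integration failed:",
                  if (inherits(out, "try-error")) as.character(out) else "solver istate < 0"))
  df <- as.data.frame(out)
  names(df)[1L] <- "t"
  df
}
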