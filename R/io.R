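# Strict JSON readers/writers for deduction problems and kinetic models,
# and full-precision CSV trajectories. Schemas carry "format_version": 1;
# unknown keys are rejected so that typos fail loudly.

check_keys <- function(x, allowed, required, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    zk_stop("invalid_problem_file",
            sprintf("unknown keys at %s: %s", where, paste(extra, collapse = ", ")))
  miss <- setdiff(required, names(x))
  if (length(miss))
    zk_stop("invalid_problem_file",
            sprintf("missing keys at %s: %s", where, paste(miss, collapse = ", ")))
}

#' Read a Zsyntax problem from JSON
#'
#' Expected keys: `molecules` (array of strings, duplicates are a
#' `distinctness_violation`), `initial` (array of arrays of strings), `evfs`
#' (array of `{reactants, products}`), optional `target`, optional
#' `max_rounds` (integer or `"fixpoint"`), optional `format_version`.
#' Unknown molecule tokens and unknown keys are errors.
#'
#' @param path Path to a JSON file.
#' @return A [zsyntax_problem()].
#' @export
read_zsyntax_problem <- function(path) {
  if (!file.exists(path)) zk_stop("io_error", sprintf("no such file: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(x, c("format_version", "molecules", "initial", "evfs", "target", "max_rounds"),
             c("molecules", "initial", "evfs"), "/")
  molecules <- vapply(x$molecules, function(m) as.character(m)[1L], character(1))
  initial <- lapply(x$initial, function(i) vapply(i, as.character, character(1)))
  evfs <- lapply(seq_along(x$evfs), function(j) {
    e <- x$evfs[[j]]
    check_keys(e, c("reactants", "products"), c("reactants", "products"),
               sprintf("/evfs/%d", j - 1L))
    if (length(e$products) == 0L)
      zk_stop("invalid_problem_file",
              sprintf("/evfs/%d/products must be non-empty", j - 1L))
    evf(vapply(e$reactants, as.character, character(1)),
        lapply(e$products, function(p) vapply(p, as.character, character(1))))
  })
  target <- if (is.null(x$target)) NULL else vapply(x$target, as.character, character(1))
  max_rounds <- x$max_rounds
  if (!is.null(max_rounds) && !identical(max_rounds, "fixpoint"))
    max_rounds <- as.integer(max_rounds)
  zsyntax_problem(initial, evfs, target = target, max_rounds = max_rounds,
                  molecules = molecules)
}

#' Write a Zsyntax problem to JSON
#'
#' Canonical key order; round-trips with [read_zsyntax_problem()].
#'
#' @param problem A [zsyntax_problem()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zsyntax_problem <- function(problem, path) {
  out <- list(format_version = 1L,
              molecules = problem$molecules,
              initial = lapply(problem$initial, as.list),
              evfs = lapply(problem$evfs, function(e)
                list(reactants = as.list(e$reactants),
                     products = lapply(e$products, as.list))))
  if (!is.null(problem$target)) out$target <- as.list(problem$target)
  if (!is.null(problem$max_rounds)) out$max_rounds <- problem$max_rounds
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a kinetic model (and optional initial state) from JSON
#'
#' Expected keys: `species` (ordered array), `reactions` (array of
#' `{type, reactants, products, kf, kr}` with sparse
#' `[{species, stoich}, ...]` term lists), optional `initial` (map species ->
#' value), optional `format_version`. Sparse terms are expanded to full
#' species order; `kr` must be 0 or absent for irreversible reactions;
#' unknown species are errors.
#'
#' @param path Path to a JSON file.
#' @return A [kinetic_model()]; if the file carries `initial`, it is attached
#'   as attribute `"initial"` (full species order).
#' @export
read_kinetic_model <- function(path) {
  if (!file.exists(path)) zk_stop("io_error", sprintf("no such file: %s", path))
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(x, c("format_version", "species", "reactions", "initial"),
             c("species", "reactions"), "/")
  species <- vapply(x$species, function(s) as.character(s)[1L], character(1))
  terms <- function(ts, where) {
    s <- numeric(0)
    for (tm in ts) {
      check_keys(tm, c("species", "stoich"), c("species", "stoich"), where)
      if (!tm$species %in% species)
        zk_stop("unknown_species",
                sprintf("%s names unknown species %s", where, tm$species))
      s[tm$species] <- as.numeric(tm$stoich)
    }
    s
  }
  rxns <- lapply(seq_along(x$reactions), function(j) {
    r <- x$reactions[[j]]
    where <- sprintf("/reactions/%d", j - 1L)
    check_keys(r, c("type", "reactants", "products", "kf", "kr"),
               c("type", "reactants", "products", "kf"), where)
    kr <- if (is.null(r$kr)) 0 else as.numeric(r$kr)
    if (identical(r$type, "irreversible") && kr != 0)
      zk_stop("invalid_reaction", sprintf("%s: irreversible reaction with kr != 0", where))
    reaction(r$type, terms(r$reactants, where), terms(r$products, where),
             kf = as.numeric(r$kf), kr = kr)
  })
  model <- kinetic_model(species, rxns)
  if (!is.null(x$initial)) {
    init <- stats::setNames(numeric(length(species)), species)
    unknown <- setdiff(names(x$initial), species)
    if (length(unknown))
      zk_stop("unknown_species",
              sprintf("/initial names unknown species: %s", paste(unknown, collapse = ", ")))
    init[names(x$initial)] <- vapply(x$initial, as.numeric, numeric(1))
    attr(model, "initial") <- init
  }
  model
}

#' Write a kinetic model to JSON
#'
#' Sparse term lists (zero-stoichiometry species omitted); round-trips with
#' [read_kinetic_model()].
#'
#' @param model A [kinetic_model()].
#' @param path Output path.
#' @param initial Optional named initial state to embed.
#' @return `path`, invisibly.
#' @export
write_kinetic_model <- function(model, path, initial = attr(model, "initial")) {
  sparse <- function(s) {
    on <- which(s > 0)
    lapply(on, function(i) list(species = names(s)[i], stoich = unname(s[i])))
  }
  out <- list(format_version = 1L,
              species = as.list(model$species),
              reactions = lapply(model$reactions, function(r) {
                o <- list(type = r$kind,
                          reactants = sparse(r$reactants),
                          products = sparse(r$products),
                          kf = r$kf)
                if (r$kind == "reversible") o$kr <- r$kr
                o
              }))
  if (!is.null(initial)) out$initial <- as.list(initial)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' Header `t,<species...>`, full double precision (round-trip stable), UNIX
#' newlines.
#'
#' @param traj Data frame as returned by [simulate_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error")) zk_stop("io_error", sprintf("cannot write %s", path))
  on.exit(close(con))
  writeLines(paste(names(traj), collapse = ","), con, sep = "\n")
  if (nrow(traj) > 0L) {
    mat <- vapply(traj, function(col) sprintf("%.17g", col), character(nrow(traj)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    writeLines(apply(mat, 1L, paste, collapse = ","), con, sep = "\n")
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path Path written by [write_trajectory()].
#' @return A data.frame with column `t` then species columns.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) zk_stop("io_error", sprintf("no such file: %s", path))
  utils::read.csv(path, check.names = FALSE)
}
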