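# Zsyntax deduction engine.
#
# A molecular *interaction* (Z-Interaction) is an ordered character vector of
# molecule names; an *aggregate* (Z-Conjunction) is an ordered list of
# interactions; an EVF (empirically valid formula) rewrites a reactant
# interaction into a product aggregate. Deduction repeatedly concatenates
# pairs of aggregate members, matches the concatenation against the EVF
# reactants, and on a match replaces the consumed pair by the EVF products.
# Order is significant everywhere: interactions are compared by exact ordered
# equality (molecular interaction is not associative) and no sorting or
# deduplication ever happens.

zk_stop <- function(name, msg, ...) {
  stop(errorCondition(msg, ..., class = c(name, "zsynkin_error")))
}

zk_warn <- function(name, msg) {
  warning(warningCondition(msg, class = c(name, "zsynkin_warning")))
}

interaction_eq <- function(a, b) {
  length(a) == length(b) && all(a == b)
}

as_aggregate <- function(x) {
  if (!is.list(x)) zk_stop("invalid_aggregate", "an aggregate must be a list of character vectors")
  lapply(x, as.character)
}

#' Construct an empirically valid formula (EVF)
#'
#' An EVF is a lab-validated rewrite rule: when the ordered concatenation of
#' two aggregate members equals `reactants` exactly, the pair is consumed and
#' `products` is appended to the aggregate.
#'
#' @param reactants Character vector, the reactant interaction (length >= 1).
#' @param products List of character vectors, the product aggregate.
#' @return An object of class `evf`.
#' @examples
#' evf(c("Kinase", "ATP"), list(c("ATP", "Kinase")))
#' @export
evf <- function(reactants, products) {
  reactants <- as.character(reactants)
  if (length(reactants) < 1L)
    zk_stop("invalid_evf", "an EVF reactant interaction must contain at least one molecule")
  products <- as_aggregate(products)
  structure(list(reactants = reactants, products = products), class = "evf")
}

#' @export
print.evf <- function(x, ...) {
  cat(format_interaction(x$reactants), "->", format_aggregate(x$products), "\n")
  invisible(x)
}

format_interaction <- function(x) paste0("[", paste(x, collapse = ","), "]")
format_aggregate <- function(x) {
  paste0("[", paste(vapply(x, format_interaction, character(1)), collapse = ";"), "]")
}

check_index <- function(i, n, what = "index") {
  if (length(i) != 1L || is.na(i) || i != trunc(i) || i < 0L || i >= n)
    zk_stop("index_out_of_range",
            sprintf("%s %s is out of range for an aggregate of length %d", what, format(i), n))
  as.integer(i)
}

#' Delete one aggregate member
#'
#' Removes the interaction at 0-based position `i`, keeping the relative
#' order of the remaining members.
#'
#' @param agg Aggregate (list of character vectors).
#' @param i 0-based index.
#' @return The shortened aggregate.
#' @examples
#' zs_delete_at(list("A", "B", "C"), 0)
#' @export
zs_delete_at <- function(agg, i) {
  agg <- as_aggregate(agg)
  i <- check_index(i, length(agg))
  agg[-(i + 1L)]
}

#' Delete a reactant pair from an aggregate
#'
#' Removes the members at 0-based positions `x` and `y`. The higher index is
#' always deleted first so that the lower index still addresses the intended
#' element. When `x == y` the definition is applied literally (delete `y`,
#' then `x` on the shortened list, i.e. two adjacent elements are removed)
#' and a warning of class `self_pair_deletion` is signalled.
#'
#' @param agg Aggregate.
#' @param x,y 0-based indices into `agg`.
#' @return The aggregate with both positions removed.
#' @examples
#' zs_delete_pair(list("A", "B", "C"), 2, 0)
#' @export
zs_delete_pair <- function(agg, x, y) {
  agg <- as_aggregate(agg)
  x <- check_index(x, length(agg), "x")
  y <- check_index(y, length(agg), "y")
  if (x == y)
    zk_warn("self_pair_deletion",
            "x == y: the literal else-branch removes positions y and y+1")
  if (x > y) {
    zs_delete_at(zs_delete_at(agg, x), y)
  } else {
    zs_delete_at(zs_delete_at(agg, y), x)
  }
}

#' Prepend the concatenation of two aggregate members
#'
#' Forms the candidate interaction for EVF matching: the ordered
#' concatenation of the molecules of `agg[x]` followed by those of `agg[y]`
#' is pushed onto the head of the aggregate; all original members shift by
#' one position.
#'
#' @param agg Aggregate.
#' @param x,y 0-based indices (x == y is allowed: self-combination).
#' @return The lengthened aggregate.
#' @examples
#' zs_introduce(list("Kinase", "ATP"), 0, 1)
#' @export
zs_introduce <- function(agg, x, y) {
  agg <- as_aggregate(agg)
  x <- check_index(x, length(agg), "x")
  y <- check_index(y, length(agg), "y")
  c(list(c(agg[[x + 1L]], agg[[y + 1L]])), agg)
}

#' Eliminate a conjunction: project onto a target interaction
#'
#' If `target` occurs in `agg` (exact ordered equality), returns the
#' one-member aggregate `list(target)`; otherwise returns `agg` unchanged.
#' Applied after deduction to ask whether the desired product was obtained.
#'
#' @param agg Aggregate.
#' @param target Character vector, the interaction looked for.
#' @return An aggregate.
#' @examples
#' zs_eliminate(list("Kinase", "pTP53", "ADP"), "pTP53")
#' @export
zs_eliminate <- function(agg, target) {
  agg <- as_aggregate(agg)
  target <- as.character(target)
  if (any(vapply(agg, interaction_eq, logical(1), target))) list(target) else agg
}

#' Match the head of an aggregate against a list of EVFs
#'
#' Scans EVF indices `p, p-1, ..., 0` in that order. At the first index whose
#' reactant interaction equals the head of `agg` exactly, returns
#' `list(matched = TRUE, aggregate = zs_delete_pair(tail ++ products, x, y))`
#' where `tail` is `agg` without its head. If no EVF matches, returns
#' `list(matched = FALSE, aggregate = tail)`.
#'
#' @param agg Aggregate whose head is the candidate interaction (as produced
#'   by [zs_introduce()]).
#' @param evfs List of [evf()] objects.
#' @param p 0-based highest EVF index to consider (scan start).
#' @param x,y 0-based indices of the consumed pair, addressing positions in
#'   `tail ++ products`.
#' @return A deduction outcome: `list(matched, aggregate)`, plus the matched
#'   EVF index (`evf`, 0-based, or `NA`).
#' @export
zs_match_evf <- function(agg, evfs, p, x, y) {
  agg <- as_aggregate(agg)
  if (length(agg) == 0L) zk_stop("empty_aggregate", "cannot match on an empty aggregate")
  if (length(evfs) == 0L) zk_stop("empty_evf_list", "the EVF list is empty")
  p <- check_index(p, length(evfs), "p")
  head <- agg[[1L]]
  tail <- agg[-1L]
  for (j in seq(p, 0L)) {
    if (interaction_eq(evfs[[j + 1L]]$reactants, head)) {
      return(list(matched = TRUE,
                  aggregate = zs_delete_pair(c(tail, evfs[[j + 1L]]$products), x, y),
                  evf = j))
    }
  }
  list(matched = FALSE, aggregate = tail, evf = NA_integer_)
}

#' One deduction round: scan all index pairs for a firing
#'
#' Enumerates candidate pairs `(x, y)` with `x` descending from
#' `length(agg) - 1` to 0 and, for each `x`, `y` descending likewise. For
#' each pair the concatenated candidate is pushed with [zs_introduce()] and
#' matched with [zs_match_evf()] starting at the last EVF index. The first
#' match fires; if none fires the aggregate is returned unchanged.
#'
#' @param agg Non-empty aggregate.
#' @param evfs Non-empty list of EVFs.
#' @return `list(matched, aggregate, x, y, evf)` where `x`, `y`, `evf` record
#'   the firing (0-based) or are `NA` when `matched` is `FALSE`.
#' @export
zs_scan <- function(agg, evfs) {
  agg <- as_aggregate(agg)
  if (length(agg) == 0L) zk_stop("empty_aggregate", "cannot scan an empty aggregate")
  if (length(evfs) == 0L) zk_stop("empty_evf_list", "the EVF list is empty")
  n <- length(agg)
  for (x in seq(n - 1L, 0L)) {
    for (y in seq(n - 1L, 0L)) {
      out <- withCallingHandlers(
        zs_match_evf(zs_introduce(agg, x, y), evfs, length(evfs) - 1L, x, y),
        self_pair_deletion = function(w) invokeRestart("muffleWarning")
      )
      if (out$matched) {
        if (x == y)
          zk_warn("self_pair_deletion",
                  sprintf("firing consumed self-pair x = y = %d (literal deletion semantics)", x))
        return(list(matched = TRUE, aggregate = out$aggregate,
                    x = x, y = y, evf = out$evf))
      }
    }
  }
  list(matched = FALSE, aggregate = agg, x = NA_integer_, y = NA_integer_, evf = NA_integer_)
}

#' Construct a Zsyntax deduction problem
#'
#' Bundles an initial aggregate, the EVF list, an optional target interaction
#' and the round bound, and validates that every molecule token is drawn from
#' a declared, duplicate-free molecule set and that every EVF has non-empty
#' products.
#'
#' @param initial Initial aggregate (list of character vectors).
#' @param evfs List of [evf()] objects.
#' @param target Optional character vector, the desired product interaction.
#' @param max_rounds Positive integer round bound, or the string `"fixpoint"`
#'   to iterate until no EVF can fire (subject to `hard_limit`). Defaults to
#'   `length(evfs)`.
#' @param molecules Declared molecule set; defaults to the distinct tokens
#'   occurring in `initial`, `evfs` and `target`. Duplicates are an error.
#' @return An object of class `zsyntax_problem`.
#' @examples
#' p <- zsyntax_problem(
#'   initial = list("CSC", "P"),
#'   evfs = list(evf("CSC", list(c("CSC", "P"))), evf(c("CSC", "P"), list("M"))),
#'   target = "M"
#' )
#' zs_deduce(p)
#' @export
zsyntax_problem <- function(initial, evfs, target = NULL,
                            max_rounds = NULL, molecules = NULL) {
  initial <- as_aggregate(initial)
  if (length(initial) == 0L) zk_stop("empty_aggregate", "the initial aggregate is empty")
  if (length(evfs) == 0L) zk_stop("empty_evf_list", "at least one EVF is required")
  evfs <- lapply(evfs, function(e) {
    if (!inherits(e, "evf")) e <- evf(e$reactants, e$products)
    if (length(e$products) == 0L)
      zk_stop("invalid_evf", "EVF products must be non-empty")
    e
  })
  used <- unique(c(unlist(initial), unlist(lapply(evfs, function(e)
    c(e$reactants, unlist(e$products)))), as.character(target)))
  if (is.null(molecules)) {
    molecules <- used
  } else {
    molecules <- as.character(molecules)
    if (anyDuplicated(molecules))
      zk_stop("distinctness_violation",
              sprintf("duplicate declared molecules: %s",
                      paste(unique(molecules[duplicated(molecules)]), collapse = ", ")))
    unknown <- setdiff(used, molecules)
    if (length(unknown))
      zk_stop("unknown_molecule",
              sprintf("undeclared molecule tokens: %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(max_rounds) && !identical(max_rounds, "fixpoint")) {
    if (!is.numeric(max_rounds) || length(max_rounds) != 1L ||
        max_rounds < 1 || max_rounds != trunc(max_rounds))
      zk_stop("invalid_problem", "max_rounds must be a positive integer or \"fixpoint\"")
    max_rounds <- as.integer(max_rounds)
  }
  structure(list(initial = initial, evfs = evfs,
                 target = if (is.null(target)) NULL else as.character(target),
                 max_rounds = max_rounds, molecules = molecules),
            class = "zsyntax_problem")
}

#' @export
print.zsyntax_problem <- function(x, ...) {
  cat("Zsyntax deduction problem\n")
  cat("  molecules:", paste(x$molecules, collapse = ", "), "\n")
  cat("  initial:  ", format_aggregate(x$initial), "\n")
  for (e in x$evfs)
    cat("  EVF:      ", format_interaction(e$reactants), "->", format_aggregate(e$products), "\n")
  if (!is.null(x$target)) cat("  target:   ", format_interaction(x$target), "\n")
  cat("  rounds:   ", if (is.null(x$max_rounds)) sprintf("%d (default: number of EVFs)", length(x$evfs))
      else as.character(x$max_rounds), "\n")
  invisible(x)
}

#' Run a Zsyntax deduction to its final aggregate
#'
#' Repeats [zs_scan()] rounds, each firing at most one EVF, until either no
#' EVF can fire or the round bound is exhausted. The default bound is the
#' number of EVFs; `max_rounds = "fixpoint"` iterates until quiescence,
#' capped by `hard_limit`. A warning of class `round_bound_exhausted` is
#' signalled if the bound ran out while a firing was still possible.
#'
#' @param problem A [zsyntax_problem()], or an aggregate (with `evfs` given).
#' @param evfs EVF list when `problem` is a bare aggregate.
#' @param max_rounds Overrides the problem's round bound.
#' @param hard_limit Iteration cap for fixpoint mode (default 10000).
#' @param trace Logical; record each firing.
#' @return The final aggregate. With `trace = TRUE` the attribute `"trace"`
#'   holds one row per firing (round, x, y, evf index, aggregate sizes).
#' @examples
#' zs_deduce(tp53_fixture())
#' @export
zs_deduce <- function(problem, evfs = NULL, max_rounds = NULL,
                      hard_limit = 10000L, trace = FALSE) {
  if (inherits(problem, "zsyntax_problem")) {
    agg <- problem$initial
    evfs <- problem$evfs
    if (is.null(max_rounds)) max_rounds <- problem$max_rounds
  } else {
    agg <- as_aggregate(problem)
    if (is.null(evfs)) zk_stop("empty_evf_list", "evfs must be supplied with a bare aggregate")
  }
  if (is.null(max_rounds)) max_rounds <- length(evfs)
  fixpoint_mode <- identical(max_rounds, "fixpoint")
  bound <- if (fixpoint_mode) as.integer(hard_limit) else as.integer(max_rounds)
  steps <- list()
  rounds <- 0L
  while (rounds < bound && length(agg) > 0L) {
    out <- zs_scan(agg, evfs)
    if (!out$matched) break
    rounds <- rounds + 1L
    if (trace)
      steps[[rounds]] <- data.frame(round = rounds, x = out$x, y = out$y,
                                    evf = out$evf, size_before = length(agg),
                                    size_after = length(out$aggregate))
    agg <- out$aggregate
  }
  if (rounds == bound && length(agg) > 0L && zs_scan(agg, evfs)$matched) {
    if (fixpoint_mode)
      zk_stop("fixpoint_not_reached",
              sprintf("no fixpoint within %d firings", bound),
              partial = agg)
    zk_warn("round_bound_exhausted",
            sprintf("round bound %d exhausted while a firing was still possible", bound))
  }
  if (trace) attr(agg, "trace") <- do.call(rbind, steps)
  agg
}

#' Deduce and project onto the problem's target
#'
#' Runs [zs_deduce()] and applies [zs_eliminate()] with the problem's target;
#' the result equals `list(target)` exactly when the target interaction was
#' produced.
#'
#' @param problem A [zsyntax_problem()] with a non-NULL target.
#' @param ... Passed to [zs_deduce()].
#' @return An aggregate.
#' @examples
#' zs_deduce_check(tp53_fixture())  # list("pTP53")
#' @export
zs_deduce_check <- function(problem, ...) {
  if (!inherits(problem, "zsyntax_problem") || is.null(problem$target))
    zk_stop("no_target", "the problem has no target interaction")
  zs_eliminate(zs_deduce(problem, ...), problem$target)
}

aggregate_key <- function(agg) {
  paste0("k:", paste(vapply(agg, function(x) paste(x, collapse = "\x1f"), character(1)),
                     collapse = "\x1e"))
}

firings <- function(agg, evfs) {
  # all (x, y, z) triples able to fire on agg
  res <- list()
  n <- length(agg)
  if (n == 0L) return(res)
  for (x in seq_len(n) - 1L) {
    for (y in seq_len(n) - 1L) {
      head <- c(agg[[x + 1L]], agg[[y + 1L]])
      for (z in seq_along(evfs) - 1L) {
        if (interaction_eq(evfs[[z + 1L]]$reactants, head))
          res[[length(res) + 1L]] <- c(x = x, y = y, z = z)
      }
    }
  }
  res
}

#' Brute-force enumeration of reachable deduction fixpoints
#'
#' Test oracle: explores every sequence of (pair choice, EVF choice) firings
#' up to `depth` levels and collects the aggregates on which no EVF can fire.
#' Intended for tiny instances only; the deterministic engine's result must
#' always be a member of this set.
#'
#' @param agg Aggregate, at most 6 members.
#' @param evfs List of at most 4 EVFs.
#' @param depth Maximum firing depth, at most 8.
#' @param max_states Safety cap on distinct visited states.
#' @return A list of aggregates (the reachable fixpoints), without duplicates.
#' @export
zs_fixpoints <- function(agg, evfs, depth, max_states = 50000L) {
  agg <- as_aggregate(agg)
  if (length(agg) > 6L || length(evfs) > 4L || depth > 8L)
    zk_stop("oracle_too_large",
            "oracle bounds exceeded (<= 6 interactions, <= 4 EVFs, depth <= 8)")
  seen <- new.env(parent = emptyenv())
  fix <- list()
  fix_keys <- character(0)
  frontier <- list(agg)
  assign(aggregate_key(agg), TRUE, envir = seen)
  n_states <- 1L
  for (d in seq_len(depth + 1L)) {
    nxt <- list()
    for (state in frontier) {
      fs <- firings(state, evfs)
      if (length(fs) == 0L) {
        key <- aggregate_key(state)
        if (!key %in% fix_keys) {
          fix_keys <- c(fix_keys, key)
          fix[[length(fix) + 1L]] <- state
        }
      } else if (d <= depth) {
        for (f in fs) {
          child <- suppressWarnings(
            zs_delete_pair(c(state, evfs[[f[["z"]] + 1L]]$products), f[["x"]], f[["y"]]))
          key <- aggregate_key(child)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            n_states <- n_states + 1L
            if (n_states > max_states)
              zk_stop("oracle_too_large", "state cap exceeded during enumeration")
            nxt[[length(nxt) + 1L]] <- child
          }
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  fix
}
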