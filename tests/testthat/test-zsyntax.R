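# Deduction engine primitives: deletion, conjunction introduction and
# elimination, EVF matching, single-round scans and full deductions.

agg3 <- list("A", "B", "C")

test_that("element deletion removes one position and keeps order", {
  expect_identical(zs_delete_at(agg3, 0), list("B", "C"))
  expect_identical(zs_delete_at(agg3, 1), list("A", "C"))
  expect_identical(zs_delete_at(list("A"), 0), list())
  expect_error(zs_delete_at(agg3, 3), class = "index_out_of_range")
  expect_error(zs_delete_at(agg3, -1), class = "index_out_of_range")
})

test_that("reactant-pair deletion removes the higher index first", {
  expect_identical(zs_delete_pair(agg3, 2, 0), list("B"))
  expect_identical(zs_delete_pair(agg3, 0, 2), list("B"))
  expect_identical(
    zs_delete_pair(list("TP53", "ATP", "Kinase", c("ATP", "Kinase")), 2, 1),
    list("TP53", c("ATP", "Kinase")))
  expect_error(zs_delete_pair(agg3, 0, 5), class = "index_out_of_range")
  # x == y applies the literal else-branch (removes positions y and y+1)
  expect_warning(out <- zs_delete_pair(agg3, 1, 1), class = "self_pair_deletion")
  expect_identical(out, list("A"))
})

test_that("conjunction introduction prepends the ordered concatenation", {
  expect_identical(zs_introduce(list("Kinase", "ATP"), 0, 1),
                   list(c("Kinase", "ATP"), "Kinase", "ATP"))
  expect_identical(zs_introduce(list("A"), 0, 0), list(c("A", "A"), "A"))
  expect_identical(zs_introduce(list("TP53", "ATP", "Kinase"), 2, 1),
                   list(c("Kinase", "ATP"), "TP53", "ATP", "Kinase"))
})

test_that("conjunction elimination projects onto a present target only", {
  expect_identical(zs_eliminate(list("Kinase", "pTP53", "ADP"), "pTP53"),
                   list("pTP53"))
  expect_identical(zs_eliminate(list("A", "B"), "C"), list("A", "B"))
  expect_identical(zs_eliminate(list("M"), "M"), list("M"))
  # ordered, not set, equality
  expect_identical(zs_eliminate(list(c("A", "B")), c("B", "A")), list(c("A", "B")))
})

test_that("EVF matching consumes the head and deletes the reactant pair", {
  tp53 <- tp53_fixture()$evfs
  out <- zs_match_evf(list(c("Kinase", "ATP"), "TP53", "ATP", "Kinase"),
                      tp53, 1, 2, 1)
  expect_true(out$matched)
  expect_identical(out$aggregate, list("TP53", c("ATP", "Kinase")))
  expect_identical(out$evf, 0L)

  csc <- csc_death_fixture()$evfs
  out <- zs_match_evf(list(c("P", "P"), "CSC", "P"), csc, 1, 1, 1)
  expect_false(out$matched)
  expect_identical(out$aggregate, list("CSC", "P"))

  out <- zs_match_evf(list("X"), list(evf("Y", list("Z"))), 0, 0, 0)
  expect_false(out$matched)
  expect_identical(out$aggregate, list())

  expect_error(zs_match_evf(list(), tp53, 0, 0, 0), class = "empty_aggregate")
  expect_error(zs_match_evf(list("X"), list(), 0, 0, 0), class = "empty_evf_list")
})

test_that("a scan fires the first match in descending pair order", {
  csc <- csc_death_fixture()
  out <- zs_scan(csc$initial, csc$evfs)
  expect_true(out$matched)
  expect_identical(out$aggregate, list("M"))

  tp53 <- tp53_fixture()
  out <- zs_scan(tp53$initial, tp53$evfs)
  expect_true(out$matched)
  expect_identical(out$aggregate, list("TP53", c("ATP", "Kinase")))
  expect_identical(c(out$x, out$y), c(2L, 1L))

  inert <- list(evf(c("Q", "Q", "Q"), list("Q")))
  out <- zs_scan(tp53$initial, inert)
  expect_false(out$matched)
  expect_identical(out$aggregate, tp53$initial)
})

test_that("full deduction reproduces the worked pathways", {
  tp53 <- tp53_fixture()
  expect_identical(zs_deduce(tp53), list("Kinase", "pTP53", "ADP"))
  expect_identical(zs_deduce_check(tp53), list("pTP53"))

  csc <- csc_death_fixture()
  expect_identical(zs_deduce(csc), list("M"))
  expect_identical(zs_deduce_check(csc), list("M"))

  # non-matching EVFs leave the aggregate unchanged
  inert <- zsyntax_problem(tp53$initial, list(evf(c("Q", "Q", "Q"), list("Q"))))
  expect_identical(zs_deduce(inert), tp53$initial)
})

test_that("deduction traces record each firing's coordinates", {
  tr <- attr(zs_deduce(tp53_fixture(), trace = TRUE), "trace")
  expect_identical(nrow(tr), 2L)
  expect_identical(tr$evf, c(0L, 1L))
  expect_identical(tr$size_after - tr$size_before, c(-1L, 1L))
})

test_that("the round bound warns when a firing remains possible", {
  # A + B -> A: two firings are needed but the default bound is one round
  prob <- zsyntax_problem(list("A", "B", "B"),
                          list(evf(c("A", "B"), list("A"))))
  expect_warning(res <- zs_deduce(prob), class = "round_bound_exhausted")
  expect_identical(res, list("B", "A"))
  expect_identical(zs_deduce(prob, max_rounds = "fixpoint"), list("A"))
  expect_error(zs_deduce(prob, max_rounds = "fixpoint", hard_limit = 1L),
               class = "fixpoint_not_reached")
})

test_that("problem validation enforces distinct declared molecules", {
  expect_error(
    zsyntax_problem(list("A"), list(evf("A", list("B"))),
                    molecules = c("A", "B", "A")),
    class = "distinctness_violation")
  expect_error(
    zsyntax_problem(list("A"), list(evf("A", list("B"))), molecules = "A"),
    class = "unknown_molecule")
  expect_error(
    zsyntax_problem(list("A"), list(list(reactants = "A", products = list()))),
    class = "invalid_evf")
  expect_error(zs_deduce_check(zsyntax_problem(list("A"), list(evf("A", list("B"))))),
               class = "no_target")
})

test_that("the brute-force oracle enumerates reachable fixpoints", {
  tp53 <- tp53_fixture()
  fx <- zs_fixpoints(tp53$initial, tp53$evfs, 5)
  expect_identical(length(fx), 1L)
  expect_identical(fx[[1L]], list("Kinase", "pTP53", "ADP"))

  csc <- csc_death_fixture()
  fx <- zs_fixpoints(csc$initial, csc$evfs, 5)
  keys <- vapply(fx, function(a) paste(vapply(a, paste, "", collapse = "*"),
                                       collapse = "|"), "")
  expect_true("M" %in% keys)

  inert <- list(evf(c("Q", "Q", "Q"), list("Q")))
  expect_identical(zs_fixpoints(list("A", "B"), inert, 3),
                   list(list("A", "B")))

  expect_error(zs_fixpoints(as.list(letters[1:7]), inert, 3),
               class = "oracle_too_large")
})
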