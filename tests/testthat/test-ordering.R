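test_that("a remission clone carrying only del14 places del14 before del12", {
  # carriers: del14 in remission + diagnosis + relapse; del12 only in the latter two
  calls <- matrix(c(
    "SUBCLONAL", "ABSENT",     # remission: del14 mosaic, no del12
    "CLONAL",    "CLONAL",     # diagnosis
    "CLONAL",    "CLONAL"),    # relapse
    nrow = 3, byrow = TRUE,
    dimnames = list(c("REM", "DX", "REL"), c("del14", "del12")))
  ord <- order_events(observation_matrix(calls))
  expect_equal(ord$relation, "precedes")
  expect_equal(ord$event_a, "del14")
  expect_equal(ord$event_b, "del12")
})

test_that("identical carrier sets co-occur; UNKNOWN cells cannot fabricate order", {
  calls <- matrix(c("CLONAL", "CLONAL",
                    "ABSENT", "ABSENT"), 2, byrow = TRUE,
                  dimnames = list(c("S1", "S2"), c("e1", "e2")))
  ord <- order_events(observation_matrix(calls))
  expect_equal(ord$relation, "co_occurring")
  # the only separating observation is UNKNOWN on one side -> no order
  calls2 <- matrix(c("CLONAL", "CLONAL",
                     "CLONAL", "UNKNOWN",
                     "ABSENT", "ABSENT"), 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2", "S3"), c("e1", "e2")))
  ord2 <- order_events(observation_matrix(calls2))
  expect_equal(ord2$relation, "co_occurring")
})

test_that("a chain of nested chr14 deletions orders totally by containment", {
  # progressive multi-step pattern: each deletion's carriers nest in the last
  calls <- matrix(c(
    "CLONAL", "ABSENT", "ABSENT",
    "CLONAL", "CLONAL", "ABSENT",
    "CLONAL", "CLONAL", "CLONAL"), 3, byrow = TRUE,
    dimnames = list(c("S1", "S2", "S3"), c("d14a", "d14b", "d14c")))
  ord <- order_events(observation_matrix(calls))
  expect_true(all(ord$relation == "precedes"))
  expect_equal(ord[ord$event_b == "d14c", ]$event_a, c("d14a", "d14b"))
  expect_equal(ord[ord$event_a == "d14a", ]$event_b, c("d14b", "d14c"))
})

test_that("containment order is a strict partial order on complete matrices", {
  set.seed(77)
  for (rep in 1:30) {
    calls <- random_iid_calls(sample(3:5, 1), sample(3:5, 1))
    ord <- order_events(observation_matrix(calls))
    prec <- ord[ord$relation == "precedes", , drop = FALSE]
    # antisymmetry: no pair ordered both ways
    expect_equal(anyDuplicated(t(apply(prec[, 1:2], 1, sort))), 0)
    # transitivity: a<b and b<c imply a<c
    before <- split(prec$event_a, prec$event_b)
    for (i in seq_len(nrow(prec))) {
      a <- prec$event_a[i]; b <- prec$event_b[i]
      for (c_ev in prec$event_b[prec$event_a == b]) {
        expect_true(a %in% (before[[c_ev]] %||% character(0)),
                    label = sprintf("%s < %s < %s chains", a, b, c_ev))
      }
    }
  }
})

test_that("hierarchies across timepoints expose the shared pre-leukemic ancestor", {
  ev <- c("del14", "del12", "ampX", "r1")
  g <- function(carried) { x <- setNames(logical(4), ev); x[carried] <- TRUE; x }
  tr <- build_hierarchy(list(
    diagnosis = rbind(D1 = g(c("del14", "del12", "ampX"))),
    relapse = rbind(R1 = g(c("del14", "del12", "r1"))),
    remission = rbind(REM = g("del14"))))
  td <- tidy(tr)
  # the diagnosis/relapse ancestor gains del12 below the remission clone and
  # is not itself any observed clone
  anc <- td$child[td$events == "del12"]
  expect_match(anc, "^anc")
  expect_setequal(td$events[td$parent == anc], c("ampX", "r1"))
  expect_equal(td$child[td$events == "del14"], "remission.REM")
})

test_that("crossing clones across timepoints raise a certificate", {
  ev <- c("e1", "e2")
  g <- function(carried) { x <- setNames(logical(2), ev); x[carried] <- TRUE; x }
  expect_error(
    build_hierarchy(list(a = rbind(A = g("e1"), B = g("e2")),
                         b = rbind(C = g(c("e1", "e2"))))),
    class = "clonemin_incompatible_error")
})

test_that("single timepoint single clone gives a two-node tree", {
  tr <- build_hierarchy(rbind(C1 = c(e1 = TRUE, e2 = TRUE)))
  expect_equal(nrow(tr$nodes), 2)
  expect_equal(tidy(tr)$child, "clones.C1")
})
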