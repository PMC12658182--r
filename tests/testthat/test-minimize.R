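test_that("the three-sample toy needs exactly clones {e1} and {e1,e2}", {
  res <- minimal_clone_set(toy_obs())
  expect_equal(res$optimum, 2)
  expect_equal(res$n_solutions, 1)
  sol <- res$solutions[[1]]
  expect_equal(unname(sol$clones),
               matrix(c(TRUE, TRUE, FALSE, TRUE), nrow = 2))  # {e1}, {e1,e2}
  expect_equal(sol$assignment$S3, c("C1", "C2"))
  verify_solution(sol, toy_obs(), lineage = FALSE)
  # brute force agrees
  expect_equal(oracle_min_clones(toy_obs()$calls), 2)
})

test_that("an all-CLONAL matrix is explained by a single clone, any cohort size", {
  for (S in c(1, 4, 8)) {
    m <- matrix("CLONAL", S, 3, dimnames = list(paste0("S", 1:S), paste0("e", 1:3)))
    res <- minimal_clone_set(observation_matrix(m))
    expect_equal(res$optimum, 1)
    td <- tidy(res$solutions[[1]]$tree)
    expect_equal(nrow(td), 1)  # root -> clone chain
  }
})

test_that("mosaicism or presence/absence disagreement forces at least two clones", {
  m <- matrix(c("CLONAL", "SUBCLONAL"), 1, dimnames = list("S1", c("e1", "e2")))
  expect_gte(minimal_clone_set(observation_matrix(m))$optimum, 2)
  # an event CLONAL in one assayed mouse and ABSENT in another
  m2 <- matrix(c("CLONAL", "ABSENT"), 2, 1, dimnames = list(c("M1", "M2"), "e1"))
  expect_gte(minimal_clone_set(observation_matrix(m2))$optimum, 2)
})

test_that("the lower bound is admissible and tight on the worked examples", {
  all_clonal <- observation_matrix(
    matrix("CLONAL", 2, 2, dimnames = list(c("S1", "S2"), c("e1", "e2"))))
  expect_equal(clone_lower_bound(all_clonal), 1)
  sub <- observation_matrix(
    matrix(c("SUBCLONAL", "CLONAL"), 1, dimnames = list("S1", c("e1", "e2"))))
  expect_gte(clone_lower_bound(sub), 2)
  expect_equal(clone_lower_bound(toy_obs()), 2)
  expect_equal(clone_lower_bound(toy_obs()), minimal_clone_set(toy_obs())$optimum)
})

test_that("lower bound never exceeds the optimum on random instances", {
  set.seed(31)
  for (rep in 1:40) {
    lam <- random_laminar_calls(6, sample(2:4, 1), 4)
    obs <- observation_matrix(lam$calls)
    expect_lte(clone_lower_bound(obs), minimal_clone_set(obs)$optimum)
  }
})

test_that("an UNKNOWN-only matrix returns the trivial founder-only solution", {
  m <- matrix("UNKNOWN", 2, 2, dimnames = list(c("S1", "S2"), c("e1", "e2")))
  res <- minimal_clone_set(observation_matrix(m, samples = flat_manifest(c("S1", "S2"), assayed = FALSE)))
  expect_equal(res$optimum, 1)
  expect_false(any(res$solutions[[1]]$clones))
  expect_equal(res$solutions[[1]]$assignment$S1, "C1")
})

test_that("every returned solution re-passes explanation and phylogeny checks", {
  set.seed(91)
  for (rep in 1:30) {
    lam <- random_laminar_calls(6, sample(2:5, 1), 4)
    obs <- observation_matrix(lam$calls)
    res <- minimal_clone_set(obs)
    for (sol in res$solutions) {
      expect_true(verify_solution(sol, obs, lineage = FALSE))
    }
  }
})

test_that("co-minimal solutions are deduplicated and deterministically ordered", {
  # symmetric instance: two mosaic events, either can pair with the base clone
  m <- matrix(c("SUBCLONAL", "SUBCLONAL"), 1, dimnames = list("S1", c("e1", "e2")))
  obs <- observation_matrix(m)
  r1 <- minimal_clone_set(obs)
  r2 <- minimal_clone_set(obs)
  expect_gte(r1$n_solutions, 2)
  key <- function(res) lapply(res$solutions, function(s) unname(s$clones))
  expect_identical(key(r1), key(r2))
})

test_that("adding a sample never decreases the minimum", {
  set.seed(47)
  for (rep in 1:20) {
    lam <- random_laminar_calls(6, 3, 4)
    obs_all <- observation_matrix(lam$calls)
    obs_less <- observation_matrix(lam$calls[-3, , drop = FALSE])
    expect_gte(minimal_clone_set(obs_all)$optimum,
               minimal_clone_set(obs_less)$optimum)
  }
})

test_that("relaxing a CLONAL call to UNKNOWN never increases the minimum", {
  set.seed(53)
  done <- 0
  for (rep in 1:40) {
    lam <- random_laminar_calls(6, 3, 4)
    idx <- which(lam$calls == "CLONAL")
    if (length(idx) == 0) next
    relaxed <- lam$calls
    relaxed[sample(idx, 1)] <- "UNKNOWN"
    expect_lte(minimal_clone_set(observation_matrix(relaxed))$optimum,
               minimal_clone_set(observation_matrix(lam$calls))$optimum)
    done <- done + 1
  }
  expect_gte(done, 20)
})

test_that("lineage containment holds in solutions and reports binding infeasibility", {
  # consistent nested cohort: DX carries both clones, M1 only the e1 clone
  calls <- matrix(c("CLONAL", "SUBCLONAL",
                    "CLONAL", "ABSENT"),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("DX", "M1"), c("e1", "e2")))
  obs <- observation_matrix(calls, samples = chain_manifest(c("DX", "M1")))
  res <- minimal_clone_set(obs, clone_options(lineage = TRUE))
  sol <- res$solutions[[1]]
  verify_solution(sol, obs, lineage = TRUE)
  expect_true(all(sol$assignment$M1 %in% sol$assignment$DX))
  # re-appearing event: ABSENT in the primary but CLONAL in its secondary is
  # unexplainable when detected assignments must be nested
  calls2 <- matrix(c("ABSENT", "CLONAL"), 2, 1,
                   dimnames = list(c("M1", "M2"), "e1"))
  obs2 <- observation_matrix(calls2, samples = chain_manifest(c("M1", "M2")))
  err <- tryCatch(minimal_clone_set(obs2, clone_options(lineage = TRUE)),
                  clonemin_infeasible_error = function(e) e)
  expect_s3_class(err, "clonemin_infeasible_error")
  expect_true(length(err$binding) > 0)
  # the shared-pool model (lineage off) explains it with one clone each
  expect_equal(minimal_clone_set(obs2, clone_options(lineage = FALSE))$optimum, 2)
})

test_that("second-hit chains constrain candidate genotypes", {
  events <- tibble::tibble(
    event_id = c("del9", "hom9"), chrom = "9", start = c(0, 10),
    end = c(100, 90), alteration_class = "DEL",
    tier = c("FIRST_HIT", "SECOND_HIT"), parent_event_id = c(NA, "del9"))
  calls <- matrix(c("CLONAL", "SUBCLONAL"), 1,
                  dimnames = list("S1", c("del9", "hom9")))
  res <- minimal_clone_set(observation_matrix(calls, events = events))
  expect_equal(res$optimum, 2)
  for (sol in res$solutions) {
    # no clone carries the second hit without the first
    expect_true(all(!sol$clones[, "hom9"] | sol$clones[, "del9"]))
  }
})

test_that("the clone cap fails loudly when set below the requirement need", {
  m <- matrix(c("CLONAL", "ABSENT", "ABSENT",
                "ABSENT", "CLONAL", "ABSENT",
                "ABSENT", "ABSENT", "CLONAL"),
              3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), paste0("e", 1:3)))
  expect_error(minimal_clone_set(observation_matrix(m), clone_options(clone_cap = 2)),
               class = "clonemin_cap_error")
})
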