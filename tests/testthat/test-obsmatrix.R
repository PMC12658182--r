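test_that("default fill is ABSENT for assayed samples and UNKNOWN otherwise", {
  rec <- read_cna_segments(tibble::tibble(
    sample = "M2", chrom = "9", start = 100, end = 900, class = "DEL",
    zygosity = "het", status = "clonal"))
  man <- chain_manifest(c("DX", "M1", "M2"))
  man$assayed <- c(TRUE, TRUE, TRUE)
  obs <- build_observation_matrix(harmonize_events(rec), man)
  expect_equal(unname(obs$calls["M2", 1]), "CLONAL")
  expect_equal(unname(obs$calls["M1", 1]), "ABSENT")  # assayed, unreported
  man$assayed <- c(TRUE, FALSE, TRUE)
  obs2 <- build_observation_matrix(harmonize_events(rec), man)
  expect_equal(unname(obs2$calls["M1", 1]), "UNKNOWN")
})

test_that("all-clonal records give an all-CLONAL matrix", {
  rec <- read_cna_segments(tidyr::crossing(
    sample = c("S1", "S2", "S3"),
    tibble::tibble(chrom = c("1", "12", "17"), start = c(1, 2, 3) * 1e6,
                   end = c(2, 3, 4) * 1e6, class = c("DEL", "DEL", "AMP"),
                   zygosity = c("het", "het", "na"), status = "clonal")))
  obs <- build_observation_matrix(harmonize_events(rec), flat_manifest(c("S1", "S2", "S3")))
  expect_true(all(obs$calls == "CLONAL"))
  expect_equal(dim(obs$calls), c(3, 3))
})

test_that("conflicting explicit statuses for one cell are rejected, duplicates pass", {
  base <- tibble::tibble(sample = "A", chrom = "9", start = 100, end = 900,
                         class = "DEL", zygosity = "het", status = "clonal")
  dup <- dplyr::bind_rows(base, base)
  expect_silent(build_observation_matrix(harmonize_events(read_cna_segments(dup)),
                                         flat_manifest("A")))
  conflict <- dplyr::bind_rows(base, dplyr::mutate(base, status = "subclonal"))
  expect_error(
    build_observation_matrix(harmonize_events(read_cna_segments(conflict)),
                             flat_manifest("A")),
    class = "clonemin_validation_error", regexp = "conflicting statuses")
})

test_that("a second-hit call raises its first-hit parent to at least its level", {
  rec <- read_cna_segments(tibble::tribble(
    ~sample, ~chrom, ~start, ~end, ~class, ~zygosity, ~status,
    "A", "9", 100, 900, "DEL", "het", "clonal",
    "B", "9", 100, 900, "DEL", "hom", "clonal"))  # B has no explicit het row
  obs <- build_observation_matrix(harmonize_events(rec), flat_manifest(c("A", "B")))
  first <- obs$events$event_id[obs$events$tier == "FIRST_HIT"]
  expect_equal(unname(obs$calls["B", first]), "CLONAL")
})

test_that("records for samples missing from the manifest are rejected", {
  rec <- read_cna_segments(tibble::tibble(
    sample = "GHOST", chrom = "9", start = 1, end = 2, class = "DEL",
    zygosity = "het", status = "clonal"))
  expect_error(build_observation_matrix(harmonize_events(rec), flat_manifest("A")),
               class = "clonemin_validation_error", regexp = "GHOST")
})

test_that("zygosity-chain invariant is enforced on construction", {
  events <- tibble::tibble(
    event_id = c("first", "second"), chrom = "9", start = c(0, 10),
    end = c(100, 90), alteration_class = "DEL",
    tier = c("FIRST_HIT", "SECOND_HIT"), parent_event_id = c(NA, "first"))
  calls <- matrix(c("ABSENT", "CLONAL"), nrow = 1,
                  dimnames = list("S1", c("first", "second")))
  expect_error(observation_matrix(calls, events = events),
               class = "clonemin_validation_error", regexp = "second-hit")
})

test_that("write/read round-trips an observation matrix cell-for-cell", {
  obs <- build_observation_matrix(harmonize_events(read_cna_segments(chr9_segments())),
                                  chr9_manifest())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_observation_matrix(obs, tsv_path = tsv, json_path = json)
  back <- read_observation_matrix(json)
  expect_identical(back$calls, obs$calls)
  expect_equal(back$events$event_id, obs$events$event_id)
  expect_equal(back$samples$sample_id, obs$samples$sample_id)
  # TSV holds the same wide matrix
  wide <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(wide$sample_id, rownames(obs$calls))
  expect_equal(unname(as.matrix(wide[, -1])), unname(obs$calls))
})

test_that("tidy and glance summarize an observation matrix", {
  obs <- toy_obs()
  td <- tidy(obs)
  expect_equal(nrow(td), 6)
  expect_setequal(unique(td$call), c("CLONAL", "ABSENT", "SUBCLONAL"))
  g <- glance(obs)
  expect_equal(g$n_samples, 3)
  expect_equal(g$n_subclonal_calls, 1)
})
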