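test_that("identical seed and config give bit-identical case files", {
  cfg <- simulation_config(n_clones = 4, n_loci = 6, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_case(cfg, d1)
  generate_case(cfg, d2)
  for (f in c("segments.tsv", "manifest.tsv", "truth.json", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a single-clone population is the event-free founder", {
  cfg <- simulation_config(n_clones = 1, n_loci = 1, seed = 3)
  truth <- simulate_clone_tree(cfg)
  expect_equal(nrow(truth$genotypes), 1)
  expect_equal(ncol(truth$genotypes), 0)
  expect_equal(nrow(truth$catalog), 0)
})

test_that("p_second_hit = 0 never produces hom-del or cnLOH events", {
  n_second <- 0L
  for (seed in 1:40) {  # ~400 branches in total
    cfg <- simulation_config(n_clones = 11, n_loci = 12, p_second_hit = 0,
                             p_amplification = 0.2, seed = seed)
    truth <- simulate_clone_tree(cfg)
    n_second <- n_second + sum(truth$catalog$tier == "SECOND_HIT")
  }
  expect_equal(n_second, 0L)
})

test_that("second hits respect the zygosity chain and single origin", {
  found <- 0L
  for (seed in 1:15) {
    cfg <- simulation_config(n_clones = 8, n_loci = 10, p_second_hit = 0.8,
                             p_amplification = 0, seed = seed)
    truth <- simulate_clone_tree(cfg)
    sec <- which(truth$catalog$tier == "SECOND_HIT")
    found <- found + length(sec)
    for (i in sec) {
      p <- match(truth$catalog$parent_event_id[i], truth$catalog$event_id)
      expect_true(all(!truth$genotypes[, i] | truth$genotypes[, p]))
      # nested within the parent segment
      expect_gte(truth$catalog$start[i], truth$catalog$start[p])
      expect_lte(truth$catalog$end[i], truth$catalog$end[p])
    }
    # the truth tree is always a valid perfect phylogeny
    expect_true(is_compatible(check_phylogeny(truth$genotypes)))
  }
  expect_gt(found, 10)
})

test_that("a huge bottleneck reproduces the inoculum frequencies", {
  cfg <- simulation_config(n_clones = 5, n_loci = 6, bottleneck_cells = 1e7,
                           n_primary = 2, n_secondary = 1, seed = 8)
  truth <- simulate_clone_tree(cfg)
  cohort <- simulate_cohort(truth, cfg)
  dx <- cohort$frequencies["DX", ]
  for (p in c("P1", "P2")) {
    expect_lt(max(abs(cohort$frequencies[p, ] - dx)), 0.01)
  }
})

test_that("a bottleneck of one cell makes every graft monoclonal and nested", {
  cfg <- simulation_config(n_clones = 5, n_loci = 6, bottleneck_cells = 1,
                           n_primary = 6, n_secondary = 2, seed = 9)
  truth <- simulate_clone_tree(cfg)
  cohort <- simulate_cohort(truth, cfg)
  freq <- cohort$frequencies
  mice <- setdiff(rownames(freq), "DX")
  expect_true(all(rowSums(freq[mice, , drop = FALSE] > 0) == 1))
  # a clone absent from a primary is absent from all its secondaries
  for (i in which(!is.na(cohort$manifest$parent_sample) &
                  cohort$manifest$parent_sample != "DX")) {
    s <- cohort$manifest$sample_id[i]
    p <- cohort$manifest$parent_sample[i]
    expect_true(all(freq[p, freq[s, ] > 0] > 0))
  }
})

test_that("censoring thresholds have the stated boundary semantics", {
  cfg <- simulation_config(n_clones = 3, n_loci = 4, seed = 5,
                           detect_absent = 0.05, detect_clonal = 0.95)
  truth <- simulate_clone_tree(cfg)
  cohort <- list(
    frequencies = matrix(c(1, 0, 0,
                           0, 1, 0,
                           0.5, 0.5, 0), nrow = 3, byrow = TRUE,
                         dimnames = list(c("A", "B", "C"),
                                         rownames(truth$genotypes))),
    manifest = flat_manifest(c("A", "B", "C")))
  obs <- observe_cohort(truth, cohort, cfg)
  f <- cohort$frequencies %*% truth$genotypes
  expect_true(all(obs$calls[f == 0] == "ABSENT"))
  expect_true(all(obs$calls[f == 1] == "CLONAL"))
  expect_true(all(obs$calls[f > 0.05 & f < 0.95] == "SUBCLONAL"))
  # lowering the clonal threshold never turns CLONAL into SUBCLONAL
  cfg2 <- cfg; cfg2$detect_clonal <- 0.80
  obs2 <- observe_cohort(truth, cohort, cfg2)
  expect_true(all(obs2$calls[obs$calls == "CLONAL"] == "CLONAL"))
})

test_that("emitted files parse back into the same observation matrix", {
  cfg <- simulation_config(n_clones = 5, n_loci = 7, p_second_hit = 0.5,
                           bottleneck_cells = 50, n_primary = 3,
                           n_secondary = 1, seed = 42)
  case <- generate_case(cfg, withr::local_tempdir())
  rec <- read_cna_segments(case$paths$segments)
  man <- read_sample_manifest(case$paths$manifest)
  obs <- build_observation_matrix(harmonize_events(rec), man)
  expect_setequal(colnames(obs$calls), colnames(case$obs$calls))
  expect_identical(obs$calls[, colnames(case$obs$calls)], case$obs$calls)
})

test_that("with perfect detection and monoclonal grafts the range collapses to the truth", {
  # n_clones = 3, every clone pinned by at least one mouse
  found <- FALSE
  for (seed in 1:20) {
    cfg <- simulation_config(n_clones = 3, n_loci = 5, bottleneck_cells = 1,
                             n_primary = 6, n_secondary = 1,
                             detect_absent = 0, detect_clonal = 1, seed = seed)
    truth <- simulate_clone_tree(cfg)
    cohort <- simulate_cohort(truth, cfg)
    mice <- setdiff(rownames(cohort$frequencies), "DX")
    seen <- unique(apply(cohort$frequencies[mice, , drop = FALSE], 1, which.max))
    if (length(seen) < 3) next
    found <- TRUE
    obs <- observe_cohort(truth, cohort, cfg)
    fit <- minimal_clone_range(obs)
    expect_equal(c(fit$min_clones, fit$max_clones), c(3L, 3L))
    break
  }
  expect_true(found)
})

test_that("a clone hidden below threshold everywhere understates the clone count", {
  # chain truth {} -> {e1} -> {e1,e2}; the deepest clone never exceeds the
  # absence threshold, so its private event vanishes and the minimum drops
  cfg <- simulation_config(n_clones = 3, n_loci = 4, seed = 21,
                           detect_absent = 0.1, detect_clonal = 0.9)
  truth <- simulate_clone_tree(cfg)
  geno <- matrix(c(FALSE, FALSE,
                   TRUE, FALSE,
                   TRUE, TRUE), nrow = 3, byrow = TRUE,
                 dimnames = list(c("T1", "T2", "T3"), c("e1", "e2")))
  catalog <- tibble::tibble(
    event_id = c("e1", "e2"), chrom = c("9", "14"), start = c(0, 0),
    end = c(1e6, 1e6), alteration_class = "DEL", tier = "FIRST_HIT",
    parent_event_id = NA_character_)
  truth$genotypes <- geno
  truth$catalog <- catalog
  freq <- matrix(c(0.5, 0.42, 0.08,
                   0.45, 0.5, 0.05), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), rownames(geno)))
  cohort <- list(frequencies = freq, manifest = flat_manifest(c("A", "B")))
  obs <- observe_cohort(truth, cohort, cfg)
  expect_true(all(obs$calls[, "e2"] == "ABSENT"))
  fit <- minimal_clone_range(obs, clone_options(lineage = FALSE))
  expect_lt(fit$max_clones, 3)
})

test_that("simulation configs validate their parameter ranges", {
  expect_error(simulation_config(detect_absent = 0.9, detect_clonal = 0.5),
               class = "clonemin_validation_error")
  expect_error(simulation_config(n_clones = 0), class = "clonemin_validation_error")
  expect_error(simulation_config(n_clones = 5, n_loci = 2),
               class = "clonemin_validation_error")
  expect_error(simulation_config(bottleneck_cells = 0),
               class = "clonemin_validation_error")
  # YAML round trip
  p <- withr::local_tempfile(fileext = ".yaml")
  cfg <- simulation_config(n_clones = 4, n_loci = 6, seed = 11)
  write_simulation_config(cfg, p)
  expect_equal(read_simulation_config(p), cfg)
})
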