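# Shared fixture builders: everything is generated in code.

# flat manifest of assayed patient samples
flat_manifest <- function(sample_ids, assayed = TRUE) {
  tibble::tibble(
    sample_id = sample_ids, patient = "P1", timepoint = "DIAGNOSIS",
    compartment = "BULK", host = "PATIENT", parent_sample = NA_character_,
    assayed = assayed
  )
}

# patient -> primary -> secondary chain manifest
chain_manifest <- function(ids = c("DX", "M1", "M2"), assayed = TRUE) {
  tibble::tibble(
    sample_id = ids, patient = "P1", timepoint = "DIAGNOSIS",
    compartment = "BULK",
    host = c("PATIENT", "PRIMARY_XENO", "SECONDARY_XENO")[seq_along(ids)],
    parent_sample = c(NA_character_, ids[-length(ids)]),
    assayed = assayed
  )
}

# the worked 3-sample toy: minimum is 2 with clones {e1} and {e1, e2}
toy_obs <- function() {
  m <- matrix(c("CLONAL", "ABSENT",
                "CLONAL", "CLONAL",
                "CLONAL", "SUBCLONAL"),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"), c("e1", "e2")))
  observation_matrix(m)
}

# chr9-style zygosity-chain segment table: het deletion everywhere, a
# homozygous deletion in one mouse and cnLOH in another, plus a chr14 del
chr9_segments <- function() {
  tibble::tribble(
    ~sample, ~chrom, ~start, ~end, ~class, ~zygosity, ~status,
    "DX", "9", 21000000, 22500000, "DEL", "het", "clonal",
    "M1", "9", 21000000, 22500000, "DEL", "het", "clonal",
    "M1", "9", 21200000, 22300000, "DEL", "hom", "subclonal",
    "M2", "9", 21000000, 22500000, "DEL", "het", "clonal",
    "M2", "9", 21200000, 22300000, "CNLOH", "cnloh", "subclonal",
    "DX", "14", 50000000, 51000000, "DEL", "het", "subclonal",
    "M1", "14", 50000000, 51000000, "DEL", "het", "clonal"
  )
}

chr9_manifest <- function() {
  tibble::tibble(
    sample_id = c("DX", "M1", "M2"), patient = "PT",
    timepoint = "DIAGNOSIS", compartment = "BULK",
    host = c("PATIENT", "PRIMARY_XENO", "PRIMARY_XENO"),
    parent_sample = c(NA, "DX", "DX"), assayed = TRUE
  )
}

# random laminar truth: grows a genotype tree (every clone adds one private
# event to a random existing genotype), then projects random per-sample
# clone subsets to calls — the data shape the model assumes, always feasible
random_laminar_calls <- function(n_events_max = 6L, n_samples = 3L,
                                 n_clones_max = 4L) {
  k <- sample.int(n_clones_max, 1)
  geno <- matrix(FALSE, nrow = 1, ncol = n_events_max,
                 dimnames = list(NULL, paste0("e", seq_len(n_events_max))))
  used <- 0L
  while (nrow(geno) < k && used < n_events_max) {
    parent <- sample.int(nrow(geno), 1)
    gain <- min(sample(1:2, 1, prob = c(0.6, 0.4)), n_events_max - used)
    g <- geno[parent, ]
    g[used + seq_len(gain)] <- TRUE
    used <- used + gain
    geno <- rbind(geno, g)
  }
  geno <- geno[, seq_len(max(used, 1L)), drop = FALSE]
  E <- ncol(geno)
  calls <- matrix("ABSENT", nrow = n_samples, ncol = E,
                  dimnames = list(paste0("S", seq_len(n_samples)), colnames(geno)))
  for (s in seq_len(n_samples)) {
    present <- which(stats::runif(nrow(geno)) < 0.6)
    if (length(present) == 0) present <- sample.int(nrow(geno), 1)
    frac <- colSums(geno[present, , drop = FALSE]) / length(present)
    calls[s, frac == 1] <- "CLONAL"
    calls[s, frac > 0 & frac < 1] <- "SUBCLONAL"
  }
  list(calls = calls, n_true = nrow(geno), genotypes = geno)
}

# raw i.i.d. random calls (may be infeasible)
random_iid_calls <- function(E, S, p_unknown = 0) {
  lv <- c("ABSENT", "SUBCLONAL", "CLONAL")
  m <- matrix(sample(lv, S * E, replace = TRUE, prob = c(0.35, 0.3, 0.35)),
              nrow = S, dimnames = list(paste0("S", seq_len(S)),
                                        paste0("e", seq_len(E))))
  if (p_unknown > 0) m[stats::runif(length(m)) < p_unknown] <- "UNKNOWN"
  m
}

min_or_inf <- function(obs, options = clone_options(lineage = FALSE)) {
  tryCatch(minimal_clone_set(obs, options)$optimum,
           clonemin_infeasible_error = function(e) Inf,
           clonemin_cap_error = function(e) Inf)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "clonemin", mustWork = TRUE)
}
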