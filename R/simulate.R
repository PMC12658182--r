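# Synthetic cohorts with the statistical structure the inference assumes:
# a branching clone tree gaining breakpoint-specific CNA events (including
# het-del -> hom-del / cnLOH zygosity progressions), Dirichlet diagnostic
# clone frequencies, multinomial transplant bottlenecks respecting lineage,
# and per-event detection censoring into {ABSENT, SUBCLONAL, CLONAL}.

#' Simulation configuration
#'
#' @param n_clones Number of clones including the event-free founder
#'   (`n_clones = 1` simulates a root-only, CNA-free population).
#' @param n_loci Number of genomic loci available for first-hit events; must
#'   be at least `n_clones - 1` since every branch gains a fresh breakpoint.
#' @param p_second_hit Probability that a branch whose ancestry carries a
#'   heterozygous deletion completes it with a second hit (homozygous
#'   deletion or cnLOH, equiprobable among the types still unused at that
#'   locus).
#' @param p_amplification Probability a first hit is an amplification rather
#'   than a deletion (amplifications take no second hit).
#' @param frequency_concentration Dirichlet concentration for diagnostic
#'   clone frequencies (1 = uniform on the simplex).
#' @param n_primary Primary transplanted mice.
#' @param n_secondary Secondary mice per primary mouse.
#' @param bottleneck_cells Cells sampled at each transplant bottleneck
#'   (multinomial size); 1 makes every graft monoclonal.
#' @param detect_absent Carrier-fraction threshold at or below which an event
#'   is called ABSENT (array sensitivity floor).
#' @param detect_clonal Carrier-fraction threshold at or above which an event
#'   is called CLONAL. Must exceed `detect_absent`.
#' @param seed Integer seed; one shared random stream per case.
#' @param genome_build Label carried through to output.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_clones = 6L, n_loci = 10L, p_second_hit = 0.25,
                              p_amplification = 0.1, frequency_concentration = 1,
                              n_primary = 4L, n_secondary = 2L,
                              bottleneck_cells = 200L,
                              detect_absent = 0.05, detect_clonal = 0.95,
                              seed = 1L, genome_build = "GRCh38") {
  cfg <- list(n_clones = as.integer(n_clones), n_loci = as.integer(n_loci),
              p_second_hit = p_second_hit, p_amplification = p_amplification,
              frequency_concentration = frequency_concentration,
              n_primary = as.integer(n_primary), n_secondary = as.integer(n_secondary),
              bottleneck_cells = as.integer(bottleneck_cells),
              detect_absent = detect_absent, detect_clonal = detect_clonal,
              seed = as.integer(seed), genome_build = genome_build)
  if (cfg$n_clones < 1) abort_invalid("n_clones must be >= 1")
  if (cfg$n_loci < cfg$n_clones - 1) abort_invalid("n_loci must be >= n_clones - 1")
  if (cfg$bottleneck_cells < 1) abort_invalid("bottleneck_cells must be >= 1")
  if (!(cfg$detect_absent >= 0 && cfg$detect_absent < cfg$detect_clonal &&
        cfg$detect_clonal <= 1)) {
    abort_invalid("detection thresholds must satisfy 0 <= detect_absent < detect_clonal <= 1")
  }
  for (p in c("p_second_hit", "p_amplification")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort_invalid(sprintf("%s must be in [0, 1]", p))
  }
  if (cfg$frequency_concentration <= 0) {
    abort_invalid("frequency_concentration must be positive")
  }
  structure(cfg, class = "simulation_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_simulation_config()]: a `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_config, vals[intersect(names(vals), names(formals(simulation_config)))])
}

#' @rdname read_simulation_config
#' @param config A `simulation_config`.
#' @return [write_simulation_config()]: `config`, invisibly.
#' @export
write_simulation_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' Simulate a clone tree with CNA events
#'
#' Grows a random rooted tree with `n_clones` clones: the founder carries no
#' events; every later clone attaches to a uniformly chosen existing clone
#' and its branch gains one first-hit event at an unused locus (deletion, or
#' amplification with probability `p_amplification`), plus — with probability
#' `p_second_hit` when its ancestry carries an uncompleted heterozygous
#' deletion — a matching second hit (homozygous deletion or cnLOH) nested
#' inside the first hit's segment. Each (locus, second-hit type) arises at
#' most once tree-wide, preserving single-origin evolution. Reproducible
#' from `config$seed` (the seed opens the case's shared random stream; the
#' cohort simulation continues it).
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_truth` (without frequencies yet):
#'   `tree` (a `clone_tree`), `genotypes` (clones x events logical matrix),
#'   `catalog` (event tibble in the harmonized format), `parents` (parent
#'   clone index per clone, 0 for the founder), `config`.
#' @export
simulate_clone_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_clones
  loci <- tibble(
    locus = seq_len(config$n_loci),
    chrom = as.character(sample(c(1:22, "X"), config$n_loci, replace = TRUE)),
    win_start = 1e6 + (seq_len(config$n_loci) - 1) * 5e6
  )
  events <- list()
  first_hit_of_locus <- rep(NA_character_, config$n_loci)
  second_types_used <- lapply(seq_len(config$n_loci), function(i) character(0))
  geno <- matrix(FALSE, nrow = n, ncol = 0)
  parents <- integer(n)
  event_locus <- integer(0)
  unused <- seq_len(config$n_loci)

  add_event <- function(row) {
    events[[row$event_id]] <<- as_tibble(row)
    geno <<- cbind(geno, FALSE)
    colnames(geno)[ncol(geno)] <<- row$event_id
  }

  for (i in seq_len(n)) {
    if (i == 1) { parents[i] <- 0L; next }
    parents[i] <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    geno[i, ] <- geno[parents[i], ]
    # first hit at a fresh locus
    li <- unused[sample.int(length(unused), 1L)]
    unused <- setdiff(unused, li)
    is_amp <- runif(1) < config$p_amplification
    start <- loci$win_start[li] + floor(runif(1) * 5e5)
    end <- start + 1e6 + floor(runif(1) * 1e6)
    cat0 <- if (is_amp) "amp" else "del"
    eid <- .event_label(cat0, loci$chrom[li], start, end)
    add_event(list(event_id = eid, chrom = loci$chrom[li], start = start, end = end,
                   alteration_class = if (is_amp) "AMP" else "DEL",
                   tier = "FIRST_HIT", parent_event_id = NA_character_))
    event_locus <- c(event_locus, li)
    if (!is_amp) first_hit_of_locus[li] <- eid
    geno[i, eid] <- TRUE
    # optional second hit completing an inherited het deletion
    path_first <- which(geno[i, ] &
                        vapply(events, function(e) e$tier == "FIRST_HIT" &&
                                 e$alteration_class == "DEL", logical(1))[colnames(geno)])
    eligible <- integer(0)
    for (j in path_first) {
      lj <- event_locus[j]
      has_second <- any(geno[i, ] & vapply(events, function(e) {
        e$tier == "SECOND_HIT" && identical(e$parent_event_id, colnames(geno)[j])
      }, logical(1))[colnames(geno)])
      types_left <- setdiff(c("homdel", "cnloh"), second_types_used[[lj]])
      if (!has_second && length(types_left)) eligible <- c(eligible, j)
    }
    if (length(eligible) && runif(1) < config$p_second_hit) {
      j <- eligible[sample.int(length(eligible), 1L)]
      lj <- event_locus[j]
      types_left <- setdiff(c("homdel", "cnloh"), second_types_used[[lj]])
      ty <- types_left[sample.int(length(types_left), 1L)]
      second_types_used[[lj]] <- c(second_types_used[[lj]], ty)
      pe <- events[[colnames(geno)[j]]]
      margin <- floor((pe$end - pe$start) * 0.1)
      s2 <- pe$start + margin; e2 <- pe$end - margin
      eid2 <- .event_label(ty, pe$chrom, s2, e2)
      add_event(list(event_id = eid2, chrom = pe$chrom, start = s2, end = e2,
                     alteration_class = if (ty == "homdel") "DEL" else "CNLOH",
                     tier = "SECOND_HIT", parent_event_id = pe$event_id))
      event_locus <- c(event_locus, lj)
      geno[i, eid2] <- TRUE
    }
  }
  rownames(geno) <- paste0("T", seq_len(n))
  catalog <- bind_rows(events)
  if (nrow(catalog)) {
    ord <- order(chrom_order_key(catalog$chrom), catalog$start, catalog$end,
                 catalog$tier, catalog$event_id)
    catalog <- catalog[ord, , drop = FALSE]
    geno <- geno[, catalog$event_id, drop = FALSE]
  } else {
    catalog <- tibble(event_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      alteration_class = character(0), tier = character(0),
                      parent_event_id = character(0))
  }
  structure(list(tree = build_clone_tree(geno), genotypes = geno,
                 catalog = catalog, parents = parents, config = config),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d clones, %d events (%d second hits), seed %d\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$catalog$tier == "SECOND_HIT"), x$config$seed))
  invisible(x)
}

#' Simulate a serial-transplant cohort from a clone tree
#'
#' Diagnostic clone frequencies are Dirichlet(`frequency_concentration`);
#' each primary mouse draws `bottleneck_cells` cells multinomially from the
#' diagnostic frequencies and each secondary mouse re-draws from its own
#' primary parent, so clone support is nested along the lineage by
#' construction. Continues the random stream opened by
#' [simulate_clone_tree()] (call them in order for a reproducible case, or
#' use [generate_case()]).
#'
#' @param truth A `synthetic_truth` from [simulate_clone_tree()].
#' @param config The same [simulation_config()].
#' @return A list with `frequencies` (samples x clones matrix, rows sum to
#'   1) and `manifest` (tibble in the sample-manifest format).
#' @export
simulate_cohort <- function(truth, config) {
  n <- config$n_clones
  alpha <- rep(config$frequency_concentration, n)
  g <- rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)
  dx <- g / sum(g)
  rows <- list(DX = dx)
  manifest <- list(tibble(sample_id = "DX", patient = "PT1", timepoint = "DIAGNOSIS",
                          compartment = "BULK", host = "PATIENT",
                          parent_sample = NA_character_, assayed = TRUE))
  for (p in seq_len(config$n_primary)) {
    pid <- paste0("P", p)
    fp <- as.vector(rmultinom(1, config$bottleneck_cells, dx)) / config$bottleneck_cells
    rows[[pid]] <- fp
    manifest[[length(manifest) + 1L]] <- tibble(
      sample_id = pid, patient = "PT1", timepoint = "DIAGNOSIS",
      compartment = "BULK", host = "PRIMARY_XENO", parent_sample = "DX", assayed = TRUE)
    for (s in seq_len(config$n_secondary)) {
      sid <- paste0("S", p, ".", s)
      fs <- as.vector(rmultinom(1, config$bottleneck_cells, fp)) / config$bottleneck_cells
      rows[[sid]] <- fs
      manifest[[length(manifest) + 1L]] <- tibble(
        sample_id = sid, patient = "PT1", timepoint = "DIAGNOSIS",
        compartment = "BULK", host = "SECONDARY_XENO", parent_sample = pid, assayed = TRUE)
    }
  }
  freq <- do.call(rbind, rows)
  colnames(freq) <- rownames(truth$genotypes)
  list(frequencies = freq, manifest = bind_rows(manifest))
}

#' Censor clone frequencies into an observation matrix
#'
#' For every sample and event the carrier fraction `f` is the summed
#' frequency of carrier clones; the call is `ABSENT` if `f <= detect_absent`,
#' `CLONAL` if `f >= detect_clonal`, `SUBCLONAL` otherwise. This is the
#' detection-threshold censoring through which sub-threshold clones hide
#' until transplantation expands them.
#'
#' @param truth A `synthetic_truth`.
#' @param cohort Output of [simulate_cohort()].
#' @param config The [simulation_config()] (only the thresholds are used,
#'   so censoring can be re-applied at different thresholds).
#' @return A `clone_obs`.
#' @export
observe_cohort <- function(truth, cohort, config) {
  f <- cohort$frequencies %*% truth$genotypes
  eps <- 1e-9
  calls <- matrix("SUBCLONAL", nrow = nrow(f), ncol = ncol(f),
                  dimnames = dimnames(f))
  calls[f <= config$detect_absent + eps] <- "ABSENT"
  calls[f >= config$detect_clonal - eps] <- "CLONAL"
  new_clone_obs(cohort$manifest, truth$catalog, calls)
}

#' Generate a complete synthetic case on disk
#'
#' Runs tree, cohort and censoring simulation from one seeded stream and
#' writes the segment table and manifest in the exact formats read by
#' [read_cna_segments()] / [read_sample_manifest()], plus the ground truth
#' as JSON and the configuration as YAML. Running the inference pipeline on
#' the emitted files is the package's main integration test.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `truth`, `cohort`, `obs` (the censored
#'   `clone_obs`) and `paths`.
#' @export
generate_case <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- simulate_clone_tree(config)
  cohort <- simulate_cohort(truth, config)
  obs <- observe_cohort(truth, cohort, config)
  paths <- list(segments = file.path(dir, "segments.tsv"),
                manifest = file.path(dir, "manifest.tsv"),
                truth = file.path(dir, "truth.json"),
                config = file.path(dir, "config.yaml"))
  write_segment_table(obs, paths$segments)
  readr::write_tsv(cohort$manifest, paths$manifest)
  jsonlite::write_json(list(
    config = unclass(config),
    clones = rownames(truth$genotypes),
    parents = truth$parents,
    genotypes = lapply(seq_len(nrow(truth$genotypes)), function(i) {
      as.list(colnames(truth$genotypes)[truth$genotypes[i, ]])
    }),
    frequencies = lapply(seq_len(nrow(cohort$frequencies)), function(i) {
      list(sample_id = rownames(cohort$frequencies)[i],
           freq = as.vector(cohort$frequencies[i, ]))
    })
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  write_simulation_config(config, paths$config)
  invisible(list(truth = truth, cohort = cohort, obs = obs, paths = paths))
}

#' Write an observation matrix as a segment-call table
#'
#' Emits one row per detected (non-ABSENT, non-UNKNOWN) cell in the format
#' read by [read_cna_segments()], encoding tier and class through the
#' class/zygosity columns (first-hit DEL -> del/het, homozygous second hit ->
#' del/hom, cnLOH -> cnloh, AMP -> amp).
#'
#' @param obs A `clone_obs`.
#' @param path Output TSV path.
#' @return `obs`, invisibly.
#' @export
write_segment_table <- function(obs, path) {
  ev <- obs$events
  rows <- list()
  for (s in rownames(obs$calls)) {
    for (j in seq_len(ncol(obs$calls))) {
      st <- obs$calls[s, j]
      if (st %in% c("ABSENT", "UNKNOWN")) next
      cls <- ev$alteration_class[j]
      zyg <- if (cls == "AMP") "na"
             else if (cls == "CNLOH") "cnloh"
             else if (ev$tier[j] == "SECOND_HIT") "hom" else "het"
      rows[[length(rows) + 1L]] <- tibble(
        sample = s, chrom = ev$chrom[j], start = ev$start[j], end = ev$end[j],
        class = if (cls == "CNLOH") "CNLOH" else cls, zygosity = zyg,
        status = tolower(st))
    }
  }
  tab <- if (length(rows)) bind_rows(rows) else {
    tibble(sample = character(0), chrom = character(0), start = numeric(0),
           end = numeric(0), class = character(0), zygosity = character(0),
           status = character(0))
  }
  readr::write_tsv(tab, path)
  invisible(obs)
}
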