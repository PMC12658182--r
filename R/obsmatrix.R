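# ObservationMatrix container: samples x events with calls in
# {ABSENT, SUBCLONAL, CLONAL, UNKNOWN}, plus sample metadata, event catalog
# and transplant lineage.

new_clone_obs <- function(samples, events, calls, ambiguities = NULL) {
  obj <- structure(list(
    samples = as_tibble(samples),
    events = as_tibble(events),
    calls = calls,
    ambiguities = ambiguities %||% list(merge = list(), link = list())
  ), class = "clone_obs")
  validate_clone_obs(obj)
}

#' Validate an observation matrix
#'
#' Checks dimensions, call values, and the zygosity-chain invariant that a
#' second-hit event is never called more clonal than its first-hit parent in
#' any sample (a homozygous deletion cannot outnumber the heterozygous
#' deletion it completes).
#'
#' @param obs A `clone_obs` object.
#' @return `obs`, invisibly usable, after validation (errors otherwise).
#' @export
validate_clone_obs <- function(obs) {
  calls <- obs$calls
  if (!is.matrix(calls) || !identical(rownames(calls), obs$samples$sample_id) ||
      !identical(colnames(calls), obs$events$event_id)) {
    abort_invalid("calls matrix must have sample_id rownames and event_id colnames")
  }
  bad <- !calls %in% call_levels()
  if (any(bad)) {
    abort_invalid(sprintf("invalid call value '%s'", calls[which(bad)[1]]))
  }
  ev <- obs$events
  # second hits whose parent is still ambiguous are validated only after a
  # resolution fixes the linking
  ambiguous_links <- vapply(obs$ambiguities$link, function(l) l$event_id, character(1))
  sec <- setdiff(which(ev$tier == "SECOND_HIT"),
                 match(ambiguous_links, ev$event_id))
  for (i in sec) {
    p <- match(ev$parent_event_id[i], ev$event_id)
    if (is.na(p)) {
      abort_invalid(sprintf("second-hit event '%s' references unknown parent '%s'",
                            ev$event_id[i], ev$parent_event_id[i]))
    }
    child <- .call_rank[calls[, i]]
    parent <- .call_rank[calls[, p]]
    viol <- which(!is.na(child) & !is.na(parent) & child > parent)
    if (length(viol)) {
      abort_invalid(sprintf(
        "sample '%s': second-hit event '%s' called %s while first-hit '%s' is %s",
        rownames(calls)[viol[1]], ev$event_id[i], calls[viol[1], i],
        ev$parent_event_id[i], calls[viol[1], p]))
    }
  }
  obs
}

#' Build the samples-by-events observation matrix
#'
#' Maps each harmonized record's status onto its event. Events never reported
#' in a sample default to `ABSENT` if the sample was assayed (supplementary
#' mosaicism tables report detected CNAs only) and to `UNKNOWN` if the
#' manifest flags the sample as unassayed. A homozygous-deletion or cnLOH
#' record additionally implies the presence of its first-hit deletion, so the
#' parent's call is raised to at least the second hit's call where no explicit
#' record contradicts it.
#'
#' @param catalog A `cna_catalog` from [harmonize_events()].
#' @param manifest Tibble from [read_sample_manifest()].
#' @return A `clone_obs` object.
#' @export
build_observation_matrix <- function(catalog, manifest) {
  stopifnot(inherits(catalog, "cna_catalog"))
  manifest <- as_tibble(manifest)
  if (!"assayed" %in% names(manifest)) manifest$assayed <- TRUE
  rec <- catalog$records
  unknown_samples <- setdiff(unique(rec$sample_id), manifest$sample_id)
  if (length(unknown_samples)) {
    abort_invalid(sprintf("segment record for sample '%s' absent from manifest",
                          unknown_samples[1]))
  }
  ev <- catalog$events
  sid <- manifest$sample_id
  eid <- ev$event_id
  calls <- matrix(ifelse(rep(manifest$assayed, times = length(eid)), "ABSENT", "UNKNOWN"),
                  nrow = length(sid), ncol = length(eid),
                  dimnames = list(sid, eid))
  explicit <- matrix(NA_integer_, nrow = length(sid), ncol = length(eid),
                     dimnames = list(sid, eid))
  for (r in seq_len(nrow(rec))) {
    s <- rec$sample_id[r]; e <- rec$event_id[r]; st <- rec$status[r]
    prev <- explicit[s, e]
    if (!is.na(prev)) {
      if (!identical(calls[s, e], st)) {
        abort_invalid(sprintf(
          "conflicting statuses for sample '%s', event '%s': rows %d (%s) and %d (%s)",
          s, e, prev, calls[s, e], rec$.row[r], st))
      }
      next
    }
    calls[s, e] <- st
    explicit[s, e] <- rec$.row[r]
  }
  # derived first-hit presence from second-hit records (a homozygous deletion
  # implies the heterozygous deletion beneath it); deferred for second hits
  # whose parent linking is ambiguous — resolutions re-derive it
  ambiguous_links <- vapply(catalog$link_ambiguities, function(l) l$event_id, character(1))
  sec <- setdiff(which(ev$tier == "SECOND_HIT"), match(ambiguous_links, ev$event_id))
  for (i in sec) {
    p <- match(ev$parent_event_id[i], eid)
    child_rank <- .call_rank[calls[, i]]
    parent_rank <- .call_rank[calls[, p]]
    raise <- which(!is.na(child_rank) & !is.na(parent_rank) & child_rank > parent_rank)
    for (s in raise) {
      if (!is.na(explicit[s, p])) {
        abort_invalid(sprintf(
          "sample '%s': explicit %s call for first-hit '%s' contradicts second-hit '%s' (%s)",
          sid[s], calls[s, p], eid[p], eid[i], calls[s, i]))
      }
      calls[s, p] <- calls[s, i]
    }
  }
  new_clone_obs(manifest, ev, calls,
                ambiguities = list(merge = catalog$merge_ambiguities,
                                   link = catalog$link_ambiguities))
}

#' @export
print.clone_obs <- function(x, ...) {
  tab <- table(factor(x$calls, levels = call_levels()))
  cat(sprintf("<clone_obs> %d samples x %d events\n", nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  calls: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  ambiguities: %d merge, %d link\n",
              length(x$ambiguities$merge), length(x$ambiguities$link)))
  invisible(x)
}

#' Long-format calls of an observation matrix
#'
#' @param x A `clone_obs`.
#' @param ... Unused.
#' @return Tibble with one row per (sample, event) cell: `sample_id`,
#'   `event_id`, `call`.
#' @export
tidy.clone_obs <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x$calls), times = ncol(x$calls)),
    event_id = rep(colnames(x$calls), each = nrow(x$calls)),
    call = as.vector(x$calls)
  )
}

#' @export
glance.clone_obs <- function(x, ...) {
  tibble(
    n_samples = nrow(x$calls), n_events = ncol(x$calls),
    n_assayed = sum(x$samples$assayed),
    n_subclonal_calls = sum(x$calls == "SUBCLONAL"),
    n_merge_ambiguities = length(x$ambiguities$merge),
    n_link_ambiguities = length(x$ambiguities$link)
  )
}

#' Write an observation matrix to TSV and JSON
#'
#' The TSV holds the samples-by-events call matrix; the JSON holds the full
#' object (samples, events with zygosity links, calls, ambiguity report) and
#' round-trips through [read_observation_matrix()] cell-for-cell.
#'
#' @param obs A `clone_obs`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return `obs`, invisibly.
#' @export
write_observation_matrix <- function(obs, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    wide <- as.data.frame(obs$calls)
    wide <- cbind(sample_id = rownames(obs$calls), wide)
    readr::write_tsv(as_tibble(wide), tsv_path)
  }
  if (!is.null(json_path)) {
    payload <- list(
      samples = obs$samples,
      events = obs$events,
      calls = list(sample_id = rownames(obs$calls),
                   event_id = colnames(obs$calls),
                   values = lapply(seq_len(nrow(obs$calls)), function(i) {
                     as.list(unname(obs$calls[i, ]))
                   })),
      ambiguities = obs$ambiguities
    )
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(obs)
}

#' Read an observation matrix written by [write_observation_matrix()]
#'
#' @param json_path Path to the JSON serialization.
#' @return A `clone_obs`.
#' @export
read_observation_matrix <- function(json_path) {
  payload <- jsonlite::read_json(json_path)
  samples <- bind_rows(lapply(payload$samples, function(r) {
    as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  samples$parent_sample <- as.character(samples$parent_sample)
  events <- bind_rows(lapply(payload$events, function(r) {
    as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  events$parent_event_id <- as.character(events$parent_event_id)
  sid <- unlist(payload$calls$sample_id)
  eid <- unlist(payload$calls$event_id)
  calls <- matrix(unlist(payload$calls$values), nrow = length(sid),
                  ncol = length(eid), byrow = TRUE, dimnames = list(sid, eid))
  amb <- list(
    merge = lapply(payload$ambiguities$merge, function(m) {
      k <- length(m$events)
      list(events = unlist(m$events),
           can_merge = matrix(unlist(m$can_merge), nrow = k, ncol = k))
    }),
    link = lapply(payload$ambiguities$link, function(l) {
      list(event_id = l$event_id, candidates = unlist(l$candidates))
    })
  )
  new_clone_obs(samples, events, calls, ambiguities = amb)
}

#' Construct an observation matrix directly from components
#'
#' Convenience constructor for analyses (and tests) that already have an
#' event catalog and a call matrix, bypassing file input.
#'
#' @param calls Character matrix (samples x events) over [call_levels()], or a
#'   data frame convertible to one; dimnames are taken as sample and event
#'   ids.
#' @param samples Optional manifest tibble; defaults to a flat manifest of
#'   assayed patient samples.
#' @param events Optional event catalog tibble; defaults to first-hit DEL
#'   events, one per column.
#' @return A `clone_obs`.
#' @export
observation_matrix <- function(calls, samples = NULL, events = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("e", seq_len(ncol(calls)))
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = rownames(calls), patient = "P1", timepoint = "DIAGNOSIS",
      compartment = "BULK", host = "PATIENT", parent_sample = NA_character_,
      assayed = TRUE
    )
  }
  if (!"assayed" %in% names(samples)) samples$assayed <- TRUE
  if (is.null(events)) {
    events <- tibble(
      event_id = colnames(calls), chrom = as.character(seq_len(ncol(calls))),
      start = 0, end = 1000, alteration_class = "DEL", tier = "FIRST_HIT",
      parent_event_id = NA_character_
    )
  }
  new_clone_obs(samples, events, calls)
}
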