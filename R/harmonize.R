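# Harmonization of per-sample CNA segment records into a cross-sample event
# catalog with zygosity-chain (first hit -> second hit) structure.

# union-find
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) { while (uf[i] != i) i <- uf[i]; i }
.uf_union <- function(uf, i, j) {
  ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
  if (ri != rj) uf[max(ri, rj)] <- min(ri, rj)
  uf
}

# category used for merging: records are only ever merged within a category
.record_category <- function(alteration_class, zygosity) {
  ifelse(alteration_class == "AMP", "amp",
    ifelse(zygosity == "HOM", "homdel",
      ifelse(zygosity == "CNLOH", "cnloh", "del")))
}

.event_label <- function(category, chrom, start, end) {
  sprintf("%s_%s_%d_%d", category, chrom, as.integer(start), as.integer(end))
}

# merge records of one (chrom, category) block; returns per-record block id
# via transitive closure of "both endpoints within tolerance"
.merge_blocks <- function(start, end, tolerance) {
  n <- length(start)
  uf <- .uf_new(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (abs(start[i] - start[j]) <= tolerance && abs(end[i] - end[j]) <= tolerance) {
          uf <- .uf_union(uf, i, j)
        }
      }
    }
  }
  vapply(seq_len(n), function(i) .uf_find(uf, i), integer(1))
}

#' Harmonize segment records into an event catalog
#'
#' Segments from different samples are merged into one first-hit event iff
#' they share chromosome and alteration category and both endpoints lie
#' within `tolerance` base pairs (by transitive closure, so merged groups can
#' drift beyond the pairwise tolerance; the merged segment is the hull of its
#' members). Homozygous-deletion and cnLOH records spawn second-hit events
#' linked to an overlapping first-hit heterozygous deletion; where several
#' linkings or near-miss merges (within `ambiguity_tolerance` but not
#' `tolerance`) are possible, all alternatives are recorded in the ambiguity
#' report consumed by [enumerate_resolutions()].
#'
#' @param records Tibble from [read_cna_segments()] (or equivalent).
#' @param tolerance Breakpoint tolerance in base pairs for merging segments
#'   into one event. Default 0: only exact endpoint matches merge, because
#'   breakpoint-distinct deletions at one locus are the signal that separates
#'   clones.
#' @param ambiguity_tolerance Larger window within which unmerged segments are
#'   reported as *possibly* the same event; resolutions then explore both
#'   readings. Defaults to `tolerance` (no merge ambiguities).
#' @param cnloh_mode `"second_hit"` (default): cnLOH completes an overlapping
#'   heterozygous deletion, the extreme of a zygosity progression.
#'   `"independent"`: cnLOH is its own first-hit event.
#' @return An object of class `cna_catalog`: a list with `events` (tibble:
#'   `event_id`, `chrom`, `start`, `end`, `alteration_class`, `tier`,
#'   `parent_event_id`), `records` (the input augmented with `event_id`),
#'   `merge_ambiguities`, `link_ambiguities` and `params`.
#' @export
harmonize_events <- function(records, tolerance = 0,
                             ambiguity_tolerance = tolerance,
                             cnloh_mode = c("second_hit", "independent")) {
  cnloh_mode <- match.arg(cnloh_mode)
  if (tolerance < 0) abort_invalid("tolerance must be >= 0")
  if (ambiguity_tolerance < tolerance) {
    abort_invalid("ambiguity_tolerance must be >= tolerance")
  }
  if (nrow(records) == 0) abort_invalid("no segment records to harmonize")
  rec <- as_tibble(records)
  rec$category <- .record_category(rec$alteration_class, rec$zygosity)
  rec$.row <- seq_len(nrow(rec))

  events <- list()
  rec$event_id <- NA_character_
  merge_amb <- list()

  for (key in unique(paste(rec$chrom, rec$category, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    idx <- which(rec$chrom == parts[1] & rec$category == parts[2])
    blk <- .merge_blocks(rec$start[idx], rec$end[idx], tolerance)
    ublk <- sort(unique(blk))
    binfo <- lapply(ublk, function(b) {
      members <- idx[blk == b]
      list(members = members,
           start = min(rec$start[members]), end = max(rec$end[members]))
    })
    ids <- vapply(binfo, function(b) {
      .event_label(parts[2], parts[1], b$start, b$end)
    }, character(1))
    for (k in seq_along(binfo)) {
      b <- binfo[[k]]
      rec$event_id[b$members] <- ids[k]
      events[[ids[k]]] <- tibble(
        event_id = ids[k], chrom = parts[1], start = b$start, end = b$end,
        alteration_class = if (parts[2] == "amp") "AMP"
                           else if (parts[2] == "cnloh") "CNLOH" else "DEL",
        tier = if (parts[2] == "homdel" ||
                   (parts[2] == "cnloh" && cnloh_mode == "second_hit"))
                 "SECOND_HIT" else "FIRST_HIT",
        parent_event_id = NA_character_
      )
    }
    # near-miss merges: blocks connected within the ambiguity window
    if (ambiguity_tolerance > tolerance && length(binfo) > 1) {
      bs <- vapply(binfo, `[[`, numeric(1), "start")
      be <- vapply(binfo, `[[`, numeric(1), "end")
      can <- outer(bs, bs, function(a, b) abs(a - b) <= ambiguity_tolerance) &
             outer(be, be, function(a, b) abs(a - b) <= ambiguity_tolerance)
      diag(can) <- FALSE
      if (any(can)) {
        # connected components of the "possibly same event" graph
        comp <- .uf_new(length(binfo))
        for (i in seq_len(length(binfo) - 1)) {
          for (j in seq(i + 1, length(binfo))) {
            if (can[i, j]) comp <- .uf_union(comp, i, j)
          }
        }
        roots <- vapply(seq_along(binfo), function(i) .uf_find(comp, i), integer(1))
        for (r in unique(roots)) {
          grp <- which(roots == r)
          if (length(grp) > 1) {
            merge_amb[[length(merge_amb) + 1]] <- list(
              events = ids[grp],
              can_merge = can[grp, grp, drop = FALSE]
            )
          }
        }
      }
    }
  }

  ev <- bind_rows(events)

  # link second hits to an overlapping first-hit DEL
  first_del <- ev[ev$tier == "FIRST_HIT" & ev$alteration_class == "DEL", , drop = FALSE]
  link_amb <- list()
  for (i in which(ev$tier == "SECOND_HIT")) {
    cand <- first_del[first_del$chrom == ev$chrom[i] &
                      first_del$start < ev$end[i] &
                      ev$start[i] < first_del$end, , drop = FALSE]
    if (nrow(cand) == 0) {
      abort_invalid(sprintf(
        "second-hit event '%s' (%s) has no overlapping heterozygous deletion in any sample",
        ev$event_id[i], ev$alteration_class[i]))
    }
    ov <- pmin(cand$end, ev$end[i]) - pmax(cand$start, ev$start[i])
    ord <- order(-ov, cand$event_id)
    cand_ids <- cand$event_id[ord]
    ev$parent_event_id[i] <- cand_ids[1]
    if (length(cand_ids) > 1) {
      link_amb[[length(link_amb) + 1]] <- list(event_id = ev$event_id[i],
                                               candidates = cand_ids)
    }
  }

  ev <- ev[order(chrom_order_key(ev$chrom), ev$start, ev$end,
                 ev$tier, ev$event_id), , drop = FALSE]
  rec$category <- NULL
  structure(list(
    events = as_tibble(ev),
    records = rec,
    merge_ambiguities = merge_amb,
    link_ambiguities = link_amb,
    params = list(tolerance = tolerance, ambiguity_tolerance = ambiguity_tolerance,
                  cnloh_mode = cnloh_mode)
  ), class = "cna_catalog")
}

#' @export
print.cna_catalog <- function(x, ...) {
  cat(sprintf("<cna_catalog> %d events (%d first-hit, %d second-hit) from %d records\n",
              nrow(x$events), sum(x$events$tier == "FIRST_HIT"),
              sum(x$events$tier == "SECOND_HIT"), nrow(x$records)))
  cat(sprintf("  ambiguities: %d merge group(s), %d second-hit linking(s)\n",
              length(x$merge_ambiguities), length(x$link_ambiguities)))
  invisible(x)
}

#' Number of distinct resolutions implied by a catalog's ambiguity report
#'
#' @param catalog A `cna_catalog`.
#' @return Integer count (product of per-ambiguity choice counts).
#' @export
n_resolutions <- function(catalog) {
  counts <- vapply(.resolution_choices(catalog)$choices, length, integer(1))
  as.integer(prod(c(1, counts)))
}
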