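# Resolutions: every consistent way of deciding which observed segments are
# the same event (merge ambiguities) and which second hits descend from which
# first hits (link ambiguities), prior to clone-set minimization.

# all set partitions of `items` such that every pair sharing a part satisfies
# can_merge; returned in deterministic canonical order
.valid_partitions <- function(items, can_merge) {
  n <- length(items)
  parts_list <- list()
  recurse <- function(i, parts) {
    if (i > n) {
      canon <- lapply(parts, function(p) sort(items[p]))
      canon <- canon[order(vapply(canon, `[[`, character(1), 1))]
      parts_list[[length(parts_list) + 1L]] <<- canon
      return(invisible())
    }
    for (k in seq_along(parts)) {
      if (all(can_merge[parts[[k]], i])) {
        p2 <- parts; p2[[k]] <- c(p2[[k]], i)
        recurse(i + 1L, p2)
      }
    }
    recurse(i + 1L, c(parts, list(i)))
  }
  recurse(2L, list(1L))
  keys <- vapply(parts_list, function(p) {
    paste(vapply(p, paste, character(1), collapse = ","), collapse = ";")
  }, character(1))
  parts_list[order(keys)]
}

# normalized choice sets from a catalog's (or clone_obs's) ambiguity report:
# a named list, keys sorted by event id, each element a list of options
.resolution_choices <- function(x) {
  amb <- if (inherits(x, "cna_catalog")) {
    list(merge = x$merge_ambiguities, link = x$link_ambiguities)
  } else if (inherits(x, "clone_obs")) {
    x$ambiguities
  } else {
    x
  }
  choices <- list()
  if (length(amb$merge)) {
    keys <- vapply(amb$merge, function(m) min(m$events), character(1))
    for (i in order(keys)) {
      m <- amb$merge[[i]]
      choices[[paste0("merge:", keys[i])]] <- .valid_partitions(m$events, m$can_merge)
    }
  }
  if (length(amb$link)) {
    keys <- vapply(amb$link, function(l) l$event_id, character(1))
    for (i in order(keys)) {
      l <- amb$link[[i]]
      choices[[paste0("link:", l$event_id)]] <- as.list(sort(l$candidates))
    }
  }
  list(choices = choices)
}

#' Enumerate all resolutions of an ambiguity report
#'
#' Yields every combination of merge-ambiguity partitions and second-hit
#' linkings, in deterministic order (keys sorted by event id, first key most
#' significant). The count equals the product of per-ambiguity choice counts.
#'
#' @param x A `cna_catalog` or `clone_obs` carrying an ambiguity report.
#' @param cap Refuse (with an error naming count and cap) if the number of
#'   resolutions exceeds this. Default 10000.
#' @return A list of `clone_resolution` objects; with no ambiguities, a
#'   single trivial resolution.
#' @export
enumerate_resolutions <- function(x, cap = 10000L) {
  ch <- .resolution_choices(x)$choices
  counts <- vapply(ch, length, integer(1))
  total <- prod(c(1, counts))
  if (total > cap) {
    abort_cap(sprintf(
      "resolution count %d exceeds the configured cap %d; raise the cap or the merge tolerance",
      total, cap))
  }
  keys <- names(ch)
  out <- vector("list", total)
  idx <- rep(1L, length(ch))
  for (r in seq_len(total)) {
    merges <- list(); links <- character(0)
    if (length(ch)) {
      for (k in seq_along(keys)) {
        val <- ch[[k]][[idx[k]]]
        if (startsWith(keys[k], "merge:")) {
          merges[[sub("^merge:", "", keys[k])]] <- val
        } else {
          links[[sub("^link:", "", keys[k])]] <- val
        }
      }
    }
    out[[r]] <- structure(list(
      id = sprintf("R%0*d", nchar(as.character(total)), r),
      merges = merges, links = links
    ), class = "clone_resolution")
    # odometer: last key fastest => enumeration is lexicographic in key order
    for (k in rev(seq_along(idx))) {
      idx[k] <- idx[k] + 1L
      if (length(ch) == 0 || idx[k] <= counts[k]) break
      idx[k] <- 1L
    }
  }
  out
}

#' @export
print.clone_resolution <- function(x, ...) {
  cat(sprintf("<clone_resolution> %s: %d merge choice(s), %d link choice(s)\n",
              x$id, length(x$merges), length(x$links)))
  invisible(x)
}

.event_category <- function(alteration_class, tier) {
  ifelse(alteration_class == "AMP", "amp",
    ifelse(alteration_class == "CNLOH", "cnloh",
      ifelse(tier == "SECOND_HIT", "homdel", "del")))
}

#' Apply a resolution to an observation matrix
#'
#' Merges the events chosen by the resolution's partitions (calls combine by
#' the most clonal status, matching the detected-CNA reading of the input
#' tables; the merged segment is the hull) and fixes each ambiguous second
#' hit to its chosen first-hit parent. The result carries no ambiguities.
#'
#' @param obs A `clone_obs`.
#' @param resolution A `clone_resolution` from [enumerate_resolutions()].
#' @return A resolved `clone_obs` with attribute `"resolution"`.
#' @export
apply_resolution <- function(obs, resolution) {
  stopifnot(inherits(obs, "clone_obs"), inherits(resolution, "clone_resolution"))
  ev <- obs$events
  calls <- obs$calls
  # map old event id -> new event id (identity unless merged)
  remap <- setNames(ev$event_id, ev$event_id)
  new_rows <- list()
  drop <- character(0)
  for (grp in resolution$merges) {
    for (block in grp) {
      if (length(block) < 2) next
      rows <- match(block, ev$event_id)
      hull_s <- min(ev$start[rows]); hull_e <- max(ev$end[rows])
      cat0 <- .event_category(ev$alteration_class[rows[1]], ev$tier[rows[1]])
      nid <- .event_label(cat0, ev$chrom[rows[1]], hull_s, hull_e)
      remap[block] <- nid
      new_rows[[nid]] <- tibble(
        event_id = nid, chrom = ev$chrom[rows[1]], start = hull_s, end = hull_e,
        alteration_class = ev$alteration_class[rows[1]], tier = ev$tier[rows[1]],
        parent_event_id = NA_character_
      )
      drop <- c(drop, block)
    }
  }
  keep <- ev[!ev$event_id %in% drop, , drop = FALSE]
  ev2 <- bind_rows(keep, bind_rows(new_rows))
  # chosen second-hit parents, then remap every parent through the merges
  if (length(resolution$links)) {
    for (e in names(resolution$links)) {
      tgt <- remap[[e]] %||% e
      ev2$parent_event_id[ev2$event_id == tgt] <- resolution$links[[e]]
    }
  }
  ev2$parent_event_id <- ifelse(is.na(ev2$parent_event_id), NA_character_,
                                unname(remap[ev2$parent_event_id]))
  # combine call columns by most clonal known status
  new_ids <- unique(unname(remap))
  calls2 <- matrix("UNKNOWN", nrow = nrow(calls), ncol = length(new_ids),
                   dimnames = list(rownames(calls), new_ids))
  for (nid in new_ids) {
    old <- names(remap)[remap == nid]
    sub <- calls[, old, drop = FALSE]
    rk <- matrix(.call_rank[sub], nrow = nrow(sub))
    best <- apply(rk, 1, function(v) if (all(is.na(v))) NA_integer_ else max(v, na.rm = TRUE))
    calls2[, nid] <- ifelse(is.na(best), "UNKNOWN",
                            names(.call_rank)[match(best, .call_rank)])
  }
  # re-derive first-hit presence under the chosen linking: a second-hit call
  # raises its parent's call where the parent is less clonal
  for (i in which(ev2$tier == "SECOND_HIT")) {
    p <- match(ev2$parent_event_id[i], ev2$event_id)
    child <- .call_rank[calls2[, ev2$event_id[i]]]
    parent <- .call_rank[calls2[, ev2$event_id[p]]]
    raise <- which(!is.na(child) & !is.na(parent) & child > parent)
    calls2[raise, ev2$event_id[p]] <- calls2[raise, ev2$event_id[i]]
  }
  ev2 <- ev2[order(chrom_order_key(ev2$chrom), ev2$start, ev2$end,
                   ev2$tier, ev2$event_id), , drop = FALSE]
  calls2 <- calls2[, ev2$event_id, drop = FALSE]
  out <- new_clone_obs(obs$samples, ev2, calls2)
  attr(out, "resolution") <- resolution
  out
}
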