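# Event-containment ordering and cross-timepoint (pre-leukemic) hierarchies.
#
# Under single-origin evolution an event carried by every carrier of a later
# event must have arisen first: strict containment of carrier sets orders
# events (the logic that places a remission-only chr14 deletion before the
# chr12 deletion it always accompanies at diagnosis and relapse).

.carrier_profile <- function(x) {
  if (inherits(x, "clone_obs")) {
    carr <- x$calls == "SUBCLONAL" | x$calls == "CLONAL"
    known <- x$calls != "UNKNOWN"
  } else if (inherits(x, "clone_solution")) {
    carr <- x$clones
    known <- matrix(TRUE, nrow(carr), ncol(carr), dimnames = dimnames(carr))
  } else {
    carr <- as.matrix(x)
    storage.mode(carr) <- "logical"
    known <- matrix(TRUE, nrow(carr), ncol(carr), dimnames = dimnames(carr))
  }
  list(carr = carr, known = known)
}

#' Partial order of events by carrier-set containment
#'
#' Event A precedes event B iff every observed carrier of B also carries A
#' and the containment is strict in at least one observation. UNKNOWN cells
#' are excluded from both sides so missing data cannot fabricate order.
#' Events with identical carrier sets are reported as co-occurring;
#' otherwise-unrelated events as incomparable.
#'
#' @param x A `clone_obs` (carriers = samples with a SUBCLONAL or CLONAL
#'   call), a `clone_solution`, or a logical clones-by-events matrix.
#' @return Tibble with one row per unordered event pair: `event_a`,
#'   `event_b`, `relation` in `precedes` (`event_a` before `event_b`;
#'   pairs are flipped so the earlier event is always `event_a`),
#'   `co_occurring`, `incomparable`.
#' @export
order_events <- function(x) {
  pr <- .carrier_profile(x)
  carr <- pr$carr; known <- pr$known
  ev <- colnames(carr)
  out <- list()
  if (length(ev) >= 2) {
    for (i in seq_len(length(ev) - 1)) {
      for (j in seq(i + 1, length(ev))) {
        m <- known[, i] & known[, j]
        a <- carr[m, i]; b <- carr[m, j]
        b_in_a <- all(a[b])            # carriers(B) subset of carriers(A)
        a_in_b <- all(b[a])
        if (!any(m) || (!b_in_a && !a_in_b)) {
          rel <- c(ev[i], ev[j], "incomparable")
        } else if (b_in_a && a_in_b) {
          rel <- c(ev[i], ev[j], "co_occurring")
        } else if (b_in_a && any(a & !b)) {
          rel <- c(ev[i], ev[j], "precedes")
        } else if (a_in_b && any(b & !a)) {
          rel <- c(ev[j], ev[i], "precedes")
        } else {
          rel <- c(ev[i], ev[j], "incomparable")
        }
        out[[length(out) + 1L]] <- rel
      }
    }
  }
  m <- do.call(rbind, out) %||% matrix(character(0), ncol = 3)
  tibble(event_a = m[, 1], event_b = m[, 2], relation = m[, 3])
}

#' Build a pre-leukemic / leukemic hierarchy across timepoints
#'
#' Pools clone genotypes observed at different timepoints (e.g. diagnosis,
#' remission, relapse) over a shared event catalog and builds the single
#' containment tree they imply: shared events define common ancestors,
#' private events define branches, and each input clone maps to exactly one
#' node. Clones whose carrier sets cross (violating single-origin evolution
#' across timepoints) raise an incompatibility error carrying the
#' certificate pair.
#'
#' @param clone_sets Named list of logical genotype matrices (rows = clones,
#'   shared event columns); names (e.g. `"diagnosis"`, `"relapse"`) prefix
#'   the clone ids. A single matrix is accepted.
#' @return A `clone_tree`.
#' @export
build_hierarchy <- function(clone_sets) {
  if (is.matrix(clone_sets) || is.data.frame(clone_sets)) {
    clone_sets <- list(clones = as.matrix(clone_sets))
  }
  mats <- imap(clone_sets, function(m, nm) {
    m <- as.matrix(m)
    storage.mode(m) <- "logical"
    if (is.null(rownames(m))) rownames(m) <- paste0("C", seq_len(nrow(m)))
    rownames(m) <- paste(nm, rownames(m), sep = ".")
    m
  })
  cols <- colnames(mats[[1]])
  for (m in mats) {
    if (!identical(colnames(m), cols)) {
      abort_invalid("all clone sets must share one event catalog (identical event columns)")
    }
  }
  all_clones <- do.call(rbind, mats)
  res <- check_phylogeny(all_clones)
  if (!is_compatible(res)) {
    abort(sprintf("clones across timepoints violate single-origin evolution: events '%s' and '%s' have crossing carrier sets",
                  res$certificate[1], res$certificate[2]),
          class = "clonemin_incompatible_error", certificate = res$certificate)
  }
  res
}
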