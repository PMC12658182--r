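# Mosaicism semantics: does a set of clones explain one sample's calls?

#' Check whether a clone subset explains a sample's calls
#'
#' A non-empty set of clones explains a per-event call row iff for every
#' event: `CLONAL` implies all clones carry it, `ABSENT` implies no clone
#' carries it, `SUBCLONAL` (mosaicism) implies at least one carrier and one
#' non-carrier, and `UNKNOWN` imposes nothing.
#'
#' @param calls_row Named character vector of calls over events (names are
#'   event ids), or a 1-row slice of a `clone_obs` calls matrix.
#' @param clones Logical matrix, one row per clone, columns named by event
#'   id (a single genotype may be given as a named logical vector).
#' @return A list with `ok` (logical) and `violations`, a tibble naming each
#'   violated event, its call and the failed condition.
#' @export
explain_sample <- function(calls_row, clones) {
  if (is.null(dim(clones))) clones <- matrix(clones, nrow = 1, dimnames = list(NULL, names(clones)))
  if (nrow(clones) == 0) abort_invalid("clone subset must be non-empty")
  ev <- names(calls_row)
  if (is.null(ev) || !all(ev %in% colnames(clones))) {
    abort_invalid("calls_row must be named by event ids present in the clone genotypes")
  }
  g <- clones[, ev, drop = FALSE]
  carriers <- colSums(g)
  k <- nrow(g)
  problem <- character(0); bad_ev <- character(0); bad_call <- character(0)
  for (j in seq_along(ev)) {
    call <- calls_row[[j]]
    p <- switch(call,
      CLONAL = if (carriers[j] < k) "not all assigned clones carry a CLONAL event",
      ABSENT = if (carriers[j] > 0) "an assigned clone carries an ABSENT event",
      SUBCLONAL = if (carriers[j] == 0 || carriers[j] == k)
        "SUBCLONAL event needs both a carrier and a non-carrier",
      UNKNOWN = NULL,
      abort_invalid(sprintf("invalid call '%s'", call))
    )
    if (!is.null(p)) {
      problem <- c(problem, p); bad_ev <- c(bad_ev, ev[j]); bad_call <- c(bad_call, call)
    }
  }
  list(ok = length(problem) == 0,
       violations = tibble(event_id = bad_ev, call = bad_call, problem = problem))
}
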