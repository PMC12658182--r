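# Independent exhaustive oracle for the minimal diagnostic clone count.
#
# Enumerates clone sets of growing size over the universe of genotypes and
# checks feasibility by the call semantics directly (a deliberately separate
# implementation from the package's requirement machinery). The universe is
# restricted to genotypes admissible for at least one sample: every clone in
# a minimal solution is assigned to at least one sample (dropping an
# unassigned clone keeps the solution valid and smaller), and an assigned
# clone carries all of that sample's CLONAL events and none of its ABSENT
# ones — i.e. it is admissible there. Assignments are taken maximal (all
# admissible chosen clones): CLONAL/ABSENT constraints are what admissibility
# encodes, and a larger assignment only helps SUBCLONAL carrier/non-carrier
# requirements, so maximality loses no solution.
oracle_min_clones <- function(calls, kmax = 6L) {
  E <- ncol(calls)
  S <- nrow(calls)
  universe <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), E)))
  colnames(universe) <- colnames(calls)
  admissible_for <- function(g, s) {
    all(g[calls[s, ] == "CLONAL"]) && !any(g[calls[s, ] == "ABSENT"])
  }
  adm_any <- apply(universe, 1, function(g) {
    any(vapply(seq_len(S), function(s) admissible_for(g, s), logical(1)))
  })
  universe <- universe[adm_any, , drop = FALSE]
  if (nrow(universe) == 0) return(Inf)
  laminar <- function(M) {
    if (ncol(M) < 2) return(TRUE)
    for (i in seq_len(ncol(M) - 1)) {
      for (j in seq(i + 1, ncol(M))) {
        a <- which(M[, i]); b <- which(M[, j])
        if (length(intersect(a, b)) > 0 &&
            length(setdiff(a, b)) > 0 && length(setdiff(b, a)) > 0) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  explains <- function(M) {
    for (s in seq_len(S)) {
      ok <- vapply(seq_len(nrow(M)), function(r) admissible_for(M[r, ], s),
                   logical(1))
      if (!any(ok)) return(FALSE)
      A <- M[ok, , drop = FALSE]
      for (e in which(calls[s, ] == "SUBCLONAL")) {
        if (sum(A[, e]) == 0 || sum(A[, e]) == nrow(A)) return(FALSE)
      }
    }
    TRUE
  }
  for (k in seq_len(min(kmax, nrow(universe)))) {
    cmb <- utils::combn(nrow(universe), k)
    for (ci in seq_len(ncol(cmb))) {
      M <- universe[cmb[, ci], , drop = FALSE]
      if (laminar(M) && explains(M)) return(k)
    }
  }
  Inf
}
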