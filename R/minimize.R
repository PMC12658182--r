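# Exact minimal diagnostic clone sets.
#
# Model: a single pool of diagnostic clones must explain every assayed
# sample (see explain_sample), the pool must admit a perfect phylogeny, and
# (optionally) detected clone sets must be nested along the transplant
# lineage ("no new mutations developed during transplantation").
#
# Search-space normalization: candidate genotypes are restricted to the
# lattice generated by the observed event combinations plus zygosity chains,
# i.e. for some assayed sample s, genotype = {CLONAL events of s} union a
# subset of s's SUBCLONAL/UNKNOWN events. This loses no solution: every
# clone in a minimal solution is assigned to at least one assayed sample
# (an unassigned clone could be dropped), must therefore carry all of that
# sample's CLONAL events, none of its ABSENT events, and anything else it
# carries is SUBCLONAL or UNKNOWN there — exactly a lattice member. Events
# constrained nowhere (never CLONAL/SUBCLONAL in any assayed sample) are
# excluded from the optional part: deleting such an event from every
# genotype preserves feasibility and laminarity, so minimal solutions need
# never carry it.

#' Options for clone-set minimization
#'
#' @param lineage Enforce containment of detected clone assignments along
#'   transplant edges (xenograft clones within inoculum clones). Default
#'   `TRUE`. Set `FALSE` for sensitivity analysis — with detection censoring
#'   a clone can travel below threshold, in which case strict containment of
#'   *detected* sets is over-strict and can certify infeasibility.
#' @param clone_cap Give up (loudly) if no solution exists with at most this
#'   many clones. Default 64.
#' @param resolution_cap Maximum number of ambiguity resolutions
#'   [minimal_clone_range()] will enumerate. Default 10000.
#' @param pool_cap Maximum number of candidate genotypes generated. Default
#'   50000.
#' @param solution_cap Maximum number of co-minimal solutions retained.
#'   Default 5000 (the count is flagged truncated beyond that).
#' @return A list of class `clone_options`.
#' @export
clone_options <- function(lineage = TRUE, clone_cap = 64L, resolution_cap = 10000L,
                          pool_cap = 50000L, solution_cap = 5000L) {
  stopifnot(clone_cap >= 1, resolution_cap >= 1, pool_cap >= 1, solution_cap >= 1)
  structure(list(lineage = isTRUE(lineage), clone_cap = as.integer(clone_cap),
                 resolution_cap = as.integer(resolution_cap),
                 pool_cap = as.integer(pool_cap),
                 solution_cap = as.integer(solution_cap)),
            class = "clone_options")
}

# Per-sample constraint sets (event indices) for assayed samples, plus the
# lineage-closed ("star") versions: a clone assigned to s is, under lineage
# containment, also assigned to every assayed ancestor of s, so it must
# satisfy their CLONAL/ABSENT constraints too.
.sample_constraints <- function(obs, lineage) {
  calls <- obs$calls
  sm <- obs$samples
  anc <- lineage_ancestors(sm)
  assayed <- sm$sample_id[sm$assayed]
  cons <- list()
  for (s in assayed) {
    row <- calls[s, ]
    cons[[s]] <- list(must = which(row == "CLONAL"),
                      forbid = which(row == "ABSENT"),
                      mosaic = which(row == "SUBCLONAL"),
                      unknown = which(row == "UNKNOWN"))
  }
  star <- list()
  for (s in assayed) {
    chain <- if (lineage) c(s, intersect(anc[[s]], assayed)) else s
    star[[s]] <- list(
      must = sort(unique(unlist(lapply(chain, function(a) cons[[a]]$must)))),
      forbid = sort(unique(unlist(lapply(chain, function(a) cons[[a]]$forbid))))
    )
  }
  list(cons = cons, star = star, assayed = assayed, ancestors = anc)
}

# Candidate genotype pool (logical matrix, canonical row order) honouring
# second-hit closure and mutual exclusion of rival second hits at one locus.
.candidate_pool <- function(obs, sc, pool_cap) {
  ev <- obs$events
  E <- nrow(ev)
  sec <- which(ev$tier == "SECOND_HIT")
  sec_parent <- match(ev$parent_event_id[sec], ev$event_id)
  # rival second hits: same first-hit parent, e.g. hom del vs cnLOH — a clone
  # completes a het deletion at most one way
  rival <- list()
  if (length(sec) > 1) {
    byp <- split(sec, sec_parent)
    rival <- byp[vapply(byp, length, integer(1)) > 1]
  }
  valid_genotype <- function(g) {
    if (length(sec) && any(g[sec] & !g[sec_parent])) return(FALSE)
    if (length(rival) && any(vapply(rival, function(r) sum(g[r]) > 1, logical(1)))) return(FALSE)
    TRUE
  }
  constrained_ev <- sort(unique(unlist(lapply(sc$cons, function(c) c(c$must, c$mosaic)))))
  total <- 0
  rows <- list()
  for (s in sc$assayed) {
    c0 <- sc$cons[[s]]
    fr <- sort(unique(c(c0$mosaic, intersect(c0$unknown, constrained_ev))))
    m <- length(fr)
    total <- total + 2^m
    if (total > pool_cap) {
      abort_cap(sprintf(
        "candidate genotype pool exceeds pool_cap = %d (sample '%s' alone contributes 2^%d); raise pool_cap",
        pool_cap, s, m))
    }
    for (mask in 0:(2^m - 1)) {
      g <- logical(E)
      g[c0$must] <- TRUE
      if (m > 0) g[fr[bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0]] <- TRUE
      if (valid_genotype(g)) rows[[length(rows) + 1L]] <- g
    }
  }
  if (length(rows) == 0) return(matrix(logical(0), nrow = 0, ncol = E,
                                       dimnames = list(NULL, ev$event_id)))
  P <- do.call(rbind, rows)
  colnames(P) <- ev$event_id
  keys <- apply(P, 1, genotype_key)
  P <- P[!duplicated(keys), , drop = FALSE]
  keys <- keys[!duplicated(keys)]
  P[order(rowSums(P), keys), , drop = FALSE]
}

# cover-style requirements; each is a set of pool indices that can satisfy it
.build_requirements <- function(obs, sc, P) {
  adm <- function(s) {
    st <- sc$star[[s]]
    ok <- rep(TRUE, nrow(P))
    if (length(st$must)) ok <- ok & rowSums(P[, st$must, drop = FALSE]) == length(st$must)
    if (length(st$forbid)) ok <- ok & rowSums(P[, st$forbid, drop = FALSE]) == 0
    which(ok)
  }
  eid <- obs$events$event_id
  reqs <- list()
  for (s in sc$assayed) {
    a <- adm(s)
    reqs[[length(reqs) + 1L]] <- list(
      label = sprintf("sample '%s' needs an admissible clone", s), cand = a)
    for (e in sc$cons[[s]]$mosaic) {
      carrier <- a[P[a, e]]
      reqs[[length(reqs) + 1L]] <- list(
        label = sprintf("sample '%s' needs a carrier of SUBCLONAL event '%s'", s, eid[e]),
        cand = carrier)
      reqs[[length(reqs) + 1L]] <- list(
        label = sprintf("sample '%s' needs a non-carrier of SUBCLONAL event '%s'", s, eid[e]),
        cand = setdiff(a, carrier))
    }
  }
  keys <- vapply(reqs, function(r) paste(r$cand, collapse = ","), character(1))
  reqs[!duplicated(keys)]
}

# greedy count of pairwise-disjoint unsatisfied requirements: an admissible
# lower bound on the number of clones still to add
.disjoint_bound <- function(reqs, pool_n) {
  if (length(reqs) == 0) return(0L)
  ord <- order(vapply(reqs, function(r) length(r$cand), integer(1)))
  used <- logical(pool_n)
  b <- 0L
  for (i in ord) {
    cand <- reqs[[i]]$cand
    if (!any(used[cand])) { b <- b + 1L; used[cand] <- TRUE }
  }
  b
}

#' Admissible lower bound on the minimal diagnostic clone count
#'
#' Returns an integer never exceeding the true minimum: at least 2 as soon
#' as any sample carries a SUBCLONAL call (mosaicism needs a carrier and a
#' non-carrier), and at least the size of a greedily-grown set of samples
#' with pairwise-incompatible clonal signatures (one sample's CLONAL event
#' ABSENT in the other), each of which needs its own clone.
#'
#' @param obs A `clone_obs`.
#' @param lineage Include transplant-lineage closure of the signatures.
#' @return Integer lower bound (>= 1 when any sample is assayed).
#' @export
clone_lower_bound <- function(obs, lineage = TRUE) {
  sc <- .sample_constraints(obs, lineage)
  if (length(sc$assayed) == 0) return(1L)
  lb1 <- max(vapply(sc$assayed, function(s) {
    if (length(sc$cons[[s]]$mosaic)) 2L else 1L
  }, integer(1)))
  sig <- sc$star
  incompat <- function(a, b) {
    length(intersect(sig[[a]]$must, sig[[b]]$forbid)) > 0 ||
      length(intersect(sig[[b]]$must, sig[[a]]$forbid)) > 0
  }
  kept <- character(0)
  for (s in sc$assayed) {
    if (all(vapply(kept, function(k) incompat(s, k), logical(1)))) kept <- c(kept, s)
  }
  max(lb1, length(kept))
}

.trivial_solution <- function(obs, options) {
  E <- nrow(obs$events)
  clones <- matrix(FALSE, nrow = 1, ncol = E,
                   dimnames = list("C1", obs$events$event_id))
  sol <- structure(list(
    clones = clones,
    assignment = setNames(rep(list("C1"), nrow(obs$samples)), obs$samples$sample_id),
    tree = build_clone_tree(clones),
    objective = 1L,
    resolution = attr(obs, "resolution")
  ), class = "clone_solution")
  structure(list(optimum = 1L, solutions = list(sol), n_solutions = 1L,
                 truncated = FALSE, pool_size = 0L, options = options),
            class = "clone_solution_set")
}

#' Exact minimum diagnostic clone set
#'
#' Finds the provably smallest set of diagnostic clone genotypes such that
#' every assayed sample is explained by a subset of them (see
#' [explain_sample()]), the set admits a perfect phylogeny, and — if lineage
#' containment is enabled — detected assignments are nested along transplant
#' edges. The search is exact: iterative deepening on the clone count with
#' branch-and-bound over cover-style requirements, pruned by an admissible
#' disjoint-requirement bound and incremental laminarity checks. All
#' distinct clone sets of minimum size are retained, deduplicated by
#' canonical genotype-set key and ordered lexicographically.
#'
#' @param obs A resolved `clone_obs` (apply a resolution first if the
#'   catalog had ambiguities; unresolved ambiguities are ignored here).
#' @param options A [clone_options()] list.
#' @return An object of class `clone_solution_set`: `optimum` (the minimum
#'   clone count), `solutions` (all co-minimal `clone_solution`s, each with
#'   `clones`, `assignment`, `tree`), `n_solutions`, `truncated`,
#'   `pool_size`.
#' @export
minimal_clone_set <- function(obs, options = clone_options()) {
  stopifnot(inherits(obs, "clone_obs"))
  sc <- .sample_constraints(obs, options$lineage)
  if (length(sc$assayed) == 0 || nrow(obs$events) == 0) {
    return(.trivial_solution(obs, options))
  }
  # direct contradiction along the lineage closure
  for (s in sc$assayed) {
    clash <- intersect(sc$star[[s]]$must, sc$star[[s]]$forbid)
    if (length(clash)) {
      abort_infeasible(
        sprintf("no clone can be assigned to sample '%s': event '%s' is CLONAL and ABSENT along its lineage",
                s, obs$events$event_id[clash[1]]),
        binding = sprintf("lineage(%s):%s", s, obs$events$event_id[clash[1]]))
    }
  }
  P <- .candidate_pool(obs, sc, options$pool_cap)
  reqs <- .build_requirements(obs, sc, P)
  empty <- vapply(reqs, function(r) length(r$cand) == 0, logical(1))
  if (any(empty)) {
    labs <- vapply(reqs[empty], `[[`, character(1), "label")
    abort_infeasible(
      paste0("observations cannot be explained by any diagnostic clone set; binding constraints:\n  ",
             paste(labs, collapse = "\n  ")),
      binding = labs)
  }
  pool_n <- nrow(P)
  k_lo <- max(clone_lower_bound(obs, options$lineage), .disjoint_bound(reqs, pool_n), 1L)
  # every clone of a minimal solution serves >= 1 requirement, so no solution
  # needs more clones than there are requirements: exhausting that many means
  # the requirements are jointly incompatible (not a cap problem)
  k_hi <- min(options$clone_cap, length(reqs))

  found <- new.env(parent = emptyenv())
  found$sets <- list(); found$seen <- new.env(parent = emptyenv())
  found$truncated <- FALSE

  for (k in (if (k_lo <= k_hi) k_lo:k_hi else integer(0))) {
    dfs <- function(chosen) {
      if (found$truncated) return(invisible())
      inset <- logical(pool_n); inset[chosen] <- TRUE
      unsat <- keep(reqs, function(r) !any(inset[r$cand]))
      if (length(unsat) == 0) {
        key <- paste(sort(chosen), collapse = ",")
        if (is.null(found$seen[[key]])) {
          found$seen[[key]] <- TRUE
          if (length(found$sets) >= options$solution_cap) {
            found$truncated <- TRUE
          } else {
            found$sets[[length(found$sets) + 1L]] <- sort(chosen)
          }
        }
        return(invisible())
      }
      if (length(chosen) + .disjoint_bound(unsat, pool_n) > k) return(invisible())
      sizes <- vapply(unsat, function(r) length(r$cand), integer(1))
      r <- unsat[[which.min(sizes)]]
      for (c in r$cand) {
        nxt <- c(chosen, c)
        if (is.null(.find_crossing(P[nxt, , drop = FALSE]))) dfs(nxt)
      }
      invisible()
    }
    dfs(integer(0))
    if (length(found$sets)) break
  }
  if (length(found$sets) == 0) {
    if (options$clone_cap < length(reqs)) {
      abort_cap(sprintf("no solution with at most clone_cap = %d clones (up to %d could be required)",
                        options$clone_cap, length(reqs)))
    }
    abort_infeasible(
      "observations cannot be explained under a perfect phylogeny: the per-sample requirements are jointly incompatible (crossing carrier sets)",
      binding = vapply(reqs, `[[`, character(1), "label"))
  }
  if (found$truncated) {
    warn(sprintf("more than solution_cap = %d co-minimal clone sets; list truncated",
                 options$solution_cap))
  }
  sets <- found$sets
  setkey <- vapply(sets, function(idx) {
    paste(sort(apply(P[idx, , drop = FALSE], 1, genotype_key)), collapse = "|")
  }, character(1))
  sets <- sets[order(setkey)]
  solutions <- lapply(sets, function(idx) .build_solution(obs, sc, P, idx, options))
  structure(list(optimum = length(sets[[1]]), solutions = solutions,
                 n_solutions = length(solutions), truncated = found$truncated,
                 pool_size = pool_n, options = options),
            class = "clone_solution_set")
}

.build_solution <- function(obs, sc, P, idx, options) {
  C <- P[idx, , drop = FALSE]
  keys <- apply(C, 1, genotype_key)
  ord <- order(rowSums(C), keys)
  C <- C[ord, , drop = FALSE]
  rownames(C) <- paste0("C", seq_len(nrow(C)))
  anc <- sc$ancestors
  assayed <- sc$assayed
  assignment <- list()
  for (s in obs$samples$sample_id) {
    chain <- intersect(if (s %in% assayed) c(s, anc[[s]]) else anc[[s]], assayed)
    if (!options$lineage) chain <- intersect(s, assayed)
    ok <- rep(TRUE, nrow(C))
    for (a in chain) {
      st <- sc$cons[[a]]
      if (length(st$must)) ok <- ok & rowSums(C[, st$must, drop = FALSE]) == length(st$must)
      if (length(st$forbid)) ok <- ok & rowSums(C[, st$forbid, drop = FALSE]) == 0
    }
    assignment[[s]] <- rownames(C)[ok]
  }
  structure(list(clones = C, assignment = assignment,
                 tree = build_clone_tree(C),
                 objective = nrow(C), resolution = attr(obs, "resolution")),
            class = "clone_solution")
}

#' @export
print.clone_solution_set <- function(x, ...) {
  cat(sprintf("<clone_solution_set> minimum %d diagnostic clone(s); %d co-minimal set(s)%s\n",
              x$optimum, x$n_solutions, if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' @export
print.clone_solution <- function(x, ...) {
  cat(sprintf("<clone_solution> %d clones over %d events\n",
              nrow(x$clones), ncol(x$clones)))
  invisible(x)
}

#' Clone-by-event table of a solution
#'
#' @param x A `clone_solution`.
#' @param ... Unused.
#' @return Long tibble: `clone_id`, `event_id`, `carried`.
#' @export
tidy.clone_solution <- function(x, ...) {
  tibble(
    clone_id = rep(rownames(x$clones), times = ncol(x$clones)),
    event_id = rep(colnames(x$clones), each = nrow(x$clones)),
    carried = as.vector(x$clones)
  )
}

#' Re-verify a solution against an observation matrix
#'
#' Independently re-checks every invariant a valid solution must satisfy:
#' each assayed sample's calls are explained by its assigned clones, the
#' clone set admits a perfect phylogeny, every assignment is non-empty, and
#' (if requested) assignments are nested along transplant edges.
#'
#' @param solution A `clone_solution`.
#' @param obs The `clone_obs` it claims to explain.
#' @param lineage Check transplant containment too.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
verify_solution <- function(solution, obs, lineage = TRUE) {
  C <- solution$clones
  for (s in obs$samples$sample_id) {
    a <- solution$assignment[[s]]
    if (length(a) == 0) abort_invalid(sprintf("empty assignment for sample '%s'", s))
    if (obs$samples$assayed[obs$samples$sample_id == s]) {
      row <- setNames(obs$calls[s, ], colnames(obs$calls))
      chk <- explain_sample(row, C[a, , drop = FALSE])
      if (!chk$ok) {
        abort_invalid(sprintf("sample '%s' not explained: %s", s,
                              paste(chk$violations$problem, collapse = "; ")))
      }
    }
  }
  if (!is_compatible(check_phylogeny(C))) {
    abort_invalid("clone set does not admit a perfect phylogeny")
  }
  if (lineage) {
    sm <- obs$samples
    for (i in which(!is.na(sm$parent_sample))) {
      s <- sm$sample_id[i]; p <- sm$parent_sample[i]
      if (!all(solution$assignment[[s]] %in% solution$assignment[[p]])) {
        abort_invalid(sprintf("lineage violation: clones of '%s' not contained in '%s'", s, p))
      }
    }
  }
  invisible(TRUE)
}
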