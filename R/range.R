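# Range of minimal clone counts over all observation resolutions.

#' Minimal clone count over every ambiguity resolution
#'
#' For each resolution of the observation matrix's ambiguity report (merge
#' partitions x second-hit linkings), computes the exact minimal diagnostic
#' clone set and records the minimum; returns the range over resolutions
#' together with the full per-resolution table and one representative
#' solution each. This is the quantity reported as "N to M diagnostic clones
#' were necessary to explain the observations".
#'
#' @param obs A `clone_obs` (ambiguities welcome; with none the range
#'   collapses to a single value).
#' @param options A [clone_options()] list.
#' @return An object of class `clone_fit` with elements `min_clones`,
#'   `max_clones`, `table` (tibble: `resolution`, `min_clones`, `n_solutions`,
#'   `feasible`, `solution` list-column, `binding` list-column of binding
#'   constraints for infeasible resolutions), `n_resolutions`, `options`.
#' @export
minimal_clone_range <- function(obs, options = clone_options()) {
  stopifnot(inherits(obs, "clone_obs"))
  resolutions <- enumerate_resolutions(obs, cap = options$resolution_cap)
  rows <- vector("list", length(resolutions))
  for (i in seq_along(resolutions)) {
    r <- resolutions[[i]]
    # a resolution can contradict the observations outright (e.g. a linking
    # that puts a clonal second hit over an absent first hit): record it as
    # infeasible rather than failing the whole range
    res <- tryCatch(minimal_clone_set(apply_resolution(obs, r), options),
                    clonemin_infeasible_error = function(e) e,
                    clonemin_validation_error = function(e) {
                      structure(list(binding = conditionMessage(e)),
                                class = c("clonemin_infeasible_error", "condition"))
                    })
    if (inherits(res, "clone_solution_set")) {
      rows[[i]] <- tibble(resolution = r$id, min_clones = res$optimum,
                          n_solutions = res$n_solutions, feasible = TRUE,
                          solution = list(res$solutions[[1]]), binding = list(character(0)))
    } else {
      rows[[i]] <- tibble(resolution = r$id, min_clones = NA_integer_,
                          n_solutions = 0L, feasible = FALSE,
                          solution = list(NULL), binding = list(res$binding %||% character(0)))
    }
  }
  tab <- bind_rows(rows)
  if (!any(tab$feasible)) {
    abort_infeasible(
      "no resolution of the observations admits any diagnostic clone set",
      binding = unique(unlist(tab$binding)))
  }
  mins <- tab$min_clones[tab$feasible]
  structure(list(min_clones = min(mins), max_clones = max(mins), table = tab,
                 n_resolutions = length(resolutions), options = options,
                 obs = obs),
            class = "clone_fit")
}

#' @export
print.clone_fit <- function(x, ...) {
  cat(sprintf("<clone_fit> %d resolution(s); minimal diagnostic clones: %d to %d\n",
              x$n_resolutions, x$min_clones, x$max_clones))
  invisible(x)
}

#' Per-resolution minima of a clone-range fit
#'
#' @param x A `clone_fit`.
#' @param ... Unused.
#' @return Tibble with one row per resolution: `resolution`, `min_clones`,
#'   `n_solutions`, `feasible`.
#' @export
tidy.clone_fit <- function(x, ...) {
  select(x$table, "resolution", "min_clones", "n_solutions", "feasible")
}

#' One-row summary of a clone-range fit
#'
#' @param x A `clone_fit`.
#' @param ... Unused.
#' @return Tibble with `min_clones`, `max_clones`, `n_resolutions`,
#'   `n_feasible`, `n_samples`, `n_events`.
#' @export
glance.clone_fit <- function(x, ...) {
  tibble(
    min_clones = x$min_clones, max_clones = x$max_clones,
    n_resolutions = x$n_resolutions, n_feasible = sum(x$table$feasible),
    n_samples = nrow(x$obs$calls), n_events = ncol(x$obs$calls)
  )
}

#' Representative solution of a clone-range fit
#'
#' @param x A `clone_fit`.
#' @param which `"min"` (default) or `"max"`: representative solution of the
#'   resolution attaining that end of the range.
#' @return A `clone_solution`.
#' @export
representative_solution <- function(x, which = c("min", "max")) {
  which <- match.arg(which)
  tab <- x$table[x$table$feasible, , drop = FALSE]
  i <- if (which == "min") which.min(tab$min_clones) else which.max(tab$min_clones)
  tab$solution[[i]]
}
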