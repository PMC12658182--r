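# End-to-end orchestration: segments + manifest -> observation matrix ->
# minimal clone range -> trees and reports. Exit codes follow the CLI
# contract: 0 ok, 2 parse error, 3 infeasible, 4 cap exceeded, 1 other.

#' Run the full clonal inference on segment calls
#'
#' Reads (or accepts) a segment table and manifest, harmonizes events,
#' builds the observation matrix and computes the minimal diagnostic clone
#' range over all ambiguity resolutions.
#'
#' @param segments Path to a segment TSV or a tibble from
#'   [read_cna_segments()].
#' @param manifest Path to a manifest TSV or a tibble from
#'   [read_sample_manifest()].
#' @param tolerance,ambiguity_tolerance,cnloh_mode Passed to
#'   [harmonize_events()].
#' @param dialect Passed to [read_cna_segments()] when `segments` is a path.
#' @param options A [clone_options()] list.
#' @return A `clone_fit` (see [minimal_clone_range()]); the observation
#'   matrix is available as `$obs`.
#' @export
infer_clones <- function(segments, manifest, tolerance = 0,
                         ambiguity_tolerance = tolerance,
                         cnloh_mode = "second_hit",
                         dialect = "zero_based",
                         options = clone_options()) {
  records <- if (is.character(segments)) read_cna_segments(segments, dialect) else segments
  mani <- if (is.character(manifest)) read_sample_manifest(manifest) else manifest
  catalog <- harmonize_events(records, tolerance = tolerance,
                              ambiguity_tolerance = ambiguity_tolerance,
                              cnloh_mode = cnloh_mode)
  obs <- build_observation_matrix(catalog, mani)
  minimal_clone_range(obs, options)
}

.run_config_defaults <- function() {
  list(tolerance = 0, ambiguity_tolerance = NULL, cnloh_mode = "second_hit",
       dialect = "zero_based", lineage = TRUE, clone_cap = 64L,
       resolution_cap = 10000L, seed = 1L)
}

#' Read a run configuration (YAML)
#'
#' Recognized keys: `tolerance`, `ambiguity_tolerance`, `cnloh_mode`,
#' `dialect`, `lineage`, `clone_cap`, `resolution_cap`, `seed`; missing keys
#' take defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .run_config_defaults()
  if (!is.null(path)) {
    vals <- yaml::read_yaml(path)
    cfg <- modifyList(cfg, vals[intersect(names(vals), names(cfg))])
  }
  if (is.null(cfg$ambiguity_tolerance)) cfg$ambiguity_tolerance <- cfg$tolerance
  cfg
}

.exit_code <- function(e) {
  if (inherits(e, "clonemin_parse_error")) 2L
  else if (inherits(e, "clonemin_infeasible_error")) 3L
  else if (inherits(e, "clonemin_cap_error")) 4L
  else 1L
}

#' Run inference and write all artifacts
#'
#' Writes the observation matrix (TSV + JSON), the per-resolution table, the
#' clone range (JSON), representative solutions (JSON), Newick trees and a
#' markdown report into `out_dir`. Errors are caught and mapped to the CLI
#' exit-code contract.
#'
#' @param segments,manifest Input paths (or tibbles).
#' @param config Path to a YAML run configuration, or a list from
#'   [read_run_config()], or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `status` (0 ok, 2 parse, 3 infeasible,
#'   4 cap exceeded, 1 other), `fit` (on success) and `error` (on failure).
#' @export
run_infer <- function(segments, manifest, config = NULL, out_dir, quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
         modifyList(read_run_config(NULL), config %||% list())
  say <- function(...) if (!quiet) message(sprintf(...))
  result <- tryCatch({
    opts <- clone_options(lineage = cfg$lineage, clone_cap = cfg$clone_cap,
                          resolution_cap = cfg$resolution_cap)
    fit <- infer_clones(segments, manifest, tolerance = cfg$tolerance,
                        ambiguity_tolerance = cfg$ambiguity_tolerance,
                        cnloh_mode = cfg$cnloh_mode, dialect = cfg$dialect,
                        options = opts)
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_observation_matrix(fit$obs,
                             tsv_path = file.path(out_dir, "observation_matrix.tsv"),
                             json_path = file.path(out_dir, "observation_matrix.json"))
    readr::write_tsv(tidy(fit), file.path(out_dir, "resolution_table.tsv"))
    jsonlite::write_json(list(min_clones = fit$min_clones, max_clones = fit$max_clones,
                              n_resolutions = fit$n_resolutions),
                         file.path(out_dir, "clone_range.json"),
                         auto_unbox = TRUE, digits = NA)
    sol_payload <- lapply(which(fit$table$feasible), function(i) {
      sol <- fit$table$solution[[i]]
      list(resolution = fit$table$resolution[i], min_clones = sol$objective,
           clones = lapply(rownames(sol$clones), function(cid) {
             list(clone_id = cid,
                  events = as.list(colnames(sol$clones)[sol$clones[cid, ]]))
           }),
           assignment = lapply(sol$assignment, as.list))
    })
    jsonlite::write_json(sol_payload, file.path(out_dir, "solutions.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in which(fit$table$feasible)) {
      sol <- fit$table$solution[[i]]
      write_newick(sol$tree,
                   file.path(out_dir, sprintf("tree_%s.nwk", fit$table$resolution[i])))
    }
    .write_report(fit, cfg, file.path(out_dir, "report.md"))
    say("minimal diagnostic clones: %d to %d over %d resolution(s)",
        fit$min_clones, fit$max_clones, fit$n_resolutions)
    list(status = 0L, fit = fit, error = NULL)
  }, error = function(e) {
    if (!quiet) message("error: ", conditionMessage(e))
    list(status = .exit_code(e), fit = NULL, error = e)
  })
  invisible(result)
}

.write_report <- function(fit, cfg, path) {
  g <- glance(fit)
  lines <- c(
    "# Clonal inference report", "",
    sprintf("- package: clonemin %s", as.character(packageVersion("clonemin"))),
    sprintf("- config hash: %s",
            substr(jsonlite::base64_enc(serialize(cfg, NULL)), 1, 16)),
    sprintf("- samples: %d (assayed: %d)", g$n_samples, sum(fit$obs$samples$assayed)),
    sprintf("- events: %d", g$n_events),
    sprintf("- resolutions: %d (feasible: %d)", g$n_resolutions, g$n_feasible),
    "",
    sprintf("## Minimal diagnostic clones: %d to %d", fit$min_clones, fit$max_clones),
    "",
    "| resolution | min clones | co-minimal sets | feasible |",
    "|---|---|---|---|"
  )
  for (i in seq_len(nrow(fit$table))) {
    lines <- c(lines, sprintf("| %s | %s | %d | %s |",
                              fit$table$resolution[i],
                              ifelse(is.na(fit$table$min_clones[i]), "-",
                                     fit$table$min_clones[i]),
                              fit$table$n_solutions[i],
                              fit$table$feasible[i]))
  }
  rep_sol <- representative_solution(fit, "min")
  lines <- c(lines, "", "## Representative minimal tree", "",
             "```", write_newick(rep_sol$tree), "```", "")
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a case and write its fixture files
#'
#' @param config A [simulation_config()], or path to its YAML.
#' @param out_dir Output directory.
#' @param quiet Suppress messages.
#' @return Invisibly, a list with `status` (0 ok, 2 parse/config, 1 other)
#'   and the [generate_case()] payload on success.
#' @export
run_simulate <- function(config, out_dir, quiet = FALSE) {
  result <- tryCatch({
    cfg <- if (is.character(config)) read_simulation_config(config) else config
    if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
    case <- generate_case(cfg, out_dir)
    if (!quiet) {
      message(sprintf("simulated %d clones, %d events, %d samples -> %s",
                      cfg$n_clones, ncol(case$truth$genotypes),
                      nrow(case$obs$calls), out_dir))
    }
    list(status = 0L, case = case, error = NULL)
  }, error = function(e) {
    if (!quiet) message("error: ", conditionMessage(e))
    code <- if (inherits(e, "clonemin_validation_error") ||
                inherits(e, "clonemin_parse_error")) 2L else 1L
    list(status = code, case = NULL, error = e)
  })
  invisible(result)
}
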