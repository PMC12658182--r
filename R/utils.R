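# Shared constants, condition helpers and small internal utilities.

#' Mosaicism call levels
#'
#' The four call states a (sample, event) cell of an observation matrix can
#' take: `ABSENT` (no detectable carrier cells), `SUBCLONAL` (mosaic: both
#' carrier and non-carrier cells present), `CLONAL` (all cells carry the
#' event) and `UNKNOWN` (sample not assayed / no information).
#'
#' @return Character vector of the four call levels.
#' @export
call_levels <- function() c("ABSENT", "SUBCLONAL", "CLONAL", "UNKNOWN")

# clonality rank used when combining duplicate/derived statuses
.call_rank <- c(ABSENT = 0L, SUBCLONAL = 1L, CLONAL = 2L, UNKNOWN = NA_integer_)

.timepoints   <- c("DIAGNOSIS", "REMISSION", "RELAPSE")
.compartments <- c("BULK", "STEMB", "PROB", "PREB", "HSC", "PROGENITOR",
                   "CD3POS", "CD3NEG", "OTHER")
.hosts        <- c("PATIENT", "PRIMARY_XENO", "SECONDARY_XENO")

abort_parse <- function(message, ...) {
  abort(message, class = "clonemin_parse_error", ...)
}

abort_invalid <- function(message, ...) {
  abort(message, class = "clonemin_validation_error", ...)
}

abort_infeasible <- function(message, binding = character(), ...) {
  abort(message, class = "clonemin_infeasible_error", binding = binding, ...)
}

abort_cap <- function(message, ...) {
  abort(message, class = "clonemin_cap_error", ...)
}

# deterministic key for a logical genotype vector
genotype_key <- function(g) paste(as.integer(g), collapse = "")

# chromosome sort key: numeric chromosomes first, then X, Y, others
chrom_order_key <- function(chrom) {
  x <- toupper(sub("^chr", "", chrom, ignore.case = TRUE))
  num <- suppressWarnings(as.integer(x))
  key <- ifelse(!is.na(num), num, ifelse(x == "X", 23L, ifelse(x == "Y", 24L, 25L)))
  key * 1e0
}

# walk parent_sample chains; returns named list sample_id -> character vector
# of ancestor sample_ids, nearest first. Errors on cycles or orphan parents.
lineage_ancestors <- function(samples) {
  ids <- samples$sample_id
  parent <- setNames(as.character(samples$parent_sample), ids)
  out <- vector("list", length(ids))
  names(out) <- ids
  for (s in ids) {
    chain <- character()
    cur <- parent[[s]]
    while (!is.na(cur) && nzchar(cur)) {
      if (!cur %in% ids) {
        abort_invalid(sprintf("sample '%s' references parent '%s' absent from the manifest", s, cur))
      }
      if (cur %in% c(chain, s)) {
        abort_invalid(sprintf("cycle in transplant lineage involving sample '%s'", cur))
      }
      chain <- c(chain, cur)
      cur <- parent[[cur]]
    }
    out[[s]] <- chain
  }
  out
}
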