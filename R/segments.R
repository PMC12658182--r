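# Readers for segment-call tables and sample manifests.
#
# Internal coordinate convention: 0-based half-open [start, end). SNP-array
# exports are commonly 1-based inclusive; the reader converts at the boundary
# via the `dialect` flag so only one convention exists inside the package.

.norm_token <- function(x, table, field, rows) {
  key <- toupper(trimws(as.character(x)))
  key[is.na(key) | key == ""] <- "NA"
  hit <- table[key]
  bad <- which(is.na(hit))
  if (length(bad)) {
    abort_invalid(sprintf(
      "unknown %s token '%s' (table row %d)", field, x[bad[1]], rows[bad[1]]))
  }
  unname(hit)
}

.status_tokens <- c(
  ABSENT = "ABSENT", SUBCLONAL = "SUBCLONAL", MOSAIC = "SUBCLONAL",
  CLONAL = "CLONAL", UNKNOWN = "UNKNOWN", "NA" = "UNKNOWN"
)
.class_tokens <- c(DEL = "DEL", DELETION = "DEL", LOSS = "DEL",
                   AMP = "AMP", AMPLIFICATION = "AMP", GAIN = "AMP",
                   CNLOH = "CNLOH", LOH = "CNLOH")
.zyg_tokens <- c(HET = "HET", HETEROZYGOUS = "HET",
                 HOM = "HOM", HOMOZYGOUS = "HOM",
                 CNLOH = "CNLOH", LOH = "CNLOH",
                 "NA" = "NA", "-" = "NA")

#' Read a segment-call table
#'
#' Reads a tab-separated table of per-sample CNA segment calls as produced
#' from SNP-array analysis. Required columns: `sample`, `chrom`, `start`,
#' `end`, `class` (DEL / AMP / CNLOH), `zygosity` (het / hom / cnLOH; ignored
#' for AMP) and `status` (absent / subclonal / clonal / unknown; `mosaic` is
#' accepted as a synonym of subclonal). Lines starting with `#` are ignored.
#'
#' @param path Path to a tab-separated file, or a data frame already holding
#'   the columns above (taken as-is apart from normalization).
#' @param dialect Coordinate dialect of the input: `"zero_based"` (half-open,
#'   the internal convention) or `"one_based"` (inclusive, common in array
#'   exports; start is decremented on read).
#' @return A tibble with columns `sample_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `alteration_class`, `zygosity`, `status`.
#' @export
read_cna_segments <- function(path, dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  if (is.data.frame(path)) {
    raw <- as_tibble(path)
  } else {
    if (!file.exists(path)) abort_parse(sprintf("segment table '%s' does not exist", path))
    raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  need <- c("sample", "chrom", "start", "end", "class", "zygosity", "status")
  alias <- c(sample = "sample_id", class = "alteration_class")
  for (nm in names(alias)) {
    if (!nm %in% names(raw) && alias[[nm]] %in% names(raw)) {
      raw[[nm]] <- raw[[alias[[nm]]]]
    }
  }
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_parse(sprintf("segment table is missing required column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  n <- nrow(raw)
  rows <- seq_len(n)
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start) | is.na(end) | is.na(raw$sample) | is.na(raw$chrom))
  if (length(bad)) {
    abort_parse(sprintf("malformed segment row at table row %d", bad[1]))
  }
  if (dialect == "one_based") start <- start - 1
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    abort_invalid(sprintf(
      "invalid segment at table row %d: start must satisfy 0 <= start < end", bad[1]))
  }
  cls <- .norm_token(raw$class, .class_tokens, "alteration class", rows)
  zyg <- .norm_token(raw$zygosity, .zyg_tokens, "zygosity", rows)
  status <- .norm_token(raw$status, .status_tokens, "status", rows)
  # cnLOH can be encoded either as class CNLOH or zygosity cnLOH on a DEL row
  zyg[cls == "CNLOH"] <- "CNLOH"
  zyg[cls == "AMP"] <- "NA"
  bad <- which(cls == "DEL" & !zyg %in% c("HET", "HOM", "CNLOH"))
  if (length(bad)) {
    abort_invalid(sprintf("DEL row at table row %d needs zygosity het, hom or cnLOH", bad[1]))
  }
  tibble(
    sample_id = as.character(raw$sample),
    chrom = sub("^chr", "", as.character(raw$chrom), ignore.case = TRUE),
    start = start, end = end,
    alteration_class = ifelse(cls == "CNLOH", "DEL", cls),
    zygosity = zyg,
    status = status
  )
}

#' Read a sample manifest
#'
#' Reads the manifest encoding patient, timepoint, sorted compartment, host
#' and transplant lineage for every sample. Required columns: `sample_id`,
#' `patient`, `timepoint` (diagnosis / remission / relapse), `compartment`
#' (bulk, StemB, ProB, PreB, HSC, progenitor, CD3pos, CD3neg, other), `host`
#' (patient / primary / secondary) and `parent_sample` (the inoculum source;
#' empty for patient samples). An optional logical `assayed` column flags
#' samples with SNP-array data (default `TRUE`); unassayed samples receive
#' all-UNKNOWN observation rows.
#'
#' The transplant lineage must form a forest: xenograft samples need an
#' existing parent and cycles are rejected.
#'
#' @param path Path to a tab-separated file, or a data frame.
#' @return A tibble with normalized columns plus `assayed`.
#' @export
read_sample_manifest <- function(path) {
  if (is.data.frame(path)) {
    raw <- as_tibble(path)
  } else {
    if (!file.exists(path)) abort_parse(sprintf("manifest '%s' does not exist", path))
    raw <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  }
  need <- c("sample_id", "patient", "timepoint", "compartment", "host", "parent_sample")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort_parse(sprintf("manifest is missing required column(s): %s",
                        paste(miss, collapse = ", ")))
  }
  rows <- seq_len(nrow(raw))
  tp <- .norm_token(raw$timepoint, setNames(.timepoints, .timepoints), "timepoint", rows)
  comp_tokens <- setNames(.compartments, .compartments)
  comp_tokens <- c(comp_tokens, "CD3+" = "CD3POS", "CD3-" = "CD3NEG")
  comp <- .norm_token(raw$compartment, comp_tokens, "compartment", rows)
  host_tokens <- c(PATIENT = "PATIENT",
                   PRIMARY = "PRIMARY_XENO", PRIMARY_XENO = "PRIMARY_XENO",
                   SECONDARY = "SECONDARY_XENO", SECONDARY_XENO = "SECONDARY_XENO")
  host <- .norm_token(raw$host, host_tokens, "host", rows)
  parent <- as.character(raw$parent_sample)
  parent[!is.na(parent) & parent %in% c("", "NA", "-")] <- NA_character_
  assayed <- if ("assayed" %in% names(raw)) {
    tolower(as.character(raw$assayed)) %in% c("true", "t", "1", "yes")
  } else {
    rep(TRUE, nrow(raw))
  }
  out <- tibble(
    sample_id = as.character(raw$sample_id),
    patient = as.character(raw$patient),
    timepoint = tp, compartment = comp, host = host,
    parent_sample = parent, assayed = assayed
  )
  if (anyDuplicated(out$sample_id)) {
    abort_invalid(sprintf("duplicate sample_id '%s' in manifest",
                          out$sample_id[duplicated(out$sample_id)][1]))
  }
  bad <- which(out$host != "PATIENT" & is.na(out$parent_sample))
  if (length(bad)) {
    abort_invalid(sprintf("xenograft sample '%s' has no parent_sample", out$sample_id[bad[1]]))
  }
  bad <- which(out$host == "PATIENT" & !is.na(out$parent_sample))
  if (length(bad)) {
    abort_invalid(sprintf("patient sample '%s' must not have a parent_sample",
                          out$sample_id[bad[1]]))
  }
  lineage_ancestors(out)  # validates forest: orphans, cycles
  out
}
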