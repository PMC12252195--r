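# Staged homolog-screening cascade with full exclusion accounting.
#
# Hits are plain data.frames with columns target_id, species, evalue, length
# and optionally sequence / taxon_group.  Two configurations of the same
# operations cover the two phases of a profile-HMM screen: a stringent query
# discovery phase (E-value <= 1e-100, best hit per species) and a relaxed
# proteome-screening phase (E-value <= 1e-20) followed by partial-sequence
# removal, a 7TM two-predictor consensus filter and exact-sequence
# deduplication.

#' Cascade configuration
#'
#' Thresholds for the staged PMTR candidate screen.  Defaults correspond to
#' the proteome-screening phase: hits are kept when their E-value is at most
#' `phase2_max_evalue` and their length falls within `[min_length,
#' max_length]`; candidates must have exactly `required_tm` transmembrane
#' segments according to at least `min_predictor_agreement` topology
#' predictors.
#'
#' @param phase1_max_evalue E-value cutoff of the stringent discovery phase.
#' @param phase2_max_evalue E-value cutoff of the proteome-screening phase.
#' @param min_length,max_length Inclusive residue-length window.
#' @param required_tm Number of transmembrane segments required (7 for PMTRs).
#' @param min_predictor_agreement Minimum number of predictors that must each
#'   report exactly `required_tm` TM segments.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(phase1_max_evalue = 1e-100,
                           phase2_max_evalue = 1e-20,
                           min_length = 200, max_length = 400,
                           required_tm = 7, min_predictor_agreement = 2) {
  if (phase1_max_evalue <= 0 || phase2_max_evalue <= 0)
    config_error("E-value cutoffs must be positive")
  if (min_length > max_length)
    config_error("min_length must not exceed max_length")
  if (required_tm < 1) config_error("required_tm must be >= 1")
  if (min_predictor_agreement < 1)
    config_error("min_predictor_agreement must be >= 1")
  structure(list(phase1_max_evalue = phase1_max_evalue,
                 phase2_max_evalue = phase2_max_evalue,
                 min_length = min_length, max_length = max_length,
                 required_tm = required_tm,
                 min_predictor_agreement = min_predictor_agreement),
            class = "cascade_config")
}

validate_hits <- function(hits, need_sequence = FALSE, need_species = FALSE) {
  required <- c("target_id", "evalue", "length")
  missing <- setdiff(required, names(hits))
  if (length(missing))
    data_error(paste0("hit table lacks column(s): ",
                      paste(missing, collapse = ", ")))
  if (any(!nzchar(hits$target_id)))
    data_error("hit table contains an empty target_id")
  bad <- which(!is.finite(hits$evalue) | hits$evalue <= 0)
  if (length(bad))
    data_error(paste0("non-positive E-value for record '",
                      hits$target_id[bad[1]], "'"))
  if (need_species) {
    if (is.null(hits$species) || anyNA(hits$species) || any(!nzchar(hits$species)))
      data_error("species missing for one or more hits")
  }
  if (need_sequence) {
    if (is.null(hits$sequence) || anyNA(hits$sequence))
      data_error("sequence missing for one or more hits")
  }
  invisible(hits)
}

#' Filter hits by E-value and length window
#'
#' A hit is retained iff `evalue <= max_evalue` and `min_length <= length <=
#' max_length` (all boundaries inclusive).  Input order is preserved.
#'
#' @param hits Hit data.frame (`target_id`, `evalue`, `length`, ...).
#' @param max_evalue E-value cutoff.
#' @param min_length,max_length Inclusive length window.
#' @return The retained subset of `hits`.
#' @export
filter_by_threshold <- function(hits, max_evalue, min_length, max_length) {
  validate_hits(hits)
  keep <- hits$evalue <= max_evalue &
    hits$length >= min_length & hits$length <= max_length
  hits[keep, , drop = FALSE]
}

#' Keep the best hit per species
#'
#' Retains, for each distinct species, the hit with the smallest E-value;
#' ties are broken by the lexicographically smallest `target_id` so the
#' selection is deterministic.
#'
#' @param hits Hit data.frame with a populated `species` column.
#' @return One row per species.
#' @export
best_hit_per_species <- function(hits) {
  validate_hits(hits, need_species = TRUE)
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$species, hits$evalue, hits$target_id)
  sorted <- hits[ord, , drop = FALSE]
  sorted[!duplicated(sorted$species), , drop = FALSE]
}

#' Remove partial sequences
#'
#' A candidate is considered partial, and excluded, when its sequence does not
#' begin with the initial methionine.
#'
#' @param hits Hit data.frame with a `sequence` column.
#' @return Hits whose sequences start with `M`.
#' @export
remove_partial <- function(hits) {
  validate_hits(hits, need_sequence = TRUE)
  if (nrow(hits) == 0) return(hits)
  if (any(!nzchar(hits$sequence)))
    data_error("empty sequence in hit table")
  keep <- substr(hits$sequence, 1, 1) == "M"
  hits[keep, , drop = FALSE]
}

# per (sequence_id, predictor) count of TM segments
tm_counts_by_predictor <- function(predictions) {
  need <- c("sequence_id", "predictor", "label")
  missing <- setdiff(need, names(predictions))
  if (length(missing))
    data_error(paste0("topology table lacks column(s): ",
                      paste(missing, collapse = ", ")))
  is_tm <- grepl("^TM", predictions$label)
  key <- interaction(predictions$sequence_id, predictions$predictor, drop = TRUE)
  counts <- tapply(is_tm, key, sum)
  ids <- tapply(predictions$sequence_id, key, `[`, 1)
  data.frame(sequence_id = as.character(ids),
             n_tm = as.integer(counts),
             row.names = NULL)
}

#' Seven-transmembrane consensus filter
#'
#' A hit is retained iff at least `config$min_predictor_agreement` predictors
#' each report exactly `config$required_tm` transmembrane segments for it.
#' Hits with no predictions at all, or with fewer prediction sets than the
#' required agreement, are a data error: the consensus is undefined for them.
#'
#' @param hits Hit data.frame.
#' @param predictions Long-form topology table (`sequence_id`, `predictor`,
#'   `label`, `start`, `end`), one row per predicted segment.
#' @param config A [cascade_config()].
#' @return Retained hits.
#' @export
topology_consensus_filter <- function(hits, predictions,
                                      config = cascade_config()) {
  validate_hits(hits)
  if (nrow(hits) == 0) return(hits)
  counts <- tm_counts_by_predictor(predictions)
  n_pred <- table(counts$sequence_id)
  absent <- setdiff(hits$target_id, names(n_pred))
  if (length(absent))
    data_error(paste0("no topology predictions for '", absent[1], "'"))
  too_few <- names(n_pred)[n_pred < config$min_predictor_agreement]
  too_few <- intersect(too_few, hits$target_id)
  if (length(too_few))
    data_error(paste0("fewer predictors than required agreement for '",
                      too_few[1], "'"))
  ok_tab <- tapply(counts$n_tm == config$required_tm, counts$sequence_id, sum)
  agree <- ok_tab[hits$target_id] >= config$min_predictor_agreement
  hits[agree, , drop = FALSE]
}

#' Remove redundant (identical-sequence) entries
#'
#' Keeps one representative per identical amino-acid sequence: the record with
#' the lowest E-value, ties broken by the lexicographically smallest
#' `target_id`.
#'
#' @param hits Hit data.frame with sequences.
#' @return Deduplicated hits (original input order of representatives).
#' @export
deduplicate <- function(hits) {
  validate_hits(hits, need_sequence = TRUE)
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$sequence, hits$evalue, hits$target_id)
  sorted <- hits[ord, , drop = FALSE]
  reps <- sorted$target_id[!duplicated(sorted$sequence)]
  hits[hits$target_id %in% reps, , drop = FALSE]
}

#' Run the full screening cascade
#'
#' Applies, in order: the E-value/length threshold filter (proteome-screening
#' phase), partial-sequence removal, the 7TM two-predictor consensus filter,
#' and exact-sequence deduplication.  Every input id is accounted for in
#' exactly one bucket of the returned report.
#'
#' @param hits Hit data.frame (`target_id`, `species`, `evalue`, `length`,
#'   `sequence`).
#' @param predictions Long-form topology prediction table (see
#'   [topology_consensus_filter()]).
#' @param config A [cascade_config()].
#' @return A list with elements `hits` (the retained data.frame) and `report`
#'   (class `cascade_report`): counts (`initial`, `after_threshold`,
#'   `excluded_threshold`, `excluded_partial`, `excluded_tm`,
#'   `excluded_redundant`, `final`), per-category id lists, and
#'   `retention_fraction` (`NA` for empty input).
#' @export
run_cascade <- function(hits, predictions, config = cascade_config()) {
  validate_hits(hits, need_sequence = nrow(hits) > 0)
  initial_ids <- hits$target_id
  if (anyDuplicated(initial_ids))
    data_error("duplicate target_id in input hit table")

  s1 <- filter_by_threshold(hits, config$phase2_max_evalue,
                            config$min_length, config$max_length)
  excl_threshold <- setdiff(initial_ids, s1$target_id)

  s2 <- if (nrow(s1)) remove_partial(s1) else s1
  excl_partial <- setdiff(s1$target_id, s2$target_id)

  s3 <- if (nrow(s2)) topology_consensus_filter(s2, predictions, config) else s2
  excl_tm <- setdiff(s2$target_id, s3$target_id)

  s4 <- if (nrow(s3)) deduplicate(s3) else s3
  excl_redundant <- setdiff(s3$target_id, s4$target_id)

  n0 <- length(initial_ids)
  report <- structure(list(
    counts = list(initial = n0,
                  after_threshold = nrow(s1),
                  excluded_threshold = length(excl_threshold),
                  excluded_partial = length(excl_partial),
                  excluded_tm = length(excl_tm),
                  excluded_redundant = length(excl_redundant),
                  final = nrow(s4)),
    ids = list(retained = s4$target_id,
               excluded_threshold = excl_threshold,
               excluded_partial = excl_partial,
               excluded_tm = excl_tm,
               excluded_redundant = excl_redundant),
    retention_fraction = if (n0 > 0) nrow(s4) / n0 else NA_real_),
    class = "cascade_report")
  list(hits = s4, report = report)
}

#' @export
print.cascade_report <- function(x, ...) {
  c0 <- x$counts
  cat("PMTR screening cascade report\n")
  cat(sprintf("  initial candidates : %d\n", c0$initial))
  cat(sprintf("  after threshold    : %d  (excluded %d)\n",
              c0$after_threshold, c0$excluded_threshold))
  cat(sprintf("  partial removed    : %d\n", c0$excluded_partial))
  cat(sprintf("  failed 7TM filter  : %d\n", c0$excluded_tm))
  cat(sprintf("  redundant removed  : %d\n", c0$excluded_redundant))
  cat(sprintf("  final homologs     : %d", c0$final))
  if (!is.na(x$retention_fraction))
    cat(sprintf("  (~%.0f%% of initial)", 100 * x$retention_fraction))
  cat("\n")
  invisible(x)
}

#' Read a HMMER tblout-style hit table
#'
#' Parses the whitespace-delimited per-target table written by `hmmsearch
#' --tblout` (lines starting with `#` are comments).  Only the target name
#' (column 1) and full-sequence E-value (column 5) are used.
#'
#' @param path Path to the tblout file.
#' @return data.frame with `target_id` and `evalue`.
#' @export
read_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(target_id = character(), evalue = numeric()))
  fields <- strsplit(trimws(lines), "\\s+")
  short <- vapply(fields, length, 1L) < 5
  if (any(short))
    parse_error(paste0("tblout line with fewer than 5 fields: '",
                       lines[which(short)[1]], "'"))
  data.frame(target_id = vapply(fields, `[`, "", 1L),
             evalue = as.numeric(vapply(fields, `[`, "", 5L)))
}

#' Read a synthetic hit TSV
#'
#' Tab-separated with header columns `target_id`, `species`, `evalue`,
#' `length` and optionally `sequence_id`/`sequence`.
#'
#' @param path Path to the TSV file.
#' @return Hit data.frame.
#' @export
read_hit_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  validate_hits(df)
  df
}

#' Write a hit table as TSV
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cascade report as JSON
#'
#' @param report A `cascade_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
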