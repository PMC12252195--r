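# Consensus 7TM topology annotations and domain-length statistics.
#
# An annotation is an ordered table of segments labelled NTD, TM1..TMk,
# ICL1..ICL3, ECL1..ECL3, CTD with 1-based inclusive coordinates that tile the
# whole sequence.  Loops are named by the side of the membrane they sit on:
# with the PMTR/GPCR convention the N-terminal domain is extracellular, so the
# loop after TM1 is intracellular (ICL1), the next extracellular (ECL1), and
# so on.

segment_df <- function(label, start, end) {
  data.frame(label = label, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Build a topology annotation from per-residue states
#'
#' Converts a per-residue state string over the alphabet `o` (outside), `i`
#' (inside) and `M` (membrane) into an ordered segment annotation.  Maximal
#' runs of `M` become TM1..TMk in N-to-C order; a flanking non-membrane run
#' before TM1 becomes the NTD and one after the last TM the CTD; intervening
#' runs become ECL/ICL according to their side.  The two loops flanking a TM
#' segment must lie on opposite sides, otherwise the orientation is
#' inconsistent and a data error is raised.
#'
#' @param states Character scalar of per-residue states (`o`/`i`/`M`), or a
#'   character vector of single states.
#' @param sequence_id Identifier stored in the annotation.
#' @return A `topology_annotation`: list with `sequence_id`, `segments`
#'   (data.frame `label`, `start`, `end`) and `n_tm`.
#' @export
segments_from_states <- function(states, sequence_id = "seq") {
  if (length(states) == 1) states <- seq_chars(states)
  if (!length(states)) data_error("empty state string")
  if (!all(states %in% c("o", "i", "M")))
    data_error("states must be drawn from {o, i, M}")
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_runs <- length(r$values)
  is_m <- r$values == "M"
  # orientation consistency: sides flanking each TM run must differ
  for (j in which(is_m)) {
    if (j > 1 && j < n_runs && !is_m[j - 1] && !is_m[j + 1] &&
        r$values[j - 1] == r$values[j + 1])
      data_error("membrane segment flanked by two same-side loops (inconsistent orientation)")
    if (j > 1 && is_m[j - 1])
      data_error("adjacent membrane runs")  # unreachable with rle, kept for clarity
  }
  labels <- character(n_runs)
  tm_i <- 0L; icl_i <- 0L; ecl_i <- 0L
  first_tm <- if (any(is_m)) which(is_m)[1] else Inf
  last_tm <- if (any(is_m)) max(which(is_m)) else -Inf
  for (j in seq_len(n_runs)) {
    if (is_m[j]) {
      tm_i <- tm_i + 1L
      labels[j] <- paste0("TM", tm_i)
    } else if (j < first_tm || !any(is_m)) {
      labels[j] <- "NTD"
    } else if (j > last_tm) {
      labels[j] <- "CTD"
    } else {
      if (r$values[j] == "i") {
        icl_i <- icl_i + 1L
        labels[j] <- paste0("ICL", icl_i)
      } else {
        ecl_i <- ecl_i + 1L
        labels[j] <- paste0("ECL", ecl_i)
      }
    }
  }
  structure(list(sequence_id = sequence_id,
                 segments = segment_df(labels, starts, ends),
                 n_tm = sum(is_m)),
            class = "topology_annotation")
}

#' Construct a topology annotation from a segment table
#'
#' @param segments data.frame with `label`, `start`, `end` (1-based,
#'   inclusive), ordered N to C and tiling `1..L`.
#' @param sequence_id Identifier stored in the annotation.
#' @return A `topology_annotation`.
#' @export
topology_annotation <- function(segments, sequence_id = "seq") {
  if (!nrow(segments)) data_error("annotation with no segments")
  if (any(segments$start > segments$end))
    data_error("segment with start > end")
  if (segments$start[1] != 1L)
    data_error("segments must start at position 1")
  if (nrow(segments) > 1 &&
      any(segments$start[-1] != segments$end[-nrow(segments)] + 1L))
    data_error("segments must be contiguous and ordered")
  structure(list(sequence_id = sequence_id,
                 segments = segment_df(segments$label, segments$start, segments$end),
                 n_tm = sum(grepl("^TM", segments$label))),
            class = "topology_annotation")
}

#' @export
print.topology_annotation <- function(x, ...) {
  cat(sprintf("topology_annotation '%s': %d segments, %d TM, length %d\n",
              x$sequence_id, nrow(x$segments), x$n_tm,
              x$segments$end[nrow(x$segments)]))
  print(x$segments)
  invisible(x)
}

#' Consensus topology across predictors
#'
#' Accepts an annotation iff at least `min_agreement` predictors report
#' exactly `required_tm` transmembrane segments.  TM counts are the only
#' quantity compared across programs; the returned segment boundaries are
#' those of the designated primary predictor (by default the first listed).
#' When the designated primary does not itself report `required_tm` TMs, the
#' first listed predictor that does is used instead.
#'
#' @param annotations Named list of `topology_annotation`s, one per predictor.
#' @param min_agreement Minimum number of agreeing predictors.
#' @param required_tm Required TM count.
#' @param primary Name or index of the predictor whose boundaries are used.
#' @return The accepted `topology_annotation` (with attribute `"predictor"`),
#'   or `NULL` when the consensus rejects the protein.
#' @export
consensus_topology <- function(annotations, min_agreement = 2,
                               required_tm = 7, primary = 1L) {
  if (!length(annotations)) data_error("no predictor annotations supplied")
  n_tm <- vapply(annotations, function(a) a$n_tm, 1L)
  agreeing <- which(n_tm == required_tm)
  if (length(agreeing) < min_agreement) return(NULL)
  idx <- if (is.character(primary)) match(primary, names(annotations)) else primary
  if (is.na(idx) || idx > length(annotations))
    config_error("primary predictor not among the supplied annotations")
  if (!(idx %in% agreeing)) idx <- agreeing[1]
  out <- annotations[[idx]]
  attr(out, "predictor") <- names(annotations)[idx] %||% idx
  out
}

#' Long-form domain-length table
#'
#' One row per (sequence, domain) with `length = end - start + 1`.
#'
#' @param annotations List of `topology_annotation`s.
#' @param groups Optional named character vector (or vector aligned with
#'   `annotations`) of group labels, e.g. phylogenetic clades.
#' @return data.frame with `sequence_id`, `group`, `domain`, `length`.
#' @export
domain_length_table <- function(annotations, groups = NULL) {
  rows <- lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    g <- if (is.null(groups)) NA_character_
         else if (!is.null(names(groups))) unname(groups[a$sequence_id])
         else groups[i]
    data.frame(sequence_id = a$sequence_id, group = g,
               domain = a$segments$label,
               length = a$segments$end - a$segments$start + 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise group comparison of domain lengths
#'
#' Compares the lengths of one domain between groups with pairwise two-sided
#' Mann-Whitney (Wilcoxon rank-sum) tests and Holm multiplicity correction.
#' Loop lengths are small counts and usually non-normal, hence the rank-based
#' test.
#'
#' @param table Long-form table from [domain_length_table()].
#' @param domain Domain label to compare (e.g. `"ECL2"`).
#' @param groups Optional subset of group labels; defaults to all groups
#'   present.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return data.frame with one row per unordered group pair: `group1`,
#'   `group2`, `statistic` (Mann-Whitney U), `p_value`, `p_adjusted`,
#'   `significant`.  Zero rows when fewer than two groups are requested.
#' @export
compare_domain_lengths <- function(table, domain, groups = NULL, alpha = 0.05) {
  sub <- table[table$domain == domain & !is.na(table$group), , drop = FALSE]
  if (is.null(groups)) groups <- sort(unique(sub$group))
  if (length(groups) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  obs <- lapply(groups, function(g) sub$length[sub$group == g])
  names(obs) <- groups
  small <- vapply(obs, length, 1L) < 2
  if (any(small))
    data_error(paste0("group '", groups[small][1],
                      "' has fewer than 2 observations for ", domain))
  pairs <- utils::combn(groups, 2)
  res <- apply(pairs, 2, function(p) {
    w <- suppressWarnings(wilcox.test(obs[[p[1]]], obs[[p[2]]],
                                      alternative = "two.sided", exact = FALSE))
    c(statistic = unname(w$statistic), p_value = w$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = res["statistic", ],
                    p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- p.adjust(out$p_value, method = "holm")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Read a long-form topology TSV
#'
#' Columns: `sequence_id`, `predictor`, `label`, `start`, `end` (1-based
#' inclusive), one row per predicted segment.
#'
#' @param path Path to the TSV.
#' @return data.frame in the same long form.
#' @export
read_topology_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sequence_id", "predictor", "label", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing))
    parse_error(paste0("topology TSV lacks column(s): ",
                       paste(missing, collapse = ", ")))
  df
}

#' Write a long-form topology TSV
#'
#' @param predictions Long-form topology data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_tsv <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a topology annotation to long form
#'
#' @param annotation A `topology_annotation`.
#' @param predictor Predictor name recorded in the rows.
#' @return Long-form data.frame (`sequence_id`, `predictor`, `label`,
#'   `start`, `end`).
#' @export
annotation_to_long <- function(annotation, predictor = "consensus") {
  data.frame(sequence_id = annotation$sequence_id, predictor = predictor,
             annotation$segments, stringsAsFactors = FALSE)
}

#' Assemble annotations from a long-form prediction table
#'
#' @param predictions Long-form topology data.frame.
#' @return Nested list: per sequence_id, per predictor, a
#'   `topology_annotation`.
#' @export
annotations_from_long <- function(predictions) {
  out <- list()
  for (sid in unique(predictions$sequence_id)) {
    rows_s <- predictions[predictions$sequence_id == sid, , drop = FALSE]
    out[[sid]] <- list()
    for (pred in unique(rows_s$predictor)) {
      seg <- rows_s[rows_s$predictor == pred, c("label", "start", "end")]
      seg <- seg[order(seg$start), , drop = FALSE]
      out[[sid]][[pred]] <- topology_annotation(seg, sequence_id = sid)
    }
  }
  out
}
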