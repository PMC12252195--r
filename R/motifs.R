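# Motif grammar, scanning and conservation analysis.
#
# Pattern grammar: uppercase letters are literal residues, 'x' matches any
# residue, 'h' matches a configurable hydrophobic class, and bracketed sets
# like [KR] match any listed residue.  All patterns are contiguous (no gaps):
# the conserved PMTR motifs (YYSEM[KR]D, DFFxE[ED], QxWEC, LPx[RK], CHG,
# LEhS, Y[LP]PhhY) are all ungapped.

#' Default hydrophobic residue class
#'
#' The residues matched by the `h` pattern element: A, V, L, I, M, F, W, C.
#' This covers the hydrophobic positions of the family motifs (e.g. the V/I of
#' LE\[VI\]S and the L,L of Y\[LP\]PhhY) while excluding residues those motifs
#' always write explicitly (Y, P, G).
#'
#' @return Character vector of one-letter codes.
#' @export
hydrophobic_class <- function() c("A", "V", "L", "I", "M", "F", "W", "C")

#' Compile a motif pattern
#'
#' @param text Pattern string, e.g. `"YYSEM[KR]D"`.
#' @param h_class Residues matched by the `h` element.
#' @return A `motif_pattern`: list of elements, each with `type`
#'   (`literal`/`set`/`wildcard`/`class`) and `residues`.
#' @export
compile_pattern <- function(text, h_class = hydrophobic_class()) {
  if (!nzchar(text)) parse_error("empty motif pattern")
  chars <- seq_chars(text)
  elements <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (!length(close)) parse_error("unbalanced '[' in motif pattern")
      close <- close[1]
      set <- chars[(i + 1):(close - 1)]
      if (!length(set) || !all(set %in% AA20))
        parse_error(paste0("illegal residue set in motif pattern: [",
                           paste(set, collapse = ""), "]"))
      elements[[length(elements) + 1]] <- list(type = "set", residues = set)
      i <- close + 1L
    } else if (ch == "]") {
      parse_error("unbalanced ']' in motif pattern")
    } else if (ch == "x") {
      elements[[length(elements) + 1]] <- list(type = "wildcard", residues = AA20)
      i <- i + 1L
    } else if (ch == "h") {
      elements[[length(elements) + 1]] <- list(type = "class", residues = h_class)
      i <- i + 1L
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1]] <- list(type = "literal", residues = ch)
      i <- i + 1L
    } else {
      parse_error(paste0("illegal character '", ch, "' in motif pattern"))
    }
  }
  structure(list(text = text, elements = elements), class = "motif_pattern")
}

#' Render a compiled pattern back to its text form
#'
#' @param pattern A `motif_pattern`.
#' @return Pattern string; `compile_pattern(render_pattern(p))` equals `p`.
#' @export
render_pattern <- function(pattern) {
  vapply(pattern$elements, function(e) {
    switch(e$type,
           literal = e$residues,
           wildcard = "x",
           class = "h",
           set = paste0("[", paste(e$residues, collapse = ""), "]"))
  }, "") |> paste(collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif_pattern '%s' (%d elements)\n", x$text,
              length(x$elements)))
  invisible(x)
}

#' Scan a sequence for motif matches
#'
#' Reports every 1-based start position at which all pattern elements match;
#' overlapping matches are allowed.
#'
#' @param sequence Amino-acid string.
#' @param pattern A `motif_pattern` or pattern string.
#' @return Integer vector of match start positions (possibly empty).
#' @export
scan_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  chars <- seq_chars(sequence)
  k <- length(pattern$elements)
  n <- length(chars)
  if (n < k) return(integer())
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & chars[seq.int(j, n - k + j)] %in% pattern$elements[[j]]$residues
  }
  which(ok)
}

#' Motif prevalence over a sequence set
#'
#' Counts the sequences containing at least one match and reports the ids of
#' those that do not.
#'
#' @param sequences Named character vector of amino-acid sequences (or
#'   `AAStringSet`).
#' @param pattern A `motif_pattern` or pattern string.
#' @return List with `count` and `non_matching` (ids).
#' @export
prevalence <- function(sequences, pattern) {
  if (inherits(sequences, "AAStringSet")) {
    ids <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- ids
  }
  if (!length(sequences)) data_error("empty sequence set")
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  hit <- vapply(sequences, function(s) length(scan_motif(s, pattern)) > 0,
                logical(1))
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  if (is.null(names(sequences))) names(hit) <- ids
  list(count = sum(hit), non_matching = ids[!hit])
}

#' Fully (or near-fully) conserved alignment columns
#'
#' Returns the columns whose conservation reaches `threshold` and whose
#' non-gap coverage reaches `min_coverage`, mapped to positions on a
#' designated reference sequence.
#'
#' @param msa Alignment (named character vector or `AAStringSet`).
#' @param reference_id Id of the reference sequence in the alignment.
#' @param threshold Minimum conservation fraction (1.0 = invariant).
#' @param min_coverage Minimum non-gap coverage.
#' @return data.frame with `column`, `residue`, `conservation`,
#'   `reference_position` (`NA` where the reference is gapped).
#' @export
fully_conserved_positions <- function(msa, reference_id, threshold = 1.0,
                                      min_coverage = 0.5) {
  m <- as_aligned_matrix(msa)
  prof <- column_conservation(msa)
  posmap <- ref_position_map(m, reference_id)
  keep <- prof$conservation >= threshold & prof$coverage >= min_coverage
  out <- prof[keep, c("column", "residue", "conservation"), drop = FALSE]
  out$reference_position <- posmap[out$column]
  rownames(out) <- NULL
  out
}

#' Write motif matches as TSV
#'
#' @param sequences Named character vector of sequences.
#' @param pattern A `motif_pattern` or pattern string.
#' @param path Output path.
#' @return The match data.frame (`sequence_id`, `start`, `matched_text`),
#'   invisibly; also written to `path`.
#' @export
write_motif_matches <- function(sequences, pattern, path) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  k <- length(pattern$elements)
  rows <- lapply(names(sequences), function(id) {
    starts <- scan_motif(sequences[[id]], pattern)
    if (!length(starts)) return(NULL)
    data.frame(sequence_id = id, start = starts,
               matched_text = substring(sequences[[id]], starts, starts + k - 1L))
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(sequence_id = character(), start = integer(),
                     matched_text = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
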