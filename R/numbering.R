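# Generic residue numbering for PMTRs, adapted from the Ballesteros-Weinstein
# scheme used for animal GPCRs.  For every TM helix the most conserved residue
# of the family alignment is chosen as reference and assigned index 50; every
# other TM residue is numbered by its offset from that reference, rendered as
# "tm.idx" (e.g. "3.50").  Labels such as "E122^3.50" combine residue,
# sequence position and generic number.

#' Per-column conservation profile of an alignment
#'
#' For every alignment column: the modal non-gap residue, the conservation
#' fraction (modal count divided by the number of non-gap residues), and the
#' coverage (non-gap fraction of sequences).  All-gap columns get conservation
#' 0 and an `NA` modal residue.  Ties for the modal residue are broken
#' alphabetically.
#'
#' @param msa Named character vector of aligned sequences (equal lengths, `-`
#'   for gaps) or a `Biostrings::AAStringSet`.
#' @return data.frame with `column`, `residue`, `conservation`, `coverage`.
#' @export
column_conservation <- function(msa) {
  msa <- as_aligned_matrix(msa)
  n <- nrow(msa)
  if (n < 2) data_error("alignment must contain at least 2 sequences")
  prof <- lapply(seq_len(ncol(msa)), function(j) {
    col <- msa[, j]
    res <- col[col != "-"]
    if (!length(res))
      return(data.frame(column = j, residue = NA_character_,
                        conservation = 0, coverage = 0))
    tab <- table(res)
    top <- sort(names(tab)[tab == max(tab)])[1]
    data.frame(column = j, residue = top,
               conservation = max(tab) / length(res),
               coverage = length(res) / n)
  })
  do.call(rbind, prof)
}

as_aligned_matrix <- function(msa) {
  if (inherits(msa, "AAStringSet")) {
    ids <- names(msa)
    msa <- as.character(msa)
    names(msa) <- ids
  }
  widths <- nchar(msa)
  if (length(unique(widths)) != 1)
    data_error("ragged alignment: sequences have unequal aligned lengths")
  m <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

# alignment column -> reference sequence position (NA at reference gaps)
ref_position_map <- function(msa_matrix, reference_id) {
  if (!reference_id %in% rownames(msa_matrix))
    data_error(paste0("reference sequence '", reference_id, "' absent from alignment"))
  refrow <- msa_matrix[reference_id, ]
  pos <- cumsum(refrow != "-")
  pos[refrow == "-"] <- NA_integer_
  pos
}

#' Pick per-TM reference residues
#'
#' For each TM segment (given in reference-sequence coordinates) the
#' reference residue is the alignment column with maximal conservation among
#' columns that (i) map to a non-gap reference position inside the TM and
#' (ii) have coverage of at least `min_coverage`.  Ties are broken by the
#' smallest reference position.  When an external per-column conservation
#' score vector is supplied (e.g. from an evolutionary-rate server), the
#' internal pick is accepted only if it lies within the top 3 external ranks
#' of its TM; otherwise the internal ranking is kept and a warning is logged
#' in the provenance note.
#'
#' @param msa Alignment (named character vector or `AAStringSet`).
#' @param reference_id Id of the reference sequence within `msa`.
#' @param tm_segments data.frame `label`, `start`, `end` with TM rows in
#'   reference coordinates.
#' @param external_scores Optional numeric vector of per-alignment-column
#'   scores (higher = more conserved).
#' @param min_coverage Minimum non-gap coverage for a column to be eligible.
#' @return A `numbering_scheme`: list with `reference_sequence_id` and a
#'   data.frame `references` (`tm`, `position`, `residue`, `conservation`,
#'   `note`).
#' @export
pick_reference_residues <- function(msa, reference_id, tm_segments,
                                    external_scores = NULL,
                                    min_coverage = 0.5) {
  m <- as_aligned_matrix(msa)
  prof <- column_conservation(msa)
  posmap <- ref_position_map(m, reference_id)
  tm_rows <- tm_segments[grepl("^TM", tm_segments$label), , drop = FALSE]
  refs <- lapply(seq_len(nrow(tm_rows)), function(i) {
    tm_label <- tm_rows$label[i]
    k <- as.integer(sub("^TM", "", tm_label))
    in_tm <- which(!is.na(posmap) & posmap >= tm_rows$start[i] &
                     posmap <= tm_rows$end[i])
    elig <- in_tm[prof$coverage[in_tm] >= min_coverage]
    if (!length(elig))
      data_error(paste0(tm_label, ": no reference-aligned column with coverage >= ",
                        min_coverage))
    ord <- elig[order(-prof$conservation[elig], posmap[elig])]
    pick <- ord[1]
    note <- "internal ranking"
    if (!is.null(external_scores)) {
      ext <- external_scores[elig]
      top3 <- elig[order(-ext)][seq_len(min(3, length(elig)))]
      if (pick %in% top3) {
        note <- "consensus with external scores"
      } else {
        warning(sprintf("%s: internal pick not in external top-3; keeping internal ranking",
                        tm_label), call. = FALSE)
        note <- "internal ranking (external disagreement)"
      }
    }
    data.frame(tm = k, position = posmap[pick],
               residue = prof$residue[pick],
               conservation = prof$conservation[pick],
               note = note, stringsAsFactors = FALSE)
  })
  refs <- do.call(rbind, refs)
  refs <- refs[order(refs$tm), , drop = FALSE]
  numbering_scheme(reference_id, refs)
}

#' Construct a numbering scheme
#'
#' @param reference_sequence_id Id of the reference receptor.
#' @param references data.frame with columns `tm` (1..7) and `position`
#'   (1-based position of the reference residue on the reference sequence;
#'   `NA` when no reference is defined for that TM), plus optional `residue`,
#'   `conservation`, `note`.
#' @return A `numbering_scheme`.
#' @export
numbering_scheme <- function(reference_sequence_id, references) {
  if (!all(c("tm", "position") %in% names(references)))
    config_error("references must have columns tm and position")
  refs <- references[order(references$tm), , drop = FALSE]
  pos <- refs$position[!is.na(refs$position)]
  if (is.unsorted(pos, strictly = TRUE))
    config_error("reference positions must be strictly increasing across TMs")
  structure(list(reference_sequence_id = reference_sequence_id,
                 references = refs),
            class = "numbering_scheme")
}

#' Default AtPMTR1 numbering scheme
#'
#' Reference positions on the AtPMTR1 sequence for TM1-TM5 and TM7
#' (55, 88, 122, 155, 183, 263).  TM6 carries no reference: it is the least
#' conserved helix of the family, with no fully conserved residues, so its
#' reference must be computed from an alignment with
#' [pick_reference_residues()] and is flagged low-confidence.
#'
#' @return A `numbering_scheme` for AtPMTR1.
#' @export
atpmtr1_scheme <- function() {
  numbering_scheme("AtPMTR1", data.frame(
    tm = 1:7,
    position = c(55L, 88L, 122L, 155L, 183L, NA, 263L),
    residue = c(NA, NA, "E", NA, NA, NA, "P"),
    note = c(rep("anchored", 5), "undefined (low-confidence TM)", "anchored"),
    stringsAsFactors = FALSE))
}

#' @export
print.numbering_scheme <- function(x, ...) {
  cat(sprintf("numbering_scheme (reference %s)\n", x$reference_sequence_id))
  print(x$references)
  invisible(x)
}

#' Generic number of one TM residue
#'
#' Computes `idx = 50 + (position - reference)` for a residue at `position`
#' in helix `tm` under `scheme`, rendered as `"tm.idx"`.
#'
#' @param position 1-based residue position on the scheme's reference
#'   sequence.
#' @param tm TM helix number (1-7).
#' @param scheme A `numbering_scheme`.
#' @return Character scalar like `"3.50"`.
#' @export
generic_label <- function(position, tm, scheme) {
  ref <- scheme$references$position[scheme$references$tm == tm]
  if (!length(ref) || is.na(ref))
    data_error(paste0("no reference residue defined for TM", tm))
  idx <- 50L + (as.integer(position) - as.integer(ref))
  if (any(idx < 1)) data_error("generic index below 1")
  paste0(tm, ".", idx)
}

#' Assign generic numbers to all TM residues
#'
#' Numbers every residue inside the topology's TM segments relative to the
#' per-TM reference residues of `scheme`; non-TM residues receive no generic
#' number.  TMs whose reference is undefined in the scheme are skipped.
#'
#' @param topology A `topology_annotation` for the scheme's reference
#'   sequence.
#' @param scheme A `numbering_scheme`.
#' @return data.frame with `position`, `tm`, `idx`, `generic` for all numbered
#'   residues.
#' @export
assign_generic_numbers <- function(topology, scheme) {
  tm_rows <- topology$segments[grepl("^TM", topology$segments$label), ,
                               drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tm_rows))) {
    k <- as.integer(sub("^TM", "", tm_rows$label[i]))
    ref <- scheme$references$position[scheme$references$tm == k]
    if (!length(ref) || is.na(ref)) next
    if (ref < tm_rows$start[i] || ref > tm_rows$end[i])
      data_error(paste0("reference residue ", ref, " lies outside TM", k,
                        " (", tm_rows$start[i], "-", tm_rows$end[i], ")"))
    pos <- seq.int(tm_rows$start[i], tm_rows$end[i])
    idx <- 50L + (pos - as.integer(ref))
    out[[length(out) + 1]] <- data.frame(position = pos, tm = k, idx = idx,
                                         generic = paste0(k, ".", idx))
  }
  if (!length(out))
    return(data.frame(position = integer(), tm = integer(), idx = integer(),
                      generic = character()))
  do.call(rbind, out)
}

#' Map a residue position across sequences through an alignment
#'
#' Returns the position in `to_id` that shares the alignment column with
#' `position` in `from_id`, or `NA` when the target sequence is gapped in
#' that column.
#'
#' @param msa Alignment (named character vector or `AAStringSet`).
#' @param from_id,to_id Sequence ids within the alignment.
#' @param position 1-based ungapped position in `from_id`.
#' @return Integer position in `to_id`, or `NA_integer_`.
#' @export
map_position <- function(msa, from_id, position, to_id) {
  m <- as_aligned_matrix(msa)
  from_map <- ref_position_map(m, from_id)
  col <- which(from_map == position)
  if (!length(col))
    data_error(paste0("position ", position, " out of range (or gapped) in '",
                      from_id, "'"))
  to_map <- ref_position_map(m, to_id)
  out <- to_map[col[1]]
  if (is.na(out)) NA_integer_ else as.integer(out)
}

#' Parse a generic residue label
#'
#' Grammar: `<AA><pos>^<tm>.<idx>` with an optional trailing receptor tag
#' (e.g. `"E122^3.50"` or `"E122^3.50At"`).
#'
#' @param label Character scalar.
#' @return List with `residue`, `position`, `tm`, `idx`, `tag`.
#' @export
parse_generic <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Z])([0-9]+)\\^([1-7])\\.([0-9]+)([A-Za-z]*)$",
                          label))[[1]]
  if (!length(m)) parse_error(paste0("malformed generic label: '", label, "'"))
  list(residue = m[2], position = as.integer(m[3]),
       tm = as.integer(m[4]), idx = as.integer(m[5]),
       tag = if (nzchar(m[6])) m[6] else NA_character_)
}

#' Render a generic residue label
#'
#' Inverse of [parse_generic()].
#'
#' @param residue One-letter amino-acid code.
#' @param position 1-based sequence position.
#' @param tm TM helix number.
#' @param idx Generic index.
#' @param tag Optional receptor tag appended after the index.
#' @return Character scalar like `"E122^3.50"`.
#' @export
render_generic <- function(residue, position, tm, idx, tag = NULL) {
  paste0(residue, position, "^", tm, ".", idx,
         if (!is.null(tag) && !is.na(tag)) tag else "")
}

#' Export a generic-number table as TSV
#'
#' @param numbers data.frame from [assign_generic_numbers()].
#' @param sequence_id Id recorded in the table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_numbering_tsv <- function(numbers, sequence_id, path) {
  df <- cbind(sequence_id = sequence_id, numbers)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a numbering scheme as JSON
#'
#' @param scheme A `numbering_scheme`.
#' @param path File path.
#' @return `path` (writer) or the scheme (reader).
#' @export
write_scheme_json <- function(scheme, path) {
  jsonlite::write_json(list(reference_sequence_id = scheme$reference_sequence_id,
                            references = scheme$references),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  refs <- as.data.frame(x$references)
  refs$position <- suppressWarnings(as.integer(refs$position))
  numbering_scheme(x$reference_sequence_id, refs)
}
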