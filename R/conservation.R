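#' Read a protein multiple alignment
#'
#' Reads FASTA or Clustal alignments via Biostrings and designates one
#' row as the reference (the human FVIII sequence in the intended use).
#' A column map from reference residue index (legacy numbering) to
#' alignment column is built by skipping gaps in the reference row.
#'
#' @param path alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param reference name of the reference row (default: first row).
#' @return A list of class `f8_alignment` with elements `seqs` (named
#'   character vector of aligned rows, equal length), `reference`, and
#'   `column_map` (integer vector: reference position -> column).
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           reference = NULL) {
  format <- match.arg(format)
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("alignment rows must be named")
  }
  new_alignment(seqs, reference %||% names(seqs)[1L])
}

new_alignment <- function(seqs, reference) {
  if (!reference %in% names(seqs)) {
    stop("reference sequence '", reference, "' absent from alignment")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) stop("alignment rows have unequal lengths")
  ref_chars <- strsplit(seqs[[reference]], "")[[1L]]
  column_map <- which(ref_chars != "-")
  if (!length(column_map)) stop("reference row contains no residues")
  out <- list(seqs = seqs, reference = reference, column_map = column_map)
  class(out) <- "f8_alignment"
  out
}

#' @export
print.f8_alignment <- function(x, ...) {
  cat("Protein alignment: ", length(x$seqs), " row(s), width ",
      nchar(x$seqs[[1L]]), "; reference '", x$reference, "' (",
      length(x$column_map), " residues)\n", sep = "")
  invisible(x)
}

#' Positional conservation from an alignment
#'
#' `conservation_fraction()` returns, for each reference position, the
#' fraction of non-reference rows whose residue at the mapped column
#' equals the reference residue; gaps in other rows count as mismatches.
#' An alignment with no non-reference rows yields 1 with a warning
#' (vacuous agreement), so pipelines without ortholog data still run.
#'
#' `is_highly_conserved()` thresholds that fraction; the default
#' threshold 1 demands identity across every aligned ortholog, the
#' strictest reading of "highly conserved".
#'
#' @param alignment a `f8_alignment`.
#' @param position_legacy integer vector of reference positions.
#' @param threshold conservation fraction required, in (0, 1].
#' @return Numeric vector in \[0, 1\] (fractions) or logical vector.
#' @export
conservation_fraction <- function(alignment, position_legacy) {
  stopifnot(inherits(alignment, "f8_alignment"))
  position_legacy <- as.integer(position_legacy)
  if (any(is.na(position_legacy)) || any(position_legacy < 1L) ||
      any(position_legacy > length(alignment$column_map))) {
    stop("position outside the reference sequence (length ",
         length(alignment$column_map), ")")
  }
  others <- setdiff(names(alignment$seqs), alignment$reference)
  if (!length(others)) {
    warning("alignment has no non-reference rows; conservation is vacuously 1")
    return(rep(1, length(position_legacy)))
  }
  cols <- alignment$column_map[position_legacy]
  ref_res <- substring(alignment$seqs[[alignment$reference]], cols, cols)
  matches <- vapply(others, function(nm) {
    substring(alignment$seqs[[nm]], cols, cols) == ref_res
  }, logical(length(cols)))
  if (length(cols) == 1L) matches <- matrix(matches, nrow = 1L)
  rowMeans(matches)
}

#' @rdname conservation_fraction
#' @export
is_highly_conserved <- function(alignment, position_legacy, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  conservation_fraction(alignment, position_legacy) >= threshold
}

#' Append conservation annotations to a cohort
#'
#' Adds `conservation_fraction` and `highly_conserved` columns computed
#' at each record's position.
#'
#' @param cohort a `f8_cohort`.
#' @param alignment a `f8_alignment` whose reference covers the cohort's
#'   positions.
#' @param threshold passed to [is_highly_conserved()].
#' @return The cohort with two added columns.
#' @export
annotate_conservation <- function(cohort, alignment, threshold = 1) {
  stopifnot(inherits(cohort, "f8_cohort"))
  cohort$conservation_fraction <- conservation_fraction(alignment, cohort$position)
  cohort$highly_conserved <- cohort$conservation_fraction >= threshold
  cohort
}
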