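#' @importFrom utils read.table write.table count.fields
NULL

# Length of the mature FVIII protein (signal peptide of 19 residues removed).
FVIII_MATURE_LENGTH <- 2332L
FVIII_SIGNAL_PEPTIDE <- 19L

AA_ONE <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

SEVERITY_LEVELS <- c("severe", "moderate", "mild")
STATUS_LEVELS <- c("positive", "negative", "unknown")

PREDICTOR_COLUMNS <- c("sift_score", "polyphen_score", "agvgd_class",
                       "kd4v_call", "mutationtaster_call")
COHORT_COLUMNS <- c("variant_id", "protein_change", "ref_aa", "position",
                    "alt_aa", "severity", "inhibitor_status",
                    PREDICTOR_COLUMNS)

#' One- and three-letter amino-acid codes
#'
#' @return `aa_alphabet()` returns the 20 one-letter codes;
#'   `aa_three_letter()` returns the named map from one-letter to
#'   three-letter codes.
#' @export
aa_alphabet <- function() AA_ONE

#' @rdname aa_alphabet
#' @export
aa_three_letter <- function() AA_THREE

three_to_one <- function(x) {
  idx <- match(tolower(x), tolower(AA_THREE))
  out <- names(AA_THREE)[idx]
  out
}

#' Parse a protein-change string
#'
#' Accepts the HGVS-style three-letter form (`"p.Arg2016Trp"`,
#' case-insensitive residue codes) and the compact one-letter form
#' (`"R593C"`). Synonymous changes (reference equal to alternate) are
#' rejected because the package models missense substitutions only.
#'
#' @param text character vector of protein-change strings.
#' @param max_position largest admissible residue index (defaults to the
#'   mature FVIII length, 2332).
#' @return A data.frame with columns `ref_aa`, `position`, `alt_aa`
#'   (one-letter codes, integer position), one row per input.
#' @examples
#' parse_protein_change("p.Arg2016Trp")
#' parse_protein_change("R593C")
#' @export
parse_protein_change <- function(text, max_position = FVIII_MATURE_LENGTH) {
  stopifnot(is.character(text), length(text) >= 1L)
  m3 <- regmatches(text, regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", text))
  m1 <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))
  ref <- alt <- character(length(text))
  pos <- integer(length(text))
  for (i in seq_along(text)) {
    tok <- text[[i]]
    if (length(m3[[i]]) == 4L) {
      r <- three_to_one(m3[[i]][2L])
      a <- three_to_one(m3[[i]][4L])
      if (is.na(r)) stop("unknown residue code '", m3[[i]][2L], "' in '", tok, "'")
      if (is.na(a)) stop("unknown residue code '", m3[[i]][4L], "' in '", tok, "'")
      p <- suppressWarnings(as.integer(m3[[i]][3L]))
    } else if (length(m1[[i]]) == 4L) {
      r <- toupper(m1[[i]][2L])
      a <- toupper(m1[[i]][4L])
      if (!r %in% AA_ONE) stop("unknown residue code '", m1[[i]][2L], "' in '", tok, "'")
      if (!a %in% AA_ONE) stop("unknown residue code '", m1[[i]][4L], "' in '", tok, "'")
      p <- suppressWarnings(as.integer(m1[[i]][3L]))
    } else {
      stop("unparseable protein change '", tok, "'")
    }
    if (is.na(p) || p < 1L) stop("invalid residue position in '", tok, "'")
    if (p > max_position) {
      stop("residue position ", p, " in '", tok, "' exceeds ", max_position)
    }
    if (r == a) stop("synonymous change '", tok, "': reference equals alternate")
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  data.frame(ref_aa = ref, position = pos, alt_aa = alt,
             stringsAsFactors = FALSE)
}

#' Convert between legacy (mature-protein) and HGVS residue numbering
#'
#' Mature FVIII lacks the 19-residue signal peptide, so HGVS protein
#' numbering exceeds legacy numbering by 19. The two maps are mutual
#' inverses on their domains; HGVS positions 1-19 fall inside the signal
#' peptide and have no mature counterpart.
#'
#' @param position_legacy,position_hgvs integer vector of residue indices.
#' @return Integer vector of converted positions.
#' @examples
#' legacy_to_hgvs(372) # 391
#' hgvs_to_legacy(391) # 372
#' @export
legacy_to_hgvs <- function(position_legacy) {
  position_legacy <- as.integer(position_legacy)
  if (any(is.na(position_legacy)) || any(position_legacy < 1L)) {
    stop("legacy positions must be positive integers")
  }
  position_legacy + FVIII_SIGNAL_PEPTIDE
}

#' @rdname legacy_to_hgvs
#' @export
hgvs_to_legacy <- function(position_hgvs) {
  position_hgvs <- as.integer(position_hgvs)
  if (any(is.na(position_hgvs)) || any(position_hgvs < 1L)) {
    stop("HGVS positions must be positive integers")
  }
  if (any(position_hgvs <= FVIII_SIGNAL_PEPTIDE)) {
    stop("HGVS positions 1-", FVIII_SIGNAL_PEPTIDE,
         " lie in the signal peptide and have no mature coordinate")
  }
  position_hgvs - FVIII_SIGNAL_PEPTIDE
}

#' Construct a variant cohort
#'
#' A cohort is a data.frame with one row per annotated missense variant:
#' `variant_id`, `protein_change`, parsed `ref_aa`/`position`/`alt_aa`
#' (legacy mature-protein numbering), `severity`, `inhibitor_status`
#' (`positive`/`negative`/`unknown`), and the five optional predictor
#' columns (`sift_score`, `polyphen_score`, `agvgd_class`, `kd4v_call`,
#' `mutationtaster_call`).
#'
#' @param df data.frame holding at least `variant_id`, `protein_change`,
#'   `severity`, `inhibitor_status`; predictor columns optional (filled
#'   with `NA` when absent). `ref_aa`/`position`/`alt_aa` are re-derived
#'   from `protein_change` when missing.
#' @param provenance free-text label describing where the table came from.
#' @return A `f8_cohort` data.frame.
#' @export
as_cohort <- function(df, provenance = "") {
  stopifnot(is.data.frame(df))
  need <- c("variant_id", "protein_change", "severity", "inhibitor_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!all(c("ref_aa", "position", "alt_aa") %in% names(df))) {
    parsed <- parse_protein_change(as.character(df$protein_change))
    df$ref_aa <- parsed$ref_aa
    df$position <- parsed$position
    df$alt_aa <- parsed$alt_aa
  }
  for (col in PREDICTOR_COLUMNS) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("sift_score", "polyphen_score")) NA_real_ else NA_character_
    }
  }
  df$variant_id <- as.character(df$variant_id)
  df$severity <- tolower(as.character(df$severity))
  df$inhibitor_status <- tolower(as.character(df$inhibitor_status))
  df$position <- as.integer(df$position)
  validate_cohort(df)
  out <- df[, COHORT_COLUMNS]
  rownames(out) <- NULL
  class(out) <- c("f8_cohort", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

validate_cohort <- function(df) {
  if (anyDuplicated(df$variant_id)) {
    stop("variant_id values must be unique within a cohort")
  }
  bad <- which(df$ref_aa == df$alt_aa)
  if (length(bad)) stop("synonymous record(s) at row(s) ", paste(bad, collapse = ", "))
  if (!all(df$ref_aa %in% AA_ONE) || !all(df$alt_aa %in% AA_ONE)) {
    stop("residues must be standard one-letter amino-acid codes")
  }
  if (any(df$position < 1L | df$position > FVIII_MATURE_LENGTH)) {
    stop("positions must lie in 1..", FVIII_MATURE_LENGTH,
         " (legacy mature-protein numbering)")
  }
  if (!all(df$severity %in% SEVERITY_LEVELS)) {
    stop("severity must be one of: ", paste(SEVERITY_LEVELS, collapse = ", "))
  }
  if (!all(df$inhibitor_status %in% STATUS_LEVELS)) {
    stop("inhibitor_status must be one of: ", paste(STATUS_LEVELS, collapse = ", "))
  }
  invisible(df)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read and write cohort tables
#'
#' Cohort tables are delimited text (comma or tab, auto-detected on read)
#' with a header row. Mandatory columns: `protein_change`, `severity`,
#' `inhibitor_status`; `variant_id` is used when present and synthesized
#' otherwise; the five predictor columns are optional. Unknown inhibitor
#' status is encoded by the literal token `"unknown"`; blank cells map to
#' unknown with a warning. Positions may be given in legacy (mature) or
#' HGVS numbering; HGVS input is shifted onto the internal legacy
#' convention on ingestion.
#'
#' @param path file path.
#' @param sep `"auto"`, `"tab"` or `"comma"`.
#' @param numbering numbering scheme of the protein-change strings.
#' @param provenance label stored on the cohort.
#' @return `read_cohort()` returns a `f8_cohort`; `write_cohort()`
#'   invisibly returns `path`.
#' @export
read_cohort <- function(path, sep = c("auto", "tab", "comma"),
                        numbering = c("legacy", "hgvs"),
                        provenance = basename(path)) {
  sep <- match.arg(sep)
  numbering <- match.arg(numbering)
  delim <- switch(sep, auto = detect_sep(path), tab = "\t", comma = ",")
  df <- read.table(path, sep = delim, header = TRUE,
                   stringsAsFactors = FALSE, quote = "\"",
                   colClasses = "character", na.strings = NULL,
                   check.names = TRUE, fileEncoding = "UTF-8")
  need <- c("protein_change", "severity", "inhibitor_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("file '", path, "' lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!"variant_id" %in% names(df)) {
    df$variant_id <- sprintf("V%04d", seq_len(nrow(df)))
  }
  max_pos <- FVIII_MATURE_LENGTH +
    if (numbering == "hgvs") FVIII_SIGNAL_PEPTIDE else 0L
  parsed <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    parsed[[i]] <- tryCatch(
      parse_protein_change(df$protein_change[[i]], max_position = max_pos),
      error = function(e) {
        stop("line ", i + 1L, " of '", path, "': ", conditionMessage(e),
             call. = FALSE)
      })
  }
  parsed <- do.call(rbind, parsed)
  if (numbering == "hgvs") parsed$position <- hgvs_to_legacy(parsed$position)
  df$ref_aa <- parsed$ref_aa
  df$position <- parsed$position
  df$alt_aa <- parsed$alt_aa
  blank <- !nzchar(trimws(df$inhibitor_status))
  if (any(blank)) {
    warning(sum(blank), " blank inhibitor_status cell(s) mapped to 'unknown'")
    df$inhibitor_status[blank] <- "unknown"
  }
  df$sift_score <- parse_optional_numeric(df, "sift_score")
  df$polyphen_score <- parse_optional_numeric(df, "polyphen_score")
  for (col in c("agvgd_class", "kd4v_call", "mutationtaster_call")) {
    df[[col]] <- parse_optional_character(df, col)
  }
  as_cohort(df, provenance = provenance)
}

parse_optional_numeric <- function(df, col) {
  if (!col %in% names(df)) return(rep(NA_real_, nrow(df)))
  x <- trimws(df[[col]])
  out <- suppressWarnings(as.numeric(x))
  bad <- nzchar(x) & is.na(out)
  if (any(bad)) {
    stop("line ", which(bad)[1L] + 1L, ": non-numeric value '",
         x[which(bad)[1L]], "' in column ", col)
  }
  out
}

parse_optional_character <- function(df, col) {
  if (!col %in% names(df)) return(rep(NA_character_, nrow(df)))
  x <- trimws(df[[col]])
  x[!nzchar(x)] <- NA_character_
  x
}

#' @rdname read_cohort
#' @param cohort a `f8_cohort`.
#' @export
write_cohort <- function(cohort, path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  stopifnot(inherits(cohort, "f8_cohort"))
  delim <- if (sep == "tab") "\t" else ","
  out <- as.data.frame(cohort)[, COHORT_COLUMNS]
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           format(out[[col]], trim = TRUE, scientific = FALSE))
    } else {
      out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
    }
  }
  write.table(out, path, sep = delim, quote = FALSE,
              row.names = FALSE, col.names = TRUE, eol = "\n",
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter a cohort by severity and inhibitor-status availability
#'
#' Order-preserving subset. With no active filters this is the identity.
#'
#' @param cohort a `f8_cohort`.
#' @param severity optional character vector of severities to keep.
#' @param known_status_only drop records with `inhibitor_status == "unknown"`.
#' @return The filtered `f8_cohort`.
#' @export
filter_cohort <- function(cohort, severity = NULL, known_status_only = FALSE) {
  stopifnot(inherits(cohort, "f8_cohort"))
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(severity)) {
    severity <- match.arg(tolower(severity), SEVERITY_LEVELS, several.ok = TRUE)
    keep <- keep & cohort$severity %in% severity
  }
  if (isTRUE(known_status_only)) {
    keep <- keep & cohort$inhibitor_status != "unknown"
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("f8_cohort", "data.frame")
  attr(out, "provenance") <- attr(cohort, "provenance")
  out
}

#' @export
print.f8_cohort <- function(x, ...) {
  cat("FVIII missense cohort: ", nrow(x), " record(s)",
      if (nzchar(attr(x, "provenance") %||% "")) paste0(" [", attr(x, "provenance"), "]"),
      "\n", sep = "")
  known <- sum(x$inhibitor_status != "unknown")
  cat("  known inhibitor status: ", known, " (",
      sum(x$inhibitor_status == "positive"), " positive)\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
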