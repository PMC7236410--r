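AA_CLASS_LEVELS <- c("hydrophobic", "polar_uncharged", "acidic", "basic")
AGVGD_BREAKS <- c(0, 15, 25, 35, 45, 55, 65)
AGVGD_LEVELS <- paste0("C", AGVGD_BREAKS)

.f8_cache <- new.env(parent = emptyenv())

#' Four-class physicochemical amino-acid table
#'
#' Assigns every standard residue to exactly one of four side-chain
#' classes: hydrophobic (A, V, F, P, M, I, L, W), polar uncharged
#' (S, Y, N, Q, C, T, H, G), acidic (D, E), basic (K, R). The table is
#' packaged as plain text and injectable, so alternative schemes can be
#' substituted for sensitivity analyses.
#'
#' @param path optional path to an alternative class table (TSV with
#'   columns `aa`, `class`).
#' @return Named character vector mapping one-letter codes to class names.
#' @export
aa_class_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.f8_cache$class_table)) return(.f8_cache$class_table)
    path <- system.file("extdata", "aa_classes.tsv", package = "f8missense",
                        mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tbl <- stats::setNames(df$class, df$aa)
  if (!setequal(names(tbl), AA_ONE) || anyDuplicated(names(tbl))) {
    stop("class table must assign each of the 20 residues exactly once")
  }
  if (!all(tbl %in% AA_CLASS_LEVELS)) {
    stop("unknown class label(s): ",
         paste(setdiff(tbl, AA_CLASS_LEVELS), collapse = ", "))
  }
  if (cache) .f8_cache$class_table <- tbl
  tbl
}

#' Classify a substitution as intra- or inter-class
#'
#' A substitution within one physicochemical class is intra-class;
#' crossing classes is inter-class. Symmetric in its arguments.
#'
#' @param ref_aa,alt_aa one-letter codes (vectorized).
#' @param table class table from [aa_class_table()].
#' @return Character vector of `"intra"` / `"inter"`.
#' @examples
#' classify_substitution("L", "I") # intra
#' classify_substitution("R", "C") # inter
#' @export
classify_substitution <- function(ref_aa, alt_aa, table = aa_class_table()) {
  bad <- setdiff(c(ref_aa, alt_aa), names(table))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  if (any(ref_aa == alt_aa)) stop("reference and alternate residues must differ")
  unname(ifelse(table[ref_aa] == table[alt_aa], "intra", "inter"))
}

#' Grantham physicochemical parameters
#'
#' Loads the 1974 composition/polarity/volume values and the weighting
#' constants from the packaged data files, and computes the scale factor
#' `rho` such that the mean distance over all 190 unordered residue pairs
#' equals 100. The MD5 digests of the data files are attached so the
#' packaged tables are verifiable.
#'
#' @return List with `properties` (data.frame `aa`, `composition`,
#'   `polarity`, `volume`), `alpha`, `beta`, `gamma`, `rho`; attribute
#'   `md5` holds the data-file digests.
#' @export
grantham_params <- function() {
  if (!is.null(.f8_cache$grantham)) return(.f8_cache$grantham)
  prop_path <- system.file("extdata", "grantham1974.tsv",
                           package = "f8missense", mustWork = TRUE)
  w_path <- system.file("extdata", "grantham_weights.tsv",
                        package = "f8missense", mustWork = TRUE)
  props <- utils::read.table(prop_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  stopifnot(setequal(props$aa, AA_ONE))
  w <- utils::read.table(w_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  w <- stats::setNames(w$value, w$parameter)
  params <- list(properties = props,
                 alpha = w[["alpha"]], beta = w[["beta"]], gamma = w[["gamma"]],
                 rho = 1)
  pairs <- utils::combn(AA_ONE, 2)
  raw <- grantham_distance(pairs[1, ], pairs[2, ], params)
  params$rho <- 100 / mean(raw)
  attr(params, "md5") <- tools::md5sum(c(prop_path, w_path))
  .f8_cache$grantham <- params
  params
}

grantham_cpv <- function(aa, params) {
  idx <- match(aa, params$properties$aa)
  if (anyNA(idx)) {
    stop("unknown residue(s): ", paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  cbind(c = params$properties$composition[idx],
        p = params$properties$polarity[idx],
        v = params$properties$volume[idx])
}

#' Grantham distance between two residues
#'
#' Weighted Euclidean difference in composition/polarity/volume space,
#' `rho * sqrt(alpha (c_i - c_j)^2 + beta (p_i - p_j)^2 +
#' gamma (v_i - v_j)^2)`, scaled so the mean over all 190 unordered
#' pairs is 100. Symmetric, non-negative, zero only for identical
#' residues (a semimetric, not a metric).
#'
#' @param ref_aa,alt_aa one-letter codes (vectorized).
#' @param params from [grantham_params()].
#' @return Numeric vector of distances.
#' @examples
#' round(grantham_distance("L", "I")) # 5, the closest pair
#' round(grantham_distance("C", "W")) # 215, the farthest pair
#' @export
grantham_distance <- function(ref_aa, alt_aa, params = grantham_params()) {
  a <- grantham_cpv(ref_aa, params)
  b <- grantham_cpv(alt_aa, params)
  params$rho * sqrt(params$alpha * (a[, "c"] - b[, "c"])^2 +
                    params$beta * (a[, "p"] - b[, "p"])^2 +
                    params$gamma * (a[, "v"] - b[, "v"])^2)
}

#' Bin a Grantham deviation into Align-GVGD-style classes
#'
#' Classes run C0 to C65; the bin is the largest threshold in
#' {0, 15, 25, 35, 45, 55, 65} not exceeding the deviation. C45-C65 are
#' read as likely to affect function, C0-C25 as unlikely; C35 sits in
#' neither stated range.
#'
#' @param gd non-negative numeric vector of GD values.
#' @return Character vector of `"C0"` ... `"C65"`.
#' @export
agvgd_bin <- function(gd) {
  if (any(is.na(gd)) || any(gd < 0)) stop("GD values must be non-negative")
  AGVGD_LEVELS[findInterval(gd, AGVGD_BREAKS)]
}

#' GV/GD scores for an alignment column
#'
#' In composition/polarity/volume space the residues observed in an
#' alignment column span an axis-aligned range box. GV (Grantham
#' variation) is the weighted norm of the box extents; GD (Grantham
#' deviation) is the same norm of the component-wise distances from the
#' substituting residue to the nearest point of the box, zero when the
#' residue falls inside it. On a single-residue column the box collapses
#' and GD reduces to the pairwise Grantham distance.
#'
#' @param observed_residues character vector (multiset) of residues in
#'   the column; gap characters (`"-"`) are dropped.
#' @param alt_aa the substituting residue.
#' @param params from [grantham_params()].
#' @return Named numeric vector `c(gv = , gd = )`.
#' @export
gv_gd_from_column <- function(observed_residues, alt_aa,
                              params = grantham_params()) {
  observed_residues <- observed_residues[observed_residues != "-"]
  if (!length(observed_residues)) stop("alignment column contains no residues")
  obs <- grantham_cpv(observed_residues, params)
  alt <- grantham_cpv(alt_aa, params)
  lo <- apply(obs, 2, min)
  hi <- apply(obs, 2, max)
  wnorm <- function(d) {
    params$rho * sqrt(params$alpha * d[1]^2 + params$beta * d[2]^2 +
                      params$gamma * d[3]^2)
  }
  gv <- wnorm(hi - lo)
  gd <- wnorm(pmax(lo - alt[1, ], 0, alt[1, ] - hi))
  c(gv = unname(gv), gd = unname(gd))
}

#' Score a single substitution
#'
#' Convenience wrapper: parses a protein-change string and reports the
#' physicochemical class call, Grantham distance and GVGD-style bin.
#'
#' @param text protein-change string, e.g. `"R593C"`.
#' @return List with `ref_aa`, `position`, `alt_aa`, `class_ref`,
#'   `class_alt`, `class_change`, `grantham`, `agvgd_bin`, `domain`.
#' @export
score_substitution <- function(text) {
  p <- parse_protein_change(text)
  tbl <- aa_class_table()
  gd <- grantham_distance(p$ref_aa, p$alt_aa)
  list(ref_aa = p$ref_aa, position = p$position, alt_aa = p$alt_aa,
       class_ref = unname(tbl[p$ref_aa]), class_alt = unname(tbl[p$alt_aa]),
       class_change = classify_substitution(p$ref_aa, p$alt_aa, tbl),
       grantham = unname(gd), agvgd_bin = agvgd_bin(gd),
       domain = domain_of(p$position))
}
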