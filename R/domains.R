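DOMAIN_NAMES <- c("A1", "A2", "B", "A3", "C1", "C2")
DOMAIN_GROUPS <- c(A1 = "A", A2 = "A", A3 = "A", B = "B", C1 = "C", C2 = "C")

#' Default FVIII domain architecture
#'
#' Mature FVIII (2332 residues, legacy numbering) is organized
#' A1-a1-A2-a2-B-a3-A3-C1-C2. The short acidic spacers a1 (337-372),
#' a2 (711-740) and a3 (1649-1689) are merged into the preceding or
#' following A domain, giving contiguous intervals
#' A1 1-372, A2 373-740, B 741-1647, A3 1648-2019, C1 2020-2172,
#' C2 2173-2332. Under this convention the A-group (A1+A2+A3) totals
#' 1112 residues; the C-group totals 313 (one more than the 312
#' sometimes quoted, a known one-residue discrepancy of contiguous
#' partitions ending at 2332).
#'
#' The architecture is data, not code: alternative boundary conventions
#' can be loaded with [read_architecture()].
#'
#' @return A `f8_architecture` data.frame with columns `domain`,
#'   `start`, `end` (legacy, 1-based, inclusive).
#' @export
default_architecture <- function() {
  path <- system.file("extdata", "fviii_domains.tsv", package = "f8missense",
                      mustWork = TRUE)
  read_architecture(path)
}

#' Read and write domain architectures
#'
#' A boundary table is tab-delimited text with columns `domain`, `start`,
#' `end` (legacy 1-based inclusive coordinates). On read the table is
#' validated as a partition: one interval per domain name, ordered,
#' non-overlapping, jointly covering residues 1..2332.
#'
#' @param path file path.
#' @return `read_architecture()` returns a `f8_architecture` data.frame.
#' @export
read_architecture <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("domain", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_architecture(df)
}

#' @rdname read_architecture
#' @param architecture a `f8_architecture`.
#' @export
write_architecture <- function(architecture, path) {
  stopifnot(inherits(architecture, "f8_architecture"))
  utils::write.table(as.data.frame(architecture), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_architecture <- function(df) {
  if (!setequal(df$domain, DOMAIN_NAMES) || anyDuplicated(df$domain)) {
    stop("architecture must contain exactly one interval per domain: ",
         paste(DOMAIN_NAMES, collapse = ", "))
  }
  df <- df[order(df$start), ]
  if (any(df$start > df$end)) stop("interval start exceeds end")
  if (df$start[1L] != 1L || df$end[nrow(df)] != FVIII_MATURE_LENGTH) {
    stop("intervals must cover 1..", FVIII_MATURE_LENGTH)
  }
  gaps <- df$start[-1L] != df$end[-nrow(df)] + 1L
  if (any(gaps)) stop("intervals must tile the mature sequence without gaps or overlaps")
  rownames(df) <- NULL
  class(df) <- c("f8_architecture", "data.frame")
  df
}

#' Export an architecture as BED-like intervals
#'
#' BED uses 0-based half-open coordinates, so `bed_start = start - 1`
#' and `bed_end = end`.
#'
#' @param architecture a `f8_architecture`.
#' @return data.frame with `name`, `bed_start`, `bed_end`.
#' @export
architecture_to_bed <- function(architecture) {
  stopifnot(inherits(architecture, "f8_architecture"))
  data.frame(name = architecture$domain,
             bed_start = architecture$start - 1L,
             bed_end = architecture$end,
             stringsAsFactors = FALSE)
}

#' Map residue positions to domains and domain groups
#'
#' `domain_of()` returns the unique domain whose interval contains each
#' position; `group_of()` collapses domains to the groups used for
#' tabulation (A = A1+A2+A3, C = C1+C2, B alone).
#'
#' @param position_legacy integer vector, legacy mature numbering.
#' @param architecture a `f8_architecture`.
#' @param domain character vector of domain names.
#' @return character vector of domain (or group) names.
#' @examples
#' domain_of(c(372, 1689, 2332)) # "A1" "A3" "C2"
#' group_of("A3")                # "A"
#' @export
domain_of <- function(position_legacy, architecture = default_architecture()) {
  stopifnot(inherits(architecture, "f8_architecture"))
  position_legacy <- as.integer(position_legacy)
  if (any(is.na(position_legacy)) ||
      any(position_legacy < 1L | position_legacy > FVIII_MATURE_LENGTH)) {
    stop("positions must lie in 1..", FVIII_MATURE_LENGTH)
  }
  idx <- findInterval(position_legacy, architecture$start)
  architecture$domain[idx]
}

#' @rdname domain_of
#' @export
group_of <- function(domain) {
  bad <- setdiff(domain, DOMAIN_NAMES)
  if (length(bad)) stop("unknown domain name(s): ", paste(bad, collapse = ", "))
  unname(DOMAIN_GROUPS[domain])
}

#' Tabulate cohort variants by domain and domain group
#'
#' B-domain variants are excluded by default, matching the analytical
#' convention that B plays no direct role in coagulation and is dropped
#' from domain tabulations.
#'
#' @param cohort a `f8_cohort`.
#' @param architecture a `f8_architecture`.
#' @param exclude_B drop B-domain records before counting.
#' @return A list of class `f8_domain_tab` with elements `domain`
#'   (named counts over A1, A2, A3, C1, C2 and, unless excluded, B),
#'   `group` (named counts over A, C and optionally B), and
#'   `percent_A_of_AC` (100 * A / (A + C), rounded to 2 decimals).
#' @export
tabulate_by_domain <- function(cohort, architecture = default_architecture(),
                               exclude_B = TRUE) {
  stopifnot(inherits(cohort, "f8_cohort"))
  dom <- if (nrow(cohort)) domain_of(cohort$position, architecture) else character(0)
  grp <- if (length(dom)) group_of(dom) else character(0)
  if (isTRUE(exclude_B)) {
    keep <- grp != "B"
    dom <- dom[keep]; grp <- grp[keep]
    dom_levels <- c("A1", "A2", "A3", "C1", "C2")
    grp_levels <- c("A", "C")
  } else {
    dom_levels <- DOMAIN_NAMES
    grp_levels <- c("A", "B", "C")
  }
  domain_counts <- table(factor(dom, levels = dom_levels))
  group_counts <- table(factor(grp, levels = grp_levels))
  ac <- sum(group_counts[c("A", "C")])
  out <- list(
    domain = stats::setNames(as.integer(domain_counts), dom_levels),
    group = stats::setNames(as.integer(group_counts), grp_levels),
    percent_A_of_AC = if (ac > 0) round(100 * group_counts[["A"]] / ac, 2) else NA_real_
  )
  class(out) <- "f8_domain_tab"
  out
}

#' @export
print.f8_domain_tab <- function(x, ...) {
  cat("Variants by domain:\n")
  print(x$domain)
  cat("By group:\n")
  print(x$group)
  if (!is.na(x$percent_A_of_AC)) {
    cat(sprintf("A-group share of A+C: %.2f%%\n", x$percent_A_of_AC))
  }
  invisible(x)
}
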