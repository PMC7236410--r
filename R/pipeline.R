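#' Run the full missense-variant analysis pipeline
#'
#' Stages, in order: filter (severity and optionally status); domain
#' annotation (B-domain records are excluded from domain tabulations);
#' substitution-class and Grantham annotation; predictor harmonization
#' and consensus; optional conservation annotation; contingency tables
#' and association tests for consensus x inhibitor, domain group x
#' inhibitor, domain x inhibitor, and class change x inhibitor, plus
#' the inter/intra tabulation among inhibitor-positive records with its
#' goodness-of-fit and two-proportion tests. Whenever a chi-square
#' expected-count rule fails, Fisher's exact test is reported alongside.
#' Records with unknown status or undetermined consensus are dropped
#' from the corresponding tables and counted in the report notes.
#'
#' @param cohort a `f8_cohort` (or path to a cohort table).
#' @param architecture a `f8_architecture`.
#' @param consensus_strategy see [consensus_call()].
#' @param alignment optional `f8_alignment` for conservation annotation.
#' @param conservation_threshold see [is_highly_conserved()].
#' @param severity severities retained at the filter stage.
#' @param known_status_only restrict to known inhibitor status at the
#'   filter stage (tables that need status drop unknowns regardless).
#' @return A list of class `f8_report`; element `cohort` is the fully
#'   annotated cohort from which every report number is recomputable.
#' @export
run_pipeline <- function(cohort,
                         architecture = default_architecture(),
                         consensus_strategy = "kd4v_primary",
                         alignment = NULL,
                         conservation_threshold = 1,
                         severity = "severe",
                         known_status_only = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "f8_cohort"))
  n_input <- nrow(cohort)
  if (n_input == 0L) stop("filter stage: empty cohort")
  cohort <- filter_cohort(cohort, severity = severity,
                          known_status_only = known_status_only)
  if (nrow(cohort) == 0L) stop("filter stage: no records match the filters")
  n_filtered <- nrow(cohort)

  cohort$domain <- domain_of(cohort$position, architecture)
  cohort$domain_group <- group_of(cohort$domain)
  cohort$class_change <- classify_substitution(cohort$ref_aa, cohort$alt_aa)
  cohort$grantham <- grantham_distance(cohort$ref_aa, cohort$alt_aa)
  cohort$grantham_bin <- agvgd_bin(cohort$grantham)
  cohort <- annotate_consensus(cohort, strategy = consensus_strategy)
  if (!is.null(alignment)) {
    cohort <- annotate_conservation(cohort, alignment, conservation_threshold)
  }

  known <- filter_cohort(cohort_like(cohort), known_status_only = TRUE)
  n_known <- nrow(known)
  n_positive <- sum(known$inhibitor_status == "positive")
  domain_tab <- tabulate_by_domain(cohort, architecture, exclude_B = TRUE)

  consensus_tab <- table(factor(known$consensus_final,
                                levels = c("deleterious", "neutral",
                                           "undetermined")))
  del_known <- known[known$consensus_final == "deleterious", ]
  neu_known <- known[known$consensus_final == "neutral", ]
  consensus_summary <- list(
    counts = consensus_tab,
    percent_positive_in_deleterious =
      if (nrow(del_known)) round(100 * mean(del_known$inhibitor_status == "positive"), 2) else NA_real_,
    percent_positive_in_neutral =
      if (nrow(neu_known)) round(100 * mean(neu_known$inhibitor_status == "positive"), 2) else NA_real_)

  positives <- known[known$inhibitor_status == "positive", ]
  class_positive_counts <- c(
    inter = sum(positives$class_change == "inter"),
    intra = sum(positives$class_change == "intra"))
  percent_inter_in_positives <-
    if (sum(class_positive_counts)) {
      round(100 * class_positive_counts[["inter"]] / sum(class_positive_counts), 2)
    } else NA_real_

  tests <- list()
  add_test <- function(name, tab, result) {
    tests[[name]] <<- list(table = tab, result = result)
    if (inherits(result, "f8_test") && !result$valid &&
        is.matrix(tab) && all(dim(tab) == c(2L, 2L))) {
      tests[[paste0(name, "_fisher")]] <<- list(table = tab,
                                                result = fisher_exact(tab))
    }
  }
  try_table <- function(rf, cf) {
    tryCatch(build_contingency(cohort_like(cohort), rf, cf),
             error = function(e) NULL)
  }
  tab1 <- try_table("consensus_final", "inhibitor_status")
  if (!is.null(tab1)) add_test("consensus_x_inhibitor", tab1, chi_square_test(tab1))
  tab2 <- try_table("domain_group", "inhibitor_status")
  if (!is.null(tab2)) add_test("group_x_inhibitor", tab2, chi_square_test(tab2))
  tab3 <- try_table("domain", "inhibitor_status")
  if (!is.null(tab3)) add_test("domain_x_inhibitor", tab3, chi_square_test(tab3))
  tab4 <- try_table("class_change", "inhibitor_status")
  if (!is.null(tab4)) add_test("class_x_inhibitor", tab4, chi_square_test(tab4))
  if (sum(class_positive_counts) > 0) {
    tests$inter_vs_intra_in_positives_gof <- list(
      table = class_positive_counts,
      result = gof_chi_square(class_positive_counts, c(0.5, 0.5)))
    tests$inter_vs_intra_in_positives_normal <- list(
      table = class_positive_counts,
      result = two_proportion_normal_test(
        class_positive_counts[["inter"]], sum(class_positive_counts),
        class_positive_counts[["intra"]], sum(class_positive_counts)))
  }
  if (nrow(del_known) && nrow(neu_known)) {
    tests$deleterious_vs_neutral_inhibitor_rate <- list(
      table = c(deleterious_positive = sum(del_known$inhibitor_status == "positive"),
                deleterious_total = nrow(del_known),
                neutral_positive = sum(neu_known$inhibitor_status == "positive"),
                neutral_total = nrow(neu_known)),
      result = two_proportion_normal_test(
        sum(del_known$inhibitor_status == "positive"), nrow(del_known),
        sum(neu_known$inhibitor_status == "positive"), nrow(neu_known)))
  }

  conservation_summary <- NULL
  if (!is.null(alignment)) {
    conservation_summary <- list(
      n_highly_conserved = sum(cohort$highly_conserved),
      percent_highly_conserved = round(100 * mean(cohort$highly_conserved), 2),
      threshold = conservation_threshold)
  }

  report <- list(
    filter_counts = c(input = n_input, filtered = n_filtered,
                      known_status = n_known, inhibitor_positive = n_positive),
    percent_known_status = round(100 * n_known / n_filtered, 2),
    percent_positive_in_known = if (n_known) round(100 * n_positive / n_known, 2) else NA_real_,
    domain_tab = domain_tab,
    consensus = consensus_summary,
    class_positive_counts = class_positive_counts,
    percent_inter_in_positives = percent_inter_in_positives,
    conservation = conservation_summary,
    tests = tests,
    notes = c(undetermined_consensus = sum(known$consensus_final == "undetermined"),
              unknown_status = n_filtered - n_known),
    metadata = list(
      consensus_strategy = consensus_strategy,
      cohort_digest = cohort_checksum(cohort_like(cohort[, COHORT_COLUMNS])),
      package_version = as.character(utils::packageVersion("f8missense"))),
    cohort = cohort)
  class(report) <- "f8_report"
  report
}

# Reassert cohort class after data.frame subsetting/column addition.
cohort_like <- function(df) {
  class(df) <- c("f8_cohort", "data.frame")
  df
}

#' @export
print.f8_report <- function(x, ...) {
  cat("FVIII missense analysis report\n")
  cat("  records: ", x$filter_counts[["input"]], " in, ",
      x$filter_counts[["filtered"]], " after filtering\n", sep = "")
  cat(sprintf("  known inhibitor status: %d (%.2f%%); positive: %d (%.2f%% of known)\n",
              x$filter_counts[["known_status"]], x$percent_known_status,
              x$filter_counts[["inhibitor_positive"]], x$percent_positive_in_known))
  cat(sprintf("  domain groups (B excluded): A %d, C %d (A share %.2f%%)\n",
              x$domain_tab$group[["A"]], x$domain_tab$group[["C"]],
              x$domain_tab$percent_A_of_AC))
  cat(sprintf("  consensus among known: deleterious %d, neutral %d, undetermined %d\n",
              x$consensus$counts[["deleterious"]], x$consensus$counts[["neutral"]],
              x$consensus$counts[["undetermined"]]))
  cat(sprintf("  inhibitor-positive rate: %.2f%% (deleterious) vs %.2f%% (neutral)\n",
              x$consensus$percent_positive_in_deleterious,
              x$consensus$percent_positive_in_neutral))
  cat(sprintf("  class change among positives: inter %d, intra %d (%.2f%% inter)\n",
              x$class_positive_counts[["inter"]], x$class_positive_counts[["intra"]],
              x$percent_inter_in_positives))
  if (!is.null(x$conservation)) {
    cat(sprintf("  highly conserved: %d (%.2f%%) at threshold %.2f\n",
                x$conservation$n_highly_conserved,
                x$conservation$percent_highly_conserved,
                x$conservation$threshold))
  }
  cat("  tests:\n")
  for (nm in names(x$tests)) {
    r <- x$tests[[nm]]$result
    cat(sprintf("    %-38s %s p = %s%s\n", nm, r$method,
                format(r$p_value, digits = 3),
                if (!r$valid) " [validity rule violated]" else ""))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the annotated cohort as a tab-delimited table
#' (`annotated_cohort.tsv`), the test results as one row per test
#' (`tests.tsv`), and a key-value summary (`summary.txt`). Every number
#' in the summary is recomputable from the annotated cohort.
#'
#' @param report a `f8_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "f8_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "annotated_cohort.tsv")
  ann <- as.data.frame(report$cohort)
  out <- ann
  for (col in names(out)) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", as.character(out[[col]]))
  }
  utils::write.table(out, cohort_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  tests_path <- file.path(dir, "tests.tsv")
  utils::write.table(tests_to_frame(lapply(report$tests, `[[`, "result")),
                     tests_path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  summary_path <- file.path(dir, "summary.txt")
  kv <- c(
    sprintf("records_input\t%d", report$filter_counts[["input"]]),
    sprintf("records_filtered\t%d", report$filter_counts[["filtered"]]),
    sprintf("known_status\t%d", report$filter_counts[["known_status"]]),
    sprintf("percent_known_status\t%.2f", report$percent_known_status),
    sprintf("inhibitor_positive\t%d", report$filter_counts[["inhibitor_positive"]]),
    sprintf("percent_positive_in_known\t%.2f", report$percent_positive_in_known),
    sprintf("domain_A_count\t%d", report$domain_tab$group[["A"]]),
    sprintf("domain_C_count\t%d", report$domain_tab$group[["C"]]),
    sprintf("percent_A_of_AC\t%.2f", report$domain_tab$percent_A_of_AC),
    sprintf("consensus_deleterious\t%d", report$consensus$counts[["deleterious"]]),
    sprintf("consensus_neutral\t%d", report$consensus$counts[["neutral"]]),
    sprintf("percent_positive_in_deleterious\t%.2f",
            report$consensus$percent_positive_in_deleterious),
    sprintf("percent_positive_in_neutral\t%.2f",
            report$consensus$percent_positive_in_neutral),
    sprintf("positives_inter\t%d", report$class_positive_counts[["inter"]]),
    sprintf("positives_intra\t%d", report$class_positive_counts[["intra"]]),
    sprintf("percent_inter_in_positives\t%.2f", report$percent_inter_in_positives),
    sprintf("consensus_strategy\t%s", report$metadata$consensus_strategy),
    sprintf("cohort_digest\t%s", report$metadata$cohort_digest))
  writeLines(kv, summary_path)
  invisible(c(cohort = cohort_path, tests = tests_path, summary = summary_path))
}
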