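SIFT_LEVELS <- c("intolerant", "potentially_intolerant", "borderline", "tolerant")
POLYPHEN_LEVELS <- c("benign", "undetermined", "possibly_damaging", "probably_damaging")
VOTE_LEVELS <- c("deleterious", "neutral", "abstain")
CONSENSUS_STRATEGIES <- c("kd4v_primary", "majority", "unanimous")
PREDICTOR_TOOLS <- c("sift", "polyphen", "agvgd", "kd4v", "mutationtaster")

#' Bin a SIFT score into the published categories
#'
#' Intolerant (0-0.05), potentially intolerant (0.051-0.10), borderline
#' (0.101-0.20), tolerant (0.201-1.00). The printed ranges leave
#' micro-gaps between bins; they are implemented as contiguous
#' upper-inclusive intervals \[0, 0.05\], (0.05, 0.10\], (0.10, 0.20\],
#' (0.20, 1\] so that every score in \[0, 1\] is classified.
#'
#' @param score numeric vector in \[0, 1\]; `NA` passes through.
#' @return Character vector of bin labels.
#' @export
bin_sift <- function(score) {
  score <- as.numeric(score)
  ok <- is.na(score) | (score >= 0 & score <= 1)
  if (!all(ok)) stop("SIFT scores must lie in [0, 1]")
  out <- as.character(cut(score, breaks = c(-Inf, 0.05, 0.10, 0.20, 1),
                          labels = SIFT_LEVELS, right = TRUE))
  out
}

#' Bin a PolyPhen-2 score into the published categories
#'
#' Probably damaging for scores >= 2.000, possibly damaging for
#' 1.500-1.999, benign for 0.000-0.999. Scores in \[1.000, 1.500) fall in
#' a band the published scheme leaves unmapped and are flagged
#' `"undetermined"` rather than silently rescaled. (This scale differs
#' from PolyPhen-2's usual 0-1 posterior; the published bands are
#' implemented verbatim.)
#'
#' @param score numeric vector, non-negative; `NA` passes through.
#' @return Character vector of bin labels.
#' @export
bin_polyphen <- function(score) {
  score <- as.numeric(score)
  ok <- is.na(score) | score >= 0
  if (!all(ok)) stop("PolyPhen scores must be non-negative")
  out <- as.character(cut(score, breaks = c(-Inf, 1, 1.5, 2, Inf),
                          labels = POLYPHEN_LEVELS, right = FALSE))
  out[!is.na(score) & score >= 2] <- "probably_damaging"
  out
}

#' Map a tool's category to a binary deleterious/neutral vote
#'
#' SIFT: intolerant and potentially intolerant vote deleterious;
#' borderline and tolerant vote neutral. PolyPhen: probably/possibly
#' damaging vote deleterious, benign votes neutral, the undetermined
#' band abstains. Align-GVGD: C45-C65 vote deleterious, C0-C25 neutral,
#' C35 abstains (it belongs to neither published likely/unlikely range).
#' KD4v and MutationTaster map one-to-one onto their own dichotomies.
#'
#' @param tool one of `"sift"`, `"polyphen"`, `"agvgd"`, `"kd4v"`,
#'   `"mutationtaster"`.
#' @param category character vector of categories valid for that tool;
#'   `NA` passes through.
#' @return Character vector of `"deleterious"`, `"neutral"`, `"abstain"`.
#' @export
binary_vote <- function(tool, category) {
  tool <- match.arg(tool, PREDICTOR_TOOLS)
  category <- as.character(category)
  map <- switch(tool,
    sift = c(intolerant = "deleterious", potentially_intolerant = "deleterious",
             borderline = "neutral", tolerant = "neutral"),
    polyphen = c(probably_damaging = "deleterious",
                 possibly_damaging = "deleterious",
                 benign = "neutral", undetermined = "abstain"),
    agvgd = c(C0 = "neutral", C15 = "neutral", C25 = "neutral",
              C35 = "abstain",
              C45 = "deleterious", C55 = "deleterious", C65 = "deleterious"),
    kd4v = c(deleterious = "deleterious", neutral = "neutral"),
    mutationtaster = c(disease_causing = "deleterious",
                       polymorphism = "neutral"))
  bad <- setdiff(category[!is.na(category)], names(map))
  if (length(bad)) {
    stop("invalid ", tool, " category: ", paste(unique(bad), collapse = ", "))
  }
  unname(map[category])
}

votes_from_predictions <- function(predictions) {
  c(sift = binary_vote("sift", bin_sift(predictions$sift_score)),
    polyphen = binary_vote("polyphen", bin_polyphen(predictions$polyphen_score)),
    agvgd = binary_vote("agvgd", predictions$agvgd_class),
    kd4v = binary_vote("kd4v", predictions$kd4v_call),
    mutationtaster = binary_vote("mutationtaster", predictions$mutationtaster_call))
}

resolve_votes <- function(votes, unanimous = FALSE) {
  votes <- votes[!is.na(votes) & votes != "abstain"]
  if (!length(votes)) return("undetermined")
  n_del <- sum(votes == "deleterious")
  n_neu <- sum(votes == "neutral")
  if (unanimous) {
    if (n_del == length(votes)) "deleterious"
    else if (n_neu == length(votes)) "neutral"
    else "undetermined"
  } else {
    if (n_del > n_neu) "deleterious"
    else if (n_neu > n_del) "neutral"
    else "undetermined"
  }
}

#' Consensus call over the five predictors
#'
#' The default `kd4v_primary` strategy adjudicates by KD4v whenever a
#' KD4v call is present (KD4v is the only tool that also considers the
#' 3D structure), falling back to the majority of the remaining votes.
#' `majority` requires a strict majority of non-abstaining votes (ties
#' give `undetermined`); `unanimous` requires all non-abstaining votes
#' to agree. `undetermined` is a value, not an error.
#'
#' @param predictions list (or one-row data.frame) with any of
#'   `sift_score`, `polyphen_score`, `agvgd_class`, `kd4v_call`,
#'   `mutationtaster_call`; absent tools are `NA`.
#' @param strategy one of `"kd4v_primary"`, `"majority"`, `"unanimous"`.
#' @return List of class `f8_consensus` with `final`, `strategy`, and
#'   the per-tool `votes` actually cast.
#' @export
consensus_call <- function(predictions, strategy = c("kd4v_primary", "majority",
                                                     "unanimous")) {
  strategy <- match.arg(strategy)
  for (f in PREDICTOR_COLUMNS) if (is.null(predictions[[f]])) predictions[f] <- NA
  votes <- votes_from_predictions(predictions)
  final <- switch(strategy,
    kd4v_primary = if (!is.na(votes[["kd4v"]])) votes[["kd4v"]]
                   else resolve_votes(votes[names(votes) != "kd4v"]),
    majority = resolve_votes(votes),
    unanimous = resolve_votes(votes, unanimous = TRUE))
  structure(list(final = final, strategy = strategy, votes = votes),
            class = "f8_consensus")
}

#' @export
print.f8_consensus <- function(x, ...) {
  cast <- x$votes[!is.na(x$votes)]
  cat("Consensus (", x$strategy, "): ", x$final, "\n  votes: ",
      paste(names(cast), cast, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Annotate a cohort with per-tool votes and the consensus call
#'
#' Adds columns `sift_bin`, `polyphen_bin`, one `<tool>_vote` column per
#' tool, `consensus_final` and `consensus_strategy`.
#'
#' @param cohort a `f8_cohort`.
#' @param strategy consensus strategy, see [consensus_call()].
#' @return The annotated cohort.
#' @export
annotate_consensus <- function(cohort, strategy = "kd4v_primary") {
  stopifnot(inherits(cohort, "f8_cohort"))
  strategy <- match.arg(strategy, CONSENSUS_STRATEGIES)
  cohort$sift_bin <- bin_sift(cohort$sift_score)
  cohort$polyphen_bin <- bin_polyphen(cohort$polyphen_score)
  cohort$sift_vote <- binary_vote("sift", cohort$sift_bin)
  cohort$polyphen_vote <- binary_vote("polyphen", cohort$polyphen_bin)
  cohort$agvgd_vote <- binary_vote("agvgd", cohort$agvgd_class)
  cohort$kd4v_vote <- binary_vote("kd4v", cohort$kd4v_call)
  cohort$mutationtaster_vote <- binary_vote("mutationtaster",
                                            cohort$mutationtaster_call)
  vote_mat <- cbind(sift = cohort$sift_vote, polyphen = cohort$polyphen_vote,
                    agvgd = cohort$agvgd_vote, kd4v = cohort$kd4v_vote,
                    mutationtaster = cohort$mutationtaster_vote)
  cohort$consensus_final <- vapply(seq_len(nrow(cohort)), function(i) {
    votes <- vote_mat[i, ]
    switch(strategy,
      kd4v_primary = if (!is.na(votes[["kd4v"]])) votes[["kd4v"]]
                     else resolve_votes(votes[names(votes) != "kd4v"]),
      majority = resolve_votes(votes),
      unanimous = resolve_votes(votes, unanimous = TRUE))
  }, character(1L))
  cohort$consensus_strategy <- strategy
  cohort
}
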