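# Shared in-code fixtures: tiny cohorts and toy alignments built at test time.

toy_cohort_df <- function() {
  data.frame(
    variant_id = c("v1", "v2", "v3"),
    protein_change = c("p.Arg2016Trp", "R593C", "p.Leu98Ile"),
    severity = c("severe", "severe", "moderate"),
    inhibitor_status = c("positive", "negative", "unknown"),
    stringsAsFactors = FALSE)
}

toy_cohort <- function() as_cohort(toy_cohort_df(), provenance = "toy")

write_toy_fasta_alignment <- function(path,
                                      seqs = c(human = "ACDEF",
                                               mouse = "ACDEF",
                                               rat   = "AC-EF",
                                               macaque = "ACDEY")) {
  writeLines(unlist(lapply(names(seqs), function(nm) {
    c(paste0(">", nm), seqs[[nm]])
  })), path)
  path
}

# Cohort contents without provenance/class metadata, for identity comparisons.
cohort_fields <- function(x) {
  x <- as.data.frame(x)
  attr(x, "provenance") <- NULL
  class(x) <- "data.frame"
  x
}

study_fixture_path <- function() {
  system.file("extdata", "study_marginals_fixture.tsv", package = "f8missense",
              mustWork = TRUE)
}

# Weighted norm used by independent oracles (duplicated on purpose so the
# oracle does not share code with the implementation).
oracle_wnorm <- function(d, params) {
  params$rho * sqrt(params$alpha * d[1]^2 + params$beta * d[2]^2 +
                    params$gamma * d[3]^2)
}

oracle_cpv <- function(aa, params) {
  i <- match(aa, params$properties$aa)
  c(params$properties$composition[i], params$properties$polarity[i],
    params$properties$volume[i])
}
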