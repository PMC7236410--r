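test_that("the generator is deterministic under a fixed seed and leaves the RNG alone", {
  cfg <- simulation_config(n_variants = 1000L, seed = 7L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(cohort_checksum(a), cohort_checksum(b))

  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_cohort(cfg))
  expect_identical(runif(3), before)  # global RNG stream unperturbed

  expect_error(simulation_config(n_variants = 10), "seed")
})

test_that("generated marginals recover the configured rates within 3 binomial SEs", {
  n <- 1e5L
  cfg <- simulation_config(
    n_variants = n,
    frac_known_status = 0.75,
    domain_group_weights = c(A = 0.8, C = 0.2),
    frac_consensus_deleterious = 0.7,
    inhibitor_rate_by_consensus = c(deleterious = 0.15, neutral = 0.10),
    inter_class_frac_by_outcome = c(positive = 0.7, negative = 0.5,
                                    unknown = 0.5),
    predictor_concordance = 1,
    seed = 20260924L)
  co <- generate_cohort(cfg)
  ann <- annotate_consensus(co)
  ann$class_change <- classify_substitution(ann$ref_aa, ann$alt_aa)
  ann$group <- group_of(domain_of(ann$position))

  band <- function(p, m) 3 * sqrt(p * (1 - p) / m)

  a_share <- mean(ann$group == "A")
  expect_lt(abs(a_share - 0.8), band(0.8, n))

  known <- ann$inhibitor_status != "unknown"
  expect_lt(abs(mean(known) - 0.75), band(0.75, n))

  del <- ann$consensus_final == "deleterious"
  expect_lt(abs(mean(del) - 0.7), band(0.7, n))

  kd <- known & del
  expect_lt(abs(mean(ann$inhibitor_status[kd] == "positive") - 0.15),
            band(0.15, sum(kd)))
  kn <- known & !del
  expect_lt(abs(mean(ann$inhibitor_status[kn] == "positive") - 0.10),
            band(0.10, sum(kn)))

  pos <- ann$inhibitor_status == "positive"
  expect_lt(abs(mean(ann$class_change[pos] == "inter") - 0.7),
            band(0.7, sum(pos)))

  # positions always land inside A- or C-group intervals (weights give B zero mass)
  expect_true(all(ann$group %in% c("A", "C")))
  expect_true(all(ann$position >= 1 & ann$position <= 2332))
})

test_that("predictor concordance below 1 produces discordant tool calls at the set rate", {
  cfg <- simulation_config(n_variants = 2e4L, predictor_concordance = 0.9,
                           seed = 11L)
  co <- generate_cohort(cfg)
  ann <- annotate_consensus(co)
  # kd4v defines the realized consensus; mutationtaster disagrees ~10%
  disagree <- mean(ann$mutationtaster_vote != ann$kd4v_vote)
  # truth-conditional concordance 0.9 per tool -> P(disagree) = 2*0.9*0.1
  expect_lt(abs(disagree - 0.18), 3 * sqrt(0.18 * 0.82 / 2e4))
})

test_that("the deterministic fixture reproduces every printed marginal exactly", {
  fx <- build_study_fixture()
  expect_identical(nrow(fx), 407L)
  known <- fx$inhibitor_status != "unknown"
  expect_identical(sum(known), 296L)
  expect_identical(sum(fx$inhibitor_status == "positive"), 40L)

  tab <- tabulate_by_domain(fx)
  expect_identical(tab$group[["A"]], 327L)
  expect_identical(tab$group[["C"]], 80L)

  ann <- annotate_consensus(fx)
  del <- ann$consensus_final == "deleterious"
  expect_identical(sum(known & del), 229L)
  expect_identical(sum(known & !del), 67L)
  expect_identical(sum(known & del & ann$inhibitor_status == "positive"), 31L)
  expect_identical(sum(known & !del & ann$inhibitor_status == "positive"), 9L)

  cls <- classify_substitution(fx$ref_aa, fx$alt_aa)
  pos <- fx$inhibitor_status == "positive"
  expect_identical(sum(cls[pos] == "inter"), 28L)
  expect_identical(sum(cls[pos] == "intra"), 12L)

  # labels are realized by residue pairs and positions, not stored flags
  expect_true(all(fx$ref_aa != fx$alt_aa))
  dom <- domain_of(fx$position)
  expect_true(all(dom %in% c("A1", "A2", "A3", "C1", "C2")))
})

test_that("the deleterious/positive reconstruction is the unique integer solution", {
  # independent enumeration oracle: D + N = 296 known-status records,
  # x + y = 40 positives, with the printed rates 13.54% and 13.43%
  sols <- list()
  for (D in 1:295) {
    N <- 296L - D
    for (x in 0:min(40L, D)) {
      y <- 40L - x
      if (y <= N && round(100 * x / D, 2) == 13.54 &&
          round(100 * y / N, 2) == 13.43) {
        sols[[length(sols) + 1L]] <- c(D = D, N = N, x = x, y = y)
      }
    }
  }
  expect_length(sols, 1L)
  expect_identical(sols[[1L]], c(D = 229L, N = 67L, x = 31L, y = 9L))
})

test_that("fixture serialization is byte-stable with a recorded digest", {
  fx <- build_study_fixture()
  digest <- cohort_checksum(fx)
  recorded <- readLines(system.file("extdata", "study_marginals_fixture.md5",
                                    package = "f8missense", mustWork = TRUE))
  expect_identical(digest, recorded)

  # the shipped file round-trips to the builder's output
  shipped <- read_cohort(study_fixture_path())
  expect_identical(cohort_fields(shipped), cohort_fields(fx))

  # any field perturbation changes the digest
  tweaked <- fx
  tweaked$inhibitor_status[1] <- "negative"
  class(tweaked) <- c("f8_cohort", "data.frame")
  expect_false(cohort_checksum(tweaked) == digest)
})
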