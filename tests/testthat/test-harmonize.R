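test_that("SIFT bins are total, exclusive and match the published boundaries", {
  expect_identical(bin_sift(0.03), "intolerant")
  expect_identical(bin_sift(0.15), "borderline")
  expect_identical(bin_sift(0.05), "intolerant")  # upper edge of the first band
  expect_identical(bin_sift(c(0, 0.051, 0.10, 0.101, 0.20, 0.201, 1)),
                   c("intolerant", "potentially_intolerant",
                     "potentially_intolerant", "borderline", "borderline",
                     "tolerant", "tolerant"))
  # totality over a dense sweep of [0, 1]
  sweep <- seq(0, 1, by = 0.001)
  bins <- bin_sift(sweep)
  expect_false(anyNA(bins))
  expect_setequal(unique(bins), c("intolerant", "potentially_intolerant",
                                  "borderline", "tolerant"))
  expect_error(bin_sift(1.2), "\\[0, 1\\]")
  expect_error(bin_sift(-0.1), "\\[0, 1\\]")
  expect_true(is.na(bin_sift(NA_real_)))
})

test_that("PolyPhen bins follow the published bands and flag the unmapped band", {
  expect_identical(bin_polyphen(2.4), "probably_damaging")
  expect_identical(bin_polyphen(2.0), "probably_damaging")
  expect_identical(bin_polyphen(c(1.5, 1.999)), rep("possibly_damaging", 2))
  expect_identical(bin_polyphen(0.2), "benign")
  expect_identical(bin_polyphen(1.2), "undetermined")
  sweep <- seq(0, 3, by = 0.001)
  expect_false(anyNA(bin_polyphen(sweep)))
  expect_error(bin_polyphen(-1), "non-negative")
})

test_that("binary votes map each tool's categories as published", {
  expect_identical(binary_vote("kd4v", "deleterious"), "deleterious")
  expect_identical(binary_vote("kd4v", "neutral"), "neutral")
  expect_identical(binary_vote("agvgd", "C35"), "abstain")
  expect_identical(binary_vote("agvgd", c("C0", "C25", "C45", "C65")),
                   c("neutral", "neutral", "deleterious", "deleterious"))
  expect_identical(binary_vote("mutationtaster", "polymorphism"), "neutral")
  expect_identical(binary_vote("polyphen", "undetermined"), "abstain")
  expect_identical(binary_vote("sift", c("intolerant", "potentially_intolerant",
                                         "borderline", "tolerant")),
                   c("deleterious", "deleterious", "neutral", "neutral"))
  expect_error(binary_vote("kd4v", "C65"), "invalid")
  expect_error(binary_vote("sift", "probably_damaging"), "invalid")
})

test_that("lower SIFT scores never yield a more neutral vote", {
  sweep <- seq(0, 1, by = 0.001)
  votes <- binary_vote("sift", bin_sift(sweep))
  # deleterious (1) -> neutral (2) transitions only, never back
  coded <- ifelse(votes == "deleterious", 1L, 2L)
  expect_true(all(diff(coded) >= 0))
})

test_that("consensus strategies resolve votes as specified", {
  kd4v_del <- list(sift_score = 0.9, polyphen_score = 0.1, agvgd_class = "C0",
                   kd4v_call = "deleterious", mutationtaster_call = "polymorphism")
  cc <- consensus_call(kd4v_del, strategy = "kd4v_primary")
  expect_identical(cc$final, "deleterious")  # KD4v overrides four neutral votes

  maj <- consensus_call(list(sift_score = 0.01, polyphen_score = 2.5,
                             mutationtaster_call = "polymorphism"),
                        strategy = "majority")
  expect_identical(maj$final, "deleterious")  # 2 of 3

  tie <- consensus_call(list(sift_score = 0.01,
                             mutationtaster_call = "polymorphism"),
                        strategy = "majority")
  expect_identical(tie$final, "undetermined")

  unan <- consensus_call(list(sift_score = 0.01, polyphen_score = 2.5),
                         strategy = "unanimous")
  expect_identical(unan$final, "deleterious")
  mixed <- consensus_call(list(sift_score = 0.01, polyphen_score = 0.2),
                          strategy = "unanimous")
  expect_identical(mixed$final, "undetermined")

  # all-abstain and empty prediction sets are undetermined, not errors
  expect_identical(consensus_call(list(agvgd_class = "C35"))$final, "undetermined")
  expect_identical(consensus_call(list())$final, "undetermined")
})

test_that("kd4v_primary is invariant to every other tool's output when KD4v is present", {
  set.seed(42)
  for (i in 1:50) {
    kd4v <- sample(c("deleterious", "neutral"), 1)
    preds <- list(
      sift_score = sample(c(NA, runif(1)), 1),
      polyphen_score = sample(c(NA, runif(1, 0, 3)), 1),
      agvgd_class = sample(c(NA, paste0("C", c(0, 15, 25, 35, 45, 55, 65))), 1),
      kd4v_call = kd4v,
      mutationtaster_call = sample(c(NA, "disease_causing", "polymorphism"), 1))
    expect_identical(consensus_call(preds, "kd4v_primary")$final, kd4v)
  }
})

test_that("cohort annotation adds per-tool bins, votes and the consensus", {
  fx <- read_cohort(study_fixture_path())
  ann <- annotate_consensus(fx, strategy = "kd4v_primary")
  expect_identical(ann$consensus_final, ann$kd4v_vote)  # fixture is concordant
  known <- ann[ann$inhibitor_status != "unknown", ]
  expect_identical(sum(known$consensus_final == "deleterious"), 229L)
  expect_identical(sum(known$consensus_final == "neutral"), 67L)
})
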