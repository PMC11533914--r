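mklesions <- function(...) {
  # each argument: c(fdg, psma) or c(fdg, psma, dot)
  rows <- list(...)
  data.frame(
    patient_id = "P1", lesion_id = seq_along(rows),
    compartment = "bones", volume_cm3 = 2,
    ratio_fdg = vapply(rows, `[`, numeric(1), 1),
    ratio_psma = vapply(rows, `[`, numeric(1), 2),
    ratio_dotatate = vapply(rows, function(r)
      if (length(r) > 2) r[3] else NA_real_, numeric(1)))
}

test_that("lesion classification is threshold-exact at ratio 1.5", {
  expect_equal(classify_lesion(c(FDG = 1.5, PSMA = 0.8))$label, "F+/P-")
  expect_equal(classify_lesion(c(FDG = 1.49, PSMA = 1.49))$label, "F-/P-")
  cls <- classify_lesion(c(FDG = 2, PSMA = 2, DOTATATE = 1.6))
  expect_equal(cls$label, "F+/P+/D+")
  expect_equal(unname(cls$status), rep("positive", 3))

  # perturbing a ratio across 1.5 by +/-1e-9 flips the status
  just_below <- classify_lesion(c(FDG = 1.5 - 1e-9, PSMA = 2))
  just_above <- classify_lesion(c(FDG = 1.5 + 1e-9, PSMA = 2))
  at <- classify_lesion(c(FDG = 1.5, PSMA = 2))
  expect_equal(just_below$status[["FDG"]], "negative")
  expect_equal(just_above$status[["FDG"]], "positive")
  expect_equal(at$status[["FDG"]], "positive")

  expect_equal(classify_lesion(c(FDG = 2))$status[["PSMA"]], "unmeasured")
  expect_error(classify_lesion(c(FDG = 2), scanned_tracers = c("FDG", "PSMA")),
               "missing ratio")
})

test_that("the DOTATATE trigger fires on any FDG+/PSMA- lesion", {
  expect_false(needs_dotatate(mklesions(c(2, 2), c(3, 1.6))))
  many <- do.call(mklesions, c(rep(list(c(2, 2)), 19), list(c(1.7, 0.4))))
  expect_true(needs_dotatate(many))
  expect_false(needs_dotatate(mklesions(c(2, 2))[0, ]))
})

test_that("IIH requires two lesions with different phenotypes", {
  expect_false(flag_iih(mklesions(c(2, 2), c(3, 3))))          # identical
  expect_true(flag_iih(mklesions(c(2, 2), c(0.5, 3))))         # F+P+ vs F-P+
  expect_false(flag_iih(mklesions(c(2, 2))))                   # single lesion
  # all-negative lesions carry no phenotype
  expect_false(flag_iih(mklesions(c(2, 2), c(0.4, 0.4))))
  expect_true(flag_iih(mklesions(c(2, 0.4, 0.4), c(2, 0.4, 2)),
                       dotatate_scanned = TRUE))               # D+ splits
})

test_that("NED and RPT eligibility follow the endpoint definitions", {
  expect_true(flag_ned(mklesions(c(2, 2, 1.6)), dotatate_scanned = TRUE))
  expect_false(flag_ned(mklesions(c(2, 2, 1.49)), dotatate_scanned = TRUE))
  expect_true(flag_ned(mklesions(c(2, 2, 1.5)), dotatate_scanned = TRUE))
  expect_error(flag_ned(mklesions(c(2, 2)), dotatate_scanned = FALSE), "scanned")

  expect_true(psma_rpt_eligible(mklesions(c(0.5, 2), c(2, 2))))
  expect_false(psma_rpt_eligible(mklesions(c(2, 0.5), c(0.5, 2))))
  expect_false(psma_rpt_eligible(mklesions(c(0.4, 0.4))))

  expect_true(dotatate_rpt_eligible(mklesions(c(2, 0.4, 2), c(0.5, 2, 2)), TRUE))
  expect_false(dotatate_rpt_eligible(mklesions(c(2, 0.4, 0.4), c(2, 0.4, 2)), TRUE))
  expect_false(dotatate_rpt_eligible(mklesions(c(2, 2, 0.4)), TRUE))
  expect_error(dotatate_rpt_eligible(mklesions(c(2, 2)), FALSE), "scanned")
})

test_that("combination labels are canonical and count phenotypes", {
  expect_equal(combination_label(mklesions(c(2, 2), c(3, 3))), "F+/P+")
  expect_equal(combination_label(mklesions(c(2, 0.5), c(2, 2), c(0.5, 2))),
               "F+/P+|F+/P-|F-/P+")
  five <- mklesions(c(2, 0.4, 0.4), c(2, 2, 0.4), c(0.4, 2, 0.4),
                    c(2, 0.4, 2), c(2, 2, 2))
  expect_equal(length(strsplit(combination_label(five, TRUE), "|",
                               fixed = TRUE)[[1]]), 5)
  expect_equal(combination_label(mklesions(c(0.4, 0.4))), "all-negative")
  # DOTATATE-negative lesions keep the dual label: scanned and unscanned
  # patients with the same F/P lesions share a combination
  expect_equal(combination_label(mklesions(c(2, 0.5, 0.5), c(2, 2, 0.5)), TRUE),
               combination_label(mklesions(c(2, 0.5), c(2, 2)), FALSE))
})

test_that("adding lesions never breaks IIH and only the first PSMA+ lesion can grant eligibility", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    les <- do.call(mklesions, lapply(seq_len(n), function(i)
      round(runif(2, 0.2, 4), 2)))
    base_iih <- flag_iih(les)
    base_elig <- psma_rpt_eligible(les)
    extra <- les[1, ]
    extra$lesion_id <- n + 1
    extra$ratio_fdg <- round(runif(1, 0.2, 4), 2)
    extra$ratio_psma <- round(runif(1, 0.2, 4), 2)
    grown <- rbind(les, extra)
    if (base_iih) expect_true(flag_iih(grown))
    if (!base_elig && psma_rpt_eligible(grown)) {
      # only possible when the new lesion is the first PSMA+ one
      expect_true(extra$ratio_psma >= 1.5)
      expect_false(any(les$ratio_psma >= 1.5))
    }
    # eligibility and the presence of an F+/P- lesion are mutually exclusive
    expect_false(psma_rpt_eligible(grown) && needs_dotatate(grown))
  }
})

test_that("profile flags match a brute-force re-evaluation on random cohorts", {
  for (s in c(5, 17)) {
    coh <- random_cohort(30, seed = s)
    prof <- build_profiles(coh$lesions, coh$patients)
    expect_equal(nrow(prof), 30)
    for (i in seq_len(nrow(prof))) {
      les <- coh$lesions[coh$lesions$patient_id == prof$patient_id[i], ]
      ds <- prof$dotatate_scanned[i]
      fpos <- les$ratio_fdg >= 1.5
      ppos <- les$ratio_psma >= 1.5
      dpos <- if (ds) les$ratio_dotatate >= 1.5 else rep(FALSE, nrow(les))
      lab <- paste0(fpos, ppos, dpos)
      lab <- lab[fpos | ppos | dpos]
      expect_identical(prof$iih[i], length(unique(lab)) >= 2)
      expect_identical(prof$has_fdg_pos_psma_neg[i], any(fpos & !ppos))
      expect_identical(prof$psma_rpt_eligible[i], any(ppos) && !any(fpos & !ppos))
      if (ds) {
        expect_identical(prof$ned[i], any(dpos))
        expect_identical(prof$dotatate_rpt_eligible[i],
                         any(dpos) && !any(fpos & !dpos))
      } else {
        expect_true(is.na(prof$ned[i]))
      }
    }
    # endpoint summary equals direct counting
    ep <- endpoint_summary(prof)
    expect_equal(ep$k[ep$endpoint == "iih"], sum(prof$iih))
    expect_equal(ep$k[ep$endpoint == "ned"],
                 sum(prof$ned[prof$dotatate_scanned]))
  }
})
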