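test_that("any-overlap matching handles the canonical cases", {
  t1 <- data.frame(start_s = 100, stop_s = 160)
  # identical intervals
  m <- match_events(t1, t1)
  expect_equal(c(m$n_tp, m$n_fn, m$n_fp), c(1, 0, 0))
  # disjoint intervals
  m2 <- match_events(t1, data.frame(start_s = 300, stop_s = 320))
  expect_equal(c(m2$n_tp, m2$n_fn, m2$n_fp), c(0, 1, 1))
  # 1-s overlap of a 60-s truth still counts
  m3 <- match_events(t1, data.frame(start_s = 159, stop_s = 200))
  expect_equal(m3$n_tp, 1)
  # touching intervals (half-open) do not overlap
  m4 <- match_events(t1, data.frame(start_s = 160, stop_s = 200))
  expect_equal(m4$n_tp, 0)
  # one detection validating two truths is never also an FP
  t2 <- data.frame(start_s = c(0, 50), stop_s = c(20, 70))
  m5 <- match_events(t2, data.frame(start_s = 10, stop_s = 60))
  expect_equal(c(m5$n_tp, m5$n_fn, m5$n_fp), c(2, 0, 0))
})

test_that("matching agrees with a raster oracle on 1000 random event sets", {
  with_seed_test(99, {
    for (rep in 1:1000) {
      truth <- random_events(sample(0:5, 1))
      det <- random_events(sample(0:5, 1))
      m <- match_events(truth, det)
      o <- raster_match_oracle(truth, det)
      expect_identical(
        c(m$n_tp, m$n_fn, m$n_fp),
        c(o$n_tp, o$n_fn, o$n_fp)
      )
      # conservation invariants
      expect_equal(m$n_tp + m$n_fn, nrow(truth))
      expect_true(m$n_fp <= nrow(det))
    }
  })
})

test_that("percent overlap is the covered fraction of the truth event", {
  tr <- data.frame(start_s = 0, stop_s = 40)
  expect_equal(percent_overlap(tr, data.frame(start_s = -10, stop_s = 50)), 100)
  expect_equal(percent_overlap(tr, data.frame(start_s = 0, stop_s = 20)), 50)
  # two detections covering [0,10] and [20,30] of a [0,40] truth
  expect_equal(
    percent_overlap(tr, data.frame(start_s = c(0, 20), stop_s = c(10, 30))),
    50
  )
  # overlapping detections are not double counted
  expect_equal(
    percent_overlap(tr, data.frame(start_s = c(0, 5), stop_s = c(10, 10))),
    25
  )
  expect_error(percent_overlap(tr, data.frame(start_s = 50, stop_s = 60)),
    "undefined")
  # widening a detection never decreases the overlap
  p1 <- percent_overlap(tr, data.frame(start_s = 10, stop_s = 20))
  p2 <- percent_overlap(tr, data.frame(start_s = 5, stop_s = 25))
  expect_gte(p2, p1)
})

test_that("subject metrics apply the stated conventions", {
  mk <- function(tp, fn, fp, nd = tp + fp) {
    structure(list(n_tp = tp, n_fn = fn, n_fp = fp, n_detections = nd),
      class = "match_result")
  }
  sm <- subject_metrics(mk(2, 1, 0), 10)
  expect_equal(sm$sensitivity, 200 / 3, tolerance = 1e-9)
  expect_equal(sm$fdr, 0)
  expect_equal(subject_metrics(mk(0, 0, 2), 10)$fdr, 0.2)
  # no truth events: sensitivity undefined
  expect_true(is.na(subject_metrics(mk(0, 0, 1), 10)$sensitivity))
  # no detections, no truths: precision 100 by convention
  expect_equal(subject_metrics(mk(0, 0, 0), 10)$precision, 100)
  # truths but no detections: precision undefined
  expect_true(is.na(subject_metrics(mk(0, 2, 0), 10)$precision))
  # detections on a truth-free subject: precision 0
  expect_equal(subject_metrics(mk(0, 0, 3), 10)$precision, 0)
  expect_error(subject_metrics(mk(1, 0, 0), 0), "record_hours")
})

test_that("cohort summary matches a direct mean/SD computation", {
  tbl <- data.frame(
    sensitivity = c(50, 100, NA, 75),
    precision = c(100, 60, 100, 80),
    fdr = c(0, 0.1, 0.05, 0)
  )
  s <- cohort_summary(tbl)
  sens <- s[s$metric == "sensitivity", ]
  expect_equal(sens$mean, mean(c(50, 100, 75)))
  expect_equal(sens$sd, sd(c(50, 100, 75)))
  expect_equal(c(sens$min, sens$max), c(50, 100))
  expect_equal(sens$n, 3)
  fdr <- s[s$metric == "fdr", ]
  expect_equal(fdr$mean, mean(tbl$fdr))
  # identical subjects -> zero SD; two subjects at 50/100 -> mean 75
  two <- cohort_summary(data.frame(
    sensitivity = c(50, 100), precision = c(80, 80), fdr = c(0, 0)
  ))
  expect_equal(two[two$metric == "sensitivity", "mean"], 75)
  expect_equal(two[two$metric == "precision", "sd"], 0)
  expect_error(cohort_summary(tbl[0, ]), "at least one")
})

test_that("rule-in metrics count subjects, not events", {
  mk <- function(tp, nd) {
    structure(list(n_tp = tp, n_fn = 0, n_fp = nd - tp, n_detections = nd),
      class = "match_result")
  }
  # 4 seizure subjects all with >= 1 TP; 7 of 10 clean subjects detection-free
  matches <- c(
    lapply(c(1, 2, 1, 3), function(k) mk(k, k)),
    lapply(c(rep(0, 7), 1, 2, 1), function(k) mk(0, k))
  )
  flags <- c(rep(TRUE, 4), rep(FALSE, 10))
  ri <- rule_in_metrics(matches, flags)
  expect_equal(ri$sensitivity, 100)
  expect_equal(ri$specificity, 70)
  # a seizure-free subject with a single FP counts against specificity
  ri2 <- rule_in_metrics(list(mk(1, 1), mk(0, 1)), c(TRUE, FALSE))
  expect_equal(ri2$specificity, 0)
})

test_that("2-of-3 consensus implements pointwise majority", {
  a <- annotation_set(0, 10, source = "reviewer_1", subject_id = "S")
  b <- annotation_set(5, 15, source = "reviewer_2", subject_id = "S")
  c3 <- annotation_set(40, 50, source = "reviewer_3", subject_id = "S")
  cons <- consensus(list(a, b, c3))
  expect_equal(cons$start_s, 5)
  expect_equal(cons$stop_s, 10)

  # three identical sets reproduce the set; idempotence up to rasterization
  same <- consensus(list(a, a, a))
  expect_equal(same$start_s, 0)
  expect_equal(same$stop_s, 10)

  # an event marked by a single reviewer is absent
  lone <- consensus(list(a, annotation_set(source = "reviewer_2", subject_id = "S"),
    annotation_set(source = "reviewer_3", subject_id = "S")))
  expect_equal(nrow(lone), 0)

  # monotonicity: adding marks to one reviewer never removes consensus time
  b_more <- annotation_set(c(5, 100), c(15, 120), source = "reviewer_2",
    subject_id = "S")
  cons2 <- consensus(list(a, b_more, c3))
  expect_true(all(cons$start_s %in% cons2$start_s))
  expect_error(consensus(list(a, b)), "exactly 3")
})

test_that("kappas match brute-force oracles on all 64 three-rater tables", {
  combos <- expand.grid(rep(list(0:1), 6))
  for (i in seq_len(nrow(combos))) {
    tab <- matrix(as.integer(combos[i, ]), nrow = 2) # 2 items x 3 raters
    expect_equal(fleiss_kappa(tab), fleiss_oracle(tab), tolerance = 1e-12)
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      ko <- cohen_oracle(tab[, pr[1]], tab[, pr[2]])
      if (!is.na(ko)) {
        expect_equal(cohens_kappa(tab[, pr[1]], tab[, pr[2]]), ko,
          tolerance = 1e-12)
      }
    }
  }
})

test_that("kappa closed-form cases and conventions hold", {
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  expect_equal(cohens_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0)), 0.5)
  # symmetry
  expect_equal(
    cohens_kappa(c(1, 0, 1, 0, 1), c(1, 1, 0, 0, 1)),
    cohens_kappa(c(1, 1, 0, 0, 1), c(1, 0, 1, 0, 1))
  )
  # degenerate unanimity
  expect_equal(cohens_kappa(c(1, 1), c(1, 1)), 1)
  expect_error(cohens_kappa(c(1, 2), c(1, 0)), "binary")

  # hand-computed Fleiss case: votes (3,0), (0,3), (2,1), (1,2) -> 1/3
  tab <- rbind(c(1, 1, 1), c(0, 0, 0), c(1, 1, 0), c(1, 0, 0))
  expect_equal(fleiss_kappa(tab), 1 / 3, tolerance = 1e-12)
  # perfect agreement with mixed categories
  expect_equal(fleiss_kappa(rbind(c(1, 1, 1), c(0, 0, 0))), 1)
  # row-order invariance
  expect_equal(fleiss_kappa(tab), fleiss_kappa(tab[c(3, 1, 4, 2), ]))
  expect_error(fleiss_kappa(rbind(c(1, NA, 1))), "ragged")
})

test_that("rater table flags any-overlap detections per known seizure", {
  truths <- list(
    annotation_set(c(100, 500), c(160, 560), subject_id = "S1"),
    annotation_set(1000, 1100, subject_id = "S2")
  )
  r_exact <- list(truths[[1]], truths[[2]])
  r_jitter <- list(
    annotation_set(c(95, 555), c(105, 570), source = "reviewer_2", subject_id = "S1"),
    annotation_set(1099, 1130, source = "reviewer_2", subject_id = "S2")
  )
  r_none <- list(
    annotation_set(source = "reviewer_3", subject_id = "S1"),
    annotation_set(source = "reviewer_3", subject_id = "S2")
  )
  tab <- build_rater_table(truths, list(
    reviewer_1 = r_exact, reviewer_2 = r_jitter, reviewer_3 = r_none
  ))
  expect_equal(dim(tab), c(3, 3))
  expect_equal(unname(tab[, "reviewer_1"]), c(1, 1, 1))
  expect_equal(unname(tab[, "reviewer_2"]), c(1, 1, 1)) # jittered but overlapping
  expect_equal(unname(tab[, "reviewer_3"]), c(0, 0, 0))
})
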