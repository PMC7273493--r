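test_that("published-style contingency tables reproduce every rounded metric", {
  cases <- list(
    # quiet environment, without / with adaptive filtering
    list(tab = c(485, 1, 14, 2487),
         pct = c(sensitivity = 97.2, specificity = 99.9, ppv = 99.8,
                 npv = 99.4, accuracy = 99.5), kappa = 0.982),
    list(tab = c(490, 3, 9, 2485),
         pct = c(sensitivity = 98.2, specificity = 99.9, ppv = 99.4,
                 npv = 99.6, accuracy = 99.6), kappa = 0.985),
    # noisy environment, without / with adaptive filtering
    list(tab = c(399, 70, 93, 2230),
         pct = c(sensitivity = 81.1, specificity = 96.9, ppv = 85.1,
                 npv = 96.0, accuracy = 94.2), kappa = 0.795),
    list(tab = c(450, 59, 42, 2241),
         pct = c(sensitivity = 91.5, specificity = 97.4, ppv = 88.4,
                 npv = 98.2, accuracy = 96.4), kappa = 0.877)
  )
  for (cs in cases) {
    m <- compute_metrics(contingency_table(tp = cs$tab[1], fp = cs$tab[2],
                                           fn = cs$tab[3], tn = cs$tab[4]))
    # printed values use mixed rounding conventions (e.g. 99.96 -> "99.9"),
    # so agreement is asserted to within one unit of the printed last digit
    for (name in names(cs$pct)) {
      expect_lt(abs(100 * m[[name]] - unname(cs$pct[name])), 0.1,
                label = sprintf("tp=%d %s", cs$tab[1], name))
    }
    expect_lt(abs(m$kappa - cs$kappa), 0.001)
  }
})

test_that("perfect agreement yields all metrics 1 and kappa 1", {
  m <- compute_metrics(contingency_table(tp = 12, fp = 0, fn = 0, tn = 88))
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv",
                          "accuracy", "kappa")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1,
                 accuracy = 1, kappa = 1))
})

test_that("zero denominators give NA, all-zero tables error, kappa stays in range", {
  m <- compute_metrics(contingency_table(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
  expect_error(compute_metrics(contingency_table(0, 0, 0, 0)),
               class = "apneasound_undefined_metrics")
  set.seed(8)
  for (i in 1:50) {
    counts <- rpois(4, 20)
    if (sum(counts) == 0) next
    m <- compute_metrics(contingency_table(counts[1], counts[2], counts[3], counts[4]))
    if (!is.na(m$kappa)) {
      expect_gte(m$kappa, -1)
      expect_lte(m$kappa, 1)
    }
  }
})

test_that("event matching: identical schedules give perfect counts and floored TN", {
  # ten 20 s reference events on a 900 s record, detected exactly:
  # flagged time 200 s, quiet time 700 s -> floor(700/15) = 46 TN
  ref <- tibble::tibble(onset_s = seq(60, 420, by = 40),
                        offset_s = seq(80, 440, by = 40), label = "apnea")
  tab <- score_events(ref, ref, 900)
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 10L, fp = 0L, fn = 0L, tn = 46L))
})

test_that("event matching handles misses, false alarms, and one-to-many overlap", {
  ref <- tibble::tibble(onset_s = c(100, 200, 300), offset_s = c(120, 220, 320))
  # nothing detected: all reference events are misses
  none <- tibble::tibble(onset_s = double(), offset_s = double())
  tab <- score_events(none, ref, 900)
  expect_equal(tab$tp, 0L); expect_equal(tab$fn, 3L); expect_equal(tab$fp, 0L)

  # one detected event spanning two reference events scores a single TP
  spanning <- tibble::tibble(onset_s = 110, offset_s = 215)
  tab2 <- score_events(spanning, ref[1:2, ], 900)
  expect_equal(tab2$tp, 1L); expect_equal(tab2$fn, 1L); expect_equal(tab2$fp, 0L)

  # a detected event with no overlap at all is a false positive
  stray <- tibble::tibble(onset_s = c(101, 500), offset_s = c(119, 520))
  tab3 <- score_events(stray, ref, 900)
  expect_equal(tab3$tp, 1L); expect_equal(tab3$fp, 1L); expect_equal(tab3$fn, 2L)

  # abutting events do not overlap (half-open intervals)
  abut <- tibble::tibble(onset_s = 120, offset_s = 140)
  tab4 <- score_events(abut, ref[1, , drop = FALSE], 900)
  expect_equal(tab4$tp, 0L); expect_equal(tab4$fp, 1L)

  # events outside the record are rejected
  expect_error(score_events(tibble::tibble(onset_s = -5, offset_s = 10), ref, 900),
               class = "apneasound_invalid_input")
})

test_that("matching is invariant to event order", {
  set.seed(15)
  ref <- tibble::tibble(onset_s = seq(50, 850, by = 100),
                        offset_s = seq(70, 870, by = 100))
  det <- tibble::tibble(onset_s = ref$onset_s + rnorm(9, 0, 3),
                        offset_s = ref$offset_s + rnorm(9, 0, 3))
  t1 <- score_events(det, ref, 900)
  perm <- sample(nrow(det))
  t2 <- score_events(det[perm, ], ref[sample(nrow(ref)), ], 900)
  expect_equal(unclass(t1), unclass(t2))
})
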