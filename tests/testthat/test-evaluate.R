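test_that("confusion tallies the 2x2 table and enforces key alignment", {
  pred <- setNames(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0), paste0("p", 1:10))
  cm <- confusion(pred, pred)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(7, 0, 0, 3))

  gold <- setNames(c(rep(1, 4), rep(0, 6)), paste0("p", 1:10))
  cm2 <- confusion(setNames(rep(0, 10), paste0("p", 1:10)), gold)
  expect_equal(c(cm2$fn, cm2$tn, cm2$tp, cm2$fp), c(4, 6, 0, 0))

  expect_error(confusion(pred, setNames(1, "other")),
               "other", class = "notephen_key_error")
})

test_that("confusion matches a hand tally on randomized 50-patient fixtures", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      ids <- paste0("p", 1:50)
      pred <- setNames(rbinom(50, 1, 0.4), ids)
      gold <- setNames(rbinom(50, 1, 0.3), ids)
      cm <- confusion(pred, gold)
      want <- oracle_confusion(pred, gold)
      expect_equal(cm$tp, unname(want$tp))
      expect_equal(cm$fp, unname(want$fp))
      expect_equal(cm$fn, unname(want$fn))
      expect_equal(cm$tn, unname(want$tn))
    }
  })
})

test_that("sens_spec: points are k/m, Wilson upper hits 1 at k = m, zero denominators error", {
  cm <- structure(list(tp = 9, fp = 2, fn = 1, tn = 8, n = 20),
                  class = "notephen_confusion")
  est <- sens_spec(cm)
  expect_equal(est$point, c(0.9, 0.8))
  expect_true(all(est$ci_low <= est$point & est$point <= est$ci_high))

  perfect <- structure(list(tp = 15, fp = 0, fn = 0, tn = 5, n = 20),
                       class = "notephen_confusion")
  est2 <- sens_spec(perfect)
  expect_equal(est2$ci_high[1], 1.0)
  # sensitivity equals 1 - miss rate computed independently
  expect_equal(est$point[1], 1 - cm$fn / (cm$tp + cm$fn))

  none <- structure(list(tp = 0, fp = 3, fn = 0, tn = 7, n = 10),
                    class = "notephen_confusion")
  expect_error(sens_spec(none), "sensitivity",
               class = "notephen_undefined_metric")
})

test_that("wilson_interval agrees with the score interval from prop.test", {
  for (km in list(c(9, 10), c(50, 50), c(1, 30), c(190, 200), c(0, 12))) {
    got <- wilson_interval(km[1], km[2])
    want <- stats::prop.test(km[1], km[2], correct = FALSE)$conf.int
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("t-quantile interval matches its closed form and stays in [0, 1]", {
  ci <- notephen:::t_normal_interval(45, 50)
  p <- 0.9
  half <- qt(0.975, 49) * sqrt(p * 0.1 / 50)
  expect_equal(unname(ci), c(p - half, p + half))
  expect_equal(unname(notephen:::t_normal_interval(50, 50)), c(1, 1))
})

test_that("mean_accuracy: equal-weight mean with SEM", {
  m <- mean_accuracy(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(m$mean, 0.5)
  expect_equal(m$sem, 0)
  expect_error(mean_accuracy(numeric(0)), class = "notephen_contract_error")
})

test_that("compare_means is the textbook pooled t-test", {
  r <- compare_means(c(1, 2, 3), c(2, 3, 4))
  want <- oracle_pooled_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, want$t, tolerance = 1e-9)
  expect_equal(r$p, want$p, tolerance = 1e-9)

  same <- compare_means(c(0.2, 0.4, 0.6), c(0.2, 0.4, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(compare_means(1, c(1, 2)), class = "notephen_contract_error")
})

test_that("Wilson 95% intervals cover the truth at nominal rate (2000 reps, m = 100)", {
  withr::with_seed(107, {
    for (p in c(0.5, 0.9, 0.98)) {
      ks <- rbinom(2000, 100, p)
      covered <- vapply(ks, function(k) {
        ci <- wilson_interval(k, 100)
        ci[1] <= p && p <= ci[2]
      }, logical(1))
      expect_gte(mean(covered), 0.93)
      expect_lte(mean(covered), 0.97)
    }
  })
})

test_that("discrepancy_breakdown tags chronic omissions and matches a join oracle", {
  # fixture with exactly 16 chronic-history comparator false negatives
  ids <- paste0("p", 1:60)
  gold <- tibble::tibble(patient_id = ids, endocarditis = c(rep(1L, 30), rep(0L, 30)))
  comparator <- gold
  comparator$endocarditis[1:20] <- 0L              # 20 comparator FNs
  note <- gold                                     # note labeling is perfect
  chronic <- tibble::tibble(patient_id = ids,
                            endocarditis = c(rep(1L, 16), rep(0L, 44)))
  disc <- discrepancy_breakdown(comparator, note, gold, chronic)
  expect_equal(
    disc$chronic_omissions$chronic_omissions[
      disc$chronic_omissions$condition == "endocarditis"
    ],
    16L
  )
  # brute-force join-and-filter oracle
  want <- sum(comparator$endocarditis == 0 & gold$endocarditis == 1 &
                chronic$endocarditis == 1)
  expect_equal(sum(disc$records$reason_tag == "chronic_omission"), want)

  # comparator correct everywhere -> no discrepancy records at all
  none <- discrepancy_breakdown(gold, gold, gold, chronic)
  expect_equal(nrow(none$records), 0L)

  # without chronic information, comparator FNs are unreviewed
  disc2 <- discrepancy_breakdown(comparator, note, gold)
  expect_true(all(disc2$records$reason_tag == "unreviewed"))
})

test_that("accuracy_table reports per-condition rows in the validation layout", {
  ids <- paste0("p", 1:30)
  gold <- tibble::tibble(patient_id = ids,
                         a = rbinom(30, 1, 0.5), b = rbinom(30, 1, 0.5))
  tab <- accuracy_table(gold, gold)
  expect_equal(tab$condition, c("a", "b"))
  expect_equal(tab$sensitivity, c(1, 1))
  expect_equal(tab$specificity, c(1, 1))
  expect_equal(tab$n, c(30L, 30L))
})

test_that("the shipped validation benchmark loads with its documented shape", {
  bench <- validation_benchmark()
  expect_equal(nrow(bench), 11L)
  expect_true(all(bench$icd_sensitivity >= 0 & bench$icd_sensitivity <= 1))
  chron <- chronic_omission_benchmark()
  expect_true("endocarditis" %in% chron$condition)
})
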