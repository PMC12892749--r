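test_that("patient classification follows the resection/outcome rules", {
  expect_equal(classify_patient(5, clinical_record("p1", c(5, 6), "I")),
               "TP")
  expect_equal(classify_patient(5, clinical_record("p2", 9, "III")), "TN")
  expect_equal(classify_patient(5, clinical_record("p3", c(5, 7), "II")),
               "FP")
  expect_equal(
    suppressWarnings(classify_patient(integer(),
                                      clinical_record("p4", 9, "I"))),
    "FN")
  expect_warning(classify_patient(integer(), clinical_record("p5", 9, "I")),
                 "empty prediction")
})

test_that("diagnostics reproduce the cohort's published statistics", {
  si <- diagnostics(contingency_table(6, 1, 4, 4))
  expect_equal(si$sensitivity, 0.600, tolerance = 1e-12)
  expect_equal(si$specificity, 0.800, tolerance = 1e-12)
  expect_equal(si$nlr, 0.500, tolerance = 1e-12)

  dc <- diagnostics(contingency_table(5, 1, 5, 4))
  expect_equal(round(dc$accuracy, 3), 0.667)
  expect_equal(dc$dor, 6.25, tolerance = 1e-12)
  expect_equal(round(dc$specificity, 3), 0.833)

  b <- diagnostics(contingency_table(0, 0, 1, 1))
  expect_equal(b$sensitivity, 0)
  expect_equal(b$specificity, 1)
  expect_match(b$method_notes, "Haldane")
  expect_error(contingency_table(0, 0, 0, 0), "empty")
})

test_that("Wilson intervals match published bounds and basic properties", {
  expect_equal(unname(round(wilson_ci(6, 10), 3)), c(0.313, 0.832))
  expect_equal(unname(round(wilson_ci(4, 5), 3)), c(0.376, 0.964))
  expect_equal(unname(round(wilson_ci(5, 6), 3)), c(0.436, 0.970))
  expect_equal(unname(round(wilson_ci(4, 10), 3)), c(0.168, 0.687))
  expect_equal(unname(wilson_ci(0, 10)[1]), 0)
  # interval contains the point estimate; width shrinks with n at fixed k/n
  for (n in c(10, 40, 160)) {
    ci <- wilson_ci(0.3 * n, n)
    expect_true(ci[1] <= 0.3 && 0.3 <= ci[2])
  }
  widths <- vapply(c(10, 40, 160),
                   function(n) diff(unname(wilson_ci(0.3 * n, n))), 0)
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_ci(5, 4), "k <= n")
})

test_that("dor = plr/nlr on random tables", {
  set.seed(19)
  for (i in 1:200) {
    ct <- contingency_table(sample(1:30, 1), sample(1:30, 1),
                            sample(1:30, 1), sample(1:30, 1))
    d <- diagnostics(ct)
    expect_equal(d$dor, d$plr / d$nlr, tolerance = 1e-12)
  }
})

test_that("metric comparison picks chi-square or Fisher appropriately", {
  a <- contingency_table(10, 5, 10, 15)
  self <- compare_metrics(a, a)
  expect_equal(self$p_value, 1, tolerance = 1e-12)
  # balanced large table -> chi-square with statistic 0
  b <- contingency_table(10, 10, 10, 10)
  cmp <- compare_metrics(b, b)
  expect_equal(cmp$test, "chi-square")
  expect_equal(cmp$statistic, 0)
  # Fisher branch matches exhaustive hypergeometric enumeration
  sparse_a <- contingency_table(1, 4, 0, 5)   # 1 correct, 9 incorrect
  sparse_b <- contingency_table(6, 2, 5, 1)   # 11 correct, 3 incorrect
  cmp2 <- compare_metrics(sparse_a, sparse_b, test = "fisher")
  expect_equal(cmp2$test, "fisher")
  tab <- rbind(c(1, 11), c(9, 3))
  expect_equal(cmp2$p_value, naive_fisher_p(t(tab)), tolerance = 1e-10)
  expect_equal(signif(cmp2$p_value, 2), 0.0028)
  # auto rule drops to Fisher when expected counts are small
  tiny_a <- contingency_table(1, 0, 1, 1)     # 2 correct, 1 incorrect
  tiny_b <- contingency_table(0, 2, 0, 1)     # 0 correct, 3 incorrect
  expect_equal(compare_metrics(tiny_a, tiny_b)$test, "fisher")
  # degenerate zero-margin comparison
  z_a <- contingency_table(1, 0, 1, 0)
  z_b <- contingency_table(2, 0, 1, 0)
  expect_equal(compare_metrics(z_a, z_b)$p_value, 1)
})

test_that("Engel summaries count favorable outcomes", {
  recs <- c(lapply(1:10, function(i) clinical_record(paste0("p", i), 1, "I")),
            lapply(11:12, function(i) clinical_record(paste0("p", i), 1, "II")),
            lapply(13:15, function(i) clinical_record(paste0("p", i), 1, "IV")))
  s <- engel_summary(recs)
  expect_equal(unname(s$counts["I"]), 10)
  expect_equal(round(s$favorable, 3), 0.667)
  expect_equal(engel_summary(list(clinical_record("a", 1, "I")))$favorable, 1)
  expect_equal(engel_summary(list(clinical_record("a", 1, "II")))$favorable, 0)
  expect_error(engel_summary(list()), "no clinical")
})

test_that("packaged printed-derived contingency fixtures load", {
  ct <- printed_contingency()
  expect_named(ct, c("si", "dc", "dcout", "dcin"))
  expect_equal(unlist(ct$si), c(tp = 6, fp = 1, tn = 4, fn = 4))
  expect_equal(unlist(ct$dcin), c(tp = 4, fp = 1, tn = 4, fn = 6))
})
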