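test_that("age normalization applies the documented rules", {
  na <- normalize_age(c("2.8-1.2", "< 1 Ma", "not dated", "7.5",
                        "12.7% in cyt-b (6.4 Ma)", "9-6", "3.0"))
  expect_equal(na$age, c(2.0, 0.5, NA, 7.5, 6.4, 7.5, 3.0))
  expect_equal(na$rule, c("midpoint", "half-Ma", "excluded", "point",
                          "point", "midpoint", "point"))
  expect_error(normalize_age("sometime"), "sometime")
  expect_error(normalize_age(""), "empty")

  # idempotent on its own numeric output
  vals <- na$age[!is.na(na$age)]
  expect_equal(normalize_age(as.character(vals))$age, vals)
})

test_that("compendium expansion reproduces the printed per-group tallies", {
  rec <- read_transition_records()
  expect_equal(nrow(rec), 89)  # 87 dated + 2 undated
  tan <- rec[rec$taxa == "Tangara", ]
  expect_equal(as.vector(table(tan$polarity)),
               c(6, 6))  # six transitions in each polarity
  expect_equal(sum(rec$taxa == "Allobates"), 5)
  birds <- rec[rec$class == "Birds", ]
  expect_equal(sum(birds$polarity == "Andes-to-Amazon"), 16)
  expect_equal(sum(birds$polarity == "Amazon-to-Andes"), 37)
  ins <- rec[rec$class == "Insects", ]
  expect_equal(as.vector(table(ins$polarity)), c(4, 4))
})

test_that("polarity summaries agree with naive two-pass statistics", {
  rec <- read_transition_records()
  s <- summarize_polarity(rec)
  ages <- split(normalize_age(rec$age_raw)$age, rec$polarity)
  for (p in s$polarity) {
    x <- ages[[p]][!is.na(ages[[p]])]
    ref <- naive_mean_ci(x)
    row <- s[s$polarity == p, ]
    expect_equal(row$mean_age, unname(ref["mean"]), tolerance = 1e-12)
    expect_equal(row$ci_lower, unname(ref["lower"]), tolerance = 1e-12)
    expect_equal(row$ci_upper, unname(ref["upper"]), tolerance = 1e-12)
  }
  w <- compare_age_means(rec)
  ref <- naive_welch(ages[["Andes-to-Amazon"]][!is.na(ages[["Andes-to-Amazon"]])],
                     ages[["Amazon-to-Andes"]][!is.na(ages[["Amazon-to-Andes"]])])
  expect_equal(w$t, unname(ref["t"]), tolerance = 1e-12)
  expect_equal(w$df, unname(ref["df"]), tolerance = 1e-12)

  # degenerate cases
  two <- data.frame(class = "x", group = "g", taxa = "t",
                    polarity = rep("Andes-to-Amazon", 2),
                    age_raw = c("3", "3"))
  s2 <- summarize_polarity(two)
  r2 <- s2[s2$polarity == "Andes-to-Amazon", ]
  expect_equal(r2$ci_lower, r2$ci_upper)

  same <- rbind(two, transform(two, polarity = "Amazon-to-Andes"))
  expect_equal(compare_age_means(same)$t, 0)

  # shifting the larger-mean group upward increases t monotonically
  shift <- function(c) {
    d <- data.frame(class = "x", group = "g", taxa = "t",
                    polarity = rep(c("Andes-to-Amazon", "Amazon-to-Andes"),
                                   each = 4),
                    age_raw = as.character(c(c(5, 6, 7, 8) + c, 1, 2, 3, 4)))
    compare_age_means(d)$t
  }
  expect_true(all(diff(sapply(c(0, 1, 3, 10), shift)) > 0))
})

test_that("polarity chi-square matches hand values and the exact null", {
  expect_equal(round(polarity_chisq(c(52, 35), 100, seed = 1)$statistic, 2),
               3.32)
  expect_equal(round(polarity_chisq(c(37, 16), 100, seed = 1)$statistic, 2),
               8.32)
  eq <- polarity_chisq(c(40, 40), 2000, seed = 2)
  expect_equal(eq$statistic, 0)
  expect_gt(eq$p_value, 0.95)
  expect_error(polarity_chisq(c(0, 0)), "zero")

  # simulated p converges to the exact binomial two-tail probability
  res <- polarity_chisq(c(12, 4), replicates = 2e5, seed = 3)
  exact <- pbinom(4, 16, 0.5) + pbinom(11, 16, 0.5, lower.tail = FALSE)
  expect_equal(res$p_value, exact, tolerance = 0.01)

  # cross-check against the independent simulation in stats::chisq.test
  set.seed(4)
  ref <- suppressWarnings(chisq.test(c(52, 35), p = c(0.5, 0.5),
                                     simulate.p.value = TRUE, B = 2e4))
  mine <- polarity_chisq(c(52, 35), replicates = 2e4, seed = 5)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(mine$p_value - ref$p.value), 0.01)
})

test_that("bin analysis counts, percentages and rates are consistent", {
  rec <- read_transition_records()
  b <- bin_analysis(rec)
  expect_equal(sum(b$n), 87)
  expect_equal(b$n[b$type == 3 & b$polarity == "Amazon-to-Andes"], 16)
  expect_equal(b$n[b$type == 3 & b$polarity == "Andes-to-Amazon"], 9)
  expect_equal(sum(b$percent), 100, tolerance = 1e-9)

  birds <- bin_analysis(rec, class_filter = "Birds")
  expect_equal(birds$rate_per_ma[birds$type == 2 &
                                 birds$polarity == "Amazon-to-Andes"], 5.4)
  # rate = count / bin width
  expect_equal(birds$rate_per_ma[is.finite(birds$width)],
               (birds$n / birds$width)[is.finite(birds$width)])
})

test_that("divergence-to-age conversion applies the clock and half-up display", {
  expect_equal(divergence_to_age(12.7), 6.4)
  expect_equal(divergence_to_age(16.3), 8.2)
  expect_equal(divergence_to_age(0), 0)
  expect_equal(divergence_to_age(12.7, round = FALSE), 6.35)
  expect_equal(divergence_to_age(10, rate = 4), 2.5)
  expect_error(divergence_to_age(5, rate = 0), "positive")
  expect_equal(round_half_up(c(0.05, 0.15, 0.25), 1), c(0.1, 0.2, 0.3))
})
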