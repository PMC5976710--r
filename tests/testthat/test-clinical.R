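test_that("the packaged treatment table carries the published cohort", {
  t1 <- read_residual_table()
  expect_equal(nrow(t1), 38)
  expect_equal(sum(t1$tumor_type == "HCC"), 28)
  expect_equal(sum(t1$tumor_type == "MET"), 10)
  expect_equal(range(t1$tumor_volume_cm3), c(0.4, 14.5))
})

test_that("score summaries agree with a direct mean/SD computation", {
  tmp <- file.path(tempdir(), "scores4.csv")
  d <- data.frame(treatment = 1:4, tumor_type = "HCC", segment = 5,
                  reg_quality_r1 = c(5, 4, 3, 4), reg_quality_r2 = c(5, 5, 4, 4),
                  position_r1 = c(4, 4, 5, 5), position_r2 = c(5, 4, 4, 5),
                  clinical_indication_r1 = c(3, 4, 5, 4),
                  clinical_indication_r2 = c(4, 4, 4, 5),
                  confidence_r1 = c(5, 5, 5, 5), confidence_r2 = c(4, 5, 5, 4))
  write.csv(d, tmp, row.names = FALSE)
  s <- summarize_scores(read_score_table(tmp))
  row <- s[s$criterion == "reg_quality" & s$rater == "r1", ]
  expect_equal(row$mean, mean(c(5, 4, 3, 4)))
  expect_equal(row$sd, sd(c(5, 4, 3, 4)))
  row2 <- s[s$criterion == "confidence" & s$rater == "r1", ]
  expect_equal(row2$mean_1dp, 5.0)
  expect_equal(row2$sd_1dp, 0.0)
  # NA rows (second tumors) are excluded from registration-quality columns
  full <- summarize_scores(read_score_table())
  expect_equal(full$n[full$criterion == "reg_quality"][1], 30)
  expect_equal(full$n[full$criterion == "position"][1], 38)
  # reported rounded means never sit 0.05 or more from the raw mean
  expect_true(all(abs(full$mean - full$mean_1dp) < 0.05))
})

test_that("Student's t matches stats::t.test and its degenerate sentinels", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- students_t(a, b, "unpaired_equal_var")
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  b2 <- c(2, 4, 3, 6)
  gp <- students_t(a, b2, "paired")
  rp <- t.test(a, b2, paired = TRUE)
  expect_equal(gp$t, unname(rp$statistic), tolerance = 1e-9)
  expect_equal(gp$p, rp$p.value, tolerance = 1e-9)
  # identical samples
  expect_equal(students_t(a, a, "unpaired_equal_var")[c("t", "p")],
               list(t = 0, p = 1))
  expect_equal(students_t(c(1, 2, 3), c(1, 2, 3), "paired")[c("t", "p")],
               list(t = 0, p = 1))
  # antisymmetry
  ab <- students_t(a, b); ba <- students_t(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  # zero variance, unequal means -> infinite-t sentinel
  z <- students_t(c(2, 2, 2), c(3, 3, 3))
  expect_true(is.infinite(z$t))
  expect_equal(z$p, 0)
  expect_error(students_t(1, c(1, 2)), "n >= 2")
  expect_error(students_t(c(1, 2), c(1, 2, 3), "paired"), "equal lengths")
})

test_that("residual aggregates partition and summarise the cohort", {
  agg <- residual_aggregates()
  expect_equal(agg$n_total, 38)
  expect_equal(agg$n_zero + agg$n_partial + agg$n_missed, agg$n_total)
  expect_equal(c(agg$n_zero, agg$n_partial, agg$n_missed), c(24, 12, 2))
  expect_true(agg$min_pct <= agg$mean_pct && agg$mean_pct <= agg$max_pct)
  expect_equal(agg$n_retreat, 6)
  expect_equal(length(agg$partial_percentages), 12)
  # one zero-residual row: partial aggregates are flagged undefined
  tmp <- file.path(tempdir(), "one.csv")
  write.csv(data.frame(tumor_volume_cm3 = 1, ablation_volume_cm3 = 3,
                       residual_volume_cm3 = 0, residual_percentage = 0),
            tmp, row.names = FALSE)
  one <- residual_aggregates(read_residual_table(tmp))
  expect_false(one$partial_defined)
  expect_true(is.na(one$mean_pct))
  expect_equal(one$n_retreat, 0)
  # the 15% cutoff mentioned as the alternative rule is supported
  expect_equal(residual_aggregates(retreat_threshold = 15)$n_retreat, 6)
})

test_that("malformed clinical tables are rejected", {
  tmp <- file.path(tempdir(), "bad.csv")
  write.csv(data.frame(tumor_volume_cm3 = 1, ablation_volume_cm3 = 3,
                       residual_volume_cm3 = 0, residual_percentage = 120),
            tmp, row.names = FALSE)
  expect_error(read_residual_table(tmp), "\\[0, 100\\]")
  write.csv(data.frame(x = 1), tmp, row.names = FALSE)
  expect_error(read_residual_table(tmp), "lacks columns")
  write.csv(data.frame(reg_quality_r1 = 9, reg_quality_r2 = 1,
                       position_r1 = 1, position_r2 = 1,
                       clinical_indication_r1 = 1, clinical_indication_r2 = 1,
                       confidence_r1 = 1, confidence_r2 = 1),
            tmp, row.names = FALSE)
  expect_error(read_score_table(tmp), "1..5")
})
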