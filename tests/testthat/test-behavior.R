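test_that("phase segmentation reproduces hand-computed intervals", {
  rs <- fixed_reports(c(2, 10, 15, 22),
                      c("integrated", "segregated", "integrated", "segregated"),
                      duration = 30)
  ph <- segment_phases(rs)
  expect_equal(ph$class, c("initial_integrated", "segregated",
                           "subsequent_integrated", "segregated"))
  expect_equal(ph$duration, c(8, 5, 7, 8))
  expect_equal(ph$completed, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(sequence_meets_criteria(ph))
  expect_equal(percent_segregation(rs), (5 + 8) / 28 * 100)

  single <- fixed_reports(2, "integrated", duration = 150)
  ph1 <- segment_phases(single)
  expect_equal(nrow(ph1), 1)
  expect_equal(ph1$class, "initial_integrated")
  expect_false(ph1$completed)
  expect_false(sequence_meets_criteria(ph1))

  expect_error(segment_phases(fixed_reports(c(1, 2), c("integrated",
                                                       "integrated"))),
               "malformed")
})

test_that("inclusion criteria require an integrated start and two completed subsequent phases", {
  seg_first <- segment_phases(fixed_reports(c(2, 9, 14, 20),
      c("segregated", "integrated", "segregated", "integrated"), 30))
  expect_false(sequence_meets_criteria(seg_first))
  one_completed <- segment_phases(fixed_reports(c(2, 9, 14),
      c("integrated", "segregated", "integrated"), 30))
  expect_false(sequence_meets_criteria(one_completed))
})

test_that("segmented durations conserve the reported interval", {
  set.seed(10)
  pp <- percept_params()
  for (i in 1:200) {
    sim <- simulate_phase_sequence(pp, sample(c("neutral", "attend_low"), 1),
                                   sample(c(4, 6), 1), duration = 60)
    ph <- segment_phases(sim$reports)
    expect_equal(sum(ph$duration),
                 sim$reports$sequence_duration - ph$onset[1])
    expect_true(all(ph$duration >= 0))
    # presses strictly increasing and alternating
    expect_true(all(diff(sim$reports$presses$time) > 0))
  }
})

test_that("transformed means match closed forms", {
  expect_equal(transformed_condition_means(50, "logit"), 50)
  expect_equal(transformed_condition_means(c(20, 80), "logit"), 50)
  expect_equal(transformed_condition_means(c(1, 100), "log"), 10)
  expect_warning(out <- transformed_condition_means(c(0, 50), "logit"),
                 "boundary")
  expect_equal(out, 50)
  lenient <- transformed_condition_means(c(0, 50), "logit", strict = FALSE,
                                         n_phases = 10)
  expect_true(lenient < 50 && lenient > 0)
})

test_that("degenerate-variance log-normal sampler returns the exact mean", {
  pp <- percept_params(sigma_log = 1e-12, between_participant_sd = 0)
  pp$mu_log[["6"]]["segregated"] <- log(4)
  set.seed(2)
  sim <- simulate_phase_sequence(pp, "neutral", 6, duration = 80)
  seg <- sim$phases[sim$phases$class == "segregated" & sim$phases$completed, ]
  expect_equal(seg$duration, rep(4, nrow(seg)), tolerance = 1e-6)
})

test_that("percent segregation rises with delta_f under default parameters", {
  set.seed(3)
  pp <- percept_params()
  pct <- sapply(c(4, 6), function(df) {
    mean(replicate(60, percent_segregation(
      simulate_phase_sequence(pp, "neutral", df, 150)$reports)))
  })
  expect_gt(pct[2], pct[1])
})

test_that("with unit multipliers all conditions share the same percept process", {
  pp <- percept_params(intention_multipliers = list(
    neutral = c(integrated = 1, segregated = 1),
    attempt_integration = c(integrated = 1, segregated = 1),
    attend_high = c(integrated = 1, segregated = 1),
    attend_low = c(integrated = 1, segregated = 1)))
  set.seed(4)
  pcts <- lapply(c("neutral", "attempt_integration", "attend_high"),
                 function(cond) {
    replicate(120, percent_segregation(
      simulate_phase_sequence(pp, cond, 6, 150)$reports))
  })
  # same distribution across conditions
  expect_gt(ks.test(pcts[[1]], pcts[[2]])$p.value, 0.01)
  expect_gt(ks.test(pcts[[1]], pcts[[3]])$p.value, 0.01)
})

test_that("paired t and d match a hand-evaluated fixture", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.2)
  y <- c(4.9, 4.2, 5.1, 5.6, 4.4)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(5))      # 2.3094 for this fixture
  res <- paired_t_with_d(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  expect_equal(res$d, t_hand / sqrt(5))
  expect_equal(res$t, t.test(x, y, paired = TRUE)$statistic[[1]])

  same <- suppressWarnings(paired_t_with_d(x, x))
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)

  # constructed differences with mean = 0.67 sd give d_z = 0.67
  set.seed(9)
  z <- scale(rnorm(25))[, 1]
  res2 <- paired_t_with_d(z * 1 + 0.67)
  expect_equal(res2$d, 0.67, tolerance = 1e-10)
  # noncentral-t CI brackets d and has correct pivot behavior
  expect_true(res2$d_ci[1] < 0.67 && res2$d_ci[2] > 0.67)
  expect_equal(pt(res2$t, 24, res2$d_ci[1] * sqrt(25)), 0.975,
               tolerance = 1e-6)
})

test_that("two-level rm ANOVA equals squared paired t with epsilon 1", {
  set.seed(11)
  d <- expand.grid(id = factor(1:10), cond = factor(c("a", "b")))
  d$y <- rnorm(20) + (d$cond == "b") * 0.8
  a <- rm_anova_hf(d, "y", "id", "cond", ci_boot = 0)
  tt <- paired_t_with_d(d$y[d$cond == "a"], d$y[d$cond == "b"])
  expect_equal(a$F, tt$t^2, tolerance = 1e-10)
  expect_equal(a$epsilon_hf, 1)
  expect_equal(a$p, tt$p, tolerance = 1e-10)
  expect_true(a$eta_sq_p >= 0 && a$eta_sq_p <= 1)
})

test_that("rm ANOVA p-values are uniform under the null", {
  set.seed(12)
  ps <- replicate(300, {
    d <- expand.grid(id = factor(1:8), cond = factor(letters[1:3]))
    d$y <- rnorm(24) + rep(rnorm(8), 3)
    rm_anova_hf(d, "y", "id", "cond", ci_boot = 0)$p
  })
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("within-participant CIs ignore participant offsets", {
  set.seed(13)
  base <- matrix(rnorm(40), 10, 4)
  shifted <- base + rnorm(10) * 5     # big per-participant offsets
  ci1 <- within_participant_ci(base)
  ci2 <- within_participant_ci(shifted)
  expect_equal(ci1$half_width, ci2$half_width, tolerance = 1e-12)
  # perfectly consistent condition effects give zero-width intervals
  consistent <- outer(rnorm(10), rep(1, 3)) + outer(rep(1, 10), c(1, 2, 3))
  ci3 <- within_participant_ci(consistent)
  expect_equal(ci3$half_width, rep(0, 3), tolerance = 1e-10)
  # hand computation for 2 conditions: correction factor sqrt(2)
  m <- matrix(c(1, 2, 3, 5, 4, 7), 3, 2)
  cent <- m - rowMeans(m) + mean(m)
  se <- apply(cent, 2, sd) / sqrt(3) * sqrt(2)
  expect_equal(within_participant_ci(m)$half_width, qt(0.975, 2) * se)
})
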