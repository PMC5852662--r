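test_that("percept means weight the two delta-f cells equally", {
  set.seed(30)
  base <- rnorm(150)
  mk <- function(n, shift) {
    matrix(rep(base + shift, n), n, 150, byrow = TRUE)
  }
  # delta-f 4: 10 epochs at +1; delta-f 6: 1000 epochs at +3
  ep <- structure(list(
    data = rbind(mk(10, 1), mk(1000, 3), mk(20, 0), mk(40, 0.5)),
    delta_f = rep(c(4, 6, 4, 6), c(10, 1000, 20, 40)),
    labels = rep(c("segregated", "segregated", "integrated", "integrated"),
                 c(10, 1000, 20, 40)),
    onsets = numeric(1070), n_samples = 150, sample_rate = 250,
    condition = rep("neutral", 1070)), class = "epoch_set")
  em <- percept_evoked_means(ep)
  # equal weighting: collapsed segregated mean = base + 2 regardless of the
  # 10 vs 1000 cell sizes
  expect_equal(em$percept_means$segregated, base + 2, tolerance = 1e-12)
  expect_equal(em$percept_means$integrated, base + 0.25, tolerance = 1e-12)
  # brute-force per-cell summation oracle
  sel <- ep$delta_f == 4 & ep$labels == "segregated"
  expect_equal(em$cell_means[["4.segregated"]],
               apply(ep$data[sel, ], 2, sum) / sum(sel))
  ep$labels[1:10] <- "integrated"
  expect_error(percept_evoked_means(ep), "empty cell")
})

test_that("identical conditions give no cluster and p = 1", {
  set.seed(31)
  a <- matrix(rnorm(8 * 150), 8, 150)
  res <- cluster_permutation_test(a, a + 0, n_perm = 50)
  expect_equal(nrow(res$clusters), 0)
  expect_equal(res$p, 1)
})

test_that("Monte-Carlo permutation null matches exhaustive enumeration", {
  set.seed(32)
  n <- 10
  a <- matrix(rnorm(n * 40), n, 40)
  b <- matrix(rnorm(n * 40), n, 40)
  b[, 15:20] <- b[, 15:20] + 1.1
  mc <- cluster_permutation_test(a, b, n_perm = 2000)
  ex <- cluster_permutation_test(a, b, all_flips = TRUE)
  expect_equal(ex$n_perm, 2^10)
  # same observed statistic, null distributions agree in distribution
  expect_equal(mc$max_cluster_mass, ex$max_cluster_mass)
  expect_equal(mc$p, ex$p, tolerance = 0.05)
  qs <- c(0.5, 0.75, 0.9)
  expect_equal(quantile(mc$null_masses, qs), quantile(ex$null_masses, qs),
               tolerance = 0.1)
})

test_that("permutation p is invariant to common rescaling of waveforms", {
  set.seed(33)
  a <- matrix(rnorm(9 * 60), 9, 60)
  b <- matrix(rnorm(9 * 60), 9, 60) + 0.5
  r1 <- cluster_permutation_test(a, b, all_flips = TRUE)
  r2 <- cluster_permutation_test(a * 37.5, b * 37.5, all_flips = TRUE)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t_series, r2$t_series, tolerance = 1e-10)
})

test_that("window selection uses the inclusive 4 ms grid", {
  w <- rep(0, 150)
  lat <- (0:149) * 4
  sel <- lat >= 216 & lat <= 288
  expect_equal(sum(sel), 19)
  w[sel] <- 1
  expect_equal(window_mean(w, c(216, 288), 250), 1)
  w2 <- seq_len(150)
  expect_equal(window_mean(w2, c(216, 288), 250),
               mean(which(sel)))            # index arithmetic oracle
  expect_error(window_mean(w, c(550, 650), 250), "outside")
  # window start is 66 ms after the L tone onset at 150 ms
  expect_equal(216 - 150, 66)
})

test_that("a constant within-window difference is recovered exactly", {
  n <- 6
  int <- matrix(rnorm(n * 150), n, 150)
  seg <- int
  lat <- (0:149) * 4
  seg[, lat >= 216 & lat <= 288] <- seg[, lat >= 216 & lat <= 288] + 0.7
  we <- suppressWarnings(window_effect(seg, int))
  expect_equal(we$values, rep(0.7, n), tolerance = 1e-12)
})

test_that("task contrasts follow the printed weights", {
  set.seed(34)
  vals <- expand.grid(participant = 1:7,
                      condition = c("attempt_integration", "attend_high",
                                    "attend_low"), stringsAsFactors = FALSE)
  x <- rnorm(7); y <- rnorm(7)
  vals$value <- ifelse(vals$condition == "attempt_integration", y, x)
  tc <- suppressWarnings(task_contrasts(vals))
  expect_equal(tc$c1$values, x - y)
  expect_equal(tc$c4$values, rep(0, 7))
  # dot-product oracle on a random fixture
  vals$value <- rnorm(21)
  w <- reshape(vals, idvar = "participant", timevar = "condition",
               direction = "wide")
  tc2 <- task_contrasts(vals)
  expect_equal(tc2$c2$values,
               w$value.attend_high - w$value.attempt_integration)
  expect_equal(tc2$c1$values,
               0.5 * w$value.attend_high + 0.5 * w$value.attend_low -
                 w$value.attempt_integration)
  expect_error(task_contrasts(vals[vals$condition != "attend_low", ]),
               "required")
})

test_that("expected non-neutral response interpolates the percept means", {
  grid <- expand.grid(participant = 1:4, delta_f = c(4, 6),
                      percept = c("integrated", "segregated"),
                      stringsAsFactors = FALSE)
  grid$value <- ifelse(grid$percept == "segregated", 2, -1)
  conds <- c("attempt_integration", "attend_high", "attend_low")
  rp <- expand.grid(participant = 1:4, delta_f = c(4, 6), condition = conds,
                    stringsAsFactors = FALSE)
  # p_seg = 1 -> expected value equals the segregated mean;
  # p_seg = 0.5 -> midpoint
  rp$p_seg <- ifelse(rp$condition == "attempt_integration", 0.5, 1)
  obs <- rp; obs$value <- 0
  res <- suppressWarnings(expected_nonneutral_response(grid, rp, obs))
  expect_equal(res$expected, rep(2 - (2 - 1) / 2, 4))
  expect_equal(res$observed, rep(0, 4))
  expect_equal(res$test$t, Inf)
})

test_that("cluster test flags the injected percept window on a calibrated cohort", {
  set.seed(35)
  cfg <- cohort_config(n_participants = 14, n_blocks = 2, n_triplets = 150,
                       min_cell = 8, seed = 41)
  seeds <- cohort_seeds(cfg$seed, cfg$n_participants)
  seg <- int <- NULL
  for (i in seq_len(cfg$n_participants)) {
    set.seed(seeds[i])
    part <- simulate_participant(cfg, i, conditions = "neutral")
    ep <- participant_epochs(part, cfg)
    if (!min_cell_count_gate(ep$labels, ep$delta_f, cfg$min_cell)$included) next
    em <- percept_evoked_means(ep)
    seg <- rbind(seg, em$percept_means$segregated)
    int <- rbind(int, em$percept_means$integrated)
  }
  res <- cluster_permutation_test(seg, int, n_perm = 300)
  top <- res$clusters[which.max(abs(res$clusters$mass)), ]
  lat <- (0:149) * 4
  # the largest cluster is positive and overlaps 216-288 ms
  expect_gt(top$sign, 0)
  expect_true(lat[top$end] >= 216 && lat[top$start] <= 288)
})
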