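test_that("the ensemble holds folds x repeats evaluations and separates easy classes", {
  set.seed(40)
  n <- 40; p <- 30
  x <- rbind(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p, 10), n, p))
  labels <- rep(c("integrated", "segregated"), each = n)
  ens <- train_decoders(x, labels, folds = 5, repeats = 4)
  expect_equal(ens$n_models, 20)
  expect_gt(ens$cv_accuracy, 95)
  # full defaults give 5 x 100 = 500 evaluations
  expect_equal(5 * 100, 500)
  expect_error(train_decoders(x[c(1:3, 41:80), ], labels[c(1:3, 41:80)]),
               "at least")
})

test_that("class imbalance is neutralized by subsampling", {
  set.seed(41)
  p <- 20
  # 300 integrated vs 30 segregated, zero signal: a biased classifier
  # would report ~91% by always answering "integrated"
  x <- matrix(rnorm(330 * p), 330, p)
  labels <- rep(c("integrated", "segregated"), c(300, 30))
  ens <- train_decoders(x, labels, folds = 5, repeats = 10)
  expect_lt(abs(ens$cv_accuracy - 50), 12)
  # every training set is balanced
  tr_labels <- table(labels[ens$train_idx[[1]]])
  expect_equal(unname(tr_labels["integrated"]), unname(tr_labels["segregated"]))
})

test_that("null-trained decoders sit at chance over seeds", {
  set.seed(42)
  accs <- replicate(12, {
    x <- matrix(rnorm(80 * 25), 80, 25)
    labels <- sample(rep(c("integrated", "segregated"), each = 40))
    train_decoders(x, labels, folds = 5, repeats = 3)$cv_accuracy
  })
  expect_lt(abs(mean(accs) - 50), 3)
})

test_that("Haufe correction recovers the signal feature and the covariance identity", {
  set.seed(43)
  n <- 150; p <- 12
  signal <- rep(c(-1, 1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 5] <- x[, 5] * 0.3 + signal          # only feature 5 carries signal
  # suppressor: pure noise correlated into the data via feature 9
  labels <- ifelse(signal > 0, "segregated", "integrated")
  ens <- train_decoders(x, labels, folds = 5, repeats = 5)
  pat <- haufe_correct(ens, x)
  expect_equal(which.max(abs(pat)), 5L)
  expect_gt(pat[5], 0)                     # positive = favors segregated
  expect_lt(max(abs(pat[-5])) / abs(pat[5]), 0.35)

  # identity covariance: pattern proportional to the raw weights
  S <- diag(p)
  w <- rnorm(p)
  expect_equal(drop(S %*% w), w)
  # equivalence form: Cov(X) w == Cov(X, X w) (per-feature covariance with
  # the decision value), brute force on a fixture
  xs <- scale(x, scale = FALSE)
  C <- crossprod(xs) / n
  dv <- drop(x %*% w)
  brute <- vapply(seq_len(p), function(j) {
    mean(xs[, j] * (dv - mean(dv)))
  }, numeric(1))
  expect_equal(drop(C %*% w), brute, tolerance = 1e-10)
})

test_that("Ledoit-Wolf covariance is well conditioned and shrinks toward identity scale", {
  set.seed(44)
  x <- matrix(rnorm(10 * 50), 10, 50)      # p >> n
  S <- ledoit_wolf_cov(x)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 1e-8)
  # with abundant data and a structured population covariance the
  # estimate approaches the sample covariance (shrinkage vanishes)
  x2 <- matrix(rnorm(5000 * 4), 5000, 4) %*% diag(c(1, 2, 3, 4))
  S2 <- ledoit_wolf_cov(x2)
  expect_equal(S2, cov(x2) * (4999 / 5000), tolerance = 0.02)
})

test_that("vote aggregation equals a brute-force loop over models", {
  set.seed(45)
  n <- 30; p <- 15
  x <- rbind(matrix(rnorm(n * p), n, p), matrix(rnorm(n * p, 1), n, p))
  labels <- rep(c("integrated", "segregated"), each = n)
  ens <- train_decoders(x, labels, folds = 5, repeats = 2)
  xnew <- matrix(rnorm(10 * p, 0.5), 10, p)
  got <- classify_epochs(ens, xnew)
  fracs <- vapply(seq_len(ens$n_models), function(m) {
    xs <- sweep(sweep(xnew, 2, ens$MU[m, ]), 2, ens$SD[m, ], "/")
    dv <- drop(xs %*% ens$W[m, ]) - ens$b[m]
    mean(dv > 0)
  }, numeric(1))
  expect_equal(got, 100 * mean(fracs), tolerance = 1e-10)
  expect_error(classify_epochs(ens, xnew[, 1:5]), "mismatch")
})

test_that("classification generalizes to epochs resembling a training class", {
  set.seed(46)
  n <- 60; p <- 20
  mu_seg <- rnorm(p)
  x <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, 0), n, p) + matrix(mu_seg * 3, n, p,
                                                    byrow = TRUE))
  labels <- rep(c("integrated", "segregated"), each = n)
  ens <- train_decoders(x, labels, folds = 5, repeats = 3)
  like_seg <- matrix(rnorm(20 * p), 20, p) + matrix(mu_seg * 3, 20, p,
                                                    byrow = TRUE)
  expect_gt(classify_epochs(ens, like_seg), 90)
  expect_lt(classify_epochs(ens, matrix(rnorm(20 * p), 20, p)), 10)
})

test_that("accuracy adjustment scales expected differences correctly", {
  conds <- c("attempt_integration", "attend_high", "attend_low")
  rp <- expand.grid(participant = 1:5, delta_f = c(4, 6), condition = conds,
                    stringsAsFactors = FALSE)
  rp$pct_seg <- ifelse(rp$condition == "attempt_integration", 20, 70)
  cls <- rp
  cls$pct_seg <- 50
  acc100 <- data.frame(participant = rep(1:5, 2),
                       delta_f = rep(c(4, 6), each = 5), cv_accuracy = 100)
  res <- suppressWarnings(adjusted_expected_difference(rp, acc100, cls))
  expect_equal(res$expected, rep(50, 5))   # (100-50)/50 = 1: raw difference
  expect_equal(res$observed, rep(0, 5))
  acc50 <- acc100; acc50$cv_accuracy <- 50
  res2 <- suppressWarnings(adjusted_expected_difference(rp, acc50, cls))
  expect_equal(res2$expected, rep(0, 5))   # chance classifier: no signal
  # worked magnitude: accuracy 53.2%, report difference 36.6 points
  accx <- acc100; accx$cv_accuracy <- 53.2
  rp2 <- rp; rp2$pct_seg <- ifelse(rp2$condition == "attempt_integration",
                                   20, 56.6)
  res3 <- suppressWarnings(adjusted_expected_difference(rp2, accx, cls))
  expect_equal(res3$expected, rep(36.6 * 0.064, 5), tolerance = 1e-10)
})

test_that("decoding accuracy increases with the injected effect amplitude", {
  set.seed(47)
  accs <- vapply(c(0, 0.45, 0.9), function(a) {
    cfg <- cohort_config(n_participants = 1, n_blocks = 2, n_triplets = 100,
                         neural = neural_params(
                           segregation_effect_amplitude = a,
                           sign_flip_probability = 0,
                           effect_jitter_sd = 0),
                         percept = percept_params(between_participant_sd = 0),
                         min_cell = 5, repeats = 2, seed = 53)
    set.seed(53)
    part <- simulate_participant(cfg, 1, conditions = "neutral")
    ep <- participant_epochs(part, cfg)
    sel <- ep$delta_f == 6
    train_decoders(ep$data[sel, ], ep$labels[sel], folds = 5,
                   repeats = 3)$cv_accuracy
  }, numeric(1))
  expect_gt(accs[2], accs[1])
  expect_gt(accs[3], accs[2] - 2)   # monotone up to small-sample noise
  expect_lt(abs(accs[1] - 50), 10)
  expect_gt(accs[3], 65)
})
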