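test_that("epoch extraction matches brute-force indexing", {
  set.seed(20)
  tl <- build_stimulus_timeline(20, delta_f = 4)
  x <- rnorm(round(tl$duration * 250))
  rec <- recording(x, 250)
  ep <- extract_epochs(rec, tl)
  expect_equal(dim(ep$data), c(20, 150))
  # independent index arithmetic
  for (i in c(1, 7, 20)) {
    start <- round(tl$triplet_onsets[i] * 250) + 1
    expect_equal(ep$data[i, ], x[start:(start + 149)])
  }
  short <- recording(x[1:1000], 250)
  expect_error(extract_epochs(short, tl), "too short")
})

test_that("a noise-free epoch equals the participant's evoked kernel", {
  np <- neural_params(noise_sd = 0, segregation_effect_amplitude = 0)
  tmpl <- list(latency_shift_ms = 0, gain = 1, effect_gain = 1)
  tl <- build_stimulus_timeline(10)
  ph <- data.frame(class = "initial_integrated", onset = 0,
                   duration = tl$duration, completed = FALSE)
  attr(ph, "duration") <- tl$duration
  rec <- synthesize_recording(tl, ph, np, tmpl)
  ep <- extract_epochs(rec, tl)
  kern <- bistream:::triplet_kernel(np, tmpl, 1000)
  # mid-sequence epochs at the synthesis rate contain kernel + spillover
  # from the previous triplet only; epoch 1 is the pure kernel
  ep1000 <- rec$data[1:600]
  expect_equal(ep1000, kern, tolerance = 1e-12)
})

test_that("press-guard mask equals a brute-force inequality oracle", {
  set.seed(21)
  for (trial in 1:200) {
    dur <- 60
    n_press <- sample(0:6, 1)
    times <- sort(runif(n_press, 0, dur))
    percepts <- rep(c("integrated", "segregated"),
                    length.out = n_press)
    rs <- fixed_reports(times, percepts, duration = dur)
    tl <- build_stimulus_timeline(100)
    ep <- list(onsets = tl$triplet_onsets, n_samples = 150, sample_rate = 250)
    class(ep) <- "epoch_set"
    guard <- runif(1, 0.5, 2)
    mask <- apply_exclusion(ep, rs, guard)
    events <- c(0, times, dur)
    oracle <- vapply(tl$triplet_onsets, function(on) {
      all(vapply(events, function(p) {
        !(on < p + guard && on + 0.6 > p - guard)
      }, logical(1)))
    }, logical(1))
    expect_identical(mask, oracle)
  }
})

test_that("retained epochs across a report boundary are at least 3.6 s apart", {
  rs <- fixed_reports(c(2, 30), c("integrated", "segregated"), duration = 150)
  tl <- build_stimulus_timeline(250)
  ep <- structure(list(onsets = tl$triplet_onsets, n_samples = 150,
                       sample_rate = 250), class = "epoch_set")
  mask <- apply_exclusion(ep, rs, 1.5)
  kept <- which(mask)
  gaps <- diff(ep$onsets[kept])
  # the smallest onset-to-onset gap across the press at 30 s
  cross <- gaps[gaps > 0.6 + 1e-9]
  expect_gte(min(cross), 3.6)
  # 1/3.6 s rounds to the 0.278 Hz high-pass cutoff
  expect_equal(round(1 / 3.6, 3), 0.278)
})

test_that("single press at start retains the guarded interior only", {
  rs <- fixed_reports(0, "integrated", duration = 150)
  tl <- build_stimulus_timeline(250)
  ep <- structure(list(onsets = tl$triplet_onsets, n_samples = 150,
                       sample_rate = 250), class = "epoch_set")
  mask <- apply_exclusion(ep, rs, 1.5)
  on <- ep$onsets
  expect_identical(mask, on >= 1.5 & on + 0.6 <= 148.5)
})

test_that("retention decreases monotonically with the guard", {
  set.seed(22)
  sim <- simulate_phase_sequence(percept_params(), "neutral", 6, 150)
  tl <- build_stimulus_timeline(250)
  ep <- structure(list(onsets = tl$triplet_onsets, n_samples = 150,
                       sample_rate = 250), class = "epoch_set")
  fr <- vapply(seq(0, 3, by = 0.25), function(g) {
    mean(apply_exclusion(ep, sim$reports, g))
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("percept labels equal a brute-force latest-press search", {
  set.seed(23)
  for (trial in 1:100) {
    n_press <- sample(0:8, 1)
    times <- sort(runif(n_press, 0, 60))
    percepts <- rep(c("integrated", "segregated"), length.out = n_press)
    if (n_press > 0 && runif(1) < 0.5) {
      percepts <- rev(rep(c("segregated", "integrated"),
                          length.out = n_press))
    }
    rs <- fixed_reports(times, percepts, duration = 60)
    ep <- structure(list(onsets = seq(0, 59.4, by = 0.6), n_samples = 150,
                         sample_rate = 250), class = "epoch_set")
    labels <- label_epochs(ep, rs)
    oracle <- vapply(ep$onsets, function(on) {
      prior <- which(times <= on)
      if (length(prior) == 0) "integrated" else percepts[max(prior)]
    }, character(1))
    expect_identical(labels, oracle)
  }
  # no presses at all: everything is integrated
  rs0 <- structure(list(presses = data.frame(time = numeric(0),
                                             percept = character(0)),
                        condition = "neutral", delta_f = 6,
                        sequence_duration = 60), class = "report_stream")
  ep <- structure(list(onsets = c(0, 10, 20), n_samples = 150,
                       sample_rate = 250), class = "epoch_set")
  expect_identical(label_epochs(ep, rs0), rep("integrated", 3))
  # interval membership
  rs2 <- fixed_reports(c(10, 20), c("segregated", "integrated"), 60)
  expect_identical(label_epochs(structure(list(onsets = 15, n_samples = 150,
                                               sample_rate = 250),
                                          class = "epoch_set"), rs2),
                   "segregated")
})

test_that("the sensitivity flag drops epochs before the first segregated report", {
  rs <- fixed_reports(c(2, 10), c("integrated", "segregated"), 60)
  ep <- structure(list(onsets = c(1, 5, 12), n_samples = 150,
                       sample_rate = 250), class = "epoch_set")
  lab <- label_epochs(ep, rs, exclude_before_first_segregated = TRUE)
  expect_identical(lab, c(NA, NA, "segregated"))
})

test_that("minimum-cell gate applies the configured threshold", {
  labels <- c(rep("integrated", 60), rep("segregated", 70),
              rep("integrated", 80), rep("segregated", 90))
  dfs <- rep(c(4, 6), c(130, 170))
  expect_true(min_cell_count_gate(labels, dfs, 55)$included)
  labels2 <- c(rep("integrated", 5), rep("segregated", 100),
               rep("integrated", 100), rep("segregated", 100))
  expect_false(min_cell_count_gate(labels2, rep(c(4, 6), c(105, 200)),
                                   55)$included)
  expect_true(min_cell_count_gate(labels2, rep(c(4, 6), c(105, 200)),
                                  0)$included)
})

test_that("no retained epoch violates the guard in simulated sessions", {
  set.seed(24)
  cfg <- small_config(seed = 31)
  part <- simulate_participant(cfg, 1, synthesize = FALSE)
  for (sq in part$sequences) {
    tl <- sq$timeline
    ep <- structure(list(onsets = tl$triplet_onsets, n_samples = 150,
                         sample_rate = 250), class = "epoch_set")
    mask <- apply_exclusion(ep, sq$reports, cfg$guard)
    press <- sq$reports$presses$time
    for (on in ep$onsets[mask]) {
      expect_true(all(on >= press + cfg$guard | on + 0.6 <= press - cfg$guard))
    }
  }
})
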