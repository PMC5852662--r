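#' Percept-conditional evoked means (neutral condition)
#'
#' Averages retained neutral epochs for each delta-f x percept cell, then
#' collapses over delta-f within each percept with equal weight (the simple
#' average of the two cell means), so percept comparisons are free of
#' stimulus confounds regardless of cell sizes.
#'
#' @param epochs An `epoch_set` of retained neutral epochs for one
#'   participant.
#' @return List with `cell_means` (named list `df.percept` -> mean
#'   waveform), `percept_means` (list `integrated`/`segregated`, delta-f
#'   collapsed), and `cell_counts`.
#' @export
percept_evoked_means <- function(epochs) {
  dfs <- sort(unique(epochs$delta_f))
  percepts <- c("integrated", "segregated")
  cell_means <- list()
  counts <- integer(0)
  for (d in dfs) for (p in percepts) {
    sel <- epochs$delta_f == d & epochs$labels == p
    if (!any(sel)) {
      stop(sprintf("empty cell: delta_f=%s, percept=%s", d, p), call. = FALSE)
    }
    key <- paste(d, p, sep = ".")
    cell_means[[key]] <- colMeans(epochs$data[sel, , drop = FALSE])
    counts[key] <- sum(sel)
  }
  percept_means <- lapply(percepts, function(p) {
    keys <- paste(dfs, p, sep = ".")
    Reduce(`+`, cell_means[keys]) / length(keys)
  })
  names(percept_means) <- percepts
  list(cell_means = cell_means, percept_means = percept_means,
       cell_counts = counts)
}

#' Cluster-based permutation test on paired time series
#'
#' Computes a paired t statistic at every time point, forms contiguous
#' clusters of samples whose |t| exceeds the two-sided critical value at
#' `alpha`, and scores each cluster by its mass (the sum of t within the
#' run; positive and negative clusters are tracked separately). The null
#' distribution of the maximum absolute cluster mass is built by randomly
#' sign-flipping each participant's difference wave (equivalent to
#' permuting the two condition labels within participant) `n_perm` times.
#' The observed statistic is included in the null, so the smallest
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param cond_a,cond_b Participant x time matrices (same dimensions).
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Cluster-forming alpha (two-sided, default 0.05).
#' @param all_flips If TRUE, enumerate all `2^n` sign-flip assignments
#'   instead of Monte-Carlo sampling (feasible for small n; ignores
#'   `n_perm`).
#' @return List of class `cluster_test` with `t_series`, `critical_t`,
#'   `clusters` (data.frame start, end, sign, mass, p), `max_cluster_mass`,
#'   `null_masses`, `p` (p of the largest cluster; 1 when no cluster).
#' @export
cluster_permutation_test <- function(cond_a, cond_b, n_perm = 1000,
                                     alpha = 0.05, all_flips = FALSE) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  n <- nrow(cond_a)
  if (n < 2L) stop("need at least two participants", call. = FALSE)
  if (!all_flips && n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  D <- cond_a - cond_b
  crit <- stats::qt(1 - alpha / 2, n - 1)

  t_of <- function(means, sds) {
    out <- means / (sds / sqrt(n))
    out[sds == 0] <- 0          # degenerate columns carry no evidence
    out
  }
  col_sd_given_means <- function(m) {
    # sign flips leave sum of squares unchanged; only the mean varies
    sqrt(pmax((q_colsums - n * m^2) / (n - 1), 0))
  }
  q_colsums <- colSums(D^2)

  obs_means <- colMeans(D)
  t_series <- t_of(obs_means, col_sd_given_means(obs_means))

  clusters <- find_clusters(t_series, crit)

  if (all_flips) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm, byrow = TRUE)
  }
  perm_means <- signs %*% D / n
  null_masses <- apply(perm_means, 1L, function(m) {
    ts <- t_of(m, col_sd_given_means(m))
    cl <- find_clusters(ts, crit)
    if (nrow(cl) == 0L) 0 else max(abs(cl$mass))
  })

  if (nrow(clusters) > 0L) {
    clusters$p <- vapply(clusters$mass, function(m) {
      # tolerance so exact ties (e.g. the identity permutation) are counted
      # identically regardless of waveform scaling
      thr <- abs(m) * (1 - 1e-9) - 1e-12
      (sum(null_masses >= thr) + 1) / (length(null_masses) + 1)
    }, numeric(1))
    max_mass <- clusters$mass[which.max(abs(clusters$mass))]
    p <- clusters$p[which.max(abs(clusters$mass))]
  } else {
    max_mass <- 0
    p <- 1
  }
  structure(list(t_series = t_series, critical_t = crit, clusters = clusters,
                 max_cluster_mass = max_mass, null_masses = null_masses,
                 p = p, n_perm = length(null_masses)),
            class = "cluster_test")
}

# maximal runs of suprathreshold |t|, per sign
find_clusters <- function(t_series, crit) {
  out <- data.frame(start = integer(0), end = integer(0),
                    sign = integer(0), mass = numeric(0))
  for (s in c(1, -1)) {
    above <- s * t_series > crit
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      out <- rbind(out, data.frame(
        start = starts[j], end = ends[j], sign = s,
        mass = sum(t_series[starts[j]:ends[j]])))
    }
  }
  out
}

#' Mean response over a latency window
#'
#' Selects samples whose latency t (ms post triplet onset, sample k at
#' `(k-1)/fs`) satisfies `window[1] <= t <= window[2]` inclusive; on the
#' 4 ms grid of 250 Hz the default 216-288 ms window holds 19 samples.
#'
#' @param waveform Numeric waveform (or matrix with waveforms in rows).
#' @param window Window in ms.
#' @param fs Sampling rate in Hz.
#' @return Scalar (or vector, for matrix input) window mean.
#' @export
window_mean <- function(waveform, window = c(216, 288), fs = 250) {
  nt <- if (is.matrix(waveform)) ncol(waveform) else length(waveform)
  lat <- (seq_len(nt) - 1) / fs * 1000
  if (window[1] < 0 || window[2] > max(lat)) {
    stop("window outside epoch", call. = FALSE)
  }
  sel <- lat >= window[1] & lat <= window[2]
  if (is.matrix(waveform)) rowMeans(waveform[, sel, drop = FALSE])
  else mean(waveform[sel])
}

#' Window-averaged percept effect with paired t and d
#'
#' Per participant, the mean over the latency window of the segregated
#' minus integrated evoked difference; tested against zero with a paired t
#' test and both d conventions.
#'
#' @param seg,int Participant x time matrices of percept means.
#' @param window,fs See [window_mean()].
#' @return List with `values` (per-participant differences), and the
#'   [paired_t_with_d()] result as `test` (d_av standardized by the two
#'   percept conditions' window-mean SDs).
#' @export
window_effect <- function(seg, int, window = c(216, 288), fs = 250) {
  ws <- window_mean(as.matrix(seg), window, fs)
  wi <- window_mean(as.matrix(int), window, fs)
  list(values = ws - wi, test = paired_t_with_d(ws, wi))
}

#' The four instruction-task contrasts
#'
#' Computes, per participant, the printed linear contrasts on a value
#' carried by each non-neutral instruction condition (window-averaged
#' evoked response, or percentage classified as segregated), with delta-f
#' conditions already equally weighted by the caller:
#' (1) mean(attend high, attend low) - attempt integration;
#' (2) attend high - attempt integration;
#' (3) attend low - attempt integration;
#' (4) attend high - attend low.
#' Each contrast is tested with a paired t test.
#'
#' @param values Data.frame with columns `participant`, `condition`
#'   (attempt_integration / attend_high / attend_low), `value`.
#' @return List of four elements (`c1`..`c4`), each with `values` (per
#'   participant) and `test`.
#' @export
task_contrasts <- function(values) {
  wide <- stats::reshape(values, idvar = "participant",
                         timevar = "condition", direction = "wide")
  need <- paste0("value.", c("attempt_integration", "attend_high", "attend_low"))
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    stop("all three non-neutral conditions are required per participant",
         call. = FALSE)
  }
  ai <- wide[[need[1]]]; ah <- wide[[need[2]]]; al <- wide[[need[3]]]
  out <- list(
    c1 = list(a = (ah + al) / 2, b = ai),
    c2 = list(a = ah, b = ai),
    c3 = list(a = al, b = ai),
    c4 = list(a = ah, b = al)
  )
  lapply(out, function(x) {
    list(values = x$a - x$b, test = paired_t_with_d(x$a, x$b))
  })
}

#' Report-weighted expected vs. observed non-neutral response
#'
#' Under the hypotheses that reports are accurate and the neutral percept
#' signature carries over, the expected window response in a non-neutral
#' condition is the report-weighted mixture of the participant's neutral
#' percept means: `p_seg * mean_seg + (1 - p_seg) * mean_int`, per delta-f.
#' The expected and observed main intention contrasts
#' (mean of the attempt-segregation conditions minus attempt-integration,
#' delta-f equally weighted) are compared with a paired t test; a
#' significant difference indicates reports out of line with the neural
#' signal (response bias).
#'
#' @param neutral_window_means Data.frame: `participant`, `delta_f`,
#'   `percept`, `value` (window mean of the neutral percept evoked mean).
#' @param report_pct Data.frame: `participant`, `delta_f`, `condition`,
#'   `p_seg` (proportion of time reporting segregation, 0-1).
#' @param observed Data.frame: `participant`, `delta_f`, `condition`,
#'   `value` (observed window mean over all epochs of that condition).
#' @return List with `expected`, `observed` (per-participant main
#'   contrasts, delta-f averaged), and `test` (paired t, expected -
#'   observed).
#' @export
expected_nonneutral_response <- function(neutral_window_means, report_pct,
                                         observed) {
  conds <- c("attempt_integration", "attend_high", "attend_low")
  sim <- merge(report_pct,
               stats::reshape(neutral_window_means, idvar = c("participant", "delta_f"),
                              timevar = "percept", direction = "wide"),
               by = c("participant", "delta_f"))
  sim$value <- sim$p_seg * sim$value.segregated +
    (1 - sim$p_seg) * sim$value.integrated

  main_contrast <- function(df) {
    # delta-f equally weighted: average value over delta_f per condition
    agg <- stats::aggregate(value ~ participant + condition, df, mean)
    wide <- stats::reshape(agg, idvar = "participant", timevar = "condition",
                           direction = "wide")
    (wide$value.attend_high + wide$value.attend_low) / 2 -
      wide$value.attempt_integration
  }
  sim <- sim[sim$condition %in% conds, ]
  obs <- observed[observed$condition %in% conds, ]
  expected <- main_contrast(sim)
  observed_c <- main_contrast(obs)
  list(expected = expected, observed = observed_c,
       test = paired_t_with_d(expected, observed_c))
}
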