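#' Extract 600 ms triplet-locked epochs
#'
#' One epoch per triplet, beginning at the triplet onset, spanning the
#' half-open window `[onset, onset + 0.6)` (150 samples at 250 Hz). Onsets
#' in seconds are mapped to sample indices by rounding to the nearest
#' sample. No baseline correction is applied: the repeating stimulus leaves
#' no silent baseline, and press-guarded exclusion means carry-over comes
#' only from triplets with the same reported percept, so epoch time can be
#' treated as circular.
#'
#' @param rec A preprocessed [recording()] (typically 250 Hz).
#' @param timeline The sequence's [build_stimulus_timeline()].
#' @return An `epoch_set`: list with `data` (n_triplets x n_samples matrix),
#'   `onsets` (s), `sample_rate`, `delta_f`, and placeholders for labels and
#'   the retention mask.
#' @export
extract_epochs <- function(rec, timeline) {
  stopifnot(inherits(rec, "recording"), inherits(timeline, "stimulus_timeline"))
  fs <- rec$sample_rate
  n_samp <- round(0.600 * fs)
  starts <- round(timeline$triplet_onsets * fs) + 1L
  bad <- starts + n_samp - 1L > length(rec$data)
  if (any(bad)) {
    stop("recording too short for triplet onsets at ",
         paste(signif(timeline$triplet_onsets[bad], 6), collapse = ", "),
         " s", call. = FALSE)
  }
  data <- matrix(0, nrow = timeline$n_triplets, ncol = n_samp)
  for (i in seq_along(starts)) {
    data[i, ] <- rec$data[starts[i]:(starts[i] + n_samp - 1L)]
  }
  structure(list(data = data, onsets = timeline$triplet_onsets,
                 sample_rate = fs, n_samples = n_samp,
                 delta_f = rep(timeline$delta_f, timeline$n_triplets),
                 condition = NULL, labels = NULL, retained = NULL),
            class = "epoch_set")
}

#' Press-guard retention mask
#'
#' An epoch is retained only if it keeps a guard distance from every button
#' press and from the sequence boundaries: epochs beginning less than
#' `guard` seconds after a press (or the sequence start) or ending less
#' than `guard` seconds before a press (or the sequence end) are excluded.
#' Equivalently, the epoch `[onset, onset + 0.6]` must not intersect the
#' open interval `(p - guard, p + guard)` around any press or boundary
#' `p`. With the 1.5 s default, the onset-to-onset distance between
#' retained epochs straddling a press is at least 3.6 s.
#'
#' @param epochs An `epoch_set`.
#' @param reports The sequence's `report_stream`.
#' @param guard Guard interval in seconds (default 1.5).
#' @return Logical retention mask (also stored in the returned epoch set if
#'   assigned by the caller).
#' @export
apply_exclusion <- function(epochs, reports, guard = 1.5) {
  onsets <- epochs$onsets
  len <- epochs$n_samples / epochs$sample_rate
  ends <- onsets + len
  events <- c(0, reports$presses$time, reports$sequence_duration)
  keep <- rep(TRUE, length(onsets))
  for (p in events) {
    keep <- keep & !(onsets < p + guard & ends > p - guard)
  }
  keep
}

#' Label epochs by the governing percept report
#'
#' Each epoch takes the percept of the most recent press at or before its
#' onset. Epochs before the first report are labeled integrated (perception
#' starts integrated and the first phase is simply not yet reported). With
#' `exclude_before_first_segregated = TRUE`, epochs before the first
#' segregated report return `NA` instead, reproducing the stricter
#' sensitivity analysis.
#'
#' @param epochs An `epoch_set`.
#' @param reports The sequence's `report_stream`.
#' @param exclude_before_first_segregated Logical flag (default FALSE).
#' @return Character vector of labels (`"integrated"`/`"segregated"`, or
#'   `NA` under the sensitivity flag).
#' @export
label_epochs <- function(epochs, reports,
                         exclude_before_first_segregated = FALSE) {
  pr <- reports$presses
  onsets <- epochs$onsets
  if (nrow(pr) == 0L) {
    labels <- rep("integrated", length(onsets))
  } else {
    idx <- findInterval(onsets, pr$time)
    labels <- ifelse(idx >= 1L, pr$percept[pmax(idx, 1L)], "integrated")
  }
  if (exclude_before_first_segregated && nrow(pr) > 0L) {
    seg_presses <- pr$time[pr$percept == "segregated"]
    if (length(seg_presses) > 0L) {
      labels[onsets < min(seg_presses)] <- NA_character_
    } else {
      labels[] <- NA_character_
    }
  }
  labels
}

#' Minimum-cell-count inclusion gate
#'
#' A participant enters the neural analyses only if every neutral
#' delta-f x percept cell holds at least `threshold` retained epochs
#' (default 55).
#'
#' @param labels Percept labels of retained neutral epochs.
#' @param delta_f Delta-f values of the same epochs.
#' @param threshold Minimum epochs per cell.
#' @return List with `included` (logical) and `cell_counts` (table).
#' @export
min_cell_count_gate <- function(labels, delta_f, threshold = 55) {
  labels <- factor(labels, levels = c("integrated", "segregated"))
  delta_f <- factor(delta_f)
  counts <- table(delta_f, labels)
  list(included = all(counts >= threshold), cell_counts = counts)
}

#' Epoch one simulated sequence end to end
#'
#' Convenience wrapper: preprocess the raw recording, extract triplet
#' epochs, apply the press guard and percept labels, and drop excluded
#' epochs.
#'
#' @param rec Raw [recording()] at the synthesis rate.
#' @param timeline Sequence [build_stimulus_timeline()].
#' @param reports Sequence `report_stream`.
#' @param guard Press guard in seconds.
#' @param preprocess Logical; set `FALSE` if `rec` is already filtered and
#'   at the target rate.
#' @param ... Passed to [preprocess_recording()].
#' @return An `epoch_set` containing only retained epochs, with `labels`,
#'   `condition` and `retained` filled in (`retained` is the pre-drop mask).
#' @export
epoch_sequence <- function(rec, timeline, reports, guard = 1.5,
                           preprocess = TRUE, ...) {
  if (preprocess) rec <- preprocess_recording(rec, ...)
  ep <- extract_epochs(rec, timeline)
  keep <- apply_exclusion(ep, reports, guard)
  labels <- label_epochs(ep, reports)
  ep$data <- ep$data[keep, , drop = FALSE]
  ep$onsets <- ep$onsets[keep]
  ep$delta_f <- ep$delta_f[keep]
  ep$labels <- labels[keep]
  ep$condition <- rep(reports$condition, sum(keep))
  ep$retained <- keep
  ep
}

#' Concatenate epoch sets across sequences
#'
#' @param ... `epoch_set` objects (or a single list of them).
#' @return A combined `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set")) sets <- sets[[1]]
  structure(list(
    data = do.call(rbind, lapply(sets, `[[`, "data")),
    onsets = unlist(lapply(sets, `[[`, "onsets")),
    sample_rate = sets[[1]]$sample_rate,
    n_samples = sets[[1]]$n_samples,
    delta_f = unlist(lapply(sets, `[[`, "delta_f")),
    condition = unlist(lapply(sets, `[[`, "condition")),
    labels = unlist(lapply(sets, `[[`, "labels")),
    retained = unlist(lapply(sets, `[[`, "retained"))
  ), class = "epoch_set")
}
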