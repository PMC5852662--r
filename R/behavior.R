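#' Segment a report stream into perceptual phases
#'
#' Phase k spans press k to press k+1; the final phase extends to the end of
#' the sequence and is flagged incomplete. The first reported phase is
#' classed `initial_integrated` if (and only if) its percept is integrated;
#' later integrated phases are `subsequent_integrated`.
#'
#' @param reports A `report_stream`.
#' @return A `phase_table` data.frame (class, onset, duration, completed)
#'   with condition/delta-f metadata in attributes.
#' @export
segment_phases <- function(reports) {
  pr <- reports$presses
  if (nrow(pr) == 0L) stop("report stream has no presses", call. = FALSE)
  if (nrow(pr) >= 2L && any(pr$percept[-1L] == pr$percept[-nrow(pr)])) {
    stop("malformed report stream: consecutive presses report the same percept",
         call. = FALSE)
  }
  n <- nrow(pr)
  ends <- c(pr$time[-1L], reports$sequence_duration)
  cls <- ifelse(pr$percept == "segregated", "segregated", "subsequent_integrated")
  if (pr$percept[1L] == "integrated") cls[1L] <- "initial_integrated"
  out <- data.frame(class = cls, onset = pr$time, duration = ends - pr$time,
                    completed = c(rep(TRUE, n - 1L), FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "condition") <- reports$condition
  attr(out, "delta_f") <- reports$delta_f
  attr(out, "duration") <- reports$sequence_duration
  class(out) <- c("phase_table", "data.frame")
  out
}

#' Does a sequence qualify for behavioral analysis?
#'
#' A sequence qualifies when (1) the first reported phase was integrated and
#' (2) at least two completed subsequent phases were reported.
#'
#' @param table A `phase_table` from [segment_phases()].
#' @return Logical scalar.
#' @export
sequence_meets_criteria <- function(table) {
  if (nrow(table) == 0L) return(FALSE)
  first_integrated <- table$class[1L] == "initial_integrated"
  completed_subsequent <- sum(table$completed[-1L])
  first_integrated && completed_subsequent >= 2L
}

#' Percentage of time reporting segregation
#'
#' Time reported segregated divided by the time from the first press to the
#' end of the sequence (the interval before the first report carries no
#' percept and is excluded from the denominator).
#'
#' @param reports A `report_stream`.
#' @return Percentage in `[0, 100]`, or `NA` if there are no presses.
#' @export
percent_segregation <- function(reports) {
  if (nrow(reports$presses) == 0L) return(NA_real_)
  ph <- segment_phases(reports)
  denom <- reports$sequence_duration - ph$onset[1L]
  100 * sum(ph$duration[ph$class == "segregated"]) / denom
}

#' Condition means on a transformed scale
#'
#' Percentages of segregation are averaged on the logit scale and phase
#' durations on the log scale, then back-transformed for reporting (so the
#' duration summary is a geometric mean). In strict mode, exact 0 or 100
#' percent values cannot be logit-transformed and are dropped with a
#' warning; lenient mode instead applies an empirical-logit correction of
#' `1/(2 n)` (with `n = n_phases`) toward the interior.
#'
#' @param values Numeric vector (percentages in `[0, 100]` for `"logit"`,
#'   positive durations for `"log"`).
#' @param transform `"logit"` or `"log"`.
#' @param strict For `"logit"`: drop boundary values (default) rather than
#'   correcting them.
#' @param n_phases Phase count used by the empirical-logit correction.
#' @return The back-transformed mean (percent or seconds).
#' @export
transformed_condition_means <- function(values, transform = c("logit", "log"),
                                        strict = TRUE, n_phases = NULL) {
  transform <- match.arg(transform)
  values <- values[!is.na(values)]
  if (transform == "log") {
    if (any(values <= 0)) stop("durations must be positive", call. = FALSE)
    return(exp(mean(log(values))))
  }
  p <- values / 100
  boundary <- p <= 0 | p >= 1
  if (any(boundary)) {
    if (strict) {
      warning("dropping ", sum(boundary), " boundary (0/100%) value(s)")
      p <- p[!boundary]
    } else {
      if (is.null(n_phases)) stop("`n_phases` needed for lenient mode",
                                  call. = FALSE)
      eps <- 1 / (2 * n_phases)
      p <- pmin(pmax(p, eps), 1 - eps)
    }
  }
  if (length(p) == 0L) return(NA_real_)
  100 * stats::plogis(mean(stats::qlogis(p)))
}

#' Repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Fits a fully within-participant ANOVA on a complete participant x factor
#' table and adjusts degrees of freedom for asphericity with the
#' Huynh-Feldt epsilon (epsilon is 1 for two-level factors, where sphericity
#' is vacuous). Reported degrees of freedom are the uncorrected ones, as is
#' conventional; the p-value uses the corrected ones. Partial eta squared is
#' SS_effect / (SS_effect + SS_error), with a participant-bootstrap CI.
#'
#' @param data Long-format data.frame.
#' @param dv,id Column names of the dependent variable and participant id.
#' @param within Character vector of within-participant factor column names
#'   (one or two factors).
#' @param effect Which effect to report (default the first factor; use
#'   e.g. `"A:B"` for the interaction).
#' @param ci_boot Number of bootstrap resamples for the eta-squared CI
#'   (0 disables).
#' @param conf_level Confidence level.
#' @return A list of class `rm_anova` with `F`, `df_num`, `df_den`,
#'   `epsilon_hf`, `p`, `eta_sq_p`, `eta_sq_p_ci`.
#' @export
rm_anova_hf <- function(data, dv, id, within, effect = within[1],
                        ci_boot = 2000, conf_level = 0.95) {
  tab <- stats::xtabs(stats::reformulate(c(id, within), response = dv),
                      data = data)
  if (any(stats::xtabs(stats::reformulate(c(id, within)), data = data) != 1)) {
    stop("design must be complete with one observation per cell", call. = FALSE)
  }
  dn <- dimnames(tab)
  idata <- expand.grid(lapply(dn[-1], factor))
  names(idata) <- within
  wide_full <- matrix(tab, nrow = dim(tab)[1])
  fit_once <- function(wide) {
    mlm <- stats::lm(wide ~ 1)
    av <- car::Anova(mlm, idata = idata,
                     idesign = stats::reformulate(within), type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    uni <- s$univariate.tests
    key <- effect
    row <- uni[key, , drop = TRUE]
    ss_n <- row[["Sum Sq"]]; ss_d <- row[["Error SS"]]
    df_n <- row[["num Df"]]; df_d <- row[["den Df"]]
    Fval <- row[["F value"]]
    eps <- 1
    if (df_n > 1 && !is.null(s$pval.adjustments) &&
        key %in% rownames(s$pval.adjustments)) {
      eps <- min(s$pval.adjustments[key, "HF eps"], 1)
    }
    p <- stats::pf(Fval, df_n * eps, df_d * eps, lower.tail = FALSE)
    list(F = Fval, df_num = df_n, df_den = df_d, epsilon_hf = eps, p = p,
         eta_sq_p = ss_n / (ss_n + ss_d))
  }
  res <- fit_once(wide_full)
  ci <- c(NA_real_, NA_real_)
  if (ci_boot > 0) {
    n <- dim(tab)[1]
    boots <- vapply(seq_len(ci_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(fit_once(wide_full[idx, , drop = FALSE])$eta_sq_p,
               error = function(e) NA_real_)
    }, numeric(1))
    alpha <- 1 - conf_level
    ci <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE))
  }
  structure(c(res, list(eta_sq_p_ci = ci, effect = effect)),
            class = "rm_anova")
}

#' Paired t test with Cohen's d and noncentral-t confidence interval
#'
#' Computes the paired t statistic, two-sided p, the difference-standardized
#' effect size `d_z = mean(diff)/sd(diff)` with a CI obtained by inverting
#' the noncentral-t distribution, and (when both condition vectors are
#' given) the average-variance-standardized `d_av = mean(diff) /
#' ((sd(x)+sd(y))/2)`, the convention under which small but consistent
#' within-participant effects receive small d values.
#'
#' @param x First condition (or the differences themselves if `y` is NULL).
#' @param y Second condition; differences are `x - y`.
#' @param conf_level Confidence level for the d CI.
#' @return A list of class `paired_t` with `t`, `df`, `p`, `mean_diff`,
#'   `d` (d_z), `d_ci`, `d_av`.
#' @export
paired_t_with_d <- function(x, y = NULL, conf_level = 0.95) {
  d_av <- NA_real_
  if (!is.null(y)) {
    stopifnot(length(x) == length(y))
    diffs <- x - y
    d_av <- mean(diffs) / ((stats::sd(x) + stats::sd(y)) / 2)
  } else {
    diffs <- x
  }
  n <- length(diffs)
  if (n < 2L) stop("need at least two pairs", call. = FALSE)
  sdd <- stats::sd(diffs)
  if (sdd == 0) {
    t_obs <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    warning("zero variance of differences")
    return(structure(list(t = t_obs, df = n - 1, p = if (t_obs == 0) 1 else 0,
                          mean_diff = mean(diffs),
                          d = if (t_obs == 0) 0 else sign(t_obs) * Inf,
                          d_ci = c(NA_real_, NA_real_), d_av = d_av),
                     class = "paired_t"))
  }
  t_obs <- mean(diffs) / (sdd / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t_obs), df)
  dz <- t_obs / sqrt(n)
  alpha <- 1 - conf_level
  ncp_ci <- noncentral_t_ci(t_obs, df, alpha)
  structure(list(t = t_obs, df = df, p = p, mean_diff = mean(diffs),
                 d = dz, d_ci = ncp_ci / sqrt(n), d_av = d_av),
            class = "paired_t")
}

# CI for the noncentrality parameter of a t statistic by pivot inversion
noncentral_t_ci <- function(t_obs, df, alpha = 0.05) {
  bound <- abs(t_obs) + 10 + 4 * abs(t_obs)
  suppressWarnings({
    lo <- tryCatch(stats::uniroot(function(ncp) {
      stats::pt(t_obs, df, ncp) - (1 - alpha / 2)
    }, c(-bound, bound), tol = 1e-8)$root, error = function(e) -bound)
    hi <- tryCatch(stats::uniroot(function(ncp) {
      stats::pt(t_obs, df, ncp) - alpha / 2
    }, c(-bound, bound), tol = 1e-8)$root, error = function(e) bound)
  })
  c(lo, hi)
}

#' Within-participant confidence intervals (Cousineau-Morey)
#'
#' Centers each participant's data on their own mean (plus the grand mean),
#' applies the Morey bias correction `sqrt(J/(J-1))` for J conditions, and
#' returns a standard t-based CI per condition. These intervals reflect the
#' within-participant variability relevant to repeated-measures contrasts
#' and are invariant to constant participant offsets.
#'
#' @param values Numeric matrix, participants x conditions (complete).
#' @param level Confidence level.
#' @return A data.frame with one row per condition: `mean`, `ci_lo`, `ci_hi`,
#'   `half_width`.
#' @export
within_participant_ci <- function(values, level = 0.95) {
  values <- as.matrix(values)
  n <- nrow(values); j <- ncol(values)
  centered <- values - rowMeans(values) + mean(values)
  correction <- sqrt(j / (j - 1))
  se <- apply(centered, 2, stats::sd) / sqrt(n) * correction
  m <- colMeans(values)
  tcrit <- stats::qt(1 - (1 - level) / 2, n - 1)
  data.frame(condition = colnames(values) %||% paste0("c", seq_len(j)),
             mean = m, ci_lo = m - tcrit * se, ci_hi = m + tcrit * se,
             half_width = tcrit * se, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
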