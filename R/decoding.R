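#' Train a balanced, repeatedly cross-validated linear-SVM percept decoder
#'
#' For one participant and one delta-f: per repeat, the larger percept
#' class is randomly subsampled without replacement to the size of the
#' smaller class (so the classifier is unbiased), epochs are split into
#' `folds` class-stratified folds, and one linear SVM (cost `C`) is trained
#' per fold on features standardized with training-fold statistics. With
#' the defaults this gives 5 x 100 = 500 fold-evaluations; cross-validated
#' accuracy is the mean percentage correct over all of them. Each model's
#' weight vector is oriented so that a positive decision value means
#' "segregated".
#'
#' @param x Epoch x feature matrix (150 time-point features at 250 Hz).
#' @param labels Character vector, `"integrated"`/`"segregated"`.
#' @param folds Number of cross-validation folds.
#' @param repeats Number of subsample/cross-validation repeats.
#' @param cost SVM cost parameter C.
#' @return A `decoder_ensemble`: list with `W` (models x features weight
#'   matrix in standardized space), `b` (decision offsets), `MU`, `SD`
#'   (models x features standardization), `train_idx` (list of training row
#'   indices per model), `fold_acc` (percent correct per fold-evaluation),
#'   `cv_accuracy` (%), `n_models`.
#' @export
train_decoders <- function(x, labels, folds = 5, repeats = 100, cost = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels))
  classes <- c("integrated", "segregated")
  idx_by_class <- lapply(classes, function(cl) which(labels == cl))
  names(idx_by_class) <- classes
  n_min <- min(lengths(idx_by_class))
  if (n_min < folds) {
    stop("each class needs at least `folds` epochs", call. = FALSE)
  }
  n_models <- folds * repeats
  p <- ncol(x)
  W <- matrix(0, n_models, p); MU <- matrix(0, n_models, p)
  SD <- matrix(1, n_models, p); b <- numeric(n_models)
  train_idx <- vector("list", n_models)
  fold_acc <- numeric(n_models)
  m <- 0L
  for (r in seq_len(repeats)) {
    sub <- lapply(idx_by_class, function(ix) sample(ix, n_min))
    # class-stratified folds over the balanced subsample
    fold_of <- lapply(sub, function(ix) {
      sample(rep_len(seq_len(folds), length(ix)))
    })
    for (f in seq_len(folds)) {
      m <- m + 1L
      tr <- c(sub$integrated[fold_of$integrated != f],
              sub$segregated[fold_of$segregated != f])
      te <- c(sub$integrated[fold_of$integrated == f],
              sub$segregated[fold_of$segregated == f])
      mu <- colMeans(x[tr, , drop = FALSE])
      sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
      sd_[sd_ == 0] <- 1
      xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sd_, "/")
      ytr <- factor(labels[tr], levels = classes)
      fit <- e1071::svm(xtr, ytr, kernel = "linear", cost = cost,
                        scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      rho <- fit$rho
      # e1071 decision values are positive for the first factor level
      # present in the training data; orient so positive = segregated
      if (fit$levels[1] == "integrated") { w <- -w; rho <- -rho }
      xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sd_, "/")
      dv <- drop(xte %*% w) - rho
      pred <- ifelse(dv > 0, "segregated", "integrated")
      fold_acc[m] <- 100 * mean(pred == labels[te])
      W[m, ] <- w; b[m] <- rho; MU[m, ] <- mu; SD[m, ] <- sd_
      train_idx[[m]] <- tr
    }
  }
  structure(list(W = W, b = b, MU = MU, SD = SD, train_idx = train_idx,
                 fold_acc = fold_acc, cv_accuracy = mean(fold_acc),
                 n_models = n_models, folds = folds, repeats = repeats,
                 cost = cost),
            class = "decoder_ensemble")
}

#' Haufe activation-pattern correction of decoder weights
#'
#' Transforms each model's weight vector into an activation pattern,
#' `pattern = Cov(X_train) %*% w`, which zeroes features that carry strong
#' weights only to cancel noise, and averages the patterns over the
#' ensemble. Covariances are computed on the standardized training folds
#' with Ledoit-Wolf shrinkage toward the scaled identity, guaranteeing
#' well-conditioned estimates on small subsamples. The sign convention is
#' inherited from the decoder: a positive pattern value means a more
#' positive response favors a segregated classification.
#'
#' @param ensemble A `decoder_ensemble`.
#' @param x The epoch x feature matrix the ensemble was trained on.
#' @return Numeric vector of corrected feature weights (length =
#'   n features).
#' @export
haufe_correct <- function(ensemble, x) {
  x <- as.matrix(x)
  p <- ncol(x)
  acc <- numeric(p)
  for (m in seq_len(ensemble$n_models)) {
    tr <- ensemble$train_idx[[m]]
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, ensemble$MU[m, ]),
                 2, ensemble$SD[m, ], "/")
    S <- ledoit_wolf_cov(xtr)
    acc <- acc + drop(S %*% ensemble$W[m, ])
  }
  acc / ensemble$n_models
}

#' Ledoit-Wolf shrinkage covariance
#'
#' Shrinks the sample covariance toward `mean(diag(S)) * I` with the
#' analytic optimal intensity, yielding an invertible, well-conditioned
#' estimate even when features outnumber observations.
#'
#' @param x Observation x feature matrix.
#' @return Shrunk covariance matrix.
#' @export
ledoit_wolf_cov <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n
  mu <- mean(diag(S))
  d2 <- sum((S - diag(mu, p))^2) / p
  # mean squared deviation of single-observation outer products around S
  b_bar <- (sum(rowSums(xc^2)^2) - n * sum(S^2)) / (n^2) / p
  b2 <- min(max(b_bar, 0), d2)
  rho <- if (d2 > 0) b2 / d2 else 0
  rho * diag(mu, p) + (1 - rho) * S
}

#' Classify epochs with a trained ensemble
#'
#' Standardizes the epochs with each model's stored training-fold
#' parameters and averages, over all models, the percentage of epochs each
#' classifies as segregated (mean-vote aggregation).
#'
#' @param ensemble A `decoder_ensemble`.
#' @param x Epoch x feature matrix (same feature count as training).
#' @return Percentage classified as segregated (scalar in `[0, 100]`).
#' @export
classify_epochs <- function(ensemble, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(ensemble$W)) {
    stop("feature-count mismatch with the trained ensemble", call. = FALSE)
  }
  V <- ensemble$W / ensemble$SD                   # models x features
  D <- x %*% t(V)                                 # epochs x models
  offset <- rowSums(ensemble$MU * V) + ensemble$b # per model
  seg_frac <- colMeans(sweep(D, 2, offset) > 0)
  100 * mean(seg_frac)
}

#' Accuracy-adjusted expected vs. observed classification difference
#'
#' A classifier that is correct on a proportion `acc/100` of neutral epochs
#' dilutes any true report difference by the factor `(acc - 50)/50`. Per
#' participant and delta-f, the reported percentages of segregation are
#' multiplied by this factor; the expected main intention contrast (mean of
#' the two attempt-segregation conditions minus attempt-integration,
#' averaged over delta-f) is then compared with the observed contrast on
#' classified percentages using a paired t test. A non-significant
#' difference means the classified differences are as large as accurate
#' reporting predicts (no residual response bias).
#'
#' @param report_pct Data.frame: `participant`, `delta_f`, `condition`,
#'   `pct_seg` (reported % segregation, 0-100).
#' @param accuracy Data.frame: `participant`, `delta_f`, `cv_accuracy` (%);
#'   a participant's accuracy is averaged over delta-f before use, the
#'   granularity at which classifier performance is assessed.
#' @param classified Data.frame: `participant`, `delta_f`, `condition`,
#'   `pct_seg` (% classified as segregated).
#' @return List with `expected`, `observed` (per participant), `test`
#'   (paired t, expected - observed).
#' @export
adjusted_expected_difference <- function(report_pct, accuracy, classified) {
  acc_p <- stats::aggregate(cv_accuracy ~ participant, accuracy, mean)
  rp <- merge(report_pct, acc_p, by = "participant")
  rp$adj <- rp$pct_seg * (rp$cv_accuracy - 50) / 50
  contrast_by_participant <- function(df, col) {
    agg <- stats::aggregate(stats::reformulate("participant + condition", col),
                            df, mean)  # delta-f equally weighted
    wide <- stats::reshape(agg, idvar = "participant", timevar = "condition",
                           direction = "wide")
    v <- function(cond) wide[[paste(col, cond, sep = ".")]]
    data.frame(participant = wide$participant,
               value = (v("attend_high") + v("attend_low")) / 2 -
                 v("attempt_integration"))
  }
  exp_c <- contrast_by_participant(rp, "adj")
  obs_c <- contrast_by_participant(classified, "pct_seg")
  stopifnot(identical(order(exp_c$participant), order(obs_c$participant)))
  m <- merge(exp_c, obs_c, by = "participant", suffixes = c(".exp", ".obs"))
  list(expected = m$value.exp, observed = m$value.obs,
       test = paired_t_with_d(m$value.exp, m$value.obs))
}
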