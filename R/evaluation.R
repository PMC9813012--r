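#' Causal Gaussian smoothing and per-unit min-max normalization
#'
#' Convolves each output unit's trace with a causal Gaussian kernel
#' (truncated at 3 standard deviations) and rescales each unit to \[0, 1\]
#' over the whole series. A constant series maps to all zeros.
#'
#' @param o `time x O` matrix (or vector) of association-layer output.
#' @param sd_ms kernel standard deviation in ms.
#' @param dt step in ms.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
smooth_and_normalize <- function(o, sd_ms = 20, dt = 1) {
  o <- as.matrix(o)
  if (nrow(o) == 0) stop("empty series")
  if (any(!is.finite(o))) stop("non-finite values in output series")
  sd_steps <- sd_ms / dt
  lags <- 0:ceiling(3 * sd_steps)
  kern <- exp(-0.5 * (lags / sd_steps)^2)
  kern <- kern / sum(kern)
  apply(o, 2, function(x) {
    xp <- c(rep(x[1], length(kern) - 1), x)  # replicate-boundary, causal
    y <- stats::filter(xp, kern, method = "convolution", sides = 1)
    y <- as.numeric(y)[length(kern) - 1 + seq_along(x)]
    rng <- range(y)
    if (diff(rng) <= 0) rep(0, length(y)) else (y - rng[1]) / diff(rng)
  })
}

#' Determine the winning output unit per presentation epoch
#'
#' For each annotated epoch, the unit with the largest epoch statistic
#' (mean of the smoothed, normalized trace by default; peak optionally) is
#' the winner, provided it reaches `threshold`; otherwise the epoch is
#' scored `"no_response"`. Ties go to the lowest unit index.
#'
#' @param smoothed `time x O` matrix from [smooth_and_normalize()].
#' @param annotations annotation data frame with `onset_ms` / `offset_ms`.
#' @param threshold no-response threshold on the normalized scale.
#' @param dt step in ms of `smoothed` rows.
#' @param statistic `"mean"` or `"peak"`.
#' @return Character vector: winning unit (`"1"`, `"2"`, ...) or
#'   `"no_response"` per epoch.
#' @export
score_epochs <- function(smoothed, annotations, threshold = 0.3, dt = 1,
                         statistic = c("mean", "peak")) {
  statistic <- match.arg(statistic)
  smoothed <- as.matrix(smoothed)
  vapply(seq_len(nrow(annotations)), function(e) {
    rows <- seq(annotations$onset_ms[e] / dt + 1,
                min(annotations$offset_ms[e] / dt, nrow(smoothed)))
    seg <- smoothed[rows, , drop = FALSE]
    score <- if (statistic == "mean") colMeans(seg) else
      apply(seg, 2, max)
    if (max(score) < threshold) "no_response" else
      as.character(which.max(score))
  }, character(1))
}

#' Confusion matrix of chunk labels against responding units
#'
#' Rows are chunk labels plus `"random"`; columns are output units plus
#' `"no_response"`. Entry (i, j) counts epochs with label i won by unit j.
#'
#' @param winners per-epoch winners from [score_epochs()].
#' @param labels per-epoch ground-truth labels.
#' @param chunk_names the chunk labels, in row order.
#' @param n_units number of output units.
#' @return Integer matrix of class `rc_confusion` with `C = length(labels)`.
#' @export
confusion_matrix <- function(winners, labels,
                             chunk_names = setdiff(unique(labels), "random"),
                             n_units = 3) {
  stopifnot(length(winners) == length(labels))
  rows <- c(chunk_names, "random")
  cols <- c(as.character(seq_len(n_units)), "no_response")
  cm <- matrix(0L, length(rows), length(cols),
               dimnames = list(label = rows, unit = cols))
  for (e in seq_along(labels)) cm[labels[e], winners[e]] <-
      cm[labels[e], winners[e]] + 1L
  structure(cm, class = c("rc_confusion", class(cm)))
}

perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

#' Accuracy of a confusion matrix under optimal unit-to-chunk assignment
#'
#' Learning is unsupervised, so no chunk selectivity is imposed on any unit
#' in advance. The unit-to-chunk assignment is chosen to maximize the
#' diagonal sum (exhaustive search over permutations; the random row is
#' always matched to the no-response column), and the accuracy is that
#' maximal diagonal sum divided by the total epoch count `C`.
#'
#' @param cm confusion matrix from [confusion_matrix()] (last row
#'   `"random"`, last column `"no_response"`).
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cm) {
  C <- sum(cm)
  if (C == 0) stop("empty confusion matrix (C = 0)")
  nr <- nrow(cm) - 1L  # chunk rows
  nc <- ncol(cm) - 1L  # unit columns
  k <- min(nr, nc)
  best <- 0
  for (p in perms(seq_len(nc))) {
    sel <- p[seq_len(k)]
    diag_sum <- sum(cm[cbind(seq_len(k), sel)])
    if (diag_sum > best) best <- diag_sum
  }
  (best + cm[nrow(cm), ncol(cm)]) / C
}

#' Evaluate a forward run against its track annotations
#'
#' Smooths and normalizes the association-level output, scores every epoch,
#' and computes the optimally assigned accuracy. Module-level accuracies
#' (scoring each module's own readouts the same way) are included.
#'
#' @param run an `rc_run` from [run_inference()].
#' @param threshold no-response threshold.
#' @param sd_ms smoothing kernel standard deviation in ms.
#' @param statistic epoch statistic, `"mean"` or `"peak"`.
#' @return An object of class `rc_eval`: list with `accuracy`, `confusion`,
#'   `accuracy_rc1`, `accuracy_rc2` and the per-epoch winners.
#' @export
evaluate_run <- function(run, threshold = 0.3, sd_ms = 20,
                         statistic = "mean") {
  ann <- run$annotations
  labels <- ann$label
  chunk_names <- setdiff(unique(labels), "random")
  one <- function(series) {
    sm <- smooth_and_normalize(series, sd_ms = sd_ms, dt = run$dt)
    w <- score_epochs(sm, ann, threshold = threshold, dt = run$dt,
                      statistic = statistic)
    cm <- confusion_matrix(w, labels, chunk_names, ncol(series))
    list(winners = w, confusion = cm, accuracy = accuracy(cm))
  }
  assoc <- one(run$o)
  rc1 <- one(run$z1)
  rc2 <- one(run$z2)
  structure(list(accuracy = assoc$accuracy, confusion = assoc$confusion,
                 winners = assoc$winners,
                 accuracy_rc1 = rc1$accuracy, accuracy_rc2 = rc2$accuracy,
                 threshold = threshold),
            class = "rc_eval")
}

#' @export
print.rc_eval <- function(x, ...) {
  cat("<rc_eval> accuracy =", round(x$accuracy, 3),
      "(RC1", round(x$accuracy_rc1, 3),
      "/ RC2", round(x$accuracy_rc2, 3), ")\n")
  print(unclass(x$confusion))
  invisible(x)
}

#' Mean activation phase of each neuron over an epoch
#'
#' Maps each neuron's min-max-normalized rate profile over an epoch of
#' length `T` onto the unit circle (`t -> exp(i 2 pi t / T)`) and returns
#' the circular-mean time in steps, in \[0, T). Used to sort the
#' readout-projecting neurons by when in the chunk they fire. Neurons with
#' zero total normalized activity have an undefined phase and return `NA`.
#'
#' @param r_epoch `T x n` matrix of rates over one epoch.
#' @return Numeric vector of length `n` of phase times in steps (`NA` where
#'   undefined).
#' @export
activation_phase <- function(r_epoch) {
  r_epoch <- as.matrix(r_epoch)
  T <- nrow(r_epoch)
  stopifnot(T >= 1)
  ts <- seq_len(T)
  apply(r_epoch, 2, function(r) {
    rng <- range(r)
    rn <- if (diff(rng) > 0) (r - rng[1]) / diff(rng) else rep(0, T)
    tot <- sum(rn)
    if (tot <= 0) return(NA_real_)
    ang <- Arg(sum(rn * exp(1i * 2 * pi * ts / T)))
    (ang %% (2 * pi)) * T / (2 * pi)
  })
}

#' Project reservoir activity onto its leading principal components
#'
#' Fits PCA (by eigendecomposition of the covariance) on the pooled
#' reservoir rate history of an evaluation run, projects every chunk epoch
#' onto the top `n_pc` components, and aligns the trials of each chunk at
#' the midpoint of the presentation (relative time 0), keeping
#' `half_window` recorded samples on either side.
#'
#' @param r_history `time x N` rate history.
#' @param annotations annotation data frame.
#' @param dt ms per recorded row of `r_history`.
#' @param n_pc number of components to keep.
#' @param half_window samples kept on either side of the midpoint.
#' @return List of class `rc_pca`: `trials` (per chunk, a
#'   `(2*half_window+1) x n_pc x n_trials` array), `eigenvalues`
#'   (normalized to sum 1), `rotation`, `n_pc`.
#' @export
pca_trajectories <- function(r_history, annotations, dt = 1, n_pc = 3,
                             half_window = 100) {
  r_history <- as.matrix(r_history)
  stopifnot(nrow(r_history) >= 2)
  mu <- colMeans(r_history)
  cen <- sweep(r_history, 2, mu)
  ev <- eigen(crossprod(cen) / (nrow(cen) - 1), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  pos <- sum(lambda > 1e-12)
  n_pc_eff <- min(n_pc, pos)
  rot <- ev$vectors[, seq_len(n_pc_eff), drop = FALSE]
  proj <- cen %*% rot
  chunk_names <- setdiff(unique(annotations$label), "random")
  trials <- list()
  for (nm in chunk_names) {
    eps <- which(annotations$label == nm)
    mats <- list()
    for (e in eps) {
      rows <- seq(annotations$onset_ms[e] / dt + 1,
                  annotations$offset_ms[e] / dt)
      rows <- rows[rows <= nrow(proj)]
      mid <- rows[1] + (length(rows) - 1) / 2
      idx <- round(mid) + seq(-half_window, half_window)
      if (idx[1] < rows[1] || idx[length(idx)] > rows[length(rows)]) {
        idx <- pmax(pmin(idx, nrow(proj)), 1)  # clamp at track edges
      }
      mats[[length(mats) + 1]] <- proj[idx, , drop = FALSE]
    }
    if (length(mats) > 0)
      trials[[nm]] <- array(unlist(mats),
                            dim = c(2 * half_window + 1, n_pc_eff,
                                    length(mats)))
  }
  structure(list(trials = trials, eigenvalues = lambda / sum(lambda),
                 rotation = rot, n_pc = n_pc_eff),
            class = "rc_pca")
}

#' Separation between per-chunk population trajectories
#'
#' For each chunk X, the trial-averaged center trajectory and the deviation
#' `sigma_X(t) = sqrt(sum of per-component variances)` are computed over the
#' aligned window; for each pair (X, Y) the center distance `d_XY(t)` and
#' the separation degree `r_XY = sum_t (sigma_X(t) + sigma_Y(t)) / d_XY(t)`
#' over the window around the midpoint. Smaller `r_XY` means better
#' separated trajectories. Pairs whose centers coincide at any summed step
#' give an infinite `r_XY` and are flagged.
#'
#' @param pca an `rc_pca` from [pca_trajectories()] (or a compatible
#'   `trials` list).
#' @return A list of class `rc_separation`: data frame `pairs` (X, Y,
#'   `r_XY`, `degenerate`), matrix `d` of time-resolved center distances
#'   (one column per pair), per-chunk `sigma` and `centers`, `n_trials`.
#' @export
trajectory_separation <- function(pca) {
  trials <- if (inherits(pca, "rc_pca")) pca$trials else pca
  stopifnot(length(trials) >= 1)
  centers <- lapply(trials, function(a) apply(a, c(1, 2), mean))
  sigmas <- lapply(trials, function(a) {
    v <- apply(a, c(1, 2), function(x) mean((x - mean(x))^2))
    sqrt(rowSums(v))
  })
  n_trials <- vapply(trials, function(a) dim(a)[3], numeric(1))
  nms <- names(trials)
  prs <- utils::combn(nms, 2, simplify = FALSE)
  d <- matrix(0, nrow(centers[[1]]), length(prs))
  colnames(d) <- vapply(prs, paste, character(1), collapse = ":")
  res <- data.frame(X = character(0), Y = character(0), r_XY = numeric(0),
                    degenerate = logical(0))
  for (j in seq_along(prs)) {
    X <- prs[[j]][1]; Y <- prs[[j]][2]
    dj <- sqrt(rowSums((centers[[X]] - centers[[Y]])^2))
    d[, j] <- dj
    degenerate <- any(dj == 0)
    r <- if (degenerate) Inf else sum((sigmas[[X]] + sigmas[[Y]]) / dj)
    res[j, c("X", "Y")] <- c(X, Y)
    res$r_XY[j] <- r
    res$degenerate[j] <- degenerate
  }
  structure(list(pairs = res, d = d, sigma = sigmas, centers = centers,
                 n_trials = n_trials),
            class = "rc_separation")
}

#' Effective dimensionality of an eigenvalue spectrum
#'
#' The inverse participation ratio `1 / sum(lambda_hat^2)` of the spectrum
#' normalized to unit sum: if `n` components share the total variance
#' equally and the rest are zero, the effective dimension is exactly `n`.
#'
#' @param lambda non-negative eigenvalues (any scale; normalized
#'   internally).
#' @return Effective dimension in \[1, length(lambda)\].
#' @export
effective_dimension <- function(lambda) {
  stopifnot(all(lambda >= 0))
  s <- sum(lambda)
  if (s == 0) stop("all-zero eigenvalue spectrum")
  lh <- lambda / s
  1 / sum(lh^2)
}

#' Cumulative contribution curve of an eigenvalue spectrum
#'
#' @param lambda non-negative eigenvalues sorted in decreasing order.
#' @return Monotone nondecreasing vector of partial sums of the normalized
#'   spectrum, ending at 1.
#' @export
cumulative_contribution <- function(lambda) {
  stopifnot(all(lambda >= 0), !is.unsorted(rev(lambda)))
  s <- sum(lambda)
  if (s == 0) stop("all-zero eigenvalue spectrum")
  cumsum(lambda / s)
}
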