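#' Sliding-window normalization of readout history
#'
#' Normalizes each readout to zero mean and unit standard deviation using
#' statistics over a sliding window of the last `window` samples (a growing
#' window before `window` samples have been seen). Where the windowed
#' standard deviation falls below `sigma_floor` the normalized value is 0.
#' This is the same incremental computation the simulation loop uses.
#'
#' @param z_history `time x O` matrix of raw readouts.
#' @param window window length in samples.
#' @param sigma_floor guard on the standard deviation.
#' @return A list with `zhat` (`time x O`), `mu` and `sigma` (same shapes).
#' @export
normalize_output <- function(z_history, window, sigma_floor = 1e-6) {
  stopifnot(nrow(z_history) >= 1, window >= 1)
  z_history <- as.matrix(z_history)
  st <- running_stats_cpp(z_history, as.integer(window))
  zhat <- (z_history - st$mu) / st$sigma
  zhat[st$sigma <= sigma_floor] <- 0
  list(zhat = zhat, mu = st$mu, sigma = st$sigma)
}

#' Soft winner-take-all teaching signal
#'
#' `f_i = [ tanh( (zhat_i - gamma * (sum_j zhat_j - zhat_i)) / beta ) ]_+`
#' where `[x]_+` is the threshold-linear function. The competition term
#' subtracts the partner readouts' summed activity, so only a readout that
#' clearly dominates receives a positive target; entries lie in \[0, 1) and
#' the map is equivariant under index permutation.
#'
#' @param zhat normalized readout vector (or `time x O` matrix, handled
#'   row-wise).
#' @param teaching [teaching_params()].
#' @return Teaching-signal vector (or matrix) of the same shape.
#' @export
teaching_signal <- function(zhat, teaching = teaching_params()) {
  f <- function(v) {
    num <- v - teaching$gamma * (sum(v) - v)
    pmax(tanh(num / teaching$beta), 0)
  }
  if (is.matrix(zhat)) t(apply(zhat, 1, f)) else f(as.numeric(zhat))
}

#' Instantaneous readout error against the teaching signal
#'
#' @param z raw readout vector.
#' @param f teaching-signal vector.
#' @return Elementwise difference `z - f`.
#' @export
output_error <- function(z, f) {
  stopifnot(length(z) == length(f))
  z - f
}

#' Fixed integrated output of the two modules
#'
#' `o_i = delta * (z1_i + z2_i)`; with `delta = 0.5` this is the mean of the
#' two modules' readouts, used for the final performance evaluation of the
#' original architecture.
#'
#' @param z1,z2 readout vectors (or `time x O` matrices) of the two modules.
#' @param delta weighting constant.
#' @return Same shape as the inputs.
#' @export
integrated_output <- function(z1, z2, delta = 0.5) {
  stopifnot(length(z1) == length(z2))
  delta * (z1 + z2)
}

#' Association-layer output and one Hebbian weight update
#'
#' The association unit `i` outputs
#' `o_i = sum_j w1_ij z1_j + sum_j w2_ij z2_j`. The weights then follow
#' `dw_ij/dt = o_i z_j - o_i (sum_j z_j)/O` (Hebbian growth with subtractive
#' normalization, which conserves each row sum exactly), integrated by one
#' Euler step of `dt` scaled by `lr`.
#'
#' @param z1,z2 readout vectors of the two modules (length `O`).
#' @param w1,w2 `O x O` association weight matrices.
#' @param dt Euler step in ms.
#' @param lr learning-rate multiplier.
#' @return List with `o` and updated `w1`, `w2`.
#' @export
assoc_output_and_hebb <- function(z1, z2, w1, w2, dt = 1, lr = 1e-4) {
  o <- as.numeric(w1 %*% z1 + w2 %*% z2)
  O <- length(o)
  dw1 <- outer(o, z1) - outer(o, rep(mean(z1), O))
  dw2 <- outer(o, z2) - outer(o, rep(mean(z2), O))
  list(o = o, w1 = w1 + dt * lr * dw1, w2 = w2 + dt * lr * dw2)
}

#' One-hot chunk teacher built from a track's annotations
#'
#' Builds the idealized teaching signal in which output unit `i` is held at
#' `amplitude` throughout every presentation of chunk `i` and at 0
#' elsewhere. Used with [train()]'s `teacher` argument as a supervised
#' upper-bound probe of the readout pipeline.
#'
#' @param track an `rc_track`.
#' @param chunk_names chunk-to-unit order (unit `i` teaches
#'   `chunk_names[i]`).
#' @param amplitude target level during a chunk's presentation.
#' @return A `time x length(chunk_names)` matrix.
#' @export
chunk_teacher <- function(track, chunk_names = c("apple", "grape", "banana"),
                          amplitude = 0.7) {
  ann <- track$annotations
  F <- matrix(0, nrow(track$modality1), length(chunk_names))
  for (e in seq_len(nrow(ann))) {
    j <- match(ann$label[e], chunk_names)
    if (!is.na(j))
      F[(ann$onset_ms[e] / track$dt + 1):(ann$offset_ms[e] / track$dt), j] <-
        amplitude
  }
  F
}

#' Build an (untrained) two-module collaborative model
#'
#' The `"original"` architecture couples the modules only through cross-fed
#' teaching signals and uses the fixed integrated output. The alternative
#' architectures couple the modules structurally, close the teaching signal
#' within each module, and read out through a Hebbian association layer:
#' \describe{
#'   \item{a1}{reservoir-to-reservoir connections: each cross matrix is
#'     `N x N` with connection probability 0.1 and N(0, 1) weights on the
#'     nonzeros (built in the same manner as `W_in`'s entries).}
#'   \item{a2}{readout-to-partner-reservoir feedback: cross matrices built
#'     like `W_back`, uniform on \[-1, 1\].}
#'   \item{a3}{all-to-all readout-to-readout coupling: the partner module's
#'     raw readouts are added through a fixed uniform \[-1, 1\] `O x O`
#'     matrix before feedback.}
#' }
#'
#' @param variant one of `"original"`, `"a1"`, `"a2"`, `"a3"`.
#' @param params1,params2 [model_params()] for the text and image modules.
#' @param teaching [teaching_params()].
#' @param cross_p connection probability of the a1 cross matrices.
#' @return An object of class `rc_model`.
#' @export
build_model <- function(variant = c("original", "a1", "a2", "a3"),
                        params1 = model_params(I = 26),
                        params2 = model_params(I = 30),
                        teaching = teaching_params(), cross_p = 0.1,
                        feedback = c("raw", "normalized")) {
  variant <- match.arg(variant)
  feedback <- match.arg(feedback)
  rc1 <- init_weights(params1)
  rc2 <- init_weights(params2)
  N1 <- params1$N; N2 <- params2$N; O <- params1$O
  stopifnot(params2$O == O)
  cross <- switch(variant,
    original = list(),
    a1 = {
      mk <- function(nr, nc) {
        M <- matrix(0, nr, nc)
        nz <- which(stats::runif(nr * nc) < cross_p)
        M[nz] <- stats::rnorm(length(nz))
        M
      }
      list(cross12 = mk(N1, N2), cross21 = mk(N2, N1))
    },
    a2 = list(cross12 = matrix(stats::runif(N1 * O, -1, 1), N1, O),
              cross21 = matrix(stats::runif(N2 * O, -1, 1), N2, O)),
    a3 = list(cross12 = matrix(stats::runif(O * O, -1, 1), O, O),
              cross21 = matrix(stats::runif(O * O, -1, 1), O, O))
  )
  assoc_w <- list(w1 = matrix(stats::runif(O * O, 0, 0.1), O, O),
                  w2 = matrix(stats::runif(O * O, 0, 0.1), O, O))
  structure(list(rc1 = rc1, rc2 = rc2, variant = variant, cross = cross,
                 assoc_w = assoc_w, teaching = teaching,
                 feedback = feedback, trained = FALSE),
            class = "rc_model")
}

simulate_ctrl <- function(model, track, learn, warmup_ms, update_interval,
                          record_stride, record_r, record_teach) {
  p1 <- model$rc1$params; p2 <- model$rc2$params
  stopifnot(ncol(track$modality1) == p1$I, ncol(track$modality2) == p2$I,
            abs(track$dt - p1$dt) < 1e-12)
  teach <- list(
    beta = model$teaching$beta, gamma = model$teaching$gamma,
    delta = model$teaching$delta,
    window = as.integer(round(model$teaching$T_ms / p1$dt)),
    sigma_floor = model$teaching$sigma_floor,
    variant = match(model$variant, c("original", "a1", "a2", "a3")) - 1L,
    assoc_lr = model$teaching$assoc_lr,
    assoc_cap = model$teaching$assoc_cap,
    smooth_steps = model$teaching$smooth_ms / p1$dt,
    assoc_w1 = model$assoc_w$w1, assoc_w2 = model$assoc_w$w2
  )
  if (model$variant != "original") {
    teach$cross12 <- model$cross$cross12
    teach$cross21 <- model$cross$cross21
  } else {
    teach$cross12 <- teach$cross21 <- matrix(0, 1, 1)
  }
  ctrl <- list(
    fb_normalized = identical(model$feedback, "normalized"),
    dt = p1$dt, learn = learn,
    warmup = as.integer(round(warmup_ms / p1$dt)),
    update_interval = as.integer(update_interval),
    record_stride = as.integer(record_stride),
    record_r = record_r, record_teach = record_teach,
    x0_1 = stats::rnorm(p1$N, 0, 0.1),
    x0_2 = stats::rnorm(p2$N, 0, 0.1)
  )
  list(teach = teach, ctrl = ctrl)
}

mod_for_cpp <- function(m) {
  list(W = m$W, W_in = m$W_in, W_back = m$W_back, wout = m$wout,
       support = m$support, P = m$P,
       params = list(tau = m$params$tau, g = m$params$g, k = m$params$k))
}

#' Train the collaborative model on a stimulus track by FORCE learning
#'
#' Steps both modules jointly at every `dt`, maintains the sliding-window
#' readout statistics, computes the teaching signals (cross-fed for the
#' original architecture, module-local for a1-a3), and applies the RLS
#' readout update at every step after the warm-up period. For the
#' alternative architectures the Hebbian association layer learns
#' concurrently. The readout-weight norm trajectory and (optionally) readout
#' and teaching-signal traces are logged.
#'
#' @param model an `rc_model`.
#' @param track an `rc_track` whose modality widths match the modules.
#' @param warmup_ms no weight updates during the first `warmup_ms` of the
#'   track while the normalization window fills (defaults to the window
#'   length `T_ms`).
#' @param update_interval apply the RLS update every this many steps.
#' @param record_stride stride (in steps) of the weight-norm log.
#' @param record_teach if `TRUE`, store per-step readout, normalized-readout
#'   and teaching-signal traces in the log.
#' @param teacher optional externally supplied teaching signal overriding
#'   the self-organized one: a `time x O` matrix applied to both modules, or
#'   a list with elements `f1` and `f2`. Useful as a supervised probe of
#'   what the FORCE pipeline can learn when the teacher is ideal.
#' @return The trained `rc_model` with a `log` field (`wout_norm` data frame
#'   and optional traces).
#' @export
train <- function(model, track, warmup_ms = model$teaching$T_ms,
                  update_interval = 1, record_stride = 50,
                  record_teach = FALSE, teacher = NULL) {
  stopifnot(inherits(model, "rc_model"), inherits(track, "rc_track"))
  if (nrow(track$modality1) == 0) return(model)
  cfg <- simulate_ctrl(model, track, learn = TRUE, warmup_ms = warmup_ms,
                       update_interval = update_interval,
                       record_stride = record_stride, record_r = FALSE,
                       record_teach = record_teach)
  if (!is.null(teacher)) {
    if (is.matrix(teacher)) teacher <- list(f1 = teacher, f2 = teacher)
    stopifnot(nrow(teacher$f1) == nrow(track$modality1),
              nrow(teacher$f2) == nrow(track$modality1))
    cfg$teach$f_ext1 <- teacher$f1
    cfg$teach$f_ext2 <- teacher$f2
  }
  res <- rc_simulate_cpp(mod_for_cpp(model$rc1), mod_for_cpp(model$rc2),
                         track$modality1, track$modality2,
                         cfg$teach, cfg$ctrl)
  model$rc1$wout <- res$wout1; model$rc1$P <- res$P1
  model$rc2$wout <- res$wout2; model$rc2$P <- res$P2
  model$assoc_w <- list(w1 = res$assoc_w1, w2 = res$assoc_w2)
  model$trained <- TRUE
  model$log <- list(wout_norm = res$wout_norm)
  if (record_teach)
    model$log <- c(model$log,
                   list(z1 = res$z1, z2 = res$z2, o = res$o,
                        f1 = res$f1, f2 = res$f2,
                        zhat1 = res$zhat1, zhat2 = res$zhat2))
  model
}

#' Forward-only pass of a trained model over a stimulus track
#'
#' No weights are updated; readouts, the association-level output and
#' (optionally) the reservoir rate histories are recorded.
#'
#' @param model a trained `rc_model`.
#' @param track an `rc_track`.
#' @param record_reservoir if `TRUE`, record both modules' rate histories.
#' @param record_stride stride (in steps) of the reservoir recording.
#' @return An object of class `rc_run`: list with `z1`, `z2`, `o`
#'   (`time x O`), optional `r1`, `r2`, the track `annotations` and `dt`.
#' @export
run_inference <- function(model, track, record_reservoir = FALSE,
                          record_stride = 1) {
  stopifnot(inherits(model, "rc_model"), inherits(track, "rc_track"))
  cfg <- simulate_ctrl(model, track, learn = FALSE, warmup_ms = 0,
                       update_interval = 1, record_stride = record_stride,
                       record_r = record_reservoir, record_teach = FALSE)
  res <- rc_simulate_cpp(mod_for_cpp(model$rc1), mod_for_cpp(model$rc2),
                         track$modality1, track$modality2,
                         cfg$teach, cfg$ctrl)
  out <- list(z1 = res$z1, z2 = res$z2, o = res$o,
              annotations = track$annotations, dt = track$dt,
              record_stride = record_stride)
  if (record_reservoir) {
    out$r1 <- res$r1
    out$r2 <- res$r2
  }
  structure(out, class = "rc_run")
}

#' @export
print.rc_model <- function(x, ...) {
  cat("<rc_model> variant =", x$variant,
      if (x$trained) "(trained)" else "(untrained)", "\n")
  cat("  RC1:"); print(x$rc1)
  cat("  RC2:"); print(x$rc2)
  invisible(x)
}
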