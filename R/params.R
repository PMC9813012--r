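#' Model parameters for one reservoir module
#'
#' Bundles the scalar hyperparameters of a single echo-state module. Defaults
#' are the desk-scale configuration used throughout the package examples and
#' tests; the full-size study configuration (`N = 1200`, `S = 300`) is
#' available by passing those values explicitly.
#'
#' @param N reservoir size (number of rate neurons).
#' @param S readout fan-in: number of reservoir neurons feeding each readout.
#' @param p recurrent connection probability, in (0, 1].
#' @param tau membrane time constant in ms.
#' @param g recurrent gain; `g > 1` yields chaotic spontaneous activity.
#' @param k amplitude of the per-step Gaussian noise term.
#' @param alpha RLS regularization; the inverse-correlation matrix is
#'   initialized to `diag(S)/alpha`. Plays the role of a learning rate in
#'   FORCE training.
#' @param I input dimensionality (26 for the text-tone channel, 30 for the
#'   image channel).
#' @param O number of linear readouts.
#' @param dt integration step in ms.
#'
#' @return An object of class `rc_model_params`.
#' @export
model_params <- function(N = 600, S = 200, p = 0.5, tau = 5, g = 1.0,
                         k = 0.2, alpha = 100, I = 26, O = 3, dt = 1) {
  stopifnot(N >= 1, S >= 1, tau > 0, dt > 0, O >= 1, alpha > 0, I >= 1)
  if (S > N) stop("readout fan-in S (", S, ") cannot exceed N (", N, ")")
  if (p <= 0 || p > 1) stop("connection probability p must be in (0, 1]")
  structure(list(N = as.integer(N), S = as.integer(S), p = p, tau = tau,
                 g = g, k = k, alpha = alpha, I = as.integer(I),
                 O = as.integer(O), dt = dt),
            class = "rc_model_params")
}

#' Teaching-signal and association-layer parameters
#'
#' @param beta gain divisor inside the tanh of the teaching signal.
#' @param gamma competition weight on the summed partner readouts. With three
#'   readouts and `gamma = 0.5` the competition term equals the mean of the
#'   other two readouts.
#' @param T_ms length in ms of the sliding window used to normalize readouts
#'   to zero mean and unit standard deviation before the teaching transform.
#' @param delta weight of the fixed association readout sum; with
#'   `delta = 0.5` the integrated output is the mean of the two modules'
#'   readouts.
#' @param sigma_floor below this value of the windowed standard deviation the
#'   normalized readout is set to 0 (guards the cold start).
#' @param assoc_lr Euler-step learning-rate multiplier for the Hebbian
#'   association layer used by the alternative architectures.
#' @param assoc_cap elementwise bound on the association weights. Plain
#'   Hebbian growth is unbounded (the subtractive normalization conserves
#'   row sums, not norms), so weights are clamped to
#'   `[-assoc_cap, assoc_cap]` after each update.
#' @param smooth_ms time constant in ms of an optional leaky integration of
#'   the normalized readouts before the winner-take-all teaching transform
#'   (0, the default, disables it and uses the instantaneous normalized
#'   readouts). Integration lags the teacher at chunk onsets and was found
#'   to destabilize an organized chunk-selective solution, so it is off by
#'   default and kept only as an experimental knob.
#'
#' @return An object of class `rc_teaching_params`.
#' @export
teaching_params <- function(beta = 3, gamma = 0.5, T_ms = 15000,
                            delta = 0.5, sigma_floor = 1e-6,
                            assoc_lr = 1e-4, assoc_cap = 1,
                            smooth_ms = 0) {
  stopifnot(beta > 0, T_ms > 0, sigma_floor >= 0, assoc_lr >= 0,
            assoc_cap > 0, smooth_ms >= 0)
  structure(list(beta = beta, gamma = gamma, T_ms = T_ms, delta = delta,
                 sigma_floor = sigma_floor, assoc_lr = assoc_lr,
                 assoc_cap = assoc_cap, smooth_ms = smooth_ms),
            class = "rc_teaching_params")
}

#' Stimulus-stream construction parameters
#'
#' @param alphabet character vector of admissible letters; input line `j` of
#'   the text channel corresponds to `alphabet[j]`.
#' @param letter_slot_ms duration in ms of one letter slot.
#' @param pulse_fraction fraction of the slot occupied by the rectangular
#'   pulse; the remainder of the slot is silent.
#' @param pulse_amplitude height of the letter pulse. The default (5) is
#'   calibrated so that the text-driven reservoir's trajectories are
#'   reproducible across repeated presentations of the same chunk (the
#'   trial-to-trial trajectory correlation of an untrained reservoir
#'   plateaus near this drive strength); a unit pulse on a single input
#'   line is too weak to quench the near-critical reservoir's sensitivity
#'   to its pre-stimulus state.
#' @param image_size canonical square image edge in pixels; images are
#'   assumed rescaled to this size before encoding.
#' @param sections number of horizontal sections each RGB channel is split
#'   into (the image channel has `3 * sections` input lines).
#' @param window_px width in pixels of the scanning window. The default (2)
#'   is deliberately narrow: pooling over a wide window would average the
#'   pixel noise of the random-separator images into a nearly identical
#'   series on every presentation, making the separators a *consistent*
#'   stimulus; a narrow window keeps each noise image's encoding unique.
#' @param image_noise_sd standard deviation of optional per-presentation
#'   additive pixel noise on chunk images (0 disables it).
#' @param dt time step in ms.
#'
#' @return An object of class `rc_stim_params`.
#' @export
stim_params <- function(alphabet = letters, letter_slot_ms = 50,
                        pulse_fraction = 0.8, pulse_amplitude = 5,
                        image_size = 60, sections = 10, window_px = NULL,
                        image_noise_sd = 0, dt = 1) {
  stopifnot(letter_slot_ms > 0, pulse_fraction > 0, pulse_fraction <= 1,
            pulse_amplitude > 0, image_size >= sections, sections >= 1,
            dt > 0, image_noise_sd >= 0)
  if (is.null(window_px)) window_px <- 2L
  structure(list(alphabet = alphabet, letter_slot_ms = letter_slot_ms,
                 pulse_fraction = pulse_fraction,
                 pulse_amplitude = pulse_amplitude,
                 image_size = as.integer(image_size),
                 sections = as.integer(sections),
                 window_px = as.integer(window_px),
                 image_noise_sd = image_noise_sd, dt = dt),
            class = "rc_stim_params")
}

#' Chunk-schedule parameters
#'
#' @param C total number of presentation epochs, counting random-sequence
#'   separators.
#' @param chunk_probabilities per-chunk selection weights (normalized to sum
#'   to 1).
#' @param use_separators if `TRUE`, chunk epochs alternate with
#'   random-sequence epochs; if `FALSE`, chunks repeat back to back.
#' @param m pair-replacement ("non-co-occurrence") probability in \[0, 1\]:
#'   each chunk epoch independently has one modality's signal replaced with
#'   probability `m`.
#' @param d inter-modal delay in ms applied to one modality's stream.
#' @param delayed_modality which channel is shifted by `d` (1 = text,
#'   2 = image).
#'
#' @return An object of class `rc_schedule_params`.
#' @export
schedule_params <- function(C = 300, chunk_probabilities = c(1, 1, 1) / 3,
                            use_separators = TRUE, m = 0, d = 0,
                            delayed_modality = 2) {
  if (C < 1) stop("C must be at least 1")
  if (m < 0 || m > 1) stop("replacement probability m must be in [0, 1]")
  if (d < 0) stop("delay d must be non-negative")
  stopifnot(all(chunk_probabilities >= 0), sum(chunk_probabilities) > 0,
            delayed_modality %in% c(1, 2))
  structure(list(C = as.integer(C),
                 chunk_probabilities =
                   chunk_probabilities / sum(chunk_probabilities),
                 use_separators = isTRUE(use_separators), m = m, d = d,
                 delayed_modality = as.integer(delayed_modality)),
            class = "rc_schedule_params")
}
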