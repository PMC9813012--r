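# Shared miniature configurations: small images and short letter slots keep
# the generated matrices tiny, and a short normalization window lets the
# miniature models start learning almost immediately.

tiny_stim <- function(...) {
  stim_params(letter_slot_ms = 10, image_size = 20, ...)
}

tiny_teaching <- function(...) {
  teaching_params(T_ms = 500, ...)
}

tiny_model <- function(variant = "original", N = 80, S = 30, k = 0.2,
                       stim = tiny_stim(), teaching = tiny_teaching(), ...) {
  build_model(variant,
              model_params(N = N, S = S, I = length(stim$alphabet),
                           k = k, ...),
              model_params(N = N, S = S, I = 3L * stim$sections,
                           k = k, ...),
              teaching)
}

tiny_track <- function(C = 10, stim = tiny_stim(), m = 0, d = 0, ...) {
  generate_track(schedule_params(C = C, m = m, d = d, ...),
                 default_chunks(stim), stim)
}

tiny_config <- function(C = 12, N = 80, S = 30, ...) {
  experiment_config(C = C, N = N, S = S, stim = tiny_stim(),
                    teaching = tiny_teaching(), ...)
}
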