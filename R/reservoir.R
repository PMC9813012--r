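#' Initialize the weights of one reservoir module
#'
#' Recurrent weights `W` are Bernoulli(`p`)-sparse with nonzero entries drawn
#' from N(0, 1/(pN)). Each row of the input matrix `W_in` has exactly one
#' nonzero entry drawn from N(0, 1), so every reservoir neuron listens to one
#' input line. Feedback weights `W_back` are uniform on \[-1, 1\] (readouts
#' project back to all reservoir neurons). Initial readout weights are
#' N(0, 1/N) on each readout's support set of `S` neurons, sampled
#' independently per readout without replacement; the RLS inverse-correlation
#' matrix `P` is initialized to `diag(S)/alpha` per readout.
#'
#' @param params [model_params()].
#' @param shared_support if `TRUE` all readouts share one support set.
#' @return An object of class `rc_module` with fields `W`, `W_in`, `W_back`,
#'   `wout` (O x S compact readout weights), `support` (S x O neuron
#'   indices), `P` (S x S x O array) and `params`.
#' @export
init_weights <- function(params, shared_support = FALSE) {
  stopifnot(inherits(params, "rc_model_params"))
  N <- params$N; S <- params$S; O <- params$O; I <- params$I
  W <- matrix(0, N, N)
  nz <- which(stats::runif(N * N) < params$p)
  W[nz] <- stats::rnorm(length(nz), 0, sqrt(1 / (params$p * N)))
  W_in <- matrix(0, N, I)
  W_in[cbind(seq_len(N), sample(I, N, replace = TRUE))] <- stats::rnorm(N)
  W_back <- matrix(stats::runif(N * O, -1, 1), N, O)
  support <- if (shared_support) {
    matrix(sample(N, S), S, O)
  } else {
    vapply(seq_len(O), function(i) sample(N, S), integer(S))
  }
  wout <- matrix(stats::rnorm(O * S, 0, sqrt(1 / N)), O, S)
  P <- array(0, dim = c(S, S, O))
  for (i in seq_len(O)) P[, , i] <- diag(S) / params$alpha
  structure(list(W = W, W_in = W_in, W_back = W_back, wout = wout,
                 support = support, P = P, params = params),
            class = "rc_module")
}

#' Expand a module's compact readout weights to the full O x N matrix
#'
#' Entries outside each readout's support set are structurally zero.
#'
#' @param module an `rc_module`.
#' @return An `O x N` matrix.
#' @export
full_wout <- function(module) {
  O <- module$params$O
  out <- matrix(0, O, module$params$N)
  for (i in seq_len(O)) out[i, module$support[, i]] <- module$wout[i, ]
  out
}

#' One Euler step of the reservoir dynamics
#'
#' Advances `tau dx/dt = -x + g W r + W_in i + W_back z + k xi` by one step
#' of `dt`, with rates `tanh(x)` and fresh standard-normal `xi` per neuron
#' when `k > 0`.
#'
#' @param module an `rc_module`.
#' @param state list with membrane vector `x` (and optionally `r`).
#' @param input input-layer activity vector (length `I`).
#' @param feedback_z readout vector fed back (length `O`).
#' @return Updated state: list with `x` and rates `r` equal to `tanh(x)`.
#' @export
reservoir_step <- function(module, state, input, feedback_z) {
  p <- module$params
  stopifnot(length(state$x) == p$N, length(input) == p$I,
            length(feedback_z) == p$O)
  if (any(!is.finite(state$x)))
    stop("reservoir state contains non-finite values (divergence)")
  st <- rc_step_cpp(state$x, module$W, module$W_in, module$W_back,
                    as.numeric(input), as.numeric(feedback_z),
                    p$tau, p$g, p$k, p$dt)
  list(x = drop(st$x), r = drop(st$r))
}

#' Linear readout of a reservoir state
#'
#' `z_i` is the weighted sum of the rates of readout `i`'s `S` support
#' neurons; all other neurons contribute exactly zero.
#'
#' @param module an `rc_module`.
#' @param r rate vector (length `N`).
#' @return Readout vector of length `O`.
#' @export
rc_readout <- function(module, r) {
  vapply(seq_len(module$params$O),
         function(i) sum(module$wout[i, ] * r[module$support[, i]]),
         numeric(1))
}

#' FORCE (recursive least squares) update of the readout weights
#'
#' For each readout `i`, with `r_s` the rates on its support set and `e_i`
#' the instantaneous output error, updates the inverse-correlation matrix
#' `P <- P - (P r_s r_s' P) / (1 + r_s' P r_s)` and the weights
#' `w <- w - e_i (P_new r_s)'`. The error on the same sample is strictly
#' reduced in magnitude for any nonzero `r_s`.
#'
#' @param module an `rc_module`.
#' @param r rate vector (length `N`).
#' @param e error vector `z - f` (length `O`).
#' @return The module with updated `wout` and `P`.
#' @export
force_update <- function(module, r, e) {
  if (any(!is.finite(e))) stop("non-finite readout error in FORCE update")
  for (i in seq_len(module$params$O)) {
    upd <- rls_update_cpp(module$P[, , i], module$wout[i, , drop = TRUE],
                          r[module$support[, i]], e[i])
    module$P[, , i] <- upd$P
    module$wout[i, ] <- upd$w
  }
  module
}

#' @export
print.rc_module <- function(x, ...) {
  p <- x$params
  cat("<rc_module> N =", p$N, " S =", p$S, " I =", p$I, " O =", p$O,
      " p =", p$p, " g =", p$g, " tau =", p$tau, "\n")
  invisible(x)
}
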