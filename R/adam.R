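# Adam optimizer: exponential moving averages of the gradient and squared
# gradient with bias correction,
#   m_t = b1 m_{t-1} + (1-b1) g_t          v_t = b2 v_{t-1} + (1-b2) g_t^2
#   mhat = m_t/(1-b1^t)                    vhat = v_t/(1-b2^t)
#   theta <- theta - eta * mhat / (sqrt(vhat) + eps)

#' Initialize Adam state
#'
#' @param params named list of numeric arrays (the parameters to be
#'   optimized).
#' @param eta learning rate.
#' @param beta1,beta2 moment decay rates (0.937 and 0.999, the momentum
#'   setting used for training here).
#' @param eps numerical stabilizer.
#' @return an `adam_state` list with step count `t = 0` and zeroed moments.
#' @export
adam_init <- function(params, eta = 1e-2, beta1 = 0.937, beta2 = 0.999,
                      eps = 1e-8) {
  zeros <- lapply(params, function(p) { p[] <- 0; p })
  structure(list(t = 0L, m = zeros, v = zeros, eta = eta,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' One Adam update
#'
#' Applies the exact moment/bias-correction/update sequence. At `t = 1`
#' the bias-corrected moments satisfy `mhat = g` and `vhat = g^2` exactly.
#'
#' @param state an [adam_init()] state.
#' @param gradients named list of gradient arrays (shapes matching
#'   `params`).
#' @param params named list of parameter arrays.
#' @param eta optional learning-rate override for this step (for
#'   schedules).
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(state, gradients, params, eta = NULL) {
  stopifnot(inherits(state, "adam_state"),
            identical(names(gradients), names(params)))
  eta <- eta %||% state$eta
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- gradients[[nm]]
    if (!identical(dim(g) %||% length(g),
                   dim(params[[nm]]) %||% length(params[[nm]])))
      stop("adam_step: shape mismatch for ", nm)
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - eta * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}
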