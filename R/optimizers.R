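# Optimizers: SGD with momentum, Nadam, and rectified Adam with a
# power-law ("fractional") learning-rate decay.

#' Specify an optimizer
#'
#' Three presets are supported: `"nadam"` (Nesterov-accelerated adaptive
#' moments, learning rate 1e-3), `"sgd"` (momentum SGD, learning rate 0.01,
#' momentum 0.9), and `"fractional_radam"` (rectified Adam at a base
#' learning rate of 5e-4 whose per-step rate decays as
#' `lr0 * (1 + t)^(-decay_exponent)`; exponent 0 reduces it to plain
#' rectified Adam, which the tests exploit for differential checking).
#'
#' @param name One of `"sgd"`, `"nadam"`, `"fractional_radam"`.
#' @param lr Learning rate; defaults to the preset above.
#' @param momentum SGD momentum (default 0.9).
#' @param decay_exponent Power-law decay exponent for `fractional_radam`
#'   (default 0.5).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param eps Adam denominator floor (default 1e-8).
#' @return An object of class `optimizer_spec`.
#' @export
optimizer_spec <- function(name = c("sgd", "nadam", "fractional_radam"),
                           lr = NULL, momentum = 0.9, decay_exponent = 0.5,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  name <- match.arg(name)
  lr <- lr %||% switch(name, sgd = 0.01, nadam = 1e-3,
                       fractional_radam = 5e-4)
  structure(list(name = name, lr = lr, momentum = momentum,
                 decay_exponent = decay_exponent, beta1 = beta1,
                 beta2 = beta2, eps = eps),
            class = "optimizer_spec")
}

#' @export
print.optimizer_spec <- function(x, ...) {
  cat(sprintf("Optimizer '%s': lr %g", x$name, x$lr))
  if (x$name == "sgd") cat(sprintf(", momentum %g", x$momentum))
  if (x$name == "fractional_radam")
    cat(sprintf(", decay exponent %g", x$decay_exponent))
  cat("\n")
  invisible(x)
}

#' Instantiate optimizer state
#'
#' Every call creates a fresh, independent state (moments at zero, step
#' counter at zero), as required when models are re-initialized per fold.
#'
#' @param spec An [optimizer_spec()].
#' @param params The nested parameter list the optimizer will update (used
#'   only to shape the state).
#' @return An object of class `cytoxai_optimizer` with a `$step(params,
#'   grads)` function returning the updated parameters.
#' @export
make_optimizer <- function(spec, params) {
  stopifnot(inherits(spec, "optimizer_spec"))
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  if (spec$name == "sgd") {
    env$v <- nn_zeros_like(params)
    step <- function(params, grads) {
      env$t <- env$t + 1L
      env$v <- nn_map2(function(v, g) spec$momentum * v + g, env$v, grads)
      nn_map2(function(p, v) p - spec$lr * v, params, env$v)
    }
  } else if (spec$name == "nadam") {
    env$m <- nn_zeros_like(params)
    env$v <- nn_zeros_like(params)
    step <- function(params, grads) {
      env$t <- env$t + 1L
      b1 <- spec$beta1; b2 <- spec$beta2; t <- env$t
      env$m <- nn_map2(function(m, g) b1 * m + (1 - b1) * g, env$m, grads)
      env$v <- nn_map2(function(v, g) b2 * v + (1 - b2) * g^2, env$v, grads)
      bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
      upd <- nn_map2(function(m, v) m / bc1, env$m, env$v)
      nadam_num <- nn_map2(function(mh, g) b1 * mh + (1 - b1) * g / bc1,
                           upd, grads)
      denom <- nn_map(function(v) sqrt(v / bc2) + spec$eps, env$v)
      delta <- nn_map2(function(n, d) spec$lr * n / d, nadam_num, denom)
      nn_map2(`-`, params, delta)
    }
  } else {  # fractional_radam
    env$m <- nn_zeros_like(params)
    env$v <- nn_zeros_like(params)
    step <- function(params, grads) {
      env$t <- env$t + 1L
      b1 <- spec$beta1; b2 <- spec$beta2; t <- env$t
      lr_t <- spec$lr * (1 + t)^(-spec$decay_exponent)
      env$m <- nn_map2(function(m, g) b1 * m + (1 - b1) * g, env$m, grads)
      env$v <- nn_map2(function(v, g) b2 * v + (1 - b2) * g^2, env$v, grads)
      mhat <- nn_map(function(m) m / (1 - b1^t), env$m)
      rho_inf <- 2 / (1 - b2) - 1
      rho_t <- rho_inf - 2 * t * b2^t / (1 - b2^t)
      if (rho_t > 4) {
        r_t <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                      ((rho_inf - 4) * (rho_inf - 2) * rho_t))
        vhat <- nn_map(function(v) sqrt(v / (1 - b2^t)) + spec$eps, env$v)
        delta <- nn_map2(function(m, v) lr_t * r_t * m / v, mhat, vhat)
      } else {
        delta <- nn_map(function(m) lr_t * m, mhat)
      }
      nn_map2(`-`, params, delta)
    }
  }
  structure(list(spec = spec, step = step, state = env),
            class = "cytoxai_optimizer")
}
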