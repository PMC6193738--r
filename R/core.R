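#' Reservoir parameters
#'
#' Parameters of one chaotic rate reservoir. With recurrent gain above 1 the
#' autonomous network shows chaotic spontaneous activity ("edge of chaos" for
#' gain 1.5); the defaults are the single-chunk configuration
#' (300 neurons, full connectivity, noise SD 0.3).
#'
#' @param n_neurons Number of reservoir neurons `N`.
#' @param gain Recurrent gain `g` (chaotic spontaneous activity for `g > 1`).
#' @param p_connect Recurrent connection probability in (0, 1].
#' @param tau Membrane time constant in ms.
#' @param sigma Standard deviation of the background noise term.
#' @param dt Integration step in ms.
#' @return A `reservoir_params` list.
#' @export
reservoir_params <- function(n_neurons = 300L, gain = 1.5, p_connect = 1,
                             tau = 10, sigma = 0.3, dt = 1) {
  if (n_neurons < 1L || p_connect <= 0 || p_connect > 1 || tau <= 0 ||
      dt <= 0 || sigma < 0)
    abort("invalid reservoir parameters.", class = "dualrc_invalid")
  structure(list(n_neurons = as.integer(n_neurons), gain = gain,
                 p_connect = p_connect, tau = tau, sigma = sigma, dt = dt),
            class = "reservoir_params")
}

#' Initialize one reservoir module
#'
#' Samples all fixed wiring of a module: recurrent weights with connection
#' probability `p_connect` and nonzero entries `N(0, 1/(p N))`; feedback
#' weights (one column per readout) uniform on `[-1, 1]`; a readout subset of
#' `n_readout` neurons drawn without replacement and shared by the module's
#' readouts (they also share one inverse-correlation matrix during learning);
#' initial readout weights `N(0, 1/n_readout)`; initial state
#' `N(0, x_sd^2)` per neuron. Recurrent and feedback weights stay fixed;
#' only readout weights are plastic.
#'
#' @param params A [reservoir_params()].
#' @param n_readouts Number of readout units `K`.
#' @param n_readout Readout fan-in `n` (number of reservoir neurons each
#'   readout reads; at most `n_neurons`).
#' @param n_input Number of input channels.
#' @param fan_in Input fan-in fraction (`NULL` = one-to-one), see
#'   [input_projection()].
#' @param projection Optional pre-built [input_projection()] (overrides
#'   `fan_in`), e.g. from [encode_images()].
#' @param x_sd Standard deviation of the initial membrane state.
#' @param seed Optional integer seed.
#' @return A `reservoir_module` list with wiring, state and readout weights.
#' @export
init_reservoir <- function(params, n_readouts = 1L, n_readout = params$n_neurons,
                           n_input = 26L, fan_in = NULL, projection = NULL,
                           x_sd = 0.5, seed = NULL) {
  N <- params$n_neurons
  if (n_readout > N)
    abort("`n_readout` cannot exceed the number of neurons.", class = "dualrc_invalid")
  with_seed_if(seed, {
    J <- matrix(rnorm(N * N, sd = sqrt(1 / (params$p_connect * N))), N, N)
    if (params$p_connect < 1) {
      mask <- matrix(runif(N * N) < params$p_connect, N, N)
      J <- J * mask
    }
    J_fb <- matrix(runif(N * n_readouts, -1, 1), N, n_readouts)
    proj <- if (!is.null(projection)) projection else
      input_projection(n_input, N, fan_in = fan_in)
    subset <- sort(sample.int(N, n_readout))
    w <- matrix(rnorm(n_readout * n_readouts, sd = sqrt(1 / n_readout)),
                n_readout, n_readouts)
    x <- rnorm(N, sd = x_sd)
    structure(list(params = params, J = J, J_fb = J_fb,
                   J_in = proj$weights, subset = subset, w = w,
                   x = x, r = tanh(x), n_readouts = as.integer(n_readouts)),
              class = "reservoir_module")
  })
}

#' @export
print.reservoir_module <- function(x, ...) {
  cat("<reservoir_module> ", x$params$n_neurons, " neurons, ", x$n_readouts,
      " readout(s) over ", length(x$subset), " neurons\n", sep = "")
  invisible(x)
}

#' One Euler-Maruyama step of the reservoir dynamics (reference)
#'
#' Reference implementation of the rate dynamics
#' `tau dx = (-x + g J r + J_fb z + I) dt + tau sigma dW`, discretized as
#' `x <- x + (dt/tau) (-x + g J r + J_fb z + I) + sigma sqrt(dt/tau) eta`
#' with fresh standard Gaussian `eta`, followed by `r <- tanh(x)` and
#' `z <- w^T r` on the readout subset. The `sqrt(dt/tau)` noise scaling makes
#' the stationary noise level independent of the integration step. The
#' training loop uses a compiled implementation of the same update; this
#' function backs single-step oracles and small simulations.
#'
#' @param module A `reservoir_module`.
#' @param input_current Length-`n_neurons` vector of external currents.
#' @param z_feedback Length-`n_readouts` vector fed back through `J_fb`.
#' @param noise Optional pre-drawn standard Gaussian vector (length
#'   `n_neurons`); defaults to fresh draws, or zeros when `sigma = 0`.
#' @return The module with updated `x`, `r` and readout outputs `z`.
#' @export
reservoir_step <- function(module, input_current = 0, z_feedback = 0,
                           noise = NULL) {
  p <- module$params
  N <- p$n_neurons
  input_current <- rep_len(input_current, N)
  z_feedback <- rep_len(z_feedback, module$n_readouts)
  if (!all(is.finite(input_current)) || !all(is.finite(z_feedback)))
    abort("non-finite inputs.", class = "dualrc_invalid")
  if (is.null(noise))
    noise <- if (p$sigma > 0) rnorm(N) else numeric(N)
  drift <- -module$x + p$gain * drop(module$J %*% module$r) +
    drop(module$J_fb %*% z_feedback) + input_current
  x_new <- module$x + (p$dt / p$tau) * drift +
    p$sigma * sqrt(p$dt / p$tau) * noise
  if (!all(is.finite(x_new)))
    abort("non-finite state after update.", class = "dualrc_numerical")
  module$x <- x_new
  module$r <- tanh(x_new)
  module$z <- drop(crossprod(module$w, module$r[module$subset]))
  module
}

#' Probe spontaneous activity of an autonomous reservoir
#'
#' Runs a single module with no input, no feedback and no noise, and returns
#' the mean (over neurons) temporal variance of the rates over the last half
#' of the run. Gain above 1 sustains chaotic activity (positive variance);
#' below 1 the network decays to rest.
#'
#' @param params A [reservoir_params()] (its `sigma` is ignored; the probe is
#'   noise-free).
#' @param duration_ms Run length in ms; must be at least `10 tau`.
#' @param seed Optional integer seed for wiring and initial state.
#' @return Scalar variance of the rates.
#' @export
spontaneous_activity <- function(params, duration_ms = 5000, seed = NULL) {
  if (duration_ms < 10 * params$tau)
    abort("`duration_ms` must be at least 10 tau.", class = "dualrc_invalid")
  params$sigma <- 0
  mod <- init_reservoir(params, n_readouts = 1L, seed = seed)
  n_steps <- floor(duration_ms / params$dt)
  keep <- seq.int(floor(n_steps / 2) + 1L, n_steps)
  rates <- matrix(0, length(keep), params$n_neurons)
  j <- 0L
  for (t in seq_len(n_steps)) {
    mod <- reservoir_step(mod, 0, 0)
    if (t >= keep[1]) {
      j <- j + 1L
      rates[j, ] <- mod$r
    }
  }
  mean(apply(rates, 2, var))
}

#' Build a dual reservoir-computing system
#'
#' Two reservoir modules with independent wiring (different seeds derived from
#' `seed`) that receive an identical input drive and, during training,
#' supervise each other's readouts. Modules are uncoupled by default; see
#' [couple_reservoirs()] for the inter-reservoir connection variant.
#'
#' @param params A [reservoir_params()] shared by both modules.
#' @param n_readouts Readout units per module (1 per chunk to learn).
#' @param n_readout Readout fan-in per module.
#' @param n_input Number of input channels.
#' @param fan_in Input fan-in fraction (`NULL` = one-to-one).
#' @param projections Optional list of two pre-built input projections.
#' @param share_projection Use the same input wiring for both modules?
#' @param seed Optional integer seed.
#' @return A `dual_system` list with `module1`, `module2`, `q = 0`.
#' @export
dual_system <- function(params, n_readouts = 1L, n_readout = params$n_neurons,
                        n_input = 26L, fan_in = NULL, projections = NULL,
                        share_projection = FALSE, seed = NULL) {
  seeds <- with_seed_if(seed, sample.int(.Machine$integer.max, 2L))
  m1 <- init_reservoir(params, n_readouts, n_readout, n_input, fan_in,
                       projection = projections[[1]], seed = seeds[1])
  m2 <- init_reservoir(params, n_readouts, n_readout, n_input, fan_in,
                       projection = if (share_projection) NULL else projections[[2]],
                       seed = seeds[2])
  if (share_projection) m2$J_in <- m1$J_in
  structure(list(module1 = m1, module2 = m2, q = 0,
                 cross12 = NULL, cross21 = NULL, seed = seed),
            class = "dual_system")
}

#' @export
print.dual_system <- function(x, ...) {
  cat("<dual_system> 2 modules of ", x$module1$params$n_neurons,
      " neurons, ", x$module1$n_readouts, " readout(s) each",
      if (x$q > 0) paste0(", coupled q = ", x$q) else "", "\n", sep = "")
  invisible(x)
}

#' Add inter-reservoir connections
#'
#' Rebuilds both modules' recurrent wiring as all-to-all Gaussian weights with
#' variance `1/((1+q) N)` and adds cross-module connections with connection
#' probability `q`, drawn from the same distribution. The `1` in the
#' denominator makes `q = 0` reduce exactly to the disconnected system.
#' Cross-module currents enter the partner's dynamics through the recurrent
#' gain, like within-module recurrence.
#'
#' @param system A [dual_system()].
#' @param q Inter-module connection probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The system with rebuilt recurrent weights and `cross12`/`cross21`
#'   matrices (current into module 1 from module 2's rates, and vice versa).
#' @export
couple_reservoirs <- function(system, q, seed = NULL) {
  if (q < 0 || q > 1) abort("`q` must lie in [0, 1].", class = "dualrc_invalid")
  N <- system$module1$params$n_neurons
  sdv <- sqrt(1 / ((1 + q) * N))
  with_seed_if(seed, {
    system$module1$J <- matrix(rnorm(N * N, sd = sdv), N, N)
    system$module2$J <- matrix(rnorm(N * N, sd = sdv), N, N)
    if (q > 0) {
      system$cross12 <- matrix(rnorm(N * N, sd = sdv) * (runif(N * N) < q), N, N)
      system$cross21 <- matrix(rnorm(N * N, sd = sdv) * (runif(N * N) < q), N, N)
    } else {
      system$cross12 <- NULL
      system$cross21 <- NULL
    }
    system$q <- q
    system
  })
}
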