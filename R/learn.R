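#' Teaching-signal configuration
#'
#' The teaching signal for each readout is a rectified sigmoid of the partner
#' module's normalized output: cooperative in the paired readout, competitive
#' (subtractive, strength `gamma`) in the partner's other readouts. The
#' competition can optionally be routed through interneurons that low-pass the
#' normalized outputs with time constant `tau_y`.
#'
#' @param beta Sigmoid scale (> 0).
#' @param gamma Competition strength (>= 0); only relevant with more than one
#'   readout per module.
#' @param use_interneurons Route competition through low-pass interneurons?
#' @param tau_y Interneuron time constant in ms.
#' @return A `teaching_config` list.
#' @export
teaching_config <- function(beta = 3, gamma = 0.5, use_interneurons = FALSE,
                            tau_y = 10) {
  if (beta <= 0 || gamma < 0 || tau_y <= 0)
    abort("invalid teaching configuration.", class = "dualrc_invalid")
  structure(list(beta = beta, gamma = gamma,
                 use_interneurons = use_interneurons, tau_y = tau_y),
            class = "teaching_config")
}

#' Recursive-least-squares (FORCE) configuration
#'
#' The inverse-correlation matrix is initialized to `I / alpha`; one matrix is
#' shared by all readouts of a module. Updates are applied every `interval_ms`
#' of simulated time.
#'
#' @param alpha Regularization scale (ridge penalty of the equivalent batch
#'   problem).
#' @param interval_ms Update interval in ms.
#' @return An `rls_config` list.
#' @export
rls_config <- function(alpha = 100, interval_ms = 2) {
  if (alpha <= 0 || interval_ms <= 0)
    abort("invalid RLS configuration.", class = "dualrc_invalid")
  structure(list(alpha = alpha, interval_ms = interval_ms), class = "rls_config")
}

#' Normalize a readout trace by trailing-window moments
#'
#' Reference implementation of the output normalization used to build teaching
#' signals: at each sample, `zhat(t) = (z(t) - mu(t)) / sd(t)` where `mu` and
#' `sd` are the mean and standard deviation over the trailing window of
#' `window` samples (a growing window before that much history exists). The
#' standard deviation is floored at `eps`, so a constant trace normalizes to 0.
#' After a stationary signal has filled the window the normalized output has
#' mean about 0 and standard deviation about 1.
#'
#' @param z Numeric vector: the raw readout trace (1 sample per ms).
#' @param window Window length in samples (default 15000, i.e. 15 s at 1 ms).
#' @param eps Variance floor.
#' @return Numeric vector of normalized outputs, same length as `z`.
#' @export
normalize_trace <- function(z, window = 15000L, eps = 1e-6) {
  if (!length(z)) abort("need at least one sample.", class = "dualrc_invalid")
  n <- length(z)
  cs <- cumsum(z)
  cs2 <- cumsum(z^2)
  t_idx <- seq_len(n)
  lo <- pmax(t_idx - window, 0L)
  cnt <- t_idx - lo
  s <- cs - c(0, cs)[lo + 1L]
  s2 <- cs2 - c(0, cs2)[lo + 1L]
  mu <- s / cnt
  sdv <- sqrt(pmax(s2 / cnt - mu^2, 0))
  (z - mu) / pmax(sdv, eps)
}

#' Teaching signals (reference implementations)
#'
#' `teaching_single()` is the one-readout rule `f = [tanh(zhat / beta)]_+`
#' applied to the partner's normalized output. `teaching_multi()` subtracts
#' the competition term `gamma * sum(zhat_competitors)` inside the sigmoid;
#' the paired readout is excluded from the sum. `teaching_interneuron()`
#' first advances the interneuron states (one Euler step of
#' `tau_y dy = -y + zhat`) and uses them in place of the raw competitor
#' outputs; at the interneuron fixed point it coincides with
#' `teaching_multi()`. All teaching outputs lie in `[0, 1)`.
#'
#' @param zhat,zhat_pair Normalized output of the paired partner readout.
#' @param zhat_comp Normalized outputs of the partner's competitor readouts
#'   (paired readout excluded).
#' @param y Interneuron states, one per competitor.
#' @param beta,gamma,tau_y See [teaching_config()].
#' @param dt Euler step in ms.
#' @return `teaching_single()`/`teaching_multi()`: scalar teaching signal.
#'   `teaching_interneuron()`: list with `f` and the updated `y`.
#' @export
teaching_single <- function(zhat, beta = 3) {
  pmax(0, tanh(zhat / beta))
}

#' @rdname teaching_single
#' @export
teaching_multi <- function(zhat_pair, zhat_comp, beta = 3, gamma = 0.5) {
  pmax(0, tanh((zhat_pair - gamma * sum(zhat_comp)) / beta))
}

#' @rdname teaching_single
#' @export
teaching_interneuron <- function(zhat_pair, zhat_comp, y, beta = 3, gamma = 0.5,
                                 dt = 1, tau_y = 10) {
  if (length(y) != length(zhat_comp))
    abort("one interneuron state per competitor is required.",
          class = "dualrc_invalid")
  y <- y + (dt / tau_y) * (-y + zhat_comp)
  list(f = pmax(0, tanh((zhat_pair - gamma * sum(y)) / beta)), y = y)
}

#' One recursive-least-squares update (reference)
#'
#' Standard RLS shared across a module's readouts: with regressor `r` (the
#' rates on the readout subset) and per-readout errors `e = z - f`,
#' `P <- P - (P r r^T P) / (1 + r^T P r)` followed by
#' `w_k <- w_k - e_k P r` with the updated `P`. Initialized at `P = I/alpha`,
#' the recursion reproduces batch ridge regression with penalty `alpha`
#' exactly. `P` stays symmetric positive definite.
#'
#' @param P Inverse-correlation matrix (`n x n`).
#' @param w Readout weights (`n x K`).
#' @param r Regressor vector (length `n`).
#' @param e Error per readout (length `K`).
#' @return List with updated `P` and `w`.
#' @export
rls_update <- function(P, w, r, e) {
  k <- drop(P %*% r)
  cc <- 1 / (1 + sum(r * k))
  P <- P - cc * tcrossprod(k)
  if (!all(is.finite(P)))
    abort("non-finite inverse-correlation matrix (alpha too small?).",
          class = "dualrc_numerical")
  w <- w - outer(k, e) * cc
  list(P = P, w = w)
}

new_engine_state <- function(module, rls, norm_win) {
  K <- module$n_readouts
  n <- length(module$subset)
  list(J = module$J, J_fb = module$J_fb, J_in = module$J_in,
       subset = as.integer(module$subset), w = module$w,
       P = diag(n) / rls$alpha, x = module$x,
       y = numeric(K), z_prev = numeric(K),
       nbuf = matrix(0, norm_win, K), nsum = numeric(K), nsumsq = numeric(K),
       ncount = 0L, npos = 0L)
}

merge_engine_state <- function(st, upd) {
  for (f in names(upd)) st[[f]] <- upd[[f]]
  st
}

engine_opts <- function(params, teaching, rls, learn, norm_win, eps) {
  list(gain = params$gain, tau = params$tau, sigma = params$sigma,
       dt = params$dt, beta = teaching$beta, gamma = teaching$gamma,
       tau_y = teaching$tau_y, eps = eps, learn = learn,
       interneurons = teaching$use_interneurons,
       rls_every = max(1L, round(rls$interval_ms / params$dt)),
       norm_win = as.integer(norm_win))
}

step_summary <- function(step, z, f, w, dt) {
  e <- z - f
  tibble(step = step,
         readout = seq_len(ncol(z)),
         mae = colMeans(abs(e)),
         rmse = sqrt(colMeans(e^2)),
         w_norm = sqrt(colSums(w^2)))
}

step_correlations <- function(step, z, indicator, offset) {
  rows <- (offset + 1L):(offset + nrow(z))
  rows <- rows[rows <= nrow(indicator)]
  zz <- z[seq_along(rows), , drop = FALSE]
  purrr::map_dfr(seq_len(ncol(indicator)), function(ch) {
    ind <- indicator[rows, ch]
    tibble(step = step, readout = seq_len(ncol(zz)), chunk = ch,
           correlation = apply(zz, 2, function(v) {
             if (sd(v) == 0 || sd(ind) == 0) 0 else cor(v, ind)
           }))
  })
}

#' Train a dual system by mutual supervision
#'
#' Runs the full unsupervised training loop: both modules integrate the same
#' drive; each millisecond their readout outputs are normalized by
#' trailing-window moments, each module's teaching signals are built from the
#' partner's normalized outputs of the same tick, and the readout weights are
#' updated by recursive least squares every `rls$interval_ms` against the
#' error `e = z - f`. A washout period precedes learning. Bookkeeping is per
#' learning step of `step_ms` (default 15 s) of simulated time: mean absolute
#' error, RMS error and weight norm per readout, plus windowed Pearson
#' correlations against every annotated chunk when `stream` is supplied.
#'
#' @param system A [dual_system()].
#' @param drive A `drive_trace` from [encode_symbols()] or [encode_images()];
#'   both modules receive it identically. Must cover
#'   `washout_ms + n_steps * step_ms`.
#' @param n_steps Number of learning steps.
#' @param stream Optional [symbol_stream()] the drive encodes, for correlation
#'   logging.
#' @param teaching A [teaching_config()].
#' @param rls An [rls_config()].
#' @param step_ms Learning-step duration in ms.
#' @param washout_ms Washout before learning starts, in ms.
#' @param norm_window Normalizer window in ms.
#' @param eps Normalizer variance floor.
#' @param seed Optional integer seed (noise stream).
#' @return A `dualrc_fit`: the trained system plus `log` and `correlations`
#'   tibbles and the persistent learning state. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
train_dual <- function(system, drive, n_steps, stream = NULL,
                       teaching = teaching_config(), rls = rls_config(),
                       step_ms = 15000, washout_ms = 1000,
                       norm_window = 15000, eps = 1e-6, seed = NULL) {
  p <- system$module1$params
  steps_per_block <- round(step_ms / p$dt)
  washout_steps <- round(washout_ms / p$dt)
  need <- washout_steps + n_steps * steps_per_block
  if (nrow(drive$currents) < need)
    abort(sprintf("drive too short: %d samples needed, %d provided.",
                  need, nrow(drive$currents)), class = "dualrc_invalid")
  norm_win <- as.integer(round(norm_window / p$dt))
  st1 <- new_engine_state(system$module1, rls, norm_win)
  st2 <- new_engine_state(system$module2, rls, norm_win)
  opts_learn <- engine_opts(p, teaching, rls, TRUE, norm_win, eps)
  opts_wash <- engine_opts(p, teaching, rls, FALSE, norm_win, eps)
  indicator <- if (!is.null(stream))
    chunk_indicator(stream, drive$symbol_ms, dt = p$dt) else NULL

  run <- function() {
    logs <- vector("list", n_steps)
    cors <- vector("list", n_steps)
    if (washout_steps > 0) {
      res <- engine_run(st1, st2, drive$currents[seq_len(washout_steps), , drop = FALSE],
                        opts_wash, system$cross12, system$cross21)
      st1 <<- merge_engine_state(st1, res$m1)
      st2 <<- merge_engine_state(st2, res$m2)
    }
    for (s in seq_len(n_steps)) {
      offset <- washout_steps + (s - 1L) * steps_per_block
      block <- drive$currents[(offset + 1L):(offset + steps_per_block), ,
                              drop = FALSE]
      res <- engine_run(st1, st2, block, opts_learn,
                        system$cross12, system$cross21)
      st1 <<- merge_engine_state(st1, res$m1)
      st2 <<- merge_engine_state(st2, res$m2)
      logs[[s]] <- dplyr::bind_rows(
        dplyr::mutate(step_summary(s, res$z1, res$f1, st1$w, p$dt), module = 1L),
        dplyr::mutate(step_summary(s, res$z2, res$f2, st2$w, p$dt), module = 2L))
      if (!is.null(indicator)) {
        cors[[s]] <- dplyr::bind_rows(
          dplyr::mutate(step_correlations(s, res$z1, indicator, offset), module = 1L),
          dplyr::mutate(step_correlations(s, res$z2, indicator, offset), module = 2L))
      }
    }
    list(log = dplyr::bind_rows(logs), correlations = dplyr::bind_rows(cors))
  }
  out <- with_seed_if(seed, run())

  system$module1$w <- st1$w
  system$module1$x <- st1$x
  system$module1$r <- tanh(st1$x)
  system$module2$w <- st2$w
  system$module2$x <- st2$x
  system$module2$r <- tanh(st2$x)
  structure(list(system = system, log = out$log,
                 correlations = out$correlations,
                 state1 = st1, state2 = st2,
                 teaching = teaching, rls = rls, step_ms = step_ms,
                 norm_window = norm_window, eps = eps, seed = seed),
            class = "dualrc_fit")
}

#' @export
print.dualrc_fit <- function(x, ...) {
  n_steps <- max(x$log$step)
  final <- dplyr::filter(x$log, .data$step == n_steps)
  cat("<dualrc_fit> ", n_steps, " learning steps of ", x$step_ms / 1000,
      " s; final mean |e| = ", signif(mean(final$mae), 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained (or untrained) dual system on a drive
#'
#' Freezes the readout weights and runs the full dynamics, feedback and output
#' normalization on a (typically held-out) drive. Normalization statistics
#' keep running during evaluation. Returns the readout traces of both modules
#' and, when `stream` is given, their windowed Pearson correlations with every
#' annotated chunk indicator.
#'
#' @param fit A `dualrc_fit` from [train_dual()], or a [dual_system()] (e.g.
#'   untrained, for pre-learning baselines).
#' @param drive A `drive_trace`.
#' @param stream Optional [symbol_stream()] the drive encodes.
#' @param teaching,rls,norm_window,eps Used only when `fit` is a bare
#'   `dual_system`; a `dualrc_fit` carries its own.
#' @param keep_rates Also return the full reservoir rate trajectories
#'   (`time x n_neurons` per module), needed for selectivity and
#'   principal-component analyses.
#' @param seed Optional integer seed (noise stream).
#' @return A `dualrc_eval`: list with `z` (tibble `time_ms`, `module`,
#'   `readout`, `z`, `f`), `correlations` tibble, and the raw trace matrices.
#' @export
evaluate_dual <- function(fit, drive, stream = NULL,
                          teaching = teaching_config(), rls = rls_config(),
                          norm_window = 15000, eps = 1e-6, keep_rates = FALSE,
                          seed = NULL) {
  if (inherits(fit, "dualrc_fit")) {
    system <- fit$system
    teaching <- fit$teaching
    rls <- fit$rls
    norm_window <- fit$norm_window
    eps <- fit$eps
    st1 <- fit$state1
    st2 <- fit$state2
  } else {
    system <- fit
    p0 <- system$module1$params
    st1 <- new_engine_state(system$module1, rls, round(norm_window / p0$dt))
    st2 <- new_engine_state(system$module2, rls, round(norm_window / p0$dt))
  }
  p <- system$module1$params
  opts <- engine_opts(p, teaching, rls, FALSE,
                      as.integer(round(norm_window / p$dt)), eps)
  opts$keep_rates <- keep_rates
  res <- with_seed_if(seed,
    engine_run(st1, st2, drive$currents, opts, system$cross12, system$cross21))
  K <- ncol(res$z1)
  T_n <- nrow(res$z1)
  z_tbl <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(K), function(k)
      tibble(module = 1L, readout = k, time_ms = (seq_len(T_n) - 1) * p$dt,
             z = res$z1[, k], f = res$f1[, k])),
    purrr::map_dfr(seq_len(K), function(k)
      tibble(module = 2L, readout = k, time_ms = (seq_len(T_n) - 1) * p$dt,
             z = res$z2[, k], f = res$f2[, k])))
  correlations <- NULL
  if (!is.null(stream)) {
    indicator <- chunk_indicator(stream, drive$symbol_ms, dt = p$dt)
    correlations <- dplyr::bind_rows(
      dplyr::mutate(step_correlations(1L, res$z1, indicator, 0L), module = 1L),
      dplyr::mutate(step_correlations(1L, res$z2, indicator, 0L), module = 2L))
    correlations$step <- NULL
  }
  structure(list(z = z_tbl, correlations = correlations,
                 z1 = res$z1, z2 = res$z2, f1 = res$f1, f2 = res$f2,
                 rates1 = res$rates1, rates2 = res$rates2,
                 subset1 = system$module1$subset,
                 subset2 = system$module2$subset,
                 w1 = system$module1$w, w2 = system$module2$w,
                 dt = p$dt, symbol_ms = drive$symbol_ms),
            class = "dualrc_eval")
}

#' @export
print.dualrc_eval <- function(x, ...) {
  cat("<dualrc_eval> ", nrow(x$z1), " samples, ", ncol(x$z1),
      " readout(s) per module\n", sep = "")
  invisible(x)
}
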