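# Pure-R mirror of the compiled training loop (src/engine.cpp), used as the
# independent route in the engine-equivalence tests. Follows the identical
# update order, including the order of RNG draws, so results must agree to
# floating-point noise.
ref_engine_run <- function(st1, st2, drive, opts, cross12 = NULL,
                           cross21 = NULL) {
  K <- ncol(st1$w)
  N <- length(st1$x)
  a <- opts$dt / opts$tau
  ns <- opts$sigma * sqrt(opts$dt / opts$tau)
  T_n <- nrow(drive)

  norm_push <- function(st, z) {
    if (st$ncount == norm_len) {
      old <- st$nbuf[st$npos + 1L, ]
      st$nsum <- st$nsum + z - old
      st$nsumsq <- st$nsumsq + z^2 - old^2
    } else {
      st$nsum <- st$nsum + z
      st$nsumsq <- st$nsumsq + z^2
      st$ncount <- st$ncount + 1L
    }
    st$nbuf[st$npos + 1L, ] <- z
    st$npos <- (st$npos + 1L) %% norm_len
    mu <- st$nsum / st$ncount
    sdv <- pmax(sqrt(pmax(st$nsumsq / st$ncount - mu^2, 0)), opts$eps)
    list(st = st, zhat = (z - mu) / sdv)
  }
  teach <- function(zhat_partner, comp) {
    if (K == 1) return(pmax(0, tanh(zhat_partner / opts$beta)))
    pmax(0, tanh((zhat_partner - opts$gamma * (sum(comp) - comp)) / opts$beta))
  }
  norm_len <- opts$norm_win
  r1 <- tanh(st1$x); r2 <- tanh(st2$x)
  z1 <- matrix(0, T_n, K); z2 <- z1; f1 <- z1; f2 <- z1
  for (t in seq_len(T_n)) {
    u <- drive[t, ]
    I1 <- drop(st1$J_in %*% u)
    I2 <- drop(st2$J_in %*% u)
    if (!is.null(cross12)) {
      I1 <- I1 + opts$gain * drop(cross12 %*% r2)
      I2 <- I2 + opts$gain * drop(cross21 %*% r1)
    }
    d1 <- -st1$x + opts$gain * drop(st1$J %*% r1) +
      drop(st1$J_fb %*% st1$z_prev) + I1
    d2 <- -st2$x + opts$gain * drop(st2$J %*% r2) +
      drop(st2$J_fb %*% st2$z_prev) + I2
    if (opts$sigma > 0) {
      st1$x <- st1$x + a * d1 + ns * rnorm(N)
      st2$x <- st2$x + a * d2 + ns * rnorm(N)
    } else {
      st1$x <- st1$x + a * d1
      st2$x <- st2$x + a * d2
    }
    r1 <- tanh(st1$x); r2 <- tanh(st2$x)
    zz1 <- drop(crossprod(st1$w, r1[st1$subset]))
    zz2 <- drop(crossprod(st2$w, r2[st2$subset]))
    p1 <- norm_push(st1, zz1); st1 <- p1$st
    p2 <- norm_push(st2, zz2); st2 <- p2$st
    st1$y <- st1$y + (opts$dt / opts$tau_y) * (-st1$y + p1$zhat)
    st2$y <- st2$y + (opts$dt / opts$tau_y) * (-st2$y + p2$zhat)
    ff1 <- teach(p2$zhat, if (opts$interneurons) st2$y else p2$zhat)
    ff2 <- teach(p1$zhat, if (opts$interneurons) st1$y else p1$zhat)
    z1[t, ] <- zz1; z2[t, ] <- zz2
    f1[t, ] <- ff1; f2[t, ] <- ff2
    if (opts$learn && t %% opts$rls_every == 0) {
      for (side in 1:2) {
        st <- if (side == 1) st1 else st2
        e <- if (side == 1) zz1 - ff1 else zz2 - ff2
        rs <- (if (side == 1) r1 else r2)[st$subset]
        k <- drop(st$P %*% rs)
        cc <- 1 / (1 + sum(rs * k))
        st$P <- st$P - cc * tcrossprod(k)
        st$w <- st$w - outer(k, e) * cc
        if (side == 1) st1 <- st else st2 <- st
      }
    }
    st1$z_prev <- zz1
    st2$z_prev <- zz2
  }
  list(st1 = st1, st2 = st2, z1 = z1, z2 = z2, f1 = f1, f2 = f2)
}

tiny_engine_setup <- function(N = 8, K = 3, n_input = 5, sigma = 0.3,
                              seed = 42, norm_win = 60) {
  p <- reservoir_params(n_neurons = N, sigma = sigma, p_connect = 1)
  sys <- dual_system(p, n_readouts = K, n_input = n_input, seed = seed)
  st1 <- dualrc:::new_engine_state(sys$module1, rls_config(), norm_win)
  st2 <- dualrc:::new_engine_state(sys$module2, rls_config(), norm_win)
  list(params = p, sys = sys, st1 = st1, st2 = st2)
}

# shared cache so expensive acceptance simulations are computed once and
# reused by several criteria
acceptance_cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = acceptance_cache))
    assign(key, compute(), envir = acceptance_cache)
  get(key, envir = acceptance_cache)
}

# one single-chunk training/evaluation run; returns pre/post headline
# correlations and the objects needed by the weight/selectivity criteria
single_chunk_run <- function(seed, n_neurons = 200, sigma = 0.3, n_steps = 8,
                             fan_in = NULL, keep_rates = FALSE,
                             eval_ms = 30000) {
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 6L))
  params <- reservoir_params(n_neurons, sigma = sigma)
  train_ms <- 1000 + n_steps * 15000
  st_train <- stream_single_chunk(n_repeats = ceiling(train_ms / 200 / 9) + 3,
                                  seed = seeds[1])
  st_eval <- stream_single_chunk(n_repeats = ceiling(eval_ms / 200 / 9) + 3,
                                 seed = seeds[3])
  dr_train <- encode_symbols(st_train)
  dr_eval <- encode_symbols(st_eval)
  sys <- dual_system(params, n_input = 26, fan_in = fan_in, seed = seeds[5])
  pre <- evaluate_dual(sys, dr_eval, st_eval, seed = seeds[6])
  fit <- train_dual(sys, dr_train, n_steps, stream = st_train, seed = seeds[2])
  post <- evaluate_dual(fit, dr_eval, st_eval, keep_rates = keep_rates,
                        seed = seeds[6])
  list(pre = mean(pre$correlations$correlation),
       post = mean(post$correlations$correlation),
       post_eval = post, stream_eval = st_eval, fit = fit)
}
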