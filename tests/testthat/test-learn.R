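test_that("trailing-window normalization matches closed forms", {
  # constant trace: variance floored, normalized output is 0
  expect_equal(normalize_trace(rep(3, 500), window = 100), rep(0, 500))

  # full-window sinusoid: mean 0, SD 1/sqrt(2), so zhat = sqrt(2) sin
  T_w <- 2000
  t_s <- seq_len(T_w)
  z <- sin(2 * pi * t_s / T_w)
  zh <- normalize_trace(z, window = T_w)
  expect_equal(zh[T_w], sqrt(2) * sin(2 * pi), tolerance = 1e-2)
  # check a quarter period after a full window has accumulated
  z2 <- sin(2 * pi * seq_len(2 * T_w) / T_w)
  zh2 <- normalize_trace(z2, window = T_w)
  expect_equal(zh2[T_w + T_w / 4], sqrt(2), tolerance = 1e-2)

  # linear ramp on [0, T]: mean T/2, SD T/sqrt(12)
  T_r <- 6000
  zr <- seq_len(T_r)
  zhr <- normalize_trace(zr, window = T_r)
  mu <- mean(zr); sdv <- sqrt(mean((zr - mu)^2))
  expect_equal(mu, T_r / 2, tolerance = 1e-3 * T_r)
  expect_equal(sdv, T_r / sqrt(12), tolerance = 1e-3 * T_r)
  expect_equal(zhr[T_r], (T_r - mu) / sdv, tolerance = 1e-9)
})

test_that("teaching signals rectify, compete and stay in [0, 1)", {
  expect_equal(teaching_single(0), 0)
  expect_equal(teaching_single(-5), 0)
  expect_equal(teaching_single(3, beta = 3), tanh(1))

  # perfect competition cancellation with three equal outputs and gamma 1/2
  expect_equal(teaching_multi(2, c(2, 2), beta = 3, gamma = 0.5), 0)
  expect_equal(teaching_multi(3, c(0, 0), beta = 3), tanh(1))
  # permutation symmetry
  zh <- c(0.9, -0.3, 0.5)
  f <- vapply(1:3, function(k) teaching_multi(zh[k], zh[-k]), numeric(1))
  perm <- c(3, 1, 2)
  fp <- vapply(1:3, function(k) teaching_multi(zh[perm][k], zh[perm][-k]),
               numeric(1))
  expect_equal(fp, f[perm])

  # boundedness under fuzzing
  withr::with_seed(1, {
    for (i in 1:200) {
      zz <- rnorm(3, sd = 10)
      expect_true(teaching_multi(zz[1], zz[-1]) >= 0)
      expect_true(teaching_multi(zz[1], zz[-1]) < 1)
      expect_true(teaching_single(zz[1]) >= 0 && teaching_single(zz[1]) < 1)
    }
  })
})

test_that("interneuron teaching relaxes to the instantaneous rule", {
  # one Euler step from rest
  out <- teaching_interneuron(0, zhat_comp = 1, y = 0, dt = 1, tau_y = 10)
  expect_equal(out$y, 0.1)

  # held constant, the interneurons converge and f matches teaching_multi
  y <- c(0, 0)
  comp <- c(0.4, -0.2)
  for (t in 1:2000) {
    out <- teaching_interneuron(1.2, comp, y, dt = 1, tau_y = 10)
    y <- out$y
  }
  expect_equal(out$f, teaching_multi(1.2, comp), tolerance = 1e-8)

  # gamma 0 makes competition irrelevant
  expect_equal(teaching_interneuron(0.7, comp, y, gamma = 0)$f,
               teaching_single(0.7))
  expect_error(teaching_interneuron(1, c(1, 2), y = 0),
               class = "dualrc_invalid")
})

test_that("recursive least squares reproduces batch ridge regression", {
  withr::with_seed(11, {
    for (trial in 1:5) {
      n <- sample(2:6, 1)
      K <- sample(1:3, 1)
      m <- sample(3:12, 1)
      alpha <- sample(c(1, 10, 100), 1)
      R <- matrix(rnorm(n * m), n, m)
      f <- matrix(rnorm(m * K), m, K)
      P <- diag(n) / alpha
      w <- matrix(0, n, K)
      for (i in seq_len(m)) {
        e <- drop(crossprod(w, R[, i])) - f[i, ]
        u <- rls_update(P, w, R[, i], e)
        P <- u$P; w <- u$w
      }
      ridge <- solve(R %*% t(R) + alpha * diag(n)) %*% (R %*% f)
      expect_equal(w, ridge, tolerance = 1e-8, ignore_attr = TRUE)
      expect_lt(max(abs(P - t(P))), 1e-10)
      expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
  # zero error leaves the weights untouched
  P <- diag(3); w <- matrix(1:6 / 10, 3, 2)
  u <- rls_update(P, w, c(1, 2, 3), c(0, 0))
  expect_equal(u$w, w)
})

test_that("the compiled engine matches the pure-R reference loop", {
  for (cfg in list(list(sigma = 0, inter = FALSE, K = 1),
                   list(sigma = 0.3, inter = FALSE, K = 3),
                   list(sigma = 0.3, inter = TRUE, K = 3))) {
    setup <- tiny_engine_setup(N = 8, K = cfg$K, sigma = cfg$sigma, seed = 21)
    drive <- withr::with_seed(2, matrix(runif(120 * 5, 0, 0.5), 120, 5))
    opts <- dualrc:::engine_opts(setup$params,
                                 teaching_config(use_interneurons = cfg$inter),
                                 rls_config(), TRUE, 60L, 1e-6)
    res_c <- withr::with_seed(33,
      dualrc:::engine_run(setup$st1, setup$st2, drive, opts, NULL, NULL))
    res_r <- withr::with_seed(33,
      ref_engine_run(setup$st1, setup$st2, drive, opts))
    expect_equal(res_c$z1, res_r$z1, tolerance = 1e-10)
    expect_equal(res_c$f2, res_r$f2, tolerance = 1e-10)
    expect_equal(res_c$m1$w, res_r$st1$w, tolerance = 1e-10)
    expect_equal(res_c$m2$P, res_r$st2$P, tolerance = 1e-8)
    expect_equal(drop(res_c$m1$x), res_r$st1$x, tolerance = 1e-10)
  }
})

test_that("the engine matches the reference with cross-coupled reservoirs", {
  setup <- tiny_engine_setup(N = 8, K = 1, sigma = 0.2, seed = 22)
  sys <- couple_reservoirs(setup$sys, 0.3, seed = 5)
  st1 <- dualrc:::new_engine_state(sys$module1, rls_config(), 60L)
  st2 <- dualrc:::new_engine_state(sys$module2, rls_config(), 60L)
  drive <- withr::with_seed(3, matrix(runif(100 * 5, 0, 0.5), 100, 5))
  opts <- dualrc:::engine_opts(setup$params, teaching_config(), rls_config(),
                               TRUE, 60L, 1e-6)
  res_c <- withr::with_seed(44,
    dualrc:::engine_run(st1, st2, drive, opts, sys$cross12, sys$cross21))
  res_r <- withr::with_seed(44,
    ref_engine_run(st1, st2, drive, opts, sys$cross12, sys$cross21))
  expect_equal(res_c$z1, res_r$z1, tolerance = 1e-10)
  expect_equal(res_c$m2$w, res_r$st2$w, tolerance = 1e-10)
})

test_that("training and evaluation are deterministic and swap-symmetric", {
  p <- reservoir_params(n_neurons = 30, sigma = 0.2)
  st <- stream_single_chunk(n_repeats = 15, seed = 2)
  dr <- encode_symbols(st)
  dr$currents <- dr$currents[1:16000, , drop = FALSE]
  sys <- dual_system(p, n_input = 26, seed = 9)
  fit1 <- train_dual(sys, dr, 1, stream = st, seed = 5)
  fit2 <- train_dual(sys, dr, 1, stream = st, seed = 5)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$correlations, fit2$correlations)

  ev1 <- evaluate_dual(fit1, dr, st, seed = 3)
  ev2 <- evaluate_dual(fit1, dr, st, seed = 3)
  expect_identical(ev1$z1, ev2$z1)
  # frozen weights: evaluation does not change the fit
  expect_identical(fit1$system$module1$w, fit2$system$module1$w)

  # with sigma = 0 the two module slots are exchangeable: swapping the module
  # wiring swaps the logged roles exactly
  p0 <- reservoir_params(n_neurons = 20, sigma = 0)
  sys_ab <- dual_system(p0, n_input = 26, seed = 11)
  sys_ba <- sys_ab
  sys_ba$module1 <- sys_ab$module2
  sys_ba$module2 <- sys_ab$module1
  fa <- train_dual(sys_ab, dr, 1, stream = st, seed = 4)
  fb <- train_dual(sys_ba, dr, 1, stream = st, seed = 4)
  expect_equal(dplyr::filter(fa$log, module == 1)$mae,
               dplyr::filter(fb$log, module == 2)$mae, tolerance = 1e-12)
  expect_equal(dplyr::filter(fa$log, module == 2)$w_norm,
               dplyr::filter(fb$log, module == 1)$w_norm, tolerance = 1e-12)
})
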