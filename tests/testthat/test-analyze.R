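make_annotated_stream <- function() {
  # fixed stream: chunk 0:3 at symbol positions 2 and 12, fillers elsewhere
  symbols <- c(5L, 6L, 0:3, 7L, 8L, 9L, 10L, 11L, 12L, 0:3, 13L, 14L)
  ann <- tibble::tibble(chunk = c(1L, 1L), start = c(2L, 12L), end = c(6L, 16L))
  symbol_stream(symbols, 26L, ann, chunks = list(0:3))
}

test_that("chunk correlation matches Pearson on indicator-like traces", {
  st <- make_annotated_stream()
  ind <- chunk_indicator(st, symbol_ms = 200)
  cc <- chunk_correlation(ind[, 1], st)
  expect_equal(cc$correlation, 1)
  cc_neg <- chunk_correlation(1 - ind[, 1], st)
  expect_equal(cc_neg$correlation, -1)

  # linear ramp from 0 to 1 inside each chunk, 0 outside: brute-force oracle
  z <- numeric(nrow(ind))
  for (i in seq_len(nrow(st$annotations))) {
    rows <- (st$annotations$start[i] * 200 + 1):(st$annotations$end[i] * 200)
    z[rows] <- seq(0, 1, length.out = length(rows))
  }
  cc_ramp <- chunk_correlation(z, st)
  oracle <- {
    x <- z; y <- ind[, 1]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc_ramp$correlation, oracle, tolerance = 1e-12)

  # Pearson is invariant to affine rescaling of the trace
  expect_equal(chunk_correlation(3 * z + 2, st)$correlation,
               cc_ramp$correlation, tolerance = 1e-12)

  flat <- chunk_correlation(rep(1, nrow(ind)), st)
  expect_equal(flat$correlation, 0)
  expect_true(flat$degenerate)
})

test_that("readout assignment is greedy with documented tie-breaks", {
  m <- matrix(0.1, 3, 3)
  diag(m) <- 0.4
  asg <- assign_readouts(m)
  expect_equal(asg$chunk, 1:3)

  tie <- matrix(c(0.5, 0.5, 0.2, 0.1), 2, 2)
  expect_equal(assign_readouts(tie)$chunk, c(1L, 2L))

  # extra readouts stay unassigned
  extra <- assign_readouts(matrix(c(0.9, 0.1, 0.1), 3, 1))
  expect_equal(extra$chunk, c(1L, NA, NA))
  expect_error(assign_readouts(matrix(0, 1, 2)), class = "dualrc_invalid")

  # against exhaustive search over all 6 permutations: greedy never exceeds
  # the optimum, and on selectivity-structured matrices (a dominant
  # readout-per-chunk correlation, as after successful learning) it attains
  # the optimum in at least 95% of draws
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  wins <- withr::with_seed(13, vapply(1:200, function(i) {
    m <- matrix(runif(9, 0, 0.15), 3, 3)
    m[cbind(sample(3), 1:3)] <- runif(3, 0.3, 0.5)
    asg <- assign_readouts(m)
    total <- sum(asg$correlation)
    best <- max(apply(perms, 1, function(p) sum(m[cbind(1:3, p)])))
    expect_lte(total, best + 1e-12)
    total >= best - 1e-12
  }, logical(1)))
  expect_gte(mean(wins), 0.95)
})

test_that("trial averaging recovers repeated responses and averages noise", {
  resp <- sin(seq(0, pi, length.out = 301))
  trace <- rep(0, 5000)
  onsets <- c(500, 1500, 2500, 3500)
  for (o in onsets) trace[o + 1:301] <- resp
  ta <- trial_average(trace, onsets, pre_ms = 0, post_ms = 300)
  expect_equal(drop(ta$mean), resp, tolerance = 1e-12)

  withr::with_seed(5, {
    onsets_many <- seq(100, 99100, by = 1000)
    noisy <- rep(0, 100500)
    for (o in onsets_many) noisy[o + 1:301] <- resp
    noisy <- noisy + rnorm(length(noisy), sd = 0.5)
    tan <- trial_average(noisy, onsets_many, pre_ms = 0, post_ms = 300)
    expect_true(all(abs(drop(tan$mean) - resp) < 4 * 0.5 / 10))
  })

  expect_error(trial_average(trace, 500, 0, 300), class = "dualrc_invalid")
  expect_warning(trial_average(trace, c(50, 1500, 2500), pre_ms = 100,
                               post_ms = 300),
                 class = "dualrc_truncated_window")
})

test_that("activation phase maps point masses to their own time", {
  r <- matrix(0, 2400, 1)
  r[601, 1] <- 1              # sample 601 is t = 600 ms
  expect_equal(activation_phase(r, 2400), 600)

  expect_warning(ph <- activation_phase(matrix(1, 2400, 1), 2400),
                 class = "dualrc_undefined_phase")
  expect_true(is.na(ph))
  anti <- matrix(0, 2400, 1)
  anti[c(101, 1301), 1] <- 1   # t0 and t0 + period/2 cancel exactly
  expect_warning(expect_true(is.na(activation_phase(anti, 2400))),
                 class = "dualrc_undefined_phase")

  # sorting by phase recovers a planted sequential activation order
  withr::with_seed(8, {
    n <- 30
    order_true <- sample(n)
    r <- matrix(0, 2400, n)
    for (j in seq_len(n)) {
      t0 <- 40 + (order_true[j] - 1) * 70
      r[t0 + 0:30, j] <- dnorm(0:30, 15, 6)
    }
    ph <- activation_phase(r, 2400)
    expect_equal(order(order(ph)), order_true)
  })
})

test_that("selectivity classification follows the 3-SD / 100-ms rule", {
  win <- tibble::tibble(chunk = 1:2, start_ms = c(400, 1600),
                        end_ms = c(1200, 2400))
  base <- withr::with_seed(3, matrix(abs(rnorm(2400 * 4, 0.1, 0.01)), 2400, 4))
  rates <- base
  rates[601:800, 1] <- 1           # 200 ms burst inside chunk 1
  rates[641:690, 2] <- 1           # only 50 ms: too brief
  rates[c(601:705, 1801:1905), 3] <- 1   # ~105-ms bursts in both chunk windows
  sel <- classify_selectivity(rates, win)
  expect_equal(sel$label, c("1", "none", "multiple", "none"))
  expect_equal(sel$chunk, c(1L, NA, NA, NA))

  # no suprathreshold excursions anywhere: every neuron is "none"
  flatish <- withr::with_seed(4, matrix(abs(rnorm(2400 * 5, 0.5, 0.05)), 2400, 5))
  expect_true(all(classify_selectivity(flatish, win)$label == "none"))
})

test_that("PC reconstruction errors match a dense eigendecomposition oracle", {
  withr::with_seed(6, {
    T_n <- 400
    rates <- cbind(sin(1:T_n / 20), cos(1:T_n / 35), rnorm(T_n, sd = 0.3))
    w <- c(0.8, -0.4, 0.2)
    z <- drop(rates %*% w) + rnorm(T_n, sd = 0.05)
    z2 <- drop(rates %*% rev(w))
    rep_ <- pca_report(rates, w, z, z_partner = z2)

    # oracle: direct dense eigendecomposition and explicit projections
    rc <- scale(rates, center = TRUE, scale = FALSE)
    C <- crossprod(rc) / (T_n - 1)
    eg <- eigen(C, symmetric = TRUE)
    expect_equal(rep_$eigenvalues, pmax(eg$values, 0), tolerance = 1e-10)
    zc <- z - mean(z)
    for (M in 1:3) {
      V <- rep_$vectors[, 1:M, drop = FALSE]
      recon <- drop(rc %*% V %*% crossprod(V, w))
      expect_equal(rep_$curves$e_within[M], mean((zc - recon)^2),
                   tolerance = 1e-10)
    }
    # complete basis reconstructs the centered output exactly
    expect_equal(rep_$curves$e_within[3],
                 mean((zc - drop(rc %*% w))^2), tolerance = 1e-10)
    # nested subspaces: the within-self curve is non-increasing
    expect_true(all(diff(rep_$curves$e_within) <= 1e-12))
    # eigenvalue sum equals the total rate variance
    expect_equal(sum(rep_$eigenvalues), rep_$total_variance,
                 tolerance = 1e-8 * rep_$total_variance)
    # orientation: correlations with the readout are nonnegative
    expect_true(all(rep_$pc_stats$cor_readout >= -1e-12))
  })
})

test_that("within-self reconstruction vanishes when z is exactly linear in rates", {
  withr::with_seed(7, {
    rates <- matrix(rnorm(200 * 5), 200, 5)
    w <- rnorm(5)
    z <- drop(rates %*% w)
    rep_ <- pca_report(rates, w, z)
    expect_lt(rep_$curves$e_within[5], 1e-20 * var(z))
  })
})

test_that("strong-weight statistics use the pooled-SD threshold", {
  ws <- weight_stats(c(0, 0, 0, 10), labels = c("none", "none", "none", "1"))
  expect_equal(ws$summary$threshold, sqrt(75 / 4), tolerance = 1e-12)
  expect_equal(ws$summary$n_strong, 1)
  expect_equal(ws$summary$fraction_encoding, 1)

  same <- weight_stats(rep(0.3, 6), labels = rep("none", 6))
  expect_true(same$summary$degenerate)
  expect_equal(same$summary$fraction_encoding, 0)

  withr::with_seed(9, {
    for (i in 1:50) {
      w <- rnorm(30)
      lab <- sample(c("1", "2", "none", "multiple"), 30, replace = TRUE)
      frac <- weight_stats(w, lab)$summary$fraction_encoding
      expect_true(frac >= 0 && frac <= 1)
    }
  })
})
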