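#' Chunk indicator traces
#'
#' Builds the 0/1 reference patterns used by the performance metric: one
#' column per chunk id, equal to 1 while that chunk (or community) is being
#' presented and 0 otherwise, sampled every `dt` ms with one symbol per
#' `symbol_ms`.
#'
#' @param stream A [symbol_stream()] with annotations.
#' @param symbol_ms Symbol slot duration in ms.
#' @param dt Sampling step in ms.
#' @return A `T x n_chunks` matrix.
#' @export
chunk_indicator <- function(stream, symbol_ms = 200, dt = 1) {
  steps <- round(symbol_ms / dt)
  T_n <- length(stream$symbols) * steps
  n_chunks <- if (nrow(stream$annotations)) max(stream$annotations$chunk) else 0L
  ind <- matrix(0, T_n, max(n_chunks, 1L))
  for (i in seq_len(nrow(stream$annotations))) {
    a <- stream$annotations[i, ]
    ind[(a$start * steps + 1L):(a$end * steps), a$chunk] <- 1
  }
  ind
}

pearson_or_zero <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(c(0, TRUE))
  c(cor(x, y), FALSE)
}

#' Instantaneous correlation between readout traces and chunk indicators
#'
#' The chunk-detection performance metric: the Pearson correlation, over
#' windows of `window_ms` (default one 15-s learning step; `NULL` for the
#' whole trace), between a readout trace and the 0/1 indicator of each chunk.
#' Zero-variance traces or indicators yield correlation 0 with a degenerate
#' flag.
#'
#' @param z Numeric vector or `T x K` matrix of readout traces.
#' @param stream A [symbol_stream()] with annotations.
#' @param symbol_ms,dt Timing of the encoding.
#' @param window_ms Window length in ms, or `NULL` for a single window.
#' @return Tibble with columns `window`, `readout`, `chunk`, `correlation`,
#'   `degenerate`.
#' @export
chunk_correlation <- function(z, stream, symbol_ms = 200, dt = 1,
                              window_ms = NULL) {
  z <- as.matrix(z)
  ind <- chunk_indicator(stream, symbol_ms, dt)
  T_n <- min(nrow(z), nrow(ind))
  win <- if (is.null(window_ms)) T_n else round(window_ms / dt)
  n_win <- max(1L, floor(T_n / win))
  purrr::map_dfr(seq_len(n_win), function(wi) {
    rows <- ((wi - 1L) * win + 1L):min(wi * win, T_n)
    purrr::map_dfr(seq_len(ncol(z)), function(k) {
      purrr::map_dfr(seq_len(ncol(ind)), function(ch) {
        pc <- pearson_or_zero(z[rows, k], ind[rows, ch])
        tibble(window = wi, readout = k, chunk = ch,
               correlation = pc[1], degenerate = as.logical(pc[2]))
      })
    })
  })
}

#' Assign readouts to chunks by greedy maximum correlation
#'
#' Repeatedly picks the largest entry of the readout-by-chunk correlation
#' matrix and assigns that readout to that chunk, removing both from further
#' consideration; exact ties are broken toward the lower readout index, then
#' the lower chunk index. Readouts left over once every chunk is assigned get
#' `NA`.
#'
#' @param cor_matrix Numeric matrix, readouts in rows, chunks in columns.
#' @return Tibble with columns `readout`, `chunk`, `correlation`.
#' @export
assign_readouts <- function(cor_matrix) {
  cor_matrix <- as.matrix(cor_matrix)
  n_r <- nrow(cor_matrix); n_c <- ncol(cor_matrix)
  if (n_r < n_c)
    abort("need at least as many readouts as chunks.", class = "dualrc_invalid")
  avail_r <- rep(TRUE, n_r); avail_c <- rep(TRUE, n_c)
  out <- tibble(readout = seq_len(n_r), chunk = NA_integer_,
                correlation = NA_real_)
  for (i in seq_len(min(n_r, n_c))) {
    sub <- cor_matrix
    sub[!avail_r, ] <- -Inf
    sub[, !avail_c] <- -Inf
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    rr <- hits[1, 1]; cc <- hits[1, 2]
    out$chunk[rr] <- cc
    out$correlation[rr] <- cor_matrix[rr, cc]
    avail_r[rr] <- FALSE; avail_c[cc] <- FALSE
  }
  out
}

#' Trial-averaged response around chunk onsets
#'
#' Aligns windows `[-pre_ms, +post_ms]` at the given onset times and averages
#' them. Works for a single readout trace or a `time x units` matrix of
#' reservoir rates; each unit can optionally be normalized by its maximum
#' average activity. Windows that would extend past the trace bounds are
#' dropped with a warning.
#'
#' @param trace Numeric vector or `time x units` matrix (1 sample per `dt`).
#' @param onsets_ms Onset times in ms; at least 2 (within bounds) required.
#' @param pre_ms,post_ms Window margins around each onset, in ms.
#' @param dt Sampling step in ms.
#' @param normalize Divide each unit's average by its maximum?
#' @return A `trial_average`: list with `lag_ms`, `mean` (window x units
#'   matrix) and `n_trials`.
#' @export
trial_average <- function(trace, onsets_ms, pre_ms = 400, post_ms = 1200,
                          dt = 1, normalize = FALSE) {
  trace <- as.matrix(trace)
  pre <- round(pre_ms / dt); post <- round(post_ms / dt)
  on_idx <- round(onsets_ms / dt) + 1L
  ok <- on_idx - pre >= 1L & on_idx + post <= nrow(trace)
  if (any(!ok))
    warn(sprintf("%d window(s) truncated by trace bounds were dropped.",
                 sum(!ok)), class = "dualrc_truncated_window")
  on_idx <- on_idx[ok]
  if (length(on_idx) < 2L)
    abort("need at least 2 in-bounds onsets.", class = "dualrc_invalid")
  lags <- seq.int(-pre, post)
  acc <- matrix(0, length(lags), ncol(trace))
  for (o in on_idx) acc <- acc + trace[o + lags, , drop = FALSE]
  m <- acc / length(on_idx)
  if (normalize) {
    mx <- apply(m, 2, max)
    m <- sweep(m, 2, pmax(mx, 1e-12), "/")
  }
  structure(list(lag_ms = lags * dt, mean = m, n_trials = length(on_idx)),
            class = "trial_average")
}

#' @export
print.trial_average <- function(x, ...) {
  cat("<trial_average> ", nrow(x$mean), " samples x ", ncol(x$mean),
      " unit(s), ", x$n_trials, " trials\n", sep = "")
  invisible(x)
}

#' @rdname trial_average
#' @param x A `trial_average`.
#' @param ... Unused.
#' @export
tidy.trial_average <- function(x, ...) {
  purrr::map_dfr(seq_len(ncol(x$mean)), function(u)
    tibble(unit = u, lag_ms = x$lag_ms, value = x$mean[, u]))
}

#' Mean activation phase of neurons over a periodic window
#'
#' Circular mean of each neuron's (nonnegative) average activity over a window
#' of length `period_ms`: `that = period/(2 pi) * Arg(sum_t r(t) exp(i 2 pi
#' t / period))`, mapped to `[0, period)`, so a point mass at `t0` returns
#' `t0`. A zero resultant vector (e.g. uniform activity, or two equal
#' antipodal peaks) has no defined phase and yields `NA` with a warning.
#'
#' @param rbar Numeric vector (one neuron) or `time x neurons` matrix of
#'   nonnegative mean rates covering exactly one period.
#' @param period_ms Sorting window length in ms (default 2400).
#' @param dt Sampling step in ms.
#' @return Numeric vector of phases in ms, one per neuron (`NA` = undefined).
#' @export
activation_phase <- function(rbar, period_ms = 2400, dt = 1) {
  rbar <- as.matrix(rbar)
  if (any(rbar < 0)) abort("`rbar` must be nonnegative.", class = "dualrc_invalid")
  t_ms <- (seq_len(nrow(rbar)) - 1) * dt
  ph <- exp(2i * pi * t_ms / period_ms)
  out <- vapply(seq_len(ncol(rbar)), function(j) {
    tot <- sum(rbar[, j])
    if (tot == 0) return(NA_real_)
    res <- sum(rbar[, j] * ph)
    if (Mod(res) / tot < 1e-9) return(NA_real_)
    (period_ms / (2 * pi)) * (Arg(res) %% (2 * pi))
  }, numeric(1))
  if (anyNA(out))
    warn("some neurons have an undefined activation phase (zero resultant).",
         class = "dualrc_undefined_phase")
  out
}

#' Classify reservoir neurons by phasic chunk selectivity
#'
#' A neuron is phasic for a chunk when its (trial-averaged) activity exceeds
#' its own mean + `threshold_sd` standard deviations — both computed over the
#' full presentation period — continuously for more than `min_ms` within that
#' chunk's window. Neurons phasic for exactly one chunk are labelled with it;
#' neurons responding to no chunk are labelled `"none"` and to several
#' `"multiple"` (the latter are conventionally excluded from ensemble
#' statistics).
#'
#' @param rates `time x neurons` matrix of (trial-averaged) rates.
#' @param chunk_windows Tibble with columns `chunk`, `start_ms`, `end_ms`
#'   (e.g. from [chunk_windows()]), on the same time axis as `rates`.
#' @param dt Sampling step in ms.
#' @param threshold_sd Threshold in SDs above the mean (default 3).
#' @param min_ms Minimum continuous suprathreshold duration (default 100 ms;
#'   strict inequality).
#' @return Tibble with columns `neuron`, `chunk` (`NA` unless uniquely
#'   selective) and `label` (`"none"`, `"multiple"`, or the chunk id as
#'   character).
#' @export
classify_selectivity <- function(rates, chunk_windows, dt = 1,
                                 threshold_sd = 3, min_ms = 100) {
  rates <- as.matrix(rates)
  mu <- colMeans(rates)
  sdv <- apply(rates, 2, sd)
  thr <- mu + threshold_sd * sdv
  min_steps <- min_ms / dt
  purrr::map_dfr(seq_len(ncol(rates)), function(j) {
    above <- rates[, j] > thr[j]
    hits <- integer()
    for (i in seq_len(nrow(chunk_windows))) {
      rows <- (round(chunk_windows$start_ms[i] / dt) + 1L):
        min(round(chunk_windows$end_ms[i] / dt), nrow(rates))
      runs <- rle(above[rows])
      if (any(runs$values & runs$lengths * dt > min_ms))
        hits <- c(hits, chunk_windows$chunk[i])
    }
    hits <- unique(hits)
    if (length(hits) == 0L)
      tibble(neuron = j, chunk = NA_integer_, label = "none")
    else if (length(hits) == 1L)
      tibble(neuron = j, chunk = as.integer(hits), label = as.character(hits))
    else
      tibble(neuron = j, chunk = NA_integer_, label = "multiple")
  })
}

#' Chunk presentation windows in ms
#'
#' Converts a stream's symbol-level annotations into millisecond windows.
#'
#' @param stream A [symbol_stream()].
#' @param symbol_ms Symbol slot duration in ms.
#' @return Tibble with columns `chunk`, `occurrence`, `start_ms`, `end_ms`.
#' @export
chunk_windows <- function(stream, symbol_ms = 200) {
  a <- stream$annotations
  tibble(chunk = a$chunk, occurrence = seq_len(nrow(a)),
         start_ms = a$start * symbol_ms, end_ms = a$end * symbol_ms)
}

#' Principal-component diagnostics of a trained reservoir
#'
#' Eigendecomposition of the (time-centered) rate covariance of one module,
#' plus the reconstruction-error curves over nested PC subspaces: the module's
#' centered output and its readout weights are projected onto the first `M`
#' eigenvectors, and the within-self difference `E(M)` is the time-mean
#' squared difference between the output and its rank-`M` reconstruction; the
#' between-partner difference substitutes the partner's centered output for
#' the module's own. The within-self curve is non-increasing in `M` and
#' reaches 0 at the full dimension. Also reports, per component, the
#' eigenvalue, the correlation with the readout trace, and the projection
#' length of the readout weights. Each eigenvector is oriented so that its
#' correlation with the readout trace is nonnegative.
#'
#' @param rates `time x n_neurons` matrix of module rates (readout subset).
#' @param w Readout weight vector over the same neurons.
#' @param z Readout trace of the module (length `time`).
#' @param z_partner Optional partner readout trace (for the between-partner
#'   curve).
#' @param M_grid Subspace dimensions to evaluate (default all).
#' @return A `pca_report`: list with `eigenvalues`, `vectors`, `pc_stats`
#'   tibble (`pc`, `eigenvalue`, `cor_readout`, `w_proj`), `curves` tibble
#'   (`M`, `e_within`, `e_between`), and `total_variance`.
#' @export
pca_report <- function(rates, w, z, z_partner = NULL, M_grid = NULL) {
  rates <- as.matrix(rates)
  N <- ncol(rates)
  if (nrow(rates) < 2L) abort("need at least 2 samples.", class = "dualrc_invalid")
  if (nrow(rates) < N)
    warn("fewer samples than neurons: covariance is rank-deficient.",
         class = "dualrc_reduced_rank")
  rc <- scale(rates, center = TRUE, scale = FALSE)
  C <- crossprod(rc) / (nrow(rc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  V <- eg$vectors
  zc <- z - mean(z)
  coords <- rc %*% V                      # time x N PC coordinates
  flip <- vapply(seq_len(N), function(k) {
    s <- sd(coords[, k])
    if (s == 0) 1 else sign(cor(coords[, k], zc) + 1e-300)
  }, numeric(1))
  V <- sweep(V, 2, flip, "*")
  coords <- sweep(coords, 2, flip, "*")
  w_proj <- drop(crossprod(V, w))
  cor_readout <- vapply(seq_len(N), function(k) {
    s <- sd(coords[, k])
    if (s == 0 || sd(zc) == 0) 0 else cor(coords[, k], zc)
  }, numeric(1))
  if (is.null(M_grid)) M_grid <- seq_len(N)
  contrib <- sweep(coords, 2, w_proj, "*")
  recon <- t(apply(contrib, 1, cumsum))   # time x N cumulative reconstruction
  zp <- if (is.null(z_partner)) NULL else z_partner - mean(z_partner)
  curves <- tibble(
    M = as.integer(M_grid),
    e_within = vapply(M_grid, function(M) mean((zc - recon[, M])^2), numeric(1)),
    e_between = if (is.null(zp)) NA_real_ else
      vapply(M_grid, function(M) mean((zp - recon[, M])^2), numeric(1)))
  structure(list(eigenvalues = vals, vectors = V,
                 pc_stats = tibble(pc = seq_len(N), eigenvalue = vals,
                                   cor_readout = cor_readout, w_proj = w_proj),
                 curves = curves, total_variance = sum(diag(C))),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat("<pca_report> ", length(x$eigenvalues), " components; top eigenvalue ",
      signif(x$eigenvalues[1], 3), "; total variance ",
      signif(x$total_variance, 3), "\n", sep = "")
  invisible(x)
}

#' Strong-weight statistics by selectivity label
#'
#' The strong-weight threshold is one standard deviation (population SD) of
#' the pooled readout-weight distribution; weights strictly above it are
#' "strong". The
#' headline statistic is the fraction of strong weights whose source neuron is
#' chunk-encoding (labelled with a chunk). With a degenerate pooled
#' distribution (zero SD) there are no strong weights and the fraction is 0
#' with a flag.
#'
#' @param w Readout weight vector, one entry per neuron.
#' @param labels Character vector of per-neuron selectivity labels, as from
#'   [classify_selectivity()] (`"none"`, `"multiple"`, or a chunk id).
#' @return List with `summary` (one-row tibble: `threshold`, `n_strong`,
#'   `fraction_encoding`, `degenerate`) and `weights` (tibble `neuron`,
#'   `weight`, `label`, `encoding`, `strong`).
#' @export
weight_stats <- function(w, labels) {
  w <- as.numeric(w)
  if (length(labels) != length(w))
    abort("`labels` must match `w` in length.", class = "dualrc_invalid")
  thr <- sqrt(mean((w - mean(w))^2))
  encoding <- !(labels %in% c("none", "multiple"))
  degenerate <- thr == 0
  strong <- if (degenerate) rep(FALSE, length(w)) else w > thr
  frac <- if (any(strong)) mean(encoding[strong]) else 0
  list(summary = tibble(threshold = thr, n_strong = sum(strong),
                        fraction_encoding = frac, degenerate = degenerate),
       weights = tibble(neuron = seq_along(w), weight = w, label = labels,
                        encoding = encoding, strong = strong))
}
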