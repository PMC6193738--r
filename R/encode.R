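#' Input-pulse kinetics
#'
#' Every symbol occurrence drives its own input channel with a
#' difference-of-exponentials pulse: with rise constant `tau_rise` and decay
#' constant `tau_decay` (both ms, rise < decay for the usual shape) the kernel
#' is `A (exp(-s/tau_decay) - exp(-s/tau_rise))` for time `s >= 0` since symbol
#' onset, scaled so its peak equals `amplitude`. The pulse is triggered at the
#' start of each symbol slot of length `symbol_ms`; its decay tail continues
#' freely into the following slots and successive pulses superpose linearly.
#'
#' @param symbol_ms Symbol slot duration in ms (default 200; chosen so that the
#'   2400-ms selectivity-sorting window spans a contiguous 12-symbol cycle of
#'   three 4-symbol chunks).
#' @param tau_rise,tau_decay Rise and decay time constants in ms.
#' @param amplitude Peak current (dimensionless).
#' @return A `pulse_kinetics` list.
#' @export
pulse_kinetics <- function(symbol_ms = 200, tau_rise = 20, tau_decay = 50,
                           amplitude = 1) {
  if (symbol_ms <= 0 || tau_rise <= 0 || tau_decay <= 0)
    abort("durations and time constants must be positive.", class = "dualrc_invalid")
  structure(list(symbol_ms = symbol_ms, tau_rise = tau_rise,
                 tau_decay = tau_decay, amplitude = amplitude),
            class = "pulse_kinetics")
}

pulse_kernel <- function(kinetics, dt, tail_factor = 8) {
  len <- ceiling((kinetics$symbol_ms + tail_factor * kinetics$tau_decay) / dt)
  s <- (seq_len(len) - 1) * dt
  raw <- exp(-s / kinetics$tau_decay) - exp(-s / kinetics$tau_rise)
  peak <- max(raw)
  if (peak <= 0) raw else kinetics$amplitude * raw / peak
}

#' Encode a symbol stream into input currents
#'
#' Builds the drive `I_mu(t)`: one channel per letter of the alphabet, sampled
#' every `dt` ms. Each symbol occurrence adds a difference-of-exponentials
#' pulse (see [pulse_kinetics()]) to its own channel only; channels of letters
#' that never occur stay identically zero.
#'
#' @param stream A [symbol_stream()].
#' @param kinetics A [pulse_kinetics()].
#' @param dt Sampling step in ms (default 1).
#' @param n_input Number of input channels; defaults to the stream's alphabet
#'   size, and must be at least that.
#' @return A `drive_trace`: list with `currents` (time x channels matrix),
#'   `dt`, `symbol_ms` and `onsets` (tibble `symbol`, `time_ms`).
#' @export
encode_symbols <- function(stream, kinetics = pulse_kinetics(), dt = 1,
                           n_input = NULL) {
  if (dt <= 0) abort("`dt` must be positive.", class = "dualrc_invalid")
  if (is.null(n_input)) n_input <- stream$alphabet_size
  if (stream$alphabet_size > n_input)
    abort("stream alphabet exceeds the number of input channels.",
          class = "dualrc_invalid")
  n_sym <- length(stream$symbols)
  steps_per_symbol <- round(kinetics$symbol_ms / dt)
  total <- n_sym * steps_per_symbol
  cur <- matrix(0, total, n_input)
  if (n_sym > 0) {
    ker <- pulse_kernel(kinetics, dt)
    for (i in seq_len(n_sym)) {
      t0 <- (i - 1L) * steps_per_symbol
      idx <- (t0 + 1L):min(t0 + length(ker), total)
      ch <- stream$symbols[i] + 1L
      cur[idx, ch] <- cur[idx, ch] + ker[seq_along(idx)]
    }
  }
  onsets <- tibble(symbol = stream$symbols,
                   time_ms = (seq_len(n_sym) - 1) * kinetics$symbol_ms)
  structure(list(currents = cur, dt = dt, symbol_ms = kinetics$symbol_ms,
                 onsets = onsets),
            class = "drive_trace")
}

#' @export
print.drive_trace <- function(x, ...) {
  cat("<drive_trace> ", nrow(x$currents), " samples x ", ncol(x$currents),
      " channels (dt = ", x$dt, " ms)\n", sep = "")
  invisible(x)
}

#' Build the input projection wiring
#'
#' In the one-to-one default (`fan_in = NULL`) each reservoir neuron selects a
#' single input channel uniformly at random, i.e. each row of the
#' `n_reservoir x n_input` weight matrix has exactly one nonzero entry. With a
#' `fan_in` fraction, each neuron selects `round(fan_in * n_input)` distinct
#' channels without replacement. All nonzero weights are standard Gaussian.
#'
#' @param n_input Number of input channels.
#' @param n_reservoir Number of reservoir neurons.
#' @param fan_in `NULL` for one-to-one, or a fraction in (0, 1].
#' @param seed Optional integer seed.
#' @return An `input_projection`: list with `weights` and `fan_in`.
#' @export
input_projection <- function(n_input, n_reservoir, fan_in = NULL, seed = NULL) {
  k <- if (is.null(fan_in)) 1L else {
    if (fan_in <= 0 || fan_in > 1)
      abort("`fan_in` must lie in (0, 1].", class = "dualrc_invalid")
    round(fan_in * n_input)
  }
  if (k < 1L)
    abort("`fan_in` selects zero input channels.", class = "dualrc_invalid")
  W <- with_seed_if(seed, {
    W <- matrix(0, n_reservoir, n_input)
    for (i in seq_len(n_reservoir)) {
      ch <- if (is.null(fan_in)) sample.int(n_input, 1L) else sample.int(n_input, k)
      W[i, ch] <- rnorm(k)
    }
    W
  })
  structure(list(weights = W, fan_in = fan_in), class = "input_projection")
}

#' Encode an image stream into pixel currents and wiring
#'
#' The flattened pixel array (`H * W * 3` channels) is the input layer.
#' Currents are piecewise constant within each presentation slot: the pixel
#' values of the scheduled frame, or a fresh clipped Gaussian noise image
#' around mid-gray for noise slots. Each reservoir neuron is wired to
#' `round(pixel_fraction * H * W * 3)` randomly chosen pixels with standard
#' Gaussian weights.
#'
#' @param stream An image stream from [stream_images()].
#' @param pixel_fraction Fraction of pixels feeding each reservoir neuron.
#' @param n_reservoir Number of reservoir neurons.
#' @param dt Sampling step in ms.
#' @param seed Optional integer seed (wiring and noise images).
#' @param noise_sd Pixel standard deviation of noise slots (clipped to [0, 1]).
#' @return List with elements `drive` (a `drive_trace`) and `projection`
#'   (an `input_projection`).
#' @export
encode_images <- function(stream, pixel_fraction = 0.1, n_reservoir, dt = 1,
                          seed = NULL, noise_sd = 0.2) {
  if (pixel_fraction <= 0 || pixel_fraction > 1)
    abort("`pixel_fraction` must lie in (0, 1].", class = "dualrc_invalid")
  if (nrow(stream$schedule) == 0)
    abort("image stream has an empty schedule.", class = "dualrc_invalid")
  n_pix <- prod(stream$resolution) * 3L
  steps_per_slot <- round(stream$slot_ms / dt)
  n_slots <- nrow(stream$schedule)
  res <- with_seed_if(seed, {
    k <- round(pixel_fraction * n_pix)
    W <- matrix(0, n_reservoir, n_pix)
    for (i in seq_len(n_reservoir)) W[i, sample.int(n_pix, k)] <- rnorm(k)
    slot_pix <- matrix(0, n_slots, n_pix)
    for (s in seq_len(n_slots)) {
      slot_pix[s, ] <- if (stream$schedule$is_noise[s]) {
        pmin(pmax(rnorm(n_pix, 0.5, noise_sd), 0), 1)
      } else as.vector(stream$frames[[stream$schedule$label[s]]])
    }
    list(W = W, slot_pix = slot_pix)
  })
  cur <- res$slot_pix[rep(seq_len(n_slots), each = steps_per_slot), , drop = FALSE]
  onsets <- tibble(symbol = ifelse(stream$schedule$is_noise, NA_integer_,
                                   stream$schedule$label - 1L),
                   time_ms = (seq_len(n_slots) - 1) * stream$slot_ms)
  list(drive = structure(list(currents = cur, dt = dt,
                              symbol_ms = stream$slot_ms, onsets = onsets),
                         class = "drive_trace"),
       projection = structure(list(weights = res$W, fan_in = pixel_fraction),
                              class = "input_projection"))
}
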