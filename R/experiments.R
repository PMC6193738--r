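experiment_names <- c("fig1_single_chunk", "fig1f_fanin", "fig2_multi",
                      "fig4_noise_sweep", "fig5_overlap", "fig6_graph",
                      "fig6_images", "s4_size_sweep", "s4d_coupling",
                      "s5_letters")

#' Build an experiment configuration
#'
#' Assembles the full parameter set of one figure-level experiment, filling
#' unspecified values from the experiment's defaults (network size,
#' connectivity, readout count, noise level, input regime). `scale` multiplies
#' the number of learning steps (training duration); the learning-step
#' bookkeeping itself stays at 15 s of simulated time.
#'
#' @param name One of `"fig1_single_chunk"`, `"fig1f_fanin"`, `"fig2_multi"`,
#'   `"fig4_noise_sweep"`, `"fig5_overlap"`, `"fig6_graph"`, `"fig6_images"`,
#'   `"s4_size_sweep"`, `"s4d_coupling"`, `"s5_letters"`.
#' @param ... Overrides for any default field (e.g. `sigma`, `n_steps`,
#'   `fan_in`, `q`, `chunk_size`, `resolution`, `seed`).
#' @param scale Duration multiplier applied to the default `n_steps`.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(name, ..., scale = 1) {
  if (!name %in% experiment_names)
    abort(paste0("unknown experiment name: ", name), class = "dualrc_invalid")
  base <- list(name = name, n_neurons = 300L, p_connect = 1, sigma = 0.3,
               gain = 1.5, tau = 10, dt = 1, n_readouts = 1L, n_readout = 300L,
               alphabet_size = 26L, chunks = list(0:3), probs = 1,
               separated = TRUE, filler_range = c(5L, 8L), fan_in = NULL,
               n_steps = 20L, eval_ms = 30000, q = 0, seed = 1L,
               washout_ms = 1000, overlap = "tail", chunk_size = 4L,
               resolution = c(32L, 32L), with_noise_slots = TRUE,
               pixel_fraction = 0.1, n_letters = 10L, letter_probs = NULL,
               analyses = character(), output_dir = NULL)
  tweak <- switch(name,
    fig1_single_chunk = list(),
    fig1f_fanin = list(fan_in = 0.1),
    fig2_multi = list(n_neurons = 600L, p_connect = 0.5, sigma = 0.1,
                      n_readouts = 3L,
                      chunks = list(0:3, 4:7, 8:11), probs = rep(1 / 3, 3)),
    fig4_noise_sweep = list(sigma = 0.25),
    fig5_overlap = list(n_neurons = 800L, sigma = 0.15, n_readouts = 2L,
                        chunks = list(c(0L, 1L, 2L, 3L), c(4L, 5L, 2L, 3L)),
                        probs = c(0.5, 0.5)),
    fig6_graph = list(n_neurons = 600L, p_connect = 0.5, sigma = 0.1,
                      n_readouts = 3L, alphabet_size = 15L),
    fig6_images = list(n_neurons = 600L, p_connect = 0.5, sigma = 0.1,
                       n_readouts = 2L),
    s4_size_sweep = list(),
    s4d_coupling = list(q = 0.1),
    s5_letters = list())
  # wholesale field replacement (modifyList would merge list-valued fields
  # such as `chunks` recursively)
  replace_fields <- function(cfg, upd) {
    for (nm in names(upd)) cfg[nm] <- list(upd[[nm]])
    cfg
  }
  cfg <- replace_fields(replace_fields(base, tweak), list(...))
  if (name == "fig5_overlap" && cfg$overlap == "middle" &&
      !"chunks" %in% names(list(...))) {
    cfg$chunks <- list(c(0L, 8L, 9L, 1L), c(2L, 8L, 9L, 3L))
    cfg$n_neurons <- 500L
    cfg$sigma <- 0.1
  }
  if (name == "s4_size_sweep" && !"chunks" %in% names(list(...))) {
    reg <- chunk_size_regime(cfg$chunk_size)
    cfg$chunks <- list(reg$chunk)
    cfg$alphabet_size <- reg$alphabet_size
    cfg$filler_range <- reg$filler_range
  }
  cfg$n_steps <- max(1L, as.integer(round(cfg$n_steps * scale)))
  cfg$n_readout <- min(cfg$n_readout, cfg$n_neurons)
  structure(cfg, class = "experiment_config")
}

symbols_needed <- function(total_ms, symbol_ms) ceiling(total_ms / symbol_ms) + 2L

make_stream <- function(cfg, total_ms, seed, symbol_ms = 200) {
  n_sym <- symbols_needed(total_ms, symbol_ms)
  if (cfg$name == "fig6_graph") {
    g <- community_graph()
    return(stream_graph_walk(g, n_sym, seed = seed))
  }
  if (cfg$name == "s5_letters") {
    return(stream_biased_letters(cfg$n_letters, cfg$letter_probs, n_sym,
                                 seed = seed))
  }
  min_cycle <- min(lengths(cfg$chunks)) +
    if (cfg$separated) cfg$filler_range[1] else 0L
  n_rep <- ceiling(n_sym / min_cycle) + 2L
  stream_multi_chunk(cfg$chunks, cfg$probs, cfg$separated, cfg$filler_range,
                     n_repeats = n_rep, alphabet_size = cfg$alphabet_size,
                     seed = seed)
}

#' Run one figure-level experiment end to end
#'
#' Generates training and held-out streams, builds (and optionally couples)
#' the dual system, evaluates the untrained system on the held-out stream
#' (pre-learning baseline), trains by mutual supervision, re-evaluates, and
#' runs any requested analyses. Everything is seeded from `config$seed`, so an
#' identical configuration reproduces identical numbers.
#'
#' @param config An [experiment_config()].
#' @return A `run_result`: list with `fit`, `pre` and `post` evaluation
#'   correlation tibbles, `assignment`, optional `selectivity` / `pca` /
#'   `weights`, and the `config`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "experiment_config"))
    abort("`config` must come from experiment_config().", class = "dualrc_invalid")
  cfg <- config
  seeds <- withr::with_seed(cfg$seed, sample.int(.Machine$integer.max, 6L))
  params <- reservoir_params(cfg$n_neurons, cfg$gain, cfg$p_connect, cfg$tau,
                             cfg$sigma, cfg$dt)
  train_ms <- cfg$washout_ms + cfg$n_steps * 15000

  if (cfg$name == "fig6_images") {
    n_slots_train <- ceiling(train_ms / 250) + 2L
    n_slots_eval <- ceiling(cfg$eval_ms / 250) + 2L
    imgs <- stream_images(2L, cfg$resolution, cfg$with_noise_slots,
                          n_slots_train, seed = seeds[1])
    enc <- encode_images(imgs, cfg$pixel_fraction, cfg$n_neurons,
                         dt = cfg$dt, seed = seeds[2])
    imgs_eval <- stream_images(2L, cfg$resolution, cfg$with_noise_slots,
                               n_slots_eval, seed = seeds[3],
                               images = imgs$frames)
    enc_eval <- encode_images(imgs_eval, cfg$pixel_fraction, cfg$n_neurons,
                              dt = cfg$dt, seed = seeds[2])
    n_pix <- prod(cfg$resolution) * 3L
    proj2 <- input_projection(n_pix, cfg$n_neurons, cfg$pixel_fraction,
                              seed = seeds[4])
    system <- dual_system(params, cfg$n_readouts, cfg$n_readout,
                          n_input = n_pix,
                          projections = list(enc$projection, proj2),
                          seed = seeds[5])
    stream_train <- image_labels_as_stream(imgs)
    stream_eval <- image_labels_as_stream(imgs_eval)
    drive_train <- enc$drive
    drive_eval <- enc_eval$drive
  } else {
    stream_train <- make_stream(cfg, train_ms, seeds[1])
    stream_eval <- make_stream(cfg, cfg$eval_ms, seeds[3])
    kin <- pulse_kinetics()
    drive_train <- encode_symbols(stream_train, kin, cfg$dt,
                                  n_input = cfg$alphabet_size)
    drive_eval <- encode_symbols(stream_eval, kin, cfg$dt,
                                 n_input = cfg$alphabet_size)
    system <- dual_system(params, cfg$n_readouts, cfg$n_readout,
                          n_input = cfg$alphabet_size, fan_in = cfg$fan_in,
                          seed = seeds[5])
  }
  if (cfg$q > 0 || cfg$name == "s4d_coupling")
    system <- couple_reservoirs(system, cfg$q, seed = seeds[4])

  pre <- evaluate_dual(system, drive_eval, stream_eval, seed = seeds[6])
  fit <- train_dual(system, drive_train, cfg$n_steps, stream = stream_train,
                    washout_ms = cfg$washout_ms, seed = seeds[2])
  post <- evaluate_dual(fit, drive_eval, stream_eval, seed = seeds[6])

  assignment <- NULL
  if (!is.null(post$correlations)) {
    assignment <- dplyr::group_modify(
      dplyr::group_by(post$correlations, .data$module),
      function(df, key) {
        cm <- tidyr::pivot_wider(df[, c("readout", "chunk", "correlation")],
                                 names_from = "chunk",
                                 values_from = "correlation")
        assign_readouts(as.matrix(cm[, -1, drop = FALSE]))
      })
    assignment <- dplyr::ungroup(assignment)
  }
  out <- structure(list(fit = fit, pre = pre$correlations,
                        post = post$correlations, post_eval = post,
                        assignment = assignment, config = cfg,
                        streams = list(train = stream_train, eval = stream_eval)),
                   class = "run_result")
  if (!is.null(cfg$output_dir)) write_run_result(out, cfg$output_dir)
  out
}

# one symbol per 250-ms slot; noise slots get the extra id n_images, and
# maximal runs of one image are annotated as that image's "chunk"
image_labels_as_stream <- function(imgs) {
  sched <- imgs$schedule
  n_img <- length(imgs$frames)
  lab <- ifelse(sched$is_noise, n_img, sched$label - 1L)
  key <- ifelse(sched$is_noise, 0L, sched$label)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  keep <- runs$values > 0L
  ann <- tibble(chunk = as.integer(runs$values[keep]),
                start = as.integer((ends - runs$lengths)[keep]),
                end = as.integer(ends[keep]))
  symbol_stream(lab, n_img + 1L, ann,
                provenance = list(generator = "image_labels"))
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> ", x$config$name, ": ", x$config$n_steps,
      " learning steps\n", sep = "")
  if (!is.null(x$assignment)) {
    cat("  post-learning assigned correlations:\n")
    print(x$assignment, n = 6)
  }
  invisible(x)
}

#' Headline performance of a run
#'
#' Mean (over modules) of the correlation obtained by greedily assigning each
#' module's readouts to chunks; the standard summary used in sweeps.
#'
#' @param result A `run_result`, or a correlations tibble with columns
#'   `module`, `readout`, `chunk`, `correlation`.
#' @return Scalar correlation.
#' @export
headline_correlation <- function(result) {
  cors <- if (inherits(result, "run_result")) result$post else result
  per_module <- vapply(split(cors, cors$module), function(df) {
    cm <- tidyr::pivot_wider(df[, c("readout", "chunk", "correlation")],
                             names_from = "chunk", values_from = "correlation")
    asg <- assign_readouts(as.matrix(cm[, -1, drop = FALSE]))
    mean(asg$correlation, na.rm = TRUE)
  }, numeric(1))
  mean(per_module)
}

#' Sweep one parameter of an experiment over values and seeds
#'
#' Runs [run_experiment()] for every combination of parameter value and seed
#' and aggregates the post-learning headline correlation.
#'
#' @param config An [experiment_config()] to start from.
#' @param param Name of the config field to sweep (e.g. `"sigma"`, `"fan_in"`,
#'   `"n_neurons"`, `"q"`).
#' @param values Vector of values (non-empty).
#' @param seeds Integer vector of seeds.
#' @return List with `runs` (tibble `param`, `value`, `seed`, `correlation`)
#'   and `summary` (tibble `value`, `mean`, `sd`, `median`, `n`).
#' @export
sweep_experiment <- function(config, param, values, seeds = 1:3) {
  if (!param %in% names(config))
    abort(paste0("unknown config field: ", param), class = "dualrc_invalid")
  if (!length(values))
    abort("`values` must be non-empty.", class = "dualrc_invalid")
  runs <- purrr::map_dfr(values, function(v) {
    purrr::map_dfr(seeds, function(s) {
      cfg <- config
      cfg[[param]] <- v
      cfg$seed <- s
      res <- run_experiment(cfg)
      tibble(param = param, value = v, seed = s,
             correlation = headline_correlation(res))
    })
  })
  summary <- dplyr::summarise(dplyr::group_by(runs, .data$value),
                              mean = mean(.data$correlation),
                              sd = sd(.data$correlation),
                              median = median(.data$correlation),
                              n = dplyr::n(), .groups = "drop")
  list(runs = runs, summary = summary)
}
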