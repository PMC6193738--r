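symbol_to_char <- function(ids) {
  ifelse(ids < 26L, strsplit("abcdefghijklmnopqrstuvwxyz", "")[[1]][ids + 1L],
         NA_character_)
}

#' Read and write symbol streams as plain text
#'
#' The stream is written as one character per symbol (letters `a`-`z` for ids
#' 0-25; larger alphabets fall back to comma-separated integers) with a JSON
#' sidecar (`<path>.json`) listing alphabet size and annotations as 0-based
#' half-open intervals.
#'
#' @param stream A [symbol_stream()].
#' @param path Output text file; the sidecar gets `.json` appended.
#' @return `write_symbol_stream()`: `path`, invisibly.
#'   `read_symbol_stream()`: a [symbol_stream()].
#' @export
write_symbol_stream <- function(stream, path) {
  txt <- if (stream$alphabet_size <= 26L)
    paste(symbol_to_char(stream$symbols), collapse = "")
  else paste(stream$symbols, collapse = ",")
  writeLines(txt, path)
  side <- list(alphabet_size = stream$alphabet_size,
               encoding = if (stream$alphabet_size <= 26L) "letters" else "integers",
               annotations = purrr::pmap(stream$annotations,
                                         function(chunk, start, end, ...)
                                           list(chunk = chunk, start = start,
                                                end = end)),
               provenance = stream$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_symbol_stream
#' @export
read_symbol_stream <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  txt <- readLines(path, n = 1L)
  symbols <- if (identical(side$encoding, "letters")) {
    if (nchar(txt)) match(strsplit(txt, "")[[1]],
                          strsplit("abcdefghijklmnopqrstuvwxyz", "")[[1]]) - 1L
    else integer()
  } else {
    if (nchar(txt)) as.integer(strsplit(txt, ",")[[1]]) else integer()
  }
  ann <- if (length(side$annotations))
    purrr::map_dfr(side$annotations, tibble::as_tibble)
  else tibble(chunk = integer(), start = integer(), end = integer())
  symbol_stream(symbols, as.integer(side$alphabet_size), ann,
                provenance = side$provenance)
}

#' Read and write community graphs as edge-list TSV
#'
#' Two tab-separated node columns (`from`, `to`, 1-based), plus an optional
#' third `community_from` column ignored on read; community labels are stored
#' in a `<path>.json` sidecar.
#'
#' @param graph A [community_graph()].
#' @param path Output TSV file.
#' @return `write_graph_tsv()`: `path`, invisibly. `read_graph_tsv()`: a
#'   [community_graph()].
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(community = graph$membership$community),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  e <- utils::read.table(path, header = TRUE, sep = "\t")
  comm <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side))
    comm <- unlist(jsonlite::read_json(side)$community)
  community_graph(edges = e, communities = comm)
}

#' Write an image stream as PNG frames plus a JSON schedule
#'
#' @param stream An image stream from [stream_images()].
#' @param dir Output directory (created if needed); frames become
#'   `frame_<k>.png` and the schedule `schedule.json`.
#' @return `dir`, invisibly.
#' @export
write_image_stream <- function(stream, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(stream$frames))
    png::writePNG(stream$frames[[k]], file.path(dir, sprintf("frame_%d.png", k)))
  jsonlite::write_json(
    list(slot_ms = stream$slot_ms, resolution = stream$resolution,
         schedule = purrr::pmap(stream$schedule,
                                function(slot, label, is_noise, duration_ms)
                                  list(slot = slot,
                                       label = if (is_noise) "noise" else label,
                                       duration_ms = duration_ms))),
    file.path(dir, "schedule.json"), auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Persist a run result as CSV and JSON
#'
#' Writes the training log and correlation log as CSV, the readout-chunk
#' assignment and configuration as JSON.
#'
#' @param result A `run_result` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$fit$log, file.path(dir, "training_log.csv"),
                   row.names = FALSE)
  if (!is.null(result$fit$correlations))
    utils::write.csv(result$fit$correlations,
                     file.path(dir, "training_correlations.csv"),
                     row.names = FALSE)
  if (!is.null(result$post))
    utils::write.csv(result$post, file.path(dir, "post_correlations.csv"),
                     row.names = FALSE)
  if (!is.null(result$assignment))
    utils::write.csv(result$assignment, file.path(dir, "assignment.csv"),
                     row.names = FALSE)
  cfg <- result$config
  cfg$chunks <- lapply(cfg$chunks, as.integer)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
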