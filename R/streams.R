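#' @useDynLib dualrc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif sd var cor quantile median
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Construct a symbol stream
#'
#' A `symbol_stream` is an ordered sequence of integer symbol ids in
#' `[0, alphabet_size)` together with ground-truth annotations: half-open,
#' 0-based `[start, end)` intervals, each labelled with the id of the chunk
#' (or community) it realizes. Streams are produced by the `stream_*()`
#' generators; this low-level constructor validates the invariants.
#'
#' @param symbols Integer vector of symbol ids, each in `[0, alphabet_size)`.
#' @param alphabet_size Positive integer.
#' @param annotations Tibble with integer columns `chunk`, `start`, `end`
#'   (0-based, half-open). May have zero rows.
#' @param chunks Optional list of chunk patterns (integer vectors), indexed by
#'   the `chunk` column of `annotations`. When supplied, every annotated
#'   interval is checked to reproduce its pattern exactly.
#' @param provenance List recording generator name, parameters and seed.
#' @return A `symbol_stream` object.
#' @export
symbol_stream <- function(symbols, alphabet_size,
                          annotations = tibble(chunk = integer(), start = integer(),
                                               end = integer()),
                          chunks = NULL, provenance = list()) {
  symbols <- as.integer(symbols)
  alphabet_size <- as.integer(alphabet_size)
  if (alphabet_size < 1L) abort("`alphabet_size` must be positive.", class = "dualrc_invalid")
  if (length(symbols) && (min(symbols) < 0L || max(symbols) >= alphabet_size))
    abort("symbol ids must lie in [0, alphabet_size).", class = "dualrc_invalid")
  annotations <- as_tibble(annotations)
  if (nrow(annotations)) {
    if (any(annotations$start < 0L) || any(annotations$end > length(symbols)) ||
        any(annotations$end <= annotations$start))
      abort("annotations must be non-empty intervals inside the stream.",
            class = "dualrc_invalid")
    if (!is.null(chunks)) {
      ok <- vapply(seq_len(nrow(annotations)), function(i) {
        pat <- chunks[[annotations$chunk[i]]]
        identical(as.integer(symbols[(annotations$start[i] + 1L):annotations$end[i]]),
                  as.integer(pat))
      }, logical(1))
      if (!all(ok)) abort("an annotated interval does not reproduce its chunk pattern.",
                          class = "dualrc_invalid")
    }
  }
  structure(list(symbols = symbols, alphabet_size = alphabet_size,
                 annotations = annotations, chunks = chunks,
                 provenance = provenance),
            class = "symbol_stream")
}

#' @export
print.symbol_stream <- function(x, ...) {
  cat("<symbol_stream> ", length(x$symbols), " symbols, alphabet ",
      x$alphabet_size, ", ", nrow(x$annotations), " annotated intervals\n", sep = "")
  if (!is.null(x$provenance$generator))
    cat("  generator: ", x$provenance$generator, "\n", sep = "")
  invisible(x)
}

#' @export
length.symbol_stream <- function(x) length(x$symbols)

#' @rdname symbol_stream
#' @param x A `symbol_stream`.
#' @param ... Unused.
#' @export
tidy.symbol_stream <- function(x, ...) {
  tibble(position = seq_along(x$symbols) - 1L, symbol = x$symbols)
}

draw_filler <- function(len, filler_alphabet) {
  filler_alphabet[sample.int(length(filler_alphabet), len, replace = TRUE)]
}

#' Generate a stream embedding one or more chunks in random fillers
#'
#' Each repetition draws one chunk according to `probs` and appends it to the
#' stream; when `separated = TRUE` a filler block follows, with length drawn
#' uniformly from `filler_range` and symbols drawn i.i.d. from the letters not
#' used by any chunk. Every chunk occurrence is annotated with its ground-truth
#' interval. Chunks may share symbols (overlapping-chunk regimes).
#'
#' @param chunks List of integer chunk patterns (symbol ids), or a single
#'   integer vector for one chunk.
#' @param probs Occurrence probability per chunk; must sum to 1.
#' @param separated Insert a random filler block after every chunk occurrence?
#' @param filler_range Length-2 integer vector `(min, max)` of filler lengths.
#' @param n_repeats Number of chunk occurrences to generate.
#' @param alphabet_size Total alphabet size (default 26).
#' @param seed Optional integer seed; the global RNG state is left untouched.
#' @return A [symbol_stream()].
#' @export
stream_multi_chunk <- function(chunks, probs = NULL, separated = TRUE,
                               filler_range = c(5L, 8L), n_repeats = 100L,
                               alphabet_size = 26L, seed = NULL) {
  if (!is.list(chunks)) chunks <- list(chunks)
  chunks <- lapply(chunks, as.integer)
  n_chunks <- length(chunks)
  if (is.null(probs)) probs <- rep(1 / n_chunks, n_chunks)
  if (length(probs) != n_chunks || any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    abort("`probs` must be nonnegative and sum to 1.", class = "dualrc_invalid")
  if (n_repeats < 0) abort("`n_repeats` must be >= 0.", class = "dualrc_invalid")
  used <- sort(unique(unlist(chunks)))
  if (length(used) && (min(used) < 0L || max(used) >= alphabet_size))
    abort("chunk symbols exceed the alphabet.", class = "dualrc_invalid")
  filler_alphabet <- setdiff(seq_len(alphabet_size) - 1L, used)
  if (separated && length(filler_alphabet) == 0L)
    abort("no symbols left for fillers: chunk uses the whole alphabet.",
          class = "dualrc_invalid")
  filler_range <- as.integer(filler_range)
  if (separated &&
      (length(filler_range) != 2L || filler_range[1] > filler_range[2] ||
       filler_range[1] < 0))
    abort("`filler_range` must be (min, max) with 0 <= min <= max.",
          class = "dualrc_invalid")

  res <- with_seed_if(seed, {
    syms <- vector("list", 2L * max(n_repeats, 0L))
    ann <- vector("list", max(n_repeats, 0L))
    pos <- 0L
    for (i in seq_len(n_repeats)) {
      k <- sample.int(n_chunks, 1L, prob = probs)
      pat <- chunks[[k]]
      syms[[2L * i - 1L]] <- pat
      ann[[i]] <- c(k, pos, pos + length(pat))
      pos <- pos + length(pat)
      if (separated) {
        len <- sample(seq.int(filler_range[1], filler_range[2]), 1L)
        syms[[2L * i]] <- draw_filler(len, filler_alphabet)
        pos <- pos + len
      }
    }
    list(symbols = unlist(syms), ann = ann)
  })
  ann <- if (n_repeats > 0) {
    m <- do.call(rbind, res$ann)
    tibble(chunk = as.integer(m[, 1]), start = as.integer(m[, 2]),
           end = as.integer(m[, 3]))
  } else tibble(chunk = integer(), start = integer(), end = integer())
  symbol_stream(if (is.null(res$symbols)) integer() else res$symbols,
                alphabet_size, ann, chunks = chunks,
                provenance = list(generator = "stream_multi_chunk",
                                  params = list(probs = probs, separated = separated,
                                                filler_range = filler_range,
                                                n_repeats = n_repeats),
                                  seed = seed))
}

#' Generate a stream alternating a single chunk with random fillers
#'
#' The base regime: one chunk (default the four letters a-b-c-d) alternates
#' with filler blocks whose lengths are drawn uniformly from `filler_range`
#' and whose symbols come from the letters not used by the chunk.
#'
#' @inheritParams stream_multi_chunk
#' @param chunk Integer vector of symbol ids forming the chunk.
#' @return A [symbol_stream()] with one annotation per chunk occurrence.
#' @export
stream_single_chunk <- function(chunk = 0:3, alphabet_size = 26L,
                                n_repeats = 100L, filler_range = c(5L, 8L),
                                seed = NULL) {
  s <- stream_multi_chunk(list(as.integer(chunk)), probs = 1, separated = TRUE,
                          filler_range = filler_range, n_repeats = n_repeats,
                          alphabet_size = alphabet_size, seed = seed)
  s$provenance$generator <- "stream_single_chunk"
  s
}

#' Chunk-size experiment regime
#'
#' For a chunk of size `s` the stream uses an alphabet of `5 s` letters: the
#' chunk occupies `s` of them, fillers draw from the remaining `4 s`, and
#' filler lengths range from `s + 2` to `s + 5`.
#'
#' @param s Chunk size (>= 1).
#' @return A list with elements `chunk`, `alphabet_size`, `filler_range`.
#' @export
chunk_size_regime <- function(s) {
  s <- as.integer(s)
  if (s < 1L) abort("chunk size must be >= 1.", class = "dualrc_invalid")
  out <- list(chunk = seq_len(s) - 1L, alphabet_size = 5L * s,
              filler_range = c(s + 2L, s + 5L))
  stopifnot(out$alphabet_size - s == 4L * s)
  out
}

#' Generate an i.i.d. letter stream with given occurrence probabilities
#'
#' Used for the frequency-bias experiments: no temporal grouping exists, so the
#' stream carries no chunk annotations.
#'
#' @param alphabet_size Number of letters.
#' @param probs Occurrence probability per letter (default uniform).
#' @param n_symbols Stream length.
#' @param seed Optional integer seed.
#' @return A [symbol_stream()] without annotations.
#' @export
stream_biased_letters <- function(alphabet_size = 10L, probs = NULL,
                                  n_symbols = 1000L, seed = NULL) {
  alphabet_size <- as.integer(alphabet_size)
  if (is.null(probs)) probs <- rep(1 / alphabet_size, alphabet_size)
  if (length(probs) != alphabet_size || any(probs < 0) ||
      abs(sum(probs) - 1) > 1e-8)
    abort("`probs` must have length `alphabet_size` and sum to 1.",
          class = "dualrc_invalid")
  syms <- with_seed_if(seed,
    sample.int(alphabet_size, n_symbols, replace = TRUE, prob = probs) - 1L)
  symbol_stream(syms, alphabet_size,
                provenance = list(generator = "stream_biased_letters",
                                  params = list(probs = probs), seed = seed))
}

#' Build a degree-regular community graph
#'
#' Default topology: `n_communities` communities of `community_size` nodes
#' each. Within a community all node pairs are connected except the pair of
#' boundary nodes; each boundary node connects instead to one boundary node of
#' the adjacent community, the communities being arranged in a ring. With the
#' default 3 x 5 layout every node has degree exactly 4, so a random walk has
#' uniform transition probabilities (1/4 per neighbor) yet the graph has clear
#' community structure.
#'
#' @param n_communities,community_size Both at least 3.
#' @param edges Optional explicit edge list (two-column matrix or data frame of
#'   1-based node ids) overriding the canonical topology.
#' @param communities With `edges`, an integer vector giving each node's
#'   community label.
#' @return A `community_graph`: list with `n_nodes`, `edges` (tibble
#'   `from`/`to`, `from < to`), and `membership` (tibble `node`/`community`).
#' @export
community_graph <- function(n_communities = 3L, community_size = 5L,
                            edges = NULL, communities = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "integer"
    if (any(edges[, 1] == edges[, 2]))
      abort("self-loops are not allowed.", class = "dualrc_invalid")
    e <- t(apply(edges, 1, sort))
    e <- unique(e)
    n_nodes <- max(e)
    if (is.null(communities)) communities <- rep(1L, n_nodes)
    return(structure(list(n_nodes = n_nodes,
                          edges = tibble(from = e[, 1], to = e[, 2]),
                          membership = tibble(node = seq_len(n_nodes),
                                              community = as.integer(communities))),
                     class = "community_graph"))
  }
  n_communities <- as.integer(n_communities)
  community_size <- as.integer(community_size)
  if (n_communities < 3L || community_size < 3L)
    abort("need at least 3 communities of at least 3 nodes for the degree-regular construction.",
          class = "dualrc_invalid")
  n_nodes <- n_communities * community_size
  edge_list <- list()
  for (c in seq_len(n_communities)) {
    nodes <- ((c - 1L) * community_size + 1L):(c * community_size)
    first <- nodes[1]; last <- nodes[community_size]
    pairs <- t(utils::combn(nodes, 2L))
    keep <- !(pairs[, 1] == first & pairs[, 2] == last)
    edge_list[[c]] <- pairs[keep, , drop = FALSE]
  }
  # ring of cross edges: last boundary node of community c -> first of c+1
  cross <- cbind(seq_len(n_communities) * community_size,
                 (seq_len(n_communities) %% n_communities) * community_size + 1L)
  cross <- t(apply(cross, 1, sort))
  e <- rbind(do.call(rbind, edge_list), cross)
  structure(list(n_nodes = n_nodes,
                 edges = tibble(from = as.integer(e[, 1]), to = as.integer(e[, 2])),
                 membership = tibble(node = seq_len(n_nodes),
                                     community = rep(seq_len(n_communities),
                                                     each = community_size))),
            class = "community_graph")
}

#' @export
print.community_graph <- function(x, ...) {
  cat("<community_graph> ", x$n_nodes, " nodes, ", nrow(x$edges), " edges, ",
      length(unique(x$membership$community)), " communities\n", sep = "")
  invisible(x)
}

#' Node degrees of a community graph
#' @param graph A [community_graph()].
#' @return Integer vector of degrees, one per node.
#' @export
graph_degrees <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = graph$n_nodes)
}

#' Adjacency and random-walk transition matrix
#' @inheritParams graph_degrees
#' @return `graph_adjacency()`: symmetric 0/1 matrix. `graph_transition()`:
#'   row-stochastic matrix of the simple random walk.
#' @export
graph_adjacency <- function(graph) {
  A <- matrix(0, graph$n_nodes, graph$n_nodes)
  A[cbind(graph$edges$from, graph$edges$to)] <- 1
  A[cbind(graph$edges$to, graph$edges$from)] <- 1
  A
}

#' @rdname graph_adjacency
#' @export
graph_transition <- function(graph) {
  A <- graph_adjacency(graph)
  sweep(A, 1, rowSums(A), "/")
}

#' Generate a stream by a random walk on a community graph
#'
#' Symbols are the visited nodes (0-based: node `k` emits symbol `k - 1`).
#' Annotations mark maximal runs spent inside one community, labelled by the
#' community id, which is what community-selective readouts are evaluated
#' against.
#'
#' @param graph A [community_graph()]; must be connected.
#' @param n_steps Number of visited nodes (>= 1).
#' @param seed Optional integer seed.
#' @param start Optional start node (default drawn uniformly).
#' @return A [symbol_stream()] with `alphabet_size = n_nodes`.
#' @export
stream_graph_walk <- function(graph, n_steps, seed = NULL, start = NULL) {
  if (n_steps < 1) abort("`n_steps` must be >= 1.", class = "dualrc_invalid")
  deg <- graph_degrees(graph)
  if (any(deg == 0)) abort("graph has isolated nodes.", class = "dualrc_invalid")
  nb <- vector("list", graph$n_nodes)
  for (i in seq_len(nrow(graph$edges))) {
    a <- graph$edges$from[i]; b <- graph$edges$to[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
  }
  nodes <- with_seed_if(seed, {
    cur <- if (is.null(start)) sample.int(graph$n_nodes, 1L) else as.integer(start)
    out <- integer(n_steps)
    out[1] <- cur
    for (t in seq_len(n_steps - 1L)) {
      cur <- nb[[cur]][sample.int(length(nb[[cur]]), 1L)]
      out[t + 1L] <- cur
    }
    out
  })
  comm <- graph$membership$community[nodes]
  runs <- rle(comm)
  ends <- cumsum(runs$lengths)
  ann <- tibble(chunk = as.integer(runs$values),
                start = as.integer(ends - runs$lengths),
                end = as.integer(ends))
  symbol_stream(nodes - 1L, graph$n_nodes, ann,
                provenance = list(generator = "stream_graph_walk",
                                  params = list(n_steps = n_steps), seed = seed))
}

smooth_random_field <- function(h, w, coarse = 8L) {
  g <- matrix(runif(coarse * coarse), coarse, coarse)
  ix <- seq(1, coarse, length.out = h)
  iy <- seq(1, coarse, length.out = w)
  i0 <- pmin(floor(ix), coarse - 1L); j0 <- pmin(floor(iy), coarse - 1L)
  fx <- ix - i0; fy <- iy - j0
  a <- g[cbind(rep(i0, w), rep(j0, each = h))]
  b <- g[cbind(rep(i0 + 1, w), rep(j0, each = h))]
  c_ <- g[cbind(rep(i0, w), rep(j0 + 1, each = h))]
  d <- g[cbind(rep(i0 + 1, w), rep(j0 + 1, each = h))]
  fxm <- rep(fx, w); fym <- rep(fy, each = h)
  v <- a * (1 - fxm) * (1 - fym) + b * fxm * (1 - fym) +
    c_ * (1 - fxm) * fym + d * fxm * fym
  m <- matrix(v, h, w)
  (m - min(m)) / max(max(m) - min(m), 1e-12)
}

#' Generate an RGB image stream with 250-ms presentation slots
#'
#' Frames default to seeded smooth random RGB fields (low-pass random patterns,
#' so any two frames are visually distinct); user images can be supplied as
#' `H x W x 3` arrays or PNG file paths. The schedule switches randomly between
#' images every `slot_ms`; with `with_noise_slots = TRUE` roughly half of the
#' slots instead show clipped Gaussian pixel noise around mid-gray.
#'
#' @param n_images Number of image frames (>= 1).
#' @param resolution `(H, W)` in pixels; channels are fixed at 3 (RGB).
#' @param with_noise_slots Interleave Gaussian-noise slots?
#' @param n_slots Number of presentation slots.
#' @param seed Optional integer seed.
#' @param slot_ms Slot duration in ms (default 250).
#' @param images Optional list of `H x W x 3` arrays in `[0, 1]` or PNG paths.
#' @return An `image_stream`: list with `frames`, `schedule` (tibble `slot`,
#'   `label`, `is_noise`, `duration_ms`), `resolution`, `slot_ms`.
#' @export
stream_images <- function(n_images = 2L, resolution = c(97L, 97L),
                          with_noise_slots = TRUE, n_slots = 100L, seed = NULL,
                          slot_ms = 250, images = NULL) {
  if (any(resolution <= 0)) abort("`resolution` must be positive.", class = "dualrc_invalid")
  if (n_images < 1L) abort("`n_images` must be >= 1.", class = "dualrc_invalid")
  h <- as.integer(resolution[1]); w <- as.integer(resolution[2])
  res <- with_seed_if(seed, {
    frames <- if (!is.null(images)) {
      lapply(images, function(im) {
        if (is.character(im)) im <- png::readPNG(im)
        if (length(dim(im)) == 2L) im <- array(rep(im, 3L), c(dim(im), 3L))
        im[, , 1:3, drop = FALSE]
      })
    } else {
      lapply(seq_len(n_images), function(i) {
        arr <- array(0, c(h, w, 3L))
        for (ch in 1:3) arr[, , ch] <- smooth_random_field(h, w)
        arr
      })
    }
    is_noise <- if (with_noise_slots) runif(n_slots) < 0.5 else rep(FALSE, n_slots)
    label <- ifelse(is_noise, NA_integer_,
                    sample.int(length(frames), n_slots, replace = TRUE))
    list(frames = frames, is_noise = is_noise, label = label)
  })
  structure(list(frames = res$frames,
                 schedule = tibble(slot = seq_len(n_slots),
                                   label = as.integer(res$label),
                                   is_noise = res$is_noise,
                                   duration_ms = rep(slot_ms, n_slots)),
                 resolution = c(h, w), slot_ms = slot_ms,
                 provenance = list(generator = "stream_images", seed = seed)),
            class = "image_stream")
}

#' @export
print.image_stream <- function(x, ...) {
  cat("<image_stream> ", length(x$frames), " frames of ", x$resolution[1], "x",
      x$resolution[2], "x3, ", nrow(x$schedule), " slots of ", x$slot_ms,
      " ms\n", sep = "")
  invisible(x)
}
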