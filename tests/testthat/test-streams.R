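test_that("single-chunk streams alternate chunk and filler with faithful annotations", {
  st <- stream_single_chunk(chunk = 0:3, alphabet_size = 26, n_repeats = 3,
                            filler_range = c(5, 8), seed = 7)
  expect_s3_class(st, "symbol_stream")
  expect_equal(nrow(st$annotations), 3)
  for (i in 1:3) {
    a <- st$annotations[i, ]
    expect_equal(st$symbols[(a$start + 1):a$end], 0:3)
  }
  in_chunk <- unlist(purrr::map2(st$annotations$start, st$annotations$end,
                                 ~ seq(.x + 1, .y)))
  fillers <- st$symbols[-in_chunk]
  expect_true(all(fillers >= 4 & fillers <= 25))
  filler_lens <- diff(c(st$annotations$start, length(st$symbols))) - 4L
  expect_true(all(filler_lens >= 5 & filler_lens <= 8))

  # determinism and the empty case
  expect_identical(st, stream_single_chunk(n_repeats = 3, seed = 7))
  empty <- stream_single_chunk(n_repeats = 0, seed = 1)
  expect_length(empty$symbols, 0)
  expect_equal(nrow(empty$annotations), 0)

  expect_error(stream_single_chunk(chunk = 0:25, seed = 1), class = "dualrc_invalid")
  expect_error(stream_single_chunk(n_repeats = -1), class = "dualrc_invalid")
})

test_that("filler lengths are uniform over their range", {
  st <- stream_single_chunk(n_repeats = 10000, seed = 1)
  lens <- diff(c(st$annotations$start, length(st$symbols))) - 4L
  n <- length(lens)
  se <- sqrt(n * 0.25 * 0.75)
  counts <- table(factor(lens, levels = 5:8))
  expect_true(all(abs(counts - n / 4) < 4 * se))
})

test_that("multi-chunk streams respect occurrence probabilities and overlap", {
  st <- stream_multi_chunk(list(0:3, 4:7, 8:11), probs = rep(1 / 3, 3),
                           separated = FALSE, n_repeats = 9999, seed = 2)
  expect_length(st$symbols, 4 * 9999)
  counts <- table(factor(st$annotations$chunk, levels = 1:3))
  se <- sqrt(9999 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 3333) < 4 * se))

  # overlapping chunks sharing their tail
  ov <- stream_multi_chunk(list(c(0L, 1L, 2L, 3L), c(4L, 5L, 2L, 3L)),
                           n_repeats = 50, seed = 3)
  expect_setequal(unique(ov$annotations$chunk), 1:2)
  for (id in 1:2) {
    a <- dplyr::filter(ov$annotations, chunk == id)[1, ]
    expect_true(all(c(2L, 3L) %in% ov$symbols[(a$start + 1):a$end]))
  }

  # single chunk with probability one reduces to the single-chunk generator
  one <- stream_multi_chunk(list(0:3), probs = 1, separated = TRUE, seed = 9)
  ref <- stream_single_chunk(0:3, n_repeats = 100, seed = 9)
  expect_identical(one$symbols, ref$symbols)
  expect_identical(one$annotations, ref$annotations)

  expect_error(stream_multi_chunk(list(0:3, 4:7), probs = c(0.7, 0.7)),
               class = "dualrc_invalid")
})

test_that("chunk-size regime ties alphabet and filler sizes to the chunk size", {
  for (s in c(4L, 7L, 10L)) {
    reg <- chunk_size_regime(s)
    expect_length(reg$chunk, s)
    expect_equal(reg$alphabet_size, 5L * s)
    expect_equal(reg$filler_range, c(s + 2L, s + 5L))
    st <- stream_single_chunk(reg$chunk, reg$alphabet_size, n_repeats = 20,
                              filler_range = reg$filler_range, seed = s)
    fillers <- setdiff(unique(st$symbols), reg$chunk)
    expect_true(all(fillers >= s & fillers < 5L * s))
  }
})

test_that("biased letter streams have the requested letter frequencies", {
  st <- stream_biased_letters(10, n_symbols = 10000, seed = 4)
  counts <- table(factor(st$symbols, levels = 0:9))
  se <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(counts - 1000) < 4 * se))
  expect_equal(nrow(st$annotations), 0)

  probs <- c(2, rep(1, 9)) / 11
  st2 <- stream_biased_letters(10, probs, n_symbols = 11000, seed = 5)
  se0 <- sqrt(11000 * (2 / 11) * (9 / 11))
  expect_lt(abs(sum(st2$symbols == 0) - 2000), 4 * se0)

  expect_identical(stream_biased_letters(1, c(1), 100, seed = 1)$symbols,
                   rep(0L, 100))
  expect_error(stream_biased_letters(10, c(0.5, 0.5), 10),
               class = "dualrc_invalid")
})

test_that("the canonical community graph is degree-4 with a uniform walk", {
  g <- community_graph(3, 5)
  expect_equal(g$n_nodes, 15)
  expect_equal(nrow(g$edges), 30)
  expect_true(all(graph_degrees(g) == 4))
  P <- graph_transition(g)
  expect_true(all(rowSums(P) == 1))
  expect_true(all(apply(P, 1, function(r) sum(r == 0.25) == 4)))
  # stationary distribution of a regular graph walk is uniform
  pi0 <- rep(1 / 15, 15)
  expect_equal(drop(pi0 %*% P), pi0, tolerance = 1e-12)
  expect_error(community_graph(2, 5), class = "dualrc_invalid")
  expect_error(community_graph(3, 2), class = "dualrc_invalid")
})

test_that("graph walks follow edges and are annotated by community runs", {
  g <- community_graph()
  st <- stream_graph_walk(g, 3000, seed = 3)
  A <- graph_adjacency(g)
  nodes <- st$symbols + 1L
  expect_true(all(A[cbind(nodes[-length(nodes)], nodes[-1])] == 1))
  # annotations are exactly the maximal same-community runs
  comm <- g$membership$community[nodes]
  runs <- rle(comm)
  expect_equal(st$annotations$chunk, runs$values)
  expect_equal(diff(c(0, cumsum(runs$lengths))), st$annotations$end -
                 st$annotations$start)

  # long-run transition frequencies are 1/4 per neighbor, and the
  # community-crossing rate matches the exact Markov-chain value
  st_long <- stream_graph_walk(g, 100000, seed = 3)
  nodes <- st_long$symbols + 1L
  from <- nodes[-length(nodes)]; to <- nodes[-1]
  for (i in c(1, 5, 8)) {
    nb <- which(A[i, ] == 1)
    cnt <- table(factor(to[from == i], levels = nb))
    n_i <- sum(from == i)
    se <- sqrt(n_i * 0.25 * 0.75)
    expect_true(all(abs(cnt - n_i / 4) < 4 * se))
  }
  P <- graph_transition(g)
  cross <- outer(g$membership$community, g$membership$community, "!=")
  exact <- sum(rep(1 / 15, 15) * rowSums(P * cross))
  obs <- mean(g$membership$community[from] != g$membership$community[to])
  expect_lt(abs(obs - exact), 4 * sqrt(exact * (1 - exact) / length(from)))
  expect_error(stream_graph_walk(g, 0), class = "dualrc_invalid")
})

test_that("image streams schedule 250-ms slots of frames and noise", {
  im <- stream_images(2, c(97, 97), with_noise_slots = TRUE, n_slots = 100,
                      seed = 5)
  expect_equal(nrow(im$schedule), 100)
  expect_true(all(im$schedule$duration_ms == 250))
  expect_true(all(im$schedule$label[!im$schedule$is_noise] %in% 1:2))
  expect_true(any(im$schedule$is_noise))
  expect_equal(dim(im$frames[[1]]), c(97, 97, 3))
  expect_true(all(im$frames[[1]] >= 0 & im$frames[[1]] <= 1))

  lo <- stream_images(2, c(32, 32), n_slots = 10, seed = 5)
  expect_equal(dim(lo$frames[[1]]), c(32, 32, 3))

  one <- stream_images(1, c(16, 16), with_noise_slots = FALSE, n_slots = 10,
                       seed = 6)
  expect_true(all(one$schedule$label == 1))
  expect_identical(stream_images(2, c(16, 16), n_slots = 5, seed = 7)$schedule,
                   stream_images(2, c(16, 16), n_slots = 5, seed = 7)$schedule)
  expect_error(stream_images(2, c(0, 16)), class = "dualrc_invalid")
})

test_that("streams and graphs round-trip through their text formats", {
  st <- stream_single_chunk(n_repeats = 10, seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_symbol_stream(st, path)
  back <- read_symbol_stream(path)
  expect_identical(back$symbols, st$symbols)
  expect_equal(back$annotations, st$annotations)

  big <- stream_biased_letters(40, n_symbols = 50, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_symbol_stream(big, path2)
  expect_identical(read_symbol_stream(path2)$symbols, big$symbols)

  g <- community_graph()
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tsv(g, gpath)
  g2 <- read_graph_tsv(gpath)
  expect_equal(graph_adjacency(g2), graph_adjacency(g))
  expect_equal(g2$membership$community, g$membership$community)
})
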