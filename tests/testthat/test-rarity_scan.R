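test_that("structure extremes agree with exhaustive stepped enumeration", {
  for (seed in c(3L, 19L)) {
    tr <- make_random_walk(n_points = 75L, seed = seed)
    tab <- build_writhe_table(tr)
    ex <- structure_extremes(tab, window_segments = 15L, step = 2L,
                             trace = tr)
    ref <- stepped_pairs_brute(tr, 15L, 2L)
    expect_equal(ex$best_pos$mutual_writhe, max(ref$mw), tolerance = 1e-9)
    expect_equal(ex$best_neg$mutual_writhe, min(ref$mw), tolerance = 1e-9)
    i <- order(-ref$mw, ref$a, ref$b)[1]
    expect_equal(ex$best_pos$A_first, ref$a[i])
    expect_equal(ex$best_pos$B_first, ref$b[i])
    # window starts stay on the stepped grid
    expect_true(all(c(ex$best_pos$A_first, ex$best_pos$B_first,
                      ex$best_neg$A_first, ex$best_neg$B_first) %% 2 == 0))
  }
})

test_that("extremes of degenerate traces", {
  line <- ca_trace(cbind(3.8 * (0:70), 0, 0))
  ex <- structure_extremes(build_writhe_table(line), 30L, 2L, trace = line)
  expect_identical(ex$best_pos$mutual_writhe, 0)
  expect_identical(ex$best_neg$mutual_writhe, 0)
  short <- make_random_walk(n_points = 30L, seed = 1L)
  expect_false(structure_extremes(build_writhe_table(short), 30L, 2L)$ok)
})

test_that("background build is order-invariant and round-trips through disk", {
  traces <- lapply(1:12, function(s) make_random_walk(70L, seed = s))
  bg <- build_background(traces, window_segments = 15L, step = 2L)
  expect_equal(nrow(bg$entries), 12L)
  bg_shuffled <- build_background(traces[c(7:12, 1:6)],
                                  window_segments = 15L, step = 2L)
  expect_identical(bg, bg_shuffled)

  p <- withr::local_tempfile(fileext = ".tsv.gz")
  write_background(bg, p)
  back <- read_background(p)
  expect_identical(back$params, bg$params)
  expect_equal(back$entries$pos_score, bg$entries$pos_score)
  expect_equal(back$entries$neg_score, bg$entries$neg_score)
  expect_identical(back$entries$structure_id, bg$entries$structure_id)
  # traces too short for any pair are skipped with a warning
  expect_warning(
    bg2 <- build_background(c(traces[1:2],
                              list(make_random_walk(20L, seed = 99L))),
                            window_segments = 15L, step = 2L),
    "skipped")
  expect_equal(nrow(bg2$entries), 2L)
})

test_that("exceedance probabilities behave like one-sided empirical frequencies", {
  traces <- lapply(1:15, function(s) make_random_walk(70L, seed = 100L + s))
  bg <- build_background(traces, window_segments = 15L, step = 2L)
  scores <- rar0_scan(traces, bg)
  n <- nrow(bg$entries)
  # a background member always exceeds itself
  expect_true(all(scores$prob_pos >= 1 / n))
  expect_true(all(scores$prob_neg >= 1 / n))
  expect_true(all(scores$prob_pos <= 1 & scores$prob_neg <= 1))
  # rank-uniformity: mean self-exceedance of distinct scores is (N+1)/2N
  expect_equal(mean(scores$prob_pos), (n + 1) / (2 * n), tolerance = 1e-12)
  # monotonicity: larger positive extreme never has larger prob_pos
  ord <- order(-scores$pos_score)
  expect_true(all(diff(scores$prob_pos[ord]) >= 0))
  # ranks are 1-based positions in the decreasing-score order
  expect_equal(scores$rank_pos, seq_len(nrow(scores)))
  expect_equal(sort(scores$rank_neg), seq_len(nrow(scores)))
})

test_that("a planted Hopf link outranks a random-walk background", {
  bg <- build_background(lapply(1:60, function(s)
    make_random_walk(64L, seed = 200L + s)),
    window_segments = 30L, step = 2L)
  query <- make_hopf_link_chain()
  scores <- rar0_scan(c(list(query), lapply(61:70, function(s)
    make_random_walk(64L, seed = 200L + s))), bg)
  expect_equal(scores$structure_id[1], "hopf_link_chain")
  expect_equal(scores$rank_pos[1], 1L)
  # the mirrored link tops the negative list instead
  mir <- make_hopf_link_chain(handedness = -1)
  scores2 <- rar0_scan(c(list(mir), lapply(61:70, function(s)
    make_random_walk(64L, seed = 200L + s))), bg, rank_by = "neg")
  expect_equal(scores2$structure_id[1], "hopf_link_chain")
  expect_equal(scores2$rank_neg[1], 1L)
})

test_that("the two tails are ranked independently on asymmetric data", {
  # a right-handed link population plus one mirrored query: the mirror is
  # common on the positive tail's scale but extreme on the negative
  bg_traces <- c(lapply(1:8, function(s) make_random_walk(64L, seed = s)),
                 list(make_hopf_link_chain()))
  bg <- build_background(bg_traces, window_segments = 30L, step = 2L)
  mir <- make_hopf_link_chain(handedness = -1)
  sc <- rar0_scan(list(mir), bg)
  expect_equal(sc$prob_neg, 0)
  expect_gt(sc$prob_pos, 0)
})

test_that("content score sums writhe beyond the threshold per tail", {
  tr <- make_hopf_link_chain()
  tab <- build_writhe_table(tr)
  ct <- structure_content(tab, 30L, 2L, threshold = 0.5)
  ref <- stepped_pairs_brute(tr, 30L, 2L)
  expect_equal(ct$pos, sum(ref$mw[ref$mw >= 0.5]), tolerance = 1e-9)
  expect_equal(ct$neg, sum(ref$mw[ref$mw <= -0.5]), tolerance = 1e-9)
  bg <- build_background(list(tr, make_random_walk(64L, seed = 5L)),
                         window_segments = 30L, step = 2L,
                         score = "content", threshold = 0.5)
  expect_equal(bg$params$score, "content")
  expect_gt(bg$entries$pos_score[bg$entries$structure_id ==
                                   "hopf_link_chain"], 0)
})

test_that("scan reports serialise with probability and rank columns", {
  traces <- lapply(1:5, function(s) make_random_walk(70L, seed = 300L + s))
  bg <- build_background(traces, window_segments = 15L, step = 2L)
  sc <- rar0_scan(traces, bg)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scan_report(sc, p, header = list(window = 15))
  df <- read.table(p, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(df), 5L)
  expect_true(all(c("structure_chain", "pos_pair", "prob_pos",
                    "rank_pos") %in% names(df)))
  # printed pairs are vertex ranges: (first, last + 1)
  expect_match(df$pos_pair[1], "^\\(\\d+,\\d+\\);\\(\\d+,\\d+\\)$")
})
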