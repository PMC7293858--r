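# brute-force loop enumeration, independent of find_closed_loops
enumerate_loops <- function(trace, min_seg = 6L, max_seg = 30L,
                            closure = 7.0) {
  pts <- trace$points
  S <- n_segments(trace)
  out <- NULL
  for (a in 0:(S - min_seg))
    for (b in (a + min_seg - 1L):min(S - 1L, a + max_seg - 1L)) {
      d <- sqrt(sum((pts[a + 1L, ] - pts[b + 2L, ])^2))
      if (d <= closure) out <- rbind(out, c(a, b))
    }
  out
}

test_that("closed-loop finder agrees with brute-force enumeration", {
  for (tr in list(make_ring_with_tails(), make_hopf_link_chain(),
                  make_pierced_loop(), make_random_walk(50L, seed = 17L))) {
    loops <- find_closed_loops(tr)
    ref <- enumerate_loops(tr)
    if (is.null(ref)) {
      expect_equal(nrow(loops), 0L)
    } else {
      ref <- ref[order(ref[, 1], ref[, 2]), , drop = FALSE]
      expect_equal(cbind(loops$first, loops$last), ref, ignore_attr = TRUE)
    }
  }
})

test_that("loop finder applies the length and closure constraints", {
  # straight trace: termini far apart at every eligible length
  line <- ca_trace(cbind(3.8 * (0:30), 0, 0))
  expect_equal(nrow(find_closed_loops(line)), 0L)
  # the planar ring interval qualifies
  rt <- make_ring_with_tails(ring_segments = 20L, closure = 5)
  loops <- find_closed_loops(rt)
  ring <- attr(rt, "ring_interval")
  expect_true(any(loops$first == ring[1] & loops$last == ring[2]))
  expect_true(all(loops$n_segments >= 6 & loops$n_segments <= 30))
  expect_true(all(loops$closure_distance <= 7))
  # a 5-segment near-closed turn is below the minimum length
  small <- make_ring_with_tails(ring_segments = 5L, closure = 3)
  expect_false(any(find_closed_loops(small)$n_segments < 6))
})

test_that("link search flags the Hopf 1-link and ignores side-by-side loops", {
  tr <- make_hopf_link_chain()
  tab <- build_writhe_table(tr)
  loops <- find_closed_loops(tr)
  links <- link_search(tab, loops, trace = tr)
  expect_true(all(links$A_last < links$B_first))
  best <- links[which.max(abs(links$mutual_writhe)), ]
  expect_gte(abs(best$mutual_writhe), 0.9)
  expect_lte(abs(best$mutual_writhe), 1.1)
  # every reported value matches the brute-force cross sum
  wm <- pairwise_writhe_matrix(tr)
  for (i in seq_len(nrow(links)))
    expect_lt(abs(links$mutual_writhe[i] -
                    gauss_integral_oracle(tr, c(links$A_first[i], links$A_last[i]),
                                          c(links$B_first[i], links$B_last[i]),
                                          wm = wm)), 1e-9)

  # two coplanar side-by-side rings: no linking
  ring1 <- make_ring_with_tails(tail_points = 2L)
  shift <- ring1$points
  shift[, 1] <- shift[, 1] + 60
  flat <- ca_trace(rbind(ring1$points, shift), structure_id = "two_flat")
  tab2 <- build_writhe_table(flat)
  loops2 <- find_closed_loops(flat)
  links2 <- link_search(tab2, loops2, trace = flat)
  expect_gt(nrow(links2), 0L)
  expect_lt(max(abs(links2$mutual_writhe)), 0.1)
})

test_that("poke search ranks the piercing rod above grazing and far rods", {
  tr <- make_pierced_loop()
  tab <- build_writhe_table(tr)
  loops <- find_closed_loops(tr)
  pokes <- poke_search(tab, loops, tr, poke_segments = 10L, keep = 5L)
  expect_true(all(pokes$kind == "poke"))
  expect_lte(nrow(pokes), 10L)
  rod <- attr(tr, "rod_interval")
  top <- pokes[which.max(abs(pokes$mutual_writhe)), ]
  # the top poke's 10-segment rod overlaps the planted rod
  expect_true(top$B_first <= rod[2] && top$B_last >= rod[1] ||
                top$A_first <= rod[2] && top$A_last >= rod[1])
  expect_gt(abs(top$mutual_writhe), 0.6)
})

test_that("unrestricted search equals the brute-force scan of window pairs", {
  tr <- make_random_walk(n_points = 80L, seed = 23L)
  tab <- build_writhe_table(tr)
  got <- unrestricted_search(tab, window_segments = 30L, keep = 5L,
                             trace = tr)
  ref <- stepped_pairs_brute(tr, 30L, 1L)
  ref_lo <- ref[order(ref$mw, ref$a, ref$b), ][1:5, ]
  ref_hi <- ref[order(-ref$mw, ref$a, ref$b), ][1:5, ]
  expect_equal(got$min_records$A_first, ref_lo$a)
  expect_equal(got$min_records$B_first, ref_lo$b)
  expect_equal(got$min_records$mutual_writhe, ref_lo$mw, tolerance = 1e-9)
  expect_equal(got$max_records$A_first, ref_hi$a)
  expect_equal(got$max_records$mutual_writhe, ref_hi$mw, tolerance = 1e-9)
})

test_that("unrestricted search on degenerate inputs", {
  # colinear trace: all mutual writhes are exactly 0
  line <- ca_trace(cbind(3.8 * (0:70), 0, 0))
  got <- unrestricted_search(build_writhe_table(line), 30L, keep = 3L,
                             trace = line)
  expect_true(all(got$min_records$mutual_writhe == 0))
  expect_true(all(got$max_records$mutual_writhe == 0))
  # too short for a disjoint pair: empty result
  short <- make_random_walk(n_points = 40L, seed = 3L)
  got2 <- unrestricted_search(build_writhe_table(short), 30L, trace = short)
  expect_equal(nrow(got2$min_records), 0L)
})

test_that("restricted hits reappear among unrestricted extremes on the Hopf fixture", {
  tr <- make_hopf_link_chain()
  tab <- build_writhe_table(tr)
  links <- link_search(tab, find_closed_loops(tr), trace = tr)
  best <- links[which.max(abs(links$mutual_writhe)), ]
  un <- unrestricted_search(tab, window_segments = best$A_last -
                              best$A_first + 1L, keep = 10L, trace = tr)
  ext <- if (best$mutual_writhe > 0) un$max_records else un$min_records
  # some extreme window pair covers both rings of the link
  covers <- ext$A_first <= best$A_first & ext$A_last >= best$A_last &
    ext$B_first <= best$B_first & ext$B_last >= best$B_last
  overlaps <- ext$A_first <= best$A_last & ext$A_last >= best$A_first &
    ext$B_first <= best$B_last & ext$B_last >= best$B_first
  expect_true(any(overlaps))
  expect_gte(max(abs(ext$mutual_writhe)), 0.9)
})

test_that("search output is invariant under rigid motion", {
  tr <- make_hopf_link_chain()
  tab <- build_writhe_table(tr)
  loops <- find_closed_loops(tr)
  links <- link_search(tab, loops, trace = tr)
  set.seed(41)
  m <- random_rigid_motion()
  tr2 <- transform_trace(tr, m$rotation, m$translation)
  tab2 <- build_writhe_table(tr2)
  loops2 <- find_closed_loops(tr2)
  expect_equal(loops2$first, loops$first)
  expect_equal(loops2$closure_distance, loops$closure_distance,
               tolerance = 1e-10)
  links2 <- link_search(tab2, loops2, trace = tr2)
  expect_equal(links2$A_first, links$A_first)
  expect_lt(max(abs(links2$mutual_writhe - links$mutual_writhe)), 1e-10)
  # window extremes on an asymmetric trace (no near-tied values)
  walk <- make_random_walk(60L, seed = 47L)
  tw <- build_writhe_table(walk)
  un <- unrestricted_search(tw, 15L, keep = 5L, trace = walk)
  walk2 <- transform_trace(walk, m$rotation, m$translation)
  un2 <- unrestricted_search(build_writhe_table(walk2), 15L, keep = 5L,
                             trace = walk2)
  expect_equal(un2$max_records$A_first, un$max_records$A_first)
  expect_lt(max(abs(un2$max_records$mutual_writhe -
                      un$max_records$mutual_writhe)), 1e-10)
})

test_that("pair records serialise as sorted 6-decimal TSV", {
  tr <- make_hopf_link_chain()
  tab <- build_writhe_table(tr)
  links <- link_search(tab, find_closed_loops(tr), trace = tr)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_pair_records(links, p, header = list(kind = "link"))
  lines <- readLines(p)
  expect_match(lines[1], "^# \\{")
  df <- read.table(p, sep = "\t", header = TRUE, comment.char = "#")
  expect_false(is.unsorted(df$mutual_writhe))
})
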