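# Exhaustive oracles, written independently of the implementation.

window_count_oracle <- function(positions, support, w, starts) {
  vapply(starts, function(s) {
    sum(support[positions >= s & positions < s + w])
  }, numeric(1))
}

peak_oracle <- function(counts, min_sep) {
  n <- length(counts)
  cand <- integer(0)
  for (i in seq_len(n)) {
    # leftmost index of its plateau
    if (i > 1 && counts[i - 1] == counts[i]) next
    # value left of the plateau
    left <- if (i == 1) -Inf else counts[i - 1]
    j <- i
    while (j < n && counts[j + 1] == counts[i]) j <- j + 1
    right <- if (j == n) -Inf else counts[j + 1]
    if (counts[i] > left && counts[i] > right) cand <- c(cand, i)
  }
  if (length(cand) <= 1) return(cand)
  kept <- integer(0)
  for (i in cand[order(-counts[cand], cand)]) {
    if (all(abs(i - kept) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

test_that("hotspot grouping splits at gaps of max_gap and above", {
  p <- call_params()
  t1 <- make_track(c(100, 105, 109), "+", "fwd", 1)
  r1 <- group_hotspots(t1, p)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(100L, 110L))

  t2 <- make_track(c(100, 110), "+", "fwd", 1)
  expect_equal(nrow(group_hotspots(t2, p)), 2)

  t3 <- make_track(c(100, 109, 118), "+", "fwd", 1)
  expect_equal(nrow(group_hotspots(t3, p)), 1)  # chained gaps of 9

  expect_equal(nrow(group_hotspots(t1[0, ], p)), 0)

  # pooled across strands and libraries
  t4 <- dplyr::bind_rows(make_track(100, "+", "fwd", 3),
                         make_track(104, "-", "rev", 3))
  expect_equal(nrow(group_hotspots(t4, p)), 1)
})

test_that("window counts match brute-force enumeration on toy tracks", {
  p <- call_params()
  m1 <- make_track(100, "+", "fwd", 6)
  wc1 <- window_counts(m1, p)
  expect_equal(wc1$window_start, 91:100)
  expect_true(all(wc1$total == 6))

  m2 <- dplyr::bind_rows(make_track(100, "+", "fwd", 3),
                         make_track(104, "-", "fwd", 3))
  wc2 <- window_counts(m2, p)
  # a window of length 10 can hold both positions; [95,105) does
  expect_equal(wc2$total[wc2$window_start == 95], 6)
  expect_equal(wc2$total[wc2$window_start == 96], 6)
  oracle <- window_count_oracle(c(100, 104), c(3, 3), 10, wc2$window_start)
  expect_equal(wc2$total, as.integer(oracle))
})

test_that("window counting equals the oracle on random tracks", {
  set.seed(11)
  p <- call_params()
  for (trial in 1:50) {
    pos <- sort(sample(0:180, sample(2:15, 1)))
    sup <- sample(1:9, length(pos), replace = TRUE)
    m <- make_track(pos, "+", "fwd", sup)
    # keep one region: collapse to positions within one hotspot
    m <- m[cumsum(c(0, diff(pos)) >= p$max_gap) == 0, ]
    wc <- window_counts(m, p)
    oracle <- window_count_oracle(m$junction, m$support, p$window,
                                  wc$window_start)
    expect_equal(wc$total, as.integer(oracle))
  }
})

test_that("peak detection obeys the strict-maximum and plateau rules", {
  p <- call_params(min_peak_separation = 1L)
  expect_equal(detect_peaks(c(0, 2, 6, 2, 0), p), 3L)
  expect_equal(detect_peaks(c(0, 6, 6, 0), p), 2L)
  expect_equal(detect_peaks(numeric(0), p), integer(0))
  expect_equal(detect_peaks(c(5, 5, 5), p), 1L)
  expect_equal(detect_peaks(c(1, 5, 1, 7, 1), p), c(2L, 4L))
})

test_that("peak detection equals the exhaustive oracle on random vectors", {
  set.seed(12)
  for (trial in 1:200) {
    v <- sample(0:8, 30, replace = TRUE)
    sep <- sample(c(1L, 5L, 10L), 1)
    p <- call_params(min_peak_separation = sep)
    expect_equal(detect_peaks(v, p), peak_oracle(v, sep))
  }
})

test_that("bidirectional support rule flags exactly the stated patterns", {
  p <- call_params()
  # 6/6 on +/- strands -> flagged as both-strands
  m <- dplyr::bind_rows(make_track(100, "+", "fwd", 6),
                        make_track(100, "-", "fwd", 6))
  s <- flag_dsb_sites(m, 95L, p)
  expect_equal(nrow(s), 1)
  expect_equal(s$evidence_class, "both-strands")
  expect_equal(s$cut_position, 100L)

  # 6/5 fails the strand branch; fwd/rev 6/6 on one strand passes the
  # library branch
  m2 <- dplyr::bind_rows(make_track(100, "+", "fwd", 6),
                         make_track(100, "+", "rev", 6),
                         make_track(101, "-", "fwd", 5))
  s2 <- flag_dsb_sites(m2, 95L, p)
  expect_equal(s2$evidence_class, "both-libraries")

  # 12/0 in a single library never flags
  m3 <- make_track(100, "+", "fwd", 12)
  expect_equal(nrow(flag_dsb_sites(m3, 95L, p)), 0)

  # modal junction tie breaks leftmost
  m4 <- dplyr::bind_rows(make_track(c(100, 102), "+", "fwd", c(6, 6)),
                         make_track(c(100, 102), "-", "rev", c(6, 6)))
  s4 <- flag_dsb_sites(m4, 95L, p)
  expect_equal(s4$cut_position, 100L)
})

test_that("raising min_support never increases the number of sites", {
  s <- small_rgn_sim(reads_per_site = 30L, background = 30L, seed = 17L)
  tracks <- sim_tracks(s$sr)
  counts <- vapply(3:12, function(ms) {
    nrow(call_dsb_sites(tracks, call_params(min_support = ms)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted sites are recovered exactly and nothing else is called", {
  s <- small_rgn_sim(cuts = c(10000L, 25000L, 40000L),
                     mismatches = c(0L, 2L, 5L),
                     reads_per_site = 40L, seed = 23L)
  tracks <- sim_tracks(s$sr)
  sites <- call_dsb_sites(tracks)
  expect_equal(nrow(sites), 3)
  truth <- sort(s$sg$sites$cut_position)
  called <- sort(sites$cut_position)
  expect_true(all(abs(called - truth) <= 1))
  expect_true(all(vapply(sites$cut_position, function(x) {
    min(abs(x - truth)) <= 25
  }, logical(1))))
  expect_s3_class(sites, "dsb_sites")
  expect_true(all(diff(sites$total_support) <= 0))
})
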