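# Exhaustive offset/strand scan oracle for ungapped guide matching.
sw_oracle <- function(grna, window) {
  L <- nchar(grna)
  W <- nchar(window)
  g <- strsplit(grna, "")[[1]]
  best <- Inf
  score_at <- function(win, off) {
    wv <- strsplit(win, "")[[1]]
    mm <- 0
    for (i in seq_len(L)) {
      p <- off + i
      if (p < 1 || p > W) mm <- mm + 1
      else if (wv[p] != g[i] || wv[p] == "N") mm <- mm + 1
    }
    mm
  }
  for (off in (-L):(W)) {
    best <- min(best, score_at(window, off), score_at(rc_oracle(window), off))
  }
  best
}

test_that("flank extraction is exact arithmetic with edge handling", {
  g <- list(chr1 = random_seq(2000, seed = 31))
  fl <- extract_flank(g, "chr1", 1000L, 25L)
  expect_equal(fl$start, 975L)
  expect_equal(fl$end, 1025L)
  expect_equal(nchar(fl$seq), 50)
  expect_equal(fl$seq, substr(g$chr1, 976, 1025))
  expect_false(fl$edge)
  expect_equal(rc_oracle(rc_oracle(fl$seq)), fl$seq)  # involution
  expect_equal(fl$revcomp, rc_oracle(fl$seq))

  expect_true(extract_flank(g, "chr1", 10L, 25L)$edge)
  expect_true(extract_flank(g, "chr1", 1990L, 25L)$edge)
})

test_that("verbatim and mutated guides are scored exactly", {
  grna <- "GGTCACCTAGATGCTGACGT"
  left <- random_seq(15, seed = 32)
  right <- random_seq(15, seed = 33)
  m0 <- sw_match(grna, paste0(left, grna, right))
  expect_equal(m0$mismatches, 0L)
  expect_equal(m0$start, 15L)
  expect_equal(m0$strand, "+")
  expect_equal(m0$matched_seq, grna)
  expect_length(m0$mismatch_positions, 0)

  # plant 7 substitutions -> beyond the off-target limit
  mut <- grna
  for (i in c(1, 4, 7, 10, 13, 16, 19)) {
    substr(mut, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, i, i))[1]
  }
  m7 <- sw_match(grna, paste0(left, mut, right))
  expect_equal(m7$mismatches, 7L)
  expect_equal(sort(m7$mismatch_positions), c(1, 4, 7, 10, 13, 16, 19))

  # reverse-complement placement is found on the minus strand
  mrc <- sw_match(grna, paste0(left, rc_oracle(grna), right))
  expect_equal(mrc$mismatches, 0L)
  expect_equal(mrc$strand, "-")
})

test_that("guide matching equals the exhaustive scan on random pairs", {
  set.seed(34)
  for (trial in 1:50) {
    L <- sample(6:12, 1)
    grna <- random_seq(L)
    window <- random_seq(sample(15:30, 1))
    expect_equal(sw_match(grna, window)$mismatches,
                 sw_oracle(grna, window))
  }
})

test_that("mismatch counting agrees with Biostrings fixed-width matching", {
  # independent cross-check: a site has <= m mismatches iff vcountPattern
  # finds the guide at max.mismatch = m on either strand
  set.seed(35)
  for (trial in 1:20) {
    grna <- random_seq(10)
    window <- random_seq(30)
    mm <- sw_match(grna, window)$mismatches
    hits_at <- function(m) {
      Biostrings::vcountPattern(grna, Biostrings::DNAStringSet(
        c(window, rc_oracle(window))), max.mismatch = m) |> sum()
    }
    expect_gt(hits_at(mm), 0)
    if (mm > 0) expect_equal(hits_at(mm - 1), 0)
  }
})

test_that("sites are classified on/off/unmatched with exact planted counts", {
  s <- small_rgn_sim(cuts = c(10000L, 25000L, 40000L),
                     mismatches = c(0L, 6L, 7L),
                     reads_per_site = 40L, seed = 36L)
  tracks <- sim_tracks(s$sr)
  sites <- call_dsb_sites(tracks)
  hits <- annotate_offtargets(sites, s$sg$genome, s$cfg$grna)
  byc <- hits[match(s$sg$sites$cut_position, hits$cut_position), ]
  expect_equal(byc$classification, c("on-target", "off-target", "unmatched"))
  expect_equal(byc$mismatches[1:2], c(0L, 6L))
  # reported mismatch counts equal planted counts for matched sites
  expect_equal(byc$protospacer[2], s$sg$sites$protospacer[2])
  # PAM annotation shows the planted NGG
  expect_match(byc$pam_observed[1], "GG$")
})

test_that("lowering max_mismatches never adds off-target rows", {
  s <- small_rgn_sim(cuts = c(10000L, 25000L, 40000L),
                     mismatches = c(0L, 3L, 6L),
                     reads_per_site = 40L, seed = 37L)
  sites <- call_dsb_sites(sim_tracks(s$sr))
  n_off <- vapply(6:0, function(mm) {
    h <- annotate_offtargets(sites, s$sg$genome, s$cfg$grna,
                             match_params(max_mismatches = mm))
    sum(h$classification == "off-target")
  }, numeric(1))
  expect_true(all(diff(n_off) <= 0))
})

test_that("strict PAM mode rejects placements without the pattern", {
  g <- list(chr1 = paste0(random_seq(500, seed = 38),
                          "GGTCACCTAGATGCTGACGT", "TAA",  # no NGG
                          random_seq(500, seed = 39)))
  sites <- tibble::tibble(chrom = "chr1", cut_position = 517L,
                          total_support = 10L)
  lax <- annotate_offtargets(sites, g, "GGTCACCTAGATGCTGACGT",
                             match_params(require_pam = FALSE))
  expect_equal(lax$classification, "on-target")
  strict <- annotate_offtargets(sites, g, "GGTCACCTAGATGCTGACGT",
                                match_params(require_pam = TRUE))
  expect_equal(strict$classification, "unmatched")
})

test_that("the report is sorted by read count with documented tie-breaks", {
  hits <- tibble::tibble(
    chrom = c("chr1", "chr2", "chr1", "chr1"),
    cut_position = c(500L, 100L, 100L, 900L),
    read_count = c(10L, 300L, 40L, 40L),
    protospacer = "ACGT", proto_start = 1L, proto_end = 5L,
    proto_strand = "+", mismatches = c(2L, 0L, 1L, 1L),
    mismatch_positions = list(c(1L, 3L), integer(0), 2L, 2L),
    pam_observed = "AGG", classification = c("off-target", "on-target",
                                             "off-target", "off-target")
  )
  attr(hits, "grna") <- "ACGT"
  class(hits) <- c("offtarget_hits", class(hits))
  rep <- classify_and_report(hits)
  expect_equal(rep$matched$read_count, c(300L, 40L, 40L, 10L))
  # equal counts: stable (chrom, position) order
  expect_equal(rep$matched$cut_position[2:3], c(100L, 900L))
  # on-target row has no highlighted positions
  expect_equal(rep$matched$mismatch_string[1], "....")
  expect_equal(rep$matched$mismatch_string[2], ".*..")
})
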