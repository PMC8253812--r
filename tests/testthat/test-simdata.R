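test_that("planted protospacers carry exactly the requested mismatches", {
  s <- small_rgn_sim(cuts = c(10000L, 25000L, 40000L),
                     mismatches = c(0L, 3L, 6L), reads_per_site = 0L)
  cfg <- s$cfg
  sg <- s$sg
  # by construction
  expect_equal(
    mapply(function(p) sum(strsplit(p, "")[[1]] !=
                             strsplit(cfg$grna, "")[[1]]),
           sg$sites$protospacer),
    setNames(c(0, 3, 6), sg$sites$protospacer),
    ignore_attr = TRUE
  )
  # the planted spacer is recoverable from the +/-25 bp flank of the cut
  for (i in seq_len(nrow(sg$sites))) {
    st <- sg$sites[i, ]
    flank <- substr(sg$genome[[st$chrom]], st$cut_position - 25 + 1,
                    st$cut_position + 25)
    if (st$mismatches == 0) {
      expect_true(grepl(cfg$grna, flank, fixed = TRUE))
    } else {
      expect_true(grepl(st$protospacer, flank, fixed = TRUE))
    }
  }
})

test_that("PAM is planted next to the protospacer and matches the pattern", {
  s <- small_rgn_sim(mismatches = c(2L, 4L), reads_per_site = 0L)
  for (i in seq_len(nrow(s$sg$sites))) {
    st <- s$sg$sites[i, ]
    pam <- substr(s$sg$genome[[st$chrom]], st$proto_end + 1,
                  st$proto_end + 3)
    expect_match(pam, "^.GG$")
  }
})

test_that("minus-strand planted sites are the reverse complement layout", {
  cfg <- sim_config(
    genome_length = 30000L,
    planted_sites = planted_site(cut_position = 15000L, strand = "-"),
    reads_per_site = 0L, seed = 3L
  )
  sg <- simulate_genome(cfg)
  st <- sg$sites[1, ]
  top <- substr(sg$genome[["chr1"]], st$proto_start + 1, st$proto_end)
  expect_equal(rc_oracle(top), cfg$grna)
  # PAM (NGG) sits 5' of the top-strand interval, reverse-complemented (CCN)
  pam_top <- substr(sg$genome[["chr1"]], st$proto_start - 3 + 1, st$proto_start)
  expect_match(pam_top, "^CC.$")
})

test_that("same seed gives byte-identical FASTA, reads and truth", {
  s1 <- small_rgn_sim(seed = 42L)
  s2 <- small_rgn_sim(seed = 42L)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(s1$sg$genome, f1)
  write_fasta(s2$sg$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$sr$reads, s2$sr$reads)
  expect_identical(s1$sr$truth, s2$sr$truth)
  s3 <- small_rgn_sim(seed = 43L)
  expect_false(identical(s1$sg$genome, s3$sg$genome))
})

test_that("every emitted read appears exactly once in the truth table", {
  s <- small_rgn_sim(background = 20L, pcr_duplicate_rate = 0.3)
  expect_equal(nrow(s$sr$reads), nrow(s$sr$truth))
  expect_false(anyDuplicated(s$sr$truth$read_id) > 0)
  expect_setequal(s$sr$reads$read_id, s$sr$truth$read_id)
})

test_that("blunt cuts give equal modal junctions on both strands", {
  s <- small_rgn_sim(cuts = 10000L, mismatches = 0L, overhang = 0L,
                     reads_per_site = 200L)
  tr <- s$sr$truth
  expect_equal(unique(tr$junction[tr$strand == "+"]), 10000L)
  expect_equal(unique(tr$junction[tr$strand == "-"]), 10000L)
})

test_that("junction arithmetic matches the hand-enumerated duplex oracle", {
  # 10-bp toy duplex cut at position c with 5' overhang k:
  #   top strand nicked before base c, bottom strand nicked before base c+k
  #   (fill-in extends the left fragment's top strand to c+k). Reads out of
  #   the Tag therefore start at c (+ strand) and end at c+k (- strand),
  #   so minus-junction - plus-junction == k for every k.
  duplex_offset_oracle <- function(k) {
    c0 <- 5L
    right_start <- c0          # first retained top-strand base right of cut
    left_end <- c0 + k         # one past last top-strand base after fill-in
    left_end - right_start + 0L
  }
  for (k in c(-2L, -1L, 0L, 1L, 2L, 4L)) {
    expect_equal(duplex_offset_oracle(k), k)
    s <- small_rgn_sim(cuts = 10000L, mismatches = 0L, overhang = k,
                       reads_per_site = 100L, seed = 20L + k)
    tr <- s$sr$truth
    plus_modal <- as.integer(names(which.max(
      table(tr$junction[tr$strand == "+"]))))
    minus_modal <- as.integer(names(which.max(
      table(tr$junction[tr$strand == "-"]))))
    expect_equal(minus_modal - plus_modal, k)
  }
})

test_that("zero duplicate rate means unique (UMI, position) molecules", {
  s <- small_rgn_sim(reads_per_site = 100L, pcr_duplicate_rate = 0)
  keys <- paste(s$sr$truth$umi, s$sr$truth$junction, s$sr$truth$strand,
                s$sr$truth$library)
  expect_false(anyDuplicated(keys) > 0)
  s2 <- small_rgn_sim(reads_per_site = 100L, pcr_duplicate_rate = 0.5)
  expect_gt(sum(s2$sr$truth$is_pcr_duplicate), 0)
})

test_that("infeasible configs fail with the offending site named", {
  cfg <- sim_config(
    genome_length = 1000L,
    planted_sites = planted_site(cut_position = 5L),
    seed = 1L
  )
  expect_error(simulate_genome(cfg), "site 1.*flank clearance")
  expect_error(
    sim_config(read_length = 10L),
    "read_length shorter"
  )
})

test_that("read 2 starts with the tag prefix followed by junction sequence", {
  s <- small_rgn_sim(cuts = 10000L, mismatches = 0L, reads_per_site = 30L)
  cfg <- s$cfg
  prefix <- substr(cfg$tag_sequence, 1, cfg$tag_r2_prefix_length)
  expect_true(all(startsWith(s$sr$reads$seq2, prefix)))
  g <- s$sg$genome[["chr1"]]
  tr <- s$sr$truth
  for (j in which(tr$strand == "+")[1:5]) {
    genomic <- substr(s$sr$reads$seq2[j], nchar(prefix) + 1,
                      nchar(prefix) + 20)
    expect_equal(genomic, substr(g, tr$junction[j] + 1, tr$junction[j] + 20))
  }
})

test_that("SAM round-trip preserves coordinates, strand, UMI and library", {
  s <- small_rgn_sim(reads_per_site = 25L)
  f <- tempfile(fileext = ".sam")
  write_sam(s$sr, s$sg$genome, f)
  aln <- load_alignments(f)
  expect_equal(nrow(aln), nrow(s$sr$alignments))
  merged <- dplyr::inner_join(aln, s$sr$alignments,
                              by = "read_id", suffix = c("", ".sim"))
  expect_equal(merged$r2_start, merged$r2_start.sim)
  expect_equal(merged$strand, merged$strand.sim)
  expect_equal(merged$umi, merged$umi.sim)
  expect_equal(merged$library, merged$library.sim)
})

test_that("transposon site picker lands on TA dinucleotides", {
  cfg <- sim_config(genome_length = 100000L, library_mode = "single",
                    seed = 9L)
  sg <- simulate_genome(cfg)
  ta <- sim_transposon_sites(sg, n = 40, seed = 2L)
  di <- substr(rep(sg$genome[["chr1"]], nrow(ta)),
               ta$cut_position, ta$cut_position + 1)
  expect_true(all(di == "TA"))
})
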