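test_that("demultiplexing routes reads by barcode and conserves counts", {
  bcs <- c(sampleA = "ACGTAC", sampleB = "TGCATG")
  umi <- strrep("A", 8)
  mk <- function(bc, n) make_pairs(
    seq1 = rep(paste0(umi, bc, random_seq(40, seed = 1)), n),
    seq2 = rep(random_seq(54, seed = 2), n)
  )
  reads <- dplyr::bind_rows(mk("ACGTAC", 10), mk("TGCATG", 10))
  reads$read_id <- sprintf("r%03d", seq_len(nrow(reads)))
  out <- demultiplex(reads, bcs, umi_length = 8)
  expect_equal(sum(out$sample == "sampleA"), 10)
  expect_equal(sum(out$sample == "sampleB"), 10)
  expect_equal(nrow(out), nrow(reads))
  expect_true(all(out$umi == umi))
  # barcode and UMI are stripped from read 1
  expect_equal(unique(nchar(out$seq1)), 40)

  stray <- mk("GGGGGG", 3)
  out2 <- demultiplex(stray, bcs, umi_length = 8)
  expect_true(all(out2$sample == "undetermined"))

  empty <- reads[0, ]
  expect_equal(nrow(demultiplex(empty, bcs)), 0)

  expect_error(demultiplex(reads, c(a = "ACGTAC", b = "ACGTAC")),
               "duplicate")
})

test_that("one-mismatch barcode rescue assigns only unambiguous reads", {
  bcs <- c(sampleA = "AAAAAA", sampleB = "TTTTTT")
  reads <- make_pairs(seq1 = paste0(strrep("A", 8), "AAAAAT",
                                    random_seq(40, seed = 3)),
                      seq2 = random_seq(54, seed = 4))
  strict <- demultiplex(reads, bcs, umi_length = 8)
  expect_equal(strict$sample, "undetermined")
  rescued <- demultiplex(reads, bcs, umi_length = 8,
                         max_barcode_mismatches = 1)
  expect_equal(rescued$sample, "sampleA")
})

test_that("tag filtering keeps only prefix-bearing pairs and strips it", {
  tag <- "ATGACCGTTA"
  genomic <- random_seq(60, seed = 5)
  with_tag <- paste0(tag, genomic)
  one_mm <- paste0("TTGACCGTTA", genomic)
  without <- paste0(random_seq(10, seed = 6), genomic)
  reads <- make_pairs(seq1 = rep(random_seq(70, seed = 7), 3),
                      seq2 = c(with_tag, one_mm, without))

  # brute-force Hamming check of the planted one-substitution prefix
  expect_equal(sum(strsplit("TTGACCGTTA", "")[[1]] !=
                     strsplit(tag, "")[[1]]), 1)

  strict <- filter_tag_reads(reads, filter_params(tag,
                                                  max_prefix_mismatches = 0))
  expect_equal(strict$read_id, "r001")
  expect_equal(strict$seq2, genomic)

  loose <- filter_tag_reads(reads, filter_params(tag,
                                                 max_prefix_mismatches = 1))
  expect_setequal(loose$read_id, c("r001", "r002"))
  rep <- attr(loose, "report")
  expect_equal(rep$input, 3)
  expect_equal(rep$retained, 2)
  expect_equal(rep$retained_fraction, 2 / 3)
})

test_that("length filter keeps 50-bp mates and discards 49-bp mates", {
  p <- filter_params("ATGACCGTTA")
  reads <- make_pairs(
    seq1 = vapply(c(49, 50, 51), random_seq, character(1)),
    seq2 = vapply(c(60, 60, 60), random_seq, character(1))
  )
  out <- trim_and_length_filter(reads, p)
  expect_setequal(out$read_id, c("r002", "r003"))
  rep <- attr(out, "report")
  expect_equal(rep$input - rep$retained, 1)
})

test_that("adapter and low-quality ends are trimmed, idempotently", {
  adapter <- "AGATCGGAAGAGC"
  core <- random_seq(60, seed = 8)
  p <- filter_params("ATGACCGTTA", adapter_sequences = adapter,
                     quality_threshold = 20)
  reads <- tibble::tibble(
    read_id = "r001",
    seq1 = paste0(core, adapter),
    qual1 = strrep("I", 60 + nchar(adapter)),
    seq2 = paste0(core, random_seq(5, seed = 9)),
    qual2 = paste0(strrep("I", 60), strrep("#", 5))  # '#' = Q2 tail
  )
  out <- trim_and_length_filter(reads, p)
  expect_equal(out$seq1, core)  # adapter removed
  expect_equal(out$seq2, core)  # low-quality tail removed
  expect_equal(nchar(out$qual2), nchar(out$seq2))
  again <- trim_and_length_filter(out, p)
  expect_equal(again$seq1, out$seq1)
  expect_equal(again$seq2, out$seq2)

  # untouched sequence passes through unchanged
  clean <- make_pairs(seq1 = core, seq2 = core)
  expect_equal(trim_and_length_filter(clean, p)$seq1, core)
})

test_that("malformed records are rejected with their index", {
  p <- filter_params("ATGACCGTTA")
  bad <- tibble::tibble(read_id = "r001", seq1 = "ACGT", qual1 = "III",
                        seq2 = "ACGT", qual2 = "IIII")
  expect_error(trim_and_length_filter(bad, p), "index 1")
})

test_that("per-stage partition: kept plus dropped equals input", {
  s <- small_rgn_sim(reads_per_site = 40L)
  reads <- s$sr$reads
  # corrupt the tag prefix on a third of the pairs
  idx <- seq(1, nrow(reads), by = 3)
  reads$seq2[idx] <- sub("^.", "N", reads$seq2[idx])
  p <- filter_params(substr(s$cfg$tag_sequence, 1,
                            s$cfg$tag_r2_prefix_length),
                     max_prefix_mismatches = 0)
  kept <- filter_tag_reads(reads, p)
  rep <- attr(kept, "report")
  expect_equal(rep$retained + length(idx), rep$input)
  expect_equal(nrow(kept), rep$retained)
})
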