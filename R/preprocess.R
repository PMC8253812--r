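#' Filtering parameters for raw tag-integration reads
#'
#' @param tag_prefix Tag-primer remnant expected at the start of Read 2.
#' @param max_prefix_mismatches Substitutions tolerated in the Read-2 tag
#'   prefix (default 1; indels are not tolerated).
#' @param min_length_after_trim Minimum mate length after trimming; pairs
#'   with either mate shorter are discarded. Default 50 bp.
#' @param quality_threshold Phred score below which terminal bases are
#'   trimmed (default 20).
#' @param adapter_sequences Character vector of adapter sequences removed
#'   from read ends.
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(tag_prefix,
                          max_prefix_mismatches = 1L,
                          min_length_after_trim = 50L,
                          quality_threshold = 20L,
                          adapter_sequences = character(0)) {
  stopifnot(nzchar(tag_prefix), min_length_after_trim >= 1)
  structure(
    list(
      tag_prefix = toupper(tag_prefix),
      max_prefix_mismatches = as.integer(max_prefix_mismatches),
      min_length_after_trim = as.integer(min_length_after_trim),
      quality_threshold = as.integer(quality_threshold),
      adapter_sequences = toupper(adapter_sequences)
    ),
    class = "filter_params"
  )
}

#' Demultiplex read pairs by sample barcode
#'
#' The UMI (first `umi_length` bases of Read 1) and the sample barcode (the
#' following bases) are extracted from Read 1; both prefixes are removed
#' from Read 1. Reads whose barcode is absent from the table go to the
#' `"undetermined"` sample. Counts are conserved.
#'
#' @param reads Tibble with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @param barcodes Named character vector `sample name -> barcode`; all
#'   barcodes must be unique and of equal length.
#' @param umi_length UMI length at the start of Read 1.
#' @param max_barcode_mismatches Substitutions tolerated in the barcode
#'   (default 0; 1-mismatch rescue only assigns a read if exactly one
#'   barcode is within range).
#' @return Tibble of the input reads plus columns `umi`, `barcode`,
#'   `sample`, with UMI+barcode stripped from `seq1`/`qual1`.
#' @export
demultiplex <- function(reads, barcodes, umi_length = 8L,
                        max_barcode_mismatches = 0L) {
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in table")
  if (length(unique(nchar(barcodes))) > 1) {
    stop("barcodes must be of equal length")
  }
  bl <- nchar(barcodes[1])
  if (nrow(reads) == 0) {
    return(mutate(reads, umi = character(0), barcode = character(0),
                  sample = character(0)))
  }
  umi <- substr(reads$seq1, 1, umi_length)
  bc <- substr(reads$seq1, umi_length + 1, umi_length + bl)
  assign_one <- function(b) {
    d <- vapply(barcodes, function(x) hamming(b, x), numeric(1))
    hit <- which(d <= max_barcode_mismatches)
    if (length(hit) == 1) names(barcodes)[hit] else "undetermined"
  }
  if (max_barcode_mismatches == 0) {
    sample_of <- names(barcodes)[match(bc, barcodes)]
    sample_of[is.na(sample_of)] <- "undetermined"
  } else {
    sample_of <- vapply(bc, assign_one, character(1), USE.NAMES = FALSE)
  }
  off <- umi_length + bl
  mutate(reads,
         umi = toupper(umi), barcode = toupper(bc), sample = sample_of,
         seq1 = substr(.data$seq1, off + 1, nchar(.data$seq1)),
         qual1 = substr(.data$qual1, off + 1, nchar(.data$qual1)))
}

#' Retain read pairs carrying the Tag prefix on Read 2
#'
#' A pair is retained iff Read 2 starts with the Tag-primer remnant within
#' `max_prefix_mismatches` substitutions; the prefix is then stripped from
#' Read 2. The retained fraction is attached as attribute `"report"`.
#'
#' @param reads Read-pair tibble (`seq2`/`qual2` present).
#' @param params A [filter_params()].
#' @return The retained pairs with the tag prefix removed from Read 2.
#' @export
filter_tag_reads <- function(reads, params) {
  stopifnot(inherits(params, "filter_params"))
  tp <- params$tag_prefix
  k <- nchar(tp)
  if (nrow(reads) == 0) {
    out <- reads
    attr(out, "report") <- tibble(input = 0L, retained = 0L,
                                  retained_fraction = NaN)
    return(out)
  }
  prefix <- substr(reads$seq2, 1, k)
  mm <- hamming_many(prefix, tp)
  mm[nchar(prefix) < k] <- Inf
  keep <- mm <= params$max_prefix_mismatches
  out <- reads[keep, , drop = FALSE]
  out <- mutate(out,
                seq2 = substr(.data$seq2, k + 1, nchar(.data$seq2)),
                qual2 = substr(.data$qual2, k + 1, nchar(.data$qual2)))
  attr(out, "report") <- tibble(
    input = nrow(reads), retained = sum(keep),
    retained_fraction = sum(keep) / nrow(reads)
  )
  out
}

# Trim adapter occurrences at either end of one sequence; returns the kept
# 1-based [from, to] window (adapter matched exactly, at the ends only).
adapter_window <- function(seq, adapters) {
  from <- 1L
  to <- nchar(seq)
  for (ad in adapters) {
    k <- nchar(ad)
    if (k == 0 || k > to - from + 1) next
    repeat {
      if (substr(seq, from, from + k - 1) == ad) from <- from + k
      else break
    }
    repeat {
      if (to - k + 1 >= from && substr(seq, to - k + 1, to) == ad) to <- to - k
      else break
    }
  }
  c(from, to)
}

# Quality-trim one read from both ends: drop terminal bases whose Phred
# score is below the threshold (sliding in from each end).
quality_window <- function(qual, threshold) {
  q <- phred_scores(qual)
  n <- length(q)
  from <- 1L
  while (from <= n && q[from] < threshold) from <- from + 1L
  to <- n
  while (to >= from && q[to] < threshold) to <- to - 1L
  c(from, to)
}

trim_one <- function(seq, qual, params) {
  w <- adapter_window(seq, params$adapter_sequences)
  seq <- substr(seq, w[1], w[2])
  qual <- substr(qual, w[1], w[2])
  if (nchar(seq) == 0) return(c("", ""))
  w <- quality_window(qual, params$quality_threshold)
  if (w[2] < w[1]) return(c("", ""))
  c(substr(seq, w[1], w[2]), substr(qual, w[1], w[2]))
}

#' Trim adapters/low-quality ends and apply the length filter
#'
#' Adapter matches at the read ends are removed, terminal bases below the
#' quality threshold are trimmed from both ends, and any pair with either
#' mate shorter than `min_length_after_trim` is discarded (the default of
#' 50 bp discards 49-bp mates and keeps 50-bp mates). The operation is
#' idempotent. Per-stage counts are attached as attribute `"report"`.
#'
#' @param reads Read-pair tibble.
#' @param params A [filter_params()].
#' @return The cleaned, retained pairs.
#' @export
trim_and_length_filter <- function(reads, params) {
  stopifnot(inherits(params, "filter_params"))
  if (nrow(reads) == 0) {
    attr(reads, "report") <- tibble(input = 0L, retained = 0L)
    return(reads)
  }
  bad_qual <- nchar(reads$seq1) != nchar(reads$qual1) |
    nchar(reads$seq2) != nchar(reads$qual2)
  if (any(bad_qual)) {
    stop("malformed record (sequence/quality length mismatch) at index ",
         which(bad_qual)[1])
  }
  t1 <- purrr::map2(reads$seq1, reads$qual1, trim_one, params = params)
  t2 <- purrr::map2(reads$seq2, reads$qual2, trim_one, params = params)
  out <- mutate(reads,
                seq1 = purrr::map_chr(t1, 1), qual1 = purrr::map_chr(t1, 2),
                seq2 = purrr::map_chr(t2, 1), qual2 = purrr::map_chr(t2, 2))
  keep <- nchar(out$seq1) >= params$min_length_after_trim &
    nchar(out$seq2) >= params$min_length_after_trim
  res <- out[keep, , drop = FALSE]
  attr(res, "report") <- tibble(input = nrow(reads), retained = sum(keep))
  res
}
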