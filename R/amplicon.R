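#' Tag discrimination parameters for amplicon insertions
#'
#' @param min_match_length Minimum aligned length for a Tag call (default
#'   16 bp; a 15-bp perfect match is not a Tag).
#' @param min_identity Minimum percent identity of the local alignment
#'   (default 50).
#' @param full_fraction Aligned fraction of the shorter of
#'   segment/Tag above which the insertion manner is called
#'   forward/reverse rather than partial (default 0.9).
#' @return A list of class `"tag_params"`.
#' @export
tag_params <- function(min_match_length = 16L, min_identity = 50,
                       full_fraction = 0.9) {
  stopifnot(min_match_length >= 1, min_identity > 0, min_identity <= 100)
  structure(
    list(min_match_length = as.integer(min_match_length),
         min_identity = min_identity, full_fraction = full_fraction),
    class = "tag_params"
  )
}

amplicon_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE, type = "DNA")
}

# Walk a gapped alignment and extract indels relative to the reference.
# Returns list(insertions = tibble(boundary, segment),
#              deletions = tibble(start, end), aligned_identity).
walk_alignment <- function(aln) {
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ref_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based
  ins <- list(); del <- list()
  i <- 1L
  n <- length(pat)
  n_match <- 0L; n_aligned <- 0L
  while (i <= n) {
    if (sub[i] == "-") {
      j <- i
      while (j <= n && sub[j] == "-") j <- j + 1L
      ins[[length(ins) + 1]] <- tibble(
        boundary = ref_pos,
        segment = paste(pat[i:(j - 1)], collapse = "")
      )
      i <- j
    } else if (pat[i] == "-") {
      j <- i
      while (j <= n && pat[j] == "-") j <- j + 1L
      del[[length(del) + 1]] <- tibble(start = ref_pos,
                                       end = ref_pos + (j - i))
      ref_pos <- ref_pos + (j - i)
      i <- j
    } else {
      n_aligned <- n_aligned + 1L
      if (pat[i] == sub[i]) n_match <- n_match + 1L
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  list(
    insertions = if (length(ins)) bind_rows(ins) else
      tibble(boundary = integer(0), segment = character(0)),
    deletions = if (length(del)) bind_rows(del) else
      tibble(start = integer(0), end = integer(0)),
    aligned_identity = if (n_aligned) n_match / n_aligned else 0
  )
}

#' Match an insertion segment against the Tag sequence
#'
#' The segment is locally aligned to the Tag on both strands; a Tag
#' insertion is called when the best alignment spans at least
#' `min_match_length` bases at `min_identity` percent identity or better.
#' The manner is forward or reverse by the matching strand, or partial when
#' only a sub-segment of the pair matches.
#'
#' @param segment Inserted sequence (non-empty).
#' @param tag Tag sequence.
#' @param params A [tag_params()].
#' @return Tibble row with `tag_matched`, `manner` (`"forward"`,
#'   `"reverse"`, `"partial"`, or `NA` when unmatched), `match_length`,
#'   `identity`.
#' @export
discriminate_tag <- function(segment, tag, params = tag_params()) {
  stopifnot(nzchar(segment))
  score_one <- function(s) {
    a <- Biostrings::pairwiseAlignment(
      s, tag, type = "local", substitutionMatrix = amplicon_submat(),
      gapOpening = 6, gapExtension = 2)
    len <- Biostrings::nchar(a)  # alignment length incl. gaps
    list(aln = a, len = len, pid = Biostrings::pid(a), score = Biostrings::score(a))
  }
  fw <- score_one(segment)
  rv <- score_one(revcomp(segment))
  best <- if (fw$score >= rv$score) fw else rv
  strand_fwd <- fw$score >= rv$score
  matched <- best$len >= params$min_match_length &&
    best$pid >= params$min_identity
  manner <- if (!matched) {
    NA_character_
  } else if (best$len >= params$full_fraction *
             min(nchar(segment), nchar(tag))) {
    if (strand_fwd) "forward" else "reverse"
  } else {
    "partial"
  }
  tibble(tag_matched = matched, manner = manner,
         match_length = as.integer(best$len), identity = best$pid)
}

#' Find insertion boundaries and classify amplicon reads
#'
#' Each read is aligned to the amplicon reference (read-global,
#' reference-local, built-in dynamic-programming alignment via Biostrings);
#' inserted and deleted segments are extracted with 0-based boundary
#' coordinates. Reads are classified `wildtype` (no indel), `indel`,
#' `donor` (an insertion segment matches the Tag per
#' [discriminate_tag()]), or `unaligned` (identity over aligned bases below
#' `min_aligned_identity`).
#'
#' @param reads Character vector of read sequences, or tibble with
#'   `read_id` and `seq`.
#' @param reference Amplicon reference sequence (<= 10 kb).
#' @param tag Tag sequence used for donor discrimination (`NULL` disables
#'   the donor class).
#' @param params A [tag_params()].
#' @param min_score_frac Alignment-score fraction (score divided by the
#'   score of a perfect full-length match) below which a read counts as
#'   unaligned (default 0.2; a read unrelated to the amplicon scores near
#'   or below zero, while reads carrying even a full-length Tag insertion
#'   stay well above).
#' @return Tibble of class `"amplicon_records"`: one row per read with
#'   `class`, `n_insertions`, `n_deletions`, list-columns `insertions` and
#'   `deletions`, and Tag-match columns for the best insertion.
#' @export
find_insertion_boundaries <- function(reads, reference, tag = NULL,
                                      params = tag_params(),
                                      min_score_frac = 0.2) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("read%05d", seq_along(reads)),
                    seq = reads)
  }
  if (nchar(reference) > 10000) {
    stop("amplicon reference larger than 10 kb; use an external aligner")
  }
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    aln <- Biostrings::pairwiseAlignment(
      reads$seq[i], reference, type = "global-local",
      substitutionMatrix = amplicon_submat(),
      gapOpening = 10, gapExtension = 0.5)
    w <- walk_alignment(aln)
    tag_row <- tibble(tag_matched = FALSE, manner = NA_character_,
                      match_length = NA_integer_, identity = NA_real_)
    if (!is.null(tag) && nrow(w$insertions)) {
      cand <- purrr::map_dfr(w$insertions$segment, discriminate_tag,
                             tag = tag, params = params)
      best <- which.max(cand$match_length * cand$tag_matched)
      if (any(cand$tag_matched)) tag_row <- cand[best, ]
    }
    score_frac <- Biostrings::score(aln) / (2 * nchar(reads$seq[i]))
    cls <- if (score_frac < min_score_frac) {
      "unaligned"
    } else if (tag_row$tag_matched) {
      "donor"
    } else if (nrow(w$insertions) || nrow(w$deletions)) {
      "indel"
    } else {
      "wildtype"
    }
    rows[[i]] <- tibble(
      read_id = reads$read_id[i], class = cls,
      n_insertions = nrow(w$insertions), n_deletions = nrow(w$deletions),
      insertions = list(w$insertions), deletions = list(w$deletions),
      tag_matched = tag_row$tag_matched, manner = tag_row$manner,
      match_length = tag_row$match_length, identity = tag_row$identity
    )
  }
  res <- if (nrow(reads)) bind_rows(rows) else tibble(
    read_id = character(0), class = character(0),
    n_insertions = integer(0), n_deletions = integer(0),
    insertions = list(), deletions = list(), tag_matched = logical(0),
    manner = character(0), match_length = integer(0), identity = numeric(0)
  )
  class(res) <- c("amplicon_records", class(res))
  res
}

#' Summarise amplicon validation metrics
#'
#' Indel frequency = indel reads / total reads; integration rate = donor
#' reads / total reads (exact ratios, no intermediate rounding). Donor
#' reads are not double-counted as indel reads.
#'
#' @param records An `"amplicon_records"` tibble.
#' @param include_unaligned Count unaligned reads in the denominator
#'   (default `FALSE`).
#' @return A one-row tibble of class `"amplicon_result"` with read counts
#'   and both ratios.
#' @export
summarize_amplicon <- function(records, include_unaligned = FALSE) {
  n_wild <- sum(records$class == "wildtype")
  n_indel <- sum(records$class == "indel")
  n_donor <- sum(records$class == "donor")
  n_unaln <- sum(records$class == "unaligned")
  total <- n_wild + n_indel + n_donor + if (include_unaligned) n_unaln else 0L
  if (total == 0) stop("no aligned reads to summarise")
  res <- tibble(
    total_reads = total, wildtype_reads = n_wild,
    indel_reads = n_indel, donor_reads = n_donor,
    unaligned_reads = n_unaln,
    indel_frequency = n_indel / total,
    integration_rate = n_donor / total
  )
  class(res) <- c("amplicon_result", class(res))
  res
}

#' Simulate amplicon deep-seq reads over a cut site
#'
#' Each read copies the reference; with probability `integration_rate` the
#' Tag is inserted at the cut, else with conditional probability such that
#' the overall indel fraction equals `indel_frequency` a short deletion is
#' placed at the cut.
#'
#' @param reference Amplicon reference sequence.
#' @param cut 0-based cut coordinate within the reference.
#' @param n Number of reads.
#' @param indel_frequency,integration_rate Planted fractions (must sum to
#'   <= 1).
#' @param tag Tag sequence inserted in donor reads.
#' @param deletion_size Deletion length for indel reads (default 3).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Tibble with `read_id`, `seq` and the planted `truth` class.
#' @export
simulate_amplicon_reads <- function(reference, cut, n,
                                    indel_frequency = 0.2,
                                    integration_rate = 0.1,
                                    tag = default_tag_sequence(),
                                    deletion_size = 3L, error_rate = 0,
                                    seed = 1L) {
  stopifnot(indel_frequency + integration_rate <= 1)
  set.seed(seed)
  u <- stats::runif(n)
  truth <- ifelse(u < integration_rate, "donor",
                  ifelse(u < integration_rate + indel_frequency,
                         "indel", "wildtype"))
  seqs <- vapply(truth, function(tr) {
    left <- substr(reference, 1, cut)
    right <- substr(reference, cut + 1, nchar(reference))
    s <- switch(tr,
                wildtype = reference,
                donor = paste0(left, tag, right),
                indel = paste0(left,
                               substr(right, deletion_size + 1,
                                      nchar(right))))
    add_seq_errors(s, error_rate)
  }, character(1), USE.NAMES = FALSE)
  tibble(read_id = sprintf("amp%05d", seq_len(n)), seq = seqs,
         truth = truth)
}
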