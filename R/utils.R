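#' Default synthetic Tag (dsODN) sequence
#'
#' A synthetic 35-nt stand-in for the double-stranded oligodeoxynucleotide
#' donor that is captured at double-strand breaks. It is constructed to the
#' GC-balance property of such donors: 16 of 35 bases are G or C, i.e. 45.7%
#' GC. It is not a deposited oligonucleotide sequence.
#'
#' @return A single character string (35 nt).
#' @examples
#' gc_content(default_tag_sequence())
#' @export
default_tag_sequence <- function() {
  "ATGACCGTTAACGATCTGCAGGTCATACGTTAGCA"
}

#' GC content of a nucleotide sequence
#'
#' @param seq Character vector of A/C/G/T(/N) sequences.
#' @param percent Return percentage (default) rather than a fraction.
#' @param digits Digits to round a percentage to (default 1, the precision
#'   GC balance is usually reported at). Use `NA` for no rounding.
#' @return Numeric vector, one value per sequence.
#' @export
gc_content <- function(seq, percent = TRUE, digits = 1) {
  stopifnot(is.character(seq))
  bases <- strsplit(toupper(seq), "")
  frac <- vapply(bases, function(b) mean(b %in% c("G", "C")), numeric(1))
  if (!percent) return(frac)
  if (is.na(digits)) frac * 100 else round(frac * 100, digits)
}

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Hamming distance between two equal-length strings; N matches nothing.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv | av == "N" | bv == "N")
}

# Vectorised Hamming distance of many strings against one reference.
hamming_many <- function(xs, ref) {
  vapply(xs, hamming, b = ref, FUN.VALUE = numeric(1), USE.NAMES = FALSE)
}

# IUPAC-aware match of an observed sequence against a pattern such as "NGG"
# or "TTTV". Observed must be plain ACGT(N); N in the observed base never
# satisfies a non-N pattern code.
iupac_match <- function(observed, pattern) {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
  if (nchar(observed) != nchar(pattern)) return(FALSE)
  ob <- strsplit(toupper(observed), "")[[1]]
  pa <- strsplit(toupper(pattern), "")[[1]]
  all(vapply(seq_along(ob), function(i) ob[i] %in% codes[[pa[i]]], logical(1)))
}

# Draw one concrete realisation of an IUPAC pattern.
realise_iupac <- function(pattern) {
  codes <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
  pa <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(pa, function(p) sample(codes[[p]], 1), character(1)),
        collapse = "")
}

# Leftmost mode of an integer vector with optional weights.
modal_value <- function(x, w = NULL) {
  if (length(x) == 0) return(NA_integer_)
  if (is.null(w)) w <- rep(1, length(x))
  agg <- rowsum(w, group = x)
  vals <- as.numeric(rownames(agg))
  best <- vals[agg[, 1] == max(agg[, 1])]
  as.integer(min(best))
}

# Random DNA of length n at a given GC fraction, as a character string.
random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or `Biostrings::DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# Write one mate of a read table as 4-line FASTQ (Phred+33 qualities).
write_fastq_mate <- function(ids, seq, qual, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    rec <- paste0("@", ids, "\n", seq, "\n+\n", qual)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Write paired reads to R1/R2 FASTQ files
#'
#' @param reads Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (as produced by [simulate_reads()]).
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  write_fastq_mate(reads$read_id, reads$seq1, reads$qual1, r1_path)
  write_fastq_mate(reads$read_id, reads$seq2, reads$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1_path,r2_path FASTQ paths for mates 1 and 2 (same order, same
#'   read ids).
#' @return Tibble with columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  parse_one <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4 != 0) {
      stop("malformed FASTQ (line count not a multiple of 4): ", path)
    }
    idx <- seq_len(length(lines) / 4)
    bad <- which(!startsWith(lines[(idx - 1) * 4 + 1], "@"))
    if (length(bad)) {
      stop("malformed FASTQ record ", bad[1], " in ", path)
    }
    tibble(
      read_id = sub("^@", "", sub("\\s.*$", "", lines[(idx - 1) * 4 + 1])),
      seq = lines[(idx - 1) * 4 + 2],
      qual = lines[(idx - 1) * 4 + 4]
    )
  }
  r1 <- parse_one(r1_path)
  r2 <- parse_one(r2_path)
  stopifnot(identical(r1$read_id, r2$read_id))
  tibble(
    read_id = r1$read_id,
    seq1 = r1$seq, qual1 = r1$qual,
    seq2 = r2$seq, qual2 = r2$qual
  )
}

# Phred+33 decoding.
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}
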