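#' Protospacer matching parameters
#'
#' Scoring follows an ungapped Smith-Waterman with +1/-1 match/mismatch and
#' gap penalties high enough to forbid gaps; under that scheme the best
#' local alignment of the full guide is the offset minimising the number of
#' substitutions, with unaligned guide ends counted as mismatches.
#'
#' @param flank Flank half-width around the cut in bp (default 25; must be
#'   >= the guide length).
#' @param max_mismatches Maximum substitutions for an off-target call
#'   (default 6).
#' @param require_pam If `TRUE`, only alignments whose PAM-side adjacent
#'   bases match `pam_pattern` are eligible.
#' @param pam_pattern IUPAC PAM pattern (used for the PAM annotation column
#'   and, when `require_pam`, for filtering).
#' @param pam_side `"3p"` or `"5p"` of the protospacer.
#' @return A list of class `"match_params"`.
#' @export
match_params <- function(flank = 25L, max_mismatches = 6L,
                         require_pam = FALSE, pam_pattern = "NGG",
                         pam_side = c("3p", "5p")) {
  pam_side <- match.arg(pam_side)
  stopifnot(flank >= 1, max_mismatches >= 0)
  structure(
    list(flank = as.integer(flank),
         max_mismatches = as.integer(max_mismatches),
         require_pam = require_pam, pam_pattern = toupper(pam_pattern),
         pam_side = pam_side),
    class = "match_params"
  )
}

#' Extract the +/- flank window around a cut position
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param cut 0-based cut coordinate.
#' @param flank Half-width in bp.
#' @return List with `seq` (the `[cut - flank, cut + flank)` window),
#'   `revcomp`, `start`, `end` and `edge` (`TRUE` when the window runs off
#'   the chromosome; `seq` is then `NA`).
#' @export
extract_flank <- function(genome, chrom, cut, flank = 25L) {
  clen <- nchar(genome[[chrom]])
  start <- cut - flank
  end <- cut + flank
  if (start < 0 || end > clen) {
    return(list(seq = NA_character_, revcomp = NA_character_,
                start = start, end = end, edge = TRUE))
  }
  s <- substr(genome[[chrom]], start + 1, end)
  list(seq = s, revcomp = revcomp(s), start = start, end = end,
       edge = FALSE)
}

#' Best ungapped local match of a guide in a window
#'
#' Scans every offset of the guide against the window on both strands,
#' including offsets where the guide overhangs a window end (overhanging
#' guide bases count as mismatches), and returns the minimum-mismatch
#' placement. Ties break to the leftmost genomic start, then the + strand.
#' `N` in the window counts as a mismatch.
#'
#' @param grna Guide spacer (plain ACGT).
#' @param window Window sequence.
#' @return List with `mismatches`, `start`/`end` (0-based half-open within
#'   the window, clipped to it), `strand`, `matched_seq` (the window bases
#'   under the guide, genome orientation), and `mismatch_positions`
#'   (1-based along the guide, 5' to 3').
#' @export
sw_match <- function(grna, window) {
  L <- nchar(grna)
  W <- nchar(window)
  g <- strsplit(toupper(grna), "")[[1]]
  scan_strand <- function(win) {
    wv <- strsplit(toupper(win), "")[[1]]
    offs <- (-L + 1L):(W - 1L)
    mms <- vapply(offs, function(o) {
      idx <- seq_len(L) + o
      inside <- idx >= 1 & idx <= W
      overhang <- sum(!inside)
      wchars <- wv[idx[inside]]
      gchars <- g[inside]
      overhang + sum(wchars != gchars | wchars == "N")
    }, numeric(1))
    list(offs = offs, mms = mms)
  }
  fw <- scan_strand(window)
  rc <- scan_strand(revcomp(window))
  # map reverse-strand offsets back to window coordinates: a guide placed at
  # offset o on the reverse complement starts (in window coordinates) at
  # W - L - o.
  cand <- bind_rows(
    tibble(mm = fw$mms, start = fw$offs, strand = "+"),
    tibble(mm = rc$mms, start = W - L - rc$offs, strand = "-")
  )
  cand <- arrange(cand, .data$mm, .data$start,
                  factor(.data$strand, levels = c("+", "-")))
  best <- cand[1, ]
  s0 <- max(0L, best$start)
  e0 <- min(W, best$start + L)
  matched <- substr(window, s0 + 1, e0)
  # mismatch positions along the guide (1-based, 5'->3' of the guide):
  # guide position i sits at window offset start + i - 1 on +, and at
  # start + L - i on -, where it is compared to revcomp(guide)
  wv <- strsplit(toupper(window), "")[[1]]
  rcv <- strsplit(revcomp(toupper(grna)), "")[[1]]
  mmpos <- vapply(seq_len(L), function(i) {
    if (best$strand == "+") {
      p <- best$start + i            # 1-based window index
      expected <- g[i]
    } else {
      p <- best$start + L - i + 1L
      expected <- rcv[L - i + 1L]
    }
    if (p < 1 || p > W) return(TRUE)
    wv[p] != expected || wv[p] == "N"
  }, logical(1))
  list(
    mismatches = as.integer(best$mm),
    start = as.integer(s0), end = as.integer(e0),
    strand = best$strand, matched_seq = matched,
    mismatch_positions = which(mmpos)
  )
}

# PAM-side adjacent bases of a matched protospacer within the window.
pam_adjacent <- function(window, m, pam_len, pam_side) {
  W <- nchar(window)
  if (m$strand == "+") {
    iv <- if (pam_side == "3p") c(m$end, m$end + pam_len)
    else c(m$start - pam_len, m$start)
    if (iv[1] < 0 || iv[2] > W) return(NA_character_)
    substr(window, iv[1] + 1, iv[2])
  } else {
    iv <- if (pam_side == "3p") c(m$start - pam_len, m$start)
    else c(m$end, m$end + pam_len)
    if (iv[1] < 0 || iv[2] > W) return(NA_character_)
    revcomp(substr(window, iv[1] + 1, iv[2]))
  }
}

#' Annotate called DSB sites against the guide
#'
#' Extracts the +/- `flank` window around each cut, finds the best-scoring
#' ungapped local alignment of the guide on either strand, and classifies
#' each site: on-target (0 mismatches), off-target (1..`max_mismatches`) or
#' unmatched. The observed PAM-side bases are reported as an annotation; in
#' strict mode (`require_pam`) placements without a pattern-matching PAM
#' are not eligible.
#'
#' @param sites A `"dsb_sites"` tibble (or any tibble with `chrom`,
#'   `cut_position`, `total_support`).
#' @param genome Named character vector of chromosome sequences.
#' @param grna Guide spacer sequence.
#' @param params A [match_params()].
#' @return Tibble of class `"offtarget_hits"`: one row per site with the
#'   matched protospacer, genomic interval, strand, mismatch count and
#'   positions, observed PAM and classification; sorted by read count
#'   descending (ties by chromosome then position).
#' @export
annotate_offtargets <- function(sites, genome, grna,
                                params = match_params()) {
  grna <- toupper(grna)
  if (params$flank < nchar(grna)) {
    stop("flank must be >= guide length")
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    fl <- extract_flank(genome, s$chrom, s$cut_position, params$flank)
    if (fl$edge) {
      rows[[i]] <- tibble(
        chrom = s$chrom, cut_position = s$cut_position,
        read_count = s$total_support, protospacer = NA_character_,
        proto_start = NA_integer_, proto_end = NA_integer_,
        proto_strand = NA_character_, mismatches = NA_integer_,
        mismatch_positions = list(integer(0)), pam_observed = NA_character_,
        classification = "edge"
      )
      next
    }
    m <- sw_match(grna, fl$seq)
    pam_obs <- pam_adjacent(fl$seq, m, nchar(params$pam_pattern),
                            params$pam_side)
    pam_ok <- !is.na(pam_obs) && iupac_match(pam_obs, params$pam_pattern)
    cls <- if (m$mismatches == 0) "on-target"
    else if (m$mismatches <= params$max_mismatches) "off-target"
    else "unmatched"
    if (params$require_pam && !pam_ok && cls != "unmatched") {
      cls <- "unmatched"
    }
    rows[[i]] <- tibble(
      chrom = s$chrom, cut_position = s$cut_position,
      read_count = s$total_support,
      protospacer = if (m$strand == "+") m$matched_seq else
        revcomp(m$matched_seq),
      proto_start = fl$start + m$start, proto_end = fl$start + m$end,
      proto_strand = m$strand, mismatches = m$mismatches,
      mismatch_positions = list(m$mismatch_positions),
      pam_observed = pam_obs, classification = cls
    )
  }
  res <- if (nrow(sites)) bind_rows(rows) else tibble(
    chrom = character(0), cut_position = integer(0),
    read_count = integer(0), protospacer = character(0),
    proto_start = integer(0), proto_end = integer(0),
    proto_strand = character(0), mismatches = integer(0),
    mismatch_positions = list(), pam_observed = character(0),
    classification = character(0)
  )
  res <- arrange(res, desc(.data$read_count), .data$chrom,
                 .data$cut_position)
  attr(res, "grna") <- grna
  class(res) <- c("offtarget_hits", class(res))
  res
}

#' Final sorted on/off-target report
#'
#' Matched sites sorted by read count descending (equal counts keep a
#' stable chromosome/position order); unmatched and edge sites are returned
#' as a separate section. A `mismatch_string` column marks mismatched guide
#' positions (`*` under a mismatch) for visualisation.
#'
#' @param hits An `"offtarget_hits"` tibble.
#' @return List with tibbles `matched` and `unmatched`.
#' @export
classify_and_report <- function(hits) {
  grna <- attr(hits, "grna")
  L <- if (is.null(grna)) NA_integer_ else nchar(grna)
  mark <- function(pos) {
    if (is.na(L)) return(NA_character_)
    v <- rep(".", L)
    v[pos[pos >= 1 & pos <= L]] <- "*"
    paste(v, collapse = "")
  }
  hits2 <- mutate(hits,
                  mismatch_string = purrr::map_chr(.data$mismatch_positions,
                                                   mark))
  matched <- filter(hits2,
                    .data$classification %in% c("on-target", "off-target"))
  unmatched <- filter(hits2,
                      !.data$classification %in% c("on-target", "off-target"))
  matched <- arrange(matched, desc(.data$read_count), .data$chrom,
                     .data$cut_position)
  list(matched = matched, unmatched = unmatched)
}
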