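#' Call transposon integration sites from a single-library track
#'
#' Runs the same hotspot/window/peak machinery as [call_dsb_sites()], but
#' with the single-arm-specific-library support rule: a peak is kept when
#' its total support is at least `min_support_transposon` with both strands
#' represented. The +/- 25 bp flank of each site is attached when a genome
#' is supplied.
#'
#' @param tracks Junction track tibble from one arm-specific library.
#' @param params A [call_params()].
#' @param genome Optional named character vector of chromosome sequences;
#'   enables the `flank_seq` column.
#' @param flank Flank half-width in bp (default 25).
#' @return Tibble of class `"integration_sites"` with `chrom`, `position`,
#'   `support_plus`, `support_minus`, `total_support` and (optionally)
#'   `flank_seq`.
#' @export
call_integration_sites <- function(tracks, params = call_params(),
                                   genome = NULL, flank = 25L) {
  regions <- group_hotspots(tracks, params)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    members <- region_members(tracks, reg)
    wc <- window_counts(members, params)
    peaks <- detect_peaks(wc$total, params)
    for (w in wc$window_start[peaks]) {
      pw <- peak_window_summary(members, w, params$window)
      if (pw$total < params$min_support_transposon) next
      if (pw$support_plus == 0 || pw$support_minus == 0) next
      rows[[length(rows) + 1]] <- tibble(
        chrom = reg$chrom, position = pw$cut,
        support_plus = pw$support_plus, support_minus = pw$support_minus,
        total_support = pw$total
      )
    }
  }
  res <- if (length(rows)) {
    arrange(bind_rows(rows), desc(.data$total_support), .data$chrom,
            .data$position)
  } else {
    tibble(chrom = character(0), position = integer(0),
           support_plus = integer(0), support_minus = integer(0),
           total_support = integer(0))
  }
  if (!is.null(genome) && nrow(res)) {
    res$flank_seq <- purrr::map2_chr(res$chrom, res$position, function(ch, p) {
      fl <- extract_flank(genome, ch, p, flank)
      if (fl$edge) NA_character_ else fl$seq
    })
  }
  class(res) <- c("integration_sites", class(res))
  res
}

#' Flank windows (+/- k bp) around integration sites
#'
#' @param sites An `"integration_sites"` tibble.
#' @param genome Named character vector of chromosome sequences.
#' @param k Half-width in bp (default 5, the motif window).
#' @return Character vector of `2k`-mers centred on each site (sites too
#'   close to a chromosome end are dropped).
#' @export
site_flanks <- function(sites, genome, k = 5L) {
  seqs <- purrr::map2_chr(sites$chrom, sites$position, function(ch, p) {
    fl <- extract_flank(genome, ch, p, k)
    if (fl$edge) NA_character_ else fl$seq
  })
  seqs[!is.na(seqs)]
}

# Dinucleotide frequencies of a set of sequences (all overlapping steps).
dinucleotide_freqs <- function(seqs) {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"),
                            c("A", "C", "G", "T"), paste0))
  if (length(seqs) == 0) return(setNames(rep(NaN, 16), dinucs))
  m <- Biostrings::dinucleotideFrequency(Biostrings::DNAStringSet(seqs))
  counts <- colSums(m)[dinucs]
  counts / sum(counts)
}

#' Dinucleotide motif enrichment at integration-site flanks
#'
#' Builds a position frequency matrix over equal-length flank windows and
#' tests the dinucleotide at the central step (the insertion point) for
#' enrichment against a background dinucleotide distribution with a
#' one-sided exact binomial test per dinucleotide. For Sleeping-Beauty-style
#' insertions the expected top motif is TA.
#'
#' @param flanks Character vector of >= 10 equal-length flank sequences
#'   (even length; the central step spans positions `len/2` and
#'   `len/2 + 1`).
#' @param background Either `"shuffle"` (column-shuffled flanks), a named
#'   16-vector of dinucleotide frequencies, or a genome (named character
#'   vector) whose dinucleotide frequencies are used.
#' @return A list of class `"motif_result"`: `pfm` (4 x width, columns sum
#'   to 1), `central` tibble (dinucleotide, observed count, expected
#'   frequency, p-value; sorted by p), `top_motif`, `n`.
#' @export
motif_enrichment <- function(flanks, background = "shuffle") {
  if (length(flanks) < 10) stop("need >= 10 flank sequences")
  lens <- unique(nchar(flanks))
  if (length(lens) != 1) stop("flank sequences must be of equal length")
  width <- lens
  if (width %% 2 != 0 || width < 2) {
    stop("flank window length must be even (cut-centred)")
  }
  mat <- do.call(rbind, strsplit(toupper(flanks), ""))
  bases <- c("A", "C", "G", "T")
  pfm <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = bases))
    as.numeric(tab) / sum(tab)
  })
  rownames(pfm) <- bases

  centre <- width %/% 2
  obs_di <- paste0(mat[, centre], mat[, centre + 1])
  n <- length(obs_di)

  bg <- if (is.character(background) && length(background) == 1 &&
            background == "shuffle") {
    shuffled <- apply(mat, 1, function(r) paste(sample(r), collapse = ""))
    dinucleotide_freqs(shuffled)
  } else if (is.numeric(background)) {
    background / sum(background)
  } else {
    dinucleotide_freqs(unname(unlist(background)))
  }

  dinucs <- names(dinucleotide_freqs(character(0)))
  central <- purrr::map_dfr(dinucs, function(d) {
    k <- sum(obs_di == d)
    p0 <- max(bg[[d]], 1e-12)
    pv <- binom.test(k, n, p = p0, alternative = "greater")$p.value
    tibble(dinucleotide = d, observed = k,
           observed_fraction = k / n, expected_fraction = unname(bg[[d]]),
           p_value = pv)
  }) |>
    arrange(.data$p_value, desc(.data$observed))

  consensus <- paste(bases[apply(pfm, 2, which.max)], collapse = "")
  res <- list(pfm = pfm, central = central,
              top_motif = central$dinucleotide[1],
              consensus = consensus, n = n)
  class(res) <- "motif_result"
  res
}

#' @export
print.motif_result <- function(x, ...) {
  cat("Central-step dinucleotide enrichment over", x$n, "sites\n")
  cat("  top motif:", x$top_motif,
      sprintf("(p = %.3g)", x$central$p_value[1]), "\n")
  invisible(x)
}

#' @export
tidy.motif_result <- function(x, ...) {
  x$central
}

#' @export
glance.motif_result <- function(x, ...) {
  tibble(top_motif = x$top_motif,
         top_p_value = x$central$p_value[1],
         top_observed_fraction = x$central$observed_fraction[1],
         n_sites = x$n, consensus = x$consensus)
}

#' Assign integration sites to genomic region classes
#'
#' Each site is assigned by interval overlap with precedence
#' exon > intron > intergenic.
#'
#' @param sites An `"integration_sites"` tibble.
#' @param annotation Tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and `type` in `{"exon", "intron"}`, or a
#'   `GenomicRanges::GRanges` with a `type` column (e.g. imported from
#'   GFF/BED via rtracklayer).
#' @return The sites tibble with a `region_class` column, plus a class
#'   histogram as attribute `"histogram"`.
#' @export
annotate_regions <- function(sites, annotation) {
  if (is.null(annotation)) {
    message("no annotation supplied; region annotation skipped")
    return(sites)
  }
  if (inherits(annotation, "GRanges")) {
    annotation <- tibble(
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation) - 1L,
      end = GenomicRanges::end(annotation),
      type = annotation$type
    )
  }
  gr_sites <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$position + 1L, width = 1L)
  )
  cls <- rep("intergenic", nrow(sites))
  for (ty in c("intron", "exon")) {  # exon applied last -> precedence
    a <- annotation[annotation$type == ty, ]
    if (nrow(a) == 0) next
    gr_a <- GenomicRanges::GRanges(
      a$chrom, IRanges::IRanges(start = a$start + 1L, end = a$end))
    hit <- IRanges::overlapsAny(gr_sites, gr_a)
    cls[hit] <- ty
  }
  cls[cls == "exon"] <- "exonic"
  cls[cls == "intron"] <- "intronic"
  out <- mutate(sites, region_class = cls)
  attr(out, "histogram") <- count(out, .data$region_class, name = "n_sites")
  out
}

#' Overlap counts of integration-site sets across samples
#'
#' Sites from different runs are considered the same integration when they
#' lie on the same chromosome within `tolerance` bp (default 5).
#'
#' @param site_lists Named list of `"integration_sites"` tibbles.
#' @param tolerance Matching tolerance in bp.
#' @return Tibble with one row per observed membership pattern and its
#'   count (Venn-style).
#' @export
overlap_sets <- function(site_lists, tolerance = 5L) {
  stopifnot(length(site_lists) >= 2, !is.null(names(site_lists)))
  all_sites <- purrr::imap_dfr(site_lists, function(s, nm) {
    tibble(sample = nm, chrom = s$chrom, position = s$position)
  })
  # cluster by chrom/position with the tolerance
  all_sites <- arrange(all_sites, .data$chrom, .data$position)
  cl <- integer(nrow(all_sites))
  cur <- 0L
  last_chrom <- ""
  last_pos <- -Inf
  for (i in seq_len(nrow(all_sites))) {
    if (all_sites$chrom[i] != last_chrom ||
        all_sites$position[i] - last_pos > tolerance) {
      cur <- cur + 1L
    }
    cl[i] <- cur
    last_chrom <- all_sites$chrom[i]
    last_pos <- all_sites$position[i]
  }
  all_sites$cluster <- cl
  all_sites |>
    group_by(.data$cluster) |>
    summarise(members = paste(sort(unique(.data$sample)), collapse = "&"),
              .groups = "drop") |>
    count(.data$members, name = "n_sites") |>
    arrange(desc(.data$n_sites))
}
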