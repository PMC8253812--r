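#' Load Read-2 alignments from a SAM/BAM file
#'
#' Reads the tag-primer mate's alignments: secondary, supplementary and
#' unmapped records are excluded, as are records below `min_mapq`. The UMI
#' and library are taken from the `RX` and `LB` tags (fall back to
#' `umi`/`library` arguments if absent). For paired files only records
#' flagged second-in-pair are used; unpaired records are treated as
#' already-extracted Read-2 alignments.
#'
#' @param path SAM or BAM file.
#' @param min_mapq Minimum mapping quality (default 0).
#' @param default_library Library label used when no `LB` tag is present.
#' @return Tibble with `read_id`, `chrom`, `r2_start` (0-based leftmost),
#'   `strand`, `mapq`, `ref_width`, `umi`, `library`, plus a `"report"`
#'   attribute with exclusion counts.
#' @export
load_alignments <- function(path, min_mapq = 0L, default_library = "fwd") {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = c("RX", "LB")
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(x$qname)
  if (n == 0) {
    out <- tibble(read_id = character(0), chrom = character(0),
                  r2_start = integer(0), strand = character(0),
                  mapq = integer(0), ref_width = integer(0),
                  umi = character(0), library = character(0))
    attr(out, "report") <- tibble(input = 0L, kept = 0L, unmapped = 0L,
                                  secondary = 0L, low_mapq = 0L,
                                  not_read2 = 0L)
    return(out)
  }
  flag <- x$flag
  paired <- bitwAnd(flag, 1L) > 0
  unmapped <- bitwAnd(flag, 4L) > 0
  secondary <- bitwAnd(flag, 256L) > 0 | bitwAnd(flag, 2048L) > 0
  second_mate <- bitwAnd(flag, 128L) > 0
  not_read2 <- paired & !second_mate
  low_mapq <- !is.na(x$mapq) & x$mapq < min_mapq
  keep <- !unmapped & !secondary & !not_read2 & !low_mapq & !is.na(x$pos)
  umi <- x$tag$RX
  lib <- x$tag$LB
  if (is.null(umi)) umi <- rep(NA_character_, n)
  if (is.null(lib)) lib <- rep(default_library, n)
  lib[is.na(lib)] <- default_library
  ref_width <- cigar_ref_width(x$cigar)
  out <- tibble(
    read_id = x$qname[keep],
    chrom = as.character(x$rname[keep]),
    r2_start = x$pos[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) > 0, "-", "+"),
    mapq = as.integer(x$mapq[keep]),
    ref_width = ref_width[keep],
    umi = umi[keep],
    library = lib[keep]
  )
  attr(out, "report") <- tibble(
    input = n, kept = sum(keep), unmapped = sum(unmapped),
    secondary = sum(secondary), low_mapq = sum(low_mapq & !unmapped),
    not_read2 = sum(not_read2)
  )
  out
}

# Reference-space width of CIGAR strings (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  as.integer(GenomicAlignments::cigarWidthAlongReferenceSpace(cigar))
}

#' Derive the tag-genome junction coordinate of each alignment
#'
#' For +-strand alignments the junction is the leftmost mapped position of
#' Read 2; for --strand alignments it is the rightmost aligned base + 1, so
#' that both strands report the tag-genome boundary rather than a
#' read-length-shifted coordinate.
#'
#' @param alignments Tibble from [load_alignments()] (or the simulator's
#'   `alignments` table; `ref_width` is computed from `cigar` if missing).
#' @return The input with a `junction` column added.
#' @export
add_junctions <- function(alignments) {
  if (!"ref_width" %in% names(alignments)) {
    alignments$ref_width <- cigar_ref_width(alignments$cigar)
  }
  mutate(alignments,
         junction = ifelse(.data$strand == "+",
                           .data$r2_start,
                           .data$r2_start + .data$ref_width))
}

#' Consolidate PCR duplicates by UMI
#'
#' Reads mapping to the same genomic position, strand and library with the
#' same UMI are taken to originate from one pre-PCR molecule and collapsed
#' to a single consensus observation. Optionally, UMIs within one
#' substitution of a more abundant UMI at the same position are merged
#' first (directional clustering).
#'
#' @param alignments Alignment tibble with `chrom`, `r2_start`, `strand`,
#'   `umi`, `library` columns.
#' @param cluster_umis Merge UMIs within Hamming distance 1 at the same
#'   position using the directional rule (count of the larger >=
#'   2 x count of the smaller - 1). Default `FALSE` (exact UMIs only).
#' @return Tibble of consolidated molecules: one row per distinct
#'   `(chrom, r2_start, strand, umi, library)` key with `n_reads`, plus the
#'   junction coordinate (see [add_junctions()]).
#' @export
consolidate_umi <- function(alignments, cluster_umis = FALSE) {
  if (any(is.na(alignments$umi))) stop("UMIs missing on some records")
  aln <- add_junctions(alignments)
  grouped <- aln |>
    count(.data$chrom, .data$r2_start, .data$strand, .data$library,
          .data$umi, .data$junction, name = "n_reads")
  if (cluster_umis && nrow(grouped)) {
    grouped <- grouped |>
      group_by(.data$chrom, .data$r2_start, .data$strand, .data$library,
               .data$junction) |>
      dplyr::group_modify(~ cluster_umis_directional(.x)) |>
      ungroup()
  }
  arrange(grouped, .data$chrom, .data$r2_start, .data$strand,
          .data$library, .data$umi)
}

# Directional UMI clustering within one position group.
cluster_umis_directional <- function(df) {
  df <- arrange(df, desc(.data$n_reads), .data$umi)
  umis <- df$umi
  counts <- df$n_reads
  parent <- seq_along(umis)
  for (i in seq_along(umis)) {
    if (parent[i] != i) next
    for (j in seq_along(umis)) {
      if (j == i || parent[j] != j) next
      if (counts[i] >= 2 * counts[j] - 1 &&
          nchar(umis[i]) == nchar(umis[j]) &&
          hamming(umis[i], umis[j]) == 1) {
        parent[j] <- i
      }
    }
  }
  agg <- rowsum(counts, group = parent)
  keep <- as.integer(rownames(agg))
  tibble(umi = umis[keep], n_reads = as.integer(agg[, 1]))
}

#' Junction position tracks per (chromosome, strand, library)
#'
#' Collapses consolidated molecules into sorted position -> molecule-count
#' tracks. Support counts molecules, not raw reads.
#'
#' @param observations Consolidated tibble from [consolidate_umi()].
#' @return Tibble with `chrom`, `junction`, `strand`, `library`, `support`,
#'   sorted by position within each track.
#' @export
junction_tracks <- function(observations) {
  observations |>
    count(.data$chrom, .data$junction, .data$strand, .data$library,
          name = "support") |>
    arrange(.data$chrom, .data$strand, .data$library, .data$junction)
}

#' Write junction tracks as a BED file
#'
#' 0-based half-open single-base intervals; the score column carries the
#' molecule support, the name column the library.
#'
#' @param tracks Tibble from [junction_tracks()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(tracks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   tracks$chrom, tracks$junction, tracks$junction + 1L,
                   tracks$library, tracks$support, tracks$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read junction tracks from a BED file written by [write_track_bed()]
#'
#' @param path BED path.
#' @return Track tibble (`chrom`, `junction`, `strand`, `library`,
#'   `support`).
#' @export
read_track_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(chrom = character(0), junction = integer(0),
                  strand = character(0), library = character(0),
                  support = integer(0)))
  }
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "library",
                                       "support", "strand"))
  tibble(chrom = d$chrom, junction = as.integer(d$start),
         strand = d$strand, library = d$library,
         support = as.integer(d$support)) |>
    arrange(.data$chrom, .data$strand, .data$library, .data$junction)
}
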