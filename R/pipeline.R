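#' Run the RGN (nuclease) mode end to end
#'
#' Preprocess (optional, when raw read pairs are supplied), load or accept
#' Read-2 alignments, consolidate PCR duplicates by UMI, build junction
#' tracks, call DSB sites, annotate them against the guide, and profile the
#' cut geometry of every called site. When `out_dir` is given, all stage
#' outputs (TSV/BED) and a manifest are written there.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param grna Guide spacer sequence.
#' @param sam Path to a SAM/BAM of Read-2 alignments (pre-aligned mode),
#'   or an alignment tibble with `chrom`, `r2_start`, `strand`, `umi`,
#'   `library` (and `cigar` or `ref_width`).
#' @param reads Optional raw read-pair tibble; it is Tag-filtered and
#'   trimmed (counts land in the report) before the aligned records are
#'   used. Alignment itself is external: `sam` must still be supplied.
#' @param filter A [filter_params()] (required with `reads`).
#' @param call A [call_params()].
#' @param match A [match_params()].
#' @param min_mapq Minimum mapping quality for loaded alignments.
#' @param out_dir Optional output directory.
#' @return List of class `"rgn_run"`: `sites`, `hits`, `profiles` (one-row
#'   [glance()] per site), `tracks`, `report`, `manifest`.
#' @export
run_rgn_mode <- function(genome, grna, sam = NULL, reads = NULL,
                         filter = NULL, call = call_params(),
                         match = match_params(), min_mapq = 0L,
                         out_dir = NULL) {
  inputs <- list()
  if (is.character(genome) && length(genome) == 1 &&
      is.null(names(genome))) {
    if (!file.exists(genome)) stop("genome file not found: ", genome)
    inputs$genome <- genome
    genome <- read_fasta(genome)
  }
  stages <- list()
  if (!is.null(reads)) {
    if (is.null(filter)) stop("filter params required with raw reads")
    filtered <- filter_tag_reads(reads, filter)
    stages$tag_filter <- attr(filtered, "report")
    cleaned <- trim_and_length_filter(filtered, filter)
    stages$trim <- attr(cleaned, "report")
  }
  if (is.null(sam)) stop("pre-aligned input (sam) required")
  if (is.character(sam)) {
    if (!file.exists(sam)) stop("alignment file not found: ", sam)
    inputs$sam <- sam
    aln <- load_alignments(sam, min_mapq = min_mapq)
    stages$load_alignments <- attr(aln, "report")
  } else {
    aln <- sam
  }
  obs <- consolidate_umi(aln)
  stages$consolidate <- tibble(input = nrow(aln), molecules = nrow(obs))
  tracks <- junction_tracks(obs)
  sites <- call_dsb_sites(tracks, call)
  stages$call <- tibble(n_sites = nrow(sites))
  hits <- annotate_offtargets(sites, genome, grna, match)
  profiles <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    glance(infer_cut_profile(sites[i, ], tracks))
  })
  report <- run_report(stages, params = list(call = call, match = match))
  manifest <- build_manifest(inputs, list(call = call, match = match),
                             list(n_sites = nrow(sites),
                                  n_tracks = nrow(tracks)))
  res <- list(sites = sites, hits = hits, profiles = profiles,
              tracks = tracks, report = report, manifest = manifest)
  class(res) <- "rgn_run"
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

#' Run the transposon (integration-site) mode end to end
#'
#' Single-arm-specific-library mode: consolidates molecules, calls
#' integration sites (total support >= `min_support_transposon`, both
#' strands represented), retrieves +/- 25 bp flanks and tests the central
#' dinucleotide step for motif enrichment.
#'
#' @param genome Named character vector of chromosome sequences or FASTA
#'   path.
#' @param sam SAM/BAM path or alignment tibble (one library).
#' @param call A [call_params()].
#' @param motif_k Motif flank half-width in bp (default 5).
#' @param background Background model for [motif_enrichment()]; default
#'   uses the genome's dinucleotide frequencies.
#' @param min_mapq Minimum mapping quality.
#' @param out_dir Optional output directory.
#' @return List of class `"transposon_run"`: `sites`, `motif`
#'   (`NULL` with < 10 usable flanks), `tracks`, `report`, `manifest`.
#' @export
run_transposon_mode <- function(genome, sam, call = call_params(),
                                motif_k = 5L, background = NULL,
                                min_mapq = 0L, out_dir = NULL) {
  inputs <- list()
  if (is.character(genome) && length(genome) == 1 &&
      is.null(names(genome))) {
    if (!file.exists(genome)) stop("genome file not found: ", genome)
    inputs$genome <- genome
    genome <- read_fasta(genome)
  }
  stages <- list()
  if (is.character(sam)) {
    if (!file.exists(sam)) stop("alignment file not found: ", sam)
    inputs$sam <- sam
    aln <- load_alignments(sam, min_mapq = min_mapq)
    stages$load_alignments <- attr(aln, "report")
  } else {
    aln <- sam
  }
  obs <- consolidate_umi(aln)
  stages$consolidate <- tibble(input = nrow(aln), molecules = nrow(obs))
  tracks <- junction_tracks(obs)
  sites <- call_integration_sites(tracks, call, genome = genome)
  stages$call <- tibble(n_sites = nrow(sites))
  flanks <- site_flanks(sites, genome, k = motif_k)
  motif <- NULL
  if (length(flanks) >= 10) {
    if (is.null(background)) background <- genome
    motif <- motif_enrichment(flanks, background = background)
  }
  report <- run_report(stages, params = list(call = call))
  manifest <- build_manifest(inputs, list(call = call),
                             list(n_sites = nrow(sites)))
  res <- list(sites = sites, motif = motif, tracks = tracks,
              report = report, manifest = manifest)
  class(res) <- "transposon_run"
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

# Manifest: input file hashes, flattened parameters, output summary.
build_manifest <- function(inputs, params, outputs) {
  hashes <- purrr::imap_dfr(inputs, function(path, nm) {
    tibble(input = nm, path = path,
           md5 = unname(tools::md5sum(path)))
  })
  flat <- purrr::imap_dfr(params, function(p, nm) {
    vals <- unclass(p)
    vals <- vals[vapply(vals, function(v)
      is.atomic(v) && length(v) == 1, logical(1))]
    tibble(group = nm, param = names(vals),
           value = vapply(vals, as.character, character(1)))
  })
  list(
    inputs = hashes, params = flat,
    outputs = as_tibble(outputs),
    version = as.character(utils::packageVersion("dsbtrace"))
  )
}

write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain <- function(df, name) {
    df <- as_tibble(unclass(df))
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_tsv_plain(res$sites, "sites.tsv")
  if (!is.null(res$hits)) write_tsv_plain(tidy(res$hits), "offtargets.tsv")
  if (!is.null(res$profiles)) write_tsv_plain(res$profiles, "profiles.tsv")
  if (!is.null(res$motif)) write_tsv_plain(tidy(res$motif), "motif.tsv")
  write_track_bed(res$tracks, file.path(out_dir, "junctions.bed"))
  write_tsv_plain(res$report$counts, "report.tsv")
  m <- res$manifest
  write_tsv_plain(m$inputs, "manifest_inputs.tsv")
  write_tsv_plain(m$params, "manifest_params.tsv")
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rgn_run <- function(x, ...) {
  cat("RGN-mode run:", nrow(x$sites), "sites,",
      sum(x$hits$classification == "off-target"), "off-target,",
      sum(x$hits$classification == "on-target"), "on-target\n")
  invisible(x)
}

#' @export
print.transposon_run <- function(x, ...) {
  cat("Transposon-mode run:", nrow(x$sites), "integration sites\n")
  if (!is.null(x$motif)) print(x$motif)
  invisible(x)
}
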