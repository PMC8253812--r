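# Shared fixture builders. Everything is generated in code at test time.

# A small dual-library RGN scenario: genome + planted sites + reads.
small_rgn_sim <- function(cuts = c(10000L, 25000L),
                          mismatches = c(0L, 3L),
                          overhang = 0L,
                          reads_per_site = 50L,
                          genome_length = 50000L,
                          background = 0L,
                          seed = 7L, ...) {
  cfg <- sim_config(
    genome_length = genome_length,
    planted_sites = planted_site(cut_position = cuts,
                                 mismatches = mismatches,
                                 overhang = overhang),
    reads_per_site = reads_per_site,
    background_integrations = background,
    seed = seed, ...
  )
  sg <- simulate_genome(cfg)
  sr <- simulate_reads(sg)
  list(cfg = cfg, sg = sg, sr = sr)
}

# Junction tracks straight from simulator truth (skips SAM round-trip).
sim_tracks <- function(sr) {
  junction_tracks(consolidate_umi(sr$alignments))
}

# Hand-rolled track rows for constructed-support tests.
make_track <- function(junction, strand, library, support,
                       chrom = "chr1") {
  tibble::tibble(chrom = chrom, junction = as.integer(junction),
                 strand = strand, library = library,
                 support = as.integer(support))
}

# Read-pair tibble with uniform qualities.
make_pairs <- function(seq1, seq2, q = "I") {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(seq1)),
    seq1 = seq1, qual1 = strrep(q, nchar(seq1)),
    seq2 = seq2, qual2 = strrep(q, nchar(seq2))
  )
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent reverse complement (no package code, no Biostrings).
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
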