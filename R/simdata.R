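#' Simulation configuration for tag-integration sequencing experiments
#'
#' Bundles every knob of the synthetic-data generator: the genome, the guide
#' and PAM, the planted cleavage sites, and the read-level parameters (UMI,
#' sample barcode, Tag-derived Read-2 prefix, sequencing error, PCR
#' duplication). The same config plus the same seed yields bit-identical
#' output.
#'
#' @param genome_length Total genome size in bp, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param gc_content Background GC fraction in `[0, 1]`.
#' @param grna Guide spacer sequence (plain ACGT, typically 20 nt).
#' @param pam PAM pattern in IUPAC codes (e.g. `"NGG"`, `"TTTV"`).
#' @param pam_side Which side of the protospacer carries the PAM: `"3p"`
#'   (Cas9-like) or `"5p"` (Cas12a/Cpf1-like).
#' @param cut_distance Distance in bp from the cut to the PAM-proximal
#'   protospacer boundary; defaults to 3 for 3' PAMs (blunt Cas9 cleavage
#'   3 bp upstream of the PAM) and 18 for 5' PAMs (Cpf1-like distal cut).
#' @param planted_sites Tibble of planted cleavage sites, one row per site,
#'   with columns `chrom`, `cut_position` (0-based top-strand nick),
#'   `strand` (`"+"`/`"-"` protospacer orientation), `mismatches` (planted
#'   substitutions vs the guide, 0..7+), `overhang` (signed nt; 0 = blunt,
#'   +k = 5' overhang of k nt) and `editing_efficiency` (fraction).
#'   See [planted_site()].
#' @param reads_per_site Tag-derived read pairs emitted per planted site.
#' @param background_integrations Number of stray single-read integrations
#'   placed uniformly at random (the false-positive null).
#' @param pcr_duplicate_rate Probability that a molecule gains one PCR
#'   duplicate read (same UMI and coordinates, independent errors).
#' @param error_rate Per-base substitution probability.
#' @param read_length Read length in bp for both mates.
#' @param umi_length UMI length in nt (Read-1 prefix).
#' @param barcode Sample barcode sequence (follows the UMI on Read 1).
#' @param tag_sequence The Tag dsODN sequence; default
#'   [default_tag_sequence()].
#' @param tag_r2_prefix_length Length of the Tag-primer remnant that starts
#'   Read 2 (taken from the start of `tag_sequence`).
#' @param library_mode `"dual"` emits forward- and reverse-tag-primer
#'   libraries (RGN mode); `"single"` emits one arm-specific library
#'   (transposon mode).
#' @param plant_protospacers Overwrite the genome with a protospacer + PAM
#'   at each planted site (RGN mode). Defaults to `TRUE` in dual-library
#'   mode and `FALSE` in single-library (transposon) mode, where planted
#'   sites mark existing genomic positions (e.g. TA dinucleotides) and the
#'   background sequence must stay untouched.
#' @param seed Integer seed; every random choice in the generator derives
#'   from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 100000L,
                       n_chromosomes = 1L,
                       gc_content = 0.41,
                       grna = "GGTCACCTAGATGCTGACGT",
                       pam = "NGG",
                       pam_side = c("3p", "5p"),
                       cut_distance = NULL,
                       planted_sites = planted_site(),
                       reads_per_site = 100L,
                       background_integrations = 0L,
                       pcr_duplicate_rate = 0,
                       error_rate = 0,
                       read_length = 100L,
                       umi_length = 8L,
                       barcode = "ACGTAC",
                       tag_sequence = default_tag_sequence(),
                       tag_r2_prefix_length = 10L,
                       library_mode = c("dual", "single"),
                       plant_protospacers = NULL,
                       seed = 1L) {
  pam_side <- match.arg(pam_side)
  library_mode <- match.arg(library_mode)
  if (is.null(plant_protospacers)) {
    plant_protospacers <- library_mode == "dual"
  }
  if (is.null(cut_distance)) {
    cut_distance <- if (pam_side == "3p") 3L else 18L
  }
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    gc_content = gc_content,
    grna = toupper(grna),
    pam = toupper(pam),
    pam_side = pam_side,
    cut_distance = as.integer(cut_distance),
    planted_sites = as_tibble(planted_sites),
    reads_per_site = as.integer(reads_per_site),
    background_integrations = as.integer(background_integrations),
    pcr_duplicate_rate = pcr_duplicate_rate,
    error_rate = error_rate,
    read_length = as.integer(read_length),
    umi_length = as.integer(umi_length),
    barcode = toupper(barcode),
    tag_sequence = toupper(tag_sequence),
    tag_r2_prefix_length = as.integer(tag_r2_prefix_length),
    library_mode = library_mode,
    plant_protospacers = plant_protospacers,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$genome_length > 0, cfg$n_chromosomes > 0,
    cfg$gc_content >= 0, cfg$gc_content <= 1,
    cfg$pcr_duplicate_rate >= 0, cfg$pcr_duplicate_rate <= 1,
    cfg$error_rate >= 0, cfg$error_rate <= 1,
    cfg$read_length > 0, cfg$umi_length > 0,
    cfg$reads_per_site >= 0, cfg$background_integrations >= 0,
    cfg$tag_r2_prefix_length >= 1,
    cfg$tag_r2_prefix_length <= nchar(cfg$tag_sequence)
  )
  if (!grepl("^[ACGT]+$", cfg$grna)) stop("grna must be plain ACGT")
  min_stub <- 20L
  if (cfg$read_length < cfg$umi_length + nchar(cfg$barcode) + min_stub) {
    stop("read_length shorter than UMI + barcode + minimum genomic stub (",
         min_stub, " bp)")
  }
  if (cfg$read_length < cfg$tag_r2_prefix_length + min_stub) {
    stop("read_length shorter than tag prefix + minimum genomic stub")
  }
  ps <- cfg$planted_sites
  if (nrow(ps)) {
    needed <- c("chrom", "cut_position", "strand", "mismatches",
                "overhang", "editing_efficiency")
    if (!all(needed %in% names(ps))) {
      stop("planted_sites must have columns: ", paste(needed, collapse = ", "))
    }
    stopifnot(all(ps$strand %in% c("+", "-")),
              all(ps$mismatches >= 0),
              all(ps$editing_efficiency >= 0 & ps$editing_efficiency <= 1))
  }
  invisible(cfg)
}

#' Planted cleavage/integration sites for the simulator
#'
#' @param chrom Chromosome name(s); recycled.
#' @param cut_position 0-based coordinate of the top-strand nick.
#' @param strand Protospacer orientation, `"+"` or `"-"`.
#' @param mismatches Substitutions planted into the protospacer vs the guide.
#' @param overhang Signed overhang in nt: 0 = blunt, +k = 5' overhang of k
#'   nt (the bottom-strand nick sits k bp to the right of the top-strand
#'   nick). A list column of integer vectors plants a staggered-multi cut:
#'   each molecule draws its overhang uniformly from the set (Cpf1-like,
#'   e.g. `list(c(4L, 5L))`).
#' @param editing_efficiency Fraction of molecules edited at the site
#'   (used by the amplicon simulator; the tag-read count per site is set by
#'   `reads_per_site`).
#' @return Tibble with one row per site.
#' @export
planted_site <- function(chrom = "chr1", cut_position = integer(0),
                         strand = "+", mismatches = 0L, overhang = 0L,
                         editing_efficiency = 1) {
  if (length(cut_position) == 0) {
    return(tibble(chrom = character(0), cut_position = integer(0),
                  strand = character(0), mismatches = integer(0),
                  overhang = integer(0), editing_efficiency = numeric(0)))
  }
  if (!is.list(overhang)) overhang <- as.integer(overhang)
  tibble(
    chrom = chrom, cut_position = as.integer(cut_position),
    strand = strand, mismatches = as.integer(mismatches),
    overhang = overhang,
    editing_efficiency = editing_efficiency
  )
}

# Protospacer+PAM layout on the top strand for a planted site.
# Returns 0-based half-open intervals and the top-strand replacement string.
site_layout <- function(cut, strand, grna_len, pam, pam_side, cut_distance) {
  pam_len <- nchar(pam)
  if (strand == "+") {
    if (pam_side == "3p") {
      proto_start <- cut + cut_distance - grna_len
    } else {
      proto_start <- cut - cut_distance
    }
    proto_end <- proto_start + grna_len
    pam_start <- if (pam_side == "3p") proto_end else proto_start - pam_len
  } else {
    if (pam_side == "3p") {
      proto_start <- cut - cut_distance
    } else {
      proto_start <- cut + cut_distance - grna_len
    }
    proto_end <- proto_start + grna_len
    pam_start <- if (pam_side == "3p") proto_start - pam_len else proto_end
  }
  list(proto_start = proto_start, proto_end = proto_end,
       pam_start = pam_start, pam_end = pam_start + pam_len)
}

# Plant `m` substitutions into the guide, each to a different base.
mutate_spacer <- function(grna, m) {
  b <- strsplit(grna, "")[[1]]
  if (m > length(b)) stop("more mismatches requested than spacer length")
  pos <- sample(seq_along(b), m)
  for (p in pos) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  }
  paste(b, collapse = "")
}

# Scan a window (both strands) for protospacer-like matches of the guide.
# Returns 0-based start offsets (relative to window start) with <= max_mm.
scan_guide_hits <- function(window, grna, max_mm) {
  L <- nchar(grna)
  W <- nchar(window)
  if (W < L) return(integer(0))
  starts <- 0:(W - L)
  subs <- substring(window, starts + 1, starts + L)
  fw <- starts[hamming_many(subs, grna) <= max_mm]
  rc <- revcomp(window)
  subs_rc <- substring(rc, starts + 1, starts + L)
  rv_rc <- starts[hamming_many(subs_rc, grna) <= max_mm]
  rv <- W - L - rv_rc
  sort(unique(c(fw, rv)))
}

#' Simulate a reference genome with planted protospacers
#'
#' Draws a random background genome at the configured GC content and
#' overwrites each planted site with a protospacer carrying exactly the
#' requested number of substitutions against the guide plus a PAM realising
#' the configured IUPAC pattern. A collision check guarantees no other
#' occurrence of the guide with <= 6 mismatches within 100 bp of any planted
#' site; colliding background is redrawn.
#'
#' @param config A [sim_config()].
#' @return A list of class `"sim_genome"` with elements `genome` (named
#'   character vector of chromosome sequences) and `sites` (tibble of planted
#'   sites with protospacer coordinates, sequence and observed PAM).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_len <- config$genome_length %/% config$n_chromosomes
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- setNames(
    vapply(chroms, function(x) random_dna(chrom_len, config$gc_content),
           character(1)),
    chroms
  )

  ps <- config$planted_sites
  L <- nchar(config$grna)
  flank_clear <- max(25L, L + nchar(config$pam) + config$cut_distance)
  out <- vector("list", nrow(ps))
  for (i in seq_len(nrow(ps))) {
    site <- ps[i, ]
    if (!site$chrom %in% names(genome)) {
      stop("planted site ", i, ": unknown chromosome ", site$chrom)
    }
    clen <- nchar(genome[[site$chrom]])
    if (site$cut_position < flank_clear ||
        site$cut_position > clen - flank_clear) {
      stop("planted site ", i, " at ", site$chrom, ":", site$cut_position,
           ": flank clearance of ", flank_clear, " bp violated")
    }
    lay <- site_layout(site$cut_position, site$strand, L,
                       config$pam, config$pam_side, config$cut_distance)
    if (lay$proto_start < 0 || lay$proto_end > clen ||
        lay$pam_start < 0 || lay$pam_end > clen) {
      stop("planted site ", i, ": protospacer/PAM out of chromosome bounds")
    }
    if (config$plant_protospacers) {
      proto <- mutate_spacer(config$grna, site$mismatches)
      pam_obs <- realise_iupac(config$pam)
      seq <- genome[[site$chrom]]
      top_proto <- if (site$strand == "+") proto else revcomp(proto)
      top_pam <- if (site$strand == "+") pam_obs else revcomp(pam_obs)
      substr(seq, lay$proto_start + 1, lay$proto_end) <- top_proto
      substr(seq, lay$pam_start + 1, lay$pam_end) <- top_pam
      genome[[site$chrom]] <- seq
    } else {
      proto <- NA_character_
      pam_obs <- NA_character_
    }
    out[[i]] <- tibble(
      site_id = paste0("site", i),
      chrom = site$chrom, cut_position = site$cut_position,
      strand = site$strand, mismatches = site$mismatches,
      overhang = site$overhang,
      editing_efficiency = site$editing_efficiency,
      protospacer = proto, pam_observed = pam_obs,
      proto_start = lay$proto_start, proto_end = lay$proto_end
    )
  }
  sites <- if (nrow(ps)) bind_rows(out) else tibble(
    site_id = character(0), chrom = character(0),
    cut_position = integer(0), strand = character(0),
    mismatches = integer(0), overhang = integer(0),
    editing_efficiency = numeric(0), protospacer = character(0),
    pam_observed = character(0), proto_start = integer(0),
    proto_end = integer(0)
  )

  # collision check: no second guide-like match (<= 6 mismatches) within
  # 100 bp of any planted site; redraw offending background if needed
  n_check <- if (config$plant_protospacers) nrow(sites) else 0L
  for (i in seq_len(n_check)) {
    s <- sites[i, ]
    clen <- nchar(genome[[s$chrom]])
    win_start <- max(0L, s$proto_start - 100L - L)
    win_end <- min(clen, s$proto_end + 100L + L)
    keep <- intervals_on_chrom(sites, s$chrom)
    for (attempt in 1:25) {
      window <- substr(genome[[s$chrom]], win_start + 1, win_end)
      hits <- win_start + scan_guide_hits(window, config$grna, 6L)
      stray <- setdiff(hits, keep$start)
      if (length(stray) == 0) break
      if (attempt == 25) {
        stop("planted site ", s$site_id,
             ": could not clear guide-like background collisions")
      }
      seq <- genome[[s$chrom]]
      for (h in stray) {
        repl_pos <- setdiff(h:(h + L - 1), unlist(
          purrr::map2(keep$start, keep$end, function(a, b) a:(b - 1))
        ))
        repl_pos <- repl_pos[repl_pos >= 0 & repl_pos < clen]
        for (p in repl_pos) {
          substr(seq, p + 1, p + 1) <-
            sample(c("A", "C", "G", "T"), 1)
        }
      }
      genome[[s$chrom]] <- seq
    }
  }

  structure(list(genome = genome, sites = sites, config = config),
            class = "sim_genome")
}

intervals_on_chrom <- function(sites, chrom) {
  s <- sites[sites$chrom == chrom, ]
  list(start = s$proto_start, end = s$proto_end)
}

# Per-base substitution errors at a flat rate.
add_seq_errors <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (p in hit) {
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  }
  paste(b, collapse = "")
}

random_umi <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate tag-integrated paired-end reads with ground truth
#'
#' Emits one read pair per molecule. Each edited molecule carries the Tag at
#' the cut with the site's overhang geometry: reads from the fragment right
#' of the cut start at the top-strand nick and map to the + strand; reads
#' from the left fragment end at the bottom-strand nick (top-strand nick +
#' overhang, after 5'-overhang fill-in) and map to the - strand. Read 1 is
#' `[UMI][barcode][genomic]`, Read 2 is `[tag-primer remnant][genomic from
#' the junction]`. Tag orientation is random per molecule, so in dual-library
#' mode molecules are split 50/50 between the forward- and reverse-primer
#' libraries.
#'
#' @param sim A `"sim_genome"` from [simulate_genome()].
#' @param config Optional [sim_config()]; defaults to the one stored in
#'   `sim`.
#' @return A list of class `"sim_reads"`: `reads` (tibble of read pairs),
#'   `truth` (one row per emitted read: origin site or background, side,
#'   library, UMI, duplicate flag, junction), and `alignments` (tibble of
#'   truth-based Read-2 alignments usable in pre-aligned mode).
#' @export
simulate_reads <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "sim_genome"))
  if (is.null(config)) config <- sim$config
  set.seed(config$seed + 1L)
  genome <- sim$genome
  tag_prefix <- substr(config$tag_sequence, 1, config$tag_r2_prefix_length)
  glen <- config$read_length - nchar(tag_prefix)
  g1len <- config$read_length - config$umi_length - nchar(config$barcode)
  libs <- if (config$library_mode == "dual") c("fwd", "rev") else "arm"

  mol <- list()
  for (i in seq_len(nrow(sim$sites))) {
    s <- sim$sites[i, ]
    n <- config$reads_per_site
    if (n == 0) next
    clen <- nchar(genome[[s$chrom]])
    ovset <- if (is.list(sim$sites$overhang)) {
      as.integer(sim$sites$overhang[[i]])
    } else {
      as.integer(s$overhang)
    }
    span <- glen + max(abs(ovset)) + 1L
    if (s$cut_position < span || s$cut_position > clen - span) {
      stop("site ", s$site_id, ": read span exceeds chromosome bounds")
    }
    mol[[length(mol) + 1]] <- tibble(
      site_id = s$site_id, chrom = s$chrom,
      side = sample(c("right", "left"), n, replace = TRUE),
      library = sample(libs, n, replace = TRUE),
      umi = random_umi(n, config$umi_length),
      cut = s$cut_position,
      overhang = if (length(ovset) == 1) rep(ovset, n) else
        sample(ovset, n, replace = TRUE)
    )
  }
  if (config$background_integrations > 0) {
    chroms <- names(genome)
    bchrom <- sample(chroms, config$background_integrations, replace = TRUE)
    bpos <- vapply(bchrom, function(ch) {
      clen <- nchar(genome[[ch]])
      sample((glen + 2L):(clen - glen - 2L), 1)
    }, integer(1), USE.NAMES = FALSE)
    mol[[length(mol) + 1]] <- tibble(
      site_id = "background", chrom = bchrom,
      side = sample(c("right", "left"), length(bpos), replace = TRUE),
      library = sample(libs, length(bpos), replace = TRUE),
      umi = random_umi(length(bpos), config$umi_length),
      cut = as.integer(bpos), overhang = 0L
    )
  }
  molecules <- if (length(mol)) bind_rows(mol) else tibble(
    site_id = character(0), chrom = character(0), side = character(0),
    library = character(0), umi = character(0), cut = integer(0),
    overhang = integer(0)
  )

  # PCR duplication: each molecule gains one duplicate with fixed probability
  if (nrow(molecules)) {
    molecules$mol_id <- seq_len(nrow(molecules))
    dup <- molecules[stats::runif(nrow(molecules)) <
                       config$pcr_duplicate_rate, ]
    molecules$is_pcr_duplicate <- FALSE
    if (nrow(dup)) {
      dup$is_pcr_duplicate <- TRUE
      molecules <- bind_rows(molecules, dup)
    }
  } else {
    molecules$mol_id <- integer(0)
    molecules$is_pcr_duplicate <- logical(0)
  }

  n_reads <- nrow(molecules)
  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  aln <- vector("list", n_reads)
  qual <- strrep("I", config$read_length)
  for (j in seq_len(n_reads)) {
    m <- molecules[j, ]
    seq <- genome[[m$chrom]]
    clen <- nchar(seq)
    if (m$side == "right") {
      junction <- m$cut
      strand <- "+"
      gseq <- substr(seq, junction + 1, junction + glen)
      r2 <- paste0(tag_prefix, gseq)
      r2_start <- junction
      frag_end <- min(clen, junction + sample(150:400, 1))
      r1g <- revcomp(substr(seq, max(1, frag_end - g1len + 1), frag_end))
    } else {
      junction <- m$cut + m$overhang
      strand <- "-"
      gseq <- substr(seq, junction - glen + 1, junction)
      r2 <- paste0(tag_prefix, revcomp(gseq))
      r2_start <- junction - glen
      frag_start <- max(0, junction - sample(150:400, 1))
      r1g <- substr(seq, frag_start + 1, frag_start + g1len)
    }
    r1 <- paste0(m$umi, config$barcode, r1g)
    r1 <- substr(paste0(r1, strrep("A", config$read_length)), 1,
                 config$read_length)
    r2 <- add_seq_errors(r2, config$error_rate)
    r1 <- add_seq_errors(r1, config$error_rate)
    read_id <- sprintf("read%06d", j)
    reads[[j]] <- tibble(
      read_id = read_id, seq1 = r1, qual1 = qual, seq2 = r2, qual2 = qual
    )
    truth[[j]] <- tibble(
      read_id = read_id, site_id = m$site_id, chrom = m$chrom,
      junction = junction, strand = strand, side = m$side,
      library = m$library, umi = m$umi,
      is_pcr_duplicate = m$is_pcr_duplicate
    )
    aligned_gseq <- substr(r2, nchar(tag_prefix) + 1, nchar(r2))
    if (strand == "-") aligned_gseq <- revcomp(aligned_gseq)
    aln[[j]] <- tibble(
      read_id = read_id, chrom = m$chrom, r2_start = r2_start,
      strand = strand, mapq = 60L, cigar = paste0(nchar(aligned_gseq), "M"),
      seq = aligned_gseq, umi = m$umi, library = m$library
    )
  }

  empty_reads <- tibble(read_id = character(0), seq1 = character(0),
                        qual1 = character(0), seq2 = character(0),
                        qual2 = character(0))
  empty_truth <- tibble(read_id = character(0), site_id = character(0),
                        chrom = character(0), junction = integer(0),
                        strand = character(0), side = character(0),
                        library = character(0), umi = character(0),
                        is_pcr_duplicate = logical(0))
  empty_aln <- tibble(read_id = character(0), chrom = character(0),
                      r2_start = integer(0), strand = character(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), umi = character(0),
                      library = character(0))
  structure(
    list(
      reads = if (n_reads) bind_rows(reads) else empty_reads,
      truth = if (n_reads) bind_rows(truth) else empty_truth,
      alignments = if (n_reads) bind_rows(aln) else empty_aln,
      config = config
    ),
    class = "sim_reads"
  )
}

#' Write simulated Read-2 alignments as a SAM file
#'
#' Emits one record per read with truth-based coordinates, a full-match
#' CIGAR, and `RX`/`LB` tags carrying the UMI and library. Suitable for the
#' pipeline's pre-aligned mode.
#'
#' @param sim_reads A `"sim_reads"` object.
#' @param genome Named character vector of chromosome sequences (for
#'   `@SQ` header lines).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim_reads, genome, path) {
  stopifnot(inherits(sim_reads, "sim_reads"))
  a <- sim_reads$alignments
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, nchar(genome[[ch]])), con)
  }
  if (nrow(a)) {
    flag <- ifelse(a$strand == "-", 16L, 0L)
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tRX:Z:%s\tLB:Z:%s",
                   a$read_id, flag, a$chrom, a$r2_start + 1L, a$mapq,
                   a$cigar, a$seq, strrep("I", nchar(a$seq)), a$umi,
                   a$library)
    writeLines(rec, con)
  }
  invisible(path)
}

#' Pick transposon insertion sites at TA dinucleotides
#'
#' Scans the genome for TA dinucleotides and samples insertion junctions for
#' a Sleeping-Beauty-style simulation: for a TA at 0-based positions
#' `(p, p+1)`, the blunt junction is planted at `p + 1`, so the central
#' dinucleotide step of the +/-5 bp flank window is the TA itself.
#'
#' @param sim A `"sim_genome"`.
#' @param n Number of insertion sites to draw.
#' @param min_spacing Minimum distance between chosen sites in bp.
#' @param clearance Distance from chromosome ends to avoid.
#' @param seed Integer seed.
#' @param at_ta If `FALSE`, sample positions uniformly instead of at TA
#'   dinucleotides (the null used for enrichment calibration).
#' @return A planted-site tibble (see [planted_site()]) with blunt cuts.
#' @export
sim_transposon_sites <- function(sim, n, min_spacing = 200L,
                                 clearance = 150L, seed = 1L,
                                 at_ta = TRUE) {
  stopifnot(inherits(sim, "sim_genome"))
  set.seed(seed)
  picks <- list()
  for (ch in names(sim$genome)) {
    seq <- sim$genome[[ch]]
    clen <- nchar(seq)
    if (at_ta) {
      hits <- as.integer(
        gregexpr("TA", seq, fixed = TRUE)[[1]]
      )
      hits <- hits[hits > 0] - 1L  # 0-based position of the T
      cand <- hits[hits >= clearance & hits <= clen - clearance]
      jun <- cand + 1L
    } else {
      jun <- seq.int(clearance, clen - clearance)
    }
    picks[[ch]] <- tibble(chrom = ch, cut_position = jun)
  }
  all <- bind_rows(picks)
  if (nrow(all) < n) stop("not enough candidate positions")
  chosen <- integer(0)
  pool <- sample(seq_len(nrow(all)))
  for (idx in pool) {
    pos <- all$cut_position[idx]
    ch <- all$chrom[idx]
    near <- chosen[all$chrom[chosen] == ch &
                     abs(all$cut_position[chosen] - pos) < min_spacing]
    if (length(near) == 0) chosen <- c(chosen, idx)
    if (length(chosen) == n) break
  }
  if (length(chosen) < n) stop("could not place ", n, " sites with spacing ",
                               min_spacing)
  sel <- all[sort(chosen), ]
  planted_site(chrom = sel$chrom, cut_position = sel$cut_position,
               strand = "+", mismatches = 0L, overhang = 0L,
               editing_efficiency = 1)
}
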