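#' Infer cleavage geometry at a called site
#'
#' The plus- and minus-strand junction observations around a site read out
#' the two nicks of the break: the fragment right of the cut starts at the
#' top-strand nick (+ observations), the left fragment ends at the
#' bottom-strand nick after 5'-overhang fill-in (- observations). The
#' signed offset distribution (minus-side junction - modal plus-side
#' junction) therefore recovers the overhang: modal offset 0 is a blunt
#' cut, +1 a 1-nt 5' overhang, and two or more offsets each carrying >= 20%
#' of the mass (or a modal |offset| >= 2) a staggered multi-overhang cut
#' (Cpf1-like).
#'
#' @param site One row of a `"dsb_sites"` tibble.
#' @param tracks Junction track tibble.
#' @param window Half-width in bp around the cut within which junctions are
#'   attributed to the site (default 15).
#' @param multi_mass_min Mass fraction an offset must carry to count as a
#'   modal overhang (default 0.2).
#' @return A list of class `"cut_profile"`: per-strand junction histograms,
#'   the offset distribution, `modal_overhangs` tibble, and
#'   `geometry_label` in `{"blunt", "1-nt 5' overhang", "staggered-multi",
#'   "undetermined"}`.
#' @export
infer_cut_profile <- function(site, tracks, window = 15L,
                              multi_mass_min = 0.2) {
  near <- filter(tracks, .data$chrom == site$chrom,
                 abs(.data$junction - site$cut_position) <= window)
  plus <- filter(near, .data$strand == "+") |>
    count(.data$junction, wt = .data$support, name = "support")
  minus <- filter(near, .data$strand == "-") |>
    count(.data$junction, wt = .data$support, name = "support")
  if (nrow(plus) == 0 || nrow(minus) == 0) {
    prof <- list(site = site, plus = plus, minus = minus,
                 offsets = tibble(offset = integer(0), fraction = numeric(0)),
                 modal_overhangs = tibble(offset = integer(0),
                                          fraction = numeric(0)),
                 geometry_label = "undetermined")
    class(prof) <- "cut_profile"
    return(prof)
  }
  jp <- modal_value(plus$junction, plus$support)
  off <- minus |>
    mutate(offset = .data$junction - jp) |>
    group_by(.data$offset) |>
    summarise(support = sum(.data$support), .groups = "drop") |>
    mutate(fraction = .data$support / sum(.data$support)) |>
    arrange(desc(.data$fraction), .data$offset)
  modal <- filter(off, .data$fraction >= multi_mass_min)
  top <- off$offset[1]
  label <- if (nrow(modal) >= 2 || abs(top) >= 2) {
    "staggered-multi"
  } else if (top == 0) {
    "blunt"
  } else {
    "1-nt 5' overhang"
  }
  prof <- list(site = site, plus = plus, minus = minus,
               offsets = select(off, "offset", "fraction"),
               modal_overhangs = select(modal, "offset", "fraction"),
               modal_offset = as.integer(top),
               geometry_label = label)
  class(prof) <- "cut_profile"
  prof
}

#' @export
print.cut_profile <- function(x, ...) {
  cat("Cut profile at", x$site$chrom, x$site$cut_position, "\n")
  cat("  geometry:", x$geometry_label, "\n")
  if (nrow(x$modal_overhangs)) {
    cat("  modal overhangs (positive = 5' overhang):",
        paste0(x$modal_overhangs$offset, " (",
               round(100 * x$modal_overhangs$fraction), "%)",
               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cut_profile <- function(x, ...) {
  mutate(x$offsets,
         chrom = x$site$chrom, cut_position = x$site$cut_position,
         .before = 1)
}

#' @export
glance.cut_profile <- function(x, ...) {
  tibble(
    chrom = x$site$chrom, cut_position = x$site$cut_position,
    geometry_label = x$geometry_label,
    modal_offset = if (is.null(x$modal_offset)) NA_integer_ else
      x$modal_offset,
    n_modal_overhangs = nrow(x$modal_overhangs),
    support_plus = sum(x$plus$support),
    support_minus = sum(x$minus$support)
  )
}

#' Distance of the cut from the PAM
#'
#' Signed distance from the consensus cut position to the PAM-proximal
#' protospacer boundary, orientation-normalised so that +- strand mirror
#' sites report the same magnitude (3-4 bp is the blunt Cas9 expectation
#' for an NGG 3' PAM; ~18 bp the Cpf1 expectation for a 5' PAM).
#'
#' @param hit One row of an `"offtarget_hits"` tibble (matched).
#' @param pam_side `"3p"` or `"5p"`.
#' @return Integer distance in bp, or `NA` for unmatched sites.
#' @export
pam_offset <- function(hit, pam_side = c("3p", "5p")) {
  pam_side <- match.arg(pam_side)
  if (is.na(hit$proto_strand) ||
      !hit$classification %in% c("on-target", "off-target")) {
    return(NA_integer_)
  }
  if (hit$proto_strand == "+") {
    boundary <- if (pam_side == "3p") hit$proto_end else hit$proto_start
    d <- if (pam_side == "3p") boundary - hit$cut_position
    else hit$cut_position - boundary
  } else {
    boundary <- if (pam_side == "3p") hit$proto_start else hit$proto_end
    d <- if (pam_side == "3p") hit$cut_position - boundary
    else boundary - hit$cut_position
  }
  as.integer(d)
}
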