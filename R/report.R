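#' Genome-wide DSB distribution plot
#'
#' One panel per chromosome; each called site is a point at its cut
#' position with point size proportional to read count. Layout is
#' deterministic.
#'
#' @param sites A `"dsb_sites"` tibble (possibly empty).
#' @param chrom_lengths Optional named vector of chromosome lengths to fix
#'   the x scale.
#' @return A ggplot object.
#' @export
plot_genomewide <- function(sites, chrom_lengths = NULL) {
  df <- as_tibble(sites)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cut_position, y = 0)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$total_support),
                        colour = "#2c7fb8", alpha = 0.8) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::labs(x = "position (bp)", y = NULL, size = "reads",
                  title = "Called DSB sites") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
  if (!is.null(chrom_lengths)) {
    p <- p + ggplot2::expand_limits(x = c(0, max(chrom_lengths)))
  }
  p
}

#' Per-site junction pileup with the cut position marked
#'
#' @param profile A `"cut_profile"` from [infer_cut_profile()].
#' @return A ggplot object; the red dashed line marks the consensus cut.
#' @export
plot_site_profile <- function(profile) {
  df <- bind_rows(
    mutate(profile$plus, strand = "+"),
    mutate(profile$minus, strand = "-")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$junction, y = .data$support,
                                   fill = .data$strand)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = profile$site$cut_position,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "junction position (bp)", y = "molecules",
                  title = paste0(profile$site$chrom, ":",
                                 profile$site$cut_position, "  [",
                                 profile$geometry_label, "]")) +
    ggplot2::theme_bw()
}

#' Off-target alignment panel (guide on top, sites below, mismatches marked)
#'
#' @param hits An `"offtarget_hits"` tibble.
#' @return A ggplot object with one row per matched site, read counts at
#'   the right, and mismatched guide positions highlighted.
#' @export
plot_offtargets <- function(hits) {
  grna <- attr(hits, "grna")
  rep_tbl <- classify_and_report(hits)$matched
  L <- nchar(grna)
  rows <- bind_rows(
    tibble(label = "gRNA", y = 0L, read_count = NA_integer_,
           seq = grna, mm = list(integer(0))),
    purrr::pmap_dfr(
      list(rep_tbl$chrom, rep_tbl$cut_position, rep_tbl$protospacer,
           rep_tbl$mismatch_positions, rep_tbl$read_count,
           rep_tbl$proto_strand, seq_len(nrow(rep_tbl))),
      function(ch, cut, proto, mm, rc, st, i) {
        s <- if (st == "-") revcomp(proto) else proto
        tibble(label = paste0(ch, ":", cut), y = i,
               read_count = rc, seq = s, mm = list(mm))
      })
  )
  cells <- purrr::pmap_dfr(
    list(rows$label, rows$y, rows$seq, rows$mm, rows$read_count),
    function(lab, y, s, mm, rc) {
      ch <- strsplit(s, "")[[1]]
      tibble(label = lab, y = y, x = seq_along(ch), base = ch,
             mismatch = seq_along(ch) %in% mm, read_count = rc)
    })
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = -.data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$mismatch),
                       colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "white",
                                          `TRUE` = "#fdae61"),
                               guide = "none") +
    ggplot2::scale_y_continuous(
      breaks = -unique(cells$y),
      labels = rows$label[match(unique(cells$y), rows$y)],
      sec.axis = ggplot2::sec_axis(
        ~., breaks = -unique(cells$y),
        labels = ifelse(is.na(rows$read_count), "reads",
                        rows$read_count)[match(unique(cells$y), rows$y)])
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "On/off-target sites") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @export
autoplot.dsb_sites <- function(object, ...) plot_genomewide(object, ...)

#' @export
autoplot.offtarget_hits <- function(object, ...) plot_offtargets(object)

#' @export
autoplot.cut_profile <- function(object, ...) plot_site_profile(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.dsb_sites <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.dsb_sites <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_both_strands = sum(x$evidence_class == "both-strands"),
    n_both_libraries = sum(x$evidence_class == "both-libraries"),
    total_support = sum(x$total_support)
  )
}

#' @export
tidy.offtarget_hits <- function(x, ...) {
  as_tibble(unclass(x)) |>
    mutate(mismatch_positions = purrr::map_chr(
      .data$mismatch_positions, paste, collapse = ","))
}

#' @export
glance.offtarget_hits <- function(x, ...) {
  tibble(
    n_on_target = sum(x$classification == "on-target"),
    n_off_target = sum(x$classification == "off-target"),
    n_unmatched = sum(!x$classification %in% c("on-target", "off-target")),
    max_read_count = if (nrow(x)) max(x$read_count) else NA_integer_
  )
}

#' Compare a specific DSB site across experiments
#'
#' @param site A list or one-row tibble with `chrom` and `cut_position`
#'   (or `position`).
#' @param runs Named list (>= 2) of site tables (`"dsb_sites"` or
#'   `"offtarget_hits"`).
#' @param tolerance Positions within this many bp of the query match
#'   (default 5).
#' @return Tibble with one row per run: read count (0 when absent) and
#'   mismatch count when available. Attribute `"found"` is `FALSE` when
#'   the site is absent from every run.
#' @export
compare_experiments <- function(site, runs, tolerance = 5L) {
  stopifnot(length(runs) >= 2, !is.null(names(runs)))
  pos <- if (!is.null(site$cut_position)) site$cut_position else
    site$position
  rows <- purrr::imap_dfr(runs, function(tbl, nm) {
    tbl <- as_tibble(tbl)
    pcol <- if ("cut_position" %in% names(tbl)) "cut_position" else
      "position"
    ccol <- if ("read_count" %in% names(tbl)) "read_count" else
      "total_support"
    hit <- tbl[tbl$chrom == site$chrom &
                 abs(tbl[[pcol]] - pos) <= tolerance, , drop = FALSE]
    if (nrow(hit) == 0) {
      return(tibble(run = nm, read_count = 0L, mismatches = NA_integer_,
                    position = NA_integer_))
    }
    hit <- hit[order(-hit[[ccol]]), , drop = FALSE][1, ]
    tibble(run = nm, read_count = as.integer(hit[[ccol]]),
           mismatches = if ("mismatches" %in% names(hit))
             hit$mismatches else NA_integer_,
           position = as.integer(hit[[pcol]]))
  })
  if (all(rows$read_count == 0)) {
    message("site not present in any run")
    attr(rows, "found") <- FALSE
  } else {
    attr(rows, "found") <- TRUE
  }
  rows
}

#' Assemble a per-stage run report
#'
#' @param stages Named list of per-stage count tibbles (the `"report"`
#'   attributes emitted by the filtering/loading steps) or single counts.
#' @param params Named list of parameter objects recorded with the run.
#' @return A list of class `"run_report"`.
#' @export
run_report <- function(stages, params = list()) {
  counts <- purrr::imap_dfr(stages, function(x, nm) {
    if (is.data.frame(x)) {
      mutate(as_tibble(x), stage = nm, .before = 1)
    } else {
      tibble(stage = nm, count = as.integer(x))
    }
  })
  structure(list(counts = counts, params = params), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Run report\n")
  print(x$counts)
  invisible(x)
}
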