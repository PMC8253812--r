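#' Peak-calling parameters for DSB site detection
#'
#' @param max_gap Junction positions closer than this (strictly) share a
#'   hotspot region. Default 10 bp.
#' @param window Sliding-window width in bp (step 1). Default 10.
#' @param min_support Molecule count each evidence class must reach for a
#'   site to be flagged ("more than five reads", i.e. >= 6). Applied per
#'   class by default; set `support_rule = "total"` for the pooled reading.
#' @param min_support_transposon Total molecule count required in
#'   single-library (transposon) mode ("at least five reads", i.e. >= 5).
#' @param min_peak_separation Minimum distance between retained peaks;
#'   defaults to `window`.
#' @param support_rule `"per_class"` (default) or `"total"`: whether
#'   `min_support` applies to each strand/library class or to their sum.
#' @return A list of class `"call_params"`.
#' @export
call_params <- function(max_gap = 10L, window = 10L, min_support = 6L,
                        min_support_transposon = 5L,
                        min_peak_separation = window,
                        support_rule = c("per_class", "total")) {
  support_rule <- match.arg(support_rule)
  stopifnot(window >= 1, min_support >= 1, max_gap >= 1,
            min_support_transposon >= 1, min_peak_separation >= 0)
  structure(
    list(max_gap = as.integer(max_gap), window = as.integer(window),
         min_support = as.integer(min_support),
         min_support_transposon = as.integer(min_support_transposon),
         min_peak_separation = as.integer(min_peak_separation),
         support_rule = support_rule),
    class = "call_params"
  )
}

#' Group junction positions into cutting hotspot regions
#'
#' Positions are pooled across strands and libraries per chromosome and
#' grouped greedily: adjacent positions strictly closer than `max_gap`
#' share a region (a gap of exactly `max_gap` splits). Regions are maximal
#' and partition the positions.
#'
#' @param tracks Junction track tibble ([junction_tracks()]).
#' @param params A [call_params()].
#' @return Tibble with `chrom`, `region_id`, `start`, `end` (0-based
#'   half-open over member positions), `n_positions`, `total_support`.
#' @export
group_hotspots <- function(tracks, params = call_params()) {
  if (nrow(tracks) == 0) {
    return(tibble(chrom = character(0), region_id = integer(0),
                  start = integer(0), end = integer(0),
                  n_positions = integer(0), total_support = integer(0)))
  }
  tracks |>
    group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      pos <- sort(unique(df$junction))
      brk <- c(0L, cumsum(diff(pos) >= params$max_gap))
      reg <- tibble(junction = pos, region = brk)
      df2 <- left_join(df, reg, by = "junction")
      df2 |>
        group_by(.data$region) |>
        summarise(start = min(.data$junction),
                  end = max(.data$junction) + 1L,
                  n_positions = dplyr::n_distinct(.data$junction),
                  total_support = sum(.data$support), .groups = "drop") |>
        select(-"region")
    }) |>
    ungroup() |>
    arrange(.data$chrom, .data$start) |>
    mutate(region_id = row_number()) |>
    select("chrom", "region_id", "start", "end", "n_positions",
           "total_support")
}

# Member rows of one hotspot region.
region_members <- function(tracks, region) {
  filter(tracks, .data$chrom == region$chrom,
         .data$junction >= region$start, .data$junction < region$end)
}

#' Sliding-window counts within a hotspot region
#'
#' Enumerates every window of width `window` (step 1) whose span intersects
#' the region's member positions, i.e. window starts from
#' `start - (window - 1)` to `end - 1`. Counts are reported per
#' (strand, library) class and summed.
#'
#' @param members Track rows of one region ([region_members()]).
#' @param params A [call_params()].
#' @return Tibble with `window_start`, one `n_<strand>_<library>` column
#'   per observed class, and `total`.
#' @export
window_counts <- function(members, params = call_params()) {
  stopifnot(nrow(members) > 0)
  w <- params$window
  lo <- min(members$junction) - (w - 1L)
  hi <- max(members$junction)
  starts <- lo:hi
  classes <- members |>
    distinct(.data$strand, .data$library) |>
    arrange(.data$strand, .data$library)
  out <- tibble(window_start = starts)
  total <- rep(0L, length(starts))
  for (i in seq_len(nrow(classes))) {
    cl <- members |>
      filter(.data$strand == classes$strand[i],
             .data$library == classes$library[i])
    tally <- integer(hi + w - lo)
    idx <- cl$junction - lo + 1L
    tally[idx] <- tally[idx] + cl$support
    cs <- c(0L, cumsum(tally))
    cnt <- cs[(starts - lo) + w + 1L] - cs[(starts - lo) + 1L]
    nm <- paste0("n_", if (classes$strand[i] == "+") "plus" else "minus",
                 "_", classes$library[i])
    out[[nm]] <- as.integer(cnt)
    total <- total + as.integer(cnt)
  }
  out$total <- total
  out
}

#' Detect peaks in a window-count vector
#'
#' A peak is a strict local maximum of the summed counts; a plateau of equal
#' maximal values yields a single peak at its leftmost window. Peaks closer
#' than `min_peak_separation` keep only the higher one (ties resolved
#' leftmost). Vector boundaries count as lower neighbours.
#'
#' @param counts Non-negative numeric vector (summed window counts).
#' @param params A [call_params()].
#' @return Sorted integer vector of 1-based peak indices.
#' @export
detect_peaks <- function(counts, params = call_params()) {
  n <- length(counts)
  if (n == 0) return(integer(0))
  r <- rle(as.numeric(counts))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  prev <- c(-Inf, r$values[-k])
  nxt <- c(r$values[-1], -Inf)
  is_peak <- r$values > prev & r$values > nxt
  cand <- starts[is_peak]
  if (length(cand) <= 1) return(cand)
  h <- counts[cand]
  ord <- order(-h, cand)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(cand[i] - kept) >= params$min_peak_separation)) {
      kept <- c(kept, cand[i])
    }
  }
  sort(kept)
}

# Per-class supports and modal cut position for one peak window.
peak_window_summary <- function(members, win_start, window) {
  inw <- filter(members, .data$junction >= win_start,
                .data$junction < win_start + window)
  by_strand <- inw |>
    group_by(.data$strand) |>
    summarise(s = sum(.data$support), .groups = "drop")
  sup <- function(st) {
    v <- by_strand$s[by_strand$strand == st]
    if (length(v)) as.integer(v) else 0L
  }
  by_lib <- inw |>
    group_by(.data$library) |>
    summarise(s = sum(.data$support), .groups = "drop")
  lsup <- function(lb) {
    v <- by_lib$s[by_lib$library == lb]
    if (length(v)) as.integer(v) else 0L
  }
  by_class <- inw |>
    group_by(.data$strand, .data$library) |>
    summarise(s = sum(.data$support), .groups = "drop")
  csup <- function(st, lb) {
    v <- by_class$s[by_class$strand == st & by_class$library == lb]
    if (length(v)) as.integer(v) else 0L
  }
  list(
    members = inw,
    cut = modal_value(inw$junction, inw$support),
    support_plus = sup("+"), support_minus = sup("-"),
    support_fwd_lib = lsup("fwd"), support_rev_lib = lsup("rev"),
    csup = csup,
    total = as.integer(sum(inw$support))
  )
}

# Bidirectional evidence rule. Returns the evidence class or NA.
evidence_class_of <- function(pw, params) {
  ms <- params$min_support
  if (params$support_rule == "total") {
    both_strand <- pw$support_plus > 0 && pw$support_minus > 0 &&
      pw$support_plus + pw$support_minus >= ms
    if (both_strand) return("both-strands")
    for (st in c("+", "-")) {
      f <- pw$csup(st, "fwd"); r <- pw$csup(st, "rev")
      if (f > 0 && r > 0 && f + r >= ms) return("both-libraries")
    }
    return(NA_character_)
  }
  if (pw$support_plus >= ms && pw$support_minus >= ms) {
    return("both-strands")
  }
  for (st in c("+", "-")) {
    if (pw$csup(st, "fwd") >= ms && pw$csup(st, "rev") >= ms) {
      return("both-libraries")
    }
  }
  NA_character_
}

#' Flag DSB sites at detected peaks
#'
#' A peak window becomes a site iff >= `min_support` molecules map to both
#' the + and - strand, or to the same strand but from both the forward- and
#' reverse-tag-primer libraries. The consensus cut position is the modal
#' junction within the peak window (ties -> leftmost). Sites are sorted by
#' total support, descending.
#'
#' @param members Region member rows.
#' @param peak_starts Window start coordinates of detected peaks.
#' @param params A [call_params()].
#' @return Tibble of flagged sites (possibly empty).
#' @export
flag_dsb_sites <- function(members, peak_starts, params = call_params()) {
  rows <- list()
  for (w in peak_starts) {
    pw <- peak_window_summary(members, w, params$window)
    ec <- evidence_class_of(pw, params)
    if (is.na(ec)) next
    rows[[length(rows) + 1]] <- tibble(
      chrom = members$chrom[1], cut_position = pw$cut,
      window_start = as.integer(w),
      window_end = as.integer(w + params$window),
      support_plus = pw$support_plus, support_minus = pw$support_minus,
      support_fwd_lib = pw$support_fwd_lib,
      support_rev_lib = pw$support_rev_lib,
      total_support = pw$total, evidence_class = ec
    )
  }
  if (length(rows) == 0) return(empty_sites())
  arrange(bind_rows(rows), desc(.data$total_support))
}

empty_sites <- function() {
  tibble(chrom = character(0), cut_position = integer(0),
         window_start = integer(0), window_end = integer(0),
         support_plus = integer(0), support_minus = integer(0),
         support_fwd_lib = integer(0), support_rev_lib = integer(0),
         total_support = integer(0), evidence_class = character(0))
}

#' Call DSB sites from junction tracks
#'
#' Runs the full chain: hotspot grouping, sliding-window counting, peak
#' detection and the bidirectional support rule, per chromosome.
#'
#' @param tracks Junction track tibble ([junction_tracks()]).
#' @param params A [call_params()].
#' @return Tibble of class `"dsb_sites"`, sorted by total support.
#' @export
call_dsb_sites <- function(tracks, params = call_params()) {
  regions <- group_hotspots(tracks, params)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    members <- region_members(tracks, reg)
    wc <- window_counts(members, params)
    peaks <- detect_peaks(wc$total, params)
    sites <- flag_dsb_sites(members, wc$window_start[peaks], params)
    if (nrow(sites)) out[[length(out) + 1]] <- sites
  }
  res <- if (length(out)) {
    arrange(bind_rows(out), desc(.data$total_support), .data$chrom,
            .data$cut_position)
  } else {
    empty_sites()
  }
  class(res) <- c("dsb_sites", class(res))
  res
}

#' Write called sites as BED
#'
#' @param sites A `"dsb_sites"` tibble.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   sites$chrom, sites$cut_position, sites$cut_position + 1L,
                   sites$evidence_class, sites$total_support)
  writeLines(lines, path)
  invisible(path)
}
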