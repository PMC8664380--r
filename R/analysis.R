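#' Per-class frame proportions for one facial region
#'
#' @param labels character vector of per-frame classes.
#' @param region `"upper"` or `"lower"`.
#' @return named proportion vector over [au_all_classes()] of the region
#'   (sums to 1).
#' @export
au_frequency <- function(labels, region) {
  if (!length(labels)) stop("empty label vector", call. = FALSE)
  classes <- au_all_classes(region)
  counts <- vapply(classes, function(cl) sum(labels == cl), 0L)
  counts / length(labels)
}

#' Co-occurrence matrix of action units across regions
#'
#' Cell (i, j) is the number of frames on which both units occur divided by
#' the total frame count of the rarer of the two units. Diagonal cells are 1
#' wherever the unit occurs at all. Units with zero frames yield `NA` cells.
#'
#' @param upper_labels,lower_labels per-frame class vectors of equal length.
#' @param units character vector of classes to cross (defaults to every
#'   non-neutral class of both regions); each is matched against its own
#'   region's labels.
#' @return square proportion matrix with `units` as dimnames.
#' @export
cooccurrence_matrix <- function(upper_labels, lower_labels,
                                units = c(au_target_classes("upper"),
                                          au_target_classes("lower"))) {
  if (length(upper_labels) != length(lower_labels))
    stop("label vectors must have equal length", call. = FALSE)
  present <- vapply(units, function(u) {
    if (u %in% au_all_classes("upper")) upper_labels == u else lower_labels == u
  }, logical(length(upper_labels)))
  n_u <- colSums(present)
  k <- length(units)
  out <- matrix(NA_real_, k, k, dimnames = list(units, units))
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      denom <- min(n_u[i], n_u[j])
      if (denom > 0)
        out[i, j] <- sum(present[, i] & present[, j]) / denom
    }
  out
}

#' Block-period definitions for a video
#'
#' @param intervals named list of period types (`enter_exit`,
#'   `shutter_open`, `shutter_closed`, or any labels); each element a
#'   two-column matrix/data frame of half-open `(start_frame, end_frame)`
#'   intervals.
#' @return object of class `block_periods`.
#' @export
block_periods <- function(intervals) {
  all_frames <- integer(0)
  for (nm in names(intervals)) {
    iv <- as.matrix(intervals[[nm]])
    if (ncol(iv) != 2L || any(iv[, 2] < iv[, 1]) || any(iv < 0))
      stop("invalid intervals for period ", nm, call. = FALSE)
    fr <- unlist(lapply(seq_len(nrow(iv)),
                        function(r) seq.int(iv[r, 1], length.out = iv[r, 2] - iv[r, 1])))
    if (any(fr %in% all_frames))
      stop("overlapping periods at frame ",
           intersect(fr, all_frames)[1], call. = FALSE)
    all_frames <- c(all_frames, fr)
  }
  structure(intervals, class = "block_periods")
}

period_frames <- function(iv) {
  iv <- as.matrix(iv)
  unlist(lapply(seq_len(nrow(iv)),
                function(r) seq.int(iv[r, 1], length.out = iv[r, 2] - iv[r, 1])))
}

#' Read period definitions from a delimited table
#'
#' Columns: `video_id`, `period_name`, `start_frame`, `end_frame`.
#'
#' @param path file path.
#' @return named list (per video) of [block_periods()].
#' @export
read_period_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$video_id), function(sub)
    block_periods(lapply(split(sub, sub$period_name), function(p)
      cbind(p$start_frame, p$end_frame))))
}

#' Proportion of an AU combination per block period
#'
#' For each period: the number of frames whose upper-face class equals
#' `combo[1]` and lower-face class equals `combo[2]`, divided by the
#' period's frame count. Empty periods give `NA`.
#'
#' @param upper_labels,lower_labels per-frame class vectors (frame `i` is
#'   0-based index `i - 1`).
#' @param periods a [block_periods()].
#' @param combo length-2 character vector `(upper class, lower class)`.
#' @return named numeric vector, one proportion per period.
#' @export
combination_proportions <- function(upper_labels, lower_labels, periods,
                                    combo) {
  stopifnot(length(upper_labels) == length(lower_labels), length(combo) == 2L)
  hit <- upper_labels == combo[1] & lower_labels == combo[2]
  vapply(periods, function(iv) {
    fr <- period_frames(iv)
    if (!length(fr)) return(NA_real_)
    if (any(fr >= length(hit)))
      stop("period frame beyond label coverage", call. = FALSE)
    mean(hit[fr + 1L])
  }, 0)
}

#' Pearson chi-square test on a contingency table
#'
#' Classical Pearson statistic `sum (O - E)^2 / E` with expectations from
#' the row/column margins, `df = (r - 1)(c - 1)`, no continuity correction.
#' Typical use: combo-present / combo-absent frame counts per block period.
#'
#' @param counts r x c matrix of non-negative counts with positive margins.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(ct$expected <= 0))
    stop("degenerate table: non-positive expected count", call. = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' Z-score a firing rate against baseline statistics
#'
#' `(fr - baseline_mean) / baseline_sd`, the standard peri-event
#' normalization.
#'
#' @param fr firing rate (spikes/s); vectorized.
#' @param baseline_mean,baseline_sd baseline firing statistics (spikes/s),
#'   `baseline_sd > 0`.
#' @return z-scored rate(s).
#' @export
normalize_firing_rate <- function(fr, baseline_mean, baseline_sd) {
  if (baseline_sd <= 0) stop("baseline_sd must be > 0", call. = FALSE)
  (fr - baseline_mean) / baseline_sd
}

#' Peri-event binned firing rates, z-scored against baseline
#'
#' Spike counts are binned in windows of `bin_ms` around each event onset,
#' converted to rates, averaged over events, and z-scored against baseline
#' statistics computed with the same bin width over a pre-block baseline
#' epoch.
#'
#' @param spike_times sorted spike times in seconds.
#' @param event_times event (AU onset) times in seconds, >= 1.
#' @param window `c(before, after)` in seconds around each event (default
#'   `c(-0.7, 0.7)`).
#' @param bin_ms bin width in milliseconds (default 300, the normalization
#'   window length).
#' @param baseline either `c(start, end)` seconds of a baseline epoch (its
#'   spikes are binned with `bin_ms` to get mean and SD), or a list with
#'   precomputed `mean` and `sd` (spikes/s).
#' @return object of class `peri_event_rates`: `bin_centers` (s, relative
#'   to onset), `counts` (events x bins), `rates`, `psth` (mean rate per
#'   bin), `z` (z-scored PSTH), `baseline_mean`, `baseline_sd`.
#' @export
peri_event_rates <- function(spike_times, event_times,
                             window = c(-0.7, 0.7), bin_ms = 300,
                             baseline) {
  if (!length(event_times)) stop("need at least one event", call. = FALSE)
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  bin_s <- bin_ms / 1000
  edges <- seq(window[1], window[2], by = bin_s)
  if (length(edges) < 2L) stop("window shorter than one bin", call. = FALSE)
  nb <- length(edges) - 1L
  counts <- t(vapply(event_times, function(ev) {
    rel <- spike_times - ev
    rel <- rel[rel >= edges[1] & rel < edges[nb + 1L]]
    tabulate(findInterval(rel, edges), nbins = nb)
  }, integer(nb)))
  rates <- counts / bin_s
  if (is.list(baseline)) {
    bmean <- baseline$mean; bsd <- baseline$sd
  } else {
    bl <- spike_times[spike_times >= baseline[1] & spike_times < baseline[2]]
    bedges <- seq(baseline[1], baseline[2], by = bin_s)
    if (length(bedges) < 3L)
      stop("insufficient baseline epoch: need >= 2 baseline bins", call. = FALSE)
    brates <- tabulate(findInterval(bl, bedges),
                       nbins = length(bedges) - 1L) / bin_s
    bmean <- mean(brates); bsd <- stats::sd(brates)
  }
  if (is.na(bsd) || bsd <= 0)
    stop("insufficient baseline: SD must be > 0", call. = FALSE)
  psth <- colMeans(rates)
  structure(list(bin_centers = edges[-1] - bin_s / 2, counts = counts,
                 rates = rates, psth = psth,
                 z = normalize_firing_rate(psth, bmean, bsd),
                 baseline_mean = bmean, baseline_sd = bsd),
            class = "peri_event_rates")
}

#' Read spike times from text
#'
#' Either a single column of times (seconds) or a table with columns
#' `unit_id` and `time_s`.
#'
#' @param path file path.
#' @param unit_id optional unit to select when the file is a table.
#' @return sorted numeric vector of spike times.
#' @export
read_spike_times <- function(path, unit_id = NULL) {
  first <- readLines(path, n = 1L)
  if (grepl("unit_id", first)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!is.null(unit_id)) df <- df[df$unit_id == unit_id, , drop = FALSE]
    sort(df$time_s)
  } else {
    sort(as.numeric(readLines(path)))
  }
}
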