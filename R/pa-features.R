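#' Minute-to-minute transition probabilities
#'
#' Fragmentation metrics of an active/sedentary minute sequence.  The
#' active-to-sedentary transition probability (ASTP) is the number of
#' active-to-sedentary transitions divided by the number of active minutes
#' excluding the final minute (which has no successor); the
#' sedentary-to-active probability (SATP) swaps the roles.  A state with
#' no eligible minutes yields `NA`, never 0: an all-active trace carries
#' no information about sedentary behaviour.
#'
#' @param active logical (or 0/1) vector, one element per minute, `TRUE` =
#'   active; length at least 2.
#' @return named numeric vector `c(SATP = , ASTP = )`, each in [0, 1] or
#'   `NA`.
#' @export
transition_probabilities <- function(active) {
  active <- as.logical(active)
  if (length(active) < 2L || any(is.na(active))) {
    stop("need an NA-free active/sedentary sequence of length >= 2", call. = FALSE)
  }
  from <- active[-length(active)]
  to <- active[-1L]
  n_active <- sum(from)
  n_sed <- sum(!from)
  astp <- if (n_active == 0L) NA_real_ else sum(from & !to) / n_active
  satp <- if (n_sed == 0L) NA_real_ else sum(!from & to) / n_sed
  c(SATP = satp, ASTP = astp)
}

#' Mean bout durations
#'
#' A bout is a maximal run of consecutive minutes in the same state.
#' Returns the mean duration (minutes) of sedentary bouts (SBout) and
#' active bouts (ABout); `NA` when the state never occurs.
#'
#' @param active logical (or 0/1) minute vector, length >= 1.
#' @return named numeric vector `c(SBout = , ABout = )`.
#' @export
bout_summaries <- function(active) {
  active <- as.logical(active)
  if (length(active) < 1L || any(is.na(active))) {
    stop("need an NA-free active/sedentary sequence of length >= 1", call. = FALSE)
  }
  r <- rle(active)
  sb <- r$lengths[!r$values]
  ab <- r$lengths[r$values]
  c(SBout = if (length(sb)) mean(sb) else NA_real_,
    ABout = if (length(ab)) mean(ab) else NA_real_)
}

# best (max or min) mean of log(1+x) over all contiguous windows of `width`
# minutes within one 1440-minute day; windows do not wrap midnight.
# Returns the window mean.  O(1440) via cumulative sums.
best_window_mean <- function(log_day, width, maximize = TRUE) {
  cs <- c(0, cumsum(log_day))
  n <- length(log_day)
  sums <- cs[(width + 1L):(n + 1L)] - cs[1:(n - width + 1L)]
  (if (maximize) max(sums) else min(sums)) / width
}

#' Circadian summaries of a minute-level day set
#'
#' Per day: M10 is the mean of `log(1 + value)` over the contiguous
#' 600-minute window maximizing that mean; L5 the mean over the
#' 300-minute window minimizing it (windows stay within the day).  The
#' relative amplitude is `RA = (M10 - L5) / (M10 + L5)` (0 when the
#' denominator vanishes), and DARE is the ratio of the log-acceleration
#' sum inside the daytime window to the day's total.  Day values are
#' averaged across days; RA and DARE are computed from the averaged
#' M10/L5/sums.
#'
#' @param values non-negative minute accelerations (milli-g), length a
#'   multiple of 1440.
#' @param daytime_window integer minutes-past-midnight `c(start, end)`
#'   half-open interval for DARE; default 08:00-20:00.
#' @return named numeric vector `c(M10 = , L5 = , RA = , DARE = )`.
#' @export
circadian_summaries <- function(values, daytime_window = c(480L, 1200L)) {
  days <- split_days(values)
  logv <- lapply(days, function(d) log1p(d))
  m10 <- mean(vapply(logv, best_window_mean, 0, width = 600L, maximize = TRUE))
  l5 <- mean(vapply(logv, best_window_mean, 0, width = 300L, maximize = FALSE))
  denom <- m10 + l5
  ra <- if (denom == 0) {
    warning("M10 + L5 is zero; RA reported as 0")
    0
  } else (m10 - l5) / denom
  day_idx <- seq.int(daytime_window[1L] + 1L, daytime_window[2L])
  tot <- vapply(logv, sum, 0)
  dayt <- vapply(logv, function(d) sum(d[day_idx]), 0)
  dare <- if (sum(tot) == 0) {
    (daytime_window[2L] - daytime_window[1L]) / 1440
  } else sum(dayt) / sum(tot)
  c(M10 = m10, L5 = l5, RA = ra, DARE = dare)
}

# split a minute trace into complete 1440-minute days, dropping (with a
# warning) a trailing partial day
split_days <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty acceleration series", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("acceleration values must be finite and non-negative", call. = FALSE)
  }
  n_days <- length(values) %/% 1440L
  if (n_days == 0L) stop("series shorter than one full day", call. = FALSE)
  if (length(values) %% 1440L != 0L) {
    warning(sprintf("dropping trailing partial day of %d minutes",
                    length(values) %% 1440L))
    values <- values[seq_len(n_days * 1440L)]
  }
  split(values, rep(seq_len(n_days), each = 1440L))
}

#' Derive the 11 physical-activity summaries from a minute-level trace
#'
#' Computes, from one participant's minute-level ENMO trace (milli-g), the
#' canonical 11-variable summary capturing volume (TLAC, LIPA, MVPA),
#' fragmentation (SBout, ABout, SATP, ASTP) and circadian rhythm (DARE,
#' M10, L5, RA) of physical activity.  Intensity classes: a minute with
#' value below `sedentary_cut` is sedentary, in `[sedentary_cut,
#' mvpa_cut)` light activity (LIPA), at or above `mvpa_cut` moderate-to-
#' vigorous (MVPA); the default MVPA cut is 193 milli-g.  "Active" means
#' at or above `sedentary_cut`.  TLAC is the per-day sum of `log(1 +
#' value)`; per-day quantities are averaged across days; transition and
#' bout statistics treat each day as a separate sequence (day totals are
#' pooled before forming the ratios/means).
#'
#' @param values numeric vector of minute accelerations in milli-g,
#'   non-negative, ordered in time, starting at midnight; length a
#'   multiple of 1440 (a trailing partial day is dropped with a warning).
#' @param sedentary_cut milli-g threshold separating sedentary from active
#'   minutes (default 30).
#' @param mvpa_cut milli-g threshold separating LIPA from MVPA (default
#'   193).
#' @param daytime_window minutes-past-midnight `c(start, end)` for DARE.
#' @return named numeric vector of the 11 summaries in canonical order
#'   TLAC, LIPA, MVPA, SBout, ABout, SATP, ASTP, DARE, M10, L5, RA.
#' @examples
#' day <- c(rep(500, 300), rep(100, 300), rep(5, 840))
#' compute_pa_summaries(day)[c("LIPA", "MVPA")]
#' @export
compute_pa_summaries <- function(values, sedentary_cut = 30,
                                 mvpa_cut = 193,
                                 daytime_window = c(480L, 1200L)) {
  if (!(sedentary_cut > 0 && sedentary_cut < mvpa_cut)) {
    stop("need 0 < sedentary_cut < mvpa_cut", call. = FALSE)
  }
  days <- split_days(values)
  n_days <- length(days)
  values <- unlist(days, use.names = FALSE)

  tlac <- mean(vapply(days, function(d) sum(log1p(d)), 0))
  lipa <- mean(vapply(days, function(d) sum(d >= sedentary_cut & d < mvpa_cut), 0))
  mvpa <- mean(vapply(days, function(d) sum(d >= mvpa_cut), 0))

  # fragmentation: per-day sequences, day counts pooled into one ratio/mean
  act_days <- lapply(days, function(d) d >= sedentary_cut)
  trans_counts <- vapply(act_days, function(a) {
    from <- a[-length(a)]; to <- a[-1L]
    c(sa = sum(!from & to), as = sum(from & !to),
      n_sed = sum(!from), n_act = sum(from))
  }, numeric(4L))
  tc <- rowSums(matrix(trans_counts, nrow = 4L,
                       dimnames = list(rownames(trans_counts), NULL)))
  satp <- if (tc[["n_sed"]] == 0) NA_real_ else tc[["sa"]] / tc[["n_sed"]]
  astp <- if (tc[["n_act"]] == 0) NA_real_ else tc[["as"]] / tc[["n_act"]]

  runs <- lapply(act_days, rle)
  sb <- unlist(lapply(runs, function(r) r$lengths[!r$values]), use.names = FALSE)
  ab <- unlist(lapply(runs, function(r) r$lengths[r$values]), use.names = FALSE)
  sbout <- if (length(sb)) mean(sb) else NA_real_
  about <- if (length(ab)) mean(ab) else NA_real_

  circ <- circadian_summaries(values, daytime_window)

  c(TLAC = tlac, LIPA = lipa, MVPA = mvpa,
    SBout = sbout, ABout = about, SATP = satp, ASTP = astp,
    DARE = circ[["DARE"]], M10 = circ[["M10"]], L5 = circ[["L5"]],
    RA = circ[["RA"]])
}

#' Build a PA feature table from long-format minute data
#'
#' @param minutes data.frame with columns `participant_id`,
#'   `minute_index` (0-based or 1-based, used only for ordering) and
#'   `enmo_mg`.
#' @param ... passed to [compute_pa_summaries()].
#' @return matrix (participants x 11) with participant ids as rownames and
#'   canonical column names.
#' @export
pa_feature_table <- function(minutes, ...) {
  need <- c("participant_id", "minute_index", "enmo_mg")
  if (!all(need %in% names(minutes))) {
    stop(sprintf("minute data must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  minutes <- minutes[order(minutes$participant_id, minutes$minute_index), ]
  by_id <- split(minutes$enmo_mg, minutes$participant_id)
  out <- t(vapply(by_id, compute_pa_summaries, numeric(11L), ...))
  colnames(out) <- pa_feature_names()
  out
}
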