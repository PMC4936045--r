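# Telemetry preparation: DOP filtering, fix-rate accounting, randomized end
# dates for successful mothers, truncation to the mating-season analysis
# window, and GPS cluster-site detection.

#' Filter relocations on dilution of precision
#'
#' Keeps exactly the relocations with `dop < threshold`; a fix with DOP equal
#' to the threshold is removed. Order is preserved and the filter is
#' idempotent.
#'
#' @param records Relocation tibble with a `dop` column.
#' @param threshold Positive DOP cutoff (default 5).
#' @return The retained rows.
#' @export
filter_dop <- function(records, threshold = 5) {
  stopifnot(is.numeric(threshold), threshold > 0)
  records[records$dop < threshold, , drop = FALSE]
}

#' Realized fix rate over a period
#'
#' Retained fixes divided by the number of scheduled fixes in the (closed)
#' date interval.
#'
#' @param records Relocation tibble.
#' @param period Length-2 Date vector, inclusive.
#' @param schedule_minutes Scheduled fix interval (default 30 min).
#' @return Fraction in \[0, 1\] (may exceed 1 if more fixes than scheduled).
#' @export
compute_fix_rate <- function(records, period, schedule_minutes = 30) {
  period <- as.Date(period)
  n_days <- as.numeric(period[2] - period[1]) + 1
  expected <- n_days * 24 * 60 / schedule_minutes
  if (!is.finite(expected) || expected <= 0)
    stop("period yields zero expected fixes")
  nrow(records) / expected
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite fractional degrees
#' of freedom and a two-sided p-value, as used to compare fix rates between
#' litter-fate groups.
#'
#' @param a,b Numeric samples, each with at least 2 values and positive
#'   combined variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("degenerate variance: both samples are constant")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Randomize monitoring end dates for successful mothers
#'
#' Each successful bear-year receives an end date sampled from a Gaussian
#' kernel-density estimate (Silverman bandwidth) over the observed litter-loss
#' dates, at day resolution, rejected and redrawn until it falls within
#' \[`season_start`, `truncation`\]. This balances the monitoring periods of
#' successful and unsuccessful mothers.
#'
#' @param bear_years List of [bear_year_record()]s (only those with fate
#'   `"survived"` are modified).
#' @param loss_events Non-empty Date vector of observed loss dates.
#' @param season_start Date (or "MM-DD" resolved per bear-year's year).
#' @param truncation Date cap: the last observed day of litter loss.
#' @param seed Integer seed.
#' @return The list with `end_date` filled in for survivors.
#' @export
assign_end_dates <- function(bear_years, loss_events, season_start,
                             truncation, seed = 1) {
  if (!length(loss_events)) stop("`loss_events` is empty")
  set.seed(seed)
  ev <- as.numeric(as.Date(loss_events))
  bw <- if (length(unique(ev)) < 2) 0 else stats::bw.nrd0(ev)
  for (i in seq_along(bear_years)) {
    b <- bear_years[[i]]
    if (is.na(b$fate) || b$fate != "survived") next
    lo <- as.numeric(resolve_season_date(season_start, b$year))
    hi <- as.numeric(resolve_season_date(truncation, b$year))
    repeat {
      d <- round(ev[sample.int(length(ev), 1)] +
                   if (bw > 0) stats::rnorm(1, 0, bw) else 0)
      if (d >= lo && d <= hi) break
    }
    bear_years[[i]]$end_date <- as.Date(d, origin = "1970-01-01")
  }
  bear_years
}

resolve_season_date <- function(x, year) {
  if (inherits(x, "Date")) return(x)
  if (is.character(x) && grepl("^\\d{2}-\\d{2}$", x))
    return(as.Date(paste0(year, "-", x)))
  as.Date(x)
}

#' Truncate a bear-year to its analysis period
#'
#' Keeps the relocations whose date lies in the closed interval from
#' `season_start` to the bear-year's end (loss date for lost litters,
#' randomized end date for survivors), never beyond the global `truncation`
#' date. Bear-years with partial litter loss are excluded outright, as their
#' exposure period is ill-defined.
#'
#' @param record A [bear_year_record()].
#' @param season_start Start of the analysis season (Date or "MM-DD").
#' @param truncation Last observed day of litter loss (Date or "MM-DD").
#' @return The record with relocations restricted (and `fix_rate` updated),
#'   or flagged `excluded` with a reason.
#' @export
truncate_period <- function(record, season_start = "05-01", truncation) {
  if (!is.na(record$fate) && record$fate == "partial_loss") {
    record$excluded <- TRUE
    record$exclusion_reason <- "partial litter loss"
    return(record)
  }
  lo <- resolve_season_date(season_start, record$year)
  cap <- resolve_season_date(truncation, record$year)
  end <- if (!is.na(record$fate) && record$fate == "lost") record$loss_date
         else record$end_date
  if (is.na(end))
    stop("bear-year ", record$bear_id, "/", record$year,
         " has no loss or end date")
  end <- min(end, cap)
  d <- as.Date(record$relocations$timestamp)
  record$relocations <- record$relocations[d >= lo & d <= end, , drop = FALSE]
  record$end_date <- end
  record$fix_rate <- compute_fix_rate(record$relocations, c(lo, end))
  record
}

#' Minimum-data exclusion rule
#'
#' Flags bear-years whose truncated telemetry spans fewer than `min_days`
#' distinct days or has fewer than `min_fixes` retained fixes.
#'
#' @param record A [bear_year_record()] (after truncation).
#' @param min_days,min_fixes Thresholds (defaults 2 days, 50 fixes).
#' @return The record, possibly flagged `excluded`.
#' @export
apply_min_data_rule <- function(record, min_days = 2, min_fixes = 50) {
  if (record$excluded) return(record)
  n <- nrow(record$relocations)
  n_days <- length(unique(as.Date(record$relocations$timestamp)))
  if (n < min_fixes || n_days < min_days) {
    record$excluded <- TRUE
    record$exclusion_reason <-
      sprintf("insufficient data (%d fixes over %d days)", n, n_days)
  }
  record
}

#' Detect GPS cluster sites
#'
#' A cluster site is a maximal run of >= `min_run` consecutive relocations
#' that all lie within `radius` of the run's centroid; the centroid is
#' recomputed greedily as the run extends, and runs never overlap. With
#' `rule = "first"` the radius is instead measured about the run's first fix.
#'
#' @param records Time-ordered relocation tibble with `x`, `y`.
#' @param min_run Minimum run length (default 3).
#' @param radius Radius in metres (default 15).
#' @param rule `"centroid"` (default) or `"first"`.
#' @return Tibble with one row per cluster: `start`, `end` (row indices),
#'   `n`, `centroid_x`, `centroid_y`.
#' @export
detect_clusters <- function(records, min_run = 3, radius = 15,
                            rule = c("centroid", "first")) {
  rule <- match.arg(rule)
  x <- records$x; y <- records$y
  n <- length(x)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n) {
      cand <- i:(j + 1L)
      if (rule == "centroid") {
        cx <- mean(x[cand]); cy <- mean(y[cand])
      } else {
        cx <- x[i]; cy <- y[i]
      }
      if (all(sqrt((x[cand] - cx)^2 + (y[cand] - cy)^2) <= radius)) j <- j + 1L
      else break
    }
    len <- j - i + 1L
    if (len >= min_run) {
      run <- i:j
      out[[length(out) + 1L]] <- tibble::tibble(
        start = i, end = j, n = len,
        centroid_x = mean(x[run]), centroid_y = mean(y[run]))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out))
    return(tibble::tibble(start = integer(), end = integer(), n = integer(),
                          centroid_x = numeric(), centroid_y = numeric()))
  do.call(rbind, out)
}

#' Prepare a simulated or observed study for analysis
#'
#' Applies the full preparation chain: DOP filter per bear-year, end-date
#' randomization for successful mothers (from the observed loss dates),
#' global truncation at the last observed loss date, and the minimum-data
#' rule. Returns retained and excluded bear-years plus an exclusion log.
#'
#' @param bear_years List of [bear_year_record()]s with fates assigned.
#' @param season_start Season start ("MM-DD" or Date).
#' @param dop_threshold DOP cutoff (default 5).
#' @param min_days,min_fixes Minimum-data thresholds.
#' @param seed Seed for the end-date randomization.
#' @return List with `bear_years` (retained, truncated), `excluded` (records),
#'   `exclusions` (tibble log), `truncation` (Date used).
#' @export
prepare_study <- function(bear_years, season_start = "05-01",
                          dop_threshold = 5, min_days = 2, min_fixes = 50,
                          seed = 1) {
  for (i in seq_along(bear_years))
    bear_years[[i]]$relocations <-
      filter_dop(bear_years[[i]]$relocations, dop_threshold)

  loss_events <- as.Date(unlist(lapply(bear_years, function(b)
    if (!is.na(b$fate) && b$fate == "lost") as.character(b$loss_date))))
  if (!length(loss_events))
    stop("no litter-loss events: cannot randomize end dates")
  truncation <- max(loss_events)
  # express the cap as month-day so multi-year studies truncate per season
  trunc_mmdd <- format(truncation, "%m-%d")

  bear_years <- assign_end_dates(bear_years, loss_events, season_start,
                                 trunc_mmdd, seed = seed)
  bear_years <- lapply(bear_years, truncate_period,
                       season_start = season_start, truncation = trunc_mmdd)
  bear_years <- lapply(bear_years, apply_min_data_rule,
                       min_days = min_days, min_fixes = min_fixes)

  excluded <- Filter(function(b) b$excluded, bear_years)
  kept <- Filter(function(b) !b$excluded, bear_years)
  log <- tibble::tibble(
    bear_id = vapply(excluded, function(b) b$bear_id, ""),
    year = vapply(excluded, function(b) b$year, 1L),
    reason = vapply(excluded, function(b) b$exclusion_reason, ""))
  list(bear_years = kept, excluded = excluded, exclusions = log,
       truncation = truncation)
}
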