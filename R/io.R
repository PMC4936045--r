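# Plain-text interchange for telemetry and fate tables (real-data mode).

#' Write / read telemetry and fate CSVs
#'
#' Telemetry columns: `bear_id`, `year`, `timestamp` (ISO-8601, UTC), `x`,
#' `y`, `dop`. Fate columns: `bear_id`, `year`, `fate`, `loss_date`,
#' `end_date`.
#'
#' @param bear_years List of [bear_year_record()]s.
#' @param path Output file.
#' @export
write_telemetry_csv <- function(bear_years, path) {
  tab <- telemetry_table(bear_years)
  tab$timestamp <- format(tab$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @export
write_fates_csv <- function(bear_years, path) {
  utils::write.csv(as.data.frame(fate_table(bear_years)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_telemetry_csv
#' @param telemetry_path,fates_path Input files as written by the writers (or
#'   equivalent exports from a telemetry database).
#' @return `read_bear_years()`: list of [bear_year_record()]s, one per
#'   bear-year present in the telemetry, with fates attached where available.
#' @export
read_bear_years <- function(telemetry_path, fates_path = NULL) {
  tel <- utils::read.csv(telemetry_path, stringsAsFactors = FALSE)
  need <- c("bear_id", "year", "timestamp", "x", "y", "dop")
  if (!all(need %in% colnames(tel)))
    stop("telemetry CSV must have columns: ", paste(need, collapse = ", "))
  tel$timestamp <- as.POSIXct(tel$timestamp, tz = "UTC",
                              tryFormats = c("%Y-%m-%dT%H:%M:%SZ",
                                             "%Y-%m-%d %H:%M:%S"))
  fates <- if (!is.null(fates_path))
    utils::read.csv(fates_path, stringsAsFactors = FALSE) else NULL
  keys <- unique(tel[, c("bear_id", "year")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- tel[tel$bear_id == keys$bear_id[i] & tel$year == keys$year[i], ]
    sub <- sub[order(sub$timestamp), ]
    rec <- bear_year_record(keys$bear_id[i], keys$year[i],
                            tibble::as_tibble(sub))
    if (!is.null(fates)) {
      fr <- fates[fates$bear_id == keys$bear_id[i] &
                    fates$year == keys$year[i], ]
      if (nrow(fr) == 1) {
        rec$fate <- fr$fate
        if (!is.na(fr$loss_date) && nzchar(fr$loss_date))
          rec$loss_date <- as.Date(fr$loss_date)
        if ("end_date" %in% colnames(fr) && !is.na(fr$end_date) &&
            nzchar(fr$end_date))
          rec$end_date <- as.Date(fr$end_date)
      }
    }
    out[[i]] <- rec
  }
  out
}
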