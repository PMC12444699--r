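#' Daily admission-count series
#'
#' The basic data container of the package: a gap-free sequence of calendar
#' dates with one non-negative integer admission count per date. All models
#' consume this type; the synthetic generator and the CSV reader produce it.
#'
#' @param dates a `Date` vector, strictly increasing and gap-free.
#' @param counts non-negative integers, one per date.
#' @return an object of class `adm_series`: a data frame with columns
#'   `date` and `count`.
#' @examples
#' s <- daily_series(as.Date("2020-01-01") + 0:9, c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9))
#' summary(s)
#' @export
daily_series <- function(dates, counts) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("empty series: at least one date is required")
  if (length(dates) != length(counts))
    stop("`dates` and `counts` must have the same length")
  if (anyNA(dates) || anyNA(counts)) stop("missing values are not allowed")
  d <- as.integer(diff(dates))
  if (length(d) && any(d != 1L))
    stop("dates must be strictly increasing and gap-free (first problem near ",
         dates[which(d != 1L)[1L]], ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  structure(data.frame(date = dates, count = as.integer(counts)),
            class = c("adm_series", "data.frame"))
}

#' @export
print.adm_series <- function(x, ...) {
  cat(sprintf("<adm_series> %d days: %s .. %s  (mean %.2f/day, %d zero days)\n",
              nrow(x), format(x$date[1L]), format(x$date[nrow(x)]),
              mean(x$count), sum(x$count == 0L)))
  invisible(x)
}

#' @export
summary.adm_series <- function(object, ...) summarize_structure(object)

#' @export
plot.adm_series <- function(x, ..., log1p_scale = TRUE) {
  y <- if (log1p_scale) log1p(x$count) else x$count
  plot(x$date, y, type = "h", xlab = "date",
       ylab = if (log1p_scale) "log(1 + admissions)" else "admissions", ...)
  invisible(x)
}

#' Windowing helper: subset a series to a date interval
#'
#' @param series an `adm_series`.
#' @param start,end inclusive date bounds (`NULL` = unbounded).
#' @return an `adm_series` restricted to `[start, end]`.
#' @export
series_window <- function(series, start = NULL, end = NULL) {
  stopifnot(inherits(series, "adm_series"))
  keep <- rep(TRUE, nrow(series))
  if (!is.null(start)) keep <- keep & series$date >= as.Date(start)
  if (!is.null(end)) keep <- keep & series$date <= as.Date(end)
  if (!any(keep)) stop("window [", start, ", ", end, "] contains no observations")
  daily_series(series$date[keep], series$count[keep])
}

#' Read a daily admission series from CSV
#'
#' Expects a two-column file with header `date,count` and ISO-8601 dates.
#' Duplicate dates are an error; calendar gaps are an error unless
#' `fill_zeros = TRUE`, in which case missing days are filled with zero
#' counts (a message reports how many).
#'
#' @param path file path.
#' @param fill_zeros fill calendar gaps with zero-count days instead of
#'   failing.
#' @return an `adm_series`.
#' @export
read_admissions_csv <- function(path, fill_zeros = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "count") %in% names(raw)))
    stop("expected CSV header `date,count`, got: ", paste(names(raw), collapse = ","))
  dates <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    bad <- which(is.na(dates))[1L]
    stop("unparseable date on data row ", bad, ": ", raw$date[bad])
  }
  counts <- suppressWarnings(as.numeric(raw$count))
  if (anyNA(counts)) {
    bad <- which(is.na(counts))[1L]
    stop("unparseable count on data row ", bad, ": ", raw$count[bad])
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0)[1L]
    stop("negative count on ", format(dates[bad]))
  }
  if (anyDuplicated(dates)) {
    dup <- dates[duplicated(dates)][1L]
    stop("duplicate date: ", format(dup))
  }
  o <- order(dates)
  dates <- dates[o]; counts <- counts[o]
  gaps <- as.integer(diff(dates)) != 1L
  if (any(gaps)) {
    if (!fill_zeros)
      stop("calendar gap after ", format(dates[which(gaps)[1L]]),
           " (use fill_zeros = TRUE to fill with zero counts)")
    full <- seq(dates[1L], dates[length(dates)], by = "day")
    filled <- setNames(rep(0L, length(full)), format(full))
    filled[format(dates)] <- as.integer(counts)
    message(length(full) - length(dates), " gap day(s) filled with zero counts")
    return(daily_series(full, unname(filled)))
  }
  daily_series(dates, counts)
}

#' Write a daily admission series to CSV (header `date,count`)
#'
#' @param series an `adm_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "adm_series"))
  write.csv(data.frame(date = format(series$date), count = series$count),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write forecasts to CSV (`date,model,point,lo95,hi95`)
#'
#' @param forecasts an `adm_forecast` or backtest forecast data frame with at
#'   least columns `date`, `model`, `point`, `lo95`, `hi95`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forecasts_csv <- function(forecasts, path) {
  need <- c("date", "model", "point", "lo95", "hi95")
  if (!all(need %in% names(forecasts)))
    stop("forecast table must have columns ", paste(need, collapse = ", "))
  out <- data.frame(date = format(as.Date(forecasts$date)),
                    model = forecasts$model,
                    point = forecasts$point,
                    lo95 = forecasts$lo95, hi95 = forecasts$hi95)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
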