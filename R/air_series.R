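#' Instantaneous air-concentration time series
#'
#' Timestamped instantaneous gas concentration, the reference record of what
#' the sampler was exposed to. Timestamps are minutes since sampler
#' deployment and must be strictly increasing; concentrations are ppbv and
#' non-negative.
#'
#' @param time_min Numeric vector of timestamps, minutes, strictly increasing.
#' @param ppbv Numeric vector of concentrations, ppbv, >= 0.
#' @return A data.frame of class `ppas_air_series` with columns `time_min`,
#'   `ppbv`.
#' @export
air_series <- function(time_min, ppbv) {
  chk_num(time_min, "time_min")
  chk_num(ppbv, "ppbv", lower = 0)
  if (length(time_min) != length(ppbv))
    stop_input("time_min and ppbv must have equal length")
  chk_increasing(time_min, "time_min")
  structure(data.frame(time_min = time_min, ppbv = ppbv),
            class = c("ppas_air_series", "data.frame"))
}

as_air_series <- function(x) {
  if (inherits(x, "ppas_air_series")) return(x)
  if (is.data.frame(x) && all(c("time_min", "ppbv") %in% names(x)))
    return(air_series(x$time_min, x$ppbv))
  stop_input("expected an air_series (columns time_min, ppbv)")
}

# interpolator on the hour scale used by the kinetics: linear inside the
# series, constant (zero-order hold) beyond either end; molar output if cond
# is supplied
air_series_fun <- function(series, cond = NULL) {
  series <- as_air_series(series)
  y <- if (is.null(cond)) series$ppbv else ppbv_to_molar(series$ppbv, cond)
  if (nrow(series) == 1L) {
    y1 <- y[1]
    return(function(t) rep(y1, length(t)))
  }
  approxfun(series$time_min / 60, y, rule = 2)
}

#' Time-weighted average concentration over a window
#'
#' Trapezoidal discretisation of the mean of the concentration over
#' `[start, end]`: `TWA = integral(C dt) / (end - start)`, with linear
#' interpolation at the window endpoints. Exact for constant and for
#' piecewise-linear series.
#'
#' @param series An [air_series()].
#' @param start,end Window bounds in minutes; default to the full series
#'   range. The window must lie inside the series range and satisfy
#'   `start < end`.
#' @return TWA concentration, ppbv.
#' @examples
#' s <- air_series(c(0, 60, 120), c(100, 300, 300))
#' twa(s)           # 250
#' twa(s, 60, 120)  # 300
#' @export
twa <- function(series, start = NULL, end = NULL) {
  series <- as_air_series(series)
  if (nrow(series) == 0L) stop_input("series is empty")
  rng <- range(series$time_min)
  if (is.null(start)) start <- rng[1]
  if (is.null(end)) end <- rng[2]
  chk_num(start, "start", len = 1L)
  chk_num(end, "end", len = 1L)
  if (start >= end) stop_input("start must be < end")
  if (start < rng[1] - 1e-9 || end > rng[2] + 1e-9)
    stop_input("window [", start, ", ", end, "] outside series range [",
               rng[1], ", ", rng[2], "]")
  if (nrow(series) == 1L) return(series$ppbv)
  inner <- series$time_min > start & series$time_min < end
  tt <- c(start, series$time_min[inner], end)
  yy <- approx(series$time_min, series$ppbv, xout = tt)$y
  trapz(tt, yy) / (end - start)
}

#' Read / write an air-concentration series CSV
#'
#' CSV dialect: mandatory header `time_min,ppbv`, UTF-8, `.` decimal
#' separator; lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @return [read_air_series()] returns a `ppas_air_series`.
#' @export
read_air_series <- function(path) {
  d <- read_ppas_csv(path, c("time_min", "ppbv"))
  air_series(d$time_min, d$ppbv)
}

#' @param x An [air_series()].
#' @param comments Optional character vector written as `#` comment lines
#'   before the header (provenance).
#' @rdname read_air_series
#' @export
write_air_series <- function(x, path, comments = NULL) {
  write_ppas_csv(as_air_series(x), path, comments)
}

# shared CSV helpers: header mandatory, '#' comments allowed
read_ppas_csv <- function(path, required_cols) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- tryCatch(
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop_input("cannot parse CSV ", path, ": ",
                                   conditionMessage(e))
  )
  missing <- setdiff(required_cols, names(d))
  if (length(missing))
    stop_input(path, " lacks required column(s): ",
               paste(missing, collapse = ", "))
  d
}

write_ppas_csv <- function(d, path, comments = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  write.csv(as.data.frame(d), con, row.names = FALSE)
  invisible(path)
}
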