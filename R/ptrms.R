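#' PTR/SRI-MS isotopologue channel series
#'
#' Raw instrument responses for the three Cl2 isotopologue channels at
#' m/z 70 (35Cl35Cl), 72 (35Cl37Cl + 37Cl35Cl) and 74 (37Cl37Cl), recorded
#' both inside and outside the exposure chamber. The net chamber signal is
#' the sum over channels of the inside-minus-outside differences.
#'
#' @param time_min Timestamps, minutes, strictly increasing.
#' @param in_70,in_72,in_74 Inside-chamber responses (counts), >= 0.
#' @param out_70,out_72,out_74 Outside-chamber responses (counts), >= 0.
#' @return A data.frame of class `ppas_channel_series`.
#' @export
channel_series <- function(time_min, in_70, in_72, in_74,
                           out_70, out_72, out_74) {
  cols <- list(time_min = time_min, in_70 = in_70, in_72 = in_72,
               in_74 = in_74, out_70 = out_70, out_72 = out_72,
               out_74 = out_74)
  n <- length(time_min)
  for (nm in names(cols)) {
    chk_num(cols[[nm]], nm)
    if (length(cols[[nm]]) == 1L && n > 1L)
      cols[[nm]] <- rep(cols[[nm]], n)
    if (length(cols[[nm]]) != n)
      stop_input("channel series columns must have equal length (", nm,
                 " has length ", length(cols[[nm]]), ", expected ", n, ")")
  }
  chk_increasing(time_min, "time_min")
  for (nm in setdiff(names(cols), "time_min"))
    chk_num(cols[[nm]], nm, lower = 0)
  structure(as.data.frame(cols),
            class = c("ppas_channel_series", "data.frame"))
}

#' PTR/SRI-MS calibration curve
#'
#' Linear calibration relating the summed net channel response to the Cl2
#' mixing ratio. The slope and intercept come from an instrument calibration
#' and are user inputs here.
#'
#' @param slope Counts per ppbv, > 0.
#' @param intercept Counts (default 0).
#' @return A `ptrms_calibration` object.
#' @export
ptrms_calibration <- function(slope, intercept = 0) {
  chk_num(slope, "slope", lower = 0, strict = TRUE, len = 1L)
  chk_num(intercept, "intercept", len = 1L)
  structure(list(slope = slope, intercept = intercept),
            class = "ptrms_calibration")
}

#' Cl2 isotopologue abundance fractions
#'
#' Binomial combination of the two chlorine isotopes in the diatomic
#' molecule: masses 70/72/74 occur with probabilities `p^2`, `2p(1-p)` and
#' `(1-p)^2` where `p` is the 35Cl atom fraction.
#'
#' @param cl35_abundance Atom fraction of 35Cl in `[0, 1]`; default is the
#'   natural abundance 0.7577.
#' @return Named numeric vector `c(m70, m72, m74)`, summing to 1.
#' @examples
#' isotopologue_fractions()      # 0.574 / 0.367 / 0.059
#' isotopologue_fractions(0.5)   # 0.25 / 0.50 / 0.25
#' @export
isotopologue_fractions <- function(cl35_abundance = 0.7577) {
  chk_num(cl35_abundance, "cl35_abundance", lower = 0, upper = 1, len = 1L)
  p <- cl35_abundance
  c(m70 = p^2, m72 = 2 * p * (1 - p), m74 = (1 - p)^2)
}

#' Instantaneous chlorine concentration from channel responses
#'
#' Per timestamp, the net response is the sum over the three isotopologue
#' channels of the inside-minus-outside difference; the concentration is the
#' calibration inversion `(net - intercept) / slope`, floored at zero.
#' If more than `floor_warn_frac` of the points are negative before
#' flooring, a warning about possible baseline drift is emitted.
#'
#' @param channels A [channel_series()].
#' @param cal A [ptrms_calibration()].
#' @param floor_warn_frac Warning threshold on the floored-point fraction
#'   (default 0.1).
#' @return An [air_series()].
#' @export
instantaneous_concentration <- function(channels, cal,
                                        floor_warn_frac = 0.1) {
  if (!inherits(channels, "ppas_channel_series"))
    channels <- do.call(channel_series, as.list(channels[c(
      "time_min", "in_70", "in_72", "in_74", "out_70", "out_72", "out_74")]))
  if (!inherits(cal, "ptrms_calibration"))
    stop_input("cal must be a ptrms_calibration")
  net <- (channels$in_70 - channels$out_70) +
    (channels$in_72 - channels$out_72) +
    (channels$in_74 - channels$out_74)
  conc <- (net - cal$intercept) / cal$slope
  n_neg <- sum(conc < 0)
  if (n_neg / length(conc) > floor_warn_frac)
    warning(sprintf(
      "%d of %d points (%.0f%%) negative after calibration; floored at 0",
      n_neg, length(conc), 100 * n_neg / length(conc)))
  air_series(channels$time_min, pmax(conc, 0))
}

#' Read / write a PTR-MS channel series CSV
#'
#' CSV dialect: mandatory header
#' `time_min,in_70,in_72,in_74,out_70,out_72,out_74`, UTF-8, `.` decimal
#' separator; `#` comment lines allowed.
#'
#' @param path File path.
#' @return [read_channel_series()] returns a `ppas_channel_series`.
#' @export
read_channel_series <- function(path) {
  cols <- c("time_min", "in_70", "in_72", "in_74",
            "out_70", "out_72", "out_74")
  d <- read_ppas_csv(path, cols)
  do.call(channel_series, as.list(d[cols]))
}

#' @param x A [channel_series()].
#' @param comments Optional `#` comment lines (provenance).
#' @rdname read_channel_series
#' @export
write_channel_series <- function(x, path, comments = NULL) {
  write_ppas_csv(x, path, comments)
}
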