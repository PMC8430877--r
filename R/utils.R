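# internal validation helpers; every user-facing error names the offending
# field so batch callers can diagnose bad rows quickly

stop_input <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("ppas_input_error", "error")))
}

stop_convergence <- function(...) {
  stop(errorCondition(paste0(...), class = c("ppas_convergence_error", "error")))
}

chk_num <- function(x, name, lower = NULL, upper = NULL, strict = FALSE,
                    len = NULL, allow_empty = FALSE) {
  if (!is.numeric(x)) stop_input(name, " must be numeric")
  if (!allow_empty && length(x) == 0L) stop_input(name, " must be non-empty")
  if (!is.null(len) && length(x) != len)
    stop_input(name, " must have length ", len)
  if (any(!is.finite(x)))
    stop_input(name, " contains non-finite values")
  if (!is.null(lower)) {
    bad <- if (strict) any(x <= lower) else any(x < lower)
    if (bad) stop_input(name, " must be ", if (strict) "> " else ">= ", lower)
  }
  if (!is.null(upper)) {
    if (any(x > upper)) stop_input(name, " must be <= ", upper)
  }
  invisible(x)
}

chk_increasing <- function(x, name) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stop_input(name, " must be strictly increasing")
  invisible(x)
}

# trapezoidal integral of y over x (irregular grid)
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# deterministic per-cell seed derivation: one base seed plus (i, j) counters,
# kept inside 32-bit integer range; adding cells never perturbs earlier ones
seed_stream <- function(seed, i, j = 0L) {
  s <- (as.double(seed) * 100003 + as.double(i) * 1009 + as.double(j)) %% 2147483629
  as.integer(s) + 1L
}

# tiny deterministic string hash (djb2) used only for provenance comments
djb2_hash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}
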