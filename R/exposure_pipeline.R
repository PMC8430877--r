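#' Molecular weight of o-dianisidine (g mol-1)
#'
#' @export
M_W_DIANISIDINE <- 244.30

#' Sampler extraction measurements
#'
#' One row per extracted sampler: the dye concentration an unexposed sampler
#' yields in the extraction solvent (`Ci_g_per_L`), the concentration after
#' exposure (`Cf_g_per_L`), the solvent volume and the deployment interval.
#' The dye consumed, `Ci - Cf`, carries the reacted-chlorine signal.
#'
#' @param replicate_id Character labels (recycled).
#' @param deployment_h Deployment time, hours, > 0.
#' @param Ci_g_per_L Initial (blank) dye concentration, g L-1, >= 0.
#' @param Cf_g_per_L Final dye concentration, g L-1, with
#'   `0 <= Cf <= Ci`.
#' @param VE_L Extraction solvent volume, litres, > 0 (default 0.01, i.e.
#'   10 mL isopropyl alcohol).
#' @return data.frame of class `ppas_extraction`.
#' @export
extraction_measurements <- function(replicate_id, deployment_h,
                                    Ci_g_per_L, Cf_g_per_L, VE_L = 0.01) {
  chk_num(deployment_h, "deployment_h", lower = 0, strict = TRUE)
  chk_num(Ci_g_per_L, "Ci_g_per_L", lower = 0)
  chk_num(Cf_g_per_L, "Cf_g_per_L", lower = 0)
  chk_num(VE_L, "VE_L", lower = 0, strict = TRUE)
  n <- max(length(replicate_id), length(deployment_h), length(Ci_g_per_L),
           length(Cf_g_per_L), length(VE_L))
  d <- data.frame(
    replicate_id = rep_len(as.character(replicate_id), n),
    deployment_h = rep_len(deployment_h, n),
    Ci_g_per_L = rep_len(Ci_g_per_L, n),
    Cf_g_per_L = rep_len(Cf_g_per_L, n),
    VE_L = rep_len(VE_L, n),
    stringsAsFactors = FALSE
  )
  if (any(d$Cf_g_per_L > d$Ci_g_per_L + 1e-12))
    stop_input("Cf_g_per_L exceeds Ci_g_per_L (would imply dye creation) ",
               "in row(s): ",
               paste(which(d$Cf_g_per_L > d$Ci_g_per_L + 1e-12),
                     collapse = ", "))
  structure(d, class = c("ppas_extraction", "data.frame"))
}

#' Reacted chlorine per sampler volume from an extraction measurement
#'
#' `C_s = (C_i - C_f) * V_E / M_w / V_sampler / stoich`: the dye consumed in
#' the extraction solvent, converted to moles and divided by the sampler
#' volume, with `stoich` moles of dye consumed per mole of Cl2 (default 2).
#'
#' @param m [extraction_measurements()] (or a data.frame with its columns).
#' @param params [sampler_params()] supplying `V_s` and `stoich`.
#' @return Numeric vector of C_s, mol m-3, one per row of `m`.
#' @examples
#' m <- extraction_measurements("a", 2, 0.100, 0.09395)
#' cs_from_extraction(m, sampler_params())  # ~1.0006 mol m-3
#' @export
cs_from_extraction <- function(m, params) {
  if (!inherits(m, "ppas_extraction"))
    m <- extraction_measurements(m$replicate_id, m$deployment_h,
                                 m$Ci_g_per_L, m$Cf_g_per_L,
                                 if (!is.null(m$VE_L)) m$VE_L else 0.01)
  stopifnot(inherits(params, "sampler_params"))
  (m$Ci_g_per_L - m$Cf_g_per_L) * m$VE_L / M_W_DIANISIDINE /
    params$V_s / params$stoich
}

#' Sampler-derived TWA exposure from reacted chlorine
#'
#' The estimation chain: `M_sampled = C_s * V_s` (moles of chlorine
#' captured), `C_v,TWA = M_sampled / (R_s * t)` (TWA air concentration over
#' the deployment), converted to ppbv, with the CT value, guideline flags
#' and a saturation warning. A sampler at or beyond
#' `saturation_warn * C_cap` no longer accumulates linearly, so its TWA is a
#' lower bound — flagged, never dropped.
#'
#' @param C_s Reacted chlorine per sampler volume, mol m-3, >= 0
#'   (vectorised).
#' @param params [sampler_params()].
#' @param deployment_time Deployment, hours, > 0 (recycled).
#' @param cond [gas_conditions()].
#' @param guidelines Guideline table for [guideline_flags()].
#' @param saturation_warn Saturation-warning threshold as a fraction of
#'   `C_cap` (default 0.9).
#' @return data.frame of class `ppas_exposure_summary` with columns
#'   `C_s_mol_m3`, `M_sampled_mol`, `C_v_TWA_molar`, `C_v_TWA_ppbv`,
#'   `duration_min`, `ct_ppbv_min`, `equiv_500ppbv_min`,
#'   `saturation_fraction`, `saturated`, `flags` (`;`-separated labels).
#' @examples
#' cv_twa_from_cs(1.0006, sampler_params(), 2)  # ~599 ppbv over 2 h
#' @export
cv_twa_from_cs <- function(C_s, params, deployment_time,
                           cond = gas_conditions(),
                           guidelines = chlorine_guidelines(),
                           saturation_warn = 0.9) {
  chk_num(C_s, "C_s", lower = 0)
  chk_num(deployment_time, "deployment_time", lower = 0, strict = TRUE)
  stopifnot(inherits(params, "sampler_params"))
  n <- max(length(C_s), length(deployment_time))
  C_s <- rep_len(C_s, n)
  t_h <- rep_len(deployment_time, n)
  M <- C_s * params$V_s
  cv_molar <- M / (params$R_s * t_h)
  cv_ppbv <- molar_to_ppbv(cv_molar, cond)
  dur_min <- t_h * 60
  ct <- cv_ppbv * dur_min
  sat_frac <- C_s / params$C_cap
  saturated <- sat_frac >= saturation_warn
  flags <- vapply(seq_len(n), function(i) {
    f <- guideline_flags(cv_ppbv[i], dur_min[i], guidelines)
    if (saturated[i]) f <- c(f, "SATURATED_LOWER_BOUND")
    paste(f, collapse = ";")
  }, character(1))
  structure(
    data.frame(C_s_mol_m3 = C_s, M_sampled_mol = M,
               C_v_TWA_molar = cv_molar, C_v_TWA_ppbv = cv_ppbv,
               duration_min = dur_min, ct_ppbv_min = ct,
               equiv_500ppbv_min = ct / 500,
               saturation_fraction = sat_frac, saturated = saturated,
               flags = flags, stringsAsFactors = FALSE),
    class = c("ppas_exposure_summary", "data.frame"))
}

#' Dye concentration from a UV/Vis absorbance reading
#'
#' Linear (Beer-Lambert) inversion `(absorbance - intercept) / slope`,
#' floored at zero. The calibration coefficients come from the user's
#' spectrophotometer standards.
#'
#' @param absorbance Absorbance units, >= 0 (vectorised).
#' @param slope AU per g L-1, > 0.
#' @param intercept AU (default 0).
#' @return Concentration, g L-1.
#' @export
absorbance_to_concentration <- function(absorbance, slope, intercept = 0) {
  chk_num(absorbance, "absorbance", lower = 0)
  chk_num(slope, "slope", lower = 0, strict = TRUE, len = 1L)
  chk_num(intercept, "intercept", len = 1L)
  pmax((absorbance - intercept) / slope, 0)
}

#' Batch exposure report with replicate aggregation
#'
#' Runs the full Eq-chain per replicate and aggregates by deployment time
#' with the sample (n-1) standard deviation, matching how triplicate chamber
#' deployments are reported. A single replicate yields `NA` SDs.
#'
#' @param measurements [extraction_measurements()].
#' @param params [sampler_params()].
#' @param cond [gas_conditions()].
#' @param ... Passed to [cv_twa_from_cs()].
#' @return List of class `ppas_exposure_report`: `replicates` (per-sampler
#'   summaries with ids) and `summary` (per-deployment-time n, mean and SD
#'   of `C_s` and of the TWA in ppbv).
#' @export
batch_report <- function(measurements, params, cond = gas_conditions(),
                         ...) {
  if (!inherits(measurements, "ppas_extraction"))
    measurements <- extraction_measurements(
      measurements$replicate_id, measurements$deployment_h,
      measurements$Ci_g_per_L, measurements$Cf_g_per_L,
      if (!is.null(measurements$VE_L)) measurements$VE_L else 0.01)
  if (nrow(measurements) == 0L) stop_input("no measurements supplied")
  C_s <- cs_from_extraction(measurements, params)
  summ <- cv_twa_from_cs(C_s, params, measurements$deployment_h,
                         cond = cond, ...)
  reps <- cbind(measurements[c("replicate_id", "deployment_h")], summ)
  groups <- split(seq_len(nrow(reps)), reps$deployment_h)
  summary <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(
      deployment_h = reps$deployment_h[idx[1]],
      n = length(idx),
      C_s_mean = mean(reps$C_s_mol_m3[idx]),
      C_s_sd = if (length(idx) > 1L) sd(reps$C_s_mol_m3[idx]) else NA_real_,
      C_v_TWA_ppbv_mean = mean(reps$C_v_TWA_ppbv[idx]),
      C_v_TWA_ppbv_sd = if (length(idx) > 1L) sd(reps$C_v_TWA_ppbv[idx])
                        else NA_real_
    )
  }))
  rownames(summary) <- NULL
  structure(list(replicates = reps, summary = summary),
            class = "ppas_exposure_report")
}

#' @export
print.ppas_exposure_report <- function(x, ...) {
  cat("exposure report:", nrow(x$replicates), "replicate(s),",
      nrow(x$summary), "deployment time(s)\n")
  print(x$summary)
  invisible(x)
}

#' Read extraction measurements from CSV
#'
#' CSV dialect: mandatory header
#' `replicate_id,deployment_h,Ci_g_per_L,Cf_g_per_L,VE_L` (missing `VE_L`
#' defaults to 0.01 L); `#` comment lines allowed.
#'
#' @param path File path.
#' @return A `ppas_extraction` data.frame.
#' @export
read_extraction_measurements <- function(path) {
  d <- read_ppas_csv(path, c("replicate_id", "deployment_h",
                             "Ci_g_per_L", "Cf_g_per_L"))
  if (nrow(d) == 0L) stop_input(path, " contains no measurement rows")
  extraction_measurements(d$replicate_id, d$deployment_h, d$Ci_g_per_L,
                          d$Cf_g_per_L,
                          if (!is.null(d$VE_L)) d$VE_L else 0.01)
}

#' Write an exposure report to CSV
#'
#' One row per replicate plus per-deployment-time summary rows,
#' distinguished by a `row_type` column.
#'
#' @param report A [batch_report()] result.
#' @param path File path.
#' @param comments Optional `#` comment lines (provenance).
#' @export
write_exposure_report <- function(report, path, comments = NULL) {
  stopifnot(inherits(report, "ppas_exposure_report"))
  reps <- cbind(row_type = "replicate", report$replicates)
  summ <- report$summary
  summ_full <- data.frame(
    row_type = "summary", replicate_id = NA_character_,
    deployment_h = summ$deployment_h, C_s_mol_m3 = summ$C_s_mean,
    M_sampled_mol = NA_real_, C_v_TWA_molar = NA_real_,
    C_v_TWA_ppbv = summ$C_v_TWA_ppbv_mean, duration_min = NA_real_,
    ct_ppbv_min = NA_real_, equiv_500ppbv_min = NA_real_,
    saturation_fraction = NA_real_, saturated = NA,
    flags = sprintf("n=%d;C_s_sd=%s;ppbv_sd=%s", summ$n,
                    formatC(summ$C_s_sd, digits = 6, format = "g"),
                    formatC(summ$C_v_TWA_ppbv_sd, digits = 6, format = "g")),
    stringsAsFactors = FALSE
  )
  write_ppas_csv(rbind(reps, summ_full), path, comments)
}
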