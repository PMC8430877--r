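#' Package defaults as a single configuration list
#'
#' Every constant the analysis uses, grouped by module, in one place:
#' gas conditions, sampler geometry and kinetics, extraction defaults,
#' PTR-MS settings and guideline thresholds. A configuration file (YAML)
#' with any subset of these keys can be merged over the defaults with
#' [read_ppas_config()].
#'
#' @return Nested named list.
#' @export
ppas_defaults <- function() {
  list(
    gas = list(temperature = 298.15, pressure = 101325),
    sampler = list(A_s = 2.25e-4, delta = 5.5e-4, V_s = NULL, K_SA = 10,
                   k_O = NULL, k_reac = 100, C_cap = 1.8, R_s = 2.53e-3,
                   stoich = 2, capacity_model = "smooth"),
    extraction = list(V_E = 0.01, C_i = 0.1, M_w = M_W_DIANISIDINE),
    ptrms = list(cl35_abundance = 0.7577, slope = 10, intercept = 0),
    reporting = list(saturation_warn = 0.9, reference_ppbv = 500)
  )
}

# recursive list merge: values in `over` win
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Read / write a configuration file
#'
#' YAML key-value files; [read_ppas_config()] merges the file over
#' [ppas_defaults()] so partial configs are valid.
#'
#' @param path File path.
#' @return [read_ppas_config()] returns the merged configuration list.
#' @export
read_ppas_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  over <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop_input("cannot parse config ", path, ": ", conditionMessage(e)))
  merge_config(ppas_defaults(), over)
}

#' @param cfg Configuration list.
#' @rdname read_ppas_config
#' @export
write_ppas_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build typed objects from a configuration list
#'
#' @param cfg Configuration list as returned by [ppas_defaults()] or
#'   [read_ppas_config()].
#' @return [params_from_config()] a [sampler_params()];
#'   [conditions_from_config()] a [gas_conditions()].
#' @export
params_from_config <- function(cfg = ppas_defaults()) {
  s <- cfg$sampler
  sampler_params(A_s = s$A_s, delta = s$delta, V_s = s$V_s, K_SA = s$K_SA,
                 k_O = s$k_O, k_reac = s$k_reac, C_cap = s$C_cap,
                 R_s = s$R_s, stoich = s$stoich,
                 capacity_model = s$capacity_model)
}

#' @rdname params_from_config
#' @export
conditions_from_config <- function(cfg = ppas_defaults()) {
  gas_conditions(cfg$gas$temperature, cfg$gas$pressure)
}

scenario_from_config <- function(sc) {
  if (inherits(sc, "ppas_scenario")) return(sc)
  known <- names(formals(scenario_config))
  do.call(scenario_config, sc[intersect(names(sc), known)])
}
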