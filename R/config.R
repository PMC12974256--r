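#' Parse a physical quantity with a unit suffix
#'
#' Configuration files may give values either as plain numbers (SI units)
#' or as strings with an explicit unit, e.g. `"30 us"`, `"500 nA"`,
#' `"320 MHz"`, `"3 pF"`, `"25 mV"`, `"75 fC"`. Supported base units are
#' s, A, Hz, F, V and C with SI prefixes f, p, n, u, m, k, M, G.
#'
#' @param x Number or string.
#' @return Numeric value in SI units.
#' @examples
#' parse_quantity("320 MHz")
#' parse_quantity("500 nA")
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (length(x) != 1 || !is.character(x))
    stop("quantity must be a number or a single string", call. = FALSE)
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([fpnumkMG]?)(s|A|Hz|F|V|C)?\\s*$", x))[[1]]
  if (length(m) == 0)
    stop(sprintf("cannot parse quantity '%s'", x), call. = FALSE)
  val <- as.numeric(m[2])
  if (is.na(val)) stop(sprintf("cannot parse quantity '%s'", x), call. = FALSE)
  scale <- c(f = 1e-15, p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3,
             k = 1e3, M = 1e6, G = 1e9)
  if (nzchar(m[3])) val <- val * scale[[m[3]]]
  val
}

pick <- function(lst, name, default) {
  if (!is.null(lst[[name]])) parse_quantity(lst[[name]]) else default
}

#' Read a full simulator configuration from YAML or JSON
#'
#' Recognized sections (all optional, each falling back to the documented
#' defaults): `film:` (k_sv, tau_sen, tau_ref, s_sen, s_ref),
#' `excitation:` (i_ext, t_stabilize, t1, t_d_sen, t_d_ref), `cdc:`
#' (f_clk, c_pd, c_parasitic, v_ref, i_dac_lsb, n_dac_bits, counter_bits,
#' dem_enabled, cell_mismatch, switch_injection_charge), `comparator:`
#' (offset, noise_rms, kickback_charge_rms) and `scaling:`
#' (n_average_cycles, headroom, lut_mode, duty_cycle, quantization_target).
#' Scalar values may carry unit suffixes, see [parse_quantity()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return List with `film`, `excitation`, `config` (the [cdc_config()])
#'   and `scaling` components.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  fl <- raw$film
  film <- film_params(
    k_sv = pick(fl, "k_sv", 0.05),
    tau_sen = pick(fl, "tau_sen", 100e-9),
    tau_ref = pick(fl, "tau_ref", 1e-6),
    s_sen = pick(fl, "s_sen", 500e-9),
    s_ref = pick(fl, "s_ref", 500e-9))

  ex <- raw$excitation
  excitation <- excitation_profile(
    i_ext = pick(ex, "i_ext", 1),
    t_stabilize = pick(ex, "t_stabilize", 10e-6),
    t1 = pick(ex, "t1", 30e-6),
    t_d_sen = pick(ex, "t_d_sen", 50e-9),
    t_d_ref = pick(ex, "t_d_ref", 6e-6))

  cp <- raw$comparator
  comparator <- comparator_params(
    offset = pick(cp, "offset", 25e-3),
    noise_rms = pick(cp, "noise_rms", 0.28e-3),
    kickback_charge_rms = pick(cp, "kickback_charge_rms", 0))

  cd <- raw$cdc
  mism <- if (!is.null(cd$cell_mismatch))
    vapply(cd$cell_mismatch, parse_quantity, numeric(1)) else NULL
  config <- cdc_config(
    f_clk = pick(cd, "f_clk", 320e6),
    c_pd = pick(cd, "c_pd", 3e-12),
    c_parasitic = pick(cd, "c_parasitic", 0.2e-12),
    v_ref = pick(cd, "v_ref", 0.8),
    i_dac_lsb = pick(cd, "i_dac_lsb", 500e-9),
    n_dac_bits = pick(cd, "n_dac_bits", 4),
    counter_bits = pick(cd, "counter_bits", 16),
    comparator = comparator,
    dem_enabled = if (!is.null(cd$dem_enabled)) isTRUE(cd$dem_enabled) else TRUE,
    cell_mismatch = mism,
    switch_injection_charge = pick(cd, "switch_injection_charge", 0))

  sc <- raw$scaling
  scaling <- scaling_config(
    n_average_cycles = pick(sc, "n_average_cycles", 100),
    headroom = pick(sc, "headroom", 1.25),
    lut_mode = if (!is.null(sc$lut_mode)) sc$lut_mode else "per_window",
    duty_cycle = pick(sc, "duty_cycle", 0.01),
    quantization_target = pick(sc, "quantization_target", 0.005))

  list(film = film, excitation = excitation, config = config,
       scaling = scaling)
}

#' Write an LR-vs-CO2 calibration table
#'
#' @param film A [film_params()].
#' @param excitation An [excitation_profile()].
#' @param pco2_grid CO2 grid, mmHg.
#' @param path Output CSV path (header `pco2_mmHg,lr`).
#' @param mode Area model, see [luminescence_ratio()].
#' @return The calibration `data.frame`, invisibly.
#' @export
write_calibration_csv <- function(film = film_params(),
                                  excitation = excitation_profile(),
                                  pco2_grid = seq(0, 76, by = 3.8),
                                  path, mode = "approximate") {
  tab <- data.frame(pco2_mmHg = pco2_grid,
                    lr = luminescence_ratio(pco2_grid, film, excitation,
                                            mode = mode))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
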