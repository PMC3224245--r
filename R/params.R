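# Model parameters, unit conversions and config I/O.

# molecules per (uM * fl): 6.02214076e23 * 1e-6 mol/L * 1e-15 L
.MOLEC_PER_uM_FL <- 602.214076
# molecules per um^3 at 1 mM
.MOLEC_PER_mM_um3 <- 6.02214076e5

#' Convert a concentration to a molecule copy number
#'
#' @param conc concentration in micromolar (uM).
#' @param volume compartment volume in femtolitres (fl).
#' @param round if `TRUE` (default) round to the nearest integer molecule.
#' @return number of molecules.
#' @examples
#' concentration_to_copy_number(5, 1.4)    # CheA: 4215
#' concentration_to_copy_number(0.16, 1.4) # CheR: 135
#' @export
concentration_to_copy_number <- function(conc, volume, round = TRUE) {
  if (any(conc < 0)) stop("conc must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  n <- conc * volume * .MOLEC_PER_uM_FL
  if (round) round(n) else n
}

#' Convert a molecule copy number to a concentration
#'
#' Inverse of [concentration_to_copy_number()].
#' @param count number of molecules.
#' @param volume volume in fl.
#' @return concentration in uM.
#' @export
copy_number_to_concentration <- function(count, volume) {
  if (any(count < 0)) stop("count must be >= 0")
  if (any(volume <= 0)) stop("volume must be > 0")
  count / (volume * .MOLEC_PER_uM_FL)
}

#' MWC receptor-complex parameters
#'
#' Two receptor types contribute to a mixed signalling complex: Tar
#' (aspartate/MeAsp, fraction `nu_a`) and Tsr (serine, fraction `nu_s`),
#' each with dissociation constants for the active (`on`) and inactive
#' (`off`) conformation. `N` receptor dimers form one complex; its activity
#' is set by a free-energy difference (see [free_energy()]).
#'
#' @param N receptors per signalling complex.
#' @param nu_a,nu_s Tar and Tsr fractions; must sum to 1.
#' @param K_a_off,K_a_on Tar dissociation constants, mM (off < on for an
#'   attractant).
#' @param K_s_off,K_s_on Tsr dissociation constants, mM.
#' @param eps0 methylation-independent free-energy offset per receptor,
#'   kBT units.
#' @return an object of class `mwc_params`.
#' @export
mwc_params <- function(N = 18, nu_a = 1 / 3, nu_s = 2 / 3,
                       K_a_off = 0.02, K_a_on = 0.5,
                       K_s_off = 100, K_s_on = 1e6, eps0 = 1) {
  p <- list(N = N, nu_a = nu_a, nu_s = nu_s, K_a_off = K_a_off,
            K_a_on = K_a_on, K_s_off = K_s_off, K_s_on = K_s_on,
            eps0 = eps0)
  class(p) <- "mwc_params"
  validate_mwc_params(p)
  p
}

validate_mwc_params <- function(p) {
  if (p$N < 1) stop("invalid mwc parameter 'N': must be >= 1")
  if (abs(p$nu_a + p$nu_s - 1) > 1e-9)
    stop("invalid mwc parameters 'nu_a', 'nu_s': must sum to 1")
  if (!(p$K_a_off > 0 && p$K_a_on > p$K_a_off))
    stop("invalid mwc parameters: need 0 < K_a_off < K_a_on")
  if (!(p$K_s_off > 0 && p$K_s_on > p$K_s_off))
    stop("invalid mwc parameters: need 0 < K_s_off < K_s_on")
  invisible(p)
}

#' Flagellar motor switching parameters
#'
#' In `"mwc"` mode the motor is a cooperative ring of `m_coop` subunits
#' binding CheY-P, with switching rates given by occupancy-averaged rate
#' expressions (see [switching_rates()]). In `"linearized"` mode the rates
#' are a first-order expansion around the adapted CheY-P concentration,
#' parameterised directly by the steady-state rates and their slopes.
#'
#' The `mwc` constants are not published for the wild-type operating point
#' and are reconstructed here so that (i) the rates are equal (CW bias 1/2)
#' at CheY-P = 3.2 uM and (ii) they take the wild-type steady-state values
#' 1.05 and 1.06 1/s there. Linearized mode is therefore the default for
#' all spectrum and SNR computations; its slope defaults are the analytic
#' derivatives of the reconstructed mwc model at 3.2 uM.
#'
#' @param mode `"linearized"` or `"mwc"`.
#' @param k_plus_star,k_minus_star steady-state CCW->CW and CW->CCW rates,
#'   1/s (linearized mode).
#' @param dkplus_dYp,dkminus_dYp rate slopes with respect to CheY-P,
#'   1/s/uM (linearized mode); `NULL` = derive from the mwc defaults.
#' @param Yp_anchor CheY-P concentration (uM) at which the starred rates
#'   apply; `NA` means "anchor at the adapted state" and is filled in by
#'   [solve_steady_state()].
#' @param m_coop number of motor subunits.
#' @param mu CheY-P binding free-energy factor (> 1 favours CW switching).
#' @param K_CCW,K_CW CheY-P dissociation constants in the CCW and CW state,
#'   uM; K_CW < K_CCW makes the CW state bind CheY-P more tightly so that
#'   k- falls with CheY-P.
#' @param k_plus_0,k_minus_0 zero-occupancy switching rates, 1/s; `NULL` =
#'   scale so the rates at 3.2 uM are 1.05 and 1.06 1/s.
#' @return an object of class `motor_params`.
#' @export
motor_params <- function(mode = c("linearized", "mwc"),
                         k_plus_star = 1.05, k_minus_star = 1.06,
                         dkplus_dYp = NULL, dkminus_dYp = NULL,
                         Yp_anchor = NA_real_,
                         m_coop = 26, mu = 1.2, K_CCW = 12, K_CW = 6,
                         k_plus_0 = NULL, k_minus_0 = NULL) {
  mode <- match.arg(mode)
  if (K_CW > K_CCW)
    stop("invalid motor parameters: K_CW must be <= K_CCW")
  ratio <- function(K) ((1 + mu * 3.2 / K_CCW) / (1 + 3.2 / K))^m_coop
  if (is.null(k_plus_0)) k_plus_0 <- 1.05 / ratio(K_CCW)
  if (is.null(k_minus_0)) k_minus_0 <- 1.06 / ratio(K_CW)
  if (any(c(k_plus_star, k_minus_star, m_coop, mu, K_CCW, K_CW,
            k_plus_0, k_minus_0) < 0))
    stop("invalid motor parameters: rates and constants must be >= 0")
  p <- list(mode = mode, k_plus_star = k_plus_star,
            k_minus_star = k_minus_star, Yp_anchor = Yp_anchor,
            m_coop = m_coop, mu = mu, K_CCW = K_CCW, K_CW = K_CW,
            k_plus_0 = k_plus_0, k_minus_0 = k_minus_0)
  class(p) <- "motor_params"
  if (is.null(dkplus_dYp) || is.null(dkminus_dYp)) {
    d <- mwc_motor_derivatives(p, 3.2)
    if (is.null(dkplus_dYp)) dkplus_dYp <- d[["dkplus_dYp"]]
    if (is.null(dkminus_dYp)) dkminus_dYp <- d[["dkminus_dYp"]]
  }
  p$dkplus_dYp <- dkplus_dYp
  p$dkminus_dYp <- dkminus_dYp
  p
}

#' Full-pathway parameters
#'
#' Collects the rate constants, total concentrations, copy numbers and
#' geometry of the pathway model. Defaults are the wild-type set; derived
#' copy numbers are computed from the concentrations and the cell volume.
#'
#' @param A_tot,B_tot,R_tot,Y_tot total CheA/CheB/CheR/CheY concentrations,
#'   uM.
#' @param V_cell cell volume, fl.
#' @param N_tot total receptor dimers per cell.
#' @param k_2 receptor-complex off-switching rate, 1/s.
#' @param k_A CheA autophosphorylation rate at full receptor activity, 1/s.
#'   The default (10 1/s) is the value consistent with the adapted
#'   operating point of the model (per-receptor activity 1/3, CheY-P
#'   about 3.2 uM); see the package vignette.
#' @param k_y,k_b phosphotransfer rate constants to CheY and CheB,
#'   1/uM/s.
#' @param k_minus_y,k_minus_b CheY-P and CheB-P dephosphorylation rates,
#'   1/s.
#' @param gamma_R methylation rate constant, 1/s.
#' @param gamma_B demethylation rate constant, 1/uM^2/s (acts with the
#'   square of the CheB-P concentration).
#' @param D ligand diffusion constant, um^2/s. Not part of the published
#'   set; default is a typical small-molecule value. All ligand-noise
#'   outputs carry the value used.
#' @param s_R receptor dimer size, nm.
#' @param mwc an [mwc_params()] object.
#' @param motor a [motor_params()] object.
#' @param gamma_B_simpl demethylation constant of the simplified
#'   (activity-cubed) adaptation model, per complex-activity^2 per s;
#'   `NULL` = choose so the adapted per-receptor activity is 1/3.
#' @param ql_factor prefactor of the ligand-noise intensity
#'   `Q_L = ql_factor * D * s * c0`; 2 matches the
#'   twice-the-one-way-flux convention used for every other source.
#' @return an object of class `pathway_params`.
#' @export
pathway_params <- function(A_tot = 5, B_tot = 0.28, R_tot = 0.16,
                           Y_tot = 9.7, V_cell = 1.4, N_tot = 7027,
                           k_2 = 1e3, k_A = 10, k_y = 100, k_b = 15,
                           k_minus_y = 5, k_minus_b = 1.35,
                           gamma_R = 0.0061, gamma_B = 3.14,
                           D = 1e3, s_R = 1,
                           mwc = mwc_params(), motor = motor_params(),
                           gamma_B_simpl = NULL, ql_factor = 2) {
  if (is.null(gamma_B_simpl))
    gamma_B_simpl <- 18 * gamma_R / mwc$N^2  # adapted A_r = 1/3
  p <- list(A_tot = A_tot, B_tot = B_tot, R_tot = R_tot, Y_tot = Y_tot,
            V_cell = V_cell, N_tot = N_tot, k_2 = k_2, k_A = k_A,
            k_y = k_y, k_b = k_b, k_minus_y = k_minus_y,
            k_minus_b = k_minus_b, gamma_R = gamma_R, gamma_B = gamma_B,
            D = D, s_R = s_R, mwc = mwc, motor = motor,
            gamma_B_simpl = gamma_B_simpl, ql_factor = ql_factor)
  class(p) <- "pathway_params"
  validate_pathway_params(p)
  p
}

#' Parameter set for cells with low motor bias
#'
#' Wild-type-like cells with reduced receptor and CheY content and a
#' strongly CCW-biased motor (CW bias about 0.3 percent): the regime in
#' which low-frequency signalling noise becomes visible on top of the
#' motor's own switching spectrum.
#'
#' @param ... overrides passed to [pathway_params()].
#' @return a [pathway_params()] object.
#' @export
params_low_bias <- function(...) {
  pathway_params(
    N_tot = 4200, Y_tot = 2,
    motor = motor_params(mode = "linearized",
                         k_plus_star = 0.015, k_minus_star = 4.75,
                         dkplus_dYp = 4.75, dkminus_dYp = -5.5),
    ...)
}

validate_pathway_params <- function(p) {
  pos <- c("A_tot", "B_tot", "R_tot", "Y_tot", "V_cell", "N_tot", "k_2",
           "k_A", "k_y", "k_b", "k_minus_y", "k_minus_b", "gamma_R",
           "gamma_B", "D", "s_R", "gamma_B_simpl")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop(sprintf("invalid parameter '%s': must be a non-negative number",
                   nm))
  }
  validate_mwc_params(p$mwc)
  invisible(p)
}

# -- derived quantities -------------------------------------------------

#' Derived copy numbers and unit factors
#'
#' @param params a [pathway_params()] object.
#' @return list with total copy numbers `N_A_tot`, `N_B_tot`, `N_R_tot`,
#'   `N_Y_tot`, the number of complexes `N_C`, the complex diameter `s_um`
#'   (um), and `conv` (uM per molecule).
#' @export
derived_counts <- function(params) {
  v <- params$V_cell
  list(
    N_A_tot = concentration_to_copy_number(params$A_tot, v),
    N_B_tot = concentration_to_copy_number(params$B_tot, v),
    N_R_tot = concentration_to_copy_number(params$R_tot, v),
    N_Y_tot = concentration_to_copy_number(params$Y_tot, v),
    N_C = max(1L, as.integer(round(params$N_tot / params$mwc$N))),
    s_um = sqrt(params$mwc$N) * params$s_R * 1e-3,
    conv = 1 / (v * .MOLEC_PER_uM_FL)
  )
}

# -- config I/O ---------------------------------------------------------

.config_scalar_keys <- c("A_tot", "B_tot", "R_tot", "Y_tot", "V_cell",
                         "N_tot", "k_2", "k_A", "k_y", "k_b", "k_minus_y",
                         "k_minus_b", "gamma_R", "gamma_B", "D", "s_R",
                         "gamma_B_simpl", "ql_factor")

#' Load pathway parameters from a YAML config file
#'
#' Keys are the flat parameter names of [pathway_params()]; `mwc:` and
#' `motor:` sub-maps set receptor-complex and motor fields. Unspecified
#' fields take the wild-type defaults. An empty file yields the full
#' default set.
#'
#' @param path path to a YAML file.
#' @return a validated [pathway_params()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad <- setdiff(names(cfg), c(.config_scalar_keys, "mwc", "motor"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- cfg[intersect(names(cfg), .config_scalar_keys)]
  if (!is.null(cfg$mwc)) args$mwc <- do.call(mwc_params, cfg$mwc)
  if (!is.null(cfg$motor)) {
    m <- cfg$motor
    if (!is.null(m$Yp_anchor) && is.character(m$Yp_anchor))
      m$Yp_anchor <- NA_real_
    args$motor <- do.call(motor_params, m)
  }
  do.call(pathway_params, args)
}

#' Save pathway parameters to a YAML config file
#'
#' Round-trips through [load_config()].
#' @param params a [pathway_params()] object.
#' @param path output path.
#' @export
save_config <- function(params, path) {
  cfg <- params[.config_scalar_keys]
  cfg$mwc <- unclass(params$mwc)
  mo <- unclass(params$motor)
  if (is.na(mo$Yp_anchor)) mo$Yp_anchor <- "adapted"
  cfg$motor <- mo
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Effective parameter set as a table
#'
#' @param params a [pathway_params()] object.
#' @return data.frame with columns symbol, value, units.
#' @export
params_table <- function(params) {
  d <- derived_counts(params)
  units <- c(A_tot = "uM", B_tot = "uM", R_tot = "uM", Y_tot = "uM",
             V_cell = "fl", N_tot = "receptors", k_2 = "1/s", k_A = "1/s",
             k_y = "1/uM/s", k_b = "1/uM/s", k_minus_y = "1/s",
             k_minus_b = "1/s", gamma_R = "1/s", gamma_B = "1/uM^2/s",
             D = "um^2/s", s_R = "nm", gamma_B_simpl = "1/s",
             ql_factor = "")
  sym <- names(units)
  df <- data.frame(symbol = sym,
                   value = vapply(sym, function(k) params[[k]], 0),
                   units = unname(units), stringsAsFactors = FALSE)
  extra <- data.frame(
    symbol = c("N", "N_C", "N_A_tot", "N_B_tot", "N_R_tot", "N_Y_tot"),
    value = c(params$mwc$N, d$N_C, d$N_A_tot, d$N_B_tot, d$N_R_tot,
              d$N_Y_tot),
    units = c("receptors/complex", "complexes", rep("molecules", 4)),
    stringsAsFactors = FALSE)
  rbind(df, extra)
}

#' @export
print.pathway_params <- function(x, ...) {
  d <- derived_counts(x)
  cat("Chemotaxis pathway parameters\n")
  cat(sprintf("  receptors: N_tot = %d, N = %d per complex, N_C = %d\n",
              as.integer(x$N_tot), as.integer(x$mwc$N), d$N_C))
  cat(sprintf("  totals (uM): CheA %.3g, CheB %.3g, CheR %.3g, CheY %.3g\n",
              x$A_tot, x$B_tot, x$R_tot, x$Y_tot))
  cat(sprintf("  adaptation: gamma_R = %.3g 1/s, gamma_B = %.3g 1/uM^2/s\n",
              x$gamma_R, x$gamma_B))
  cat(sprintf("  motor mode: %s\n", x$motor$mode))
  invisible(x)
}
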