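# MWC receptor-complex activity, free energy, sensitivities and
# adapted-state solvers.

#' Free-energy difference of an MWC receptor complex
#'
#' The complex of `N` receptors switches between an active (`on`) and an
#' inactive (`off`) conformation. The free-energy difference (in kBT)
#' between the two states is
#' \deqn{F(c, M) = N \epsilon_0 - M/2 + N [\nu_a \ln\frac{1 + c/K_a^{off}}
#'   {1 + c/K_a^{on}} + \nu_s \ln\frac{1 + c/K_s^{off}}{1 + c/K_s^{on}}]}
#' so that each methyl group lowers the free energy by 1/2 kBT
#' (`dF/dM = -1/2`) while the ligand term, like the offset, is additive
#' over the `N` receptors (`dF/dc` proportional to `N`).
#'
#' @param c ligand (MeAsp) concentration at the complex, mM.
#' @param M total methylation level of the complex (methyl groups).
#' @param mwc an [mwc_params()] object.
#' @return free energy in kBT units (vectorised over `c` and `M`).
#' @export
free_energy <- function(c, M, mwc = mwc_params()) {
  if (any(c < 0)) stop("c must be >= 0")
  N <- mwc$N
  lig <- mwc$nu_a * (log1p(c / mwc$K_a_off) - log1p(c / mwc$K_a_on)) +
         mwc$nu_s * (log1p(c / mwc$K_s_off) - log1p(c / mwc$K_s_on))
  N * mwc$eps0 - M / 2 + N * lig
}

#' Mean activity of an MWC receptor complex
#'
#' `A = N / (1 + exp(F))`, ranging from 0 (fully inactive) to `N`.
#' Numerically safe for arbitrarily large |F|.
#'
#' @inheritParams free_energy
#' @return complex activity in `[0, N]`.
#' @export
receptor_activity <- function(c, M, mwc = mwc_params()) {
  mwc$N * stats::plogis(-free_energy(c, M, mwc))
}

#' Analytic sensitivities of the complex activity
#'
#' Closed-form derivatives of the MWC activity:
#' `dA/dM = N Ar (1 - Ar) / 2` and `dA/dc = -N Ar (1 - Ar) dF/dc`, with
#' `Ar = A/N` the per-receptor activity and `dF/dc` itself proportional
#' to `N`, so that the magnitude of `dA/dc` grows as `N^2` at fixed `Ar`.
#' `dA/dc` is negative for an attractant.
#'
#' @inheritParams free_energy
#' @return list with `dA_dc` (per mM, signed), `dA_dM` (per methyl group)
#'   and `dF_dc` (per mM).
#' @export
receptor_sensitivities <- function(c, M, mwc = mwc_params()) {
  N <- mwc$N
  Ar <- stats::plogis(-free_energy(c, M, mwc))
  dF_dc <- N * (mwc$nu_a * (1 / (mwc$K_a_off + c) - 1 / (mwc$K_a_on + c)) +
                mwc$nu_s * (1 / (mwc$K_s_off + c) - 1 / (mwc$K_s_on + c)))
  list(dA_dc = -N * Ar * (1 - Ar) * dF_dc,
       dA_dM = N * Ar * (1 - Ar) / 2,
       dF_dc = dF_dc)
}

#' Adapted per-receptor activity of the simplified adaptation model
#'
#' In the simplified pathway, methylation balances activity-dependent
#' demethylation (rate proportional to activity cubed), and the adapted
#' per-receptor activity solves the depressed cubic
#' `Ar^3 + beta * Ar - beta = 0` with `beta = gamma_R / gamma_B` (the
#' demethylation constant taken per receptor). The unique real root in
#' (0, 1) is returned in Cardano form. For small `beta` it scales as
#' `beta^(1/3)`.
#'
#' @param beta ratio of methylation to (per-receptor) demethylation rate
#'   constants; must be > 0.
#' @return adapted per-receptor activity in (0, 1); vectorised.
#' @export
adapted_activity_simplified <- function(beta) {
  if (any(beta <= 0)) stop("beta must be > 0")
  u <- (beta / 2 + sqrt(beta^2 / 4 + beta^3 / 27))^(1 / 3)
  u - beta / (3 * u)
}

#' Methylation level that adapts a complex to a given activity
#'
#' Inverts the free energy at concentration `c0` so that
#' `receptor_activity(c0, M*) = N * A_r_target`. Closed form, exact to
#' machine precision; `M*` increases with `c0` for an attractant.
#'
#' @param c0 background ligand concentration, mM.
#' @param A_r_target target per-receptor activity, in (0, 1).
#' @param mwc an [mwc_params()] object.
#' @return adapted methylation level `M*`.
#' @export
adapted_methylation <- function(c0, A_r_target, mwc = mwc_params()) {
  if (any(A_r_target <= 0 | A_r_target >= 1))
    stop("A_r_target must lie strictly inside (0, 1)")
  # A_r = 1/(1+e^F)  =>  F = log((1 - A_r)/A_r); solve F(c0, M) = F_target
  F_target <- log((1 - A_r_target) / A_r_target)
  F_at_M0 <- free_energy(c0, 0, mwc)
  2 * (F_at_M0 - F_target)
}
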