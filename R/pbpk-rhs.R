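#' Interfacial flux from saliva into mucosa
#'
#' Permeability-limited flux across the saliva-mucosa interface,
#' J_SM = P_SM * (C_S - C_T / K_p_T). Positive values move drug from
#' saliva into tissue; the flux vanishes at partition equilibrium
#' C_T = K_p_T * C_S.
#'
#' @param C_S saliva concentration [ug/mL]
#' @param C_T tissue concentration [ug/mL]
#' @param p [oral_physiology()] in canonical units
#' @return flux [ug cm^-2 min^-1]
#' @export
flux_saliva_mucosa <- function(C_S, C_T, p) {
  p$P_SM * (C_S - C_T / p$K_p_T)
}

#' Pellicle surface-binding kinetics
#'
#' Langmuir-type reversible adsorption to the pellicle layer:
#' dGamma/dt = k_ads * C_S * (Gamma_max - Gamma) - k_des * Gamma.
#' At fixed saliva concentration the equilibrium load is
#' Gamma_max * k_ads * C_S / (k_ads * C_S + k_des).
#'
#' @param C_S saliva concentration [ug/mL]
#' @param Gamma adsorbed surface density [ug/cm2]
#' @param p [oral_physiology()] in canonical units
#' @return dGamma/dt [ug cm^-2 min^-1]
#' @export
rhs_pellicle <- function(C_S, Gamma, p) {
  p$k_ads * C_S * (p$Gamma_max - Gamma) - p$k_des * Gamma
}

#' Mucosal tissue mass balance
#'
#' dC_T/dt = (P_SM A_SM / V_T) (C_S - C_T/K_p_T) - (CL_local/V_T) C_T:
#' permeability-limited uptake from saliva and first-order local clearance.
#'
#' @inheritParams rhs_pellicle
#' @param C_T tissue concentration [ug/mL]
#' @return dC_T/dt [ug mL^-1 min^-1]
#' @export
rhs_tissue <- function(C_S, C_T, p) {
  (p$P_SM * p$A_SM / p$V_T) * (C_S - C_T / p$K_p_T) -
    (p$CL_local / p$V_T) * C_T
}

#' Saliva compartment mass balance
#'
#' dC_S/dt = (1/V_S) (R_in - Q_S C_S - J_SM A_SM - J_SB A_SB - J_SP A_SP)
#' minus the pellicle adsorption term (A_SM/V_S) dGamma/dt, so that drug
#' stored on the pellicle is debited from saliva and total mass is
#' conserved. J_SB, the diffusive flux into the biofilm face, depends on
#' the biofilm discretization and is supplied by the caller (the simulator
#' computes it from the surface node); J_SP is the optional direct
#' saliva-pocket leak P_SP (C_S - C_P).
#'
#' @inheritParams rhs_tissue
#' @param Gamma pellicle surface density [ug/cm2]
#' @param R_in drug input rate into saliva [ug/min]
#' @param J_SB flux into the biofilm face [ug cm^-2 min^-1] (default 0)
#' @param C_P pocket concentration [ug/mL], used only when P_SP > 0
#' @return dC_S/dt [ug mL^-1 min^-1]
#' @export
rhs_saliva <- function(C_S, Gamma, C_T, p, R_in = p$R_in, J_SB = 0, C_P = 0) {
  J_SM <- flux_saliva_mucosa(C_S, C_T, p)
  J_SP <- p$P_SP * (C_S - C_P)
  (R_in - p$Q_S * C_S - J_SM * p$A_SM - J_SB * p$A_SB - J_SP * p$A_SP) /
    p$V_S - (p$A_SM / p$V_S) * rhs_pellicle(C_S, Gamma, p)
}

#' Periodontal pocket mass balance
#'
#' dC_P/dt = (J_BP A_BP + R_release - Q_GCF C_P) / V_P: influx across the
#' biofilm-pocket face, direct release from a subgingivally placed
#' formulation, and first-order wash-out by gingival crevicular fluid.
#' With sources off the pocket decays with half-life V_P ln2 / Q_GCF.
#'
#' @param C_P pocket concentration [ug/mL]
#' @param J_BP flux from biofilm into pocket [ug cm^-2 min^-1]
#' @param R_release formulation release rate [ug/min]
#' @param p [oral_physiology()] in canonical units
#' @return dC_P/dt [ug mL^-1 min^-1]
#' @export
rhs_pocket <- function(C_P, J_BP, R_release, p) {
  (J_BP * p$A_BP + R_release - p$Q_GCF * C_P) / p$V_P
}

#' Biofilm reaction-diffusion derivatives (method of lines)
#'
#' Finite-volume discretization of the one-dimensional biofilm slab
#' dC_B/dt = D_eff d2C_B/dx2 - k_bind C_B on [0, L_B], with N_x uniform
#' cells centred at x_i = (i - 1/2) dx. The saliva face (x = 0) is a
#' Dirichlet boundary C_B(0, t) = C_S coupled through a half-cell gradient;
#' the pocket face (x = L_B) is either \code{"sealed"} (zero flux, the
#' literal zero-gradient condition) or \code{"coupled"} (mass-transfer flux
#' J_BP = k_m (C_B(L_B) - C_P) with k_m defaulting to D_eff/dx, the
#' discrete-gradient surrogate). The conservative form makes the
#' semi-discrete system conserve mass exactly.
#'
#' @param C_B biofilm node concentrations [ug/mL], length N_x
#' @param C_S saliva (surface) concentration [ug/mL]
#' @param C_P pocket concentration [ug/mL] (used in coupled mode)
#' @param p [oral_physiology()] in canonical units
#' @param mode far-boundary mode, \code{"sealed"} or \code{"coupled"}
#' @param k_m mass-transfer coefficient for coupled mode [cm/min];
#'   default D_eff/dx
#' @param area_ratio ratio of the pocket-face area to the slab
#'   cross-section area (A_BP/A_SB in the full simulator, 1 for a
#'   stand-alone slab), applied to the far-face outflux so amounts balance
#'   when the two faces differ in area
#' @return list with \code{dC_B} (per-node derivatives), \code{J_SB} (flux
#'   into the biofilm at the saliva face, ug cm^-2 min^-1) and \code{J_BP}
#'   (flux into the pocket at the far face)
#' @export
biofilm_derivatives <- function(C_B, C_S, C_P, p, mode = c("sealed", "coupled"),
                                k_m = NULL, area_ratio = 1) {
  mode <- match.arg(mode)
  N <- length(C_B)
  dx <- p$L_B / N
  D <- p$D_eff
  if (is.null(k_m)) k_m <- D / dx
  J_SB <- D * (C_S - C_B[1]) / (dx / 2)
  J_BP <- if (mode == "coupled") k_m * (C_B[N] - C_P) else 0
  # interface diffusive fluxes between cells i and i+1 (positive downward)
  J_int <- if (N > 1) D * (C_B[-N] - C_B[-1]) / dx else numeric(0)
  influx  <- c(J_SB, J_int)            # into cell i from above
  outflux <- c(J_int, J_BP * area_ratio)
  dC_B <- (influx - outflux) / dx - p$k_bind * C_B
  list(dC_B = dC_B, J_SB = J_SB, J_BP = J_BP)
}
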