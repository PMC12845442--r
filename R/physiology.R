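#' Oral-cavity physiology parameter set
#'
#' Constructs the parameter object describing the five-region transport
#' system: saliva (S), pellicle binding layer on the mucosal surface (M),
#' mucosal tissue (T), dental biofilm slab (B) and periodontal pocket (P).
#' Values are given in "user" units, the mixture of conventional units in
#' which oral physiology is usually reported (mL, mL/min, cm2, cm2/s, uL,
#' uL/min); [to_canonical()] converts to the single internal unit system
#' (cm, min, ug, mL) used by the simulator.
#'
#' Zero is accepted for flows, rates and interface areas so that individual
#' transport pathways can be switched off (e.g. a dilution-only or fully
#' closed system); volumes, lengths, the binding capacity, the diffusivity
#' and the partition coefficient must be strictly positive.
#'
#' @param V_S saliva volume [mL]
#' @param Q_S salivary flow [mL/min]
#' @param R_in constant drug input rate into saliva [ug/min]
#' @param A_SM,A_SB,A_SP saliva-mucosa, saliva-biofilm and saliva-pocket
#'   interface areas [cm2]
#' @param Gamma_max pellicle binding capacity [ug/cm2]
#' @param k_ads pellicle adsorption rate constant [mL cm^-2 min^-1]
#' @param k_des pellicle desorption rate constant [min^-1]
#' @param P_SM transmucosal permeability [cm/min]
#' @param K_p_T tissue:saliva partition coefficient [-]
#' @param V_T mucosal tissue volume [mL]
#' @param CL_local local tissue clearance [mL/min]
#' @param D_eff effective biofilm diffusivity [cm2/s]
#' @param k_bind first-order biofilm binding rate [1/s]
#' @param L_B biofilm thickness [cm]
#' @param A_BP biofilm-pocket interface area [cm2]
#' @param V_P pocket volume [uL]
#' @param Q_GCF gingival crevicular fluid outflow [uL/min]
#' @param P_SP optional direct saliva-pocket permeability [cm/min]; the
#'   pocket is semi-isolated from saliva, so the default is 0
#' @return an object of class \code{oral_physiology} (a named list with a
#'   \code{units} attribute, \code{"user"} or \code{"canonical"})
#' @seealso [validate_physiology()], [to_canonical()]
#' @export
oral_physiology <- function(V_S = 0.8, Q_S = 0.4, R_in = 0,
                            A_SM = 4, A_SB = 2, A_SP = 0.05,
                            Gamma_max = 10, k_ads = 0.5, k_des = 0.05,
                            P_SM = 5e-5, K_p_T = 5,
                            V_T = 0.075, CL_local = 0.05,
                            D_eff = 3e-7, k_bind = 5e-5, L_B = 0.02,
                            A_BP = 0.1, V_P = 1, Q_GCF = 0.075,
                            P_SP = 0) {
  p <- list(V_S = V_S, Q_S = Q_S, R_in = R_in,
            A_SM = A_SM, A_SB = A_SB, A_SP = A_SP,
            Gamma_max = Gamma_max, k_ads = k_ads, k_des = k_des,
            P_SM = P_SM, K_p_T = K_p_T, V_T = V_T, CL_local = CL_local,
            D_eff = D_eff, k_bind = k_bind, L_B = L_B, A_BP = A_BP,
            V_P = V_P, Q_GCF = Q_GCF, P_SP = P_SP)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("physiology parameter '", nm, "' must be a single finite number")
  }
  strict <- c("V_S", "V_T", "V_P", "L_B", "Gamma_max", "K_p_T", "D_eff")
  for (nm in strict)
    if (p[[nm]] <= 0) stop("physiology parameter '", nm, "' must be > 0")
  for (nm in setdiff(names(p), strict))
    if (p[[nm]] < 0) stop("physiology parameter '", nm, "' must be >= 0")
  structure(p, class = "oral_physiology", units = "user")
}

#' @export
print.oral_physiology <- function(x, ...) {
  cat("<oral_physiology> (", attr(x, "units"), " units)\n", sep = "")
  cat(sprintf("  saliva:  V_S=%g mL, Q_S=%g mL/min, R_in=%g ug/min\n",
              x$V_S, x$Q_S, x$R_in))
  cat(sprintf("  pellicle: Gamma_max=%g ug/cm2, k_ads=%g, k_des=%g\n",
              x$Gamma_max, x$k_ads, x$k_des))
  cat(sprintf("  tissue:  P_SM=%g, K_p_T=%g, V_T=%g mL, CL_local=%g mL/min\n",
              x$P_SM, x$K_p_T, x$V_T, x$CL_local))
  cat(sprintf("  biofilm: D_eff=%g, k_bind=%g, L_B=%g cm\n",
              x$D_eff, x$k_bind, x$L_B))
  cat(sprintf("  pocket:  V_P=%g, Q_GCF=%g\n", x$V_P, x$Q_GCF))
  cat(sprintf("  areas:   A_SM=%g, A_SB=%g, A_SP=%g, A_BP=%g cm2\n",
              x$A_SM, x$A_SB, x$A_SP, x$A_BP))
  invisible(x)
}

# Published typical ranges, in user units. Q_S spans resting through
# stimulated flow; Q_GCF spans healthy through inflamed pockets. Parameters
# absent here (R_in, interface areas, k_bind, P_SP) have no published range.
.physiology_ranges <- list(
  V_S       = c(0.7, 1.0),      # mL
  Q_S       = c(0.3, 2.0),      # mL/min (resting 0.3-0.5, stimulated 1-2)
  Gamma_max = c(5, 15),         # ug/cm2
  k_ads     = c(0.1, 1.2),      # mL cm^-2 min^-1
  k_des     = c(0.01, 0.1),     # min^-1
  P_SM      = c(1e-5, 1e-4),    # cm/min
  K_p_T     = c(2, 10),
  V_T       = c(0.05, 0.1),     # mL
  A_SM      = c(2, 6),          # cm2
  CL_local  = c(0.01, 0.1),     # mL/min
  D_eff     = c(1e-7, 5e-7),    # cm2/s
  L_B       = c(0.01, 0.03),    # cm (100-300 um)
  V_P       = c(0.5, 2),        # uL
  Q_GCF     = c(0.05, 0.5)      # uL/min (healthy 0.05-0.1, inflamed 0.2-0.5)
)

.physiology_range_units <- c(
  V_S = "mL", Q_S = "mL/min", Gamma_max = "ug/cm2",
  k_ads = "mL.cm-2.min-1", k_des = "1/min", P_SM = "cm/min", K_p_T = "-",
  V_T = "mL", A_SM = "cm2", CL_local = "mL/min", D_eff = "cm2/s",
  L_B = "cm", V_P = "uL", Q_GCF = "uL/min")

#' Check a physiology against published typical ranges
#'
#' Non-positive volumes, flows or transport parameters are errors; values
#' outside the published typical ranges only generate warnings, returned as
#' a character vector, because those ranges are illustrative rather than
#' prescriptive. An empty return value means every range-checked parameter
#' lies inside its range.
#'
#' @param p an [oral_physiology()] in user units
#' @return character vector of warning messages (possibly empty), invisibly
#'   classed as \code{physiology_warnings}
#' @export
validate_physiology <- function(p) {
  stopifnot(inherits(p, "oral_physiology"))
  if (identical(attr(p, "units"), "canonical"))
    stop("validate_physiology() expects user units; validate before to_canonical()")
  nonneg <- c("R_in", "A_SB", "A_SP", "A_BP", "k_bind", "P_SP")
  for (nm in names(unclass(p))) {
    v <- p[[nm]]
    if (nm %in% nonneg) {
      if (v < 0) stop("physiology parameter '", nm, "' is negative")
    } else if (v <= 0) {
      stop("physiology parameter '", nm, "' is non-positive")
    }
  }
  warnings <- character(0)
  for (nm in names(.physiology_ranges)) {
    rng <- .physiology_ranges[[nm]]
    v <- p[[nm]]
    if (v < rng[1] || v > rng[2])
      warnings <- c(warnings, sprintf(
        "%s = %g %s outside typical range %g-%g %s",
        nm, v, .physiology_range_units[[nm]], rng[1], rng[2],
        .physiology_range_units[[nm]]))
  }
  structure(warnings, class = "physiology_warnings")
}

#' Convert a physiology to the canonical internal unit system
#'
#' The simulator works in a single unit system (length cm, time min, amount
#' ug, volume mL). Conversion from user units: \code{D_eff} and
#' \code{k_bind} are per-second quantities and are multiplied by 60;
#' \code{V_P} and \code{Q_GCF} are given in uL and are divided by 1000.
#' All other parameters are already canonical. The conversion is idempotent
#' (tracked through the \code{units} attribute) and exactly invertible.
#'
#' @param p an [oral_physiology()]
#' @return the same object with \code{units} attribute \code{"canonical"}
#' @export
to_canonical <- function(p) {
  stopifnot(inherits(p, "oral_physiology"))
  if (identical(attr(p, "units"), "canonical")) return(p)
  p$D_eff  <- p$D_eff * 60      # cm2/s   -> cm2/min
  p$k_bind <- p$k_bind * 60     # 1/s     -> 1/min
  p$V_P    <- p$V_P / 1000      # uL      -> mL
  p$Q_GCF  <- p$Q_GCF / 1000    # uL/min  -> mL/min
  attr(p, "units") <- "canonical"
  p
}

#' Convert a canonical physiology back to user units
#'
#' Exact inverse of [to_canonical()]; round-tripping reproduces the input
#' to full floating-point precision.
#'
#' @param p an [oral_physiology()] in canonical units
#' @return the same object with \code{units} attribute \code{"user"}
#' @export
from_canonical <- function(p) {
  stopifnot(inherits(p, "oral_physiology"))
  if (identical(attr(p, "units"), "user")) return(p)
  p$D_eff  <- p$D_eff / 60
  p$k_bind <- p$k_bind / 60
  p$V_P    <- p$V_P * 1000
  p$Q_GCF  <- p$Q_GCF * 1000
  attr(p, "units") <- "user"
  p
}

#' Dosing event
#'
#' Describes one administration. Routes:
#' \describe{
#'   \item{saliva_bolus}{instantaneous amount added to saliva at
#'     \code{start} (a mouthrinse-like input), raising \code{C_S} by
#'     \code{amount / V_S}.}
#'   \item{saliva_infusion}{constant input \code{amount / duration} into
#'     saliva over \code{[start, start + duration]}.}
#'   \item{pocket_formulation}{a subgingivally placed carrier releasing
#'     directly into the pocket; the release-rate profile comes from a
#'     [release_model()] with total dose \code{amount}, started at
#'     \code{start}.}
#' }
#'
#' @param amount dose amount [ug]
#' @param route one of \code{"saliva_bolus"}, \code{"saliva_infusion"},
#'   \code{"pocket_formulation"}
#' @param start start time [min]
#' @param duration infusion duration [min]; ignored for boluses and
#'   formulations (a formulation's own kinetics set its duration)
#' @return an object of class \code{dose_event}
#' @export
dose_event <- function(amount, route = c("saliva_bolus", "saliva_infusion",
                                         "pocket_formulation"),
                       start = 0, duration = 0) {
  route <- match.arg(route)
  stopifnot(is.numeric(amount), length(amount) == 1L, is.finite(amount))
  if (amount <= 0) stop("dose amount must be > 0")
  if (start < 0) stop("dose start time must be >= 0")
  if (duration < 0) stop("dose duration must be >= 0")
  if (route == "saliva_infusion" && duration == 0)
    stop("saliva_infusion requires duration > 0")
  structure(list(amount = amount, route = route, start = start,
                 duration = duration),
            class = "dose_event")
}
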