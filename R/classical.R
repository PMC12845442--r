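#' Classical compartmental pharmacokinetic parameters
#'
#' One-compartment disposition parameters for interpreting any systemically
#' absorbed fraction of a locally delivered dose.
#'
#' @param V distribution volume [mL]
#' @param k first-order elimination rate [1/min]
#' @param k_a first-order absorption rate [1/min]
#' @param F_bio bioavailable fraction, in (0, 1]
#' @param Vmax maximum saturable elimination rate [ug/min]
#' @param Km Michaelis constant [ug/mL]
#' @return object of class \code{classical_pk_params}
#' @export
classical_pk_params <- function(V, k, k_a = NA_real_, F_bio = 1,
                                Vmax = NA_real_, Km = NA_real_) {
  stopifnot(V > 0, k > 0)
  if (!is.na(k_a) && k_a <= 0) stop("k_a must be > 0")
  if (F_bio <= 0 || F_bio > 1) stop("F_bio must be in (0, 1]")
  if (!is.na(Vmax) && Vmax <= 0) stop("Vmax must be > 0")
  if (!is.na(Km) && Km <= 0) stop("Km must be > 0")
  structure(list(V = V, k = k, k_a = k_a, F_bio = F_bio,
                 Vmax = Vmax, Km = Km),
            class = "classical_pk_params")
}

#' Intravenous bolus concentration, C(t) = C0 exp(-k t)
#'
#' @param C0 initial concentration [ug/mL]
#' @param k elimination rate [1/min]
#' @param t time(s) [min], >= 0
#' @return concentration(s) [ug/mL]
#' @export
iv_bolus_concentration <- function(C0, k, t) {
  stopifnot(C0 >= 0, k > 0, all(t >= 0))
  C0 * exp(-k * t)
}

#' Clearance from volume and elimination rate, CL = V k
#'
#' @param V distribution volume [mL]
#' @param k elimination rate [1/min]
#' @return clearance [mL/min]
#' @export
clearance <- function(V, k) {
  stopifnot(V > 0, k > 0)
  V * k
}

#' Bateman first-order absorption/elimination concentration
#'
#' C(t) = F dose k_a / (V (k_a - k)) * (exp(-k t) - exp(-k_a t)), with the
#' removable singularity at k_a = k handled by the analytic limit
#' (F dose / V) k t exp(-k t) when |k_a - k| < 1e-9 k. The returned object
#' carries a flip-flop flag, TRUE when absorption is slower than
#' elimination (k_a < k) so the terminal slope reflects absorption.
#'
#' @param dose administered amount [ug]
#' @param F_bio bioavailable fraction
#' @param V distribution volume [mL]
#' @param k_a absorption rate [1/min]
#' @param k elimination rate [1/min]
#' @param t time(s) [min]
#' @return list with \code{concentration} (vector) and \code{flip_flop}
#'   (logical)
#' @export
bateman_concentration <- function(dose, F_bio, V, k_a, k, t) {
  stopifnot(dose > 0, F_bio > 0, F_bio <= 1, V > 0, k_a > 0, k > 0,
            all(t >= 0))
  conc <- if (abs(k_a - k) < 1e-9 * k) {
    (F_bio * dose / V) * k * t * exp(-k * t)
  } else {
    (F_bio * dose * k_a) / (V * (k_a - k)) * (exp(-k * t) - exp(-k_a * t))
  }
  list(concentration = conc, flip_flop = k_a < k)
}

#' Michaelis-Menten (saturable) elimination derivative
#'
#' dC/dt = -(Vmax / (Km + C)) * C / V: concentration-dependent clearance
#' CL(C) = Vmax / (Km + C). First-order with k = Vmax/(Km V) when C << Km;
#' zero-order decline at Vmax/V when C >> Km.
#'
#' @param C concentration [ug/mL], >= 0
#' @param Vmax maximum elimination rate [ug/min]
#' @param Km Michaelis constant [ug/mL]
#' @param V distribution volume [mL]
#' @return dC/dt [ug mL^-1 min^-1]
#' @export
mm_elimination_ode <- function(C, Vmax, Km, V) {
  stopifnot(all(C >= 0), Vmax > 0, Km > 0, V > 0)
  -(Vmax / (Km + C)) * C / V
}

#' Integrate a Michaelis-Menten decline from an initial concentration
#'
#' @param C0 initial concentration [ug/mL]
#' @param Vmax,Km,V saturable-elimination parameters
#' @param times output times [min], starting at 0
#' @return data.frame with time and concentration
#' @export
mm_concentration <- function(C0, Vmax, Km, V, times) {
  stopifnot(C0 >= 0, times[1] == 0)
  sol <- deSolve::ode(y = c(C = C0), times = times,
                      func = function(t, y, parms)
                        list(mm_elimination_ode(y[1], Vmax, Km, V)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(time = sol[, 1], concentration = pmax(sol[, 2], 0))
}
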