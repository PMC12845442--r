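#' Simulation grid and solver settings
#'
#' @param t_end simulation end time [min]
#' @param dt_out output time step [min]
#' @param N_x number of biofilm cells (>= 10)
#' @param rtol,atol solver relative/absolute tolerances, in (0, 1e-2].
#'   The defaults (1e-8, 1e-10) hold the mass-balance audit well below the
#'   1e-6 gate.
#' @return object of class \code{simulation_grid}
#' @export
simulation_grid <- function(t_end, dt_out = t_end / 200, N_x = 200,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end > 0, dt_out > 0)
  if (N_x < 10) stop("N_x must be >= 10")
  for (tol in c(rtol, atol))
    if (tol <= 0 || tol > 1e-2) stop("tolerances must lie in (0, 1e-2]")
  structure(list(t_end = t_end, dt_out = dt_out, N_x = as.integer(N_x),
                 rtol = rtol, atol = atol),
            class = "simulation_grid")
}

# State vector layout for the coupled system.
.state_index <- function(N_x) {
  list(C_S = 1L, Gamma = 2L, C_T = 3L,
       C_B = 3L + seq_len(N_x),
       C_P = 4L + N_x,
       led = 4L + N_x + 1:6)  # swallowed, gcf, tissue, bound, released, infused
}

.led_names <- c("swallowed", "gcf_outflow", "tissue_clearance",
                "biofilm_bound", "released", "infused")

# Total release rate [ug/min] from all pocket formulations at time t.
.formulation_rate <- function(t, formulations) {
  r <- 0
  for (f in formulations)
    if (t > f$start) r <- r + release_rate(f$model, t - f$start)
  r
}

# Infusion rate (constant physiology R_in plus active infusion events).
.infusion_rate <- function(t, p, infusions) {
  r <- p$R_in
  for (inf in infusions)
    if (t >= inf$start && t < inf$start + inf$duration)
      r <- r + inf$amount / inf$duration
  r
}

#' Simulate the coupled oral-cavity transport system
#'
#' Integrates the five-region mass balance — saliva, pellicle surface
#' binding, mucosal tissue, the spatially discretized biofilm slab and the
#' periodontal pocket — as a stiff method-of-lines ODE system, together
#' with cumulative outflow ledgers (swallowed saliva, GCF wash-out, tissue
#' clearance, irreversibly biofilm-bound drug, dose released and infused so
#' far). Saliva boluses are applied as instantaneous concentration jumps of
#' amount/V_S with the integrator restarted at each event; infusion and
#' formulation start/stop times also break the integration so the solver
#' never steps across a source discontinuity.
#'
#' @param p an [oral_physiology()] (user or canonical units; converted
#'   internally)
#' @param doses list of [dose_event()] (or a single one)
#' @param release a [release_model()] driving any \code{pocket_formulation}
#'   doses (its \code{M_inf} is overridden by each dose amount), or NULL
#' @param grid a [simulation_grid()]
#' @param mode biofilm far-boundary mode: \code{"auto"} (coupled when any
#'   pocket formulation dose is present, sealed otherwise),
#'   \code{"sealed"} or \code{"coupled"}
#' @param init optional named list of initial values: \code{C_S},
#'   \code{Gamma}, \code{C_T}, \code{C_P} (scalars) and/or \code{C_B}
#'   (scalar or length-N_x vector), all in canonical units (ug/mL, ug/cm2)
#' @param k_m coupled-mode mass-transfer coefficient for the
#'   biofilm-pocket face [cm/min]; the default D_eff/(L_B/200) is the
#'   discrete-gradient surrogate evaluated at the reference spatial
#'   resolution (200 cells) and is held fixed regardless of the runtime
#'   grid, so that refining N_x converges instead of changing the physics
#' @return object of class \code{oral_simulation}: \code{times},
#'   \code{C_S}, \code{Gamma}, \code{C_T}, \code{C_P} (vectors),
#'   \code{C_B} (time x node matrix), \code{x} (cell-centre coordinates,
#'   cm), \code{ledgers} (data.frame of cumulative outflows and inputs,
#'   ug), \code{dosed} (cumulative bolus input, ug), \code{physiology}
#'   (canonical), \code{grid}, \code{mode}, \code{diagnostics}
#' @export
simulate_oral <- function(p, doses = list(), release = NULL, grid,
                          mode = c("auto", "sealed", "coupled"),
                          init = NULL, k_m = NULL) {
  stopifnot(inherits(p, "oral_physiology"), inherits(grid, "simulation_grid"))
  mode <- match.arg(mode)
  pc <- to_canonical(p)
  if (inherits(doses, "dose_event")) doses <- list(doses)
  for (d in doses) stopifnot(inherits(d, "dose_event"))

  boluses <- Filter(function(d) d$route == "saliva_bolus", doses)
  infusions <- Filter(function(d) d$route == "saliva_infusion", doses)
  formul_doses <- Filter(function(d) d$route == "pocket_formulation", doses)
  if (length(formul_doses) && is.null(release))
    stop("pocket_formulation doses require a release model")
  formulations <- lapply(formul_doses, function(d) {
    m <- release
    m$M_inf <- d$amount
    list(start = d$start, model = m)
  })
  if (mode == "auto")
    mode <- if (length(formulations)) "coupled" else "sealed"

  N_x <- grid$N_x
  dx <- pc$L_B / N_x
  if (is.null(k_m)) k_m <- pc$D_eff / (pc$L_B / 200)
  use_biofilm <- pc$A_SB > 0
  area_ratio <- if (use_biofilm) pc$A_BP / pc$A_SB else 1
  idx <- .state_index(N_x)
  n_state <- 4L + N_x + 6L

  rhs <- function(t, y, parms) {
    C_S <- y[1]; Gamma <- y[2]; C_T <- y[3]
    C_B <- y[idx$C_B]; C_P <- y[idx$C_P]
    R_rel <- .formulation_rate(t, formulations)
    R_in <- .infusion_rate(t, pc, infusions)
    if (use_biofilm) {
      bf <- biofilm_derivatives(C_B, C_S, C_P, pc, mode = mode, k_m = k_m,
                                area_ratio = area_ratio)
    } else {
      bf <- list(dC_B = numeric(N_x), J_SB = 0, J_BP = 0)
    }
    dGamma <- rhs_pellicle(C_S, Gamma, pc)
    J_SM <- flux_saliva_mucosa(C_S, C_T, pc)
    J_SP <- pc$P_SP * (C_S - C_P)
    dC_S <- (R_in - pc$Q_S * C_S - J_SM * pc$A_SM - bf$J_SB * pc$A_SB -
               J_SP * pc$A_SP) / pc$V_S - (pc$A_SM / pc$V_S) * dGamma
    dC_T <- rhs_tissue(C_S, C_T, pc)
    dC_P <- (bf$J_BP * pc$A_BP + J_SP * pc$A_SP + R_rel -
               pc$Q_GCF * C_P) / pc$V_P
    dled <- c(pc$Q_S * C_S,                      # swallowed
              pc$Q_GCF * C_P,                    # gcf outflow
              pc$CL_local * C_T,                 # tissue clearance
              pc$k_bind * pc$A_SB * dx * sum(C_B),  # biofilm-bound sink
              R_rel,                             # released from formulation
              R_in)                              # infused into saliva
    list(c(dC_S, dGamma, dC_T, bf$dC_B, dC_P, dled))
  }

  y0 <- numeric(n_state)
  if (!is.null(init)) {
    for (nm in names(init)) {
      v <- init[[nm]]
      if (nm == "C_B") {
        y0[idx$C_B] <- if (length(v) == 1L) rep(v, N_x) else {
          stopifnot(length(v) == N_x); v
        }
      } else if (nm %in% c("C_S", "Gamma", "C_T", "C_P")) {
        y0[idx[[nm]]] <- v
      } else stop("unknown init component '", nm, "'")
    }
  }

  out_times <- unique(sort(c(seq(0, grid$t_end, by = grid$dt_out),
                             grid$t_end)))
  breaks <- c(0, grid$t_end,
              vapply(boluses, `[[`, 0, "start"),
              vapply(infusions, `[[`, 0, "start"),
              vapply(infusions, function(d) d$start + d$duration, 0),
              vapply(formul_doses, `[[`, 0, "start"))
  breaks <- sort(unique(pmin(pmax(breaks, 0), grid$t_end)))

  dosed_bolus <- 0
  traj <- matrix(NA_real_, nrow = length(out_times), ncol = n_state)
  record <- function(tt, y) {
    j <- which(abs(out_times - tt) < 1e-9)
    if (length(j)) traj[j, ] <<- rep(y, each = length(j))
  }
  n_steps <- 0L
  y <- y0
  for (s in seq_len(length(breaks) - 1L)) {
    a <- breaks[s]; b <- breaks[s + 1L]
    for (d in boluses)
      if (abs(d$start - a) < 1e-12) {
        y[1] <- y[1] + d$amount / pc$V_S
        dosed_bolus <- dosed_bolus + d$amount
      }
    # report post-event state at the event time itself
    record(a, y)
    seg_times <- unique(sort(c(a, b, out_times[out_times > a & out_times < b])))
    sol <- deSolve::ode(y = y, times = seg_times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = grid$rtol, atol = grid$atol,
                        maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf(
        "solver failure at t = %.6g min (segment %g-%g); state snapshot: C_S=%.4g, C_P=%.4g",
        utils::tail(sol[, 1], 1), a, b, utils::tail(sol[, 2], 1),
        utils::tail(sol[, 1 + idx$C_P], 1)))
    n_steps <- n_steps + attr(sol, "istate")[3]
    for (r in seq_len(nrow(sol)))
      if (sol[r, 1] > a || s == 1L) record(sol[r, 1], sol[r, -1])
    y <- sol[nrow(sol), -1]
  }

  neg <- min(traj, na.rm = TRUE)
  if (neg < -10 * grid$atol)
    stop("negative state excursion ", signif(neg, 4),
         " exceeds -10*atol; reduce tolerances or check inputs")
  traj[traj < 0] <- 0

  led <- as.data.frame(traj[, idx$led, drop = FALSE])
  names(led) <- .led_names
  structure(list(
    times = out_times,
    C_S = traj[, idx$C_S], Gamma = traj[, idx$Gamma],
    C_T = traj[, idx$C_T], C_P = traj[, idx$C_P],
    C_B = traj[, idx$C_B, drop = FALSE],
    x = (seq_len(N_x) - 0.5) * dx,
    ledgers = led,
    dosed = dosed_bolus,
    bolus_times = vapply(boluses, `[[`, 0, "start"),
    bolus_amounts = vapply(boluses, `[[`, 0, "amount"),
    physiology = pc, grid = grid, mode = mode,
    diagnostics = list(n_steps = n_steps, n_segments = length(breaks) - 1L)),
    class = "oral_simulation")
}

#' @export
print.oral_simulation <- function(x, ...) {
  cat("<oral_simulation> ", length(x$times), " time points to t = ",
      max(x$times), " min; biofilm N_x = ", ncol(x$C_B),
      " (", x$mode, " far boundary)\n", sep = "")
  cat(sprintf("  final: C_S = %.4g, C_T = %.4g, C_P = %.4g ug/mL, Gamma = %.4g ug/cm2\n",
              utils::tail(x$C_S, 1), utils::tail(x$C_T, 1),
              utils::tail(x$C_P, 1), utils::tail(x$Gamma, 1)))
  mb <- mass_balance(x)
  cat(sprintf("  mass balance: max relative error %.3g\n",
              max(abs(mb$relative_error))))
  invisible(x)
}

#' Mass-balance audit of a simulation
#'
#' At every output time, compares total drug input so far (saliva boluses,
#' integrated infusion, integrated formulation release) against drug stored
#' in all compartments plus the cumulative outflow ledgers. For a closed
#' system the total is constant; in all cases the relative error should be
#' below 1e-6 at the default solver tolerances.
#'
#' @param sim an [simulate_oral()] result
#' @return data.frame with time, input, stored, outflow and relative error
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "oral_simulation"))
  p <- sim$physiology
  dx <- p$L_B / ncol(sim$C_B)
  stored <- p$V_S * sim$C_S + p$A_SM * sim$Gamma + p$V_T * sim$C_T +
    p$A_SB * dx * rowSums(sim$C_B) + p$V_P * sim$C_P
  outflow <- rowSums(sim$ledgers[, c("swallowed", "gcf_outflow",
                                     "tissue_clearance", "biofilm_bound")])
  # bolus input is a step function of time
  bolus_cum <- vapply(sim$times, function(tt)
    sum(sim$bolus_amounts[sim$bolus_times <= tt + 1e-12]), 0)
  input <- bolus_cum + sim$ledgers$released + sim$ledgers$infused
  # drug present at t = 0 counts as input too
  stored0 <- stored[1] - if (length(sim$bolus_times))
    sum(sim$bolus_amounts[sim$bolus_times <= 1e-12]) else 0
  total_in <- input + stored0 - (sim$ledgers$released[1] +
                                   sim$ledgers$infused[1])
  scale <- pmax(total_in, max(total_in) * 1e-12, .Machine$double.xmin)
  data.frame(time = sim$times, input = total_in, stored = stored,
             outflow = outflow,
             relative_error = ifelse(total_in > 0,
                                     (total_in - stored - outflow) / scale,
                                     0))
}

#' Simulate a stand-alone biofilm slab with a fixed surface concentration
#'
#' Integrates only the biofilm reaction-diffusion equation with a constant
#' Dirichlet concentration C0 at the saliva face, for verifying the spatial
#' scheme against the semi-infinite analytic solution
#' C(x, t) = C0 erfc(x / (2 sqrt(D_eff t))) (valid for k_bind = 0 at times
#' well below L_B^2/D_eff) and for measuring penetration times.
#'
#' @param p an [oral_physiology()] (converted to canonical internally)
#' @param C0 surface concentration [ug/mL]
#' @param grid a [simulation_grid()]
#' @param mode far-boundary mode (\code{"sealed"} or \code{"coupled"}; in
#'   coupled mode the far side empties into a zero-concentration sink)
#' @return list with \code{times}, \code{x} (cell centres, cm), \code{C_B}
#'   (time x node matrix)
#' @export
simulate_biofilm_slab <- function(p, C0, grid, mode = c("sealed", "coupled")) {
  mode <- match.arg(mode)
  pc <- to_canonical(p)
  N_x <- grid$N_x
  rhs <- function(t, y, parms)
    list(biofilm_derivatives(y, C0, 0, pc, mode = mode)$dC_B)
  times <- unique(sort(c(seq(0, grid$t_end, by = grid$dt_out), grid$t_end)))
  sol <- deSolve::ode(y = numeric(N_x), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = grid$rtol, atol = grid$atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) stop("biofilm slab solver failure")
  list(times = sol[, 1], x = (seq_len(N_x) - 0.5) * (pc$L_B / N_x),
       C_B = unname(sol[, -1, drop = FALSE]))
}
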