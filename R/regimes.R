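# Operating-regime taxonomy.  "Oscillation" is operationalized as at
# least 3 alternating flexor bursts within the classification window
# (30 s, transient discarded); "intrinsic bursting" of the isolated
# flexor half-center is tested at the time-averaged excitatory conductance
# it receives in situ.

#' Classify the operating regime of one rhythm generator
#'
#' Decision procedure: (1) simulate the full network with all phasic
#' feedback frozen at zero; if the side shows no rhythmic flexor-extensor
#' alternation the regime is `state_machine` when the full model (with
#' feedback) oscillates, otherwise `non_oscillating`.  (2) If the side
#' oscillates without feedback, isolate its flexor half-center at the mean
#' excitatory conductance it received in situ; intrinsic bursting there
#' means `flexor_driven`.  (3) Otherwise the rhythm requires the mutual
#' inhibition of the coupled pair: `half_center`.
#'
#' @param network a `cpg_network` in any lesion state.
#' @param side `"left"` or `"right"`.
#' @param belts a [belt_condition()].
#' @param drives optional drive override (see [drive_schedule()]).
#' @param duration classification window (s).
#' @param min_bursts alternating bursts required to call oscillation.
#' @return list with elements `regime` (one of `"state_machine"`,
#'   `"flexor_driven"`, `"half_center"`, `"non_oscillating"`), `ambiguous`
#'   (flag set when oscillation persists for less than the classification
#'   window), and `mean_gE_F` (conductance used for the isolation test).
#' @export
classify_regime <- function(network, side = c("left", "right"), belts,
                            drives = NULL, duration = 30, min_bursts = 3) {
  side <- match.arg(side)
  funit <- .unit_name("F", side)
  eunit <- .unit_name("E", side)

  nofb <- simulate_network(network, belts, duration = duration,
                           drives = drives, k_E1 = 0, k_E2 = 0)
  osc_nofb <- .side_oscillates(nofb, funit, eunit, min_bursts)

  if (!osc_nofb$oscillates) {
    full <- simulate_network(network, belts, duration = duration,
                             drives = drives)
    osc_full <- .side_oscillates(full, funit, eunit, min_bursts)
    regime <- if (osc_full$oscillates) "state_machine" else "non_oscillating"
    return(list(regime = regime, ambiguous = osc_full$ambiguous,
                mean_gE_F = NA_real_))
  }

  gE <- .mean_excitatory_conductance(nofb, network, funit)
  if (isolated_f_bursts(network, gE, duration = duration,
                        min_bursts = min_bursts))
    list(regime = "flexor_driven", ambiguous = osc_nofb$ambiguous,
         mean_gE_F = gE)
  else
    list(regime = "half_center", ambiguous = osc_nofb$ambiguous,
         mean_gE_F = gE)
}

# >= min_bursts flexor bursts after the transient, each followed by a
# return of the extensor (alternation); ambiguous when bursting stops
# before the end of the window
.side_oscillates <- function(sim, funit, eunit, min_bursts,
                             threshold = 0.05, transient = 10) {
  tm <- sim$time
  fF <- sim$f[, funit]
  fE <- sim$f[, eunit]
  on <- .debounce(.crossings(tm, fF, threshold, +1), 0.05)
  on <- on[on >= transient]
  if (length(on) < min_bursts)
    return(list(oscillates = FALSE, ambiguous = FALSE))
  # alternation: extensor must come up between consecutive flexor onsets
  alt <- vapply(seq_len(length(on) - 1), function(i) {
    win <- tm > on[i] & tm < on[i + 1]
    any(fE[win] > threshold)
  }, logical(1))
  osc <- sum(alt) >= min_bursts - 1
  # ambiguous: oscillation died out well before the end of the window
  ambiguous <- osc && (max(on) < max(tm) - 5 * stats::median(diff(on)))
  list(oscillates = osc, ambiguous = ambiguous)
}

# time-averaged excitatory conductance received by one unit over the
# post-transient window, reconstructed from the recorded output traces
.mean_excitatory_conductance <- function(sim, network, unit,
                                         transient = 10) {
  par <- compile_network(network, sim$belts, sim$drives,
                         k_E1 = 0, k_E2 = 0)
  n <- par$n
  WE <- matrix(par$WE, n, n, byrow = TRUE)
  i <- match(unit, par$pop_names)
  win <- sim$time >= transient
  gsyn <- drop(sim$f[win, , drop = FALSE] %*% WE[i, ])
  mean(gsyn) + par$dE[i]
}

#' Does an isolated flexor half-center burst at a given drive conductance?
#'
#' Simulates a single conditional burster (flexor parameters from the
#' network) under a constant excitatory conductance and reports whether it
#' produces sustained rhythmic bursting.
#'
#' @param network a `cpg_network` (source of the burster parameters).
#' @param gE constant excitatory conductance (nS).
#' @param duration window (s).
#' @param min_bursts bursts required.
#' @return logical.
#' @export
isolated_f_bursts <- function(network, gE, duration = 30, min_bursts = 3) {
  pop <- network$populations
  i <- match("F_L", pop$name)
  gl <- network$globals
  par <- list(
    n = 1L, C = pop$C[i], gL = pop$gL[i], EL = pop$EL[i],
    bidx = 0L, gNaP = pop$gNaP[i], ENa = pop$ENa[i],
    theta_m = pop$theta_m[i], sigma_m = pop$sigma_m[i],
    theta_h = pop$theta_h[i], sigma_h = pop$sigma_h[i], tau0 = pop$tau0[i],
    WE = 0, WI = 0, dE = gE, dI = 0,
    FBE = numeric(4), FBI = numeric(4),
    ESynE = gl$E_SynE, ESynI = gl$E_SynI,
    iFL = 0L, iFR = -1L, iEL = -1L, iER = -1L,
    kE1 = 0, kE2 = 0, betaL = 0.4, betaR = 0.4,
    Tramp = gl$T_ramp, tauReset = gl$tau_reset,
    Vthr = gl$V_thr, Vmax = gl$V_max,
    pop_names = "F", burster_names = "F")
  h0 <- 1 / (1 + exp((par$EL - par$theta_h) / par$sigma_h))
  res <- net_integrate_cpp(c(par$EL, h0, 0, 0), 0, duration, 1e-3, par,
                           1e-8, 1e-10, 5e-3)
  V <- res$states[, 1]
  f <- output_fun(V, par$Vthr, par$Vmax)
  tm <- res$time
  on <- .debounce(.crossings(tm, f, 0.05, +1), 0.05)
  off <- .debounce(.crossings(tm, f, 0.05, -1), 0.05)
  # bursting = repeated onsets AND repeated offsets (tonic activity has
  # at most one onset and no offsets)
  length(on[on >= 5]) >= min_bursts && length(off[off >= 5]) >= min_bursts
}

#' Bilateral oscillation threshold of the intact model without feedback
#'
#' With all phasic feedback gains frozen at zero and equal bilateral
#' flexor drives (`alpha_L = alpha_R = alpha`, extensor drives at their
#' default), bisect `alpha` for the smallest value sustaining rhythmic
#' left-right alternation (>= 3 alternating flexor bursts within the
#' window after the transient).
#'
#' @param network an intact `cpg_network`.
#' @param lower,upper bisection bracket for alpha.
#' @param tol bisection tolerance.
#' @param beta belt parameter used for the (feedback-free) condition.
#' @param duration simulation window per probe (s).
#' @return list with `threshold` (the midpoint estimate), `n_eval`
#'   (simulations used), and `history` (alpha, oscillates).
#' @export
oscillation_threshold <- function(network, lower = 0.1, upper = 0.6,
                                  tol = 0.01, beta = 0.5, duration = 30) {
  belts <- belt_condition("tied", beta)
  probe <- function(alpha) {
    drv <- drive_schedule(belts, network$lesion, alpha = alpha)
    sim <- simulate_network(network, belts, duration = duration,
                            drives = drv, k_E1 = 0, k_E2 = 0)
    l <- .side_oscillates(sim, "F_L", "E_L", 3)
    r <- .side_oscillates(sim, "F_R", "E_R", 3)
    l$oscillates && r$oscillates
  }
  hist <- data.frame(alpha = numeric(0), oscillates = logical(0))
  note <- function(a, o) hist[nrow(hist) + 1, ] <<- list(a, o)
  lo <- lower; hi <- upper
  o_lo <- probe(lo); note(lo, o_lo)
  o_hi <- probe(hi); note(hi, o_hi)
  if (o_lo) return(list(threshold = lo, n_eval = nrow(hist),
                        history = hist))
  if (!o_hi) stop("no oscillation at upper bracket alpha = ", hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    o <- probe(mid); note(mid, o)
    if (o) hi <- mid else lo <- mid
  }
  list(threshold = (lo + hi) / 2, n_eval = nrow(hist), history = hist)
}
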