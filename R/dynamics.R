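#' Piecewise-linear output function
#'
#' Maps membrane potential to a bounded unit output: 0 at or below
#' `V_thr` (-50 mV), 1 at or above `V_max` (0 mV), linear in between.
#'
#' @param V membrane potential (mV), vectorized.
#' @param V_thr,V_max threshold and saturation potentials (mV).
#' @return output in `[0, 1]`.
#' @export
output_fun <- function(V, V_thr = -50, V_max = 0) {
  pmin(1, pmax(0, (V - V_thr) / (V_max - V_thr)))
}

# Compile a network + belt condition + drives into the flat parameter list
# consumed by the C++ right-hand side.  Drive conductances and presynaptic
# gains are constant within a run, so they are folded in here.
compile_network <- function(network, belts, drives = NULL,
                            k_E1 = NULL, k_E2 = NULL) {
  stopifnot(inherits(network, "cpg_network"))
  if (is.null(drives)) drives <- drive_schedule(belts, network$lesion)
  gl <- network$globals
  if (is.null(k_E1)) k_E1 <- gl$k_E1
  if (is.null(k_E2)) k_E2 <- gl$k_E2
  pop <- network$populations
  n <- nrow(pop)
  idx <- setNames(seq_len(n), pop$name)

  WE <- WI <- matrix(0, n, n)
  for (i in seq_len(nrow(network$connections))) {
    cn <- network$connections[i, ]
    if (cn$sign == "excitatory")
      WE[idx[cn$target], idx[cn$source]] <-
        WE[idx[cn$target], idx[cn$source]] + cn$weight
    else
      WI[idx[cn$target], idx[cn$source]] <-
        WI[idx[cn$target], idx[cn$source]] + cn$weight
  }

  dval <- c(alpha_L = drives$alpha_L, alpha_R = drives$alpha_R,
            gamma_L = drives$gamma_L, gamma_R = drives$gamma_R)
  dE <- dI <- numeric(n)
  if (nrow(network$drives)) for (i in seq_len(nrow(network$drives))) {
    dr <- network$drives[i, ]
    v <- dval[[dr$drive]] * dr$weight
    if (dr$sign == "excitatory") dE[idx[dr$target]] <- dE[idx[dr$target]] + v
    else dI[idx[dr$target]] <- dI[idx[dr$target]] + v
  }

  # presynaptic gain per feedback signal, keyed by the signal's own side
  gains <- c(SF_E1_L = presynaptic_gain(drives$alpha_L, gl$k_PSI),
             SF_E1_R = presynaptic_gain(drives$alpha_R, gl$k_PSI),
             SF_E2_L = presynaptic_gain(drives$alpha_L, gl$k_PSI),
             SF_E2_R = presynaptic_gain(drives$alpha_R, gl$k_PSI))
  fb_cols <- c("SF_E1_L", "SF_E1_R", "SF_E2_L", "SF_E2_R")
  FBE <- FBI <- matrix(0, n, 4, dimnames = list(pop$name, fb_cols))
  for (i in seq_len(nrow(network$feedback))) {
    fb <- network$feedback[i, ]
    g <- if (isTRUE(fb$gated)) gains[[fb$feedback]] else 1
    v <- fb$weight * g
    s <- match(fb$feedback, fb_cols)
    if (fb$sign == "excitatory")
      FBE[idx[fb$target], s] <- FBE[idx[fb$target], s] + v
    else FBI[idx[fb$target], s] <- FBI[idx[fb$target], s] + v
  }

  bursters <- which(pop$kind == "burster")
  list(
    n = n,
    C = pop$C, gL = pop$gL, EL = pop$EL,
    bidx = as.integer(bursters - 1L),
    gNaP = pop$gNaP[bursters],
    ENa = pop$ENa[bursters],
    theta_m = pop$theta_m[bursters], sigma_m = pop$sigma_m[bursters],
    theta_h = pop$theta_h[bursters], sigma_h = pop$sigma_h[bursters],
    tau0 = pop$tau0[bursters],
    WE = as.numeric(t(WE)), WI = as.numeric(t(WI)),
    dE = dE, dI = dI,
    FBE = as.numeric(t(FBE)), FBI = as.numeric(t(FBI)),
    ESynE = gl$E_SynE, ESynI = gl$E_SynI,
    iFL = idx[["F_L"]] - 1L, iFR = idx[["F_R"]] - 1L,
    iEL = idx[["E_L"]] - 1L, iER = idx[["E_R"]] - 1L,
    kE1 = k_E1, kE2 = k_E2,
    betaL = belts$beta_L, betaR = belts$beta_R,
    Tramp = gl$T_ramp, tauReset = gl$tau_reset,
    Vthr = gl$V_thr, Vmax = gl$V_max,
    pop_names = pop$name, burster_names = pop$name[bursters]
  )
}

# Default initial state: all units at their leak reversal with h at
# steady state, plus a small depolarization of the left flexor to break
# the left/right tie deterministically.
initial_state <- function(par, kick = 5) {
  V <- par$EL
  h <- 1 / (1 + exp((V[par$bidx + 1L] - par$theta_h) / par$sigma_h))
  V[par$iFL + 1L] <- V[par$iFL + 1L] + kick
  c(V, h, 0, 0)
}

#' Network right-hand side (reference implementation)
#'
#' Pure-R evaluation of the model vector field, mirroring the compiled
#' integrator step for verification.  Bursters follow persistent-sodium
#' dynamics, `C dV/dt = -gNaP m_inf(V) h (V - E_Na) - gL (V - E_L) -
#' gE (V - E_SynE) - gI (V - E_SynI)` with first-order inactivation `h`;
#' simple units are the same without the sodium term.  Synaptic
#' conductances are weighted sums of presynaptic outputs, constant drive
#' terms, and presynaptically gated feedback terms.
#'
#' @param t time (s); the system is autonomous, `t` is ignored.
#' @param state numeric state vector `[V, h, chi_L, chi_R]`.
#' @param network a `cpg_network`.
#' @param belts a [belt_condition()].
#' @param drives optional [drive_schedule()] output.
#' @return the state derivative (mV/s, 1/s).
#' @export
network_rhs <- function(t, state, network, belts, drives = NULL) {
  par <- compile_network(network, belts, drives)
  if (any(!is.finite(state))) stop("non-finite state (solver blow-up)")
  n <- par$n; nb <- length(par$bidx)
  V <- state[1:n]; h <- state[n + seq_len(nb)]
  chi <- state[n + nb + 1:2]
  out <- output_fun(V, par$Vthr, par$Vmax)
  fE <- c(out[par$iEL + 1L], out[par$iER + 1L])
  u <- c(ifelse(fE[1] > 0, par$kE1 * par$betaL * min(chi[1], 1), 0),
         ifelse(fE[2] > 0, par$kE1 * par$betaR * min(chi[2], 1), 0),
         par$kE2 * fE[1], par$kE2 * fE[2])
  WE <- matrix(par$WE, n, n, byrow = TRUE)
  WI <- matrix(par$WI, n, n, byrow = TRUE)
  FBE <- matrix(par$FBE, n, 4, byrow = TRUE)
  FBI <- matrix(par$FBI, n, 4, byrow = TRUE)
  gE <- drop(WE %*% out) + par$dE + drop(FBE %*% u)
  gI <- drop(WI %*% out) + par$dI + drop(FBI %*% u)
  I <- -par$gL * (V - par$EL) - gE * (V - par$ESynE) - gI * (V - par$ESynI)
  dh <- numeric(nb)
  for (b in seq_len(nb)) {
    i <- par$bidx[b] + 1L
    minf <- 1 / (1 + exp(-(V[i] - par$theta_m[b]) / par$sigma_m[b]))
    hinf <- 1 / (1 + exp((V[i] - par$theta_h[b]) / par$sigma_h[b]))
    tauh <- par$tau0[b] / cosh((V[i] - par$theta_h[b]) / (2 * par$sigma_h[b]))
    I[i] <- I[i] - par$gNaP[b] * minf * h[b] * (V[i] - par$ENa[b])
    dh[b] <- (hinf - h[b]) / (tauh / 1000)
  }
  fF <- c(out[par$iFL + 1L], out[par$iFR + 1L])
  dchi <- ifelse(fF <= 0, ifelse(chi < 2, 1 / par$Tramp, 0),
                 -chi / par$tauReset)
  c(I / par$C * 1000, dh, dchi)
}

#' Somatosensory feedback signals
#'
#' SF-E1 (hip-flexor stretch proxy) ramps with normalized time-in-stance
#' and ipsilateral belt speed: `k_E1 * beta * min(chi, 1)`.  SF-E2
#' (extensor force proxy) follows extensor output: `k_E2 * f(V_E)`.  Both
#' are forced to zero whenever the ipsilateral extensor output is zero.
#' Presynaptic gating is applied at the synaptic entry, not here.
#'
#' @param state state vector as in [network_rhs()], or a named list with
#'   elements `V_E_L`, `V_E_R` (extensor potentials, mV).
#' @param chi length-2 stance-phase clocks (left, right), in `[0, 1]`.
#' @param belts a [belt_condition()].
#' @param network a `cpg_network` (for gains and output constants).
#' @return named list `SF_E1_L`, `SF_E1_R`, `SF_E2_L`, `SF_E2_R`, `chi_L`,
#'   `chi_R`.
#' @export
compute_feedback <- function(state, chi, belts, network) {
  gl <- network$globals
  if (is.list(state)) {
    VE <- c(state$V_E_L, state$V_E_R)
  } else {
    pop <- network$populations$name
    n <- length(pop)
    VE <- state[match(c("E_L", "E_R"), pop)]
  }
  fE <- output_fun(VE, gl$V_thr, gl$V_max)
  beta <- c(belts$beta_L, belts$beta_R)
  e1 <- ifelse(fE > 0, gl$k_E1 * beta * pmin(chi, 1), 0)
  e2 <- gl$k_E2 * fE
  list(SF_E1_L = e1[1], SF_E1_R = e1[2],
       SF_E2_L = e2[1], SF_E2_R = e2[2],
       chi_L = chi[1], chi_R = chi[2])
}
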