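#' Simulate the network over a belt condition
#'
#' Integrates the circuit with an adaptive Dormand-Prince 5(4) solver
#' (relative tolerance 1e-8, absolute 1e-10, maximum step 5 ms) and
#' records unit outputs on a uniform 1 ms grid.  Stance-phase clocks are
#' maintained inside the integrator (ramp during extension, fast reset
#' during flexion).  The trajectory is fully deterministic given the
#' initial state.
#'
#' @param network a `cpg_network` (possibly lesioned).
#' @param belts a [belt_condition()].
#' @param duration simulated time (s); >= 20 s recommended (10 s transient
#'   plus at least ten cycles).
#' @param drives optional [drive_schedule()] override; defaults to the
#'   schedule implied by `belts` and the network's lesion state.
#' @param init initial state vector (e.g. the `final_state` of a previous
#'   run, for warm starts), or `NULL` for the default rest state.
#' @param k_E1,k_E2 optional feedback-gain overrides (set both to 0 to
#'   freeze phasic feedback).
#' @param rtol,atol,max_step solver controls.
#' @param dt_out output grid step (s).
#' @return object of class `sim_result`: list with `time`, `f` (time x
#'   unit output matrix in `[0,1]`), `V`, `h`, `chi`, `feedback` (SF-E1/
#'   SF-E2 traces), `final_state`, `belts`, `drives`, `diagnostics`.
#' @export
simulate_network <- function(network, belts, duration = 30, drives = NULL,
                             init = NULL, k_E1 = NULL, k_E2 = NULL,
                             rtol = 1e-8, atol = 1e-10, max_step = 5e-3,
                             dt_out = 1e-3) {
  stopifnot(duration > 0)
  par <- compile_network(network, belts, drives, k_E1 = k_E1, k_E2 = k_E2)
  if (is.null(init)) init <- initial_state(par)
  if (any(!is.finite(init))) stop("non-finite initial state")
  res <- net_integrate_cpp(init, 0, duration, dt_out, par, rtol, atol,
                           max_step)
  X <- res$states
  n <- par$n; nb <- length(par$bidx)
  V <- X[, 1:n, drop = FALSE]
  colnames(V) <- par$pop_names
  f <- output_fun(V, par$Vthr, par$Vmax)
  dim(f) <- dim(V); dimnames(f) <- dimnames(V)
  h <- X[, n + seq_len(nb), drop = FALSE]
  colnames(h) <- par$burster_names
  chi <- X[, n + nb + 1:2, drop = FALSE]
  colnames(chi) <- c("chi_L", "chi_R")
  fb <- cbind(
    SF_E1_L = ifelse(f[, "E_L"] > 0,
                     par$kE1 * par$betaL * pmin(chi[, 1], 1), 0),
    SF_E1_R = ifelse(f[, "E_R"] > 0,
                     par$kE1 * par$betaR * pmin(chi[, 2], 1), 0),
    SF_E2_L = par$kE2 * f[, "E_L"],
    SF_E2_R = par$kE2 * f[, "E_R"])
  structure(list(
    time = res$time, f = f, V = V, h = h, chi = chi, feedback = fb,
    final_state = X[nrow(X), ], belts = belts,
    drives = if (is.null(drives)) drive_schedule(belts, network$lesion)
             else drives,
    diagnostics = list(nsteps = res$nsteps, nreject = res$nreject,
                       nforced = res$nforced)),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Simulation:", length(x$time) - 1L, "ms,",
      ncol(x$f), "units; belts (",
      x$belts$beta_L, ",", x$belts$beta_R, ") [", x$belts$protocol, "]\n")
  invisible(x)
}

# threshold crossings of a trace on a uniform grid, with linear sub-step
# interpolation; direction +1 upward, -1 downward
.crossings <- function(time, y, threshold, direction) {
  d <- y - threshold
  if (direction > 0) i <- which(d[-length(d)] < 0 & d[-1] >= 0)
  else i <- which(d[-length(d)] >= 0 & d[-1] < 0)
  if (!length(i)) return(numeric(0))
  frac <- d[i] / (d[i] - d[i + 1])
  time[i] + frac * (time[i + 1] - time[i])
}

.debounce <- function(times, min_gap) {
  if (length(times) < 2) return(times)
  keep <- c(TRUE, diff(times) >= min_gap)
  # iterate: removing an event can merge gaps
  while (any(!keep)) {
    times <- times[keep]
    if (length(times) < 2) break
    keep <- c(TRUE, diff(times) >= min_gap)
  }
  times
}

#' Detect flexion onset/offset events
#'
#' Flexion onset is an upward crossing of the flexor output through the
#' threshold, flexion offset a downward crossing; sub-step times come from
#' linear interpolation.  Events inside the transient window are
#' discarded, and same-type events closer than the debounce gap are
#' merged.  Onsets and offsets are paired so they alternate starting with
#' an onset.
#'
#' @param result a `sim_result`.
#' @param threshold output level in (0,1), default 0.05.
#' @param transient initial window to discard (s), default 10.
#' @param debounce minimum gap between same-type events (s), default 0.05.
#' @param min_cycles minimum number of complete cycles required per side.
#' @return object of class `phase_events`: per side, ordered vectors
#'   `onset` and `offset` (s), alternating and strictly increasing.
#' @export
detect_events <- function(result, threshold = 0.05, transient = 10,
                          debounce = 0.05, min_cycles = 3) {
  stopifnot(threshold > 0, threshold < 1)
  ev <- lapply(c(left = "F_L", right = "F_R"), function(unit) {
    y <- result$f[, unit]
    on <- .debounce(.crossings(result$time, y, threshold, +1), debounce)
    off <- .debounce(.crossings(result$time, y, threshold, -1), debounce)
    on <- on[on >= transient]
    off <- off[off >= transient]
    # align: first offset after first onset, then strict alternation
    if (length(on)) off <- off[off > on[1]]
    k <- min(length(on), length(off))
    on <- on[seq_len(min(length(on), k + 1))]
    off <- off[seq_len(k)]
    if (length(on) - 1L < min_cycles)
      stop("insufficient cycles: ", max(0, length(on) - 1L),
           " complete cycles on ", unit, " (need >= ", min_cycles, ")")
    list(onset = on, offset = off)
  })
  structure(ev, class = "phase_events")
}

#' Temporal gait metrics from phase events
#'
#' Per side: cycle_i = onset_(i+1) - onset_i, swing_i = offset_i -
#' onset_i, stance_i = cycle_i - swing_i (flexion = swing, extension =
#' stance).  The per-cycle identity cycle = stance + swing is exact by
#' construction.
#'
#' @param events a `phase_events` object (or a list with `onset`/`offset`
#'   vectors per side).
#' @return object of class `gait_metrics`: a data frame with one row per
#'   side, columns `side`, `cycle_s`, `stance_s`, `swing_s`,
#'   `duty_factor`, `n_cycles`, `cycle_sd`, `stance_sd`, `swing_sd`, plus
#'   attribute `per_cycle` (list of per-cycle data frames).
#' @export
compute_gait_metrics <- function(events) {
  per_cycle <- lapply(events, function(e) {
    on <- e$onset; off <- e$offset
    if (is.unsorted(on, strictly = TRUE) ||
        is.unsorted(off, strictly = TRUE))
      stop("event times must be strictly increasing")
    ncyc <- length(on) - 1L
    if (ncyc < 1) stop("insufficient cycles")
    off <- off[seq_len(ncyc)]
    if (any(off <= on[seq_len(ncyc)]) || any(off >= on[-1]))
      stop("onsets and offsets must alternate")
    cycle <- diff(on)
    swing <- off - on[seq_len(ncyc)]
    data.frame(cycle = cycle, swing = swing, stance = cycle - swing)
  })
  tab <- do.call(rbind, lapply(names(per_cycle), function(s) {
    pc <- per_cycle[[s]]
    data.frame(side = s,
               cycle_s = mean(pc$cycle), stance_s = mean(pc$stance),
               swing_s = mean(pc$swing),
               duty_factor = mean(pc$stance) / mean(pc$cycle),
               n_cycles = nrow(pc),
               cycle_sd = sd(pc$cycle), stance_sd = sd(pc$stance),
               swing_sd = sd(pc$swing),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(tab, per_cycle = per_cycle, class = c("gait_metrics",
                                                  "data.frame"))
}
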