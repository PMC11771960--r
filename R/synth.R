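# Seeded generator of experimental-style gait event streams with the
# statistical structure the analysis pipeline assumes: power-law cycle vs
# speed, near-linear swing vs speed, multiplicative lognormal per-cycle
# noise, subject random effects on the cycle amplitude, and localized
# hemisection effects per condition.

#' Synthetic gait generator parameters
#'
#' Cycle duration follows `T(v) = a * v^-k` (s); tied-belt swing follows
#' `S(v) = c0 + c1 * v` (s); split-belt cycle uses the belt-average speed
#' and the fast limb's swing is the cycle fraction `w0 + w1 * (v_f - 0.4)`.
#' Hemisection effects: ipsilesional (right) swing multiplier `delta_sw`
#' when the right limb is on the fast or tied belt, the smaller
#' `delta_sw_slow` when it is on the slow belt, and a contralesional
#' (left) stance additive `delta_st` (s) in tied and left-slow conditions.
#' Per-cycle phases carry multiplicative lognormal noise with log-SD
#' `sigma`; subjects carry a lognormal random effect with log-SD
#' `subject_sd` on `a` only.
#'
#' @param ... overrides of the defaults.
#' @return a `synth_params` list.
#' @export
synth_params <- function(...) {
  p <- list(
    a = 0.72, k = 0.45,          # cycle curve T(v) = a v^-k
    c0 = 0.25, c1 = -0.03,       # tied swing curve (s, s per m/s)
    w0 = 0.275, w1 = 0.35,       # fast-limb swing fraction in split
    delta_sw = 1.35,             # ipsilesional swing multiplier (fast/tied)
    delta_sw_slow = 1.08,        # ipsilesional swing multiplier (slow belt)
    delta_st = 0.05,             # contralesional stance additive (s)
    sigma = 0.05,                # per-cycle lognormal log-SD
    subject_sd = 0.05,           # subject lognormal log-SD on a
    n_subjects = 6, n_cycles = 15,
    seed = 20260911              # fixed documented default seed
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown synth parameters: ",
                        paste(bad, collapse = ", "))
  p <- modifyList(p, ov)
  if (p$sigma < 0 || p$subject_sd < 0) stop("noise SDs must be >= 0")
  if (p$delta_sw <= 0 || p$delta_sw_slow <= 0)
    stop("swing multipliers must be > 0")
  structure(p, class = "synth_params")
}

# expected (noise-free, subject-effect-free) phase durations for one cell
.synth_cell_means <- function(p, condition, state, speed, limb) {
  hemi <- state == "hemisected"
  if (condition == "tied") {
    T <- p$a * speed^(-p$k)
    swing <- p$c0 + p$c1 * speed
    stance <- T - swing
    if (hemi && limb == "right") {
      swing <- swing * p$delta_sw
      stance <- T - swing                      # cycle preserved
    }
    if (hemi && limb == "left") stance <- stance + p$delta_st
  } else {
    vbar <- (0.4 + speed) / 2
    T <- p$a * vbar^(-p$k)
    fast_limb <- if (condition == "split_ls_rf") "right" else "left"
    if (limb == fast_limb) {
      swing <- T * (p$w0 + p$w1 * (speed - 0.4))
    } else {
      swing <- p$c0 + p$c1 * 0.4
    }
    stance <- T - swing
    if (hemi) {
      if (condition == "split_ls_rf") {
        if (limb == "right") {                 # ipsilesional on fast belt
          swing <- swing * p$delta_sw
          stance <- T - swing
        } else stance <- stance + p$delta_st   # contralesional slow limb
      } else {
        if (limb == "right") {                 # ipsilesional on slow belt
          swing <- swing * p$delta_sw_slow
          stance <- T - swing
        }
      }
    }
  }
  c(swing = swing, stance = stance)
}

.protocol_speeds <- function(protocol) {
  switch(protocol, tied = seq(0.4, 1.0, by = 0.1),
         split_ls_rf = , split_lf_rs = seq(0.5, 1.0, by = 0.1),
         stop("unknown protocol: ", protocol))
}

#' Generate a synthetic gait event series
#'
#' Draws per-cycle swing and stance durations from the parametric curves
#' with lognormal noise and per-subject effects, then accumulates them
#' into contact and stance-end timestamps.  The RNG stream is derived
#' from the seed and consumed in a fixed enumeration order, so identical
#' seeds give byte-identical output and changing an effect size leaves
#' every unaffected limb's draws untouched.
#'
#' @param params a [synth_params()] list.
#' @param protocol `"tied"`, `"split_ls_rf"` or `"split_lf_rs"`.
#' @param states states to generate (default both).
#' @param seed RNG seed; defaults to `params$seed`.
#' @return a gait event series data frame (see [validate_gait_series()]).
#' @export
generate_gait_data <- function(params = synth_params(),
                               protocol = .protocols,
                               states = c("intact", "hemisected"),
                               seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(params, "synth_params"))
  if (is.null(seed)) seed <- params$seed
  speeds <- .protocol_speeds(protocol)

  # refuse parameter combinations yielding non-positive stance anywhere
  for (st in c("intact", "hemisected")[c("intact", "hemisected") %in% states])
    for (v in speeds) for (lb in c("left", "right")) {
      mu <- .synth_cell_means(params, protocol, st, v, lb)
      if (mu["stance"] <= 0 || mu["swing"] <= 0)
        stop("non-positive phase duration at ", st, " ", protocol, " ",
             v, " m/s (", lb, "): stance = ", round(mu["stance"], 4),
             " s, swing = ", round(mu["swing"], 4), " s")
    }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(seed)

  rows <- list()
  for (subj in seq_len(params$n_subjects)) {
    a_eff <- exp(rnorm(1, 0, params$subject_sd))   # subject effect on a
    for (state in c("intact", "hemisected")) {
      for (v in speeds) for (limb in c("left", "right")) {
        z_sw <- rnorm(params$n_cycles, 0, params$sigma)
        z_st <- rnorm(params$n_cycles, 0, params$sigma)
        if (!(state %in% states)) next
        mu <- .synth_cell_means(params, protocol, state, v, limb)
        # subject effect scales the whole cycle (both phases)
        swing <- a_eff * mu["swing"] * exp(z_sw)
        stance <- a_eff * mu["stance"] * exp(z_st)
        cycle <- swing + stance
        contact <- cumsum(c(0, cycle))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("S%02d", subj), state = state,
          condition = protocol, speed_mps = v, limb = limb,
          contact_s = round(contact, 6),
          stance_end_s = round(c(contact[-length(contact)] + stance, NA), 6),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_gait_series(out)
  out
}

#' Fit generator parameters back from intact tied-belt data
#'
#' Recovery check used by the tests: fits `log(cycle) ~ log(speed)` (the
#' slope estimates `-k`) and `swing ~ speed` (the slope estimates `c1`)
#' on intact tied-belt per-cycle metrics.
#'
#' @param metrics per-cycle metrics from [durations_from_events()].
#' @return list with `k_hat`, `k_se`, `c1_hat`, `c1_se`.
#' @export
fit_synth_curves <- function(metrics) {
  m <- metrics[metrics$state == "intact" & metrics$condition == "tied", ]
  if (!nrow(m)) stop("no intact tied-belt cycles in input")
  fk <- lm(log(cycle_s) ~ log(speed_mps), data = m)
  fc <- lm(swing_s ~ speed_mps, data = m)
  list(k_hat = -unname(coef(fk)[2]),
       k_se = unname(sqrt(diag(vcov(fk)))[2]),
       c1_hat = unname(coef(fc)[2]),
       c1_se = unname(sqrt(diag(vcov(fc)))[2]))
}
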