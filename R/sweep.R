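#' Speed sweep over a belt protocol
#'
#' Runs one simulation per grid point and collects per-side temporal gait
#' metrics.  Each point is warm-started from the previous point's final
#' state to shorten transients (the first point runs from rest with an
#' extended duration).  Per-point failures (e.g. no sustained rhythm) are
#' returned as flagged rows, not errors.
#'
#' @param network a `cpg_network`.
#' @param protocol `"tied"`, `"split_ls_rf"` or `"split_lf_rs"`.
#' @param betas numeric grid for the varied belt (both belts for tied, the
#'   fast belt for split protocols), within `[0.3, 1.1]`.
#' @param duration simulated seconds per grid point.
#' @param classify if `TRUE`, add an operating-regime label per side and
#'   point (costs extra simulations; see [classify_regime()]).
#' @param warm_start warm-start each point from the previous final state.
#' @param transient seconds discarded before event detection.
#' @param ... further arguments passed to [simulate_network()].
#' @return a `sweep_table` data frame with columns `protocol`,
#'   `model_state`, `beta_L`, `beta_R`, `side`, `cycle_s`, `stance_s`,
#'   `swing_s`, `duty_factor`, `n_cycles`, `regime`, `ok`.
#' @export
speed_sweep <- function(network, protocol = .protocols,
                        betas = seq(0.4, 1.0, by = 0.1), duration = 30,
                        classify = FALSE, warm_start = TRUE,
                        transient = 10, ...) {
  protocol <- match.arg(protocol)
  if (any(betas < 0.3 - 1e-9 | betas > 1.1 + 1e-9))
    stop("beta grid must lie within [0.3, 1.1]")
  state <- NULL
  rows <- list()
  for (b in betas) {
    belts <- belt_condition(protocol, b)
    row_base <- data.frame(protocol = protocol,
                           model_state = network$lesion,
                           beta_L = belts$beta_L, beta_R = belts$beta_R,
                           stringsAsFactors = FALSE)
    res <- tryCatch({
      cold <- is.null(state)
      sim <- simulate_network(network, belts, duration = duration,
                              init = state, ...)
      if (warm_start) state <- sim$final_state
      ev <- detect_events(sim, transient = if (cold) transient
                                           else min(transient, 5))
      m <- compute_gait_metrics(ev)
      cbind(row_base[rep(1, nrow(m)), ], m, ok = TRUE)
    }, error = function(e) {
      state <<- NULL  # cold-start the next point after a failure
      cbind(row_base[rep(1, 2), ],
            data.frame(side = c("left", "right"), cycle_s = NA_real_,
                       stance_s = NA_real_, swing_s = NA_real_,
                       duty_factor = NA_real_, n_cycles = 0L,
                       cycle_sd = NA_real_, stance_sd = NA_real_,
                       swing_sd = NA_real_),
            ok = FALSE)
    })
    res$regime <- NA_character_
    if (classify && all(res$ok)) {
      for (s in c("left", "right"))
        res$regime[res$side == s] <-
          classify_regime(network, s, belts)$regime
    }
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_table", "data.frame")
  out
}

#' Locate the swing/stance crossing in a sweep
#'
#' Linearly interpolates `swing - stance` between adjacent grid rows of
#' one side and returns the belt speed(s) where it changes sign.  The
#' varied belt is inferred from the protocol (both belts for tied, the
#' fast belt for split protocols).
#'
#' @param sweep a `sweep_table`.
#' @param side `"left"` or `"right"`.
#' @return numeric vector of interpolated crossing speeds (length 0 if
#'   swing and stance never cross; length > 1, with a warning, if the
#'   difference is non-monotone and crosses several times).
#' @export
find_crossing <- function(sweep, side = c("left", "right")) {
  side <- match.arg(side)
  rows <- sweep[sweep$side == side & sweep$ok, , drop = FALSE]
  if (nrow(rows) < 2) stop("need >= 2 valid sweep rows")
  beta_col <- switch(rows$protocol[1], tied = "beta_L",
                     split_ls_rf = "beta_R", split_lf_rs = "beta_L")
  b <- rows[[beta_col]]
  rows <- rows[order(b), , drop = FALSE]
  b <- sort(b)
  d <- rows$swing_s - rows$stance_s
  roots <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0) roots <- c(roots, b[i])
    else if (d[i] * d[i + 1] < 0)
      roots <- c(roots, b[i] + d[i] / (d[i] - d[i + 1]) * (b[i + 1] - b[i]))
  }
  if (d[length(d)] == 0) roots <- c(roots, b[length(d)])
  roots <- unique(roots)
  if (length(roots) > 1)
    warning("multiple swing/stance crossings: non-monotone difference")
  roots
}

#' Write a sweep table to CSV
#'
#' RFC-4180 CSV with "." decimal separator, UTF-8; columns `condition`
#' (protocol), `model_state`, `beta_L`, `beta_R`, `side`, `cycle_s`,
#' `stance_s`, `swing_s`, `duty_factor`, `n_cycles`, `regime`.
#'
#' @param sweep a `sweep_table`.
#' @param path output file path.
#' @export
write_sweep_csv <- function(sweep, path) {
  out <- data.frame(condition = sweep$protocol,
                    model_state = sweep$model_state,
                    beta_L = sweep$beta_L, beta_R = sweep$beta_R,
                    side = sweep$side, cycle_s = sweep$cycle_s,
                    stance_s = sweep$stance_s, swing_s = sweep$swing_s,
                    duty_factor = sweep$duty_factor,
                    n_cycles = sweep$n_cycles, regime = sweep$regime,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
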