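# Analysis of experimental-style gait event streams: per-limb paw-contact
# and stance-end timestamps -> per-cycle temporal metrics -> speed-indexed
# summaries -> intact vs hemisected comparisons.

.series_cols <- c("subject", "state", "condition", "speed_mps", "limb",
                  "contact_s", "stance_end_s")
.group_cols <- c("subject", "state", "condition", "speed_mps", "limb")

#' Validate a gait event series
#'
#' A gait event series is a data frame with columns `subject`, `state`
#' (`intact`/`hemisected`), `condition` (protocol label), `speed_mps`,
#' `limb` (`left`/`right`), `contact_s`, `stance_end_s` — one row per paw
#' contact, carrying the stance-end time of that cycle (`NA` on the final
#' contact of a pass).  Within each pass, contacts must be strictly
#' increasing and each stance end must lie strictly between its contact
#' and the next contact.
#'
#' @param series a data frame as above.
#' @return the validated series, invisibly.
#' @export
validate_gait_series <- function(series) {
  miss <- setdiff(.series_cols, names(series))
  if (length(miss))
    stop("gait series lacks columns: ", paste(miss, collapse = ", "))
  grp <- interaction(series[.group_cols], drop = TRUE)
  for (g in levels(grp)) {
    s <- series[grp == g, ]
    s <- s[order(s$contact_s), ]
    if (is.unsorted(s$contact_s, strictly = TRUE))
      stop("contacts not strictly increasing in cell ", g)
    n <- nrow(s)
    se <- s$stance_end_s[-n]
    ct <- s$contact_s
    bad <- which(!is.na(se) & (se <= ct[-n] | se >= ct[-1]))
    if (length(bad))
      stop("stance end ", format(se[bad[1]]),
           " s outside its cycle (contact ", format(ct[bad[1]]),
           " s) in cell ", g)
  }
  invisible(series)
}

#' Per-cycle durations from a gait event series
#'
#' cycle_i = contact_(i+1) - contact_i; stance_i = stance_end_i -
#' contact_i; swing_i = cycle_i - stance_i; duty_i = stance_i / cycle_i.
#' The final partial cycle of each pass is discarded.  Cycles whose duty
#' factor falls outside (0.05, 0.95) are flagged as tracking artifacts.
#'
#' @param series a gait event series (see [validate_gait_series()]).
#' @return data frame with the grouping columns plus `cycle_s`,
#'   `stance_s`, `swing_s`, `duty_factor`, `artifact`.
#' @export
durations_from_events <- function(series) {
  validate_gait_series(series)
  grp <- interaction(series[.group_cols], drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    s <- series[grp == g, ]
    s <- s[order(s$contact_s), ]
    n <- nrow(s)
    if (n < 2) return(NULL)
    cycle <- diff(s$contact_s)
    stance <- s$stance_end_s[-n] - s$contact_s[-n]
    keep <- !is.na(stance)
    if (!any(keep)) return(NULL)
    data.frame(s[rep(1, sum(keep)), .group_cols],
               cycle_s = cycle[keep], stance_s = stance[keep],
               swing_s = (cycle - stance)[keep],
               duty_factor = (stance / cycle)[keep],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$artifact <- out$duty_factor <= 0.05 | out$duty_factor >= 0.95
  out
}

#' Speed-indexed summary of per-cycle metrics
#'
#' Means, SDs and cycle counts per (state, condition, limb, speed) cell,
#' pooled across subjects.  Artifact-flagged cycles are excluded; cells
#' with fewer than `min_cycles` cycles are omitted with a warning.
#'
#' @param metrics output of [durations_from_events()].
#' @param min_cycles minimum cycles per cell (default 3).
#' @return data frame with one row per cell: `state`, `condition`,
#'   `speed_mps`, `limb`, then `mean`, `sd` for cycle/stance/swing/duty
#'   and `n_cycles`.
#' @export
summarize_by_speed <- function(metrics, min_cycles = 3) {
  m <- metrics[!metrics$artifact, , drop = FALSE]
  key <- c("state", "condition", "limb", "speed_mps")
  agg <- function(v, f, nm) {
    a <- aggregate(m[[v]], m[key], f)
    names(a)[ncol(a)] <- nm
    a
  }
  out <- agg("cycle_s", mean, "cycle_mean")
  for (spec in list(c("cycle_s", "cycle_sd"),
                    c("stance_s", "stance_mean"), c("stance_s", "stance_sd"),
                    c("swing_s", "swing_mean"), c("swing_s", "swing_sd"),
                    c("duty_factor", "duty_mean"))) {
    f <- if (grepl("_sd$", spec[2])) sd else mean
    out <- merge(out, agg(spec[1], f, spec[2]), by = key)
  }
  out <- merge(out, agg("cycle_s", length, "n_cycles"), by = key)
  low <- out$n_cycles < min_cycles
  if (any(low)) {
    warning(sum(low), " cell(s) omitted with < ", min_cycles, " cycles")
    out <- out[!low, , drop = FALSE]
  }
  out <- out[order(out$state, out$condition, out$limb, out$speed_mps), ]
  rownames(out) <- NULL
  out
}

# roots of a piecewise-linear function d(x) given on a grid
.interp_roots <- function(x, d) {
  o <- order(x); x <- x[o]; d <- d[o]
  roots <- numeric(0)
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0) roots <- c(roots, x[i])
    else if (d[i] * d[i + 1] < 0)
      roots <- c(roots, x[i] + d[i] / (d[i] - d[i + 1]) * (x[i + 1] - x[i]))
  }
  if (d[length(d)] == 0) roots <- c(roots, x[length(d)])
  unique(roots)
}

#' Compare intact vs hemisected summaries
#'
#' Pairs the two states per (condition, speed, limb) cell and reports mean
#' differences (hemisected - intact) and ratios, plus the swing/stance
#' crossing speed per (state, condition, limb) obtained by linear
#' interpolation of `swing_mean - stance_mean` across speeds.
#'
#' @param summary output of [summarize_by_speed()] containing both states.
#' @return list with `table` (paired cells; rows where a state is missing
#'   are kept with `NA`s and flagged in `complete`) and `crossings` (one
#'   row per state/condition/limb with the first crossing speed or `NA`).
#' @export
compare_states <- function(summary) {
  states <- unique(summary$state)
  if (!all(c("intact", "hemisected") %in% states))
    warning("missing state: ",
            paste(setdiff(c("intact", "hemisected"), states),
                  collapse = ", "), " (partial table)")
  key <- c("condition", "limb", "speed_mps")
  a <- summary[summary$state == "intact", c(key, "cycle_mean",
        "stance_mean", "swing_mean", "duty_mean", "n_cycles")]
  b <- summary[summary$state == "hemisected", c(key, "cycle_mean",
        "stance_mean", "swing_mean", "duty_mean", "n_cycles")]
  names(a)[-(1:3)] <- paste0("intact_", names(a)[-(1:3)])
  names(b)[-(1:3)] <- paste0("hemi_", names(b)[-(1:3)])
  tab <- merge(a, b, by = key, all = TRUE)
  for (v in c("cycle", "stance", "swing", "duty")) {
    tab[[paste0(v, "_diff")]] <-
      tab[[paste0("hemi_", v, "_mean")]] - tab[[paste0("intact_", v, "_mean")]]
    tab[[paste0(v, "_ratio")]] <-
      tab[[paste0("hemi_", v, "_mean")]] / tab[[paste0("intact_", v, "_mean")]]
  }
  tab$complete <- !is.na(tab$intact_cycle_mean) & !is.na(tab$hemi_cycle_mean)
  tab <- tab[order(tab$condition, tab$limb, tab$speed_mps), ]
  rownames(tab) <- NULL

  cells <- unique(summary[c("state", "condition", "limb")])
  crossings <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- summary[summary$state == cells$state[i] &
                 summary$condition == cells$condition[i] &
                 summary$limb == cells$limb[i], ]
    r <- if (nrow(s) >= 2)
      .interp_roots(s$speed_mps, s$swing_mean - s$stance_mean)
    else numeric(0)
    data.frame(cells[i, ], crossing_mps = if (length(r)) r[1] else NA_real_,
               n_crossings = length(r), row.names = NULL)
  }))
  list(table = tab, crossings = crossings)
}

#' Read / write a gait event series CSV
#'
#' CSV dialect: RFC-4180, "." decimal, UTF-8; columns `subject`, `state`,
#' `condition`, `speed_mps`, `limb`, `contact_s`, `stance_end_s`.
#'
#' @param path file path.
#' @return `read_gait_series()`: the validated series data frame.
#' @export
read_gait_series <- function(path) {
  s <- read.csv(path, stringsAsFactors = FALSE)
  validate_gait_series(s)
  s
}

#' @rdname read_gait_series
#' @param series a gait event series data frame.
#' @export
write_gait_series <- function(series, path) {
  write.csv(series[.series_cols], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}
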