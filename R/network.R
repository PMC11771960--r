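#' Build the bilateral locomotor network
#'
#' Constructs the mirror-symmetric two-sided circuit: per side a rhythm
#' generator made of flexor (F) and extensor (E) conditional bursters
#' inhibiting each other through InF and InE, coupled across the midline by
#' V0D (crossed inhibition of F), V2a–V0V–Ini (crossed inhibition of F),
#' V3 (crossed excitation of F) and V3E (crossed excitation of E); plus
#' supraspinal drive entries (alpha to flexor side, gamma to extensor side)
#' and presynaptically gated somatosensory feedback entries (SF-E1 to F and
#' to contralateral Ini, SF-E2 to E and to V3E).
#'
#' @param config `NULL` for the shipped defaults, a nested list merged over
#'   [default_config()], or the path of a JSON file holding such a list.
#' @param allow_asymmetric if `TRUE`, `config$asymmetric` may list
#'   connection overrides that break left/right mirror symmetry.
#' @return An object of class `cpg_network`: a list with data frames
#'   `populations`, `connections`, `drives`, `feedback`, the `globals`
#'   list, and the `lesion` state (initially `"intact"`).
#' @export
build_network <- function(config = NULL, allow_asymmetric = FALSE) {
  cfg <- default_config()
  if (is.character(config)) config <- read_model_config(config)
  if (!is.null(config)) {
    stopifnot(is.list(config))
    for (sec in c("units", "weights", "globals")) {
      if (!is.null(config[[sec]])) {
        extra <- setdiff(names(config[[sec]]), names(cfg[[sec]]))
        if (sec != "units" && length(extra))
          stop("unknown ", sec, " entries: ", paste(extra, collapse = ", "))
        cfg[[sec]] <- modifyList(cfg[[sec]], config[[sec]])
      }
    }
  }
  w <- cfg$weights
  if (any(unlist(w) < 0)) stop("connection weights must be >= 0")

  pops <- do.call(rbind, lapply(.side_levels, function(side) {
    data.frame(
      name = .unit_name(.pop_labels, side),
      label = .pop_labels,
      side = side,
      kind = ifelse(.pop_labels %in% c("F", "E"), "burster", "simple"),
      stringsAsFactors = FALSE
    )
  }))
  upar <- lapply(seq_len(nrow(pops)), function(i) {
    if (pops$label[i] == "F") cfg$units$burster_F
    else if (pops$label[i] == "E") cfg$units$burster_E
    else cfg$units$simple
  })
  for (fld in c("C", "gL", "EL", "gNaP", "ENa", "theta_m", "sigma_m",
                "theta_h", "sigma_h", "tau0")) {
    pops[[fld]] <- vapply(upar, function(p) {
      v <- p[[fld]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }

  con <- function(src, tgt, weight, sign) {
    data.frame(source = src, target = tgt, weight = weight, sign = sign,
               stringsAsFactors = FALSE)
  }
  conns <- list(); drvs <- list(); fbs <- list()
  for (s in .side_levels) {
    o <- .other_side(s)
    u <- function(lab) .unit_name(lab, s)
    uo <- function(lab) .unit_name(lab, o)
    conns[[s]] <- rbind(
      con(u("F"), u("InF"), w$F_InF, "excitatory"),
      con(u("InF"), u("E"), w$InF_E, "inhibitory"),
      con(u("E"), u("InE"), w$E_InE, "excitatory"),
      con(u("InE"), u("F"), w$InE_F, "inhibitory"),
      con(u("F"), u("V0D"), w$F_V0D, "excitatory"),
      con(u("V0D"), uo("F"), w$V0D_F, "inhibitory"),
      con(u("F"), u("V2a"), w$F_V2a, "excitatory"),
      con(u("V2a"), u("V0V"), w$V2a_V0V, "excitatory"),
      con(u("V0V"), uo("Ini"), w$V0V_Ini, "excitatory"),
      con(u("Ini"), u("F"), w$Ini_F, "inhibitory"),
      con(u("F"), u("V3"), w$F_V3, "excitatory"),
      con(u("V3"), uo("F"), w$V3_F, "excitatory"),
      con(u("E"), u("V3E"), w$E_V3E, "excitatory"),
      con(u("V3E"), uo("E"), w$V3E_E, "excitatory")
    )
    a <- paste0("alpha_", substr(s, 1, 1) |> toupper())
    g <- paste0("gamma_", substr(s, 1, 1) |> toupper())
    drvs[[s]] <- rbind(
      data.frame(drive = a, target = u("F"), weight = w$a_F,
                 sign = "excitatory", stringsAsFactors = FALSE),
      data.frame(drive = a, target = uo("F"), weight = w$a_Fc,
                 sign = "excitatory", stringsAsFactors = FALSE),
      data.frame(drive = a, target = u("V2a"), weight = w$a_V2a,
                 sign = "excitatory", stringsAsFactors = FALSE),
      data.frame(drive = a, target = u("V0V"), weight = w$a_V0V,
                 sign = "excitatory", stringsAsFactors = FALSE),
      data.frame(drive = g, target = u("E"), weight = w$g_E,
                 sign = "excitatory", stringsAsFactors = FALSE)
    )
    e1 <- paste0("SF_E1_", toupper(substr(s, 1, 1)))
    e2 <- paste0("SF_E2_", toupper(substr(s, 1, 1)))
    fbs[[s]] <- rbind(
      data.frame(feedback = e1, target = u("F"), weight = w$E1_F,
                 sign = "excitatory", gated = TRUE, stringsAsFactors = FALSE),
      data.frame(feedback = e1, target = uo("Ini"), weight = w$E1_Ini,
                 sign = "excitatory", gated = TRUE, stringsAsFactors = FALSE),
      data.frame(feedback = e2, target = u("E"), weight = w$E2_E,
                 sign = "excitatory", gated = TRUE, stringsAsFactors = FALSE),
      data.frame(feedback = e2, target = u("V3E"), weight = w$E2_V3E,
                 sign = "excitatory", gated = TRUE, stringsAsFactors = FALSE)
    )
  }
  connections <- do.call(rbind, c(conns, list(make.row.names = FALSE)))
  drives <- do.call(rbind, c(drvs, list(make.row.names = FALSE)))
  feedback <- do.call(rbind, c(fbs, list(make.row.names = FALSE)))

  if (!is.null(config$asymmetric)) {
    if (!allow_asymmetric)
      stop("asymmetric weight specification without explicit override ",
           "(set allow_asymmetric = TRUE)")
    for (ov in config$asymmetric) {
      if (!all(c(ov$source, ov$target) %in% pops$name))
        stop("unknown population label in config: ",
             paste(setdiff(c(ov$source, ov$target), pops$name),
                   collapse = ", "))
      if (ov$weight < 0) stop("connection weights must be >= 0")
      hit <- connections$source == ov$source & connections$target == ov$target
      if (any(hit)) connections$weight[hit] <- ov$weight
      else connections <- rbind(connections,
        data.frame(source = ov$source, target = ov$target,
                   weight = ov$weight, sign = ov$sign,
                   stringsAsFactors = FALSE))
    }
  }

  bad <- setdiff(unique(c(connections$source, connections$target,
                          drives$target, feedback$target)), pops$name)
  if (length(bad))
    stop("unknown population label in config: ", paste(bad, collapse = ", "))

  net <- list(populations = pops, connections = connections,
              drives = drives, feedback = feedback,
              globals = cfg$globals, lesion = "intact")
  class(net) <- "cpg_network"
  net
}

#' @export
print.cpg_network <- function(x, ...) {
  cat("Bilateral locomotor network (", x$lesion, ")\n", sep = "")
  cat("  populations:", nrow(x$populations),
      "| connections:", nrow(x$connections),
      "| drive entries:", nrow(x$drives),
      "| feedback entries:", nrow(x$feedback), "\n")
  invisible(x)
}

#' Read / write a model configuration (JSON)
#'
#' @param path file path of a JSON configuration document with any of the
#'   sections `units`, `weights`, `globals`, `lesion`.
#' @return `read_model_config()`: the configuration list.
#' @export
read_model_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_model_config
#' @param config a configuration list.
#' @export
write_model_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Apply a lesion to the network
#'
#' For each hemisected side, all supraspinal drive entries originating from
#' that side are removed, which also fixes the presynaptic gate on that
#' side's somatosensory feedback fully open (the gate gain is
#' `max(0, 1 - k_PSI * alpha)` and `alpha` becomes 0).  No synaptic weight
#' changes.  A transection is a hemisection of both sides.  The operation
#' is idempotent and composes: left after right equals transected.
#'
#' @param network a `cpg_network`.
#' @param lesion one of `"intact"`, `"right_hemisected"`,
#'   `"left_hemisected"`, `"transected"`.
#' @return the lesioned `cpg_network`.
#' @export
apply_lesion <- function(network, lesion = .lesion_states) {
  lesion <- match.arg(lesion)
  stopifnot(inherits(network, "cpg_network"))
  sides <- switch(lesion,
    intact = character(0),
    right_hemisected = "R",
    left_hemisected = "L",
    transected = c("L", "R"))
  if (length(sides)) {
    drop <- grepl(paste0("_(", paste(sides, collapse = "|"), ")$"),
                  network$drives$drive)
    network$drives <- network$drives[!drop, , drop = FALSE]
    rownames(network$drives) <- NULL
  }
  prev <- .lesioned_sides(network$lesion)
  now <- sort(unique(c(prev, sides)))
  network$lesion <- if (length(now) == 2) "transected"
    else if (identical(now, "L")) "left_hemisected"
    else if (identical(now, "R")) "right_hemisected"
    else "intact"
  network
}

.lesioned_sides <- function(lesion) {
  switch(lesion, intact = character(0), right_hemisected = "R",
         left_hemisected = "L", transected = c("L", "R"))
}

#' Belt condition constructor
#'
#' Belt-speed parameters are dimensionless but numerically identified with
#' treadmill speed in m/s.  The split protocols fix the slow belt at 0.4.
#'
#' @param protocol `"tied"`, `"split_ls_rf"` (left slow / right fast) or
#'   `"split_lf_rs"` (left fast / right slow).
#' @param beta speed of the varied belt: both belts for `tied`, the fast
#'   belt for the split protocols.
#' @param beta_slow slow-belt speed for split protocols (default 0.4).
#' @return a `belt_condition` list with `beta_L`, `beta_R`, `protocol`.
#' @export
belt_condition <- function(protocol = .protocols, beta, beta_slow = 0.4) {
  protocol <- match.arg(protocol)
  bl <- switch(protocol, tied = beta, split_ls_rf = beta_slow,
               split_lf_rs = beta)
  br <- switch(protocol, tied = beta, split_ls_rf = beta,
               split_lf_rs = beta_slow)
  if (any(c(bl, br) < 0.3 - 1e-9) || any(c(bl, br) > 1.1 + 1e-9))
    stop("belt speeds must lie in [0.3, 1.1]")
  if (protocol == "split_ls_rf" && br < bl)
    stop("split_ls_rf requires beta_R >= beta_L = ", beta_slow)
  if (protocol == "split_lf_rs" && bl < br)
    stop("split_lf_rs requires beta_L >= beta_R = ", beta_slow)
  structure(list(beta_L = bl, beta_R = br, protocol = protocol),
            class = "belt_condition")
}

#' Map a belt condition to supraspinal drives
#'
#' On intact sides the flexor-directed drive tracks belt speed with a
#' small constant offset, `alpha = min(beta + 0.1, 1.1)` (the animal's
#' voluntary speed compensation; the offset keeps the presynaptic gate
#' closed, `gain = 0`, across the whole belt range so the intact pattern
#' is set by the drives), and the extensor-directed drive is constant
#' (`gamma`, default 0.5).  Hemisected sides receive identically zero
#' drives.
#'
#' @param belts a [belt_condition()].
#' @param lesion lesion state of the network the drives will feed.
#' @param alpha optional length-1 or length-2 (`L`, `R`) override of the
#'   alpha drives on intact sides.
#' @param gamma extensor drive value on intact sides.
#' @return named list `alpha_L`, `alpha_R`, `gamma_L`, `gamma_R`.
#' @export
drive_schedule <- function(belts, lesion = "intact", alpha = NULL,
                           gamma = 0.5) {
  stopifnot(inherits(belts, "belt_condition"))
  sides <- .lesioned_sides(lesion)
  a <- pmin(c(L = belts$beta_L, R = belts$beta_R) + 0.1, 1.1)
  if (!is.null(alpha)) {
    a[] <- if (length(alpha) == 1) alpha else alpha
  }
  g <- c(L = gamma, R = gamma)
  a[sides] <- 0
  g[sides] <- 0
  if (any(c(a, g) < 0) || any(a > 1.1 + 1e-9))
    stop("drives must lie in [0, 1.1]")
  list(alpha_L = unname(a["L"]), alpha_R = unname(a["R"]),
       gamma_L = unname(g["L"]), gamma_R = unname(g["R"]))
}

#' Presynaptic gating of somatosensory feedback
#'
#' The ipsilateral flexor-directed drive attenuates every gated feedback
#' entry on its side multiplicatively: `gain = max(0, 1 - k_PSI * alpha)`.
#' With `alpha = 0` (hemisected side) feedback acts at full strength.
#'
#' @param alpha drive value(s), >= 0.
#' @param k_PSI slope of the attenuation (default 2).
#' @return gain in `[0, 1]`, same length as `alpha`.
#' @export
presynaptic_gain <- function(alpha, k_PSI = 2) {
  stopifnot(all(alpha >= 0))
  pmax(0, 1 - k_PSI * alpha)
}
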