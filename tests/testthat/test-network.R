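# model_core: network construction, lesions, drives, gating, feedback

test_that("default network has the full bilateral roster", {
  net <- fx_net()
  pops <- net$populations
  expect_equal(nrow(pops), 20L)
  for (s in c("left", "right")) {
    labs <- pops$label[pops$side == s]
    expect_setequal(labs, c("F", "E", "InF", "InE", "V0D", "V0V", "V2a",
                            "V3", "V3E", "Ini"))
    expect_setequal(setdiff(labs, c("F", "E", "InF", "InE")),
                    c("V0D", "V0V", "V2a", "V3", "V3E", "Ini"))
  }
  expect_setequal(pops$label[pops$kind == "burster"], c("F", "E"))
  expect_equal(sum(pops$kind == "burster"), 4L)
})

test_that("state vector counts 20 membrane potentials + 4 inactivation", {
  par <- hemigait:::compile_network(fx_net(), belt_condition("tied", 0.5))
  expect_equal(par$n, 20L)
  expect_equal(length(par$bidx), 4L)
  expect_equal(par$n + length(par$bidx), 24L)
  # the integrator carries two auxiliary stance clocks on top
  expect_equal(length(hemigait:::initial_state(par)), 26L)
})

test_that("connection table is its own left-right mirror", {
  net <- fx_net()
  swap <- function(x) chartr("LR", "RL", x)
  con <- net$connections
  mirrored <- data.frame(source = swap(con$source),
                         target = swap(con$target),
                         weight = con$weight, sign = con$sign,
                         stringsAsFactors = FALSE)
  key <- function(d) do.call(paste, c(d[order(d$source, d$target), ],
                                      sep = "|"))
  expect_setequal(key(con), key(mirrored))
})

test_that("all principal pathways of the circuit are present", {
  con <- fx_net()$connections
  has <- function(src, tgt, sign) {
    any(con$source == src & con$target == tgt & con$sign == sign &
        con$weight > 0)
  }
  # within-RG half-center core, left side
  expect_true(has("F_L", "InF_L", "excitatory"))
  expect_true(has("InF_L", "E_L", "inhibitory"))
  expect_true(has("E_L", "InE_L", "excitatory"))
  expect_true(has("InE_L", "F_L", "inhibitory"))
  # commissural pathways
  expect_true(has("F_L", "V0D_L", "excitatory"))
  expect_true(has("V0D_L", "F_R", "inhibitory"))
  expect_true(has("F_L", "V2a_L", "excitatory"))
  expect_true(has("V2a_L", "V0V_L", "excitatory"))
  expect_true(has("V0V_L", "Ini_R", "excitatory"))
  expect_true(has("Ini_R", "F_R", "inhibitory"))
  expect_true(has("V3_L", "F_R", "excitatory"))
  expect_true(has("V3E_L", "E_R", "excitatory"))
  # drives and feedback entry points
  drv <- fx_net()$drives
  expect_true(any(drv$drive == "alpha_L" & drv$target == "F_L"))
  expect_true(any(drv$drive == "alpha_L" & drv$target == "F_R"))
  expect_true(any(drv$drive == "gamma_L" & drv$target == "E_L"))
  fb <- fx_net()$feedback
  expect_true(any(fb$feedback == "SF_E1_L" & fb$target == "F_L" &
                  fb$sign == "excitatory"))
  expect_true(any(fb$feedback == "SF_E1_L" & fb$target == "Ini_R"))
  expect_true(any(fb$feedback == "SF_E2_L" & fb$target == "E_L"))
  expect_true(all(fb$gated))
})

test_that("configuration errors are rejected", {
  expect_error(build_network(list(weights = list(a_F = -1))), ">= 0")
  expect_error(build_network(list(weights = list(no_such = 1))), "unknown")
  asym <- list(asymmetric = list(list(source = "F_L", target = "InF_L",
                                      weight = 3, sign = "excitatory")))
  expect_error(build_network(asym), "explicit override")
  net <- build_network(asym, allow_asymmetric = TRUE)
  expect_equal(net$connections$weight[net$connections$source == "F_L" &
                                      net$connections$target == "InF_L"], 3)
  bad <- list(asymmetric = list(list(source = "F_L", target = "Xq_9",
                                     weight = 1, sign = "excitatory")))
  expect_error(build_network(bad, allow_asymmetric = TRUE),
               "unknown population")
})

test_that("lesions remove drives only, compose, and are idempotent", {
  net <- fx_net()
  hemi <- apply_lesion(net, "right_hemisected")
  expect_false(any(grepl("_R$", hemi$drives$drive)))
  expect_identical(hemi$connections, net$connections)
  expect_identical(hemi$feedback, net$feedback)
  expect_identical(apply_lesion(hemi, "right_hemisected"), hemi)
  # left after right equals transected, exact structural equality
  both <- apply_lesion(hemi, "left_hemisected")
  trans <- apply_lesion(net, "transected")
  expect_identical(both, trans)
  expect_equal(trans$lesion, "transected")
  expect_equal(nrow(trans$drives), 0L)
})

test_that("presynaptic gain follows the linear clamp", {
  expect_equal(presynaptic_gain(0), 1)
  expect_equal(presynaptic_gain(0.5), 0)          # alpha = 1/k_PSI
  expect_equal(presynaptic_gain(0.35, k_PSI = 2), 0.30)
  expect_equal(presynaptic_gain(2), 0)
  expect_error(presynaptic_gain(-0.1))
  a <- seq(0, 1.1, by = 0.05)
  g <- presynaptic_gain(a)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g) <= 0))
})

test_that("drive schedule maps belts and lesions", {
  b <- belt_condition("tied", 0.5)
  d <- drive_schedule(b, "intact")
  expect_equal(d$alpha_L, 0.6)      # beta + 0.1 speed-compensation offset
  expect_equal(d$gamma_R, 0.5)
  dh <- drive_schedule(b, "right_hemisected")
  expect_equal(dh$alpha_R, 0)
  expect_equal(dh$gamma_R, 0)
  expect_equal(dh$alpha_L, 0.6)
  dt <- drive_schedule(b, "transected")
  expect_equal(unlist(dt), c(alpha_L = 0, alpha_R = 0,
                             gamma_L = 0, gamma_R = 0))
  expect_equal(drive_schedule(b, "intact", alpha = 1)$alpha_L, 1)
})

test_that("belt condition invariants are enforced", {
  expect_error(belt_condition("tied", 0.2), "0.3")
  expect_error(belt_condition("split_ls_rf", 0.35), "beta_R >=")
  b <- belt_condition("split_ls_rf", 0.8)
  expect_equal(b$beta_L, 0.4)
  expect_equal(b$beta_R, 0.8)
  b2 <- belt_condition("split_lf_rs", 0.9)
  expect_equal(b2$beta_R, 0.4)
})

test_that("feedback signals obey gating and scaling", {
  net <- fx_net()
  b <- belt_condition("tied", 0.5)
  # flexion: extensor silent -> both signals zero
  off <- compute_feedback(list(V_E_L = -60, V_E_R = -60), c(0.5, 0.5), b, net)
  expect_equal(off$SF_E1_L, 0)
  expect_equal(off$SF_E2_R, 0)
  # doubling beta doubles SF-E1 at fixed chi
  b4 <- belt_condition("tied", 0.4); b8 <- belt_condition("tied", 0.8)
  s4 <- compute_feedback(list(V_E_L = -30, V_E_R = -30), c(0.5, 0.5), b4, net)
  s8 <- compute_feedback(list(V_E_L = -30, V_E_R = -30), c(0.5, 0.5), b8, net)
  expect_equal(s8$SF_E1_L / s4$SF_E1_L, 2)
  # closed form: chi = 0.25, beta = 0.5, k_E1 = 1 -> 0.125
  s <- compute_feedback(list(V_E_L = -30, V_E_R = -30), c(0.25, 0.25),
                        belt_condition("tied", 0.5), net)
  expect_equal(s$SF_E1_L, 0.125)
  # chi clipped at 1
  sc <- compute_feedback(list(V_E_L = -30, V_E_R = -30), c(1.8, 1.8),
                         belt_condition("tied", 0.5), net)
  expect_equal(sc$SF_E1_L, 0.5)
  # monotone non-decreasing in beta at fixed chi (property)
  for (chi in c(0.1, 0.5, 1)) {
    vals <- vapply(seq(0.3, 1.1, 0.1), function(bb)
      compute_feedback(list(V_E_L = -30, V_E_R = -30), c(chi, chi),
                       belt_condition("tied", bb), net)$SF_E1_L, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("output function matches its piecewise-linear definition", {
  expect_equal(output_fun(-60), 0)
  expect_equal(output_fun(-50), 0)
  expect_equal(output_fun(0), 1)
  expect_equal(output_fun(10), 1)
  expect_equal(output_fun(-25), 0.5)
})

test_that("R and compiled right-hand sides agree on random states", {
  net <- fx_net()
  b <- belt_condition("split_ls_rf", 0.7)
  par <- hemigait:::compile_network(net, b)
  set.seed(11)
  for (i in 1:8) {
    x <- c(runif(20, -70, -10), runif(4), runif(2, 0, 1.5))
    d_r <- network_rhs(0, x, net, b)
    d_c <- hemigait:::net_rhs_cpp(x, par)
    expect_equal(d_r, d_c, tolerance = 1e-12)
  }
})

test_that("rest is a fixed point and non-finite states error", {
  # transected, feedback off: settle, then the settled state is a fixed
  # point of the vector field (feedback disabled via the configuration so
  # the reference vector field matches the simulated one)
  net <- apply_lesion(build_network(list(globals = list(k_E1 = 0,
                                                        k_E2 = 0))),
                      "transected")
  b <- belt_condition("tied", 0.4)
  s <- simulate_network(net, b, duration = 20)
  d <- network_rhs(0, s$final_state, net, b)
  expect_lt(max(abs(d[1:20])), 1e-4)    # mV/s
  expect_error(network_rhs(0, rep(NaN, 26), net, b), "non-finite")
})

test_that("hemisected gate and explicit zero drives give identical paths", {
  net <- fx_net()
  hemi <- fx_hemi()
  b <- belt_condition("tied", 0.6)
  drv <- drive_schedule(b, "right_hemisected")
  s1 <- simulate_network(hemi, b, duration = 5)
  s2 <- simulate_network(net, b, duration = 5, drives = drv)
  expect_identical(s1$f, s2$f)
  expect_identical(s1$h, s2$h)
})

test_that("trajectories are mirror-invariant under left-right relabel", {
  net <- fx_net()
  b <- belt_condition("tied", 0.6)
  par <- hemigait:::compile_network(net, b)
  x0 <- hemigait:::initial_state(par)          # left flexor kicked
  s1 <- simulate_network(net, b, duration = 8, init = x0)
  # mirrored initial state: swap sides in V, h, chi
  swapV <- c(11:20, 1:10)
  x0m <- c(x0[1:20][swapV], x0[21:24][c(3, 4, 1, 2)], x0[26], x0[25])
  s2 <- simulate_network(net, b, duration = 8, init = x0m)
  expect_equal(s1$f[, "F_L"], s2$f[, "F_R"], tolerance = 1e-8)
  expect_equal(s1$f[, "E_L"], s2$f[, "E_R"], tolerance = 1e-8)
})

test_that("outputs and inactivation stay within bounds during simulation", {
  s <- fx("sim_hemi_06", function()
    simulate_network(fx_hemi(), belt_condition("tied", 0.6), duration = 15))
  expect_true(all(s$f >= 0 & s$f <= 1))
  expect_true(all(s$h >= 0 & s$h <= 1))
  expect_true(all(is.finite(s$V)))
})

test_that("model configuration round-trips through JSON", {
  cfg <- default_config()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_config(cfg, path)
  back <- read_model_config(path)
  expect_equal(back$weights$V0D_F, cfg$weights$V0D_F)
  expect_equal(back$units$burster_F$theta_h, cfg$units$burster_F$theta_h)
  net <- build_network(path)
  expect_identical(net$connections, build_network()$connections)
})
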