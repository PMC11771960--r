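# Shared, lazily built fixtures.  Simulations are deterministic, so each
# is built once per test run and reused across files.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) assign(name, build(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

fx_net <- function() fx("net", function() build_network())
fx_hemi <- function() fx("hemi", function()
  apply_lesion(build_network(), "right_hemisected"))
fx_trans <- function() fx("trans", function()
  apply_lesion(build_network(), "transected"))

fx_sweep <- function(tag, network, protocol, betas) {
  fx(tag, function() speed_sweep(network, protocol, betas))
}
fx_intact_tied <- function()
  fx_sweep("sw_intact_tied", fx_net(), "tied", seq(0.4, 1, 0.1))
fx_hemi_tied <- function()
  fx_sweep("sw_hemi_tied", fx_hemi(), "tied", seq(0.4, 1, 0.1))
fx_hemi_lsrf <- function()
  fx_sweep("sw_hemi_lsrf", fx_hemi(), "split_ls_rf", seq(0.5, 1, 0.1))
fx_intact_lfrs <- function()
  fx_sweep("sw_intact_lfrs", fx_net(), "split_lf_rs", seq(0.5, 1, 0.1))
fx_hemi_lfrs <- function()
  fx_sweep("sw_hemi_lfrs", fx_hemi(), "split_lf_rs", seq(0.5, 1, 0.1))

# a sim_result-like object around a constructed flexor trace, for event
# detection tests that need a known signal
fake_sim <- function(time, f_left, f_right = f_left) {
  f <- cbind(F_L = f_left, E_L = 1 - f_left, F_R = f_right,
             E_R = 1 - f_right)
  structure(list(time = time, f = f), class = "sim_result")
}

by_side <- function(sw, side, col) sw[sw$side == side, col]
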