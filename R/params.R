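#' Default model configuration
#'
#' Returns the complete default configuration of the bilateral locomotor
#' circuit: intrinsic unit parameters, connection weights, drive and
#' feedback entry weights, and global constants.  These are the calibrated
#' values shipped with the package; [build_network()] merges a user
#' configuration over them.
#'
#' Units: capacitance in pF, conductances in nS, potentials in mV, time
#' constants in ms (`tau0`) or s (`T_ramp`, `tau_reset`).  Connection,
#' drive and feedback weights are synaptic conductances (nS) recruited per
#' unit of presynaptic output / drive / feedback signal.
#'
#' @return A nested list with elements `units`, `weights`, `globals`.
#' @export
default_config <- function() {
  list(
    units = list(
      # flexor half-centers: conditional bursters, quiescent without
      # drive, bursting over an excitatory-conductance window of roughly
      # 0.13-0.45 nS (tonic plateau above) with period 1.2 s (low drive)
      # to 0.6 s (high drive) and 0.30-0.38 s bursts that lengthen with
      # drive
      burster_F = list(C = 20, gL = 2.8, EL = -68, gNaP = 6, ENa = 50,
                       theta_m = -40, sigma_m = 6, theta_h = -45,
                       sigma_h = 8, tau0 = 600),
      # extensor half-centers: same kinetics but depolarized leak
      # reversal (stable tonic activity, f ~ 0.37, at rest so stance is
      # sustained even without supraspinal drive) and faster inactivation
      # giving a within-stance sag of extensor output
      burster_E = list(C = 20, gL = 2.8, EL = -50, gNaP = 6, ENa = 50,
                       theta_m = -40, sigma_m = 6, theta_h = -45,
                       sigma_h = 8, tau0 = 300),
      # fast relay interneurons
      simple = list(C = 20, gL = 1.0, EL = -52)
    ),
    weights = list(
      # within-RG half-center core
      F_InF = 2.0,   InF_E = 1.69,  # F inhibits E via InF
      E_InE = 2.0,   InE_F = 0.61,  # E inhibits F via InE
      # commissural pathways; strong V0D inhibition enforces strict
      # left-right alternation and 1:1 entrainment after hemisection
      F_V0D = 2.0,   V0D_F = 7.0,               # crossed inhibition
      F_V2a = 2.0,   V2a_V0V = 2.0, V0V_Ini = 2.0, Ini_F = 1.0,
      F_V3 = 1.5,    V3_F = 0.15,               # crossed excitation
      E_V3E = 0.5,   V3E_E = 0.15,              # crossed extensor support
      # supraspinal drive entries
      a_F = 0.35, a_Fc = 0.14, a_V2a = 0.1, a_V0V = 0.2, g_E = 1.0,
      # somatosensory feedback entries (all presynaptically gated)
      E1_F = 1.6, E1_Ini = 0.374, E2_E = 1.11, E2_V3E = 0.5
    ),
    globals = list(
      k_PSI = 2,        # presynaptic-inhibition slope vs alpha
      k_E1 = 1,         # SF-E1 feedback gain
      k_E2 = 1,         # SF-E2 feedback gain
      T_ramp = 1.0,     # s, stance clock ramp time
      tau_reset = 0.52, # s, clock decay time constant during flexion
      E_SynE = -10, E_SynI = -75,
      V_thr = -50, V_max = 0,
      gamma = 0.5       # extensor-directed drive (speed-independent)
    )
  )
}
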