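#' Single-compartment neuron parameters
#'
#' Parameter set for the conductance-based point-neuron model used by
#' [simulate_neuron()]: a leak conductance, a hyperpolarization-activated
#' cation conductance (h-current, carried by HCN channels) and a
#' non-inactivating potassium conductance, each with first-order gating.
#'
#' @param C_m membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L leak reversal potential, mV.
#' @param g_h maximal h-conductance, nS (0 disables the h-current).
#' @param E_h h-current reversal potential, mV.
#' @param V_half_h h-gate half-activation voltage, mV.
#' @param k_h h-gate slope factor, mV (positive; the gate opens on
#'   hyperpolarization).
#' @param tau_h h-gate time constant, ms.
#' @param g_K maximal non-inactivating K conductance, nS.
#' @param E_K_rev potassium reversal potential, mV.
#' @param V_half_K,k_K K-gate half-activation voltage and slope, mV
#'   (the gate opens on depolarization).
#' @param tau_K K-gate time constant, ms.
#' @param noise_sd additive voltage observation noise, mV.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(C_m = 100, g_L = 10, E_L = -80,
                          g_h = 2, E_h = -30, V_half_h = -82, k_h = 7,
                          tau_h = 100,
                          g_K = 2, E_K_rev = -100, V_half_K = -30, k_K = 10,
                          tau_K = 50, noise_sd = 0) {
  if (C_m <= 0) stop("C_m must be > 0")
  if (g_L <= 0) stop("g_L must be > 0")
  if (g_h < 0) stop("g_h must be >= 0")
  if (g_K < 0) stop("g_K must be >= 0")
  if (k_h <= 0) stop("k_h must be > 0")
  if (tau_h <= 0) stop("tau_h must be > 0")
  if (tau_K <= 0) stop("tau_K must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(C_m = C_m, g_L = g_L, E_L = E_L, g_h = g_h, E_h = E_h,
         V_half_h = V_half_h, k_h = k_h, tau_h = tau_h, g_K = g_K,
         E_K_rev = E_K_rev, V_half_K = V_half_K, k_K = k_K, tau_K = tau_K,
         noise_sd = noise_sd),
    class = "neuron_params"
  )
}

#' Spontaneous EPSC generator preset
#'
#' Parameters of the synthetic gap-free voltage-clamp recording: a
#' homogeneous Poisson train of inward biexponential current events in
#' Gaussian noise.
#'
#' @param rate event rate, Hz.
#' @param amp kernel peak amplitude, pA (negative = inward).
#' @param tau_rise,tau_decay kernel time constants, ms
#'   (`tau_decay > tau_rise > 0`).
#' @param noise_sd baseline current noise SD, pA.
#' @param duration recording duration, s.
#' @return An object of class `sepsc_preset`.
#' @export
sepsc_preset <- function(rate = 2, amp = -20, tau_rise = 0.8,
                         tau_decay = 4, noise_sd = 2, duration = 30) {
  if (rate < 0) stop("rate must be >= 0")
  if (!(tau_decay > tau_rise && tau_rise > 0))
    stop("need tau_decay > tau_rise > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(
    list(rate = rate, amp = amp, tau_rise = tau_rise, tau_decay = tau_decay,
         noise_sd = noise_sd, duration = duration),
    class = "sepsc_preset"
  )
}

#' Synaptic-vesicle map generator preset
#'
#' Parameters of the synthetic 2-D presynaptic vesicle point pattern: a
#' negative-binomial vesicle count, an isotropic Gaussian cluster above
#' the active-zone segment with a hard-core exclusion at one mean
#' vesicle diameter, a docked subpopulation apposed to the active zone,
#' and an optional dense-core vesicle (DCV) complement.
#'
#' @param mean_sv_count mean synaptic-vesicle count per terminal.
#' @param count_dispersion negative-binomial size (dispersion) parameter.
#' @param cluster_sd per-axis SD of the Gaussian vesicle cluster, nm.
#' @param sv_diameter_mean,sv_diameter_sd vesicle diameter mean and SD, nm.
#' @param az_length active-zone segment length, nm.
#' @param docked_fraction_true fraction of vesicles placed docked at the
#'   active zone (membrane gap below 2 nm).
#' @param dcv_prob probability that a synapse contains at least one DCV.
#' @param presyn_area_mean mean presynaptic terminal area, um^2.
#' @return An object of class `vesicle_preset`.
#' @export
vesicle_preset <- function(mean_sv_count = 110, count_dispersion = 10,
                           cluster_sd = 200, sv_diameter_mean = 40,
                           sv_diameter_sd = 4, az_length = 500,
                           docked_fraction_true = 0.05, dcv_prob = 0.3,
                           presyn_area_mean = 0.35) {
  if (mean_sv_count <= 0) stop("mean_sv_count must be > 0")
  if (cluster_sd <= 0) stop("cluster_sd must be > 0")
  if (dcv_prob < 0 || dcv_prob > 1) stop("dcv_prob must be in [0, 1]")
  if (docked_fraction_true < 0 || docked_fraction_true > 1)
    stop("docked_fraction_true must be in [0, 1]")
  structure(
    list(mean_sv_count = mean_sv_count, count_dispersion = count_dispersion,
         cluster_sd = cluster_sd, sv_diameter_mean = sv_diameter_mean,
         sv_diameter_sd = sv_diameter_sd, az_length = az_length,
         docked_fraction_true = docked_fraction_true, dcv_prob = dcv_prob,
         presyn_area_mean = presyn_area_mean),
    class = "vesicle_preset"
  )
}

#' Dendritic-tree generator preset
#'
#' Parameters of the stochastic morphology generator: a rooted tree grown
#' by recursive bifurcation with typed spines placed along the cable as a
#' Poisson process.
#'
#' @param branch_prob probability that a segment end bifurcates.
#' @param segment_len_mean mean segment length, um.
#' @param max_depth maximum tree depth (segments from soma to tip).
#' @param n_primary number of primary dendrites leaving the soma.
#' @param soma_radius soma radius, um.
#' @param spine_density_true ground-truth spine density, spines/um.
#' @param spine_type_probs length-3 probability vector
#'   (stubby, thin, mushroom), summing to 1.
#' @return An object of class `morph_preset`.
#' @export
morph_preset <- function(branch_prob = 0.9, segment_len_mean = 30,
                         max_depth = 2, n_primary = 10, soma_radius = 7,
                         spine_density_true = 0.8,
                         spine_type_probs = c(stubby = 0.25, thin = 0.35,
                                              mushroom = 0.40)) {
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (branch_prob < 0 || branch_prob > 1) stop("branch_prob must be in [0,1]")
  if (spine_density_true < 0) stop("spine_density_true must be >= 0")
  if (length(spine_type_probs) != 3L || any(spine_type_probs < 0) ||
      abs(sum(spine_type_probs) - 1) > 1e-8)
    stop("spine_type_probs must be 3 non-negative probabilities summing to 1")
  names(spine_type_probs) <- c("stubby", "thin", "mushroom")
  structure(
    list(branch_prob = branch_prob, segment_len_mean = segment_len_mean,
         max_depth = as.integer(max_depth), n_primary = as.integer(n_primary),
         soma_radius = soma_radius, spine_density_true = spine_density_true,
         spine_type_probs = spine_type_probs),
    class = "morph_preset"
  )
}

## ---------------------------------------------------------------------------
## Genotype / age preset tables.
##
## The WT presets define the baseline condition; Tau35 presets encode the
## effect sizes of the modelled tauopathy phenotype (see the methods
## vignette). Values marked "calibrated" were fixed once by brute-force
## simulation of the corresponding measurement (sag ratio, kernel kinetics,
## nearest-neighbor gap) and are frozen here.

#' Genotype presets for the neuron simulator
#'
#' `"WT"` uses the baseline h-conductance; `"Tau35"` uses an
#' h-conductance calibrated so that the measured subtraction sag roughly
#' doubles relative to WT, the modelled consequence of elevated HCN
#' channel expression.
#'
#' @param genotype `"WT"` or `"Tau35"`.
#' @param ... overrides passed to [neuron_params()].
#' @return A `neuron_params` object.
#' @export
default_neuron_params <- function(genotype = c("WT", "Tau35"), ...) {
  genotype <- match.arg(genotype)
  g_h <- if (genotype == "WT") 2 else 6.24  # calibrated: sag_sub ratio ~ 2
  neuron_params(g_h = g_h, ...)
}

#' Genotype presets for the sEPSC generator
#'
#' Tau35 events are rarer (77% rate reduction), equally large (no
#' amplitude change), and kinetically slower: the kernel time constants
#' are calibrated so the measured rate of rise falls to 43% of WT and
#' the half-width grows about 2.3-fold.
#'
#' @param genotype `"WT"` or `"Tau35"`.
#' @param ... overrides passed to [sepsc_preset()].
#' @return An `sepsc_preset` object.
#' @export
default_sepsc_preset <- function(genotype = c("WT", "Tau35"), ...) {
  genotype <- match.arg(genotype)
  args <- if (genotype == "WT") {
    list(rate = 2.0, amp = -20, tau_rise = 0.8, tau_decay = 4)
  } else {
    # calibrated against the analytic kernel (rate-of-rise ratio 0.43,
    # half-width ratio 2.3)
    list(rate = 0.46, amp = -20, tau_rise = 2.716, tau_decay = 7.250)
  }
  override <- list(...)
  args[names(override)] <- override
  do.call(sepsc_preset, args)
}

#' Genotype x age presets for the vesicle-map generator
#'
#' Mean vesicle counts encode a 27% (4 months) and 39% (10 months)
#' reduction in Tau35; DCV probability encodes a 74% reduction at
#' 10 months only; `cluster_sd` is calibrated so the true mean
#' nearest-neighbor distance is 10 nm larger in Tau35 at both ages.
#'
#' @param genotype `"WT"` or `"Tau35"`.
#' @param age `"4mo"` or `"10mo"`.
#' @param ... overrides passed to [vesicle_preset()].
#' @return A `vesicle_preset` object.
#' @export
default_vesicle_preset <- function(genotype = c("WT", "Tau35"),
                                   age = c("4mo", "10mo"), ...) {
  genotype <- match.arg(genotype)
  age <- match.arg(age)
  key <- paste(genotype, age, sep = "_")
  args <- switch(key,
    WT_4mo     = list(mean_sv_count = 110,  dcv_prob = 0.30,
                      cluster_sd = 200),
    Tau35_4mo  = list(mean_sv_count = 80.3, dcv_prob = 0.30,
                      cluster_sd = 236),
    WT_10mo    = list(mean_sv_count = 100,  dcv_prob = 0.30,
                      cluster_sd = 200),
    Tau35_10mo = list(mean_sv_count = 61,   dcv_prob = 0.078,
                      cluster_sd = 210)
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(vesicle_preset, args)
}

#' Genotype presets for the morphology generator
#'
#' Branching probability and segment length are calibrated so the
#' expected branch-point count drops 44% (9 to 5.04 per neuron) and the
#' mean dendrite length drops 20% in Tau35; spine density drops 59%
#' and spine-type mass shifts from mushroom to thin spines.
#'
#' @param genotype `"WT"` or `"Tau35"`.
#' @param ... overrides passed to [morph_preset()].
#' @return A `morph_preset` object.
#' @export
default_morph_preset <- function(genotype = c("WT", "Tau35"), ...) {
  genotype <- match.arg(genotype)
  args <- if (genotype == "WT") {
    list(branch_prob = 0.9, segment_len_mean = 30,
         spine_density_true = 0.80,
         spine_type_probs = c(stubby = 0.25, thin = 0.35, mushroom = 0.40))
  } else {
    # calibrated: E[branch points] = 5.04, E[mean dendrite length] = 0.8x WT
    list(branch_prob = 0.504, segment_len_mean = 33.466,
         spine_density_true = 0.328,
         spine_type_probs = c(stubby = 0.25, thin = 0.55, mushroom = 0.20))
  }
  override <- list(...)
  args[names(override)] <- override
  do.call(morph_preset, args)
}
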