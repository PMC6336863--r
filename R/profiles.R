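#' Simulation profile for multielectrode-array spike trains
#'
#' Parameter bundle for [simulate_spike_trains()]. Defaults describe a mature
#' wild-type-like culture recorded on an 8-electrode well for a 30 minute
#' session: sparse background firing on every electrode plus network bursts
#' that recruit most electrodes near-simultaneously.
#'
#' @param n_electrodes Number of electrodes in the well.
#' @param duration_s Recording length in seconds (default 1800 s = 30 min).
#' @param base_rate_hz Per-electrode background Poisson firing rate (Hz).
#' @param burst_rate_per_min Network-burst onset rate (bursts per minute,
#'   homogeneous Poisson process).
#' @param burst_duration_s Duration of each network burst (s).
#' @param burst_participation Fraction of electrodes recruited per burst,
#'   in \[0, 1\].
#' @param within_burst_rate_hz Per-electrode firing rate inside a burst (Hz).
#' @param synchrony_coupling Probability in \[0, 1\] that a recruited
#'   electrode copies a spike of the burst's shared mother train. In-burst
#'   spikes not copied from the mother are drawn independently at rate
#'   `(1 - synchrony_coupling) * within_burst_rate_hz`, so this knob moves
#'   synchrony without changing the expected in-burst rate.
#' @param seed Integer seed; identical seeds give identical output.
#'
#' @return A list of class `sim_profile`.
#' @export
#' @examples
#' sim_profile(duration_s = 60, seed = 1)
sim_profile <- function(n_electrodes = 8, duration_s = 1800, base_rate_hz = 1,
                        burst_rate_per_min = 6, burst_duration_s = 0.5,
                        burst_participation = 1, within_burst_rate_hz = 50,
                        synchrony_coupling = 0.8, seed = 1) {
  check_scalar(n_electrodes, "n_electrodes", min = 1, integer = TRUE)
  check_scalar(duration_s, "duration_s", min = .Machine$double.eps)
  check_scalar(base_rate_hz, "base_rate_hz", min = 0)
  check_scalar(burst_rate_per_min, "burst_rate_per_min", min = 0)
  check_scalar(burst_duration_s, "burst_duration_s", min = 0)
  check_scalar(burst_participation, "burst_participation", min = 0, max = 1)
  check_scalar(within_burst_rate_hz, "within_burst_rate_hz", min = 0)
  check_scalar(synchrony_coupling, "synchrony_coupling", min = 0, max = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_electrodes = as.integer(n_electrodes), duration_s = duration_s,
         base_rate_hz = base_rate_hz, burst_rate_per_min = burst_rate_per_min,
         burst_duration_s = burst_duration_s,
         burst_participation = burst_participation,
         within_burst_rate_hz = within_burst_rate_hz,
         synchrony_coupling = synchrony_coupling, seed = as.integer(seed)),
    class = "sim_profile")
}

#' Simulation profile for calcium fluorescence traces
#'
#' Parameter bundle for [simulate_calcium()]. Emulates somatic recordings of a
#' fluorescent calcium indicator (e.g. Fluo-4) sampled at a few Hz: each cell's
#' trace is a baseline plus transient events convolved with a
#' difference-of-exponentials indicator kernel, plus Gaussian noise. A shared
#' network drive generates population events that each cell accepts with its
#' coupling weight.
#'
#' @param n_cells Number of cells.
#' @param fs_hz Sampling rate (Hz).
#' @param coupling_per_cell Weight(s) in \[0, 1\]: probability that a cell
#'   accepts each shared drive event. Scalar is recycled to all cells.
#' @param tau_rise_s,tau_decay_s Kernel time constants (s); decay must exceed
#'   rise.
#' @param noise_sd Additive Gaussian noise SD in dF/F units.
#' @param seed Integer seed.
#'
#' @return A list of class `calcium_profile`.
#' @export
calcium_profile <- function(n_cells = 50, fs_hz = 10, coupling_per_cell = 0.8,
                            tau_rise_s = 0.2, tau_decay_s = 1.5,
                            noise_sd = 0.05, seed = 1) {
  check_scalar(n_cells, "n_cells", min = 1, integer = TRUE)
  check_scalar(fs_hz, "fs_hz", min = .Machine$double.eps)
  if (!is.numeric(coupling_per_cell) ||
      !length(coupling_per_cell) %in% c(1L, n_cells) ||
      any(!is.finite(coupling_per_cell)) ||
      any(coupling_per_cell < 0 | coupling_per_cell > 1)) {
    abort("`coupling_per_cell` must be length 1 or n_cells, with values in [0, 1].")
  }
  check_scalar(tau_rise_s, "tau_rise_s", min = .Machine$double.eps)
  check_scalar(tau_decay_s, "tau_decay_s", min = .Machine$double.eps)
  if (tau_decay_s <= tau_rise_s) abort("`tau_decay_s` must exceed `tau_rise_s`.")
  check_scalar(noise_sd, "noise_sd", min = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(n_cells = as.integer(n_cells), fs_hz = fs_hz,
         coupling_per_cell = rep_len(coupling_per_cell, n_cells),
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "calcium_profile")
}

#' Parameters for synthetic neuron morphologies
#'
#' Parameter bundle for [generate_morphology()]. Defaults emulate a traced
#' wild-type cortical projection neuron: about three primary neurites, total
#' neuritic outgrowth near 848 um and a soma of about 258 um^2 (radius
#' 9.06 um).
#'
#' @param n_primary_neurites Neurites leaving the soma.
#' @param mean_segment_um Mean length of one grown segment (um).
#' @param branch_prob Probability that a tip bifurcates after each segment.
#' @param target_total_length_um Target total neurite length (um); generation
#'   stops when the running total reaches it (the final segment is truncated),
#'   so the result matches the target to within one segment.
#' @param soma_radius_um Soma radius (um).
#' @param seed Integer seed.
#'
#' @return A list of class `morphology_params`.
#' @export
morphology_params <- function(n_primary_neurites = 3, mean_segment_um = 20,
                              branch_prob = 0.3, target_total_length_um = 848,
                              soma_radius_um = 9.06, seed = 1) {
  check_scalar(n_primary_neurites, "n_primary_neurites", min = 1, integer = TRUE)
  check_scalar(mean_segment_um, "mean_segment_um", min = .Machine$double.eps)
  check_scalar(branch_prob, "branch_prob", min = 0, max = 1)
  check_scalar(target_total_length_um, "target_total_length_um",
               min = .Machine$double.eps)
  check_scalar(soma_radius_um, "soma_radius_um", min = .Machine$double.eps)
  check_scalar(seed, "seed", integer = TRUE)
  if (target_total_length_um < mean_segment_um) {
    abort("`target_total_length_um` must be at least `mean_segment_um`.")
  }
  structure(
    list(n_primary_neurites = as.integer(n_primary_neurites),
         mean_segment_um = mean_segment_um, branch_prob = branch_prob,
         target_total_length_um = target_total_length_um,
         soma_radius_um = soma_radius_um, seed = as.integer(seed)),
    class = "morphology_params")
}

#' Parameters for synthetic synaptic-puncta fields
#'
#' Parameter bundle for [generate_puncta()]. Emulates a two-channel
#' immunofluorescence field of pre-synaptic (e.g. VGLUT1) and post-synaptic
#' (e.g. HOMER1) puncta along a straight neurite stretch. Defaults put about
#' 11 colocalized pairs per 50 um (pre density 0.37/um times colocalization
#' fraction 0.6), a typical wild-type synapse density.
#'
#' @param neurite_length_um Length of the imaged neurite stretch (um).
#' @param pre_density_per_um,post_density_per_um Puncta densities (per um).
#' @param colocalization_fraction Fraction of pre puncta given a post partner
#'   within `jitter_um`.
#' @param jitter_um Maximum pre/post partner offset (um).
#' @param pixel_size_um Pixel size for rendering (um/pixel).
#' @param image_shape Integer vector (rows, cols) of the rendered image.
#' @param psf_sigma_um Gaussian point-spread sigma for rendering (um).
#' @param seed Integer seed.
#'
#' @return A list of class `puncta_params`.
#' @export
puncta_params <- function(neurite_length_um = 50, pre_density_per_um = 0.37,
                          post_density_per_um = 0.37,
                          colocalization_fraction = 0.6, jitter_um = 0.2,
                          pixel_size_um = 0.1, image_shape = c(96, 560),
                          psf_sigma_um = 0.15, seed = 1) {
  check_scalar(neurite_length_um, "neurite_length_um", min = .Machine$double.eps)
  check_scalar(pre_density_per_um, "pre_density_per_um", min = 0)
  check_scalar(post_density_per_um, "post_density_per_um", min = 0)
  check_scalar(colocalization_fraction, "colocalization_fraction",
               min = 0, max = 1)
  check_scalar(jitter_um, "jitter_um", min = 0)
  check_scalar(pixel_size_um, "pixel_size_um", min = .Machine$double.eps)
  if (length(image_shape) != 2L || any(image_shape < 4) ||
      any(image_shape != round(image_shape))) {
    abort("`image_shape` must be two whole numbers (rows, cols), each >= 4.")
  }
  check_scalar(psf_sigma_um, "psf_sigma_um", min = .Machine$double.eps)
  check_scalar(seed, "seed", integer = TRUE)
  structure(
    list(neurite_length_um = neurite_length_um,
         pre_density_per_um = pre_density_per_um,
         post_density_per_um = post_density_per_um,
         colocalization_fraction = colocalization_fraction,
         jitter_um = jitter_um, pixel_size_um = pixel_size_um,
         image_shape = as.integer(image_shape), psf_sigma_um = psf_sigma_um,
         seed = as.integer(seed)),
    class = "puncta_params")
}
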