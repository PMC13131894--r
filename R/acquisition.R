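#' Linear-array transducer specification
#'
#' Describes the imaging array used for both displacement imaging and
#' functional ultrasound: a 128-element linear probe driven at a 15.625 MHz
#' carrier, sampled at four times the carrier by default.
#'
#' @param n_elements Number of array elements.
#' @param pitch Element pitch in metres.
#' @param carrier_freq Transmit carrier frequency in Hz.
#' @param sampling_freq Receive sampling frequency in Hz; must satisfy
#'   Nyquist (`>= 2 * carrier_freq`).
#' @param sound_speed Assumed speed of sound in m/s.
#' @return An object of class `transducer_spec`.
#' @export
transducer_spec <- function(n_elements = 128L,
                            pitch = 100e-6,
                            carrier_freq = 15.625e6,
                            sampling_freq = 4 * carrier_freq,
                            sound_speed = DEFAULT_SOUND_SPEED) {
  if (n_elements <= 0) stop_invalid("n_elements must be positive")
  if (pitch <= 0) stop_invalid("pitch must be positive")
  if (carrier_freq <= 0) stop_invalid("carrier_freq must be positive")
  if (sampling_freq < 2 * carrier_freq)
    stop_invalid("sampling_freq must be at least twice carrier_freq")
  structure(list(
    n_elements = as.integer(n_elements), pitch = pitch,
    carrier_freq = carrier_freq, sampling_freq = sampling_freq,
    sound_speed = sound_speed
  ), class = "transducer_spec")
}

#' Element lateral positions (m), centred on the array midpoint
#' @param transducer A [transducer_spec()].
#' @return Numeric vector of length `n_elements`.
#' @export
element_positions <- function(transducer) {
  n <- transducer$n_elements
  (seq_len(n) - (n + 1) / 2) * transducer$pitch
}

#' Plane-wave transmit scheme
#'
#' Angles are evenly spaced and inclusive of both endpoints of
#' `[-max_angle, +max_angle]`, so they are symmetric about zero.
#'
#' @param n_angles Number of plane-wave tilts per compound frame.
#' @param max_angle Maximum tilt, degrees.
#' @param tx_cycles Transmitted cycles per pulse (1.5 for both presets).
#' @param compound_prf Compound-frame rate, Hz.
#' @param frames_per_pd Compound frames accumulated per power-Doppler image.
#' @param frame_interval Time between successive compound frames, s.
#' @return An object of class `plane_wave_scheme` with an `angles` field
#'   in degrees.
#' @export
plane_wave_scheme <- function(n_angles, max_angle, tx_cycles = 1.5,
                              compound_prf = NA_real_,
                              frames_per_pd = NA_integer_,
                              frame_interval = NA_real_) {
  if (n_angles < 1) stop_invalid("n_angles must be >= 1")
  if (max_angle < 0) stop_invalid("max_angle must be non-negative")
  angles <- if (n_angles == 1) 0 else
    seq(-max_angle, max_angle, length.out = n_angles)
  if (is.na(frame_interval) && is.finite(compound_prf))
    frame_interval <- 1 / compound_prf
  structure(list(
    n_angles = as.integer(n_angles), max_angle = max_angle, angles = angles,
    tx_cycles = tx_cycles, compound_prf = compound_prf,
    frames_per_pd = frames_per_pd, frame_interval = frame_interval
  ), class = "plane_wave_scheme")
}

#' Displacement-imaging plane-wave preset: 12 angles in +/-3 deg, one RF
#' frame every 0.768 ms.
#' @return A [plane_wave_scheme()].
#' @export
displacement_scheme_preset <- function() {
  plane_wave_scheme(n_angles = 12L, max_angle = 3, tx_cycles = 1.5,
                    frames_per_pd = 1L, frame_interval = 0.768e-3)
}

#' Doppler plane-wave preset: 13 angles in +/-7 deg, 500 Hz compound PRF,
#' 150 compound frames per power-Doppler image at a 1 Hz functional rate.
#' @return A [plane_wave_scheme()].
#' @export
doppler_scheme_preset <- function() {
  plane_wave_scheme(n_angles = 13L, max_angle = 7, tx_cycles = 1.5,
                    compound_prf = 500, frames_per_pd = 150L)
}

#' FUS pulse specification
#'
#' @param center_freq FUS carrier frequency, Hz.
#' @param pulse_duration Single continuous pulse duration, s.
#' @param prf Pulse repetition frequency, Hz.
#' @param sonication_duration Total train duration, s.
#' @param pressure Derated peak pressure, MPa.
#' @return An object of class `fus_pulse_spec`.
#' @export
fus_pulse_spec <- function(center_freq = 4e6, pulse_duration = 80e-3,
                           prf = 1, sonication_duration = 10,
                           pressure = 3.39) {
  if (pressure < 0) stop_invalid("pressure must be non-negative")
  if (pulse_duration * prf > 1)
    stop_invalid("duty cycle pulse_duration * prf exceeds 1")
  structure(list(
    center_freq = center_freq, pulse_duration = pulse_duration, prf = prf,
    sonication_duration = sonication_duration, pressure = pressure
  ), class = "fus_pulse_spec")
}

#' Functional-session specification
#'
#' The default session is 270 samples at 1 Hz with seven 10 s stimulation
#' periods.  The inter-stimulus interval is a package choice (30 s baseline,
#' onsets every 34 s), since only the counts are fixed by the protocol.
#'
#' @param functional_rate Functional frame rate, Hz.
#' @param n_samples Session length in functional samples.
#' @param stim_onsets Stimulation onset times, s.
#' @param stim_duration Stimulation period duration, s.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(functional_rate = 1, n_samples = 270L,
                         stim_onsets = seq(30, by = 34, length.out = 7),
                         stim_duration = 10) {
  n_stim <- length(stim_onsets)
  dur <- n_samples / functional_rate
  if (n_stim > 1 && any(diff(sort(stim_onsets)) < stim_duration))
    stop_invalid("stimulation periods overlap")
  if (n_stim > 0 && (min(stim_onsets) < 0 ||
                     max(stim_onsets) + stim_duration > dur))
    stop_invalid("stimulation periods fall outside the session")
  structure(list(
    functional_rate = functional_rate, n_samples = as.integer(n_samples),
    stim_onsets = as.numeric(stim_onsets), stim_duration = stim_duration,
    n_stim_periods = n_stim
  ), class = "session_spec")
}

#' Mechanical index
#'
#' MI = derated peak pressure (MPa) / sqrt(centre frequency (MHz)),
#' truncated (not rounded) to two decimals as conventionally reported.
#'
#' @param pressure_mpa Derated peak pressure, MPa.
#' @param fc_mhz Centre frequency, MHz.
#' @return Dimensionless MI, truncated to two decimals.
#' @examples
#' mechanical_index(3.39, 4)  # 1.69
#' @export
mechanical_index <- function(pressure_mpa, fc_mhz) {
  if (any(fc_mhz <= 0)) stop_invalid("fc_mhz must be positive")
  if (any(pressure_mpa < 0)) stop_invalid("pressure_mpa must be non-negative")
  mi <- pressure_mpa / sqrt(fc_mhz)
  floor(mi * 100 + 1e-9) / 100
}

#' Cycles in a continuous tone burst
#' @param pulse_duration Pulse duration, s.
#' @param fc Carrier frequency, Hz.
#' @return Integer cycle count (`round(pulse_duration * fc)`).
#' @examples
#' pulse_cycles(0.080, 4e6)  # 320000
#' @export
pulse_cycles <- function(pulse_duration, fc) {
  if (any(pulse_duration < 0) || any(fc < 0))
    stop_invalid("pulse_duration and fc must be non-negative")
  as.integer(round(pulse_duration * fc))
}

#' Number of FUS pulses in a sonication train
#'
#' Pulse onsets fall at `k / prf`, `k = 0 .. n - 1`.
#'
#' @param duration Train duration, s.
#' @param prf Pulse repetition frequency, Hz.
#' @return Integer pulse count with attribute `onsets` (s).
#' @examples
#' pulses_per_session(120, 1)  # 120 pulses
#' @export
pulses_per_session <- function(duration, prf) {
  if (prf <= 0) stop_invalid("prf must be positive")
  if (duration < 0) stop_invalid("duration must be non-negative")
  n <- as.integer(floor(duration * prf + 1e-9))
  structure(n, onsets = if (n > 0) (seq_len(n) - 1) / prf else numeric(0))
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf("<transducer_spec> %d elements, pitch %.0f um, fc %.3f MHz, fs %.1f MHz, c %.0f m/s\n",
              x$n_elements, x$pitch * 1e6, x$carrier_freq / 1e6,
              x$sampling_freq / 1e6, x$sound_speed))
  invisible(x)
}

#' @export
print.plane_wave_scheme <- function(x, ...) {
  cat(sprintf("<plane_wave_scheme> %d angles in +/-%g deg, %.1f cycles\n",
              x$n_angles, x$max_angle, x$tx_cycles))
  invisible(x)
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> %d samples @ %g Hz, %d x %g s stimulations\n",
              x$n_samples, x$functional_rate, x$n_stim_periods,
              x$stim_duration))
  invisible(x)
}

#' Read an acquisition configuration from YAML
#'
#' The file may contain `transducer`, `doppler_scheme`,
#' `displacement_scheme`, `fus` and `session` blocks whose keys are the
#' constructor arguments; missing blocks fall back to the package presets.
#'
#' @param path Path to a YAML file.
#' @return Named list of validated spec objects.
#' @export
read_acquisition_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(block, ctor, preset) {
    if (is.null(raw[[block]])) return(preset)
    do.call(ctor, raw[[block]])
  }
  list(
    transducer = build("transducer", transducer_spec, transducer_spec()),
    doppler_scheme = build("doppler_scheme", plane_wave_scheme,
                           doppler_scheme_preset()),
    displacement_scheme = build("displacement_scheme", plane_wave_scheme,
                                displacement_scheme_preset()),
    fus = build("fus", fus_pulse_spec, fus_pulse_spec()),
    session = build("session", session_spec, session_spec())
  )
}

#' Validate an acquisition configuration file
#'
#' @param path Path to a YAML file.
#' @return `TRUE` invisibly if every block validates; otherwise an error.
#' @export
validate_acquisition_config <- function(path) {
  invisible(!is.null(read_acquisition_config(path)))
}
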