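#' Saturation / readout sequence settings
#'
#' Describes a pulsed-saturation CEST acquisition: a train of `n_pulses`
#' shaped pulses of amplitude `b1_uT` and duration `tp_ms`, separated by
#' `td_ms` of free relaxation (duty cycle `tp / (tp + td)`), repeated at
#' every entry of `offsets_ppm`. TE/TR are recorded protocol metadata; by
#' default they do not alter the simulated Z-value.
#'
#' @param b1_uT nominal saturation amplitude (microtesla).
#' @param tp_ms pulse duration (ms).
#' @param td_ms interpulse delay (ms).
#' @param n_pulses number of saturation pulses.
#' @param offsets_ppm ordered saturation offsets (ppm relative to water).
#' @param ref_offset_ppm offset of the unsaturated reference image (ppm).
#' @param b0_T static field strength (Tesla).
#' @param te_ms,tr_ms echo / repetition time (ms), metadata only.
#' @param pulse_shape `"gauss"` (truncated Gaussian envelope) or `"block"`.
#' @return an object of class `cest_sequence`.
#' @examples
#' seq <- cest_sequence(b1_uT = 0.9, offsets_ppm = seq(-5, 5, length.out = 50))
#' seq$dc
#' @export
cest_sequence <- function(b1_uT = 0.9, tp_ms = 100, td_ms = 100,
                          n_pulses = 10L,
                          offsets_ppm = seq(-5, 5, length.out = 50),
                          ref_offset_ppm = 300, b0_T = 3,
                          te_ms = 20, tr_ms = 30,
                          pulse_shape = c("gauss", "block")) {
  pulse_shape <- match.arg(pulse_shape)
  stopifnot(b1_uT >= 0, tp_ms > 0, td_ms >= 0, n_pulses >= 1,
            length(offsets_ppm) >= 1, b0_T > 0)
  structure(list(b1_uT = b1_uT, tp_ms = tp_ms, td_ms = td_ms,
                 dc = tp_ms / (tp_ms + td_ms), n_pulses = as.integer(n_pulses),
                 offsets_ppm = as.numeric(offsets_ppm),
                 dyn = length(offsets_ppm),
                 ref_offset_ppm = ref_offset_ppm, b0_T = b0_T,
                 te_ms = te_ms, tr_ms = tr_ms, pulse_shape = pulse_shape),
            class = "cest_sequence")
}

#' @export
print.cest_sequence <- function(x, ...) {
  cat(sprintf(
    "CEST sequence: B1 %.2f uT, %d x %g ms pulses (DC %.2f, %s), %d offsets [%.2f, %.2f] ppm @ %g T\n",
    x$b1_uT, x$n_pulses, x$tp_ms, x$dc, x$pulse_shape, x$dyn,
    min(x$offsets_ppm), max(x$offsets_ppm), x$b0_T))
  invisible(x)
}

#' Draw a random sequence from the protocol ranges
#'
#' Samples the saturation settings uniformly from [protocol_ranges()]:
#' offset half-range, pulse count, pulse duration (delay fixed by duty
#' cycle 0.5) and TE/TR metadata. The offset axis is symmetric about 0 and
#' equidistant with `dyn` entries.
#'
#' @param ranges interval list, see [protocol_ranges()].
#' @param b1_uT saturation amplitude (not part of the stated ranges; the
#'   in vivo protocol value 0.9 uT is the default).
#' @return a [cest_sequence()].
#' @export
sample_sequence <- function(ranges = protocol_ranges(), b1_uT = 0.9) {
  s <- ranges$sequence
  dw <- runif1(s$dw_half_ppm)
  tp <- runif1(s$tp_ms)
  td <- tp * (1 - s$dc) / s$dc
  cest_sequence(b1_uT = b1_uT, tp_ms = tp, td_ms = td,
                n_pulses = sample(seq(s$n_pulses[1], s$n_pulses[2]), 1),
                offsets_ppm = seq(-dw, dw, length.out = s$dyn),
                te_ms = runif1(s$te_ms), tr_ms = runif1(s$tr_ms))
}

# ppm -> rad/s at the sequence field strength
ppm_to_rad <- function(ppm, b0_T) {
  ppm * 1e-6 * 2 * pi * .GAMMA_HZ_PER_UT * 1e6 * b0_T
}

# piecewise-constant amplitudes (rad/s) of one shaped pulse.  The Gaussian
# envelope is truncated at +/-2.5 sigma and area-calibrated so the mean
# amplitude over tp equals the nominal B1.
pulse_segments <- function(seq, n_seg = 64L) {
  w1 <- 2 * pi * .GAMMA_HZ_PER_UT * seq$b1_uT   # rad/s
  if (seq$pulse_shape == "block" || seq$b1_uT == 0)
    return(list(w1 = w1, dt = seq$tp_ms / 1000))
  tc <- (seq_len(n_seg) - 0.5) / n_seg - 0.5    # in units of tp, centred
  env <- exp(-(tc * 5)^2 / 2)                   # sigma_pulse = tp / 5
  env <- env / mean(env)
  list(w1 = w1 * env, dt = seq$tp_ms / 1000 / n_seg)
}
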