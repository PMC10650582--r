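#' Proton pool parameters
#'
#' A pool is a population of exchangeable protons (free water or a labile
#' metabolite site) characterised by its relaxation times, chemical shift
#' relative to water, exchange rate towards water, and concentration.
#'
#' @param t1_s longitudinal relaxation time (s).
#' @param t2_ms transverse relaxation time (ms).
#' @param delta_ppm chemical shift relative to water (ppm); 0 for water.
#' @param k_hz exchange rate pool -> water (Hz); 0 for water.
#' @param conc_mM proton concentration (mM). The water pool is the
#'   reference and its concentration is fixed at 111000 mM (2 x 55.5 M).
#' @return an object of class `pool_params`.
#' @examples
#' water_pool(t1_s = 1.5, t2_ms = 80)
#' creatine <- pool_params(1.2, 10, delta_ppm = 1.9, k_hz = 950, conc_mM = 100)
#' @export
pool_params <- function(t1_s, t2_ms, delta_ppm, k_hz, conc_mM) {
  stopifnot(t1_s > 0, t2_ms > 0, k_hz >= 0, conc_mM >= 0)
  structure(list(t1_s = t1_s, t2_ms = t2_ms, delta_ppm = delta_ppm,
                 k_hz = k_hz, conc_mM = conc_mM),
            class = "pool_params")
}

#' @rdname pool_params
#' @export
water_pool <- function(t1_s = 1.5, t2_ms = 100) {
  pool_params(t1_s, t2_ms, delta_ppm = 0, k_hz = 0, conc_mM = .WATER_CONC_MM)
}

#' @export
print.pool_params <- function(x, ...) {
  cat(sprintf("pool: T1 %.3g s, T2 %.3g ms, shift %+.2f ppm, k %.0f Hz, %.0f mM\n",
              x$t1_s, x$t2_ms, x$delta_ppm, x$k_hz, x$conc_mM))
  invisible(x)
}

#' Parameter ranges of the simulation protocol
#'
#' Intervals from which phantom pool parameters and sequence settings are
#' drawn: water T1 0.5--2.5 s and T2 40--500 ms; metabolite T1 0.5--2.5 s,
#' T2 1--20 ms, exchange rate 50--4000 Hz, concentration 0--800 mM, shift
#' 0.5--5 ppm; saturation-offset half-range 4--6 ppm, 8--40 pulses of
#' 20--100 ms at duty cycle 0.5, TE 2--40 ms, TR 11--60 ms, 50 offsets.
#'
#' @return a nested list of `c(min, max)` intervals with components
#'   `water`, `metabolite` and `sequence`.
#' @export
protocol_ranges <- function() {
  list(
    water = list(t1_s = c(0.5, 2.5), t2_ms = c(40, 500)),
    metabolite = list(t1_s = c(0.5, 2.5), t2_ms = c(1, 20),
                      k_hz = c(50, 4000), conc_mM = c(0, 800),
                      delta_ppm = c(0.5, 5.0)),
    sequence = list(dw_half_ppm = c(4, 6), n_pulses = c(8L, 40L),
                    tp_ms = c(20, 100), dc = 0.5, te_ms = c(2, 40),
                    tr_ms = c(11, 60), dyn = 50L)
  )
}

runif1 <- function(rg) stats::runif(1, rg[1], rg[2])

# one uniform draw of a water / metabolite pool from the stated ranges
sample_water_pool <- function(ranges) {
  water_pool(t1_s = runif1(ranges$water$t1_s), t2_ms = runif1(ranges$water$t2_ms))
}

sample_metabolite_pool <- function(ranges) {
  m <- ranges$metabolite
  pool_params(t1_s = runif1(m$t1_s), t2_ms = runif1(m$t2_ms),
              delta_ppm = runif1(m$delta_ppm), k_hz = runif1(m$k_hz),
              conc_mM = runif1(m$conc_mM))
}
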