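# Monte Carlo detector chain: expected photons -> realized photons (shot
# noise) -> photoelectrons (QE thinning + dark current) -> EM amplification
# (Gamma cascade model) -> readout (binning, Gaussian read noise, linear A/D
# conversion, offset, quantization, clipping). Every stochastic stage is
# bit-reproducible under a fixed seed; the chain wrappers fan one master seed
# out into independent per-stage streams.

#' EMCCD/CMOS camera configuration
#'
#' Defaults are a typical back-illuminated EMCCD operating point; the
#' published supporting material holds instrument-specific values, so treat
#' every field as configuration, not truth.
#'
#' @param qe Quantum efficiency in \[0, 1\].
#' @param readout_noise Readout noise RMS, electrons.
#' @param dark_current Dark current, electrons/pixel/s.
#' @param em_gain Electron-multiplying gain (>= 1; 1 disables the register).
#' @param conversion_gain Electrons per A/D count (> 0).
#' @param offset Bias offset, A/D counts.
#' @param bit_depth A/D bit depth, 8..16.
#' @param binning Hardware binning factor b (b x b pixel blocks summed
#'   before readout).
#' @param exposure_s Exposure time per frame, seconds.
#' @return A `camera_config` object.
#' @export
camera_config <- function(qe = 0.92, readout_noise = 100, dark_current = 0.005,
                          em_gain = 300, conversion_gain = 5.8, offset = 2000,
                          bit_depth = 16L, binning = 1L, exposure_s = 0.030) {
  if (qe < 0 || qe > 1) stop_arg("'qe' must be in [0, 1]")
  if (em_gain < 1) stop_arg("'em_gain' must be >= 1")
  if (conversion_gain <= 0) stop_arg("'conversion_gain' must be positive")
  if (!(bit_depth %in% 8:16)) stop_arg("'bit_depth' must be in 8..16")
  if (binning < 1) stop_arg("'binning' must be >= 1")
  if (readout_noise < 0 || dark_current < 0)
    stop_arg("noise terms must be >= 0")
  if (exposure_s <= 0) stop_arg("'exposure_s' must be positive")
  structure(list(qe = qe, readout_noise = readout_noise,
                 dark_current = dark_current, em_gain = em_gain,
                 conversion_gain = conversion_gain, offset = offset,
                 bit_depth = as.integer(bit_depth),
                 binning = as.integer(binning), exposure_s = exposure_s),
            class = "camera_config")
}

#' Photomultiplier (PMT) configuration
#'
#' Photon-counting PMT model for the confocal detector: detected pulses are
#' QE-thinned photons plus Poisson dark counts; the digital value is a linear
#' conversion of the pulse count.
#'
#' @param qe Quantum efficiency in \[0, 1\].
#' @param dark_count_rate Dark counts per second.
#' @param gain Pulse amplification factor applied before A/D conversion.
#' @param conversion_gain Pulses (times gain) per A/D count.
#' @param offset Bias offset, A/D counts.
#' @param bit_depth A/D bit depth, 8..16.
#' @return A `pmt_config` object.
#' @export
pmt_config <- function(qe = 0.30, dark_count_rate = 50, gain = 1,
                       conversion_gain = 1, offset = 0, bit_depth = 12L) {
  if (qe < 0 || qe > 1) stop_arg("'qe' must be in [0, 1]")
  if (gain < 1) stop_arg("'gain' must be >= 1")
  if (conversion_gain <= 0) stop_arg("'conversion_gain' must be positive")
  if (!(bit_depth %in% 8:16)) stop_arg("'bit_depth' must be in 8..16")
  if (dark_count_rate < 0) stop_arg("'dark_count_rate' must be >= 0")
  structure(list(qe = qe, dark_count_rate = dark_count_rate, gain = gain,
                 conversion_gain = conversion_gain, offset = offset,
                 bit_depth = as.integer(bit_depth)), class = "pmt_config")
}

new_digital_image <- function(mat, bit_depth, saturated) {
  structure(mat, units = "A/D counts", bit_depth = as.integer(bit_depth),
            saturated = saturated,
            class = c("digital_image", "matrix", "array"))
}

#' @export
print.digital_image <- function(x, ...) {
  cat(sprintf("<digital_image> %d x %d px, %d-bit, units %s%s\n",
              nrow(x), ncol(x), attr(x, "bit_depth"), attr(x, "units"),
              if (isTRUE(attr(x, "saturated"))) " [saturated]" else ""))
  cat(sprintf("  range %d .. %d counts, mean %.2f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @export
plot.digital_image <- function(x, main = "digital image (A/D counts)", ...) {
  graphics::image(seq_len(nrow(x)), seq_len(ncol(x)), unclass(x),
                  col = grDevices::gray.colors(256, 0, 1), asp = 1,
                  xlab = "pixel x", ylab = "pixel y", main = main,
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Photon shot noise
#'
#' Independent Poisson draw per pixel with mean equal to the expected photon
#' count.
#'
#' @param expected An [expected_image()][expected_image_tirf] or non-negative
#'   numeric matrix.
#' @param seed Integer seed (optional but required for reproducibility).
#' @return Integer photon-count matrix of the same shape.
#' @export
sample_photons <- function(expected, seed = NULL) {
  ex <- unclass(expected)
  if (any(ex < 0) || any(!is.finite(ex)))
    stop_arg("expected image must be finite and >= 0")
  out <- with_seed(seed, stats::rpois(length(ex), ex))
  matrix(out, nrow(ex), ncol(ex))
}

#' Photons to photoelectrons
#'
#' Binomial thinning of realized photons with probability QE (preserving the
#' photon -> photoelectron accounting), plus Poisson dark electrons.
#'
#' @param photons Integer photon image.
#' @param qe Quantum efficiency in \[0, 1\].
#' @param dark_electrons Mean dark electrons per pixel for this exposure
#'   (dark current x exposure time).
#' @param seed Integer seed.
#' @return Integer photoelectron matrix.
#' @export
photoelectron_conversion <- function(photons, qe, dark_electrons = 0,
                                     seed = NULL) {
  if (qe < 0 || qe > 1) stop_arg("'qe' must be in [0, 1]")
  if (dark_electrons < 0) stop_arg("'dark_electrons' must be >= 0")
  ph <- as.vector(photons)
  out <- with_seed(seed, {
    pe <- if (qe == 1) ph else stats::rbinom(length(ph), ph, qe)
    if (dark_electrons > 0)
      pe <- pe + stats::rpois(length(ph), dark_electrons)
    pe
  })
  matrix(out, nrow(photons), ncol(photons))
}

#' Electron-multiplying amplification
#'
#' The EM register is modeled by its high-gain limit: `n` input electrons
#' produce `Gamma(shape = n, scale = g)` output electrons. This reproduces
#' the mean `n g` and variance `2 n g^2` of the cascade branching process —
#' the excess noise factor of 2 in variance — without simulating hundreds of
#' register stages. `em_gain = 1` is an exact identity; zero input maps to
#' zero output.
#'
#' @param photoelectrons Integer photoelectron image.
#' @param em_gain EM gain (>= 1).
#' @param seed Integer seed.
#' @return Real-valued electron matrix.
#' @export
em_amplify <- function(photoelectrons, em_gain, seed = NULL) {
  if (em_gain < 1) stop_arg("'em_gain' must be >= 1")
  pe <- as.vector(photoelectrons)
  if (em_gain == 1) return(matrix(as.numeric(pe), nrow(photoelectrons),
                                  ncol(photoelectrons)))
  out <- with_seed(seed, {
    res <- numeric(length(pe))
    pos <- pe > 0
    res[pos] <- stats::rgamma(sum(pos), shape = pe[pos], scale = em_gain)
    res
  })
  matrix(out, nrow(photoelectrons), ncol(photoelectrons))
}

# Sum b x b blocks (hardware binning: charge is combined before readout).
bin_blocks <- function(m, b) {
  if (b == 1L) return(m)
  nx <- floor(nrow(m) / b) * b
  ny <- floor(ncol(m) / b) * b
  m <- m[seq_len(nx), seq_len(ny), drop = FALSE]
  x <- rowsum(m, rep(seq_len(nx / b), each = b))
  t(rowsum(t(x), rep(seq_len(ny / b), each = b)))
}

#' Readout and A/D conversion
#'
#' Charge is summed over `b x b` binning blocks, a single Gaussian readout
#' noise draw is added per binned pixel, and the result is linearly converted
#' to A/D counts: divide by the conversion gain, add the offset, floor to an
#' integer and clip to the bit-depth range. Saturated pixels are clipped,
#' never wrapped, and flagged in the `saturated` attribute.
#'
#' @param electrons Real-valued electron image.
#' @param cam A [camera_config()].
#' @param seed Integer seed.
#' @return A `digital_image`.
#' @export
readout <- function(electrons, cam, seed = NULL) {
  stopifnot(inherits(cam, "camera_config"))
  e <- bin_blocks(unclass(electrons), cam$binning)
  e <- with_seed(seed, {
    if (cam$readout_noise > 0)
      e + stats::rnorm(length(e), 0, cam$readout_noise)
    else e
  })
  adu <- floor(e / cam$conversion_gain + cam$offset)
  top <- 2^cam$bit_depth - 1
  sat <- any(adu > top)
  adu <- pmin(pmax(adu, 0), top)
  new_digital_image(matrix(as.integer(adu), nrow(e), ncol(e)),
                    cam$bit_depth, sat)
}

#' Full EMCCD detection chain
#'
#' Composition `sample_photons` -> `photoelectron_conversion` ->
#' `em_amplify` -> `readout`, converting an expected image in photons to a
#' digital image in A/D counts. One master seed fans out into four
#' independent per-stage streams, so the chain is bit-reproducible and the
#' stages stay decoupled. Dark-current electrons pass through EM
#' amplification (they are charge).
#'
#' @param expected An expected image (photons).
#' @param cam A [camera_config()].
#' @param seed Integer master seed.
#' @return A `digital_image`.
#' @export
emccd_chain <- function(expected, cam, seed = NULL) {
  stopifnot(inherits(cam, "camera_config"))
  seeds <- if (is.null(seed)) rep(list(NULL), 4L) else derive_seeds(seed, 4L)
  ph <- sample_photons(expected, seeds[[1L]])
  pe <- photoelectron_conversion(ph, cam$qe,
                                 cam$dark_current * cam$exposure_s,
                                 seeds[[2L]])
  el <- em_amplify(pe, cam$em_gain, seeds[[3L]])
  readout(el, cam, seeds[[4L]])
}

#' PMT detection chain (photon counting)
#'
#' Per pixel: Poisson photon draw from the expected image, binomial QE
#' thinning, plus Poisson dark counts (`dark_count_rate x dwell`), giving the
#' detected pulse count; the digital value is
#' `floor(pulses * gain / conversion_gain + offset)` clipped to the bit
#' depth. The pre-gain pulse image — the quantity a photon-counting confocal
#' actually reports — is attached as attribute `pulse_image`.
#'
#' @param expected An expected image (photons).
#' @param pmt A [pmt_config()].
#' @param scan A [scan_config()] (supplies the per-pixel dwell time for dark
#'   counts).
#' @param seed Integer master seed.
#' @return A `digital_image` with attribute `pulse_image`.
#' @export
pmt_chain <- function(expected, pmt, scan, seed = NULL) {
  stopifnot(inherits(pmt, "pmt_config"), inherits(scan, "scan_config"))
  seeds <- if (is.null(seed)) rep(list(NULL), 3L) else derive_seeds(seed, 3L)
  ph <- sample_photons(expected, seeds[[1L]])
  pulses <- photoelectron_conversion(ph, pmt$qe, 0, seeds[[2L]])
  dark <- pmt$dark_count_rate * scan$dwell_s
  if (dark > 0)
    pulses <- pulses + with_seed(seeds[[3L]],
                                 matrix(stats::rpois(length(pulses), dark),
                                        nrow(pulses), ncol(pulses)))
  adu <- floor(pulses * pmt$gain / pmt$conversion_gain + pmt$offset)
  top <- 2^pmt$bit_depth - 1
  sat <- any(adu > top)
  adu <- pmin(pmax(adu, 0), top)
  out <- new_digital_image(matrix(as.integer(adu), nrow(pulses),
                                  ncol(pulses)), pmt$bit_depth, sat)
  attr(out, "pulse_image") <- pulses
  out
}
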