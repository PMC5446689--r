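# HDR tone mapping: luminance / equalization / gamma, then quantization.
#
# Compositing many channels in 32-bit float deliberately produces pixels
# above the display range; instead of clipping (which collapses colocalized
# detail to a flat highlight), a monotone tone curve compresses the high end
# so that relative intensity differences survive quantization.

#' Tone-mapping parameters
#'
#' @param luminance positive scale applied uniformly to intensity.
#' @param gamma positive; mid-tone contrast, applied as `v^(1/gamma)` after
#'   equalization.  Independent of any per-channel gamma.
#' @param equalization in `[0, 1]`; strength of the rational compression
#'   curve `v -> v / ((1 + e)(1 + e v))`, which pulls over-range intensity
#'   back under the display ceiling while preserving the brightness order
#'   of every pixel (identity at 0).  Mid equalization (0.5) maps HDR
#'   values up to about 6 into `[0, 1)` without clipping.
#' @return an object of class `fv_tone_params`.
#' @export
tone_params <- function(luminance = 1, gamma = 1, equalization = 0) {
  if (luminance <= 0) stop("luminance must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  if (equalization < 0 || equalization > 1) stop("equalization must be in [0, 1]")
  structure(list(luminance = luminance, gamma = gamma, equalization = equalization),
            class = "fv_tone_params")
}

tone_curve <- function(x, params) {
  v <- params$luminance * x
  e <- params$equalization
  if (e > 0) v <- v / ((1 + e) * (1 + e * v))
  v^(1 / params$gamma)
}

#' Tone-map an HDR frame buffer to a display image
#'
#' Per component, in fixed order: luminance scaling, the equalization curve,
#' the gamma map, then the clamp to `[0, 1]`.  The curve is applied to
#' un-premultiplied color (color divided by alpha where alpha > 0) and the
#' result re-premultiplied by the full (unclamped) alpha, so additive
#' accumulation across channels still brightens -- and, at identity
#' parameters, clips -- before the final clamp composites the image over the
#' display background.
#'
#' @param hdr an `fv_framebuffer` (premultiplied RGBA, components >= 0).
#' @param params a [tone_params()] object.
#' @param background display background RGB, default black.
#' @return H x W x 3 array with components in `[0, 1]`.
#' @export
tone_map <- function(hdr, params = tone_params(), background = c(0, 0, 0)) {
  stopifnot(length(dim(hdr)) == 3, dim(hdr)[3] == 4)
  if (min(hdr) < 0) stop("negative HDR input: upstream frame buffer invariant violated")
  a <- hdr[, , 4]
  ad <- clamp01(a)
  out <- array(0, c(dim(hdr)[1], dim(hdr)[2], 3))
  pos <- a > 0
  for (k in 1:3) {
    comp <- hdr[, , k]
    un <- comp
    un[pos] <- comp[pos] / a[pos]
    toned <- tone_curve(un, params)
    toned[pos] <- toned[pos] * a[pos]  # re-premultiply with the full alpha
    out[, , k] <- clamp01(toned) + background[k] * (1 - ad)
  }
  out
}

#' Quantize a display image to 8 or 10 bits
#'
#' `round(v * (2^bits - 1))`, round-half-up; 10-bit output is intended to be
#' written into 16-bit containers.
#'
#' @param img array with components in `[0, 1]`.
#' @param bits 8 or 10.
#' @return integer array of the same shape.
#' @export
quantize <- function(img, bits = 8) {
  if (!bits %in% c(8, 10)) stop("bits must be 8 or 10")
  if (min(img) < 0 || max(img) > 1) stop("quantize expects components in [0, 1]")
  full <- 2^bits - 1
  array(as.integer(floor(img * full + 0.5)), dim(img))
}
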