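# Intensity transforms (the GDBSP action set) and the four histogram-based
# benchmark preprocessors.  All transforms operate in floating point on the
# 0-255 scale; 8-bit quantization happens once, at final render.

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Quantize a float image to 8-bit
#'
#' @param img `section_image` or matrix on the 0--255 scale.
#' @return Same type, values rounded to integers in \[0, 255\].
#' @export
quantize8 <- function(img) {
  with_pixels(img, round(clip255(as_pixels(img))))
}

#' Gamma adjustment
#'
#' `out = 255 * (in/255)^gamma`, computed in floating point and clipped.
#' Endpoints 0 and 255 are fixed for any gamma; gamma < 1 brightens.
#'
#' @param img `section_image` or numeric matrix (0--255 scale).
#' @param gamma positive exponent.
#' @return Same type as `img`, unquantized float pixels.
#' @export
apply_gamma <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0)
    stop("`gamma` must be a single positive number")
  px <- as_pixels(img)
  with_pixels(img, clip255(255 * (px / 255)^gamma))
}

#' Brightness adjustment
#'
#' Additive offset: `out = in + amount * 255`, clipped to \[0, 255\].
#' An `amount` of +0.10 lifts every pixel by 10% of full scale.
#'
#' @param img `section_image` or numeric matrix.
#' @param amount signed fraction, `|amount| <= 1`.
#' @return Same type as `img`, unquantized float pixels.
#' @export
apply_brightness <- function(img, amount) {
  if (!is.numeric(amount) || length(amount) != 1 || !is.finite(amount) ||
      abs(amount) > 1)
    stop("brightness `amount` must be a single number with |amount| <= 1")
  px <- as_pixels(img)
  with_pixels(img, clip255(px + amount * 255))
}

#' Contrast adjustment
#'
#' Scales deviations about mid-scale: `out = 127.5 + (1 + amount) *
#' (in - 127.5)`, clipped.  Mid-gray 127.5 is a fixed point; `amount` of
#' +0.10 stretches contrast by 10%.
#'
#' @param img `section_image` or numeric matrix.
#' @param amount signed fraction, must exceed -1.
#' @return Same type as `img`, unquantized float pixels.
#' @export
apply_contrast <- function(img, amount) {
  if (!is.numeric(amount) || length(amount) != 1 || !is.finite(amount) ||
      amount <= -1)
    stop("contrast `amount` must be a single number > -1")
  px <- as_pixels(img)
  with_pixels(img, clip255(127.5 + (1 + amount) * (px - 127.5)))
}

#' Render an adjustment chain from the raw image
#'
#' Applies the chain's transforms in order, always starting from the raw
#' (untouched) image and staying in floating point throughout; the result
#' is quantized to 8-bit once at the end.  Re-rendering from raw rather
#' than stacking onto previously adjusted images prevents cumulative
#' rounding drift and means an erroneous adjustment never destroys
#' information needed later.
#'
#' @param raw `section_image` or numeric matrix (the raw pixels).
#' @param chain an [adjust_chain()].
#' @param quantize round to 8-bit at the end (default `TRUE`).  Searches
#'   evaluating candidate chains keep the float path.
#' @return Same type as `raw`.
#' @export
render_chain <- function(raw, chain, quantize = TRUE) {
  stopifnot(inherits(chain, "adjust_chain"))
  px <- as_pixels(raw)
  out <- raw
  if (length(chain) > 0) {
    for (i in seq_along(chain$ops)) {
      out <- switch(chain$ops[i],
        gamma      = apply_gamma(out, chain$amounts[i]),
        brightness = apply_brightness(out, chain$amounts[i]),
        contrast   = apply_contrast(out, chain$amounts[i]),
        stop(sprintf("invalid op in chain: '%s'", chain$ops[i])))
    }
  }
  if (quantize) quantize8(out) else out
}

#' Difference-of-Gaussians band-pass filter
#'
#' Subtracts a strongly blurred copy from a lightly blurred copy,
#' attenuating structure outside the band between the two scales, then
#' rescales the response affinely to \[0, 255\].
#'
#' @param img `section_image` or numeric matrix.
#' @param sigma_low,sigma_high Gaussian standard deviations in pixels,
#'   `0 < sigma_low < sigma_high`.
#' @return Same type as `img`, 8-bit.
#' @export
difference_of_gaussians <- function(img, sigma_low = 1, sigma_high = 10) {
  if (!(sigma_high > sigma_low && sigma_low > 0))
    stop("need sigma_high > sigma_low > 0")
  px <- as_pixels(img) / 255
  # truncate the Gaussian support so small images stay filterable
  radius_for <- function(sigma) {
    r <- 2 * ceiling(3 * sigma) + 1          # odd full kernel size
    lim <- min(dim(px))
    if (lim %% 2 == 0) lim <- lim - 1
    max(3, min(r, lim))
  }
  lo <- EBImage::gblur(px, sigma = sigma_low, radius = radius_for(sigma_low))
  hi <- EBImage::gblur(px, sigma = sigma_high, radius = radius_for(sigma_high))
  d <- lo - hi
  rng <- range(d)
  out <- if (diff(rng) == 0) matrix(127.5, nrow(px), ncol(px))
         else (d - rng[1]) / diff(rng) * 255
  quantize8(with_pixels(img, out))
}

#' Global histogram equalization
#'
#' Remaps intensities through the image's own cumulative distribution so
#' the output histogram is as uniform as 8-bit quantization allows.
#'
#' @param img `section_image` or numeric matrix.
#' @return Same type as `img`, 8-bit.
#' @export
hist_equalize <- function(img) {
  px <- as_pixels(img)
  out <- EBImage::equalize(px / 255, range = c(0, 1), levels = 256) * 255
  quantize8(with_pixels(img, out))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Histogram equalization as a sliding-window operation, with the local
#' cumulative distribution clipped to limit over-amplification of
#' near-constant regions.
#'
#' @param img `section_image` or numeric matrix.
#' @param window tile size in pixels (>= 8); the image is divided into
#'   roughly `dim/window` tiles per axis.
#' @param clip_limit normalized clip limit in (0, 1\]; the local histogram
#'   is clipped at `clip_limit * 256` times the uniform bin height.
#' @return Same type as `img`, 8-bit.
#' @export
adaptive_hist_equalize <- function(img, window = NULL, clip_limit = 0.01) {
  px <- as_pixels(img)
  if (is.null(window)) window <- max(8, floor(min(dim(px)) / 8))
  if (!is.numeric(window) || window < 8)
    stop("`window` must be >= 8 pixels")
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1)
    stop("`clip_limit` must be in (0, 1]")
  nx <- max(1, round(ncol(px) / window))
  ny <- max(1, round(nrow(px) / window))
  out <- EBImage::clahe(px / 255, nx = nx, ny = ny, bins = 256,
                        limit = clip_limit * 256) * 255
  quantize8(with_pixels(img, out))
}

#' Histogram matching
#'
#' Monotone remapping of intensities so that the output's empirical
#' cumulative distribution matches that of a target image (e.g. the
#' expert-designated reference section).
#'
#' @param img `section_image` or numeric matrix to remap.
#' @param target_img image supplying the target histogram.
#' @return Same type as `img`, 8-bit.
#' @export
hist_match <- function(img, target_img) {
  px <- round(clip255(as_pixels(img)))
  tg <- round(clip255(as_pixels(target_img)))
  cdf_src <- cumsum(tabulate(px + 1, nbins = 256)) / length(px)
  cdf_tgt <- cumsum(tabulate(tg + 1, nbins = 256)) / length(tg)
  # For each source level, the smallest target level whose CDF reaches the
  # source quantile; monotone by construction.
  lut <- vapply(cdf_src, function(q) which(cdf_tgt >= q - 1e-12)[1] - 1,
                numeric(1))
  with_pixels(img, matrix(lut[px + 1], nrow(px), ncol(px)))
}

#' Apply a named benchmark preprocessor
#'
#' Dispatch over the non-semantic preprocessing methods compared against
#' SP/BSP/GDBSP: raw (no-op), difference of Gaussians, histogram
#' equalization, adaptive histogram equalization, and histogram matching.
#'
#' @param img `section_image` or matrix.
#' @param method one of `"raw"`, `"dog"`, `"he"`, `"ahe"`, `"hm"`.
#' @param target_img reference image, required for `"hm"`.
#' @param ... further arguments passed to the specific preprocessor.
#' @return Preprocessed image, same type as `img`.
#' @export
preprocess <- function(img, method = c("raw", "dog", "he", "ahe", "hm"),
                       target_img = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    raw = img,
    dog = difference_of_gaussians(img, ...),
    he  = hist_equalize(img),
    ahe = adaptive_hist_equalize(img, ...),
    hm  = {
      if (is.null(target_img))
        stop("histogram matching needs a `target_img`")
      hist_match(img, target_img)
    })
}
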