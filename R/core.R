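#' @importFrom stats rnorm runif sd
NULL

# Class codes used throughout: 0 = none (background), 1 = risk (ischemic
# area-at-risk), 2 = normal (lectin-perfused tissue).  Colors are applied
# only at I/O time.
CLASS_LEVELS <- c("none", "risk", "normal")
CLASS_NONE   <- 0L
CLASS_RISK   <- 1L
CLASS_NORMAL <- 2L

#' Single-channel section image
#'
#' An 8-bit grayscale image of one fluorescence channel of a heart section.
#' Pixel values live on the 0--255 scale; both channels of one section must
#' share dimensions.
#'
#' @param pixels numeric matrix with values in \[0, 255\].
#' @param channel one of `"nuclear"` (nuclear stain, delimits tissue) or
#'   `"lectin"` (lectin-488, marks perfused tissue).
#' @param section_id opaque identifier.
#' @param resolution_nm_per_px acquisition resolution, nanometres per pixel.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, channel = c("nuclear", "lectin"),
                          section_id = "section",
                          resolution_nm_per_px = 541.67) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must be finite and within [0, 255]")
  structure(
    list(pixels = pixels, channel = channel, section_id = section_id,
         resolution_nm_per_px = resolution_nm_per_px),
    class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %s [%s] %dx%d px, range [%.1f, %.1f]\n",
              x$section_id, x$channel, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.section_image <- function(x) dim(x$pixels)

# Accept either a section_image or a bare matrix; return the pixel matrix.
as_pixels <- function(img) {
  if (inherits(img, "section_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else stop("expected a section_image or numeric matrix")
}

# Rebuild an image like `img` but with new pixels (keeps metadata).
with_pixels <- function(img, pixels) {
  if (inherits(img, "section_image")) { img$pixels <- pixels; img }
  else pixels
}

#' Per-pixel three-class segmentation map
#'
#' @param labels integer matrix over codes 0 (none), 1 (risk), 2 (normal).
#' @param section_id identifier of the section the map belongs to.
#' @return A `class_map` object.
#' @export
class_map <- function(labels, section_id = "section") {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || !all(labels %in% c(0L, 1L, 2L)))
    stop("labels must be 0 (none), 1 (risk) or 2 (normal)")
  structure(list(labels = labels, section_id = section_id),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:2, labels = CLASS_LEVELS))
  cat(sprintf("<class_map> %s %dx%d px (none %d, risk %d, normal %d)\n",
              x$section_id, nrow(x$labels), ncol(x$labels),
              tab[["none"]], tab[["risk"]], tab[["normal"]]))
  invisible(x)
}

#' @export
dim.class_map <- function(x) dim(x$labels)

as_labels <- function(x) {
  if (inherits(x, "class_map")) x$labels
  else if (is.matrix(x)) { storage.mode(x) <- "integer"; x }
  else stop("expected a class_map or integer matrix")
}

#' Per-pixel ensemble confidence map
#'
#' Stores the proportion of ensemble votes won by the plurality class at
#' each pixel, plus its section-wide mean `f` (the acquisition score used
#' by active deep learning).
#'
#' @param proportions numeric matrix of winning-vote fractions in \[0, 1\].
#' @param section_id identifier.
#' @return A `confidence_map` with fields `proportions` and
#'   `mean_confidence`.
#' @export
confidence_map <- function(proportions, section_id = "section") {
  if (!is.matrix(proportions) || anyNA(proportions) ||
      min(proportions) < 0 || max(proportions) > 1)
    stop("`proportions` must be a numeric matrix within [0, 1]")
  structure(list(proportions = proportions,
                 mean_confidence = mean(proportions),
                 section_id = section_id),
            class = "confidence_map")
}

#' Semantic metric of a segmented image
#'
#' The per-class-area intensity statistics that semantic preprocessing
#' steers: mean background and foreground pixel value on the 0--255 scale,
#' optionally with the per-region standard deviations (the 4-D coordinate
#' used by the gradient-descent variant).
#'
#' @param bg_mean,fg_mean region means on the 0--255 scale.
#' @param bg_std,fg_std optional region standard deviations (population).
#' @param degenerate flag set when one region was empty; searches skip
#'   adjustment for degenerate metrics.
#' @return A `semantic_metric` object.
#' @export
semantic_metric <- function(bg_mean, fg_mean, bg_std = NULL, fg_std = NULL,
                            degenerate = FALSE) {
  if (xor(is.null(bg_std), is.null(fg_std)))
    stop("bg_std and fg_std must be supplied together")
  structure(list(bg_mean = bg_mean, fg_mean = fg_mean,
                 bg_std = bg_std, fg_std = fg_std,
                 degenerate = isTRUE(degenerate)),
            class = "semantic_metric")
}

#' @export
print.semantic_metric <- function(x, ...) {
  if (is.null(x$bg_std))
    cat(sprintf("<semantic_metric> bg %.2f fg %.2f%s\n", x$bg_mean, x$fg_mean,
                if (x$degenerate) " (degenerate)" else ""))
  else
    cat(sprintf("<semantic_metric> bg %.2f±%.2f fg %.2f±%.2f%s\n",
                x$bg_mean, x$bg_std, x$fg_mean, x$fg_std,
                if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

metric_coords <- function(m) {
  stopifnot(inherits(m, "semantic_metric"))
  if (is.null(m$bg_std)) c(bg_mean = m$bg_mean, fg_mean = m$fg_mean)
  else c(bg_mean = m$bg_mean, fg_mean = m$fg_mean,
         bg_std = m$bg_std, fg_std = m$fg_std)
}

#' Euclidean distance between two semantic metrics
#'
#' 2-D (means only) for plain semantic preprocessing, 4-D (means and
#' standard deviations) for the gradient-descent variant.  Both metrics
#' must populate the same coordinates.
#'
#' @param m1,m2 `semantic_metric` objects.
#' @return Non-negative distance.
#' @export
metric_distance <- function(m1, m2) {
  c1 <- metric_coords(m1); c2 <- metric_coords(m2)
  if (length(c1) != length(c2))
    stop(sprintf(
      "metrics populate different coordinates (%d-D vs %d-D)",
      length(c1), length(c2)))
  sqrt(sum((c1 - c2)^2))
}

#' Ordered chain of intensity adjustments
#'
#' A sequence of gamma / brightness / contrast transforms.  Chains are
#' always re-rendered from the raw image in floating point (see
#' [render_chain()]); the empty chain is the identity.
#'
#' @param ops character vector over `"gamma"`, `"brightness"`, `"contrast"`.
#' @param amounts numeric vector, one per op.  Gamma amounts are the gamma
#'   exponent itself; brightness/contrast amounts are signed fractions.
#' @return An `adjust_chain` object.
#' @export
adjust_chain <- function(ops = character(), amounts = numeric()) {
  if (length(ops) != length(amounts))
    stop("`ops` and `amounts` must have equal length")
  if (!all(ops %in% c("gamma", "brightness", "contrast")))
    stop("ops must be 'gamma', 'brightness' or 'contrast'")
  structure(list(ops = as.character(ops), amounts = as.numeric(amounts)),
            class = "adjust_chain")
}

#' @export
length.adjust_chain <- function(x) length(x$ops)

chain_append <- function(chain, op, amount) {
  adjust_chain(c(chain$ops, op), c(chain$amounts, amount))
}

#' @export
print.adjust_chain <- function(x, ...) {
  if (length(x) == 0) cat("<adjust_chain> identity\n")
  else cat("<adjust_chain>",
           paste(sprintf("%s(%+.4g)", x$ops, x$amounts), collapse = " -> "),
           "\n")
  invisible(x)
}

#' @export
format.adjust_chain <- function(x, ...) {
  if (length(x) == 0) "identity"
  else paste(sprintf("%s(%+.4g)", x$ops, x$amounts), collapse = " -> ")
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db))
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  invisible(TRUE)
}

#' Dice overlap score
#'
#' For two binary masks, `2|A∩B| / (|A| + |B|)`.  For two class maps the
#' score is computed per class and reported together with the macro
#' (unweighted) mean.  Two empty masks agree on absence and score 1.
#'
#' @param a,b logical matrices (binary masks) or `class_map`s / integer
#'   label matrices of identical shape.
#' @return A single number for binary masks; for class maps a named vector
#'   with one entry per class plus `"macro"`.
#' @export
dice <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    check_same_shape(a, b, "masks")
    return(dice_binary(a, b))
  }
  la <- as_labels(a); lb <- as_labels(b)
  check_same_shape(la, lb, "class maps")
  per <- vapply(0:2, function(k) dice_binary(la == k, lb == k), numeric(1))
  names(per) <- CLASS_LEVELS
  c(per, macro = mean(per))
}

dice_binary <- function(a, b) {
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Macro Dice between two class maps
#'
#' Convenience wrapper returning only the unweighted mean of the three
#' per-class Dice scores.
#'
#' @inheritParams dice
#' @return A number in \[0, 1\].
#' @export
macro_dice <- function(a, b) unname(dice(a, b)[["macro"]])
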