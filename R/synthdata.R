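# Seeded generator of synthetic two-channel sections with ground truth
# and cohort-style acquisition inconsistency.  The geometry emulates the
# real material statistically: a tissue-shaped blob on a dark slide, a
# perfused sub-region rendered as vessel-like curvilinear strokes in the
# lectin channel, per-section exposure shifts that positively correlate
# foreground and background means, and an optional bleed-through
# brightening of the lectin channel.

#' Cohort generation settings
#'
#' @param n_sections sections to generate.
#' @param section_size side length in pixels (desk-scale default 256;
#'   full-scale ~10,000-px sections are supported but not default).
#' @param gamma_range per-section gamma drawn uniformly from this range.
#' @param brightness_range per-section brightness offset (signed
#'   fraction of full scale) drawn uniformly from this range; the shared
#'   exposure latent behind the foreground/background mean correlation.
#' @param fg_bg_corr target correlation of per-section class-area means
#'   in (0, 1); independent per-section level jitter is sized as
#'   `sigma_exposure * sqrt((1-rho)/rho)` so the correlation lands near
#'   the target.
#' @param bleedthrough_frac fraction of the nuclear signal added to the
#'   lectin channel (secondary-antibody bleed-through artifact), in
#'   \[0, 0.5\].
#' @param noise_sd pixel noise standard deviation (0--255 scale).
#' @param margin_px radius (pixels) by which the vessel signal is dilated
#'   to form the "normal" ground-truth class; see [margin_radius_px()]
#'   for the physical full-scale value.
#' @param seed base RNG seed for the cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_sections = 6L, section_size = 256L,
                        gamma_range = c(0.95, 1.05),
                        brightness_range = c(-0.05, 0.05),
                        fg_bg_corr = 0.65, bleedthrough_frac = 0,
                        noise_sd = 5, margin_px = 4L, seed = 1L) {
  stopifnot(n_sections >= 1, section_size >= 16,
            all(is.finite(gamma_range)), all(gamma_range > 0),
            all(is.finite(brightness_range)),
            fg_bg_corr > 0, fg_bg_corr < 1,
            bleedthrough_frac >= 0, bleedthrough_frac <= 0.5,
            noise_sd >= 0, margin_px >= 0)
  structure(list(n_sections = as.integer(n_sections),
                 section_size = as.integer(section_size),
                 gamma_range = gamma_range,
                 brightness_range = brightness_range,
                 fg_bg_corr = fg_bg_corr,
                 bleedthrough_frac = bleedthrough_frac,
                 noise_sd = noise_sd, margin_px = as.integer(margin_px),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Ground-truth margin radius in pixels
#'
#' Healthy tissue extends up to `margin_um` (26 um by default, the mean
#' nucleus-to-cell-wall distance) beyond the lectin vascular signal, so
#' the normal class is the vessel signal dilated by this radius.
#'
#' @param margin_um margin in micrometres.
#' @param resolution_nm_per_px acquisition resolution.
#' @return Integer pixel radius, `round(margin_um * 1000 / resolution)`.
#' @export
margin_radius_px <- function(margin_um = 26,
                             resolution_nm_per_px = 541.67) {
  as.integer(round(margin_um * 1000 / resolution_nm_per_px))
}

# Star-shaped smooth blob mask around (cy, cx) with base radius r0.
star_blob <- function(size, cy, cx, r0, wobble = 0.10) {
  yy <- matrix(seq_len(size), size, size)
  xx <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  ang <- atan2(dy, dx)
  amp <- rnorm(3, sd = wobble)
  ph <- runif(3, 0, 2 * pi)
  rmod <- r0 * (1 + amp[1] * cos(2 * ang + ph[1]) +
                    amp[2] * cos(3 * ang + ph[2]) +
                    amp[3] * cos(4 * ang + ph[3]))
  sqrt(dy^2 + dx^2) <= rmod
}

# Random smooth strokes inside `region`; returns a soft intensity canvas
# in [0, 1] with a Gaussian cross-profile.
vessel_strokes <- function(region, n_strokes = 6L, sigma = 1.4) {
  size <- nrow(region)
  canvas <- matrix(0, size, size)
  inside <- which(region)
  if (length(inside) == 0) return(canvas)
  for (s in seq_len(n_strokes)) {
    start <- inside[sample.int(length(inside), 1L)]
    y <- ((start - 1L) %% size) + 1L
    x <- ((start - 1L) %/% size) + 1L
    theta <- runif(1, 0, 2 * pi)
    n_steps <- round(2.5 * sqrt(length(inside)))
    for (t in seq_len(n_steps)) {
      y <- y + 1.2 * sin(theta); x <- x + 1.2 * cos(theta)
      theta <- theta + rnorm(1, sd = 0.35)
      yi <- round(y); xi <- round(x)
      if (yi < 1 || yi > size || xi < 1 || xi > size || !region[yi, xi])
        break
      canvas[yi, xi] <- 1
    }
  }
  sm <- EBImage::gblur(canvas, sigma = sigma)
  if (max(sm) > 0) sm / max(sm) else sm
}

#' Generate one synthetic two-channel section with ground truth
#'
#' Builds the clean section geometry (tissue blob, vessel strokes,
#' nuclei speckle), derives the three-class ground truth (normal = vessel
#' signal dilated by the margin radius, risk = remaining tissue, none =
#' slide), then applies the per-section acquisition perturbation -- a
#' gamma/brightness chain drawn from the cohort spec, rendered from the
#' clean image -- and the optional lectin bleed-through.
#'
#' @param spec a [cohort_spec()].
#' @param section_id identifier for the section.
#' @param seed RNG seed; identical seeds give bit-identical sections.
#' @return List with `nuclear` and `lectin` [section_image()]s, `truth`
#'   (a [class_map()]) and `perturbation` (the per-channel chains
#'   applied).
#' @export
generate_section <- function(spec, section_id = "S1", seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  S <- spec$section_size
  cy <- S / 2 + runif(1, -S / 16, S / 16)
  cx <- S / 2 + runif(1, -S / 16, S / 16)
  tissue <- star_blob(S, cy, cx, r0 = 0.36 * S)
  off <- runif(2, -0.06 * S, 0.06 * S)
  sub <- star_blob(S, cy + off[1], cx + off[2], r0 = 0.26 * S) & tissue
  vess <- vessel_strokes(sub, n_strokes = 10L)
  vess_region <- vess > 0.12
  brush_size <- 2L * spec$margin_px + 1L
  normal <- if (spec$margin_px > 0 && any(vess_region)) {
    as.matrix(EBImage::dilate(
      EBImage::Image(vess_region + 0),
      EBImage::makeBrush(brush_size, shape = "disc"))) > 0
  } else vess_region
  normal <- normal & tissue
  labels <- matrix(CLASS_NONE, S, S)
  labels[tissue & !normal] <- CLASS_RISK
  labels[normal] <- CLASS_NORMAL
  truth <- class_map(labels, section_id)

  # exposure latent: one gamma/brightness chain per channel, plus
  # independent base-level jitter sized against the correlation target.
  # Gamma spreads the foreground more than the background, diluting the
  # shared-exposure variance; the 0.7 factor compensates (calibrated once
  # on the default spec).
  sd_expo <- 255 * diff(range(spec$brightness_range)) / sqrt(12)
  sd_jit <- 0.7 * sd_expo * sqrt((1 - spec$fg_bg_corr) / spec$fg_bg_corr)
  jit <- rnorm(4, sd = sd_jit)   # nuclear bg/fg, lectin bg/fg

  speckle <- matrix(0, S, S)
  tpix <- which(tissue)
  if (length(tpix) > 0) {
    dots <- tpix[sample.int(length(tpix),
                            max(1L, round(0.012 * length(tpix))))]
    speckle[dots] <- 1
    speckle <- EBImage::gblur(speckle, sigma = 0.8)
    if (max(speckle) > 0) speckle <- speckle / max(speckle)
  }

  noise <- function() if (spec$noise_sd > 0)
    matrix(rnorm(S * S, sd = spec$noise_sd), S, S) else 0

  # diffuse perfusion halo around the vessels: lectin signal between
  # vessels in perfused tissue is elevated, not dark
  halo <- EBImage::gblur(vess, sigma = max(2, 1.5 * spec$margin_px))
  if (max(halo) > 0) halo <- halo / max(halo)

  nuc_clean <- clip255(
    (25 + jit[1]) + (110 + jit[2] - 25 - jit[1]) * tissue +
      70 * speckle + noise())
  lec_clean <- clip255(
    (18 + jit[3]) + 12 * tissue + 45 * halo * tissue +
      (150 + jit[4] - 18 - jit[3]) * vess + noise())

  draw_chain <- function() adjust_chain(
    c("gamma", "brightness"),
    c(runif(1, spec$gamma_range[1], spec$gamma_range[2]),
      runif(1, spec$brightness_range[1], spec$brightness_range[2])))
  chains <- list(nuclear = draw_chain(), lectin = draw_chain())
  nuc <- render_chain(nuc_clean, chains$nuclear, quantize = FALSE)
  lec <- render_chain(lec_clean, chains$lectin, quantize = FALSE)
  if (spec$bleedthrough_frac > 0)
    lec <- clip255(lec + spec$bleedthrough_frac * nuc)
  list(nuclear = section_image(round(clip255(nuc)), "nuclear", section_id),
       lectin = section_image(round(clip255(lec)), "lectin", section_id),
       truth = truth,
       perturbation = chains)
}

#' Generate a three-cohort dataset
#'
#' Cohort 1 plays the expert-labeled base set and exposes its ground
#' truth; cohorts 2 and 3 form the active set and their truths are kept
#' hidden from the public view, retained only for the simulated expert
#' (see [expert_truth()]).  Default specs give cohort 2 a brighter
#' acquisition and cohort 3 a lectin bleed-through artifact.
#'
#' @param specs named list with `cohort1`, `cohort2`, `cohort3`
#'   [cohort_spec()]s.
#' @return An `sp_dataset`: `sections` (named list with `nuclear`,
#'   `lectin`, `cohort` per section), `truths` (cohort-1 truths only) and
#'   a sealed environment holding the active-set truths.
#' @export
generate_cohorts <- function(specs = default_cohort_specs()) {
  stopifnot(all(c("cohort1", "cohort2", "cohort3") %in% names(specs)))
  sections <- list()
  truths <- list()
  hidden <- new.env(parent = emptyenv())
  for (ci in 1:3) {
    spec <- specs[[sprintf("cohort%d", ci)]]
    for (k in seq_len(spec$n_sections)) {
      id <- sprintf("c%d_s%02d", ci, k)
      sec <- generate_section(spec, section_id = id,
                              seed = spec$seed * 1000L + k)
      sections[[id]] <- list(nuclear = sec$nuclear, lectin = sec$lectin,
                             cohort = ci)
      if (ci == 1L) truths[[id]] <- sec$truth
      else assign(id, sec$truth, envir = hidden)
    }
  }
  structure(list(sections = sections, truths = truths,
                 .hidden = hidden),
            class = "sp_dataset")
}

#' @export
print.sp_dataset <- function(x, ...) {
  coh <- vapply(x$sections, function(s) s$cohort, numeric(1))
  cat(sprintf(
    "<sp_dataset> %d sections (cohort1 %d labeled, cohort2 %d, cohort3 %d unlabeled)\n",
    length(coh), sum(coh == 1), sum(coh == 2), sum(coh == 3)))
  invisible(x)
}

#' Hidden ground truth for the simulated expert
#'
#' Retrieves the withheld truth of an active-set section.  Only the
#' simulated expert may consult this; the public dataset view never
#' exposes it.
#'
#' @param dataset an `sp_dataset`.
#' @param section_id active-set section identifier.
#' @return The [class_map()] truth.
#' @export
expert_truth <- function(dataset, section_id) {
  if (section_id %in% names(dataset$truths))
    return(dataset$truths[[section_id]])
  if (!exists(section_id, envir = dataset$.hidden))
    stop(sprintf("no truth stored for section '%s'", section_id))
  get(section_id, envir = dataset$.hidden)
}

#' Default desk-scale cohort specs
#'
#' Cohort 1: mild acquisition variability (the curated base set).
#' Cohort 2: markedly brighter exposures (bright nuclear channel).
#' Cohort 3: bleed-through lifting the lectin background, plus moderate
#' exposure drift.
#'
#' @param n1,n2,n3 sections per cohort.
#' @param section_size section side length.
#' @param seed base seed (cohort seeds derive from it).
#' @return Named list of three [cohort_spec()]s.
#' @export
default_cohort_specs <- function(n1 = 6L, n2 = 3L, n3 = 3L,
                                 section_size = 256L, seed = 1L) {
  list(
    cohort1 = cohort_spec(n1, section_size,
                          gamma_range = c(0.95, 1.05),
                          brightness_range = c(-0.04, 0.04),
                          seed = seed),
    cohort2 = cohort_spec(n2, section_size,
                          gamma_range = c(0.70, 0.85),
                          brightness_range = c(0.12, 0.25),
                          seed = seed + 1L),
    cohort3 = cohort_spec(n3, section_size,
                          gamma_range = c(0.90, 1.15),
                          brightness_range = c(-0.02, 0.10),
                          bleedthrough_frac = 0.30,
                          seed = seed + 2L))
}
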