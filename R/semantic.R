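# Semantic preprocessing: Otsu-seeded metric extraction, the SP gamma
# search, the annealed gradient-descent search over
# contrast/brightness/gamma (GDBSP), and the bootstrap loop that
# alternates adjustment with model prediction.

#' Semantic-preprocessing configuration
#'
#' @param gamma_step multiplicative gamma step for the SP search (0.05
#'   means candidate gammas `g*1.05` and `g*0.95`).
#' @param gd_initial_step initial step fraction of the annealed descent
#'   (default 0.10, i.e. 10% moves).
#' @param gd_step_decrement annealing decrement (default 0.01); when no
#'   10% move improves, the step shrinks 1% at a time down to 1%.
#' @param bootstrap_iters number of adjust/predict bootstrap iterations.
#' @param use_std include per-region standard deviations in the metric
#'   (the 4-D GDBSP space) and use the gradient-descent search.
#' @return An `sp_config` object.
#' @export
sp_config <- function(gamma_step = 0.05, gd_initial_step = 0.10,
                      gd_step_decrement = 0.01, bootstrap_iters = 5,
                      use_std = FALSE) {
  stopifnot(gamma_step > 0,
            gd_step_decrement > 0,
            gd_step_decrement <= gd_initial_step,
            gd_initial_step <= 1,
            bootstrap_iters >= 1)
  structure(list(gamma_step = gamma_step,
                 gd_initial_step = gd_initial_step,
                 gd_step_decrement = gd_step_decrement,
                 bootstrap_iters = as.integer(bootstrap_iters),
                 use_std = isTRUE(use_std)),
            class = "sp_config")
}

#' Binary Otsu threshold of a section image
#'
#' Chooses the cut maximizing between-class variance of the 8-bit
#' histogram; pixels strictly above the threshold are foreground.  Used to
#' seed semantic preprocessing with an approximate foreground/background
#' segmentation before any model prediction exists.
#'
#' @param img `section_image` or numeric matrix.
#' @return Logical matrix (`TRUE` = foreground) with the chosen threshold
#'   attached as attribute `"threshold"` (0--255 scale).
#' @export
otsu_binary <- function(img) {
  px <- round(clip255(as_pixels(img)))
  if (length(unique(as.vector(px))) < 2)
    stop("degenerate histogram: image has a single intensity value")
  h <- tabulate(px + 1L, nbins = 256L)
  n <- sum(h)
  lev <- 0:255
  # cut at t: background = levels <= t, foreground = levels > t
  w0 <- cumsum(h)[1:255]
  w1 <- n - w0
  s0 <- cumsum(h * lev)[1:255]
  m0 <- ifelse(w0 > 0, s0 / w0, 0)
  m1 <- ifelse(w1 > 0, (sum(h * lev) - s0) / w1, 0)
  bcv <- w0 * w1 * (m0 - m1)^2
  # empty bins create plateaus of maximizing cuts that all induce the
  # same split; take the middle one so the threshold sits between the
  # separated modes rather than hugging the lower
  maxima <- which(bcv == max(bcv))
  thr <- lev[maxima[ceiling(length(maxima) / 2)]]
  mask <- px > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Extract the semantic metric of a masked image
#'
#' Mean (and optionally population standard deviation) of the pixel values
#' inside and outside the mask, on the 0--255 scale.  If either region is
#' empty the metric is flagged degenerate and searches will skip
#' adjustment.
#'
#' @param img `section_image` or numeric matrix.
#' @param mask logical matrix, `TRUE` = foreground.
#' @param use_std also compute per-region standard deviations.
#' @return A [semantic_metric()].
#' @export
extract_metric <- function(img, mask, use_std = FALSE) {
  px <- as_pixels(img)
  check_same_shape(px, mask, "image and mask")
  fg <- px[mask]; bg <- px[!mask]
  if (length(fg) == 0 || length(bg) == 0) {
    m <- mean(px)
    return(semantic_metric(m, m,
                           if (use_std) 0 else NULL,
                           if (use_std) 0 else NULL,
                           degenerate = TRUE))
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  semantic_metric(mean(bg), mean(fg),
                  if (use_std) pop_sd(bg) else NULL,
                  if (use_std) pop_sd(fg) else NULL)
}

# Distance of a rendered (float-path) chain to the target metric.
chain_distance <- function(raw, chain, mask, target,
                           use_std = !is.null(target$bg_std)) {
  adj <- render_chain(raw, chain, quantize = FALSE)
  metric_distance(extract_metric(adj, mask, use_std = use_std), target)
}

#' SP gamma search
#'
#' Greedy search over whole-image gamma: starting from gamma 1, the
#' current gamma is repeatedly nudged up or down by a multiplicative 5%
#' step, moving to whichever candidate strictly reduces the 2-D metric
#' distance (background mean, foreground mean) to the target; the search
#' stops when neither direction improves.
#'
#' @param raw raw `section_image` or matrix (adjustments are always
#'   re-applied to the raw image).
#' @param mask logical foreground mask defining the two class areas.
#' @param target [semantic_metric()] with means only (from the reference
#'   section).
#' @param cfg an [sp_config()].
#' @return An [adjust_chain()] (empty if no step improved, or if the mask
#'   or target is degenerate), with a `"trace"` attribute recording the
#'   accepted gammas and distances.
#' @export
sp_gamma_search <- function(raw, mask, target, cfg = sp_config()) {
  if (!is.null(target$bg_std))
    stop("SP search expects a 2-D (means-only) target metric")
  if (target$degenerate || sum(mask) == 0 || sum(!mask) == 0) {
    warning("degenerate mask or target; skipping adjustment")
    return(structure(adjust_chain(), trace = data.frame()))
  }
  tol <- 1e-9
  g <- 1
  d <- chain_distance(raw, adjust_chain(), mask, target, use_std = FALSE)
  trace <- list(list(gamma = 1, distance = d))
  repeat {
    cand <- c(g * (1 + cfg$gamma_step), g * (1 - cfg$gamma_step))
    dc <- vapply(cand, function(gc)
      chain_distance(raw, adjust_chain("gamma", gc), mask, target,
                     use_std = FALSE), numeric(1))
    if (min(dc) < d - tol) {
      k <- which.min(dc)
      g <- cand[k]; d <- dc[k]
      trace[[length(trace) + 1]] <- list(gamma = g, distance = d)
    } else break
  }
  chain <- if (g == 1) adjust_chain() else adjust_chain("gamma", g)
  structure(chain,
            trace = do.call(rbind, lapply(trace, as.data.frame)))
}

#' Annealed gradient-descent search (GDBSP adjustment step)
#'
#' Probes moves of contrast, brightness and gamma in both directions at
#' the current step size (initially 10%), always re-rendering the whole
#' candidate chain from the raw image, and accepts the move with the
#' greatest strict reduction of the 4-D metric distance (means and
#' standard deviations of both class areas).  When no move at the current
#' step improves, the step anneals down 1% at a time; the search ends when
#' it would drop below 1% with no improving move.
#'
#' Gamma steps are multiplicative: a gamma move at step `s` appends a
#' `gamma(1 +/- s)` op, multiplying the effective exponent.  Ties are
#' broken by the fixed candidate order contrast, brightness, gamma, with
#' `+` before `-`.
#'
#' @inheritParams sp_gamma_search
#' @param target [semantic_metric()] with means and standard deviations
#'   (the 4-D GDBSP space); a means-only target restricts the distance to
#'   2-D (useful with `ops = "gamma"`, where the search walks the same
#'   multiplicative lattice as [sp_gamma_search()]).
#' @param ops which adjustment knobs to probe, in tie-break priority
#'   order.
#' @return An [adjust_chain()] of the accepted moves, with a `"trace"`
#'   attribute (one row per accepted move: step, op, amount, distance).
#' @export
gd_search <- function(raw, mask, target, cfg = sp_config(use_std = TRUE),
                      ops = c("contrast", "brightness", "gamma")) {
  if (target$degenerate || sum(mask) == 0 || sum(!mask) == 0) {
    warning("degenerate mask or target; skipping adjustment")
    return(structure(adjust_chain(), trace = data.frame()))
  }
  use_std <- !is.null(target$bg_std)
  tol <- 1e-9
  chain <- adjust_chain()
  d <- chain_distance(raw, chain, mask, target, use_std = use_std)
  trace <- list()
  # step sizes handled in integer hundredths to avoid float drift
  s100 <- round(cfg$gd_initial_step * 100)
  dec100 <- round(cfg$gd_step_decrement * 100)
  while (s100 >= 1) {
    s <- s100 / 100
    cands <- list()
    for (op in ops) for (sign in c(+1, -1))
      cands[[length(cands) + 1L]] <- list(
        op = op, amount = if (op == "gamma") 1 + sign * s else sign * s)
    dc <- vapply(cands, function(cd)
      chain_distance(raw, chain_append(chain, cd$op, cd$amount), mask,
                     target, use_std = use_std), numeric(1))
    if (min(dc) < d - tol) {
      k <- which.min(dc)   # first max-reduction candidate in fixed order
      chain <- chain_append(chain, cands[[k]]$op, cands[[k]]$amount)
      d <- dc[k]
      trace[[length(trace) + 1]] <-
        data.frame(step = s, op = cands[[k]]$op,
                   amount = cands[[k]]$amount, distance = d)
    } else {
      s100 <- s100 - dec100
    }
  }
  structure(chain, trace = do.call(rbind, trace))
}

#' Compose the three-class map from two binary channel masks
#'
#' Normal wherever the lectin channel is foreground; risk where the
#' nuclear channel is foreground but lectin is not; none elsewhere.
#'
#' @param nuclear_mask,lectin_mask logical matrices of identical shape.
#' @param section_id identifier for the resulting map.
#' @return A [class_map()].
#' @export
compose_class_map <- function(nuclear_mask, lectin_mask,
                              section_id = "section") {
  check_same_shape(nuclear_mask, lectin_mask, "channel masks")
  labels <- matrix(CLASS_NONE, nrow(nuclear_mask), ncol(nuclear_mask))
  labels[nuclear_mask & !lectin_mask] <- CLASS_RISK
  labels[lectin_mask] <- CLASS_NORMAL
  class_map(labels, section_id)
}

# Binary channel masks derived from a predicted class map, mirroring the
# two binary problems: nuclear = tissue-vs-slide, lectin = normal-vs-rest.
masks_from_map <- function(map) {
  labels <- as_labels(map)
  list(nuclear = labels != CLASS_NONE, lectin = labels == CLASS_NORMAL)
}

# Run a model on a two-channel section.  Accepts either a plain function
# (nuclear, lectin) -> class_map (oracle stubs in tests) or a trained
# segmenter, which goes through sliding-window prediction and stitching.
run_segmenter <- function(model, nuclear, lectin, grid) {
  if (is.function(model)) return(model(nuclear, lectin))
  predict_section(model, nuclear, lectin, grid = grid)$map
}

#' Bootstrapped semantic preprocessing of one section
#'
#' Alternates semantic adjustment with model re-prediction.  Iteration 0
#' seeds the per-channel foreground masks with binary Otsu thresholds;
#' each bootstrap iteration then (1) searches for the adjustment chain
#' (SP gamma search, or the annealed gradient descent when
#' `cfg$use_std`) per channel, always starting from the raw images, (2)
#' renders the adjusted channels, (3) predicts a class map with the
#' segmenter, and (4) derives the next iteration's masks from that
#' prediction (nuclear = not-none, lectin = normal).  Channels are
#' adjusted fully independently.
#'
#' @param nuclear,lectin raw `section_image`s of the two channels.
#' @param model a trained segmenter (see [build_model()]) or a function
#'   `(nuclear, lectin) -> class_map` used as an oracle.
#' @param target named list with elements `nuclear` and `lectin`, each a
#'   [semantic_metric()] extracted from the reference section.
#' @param cfg an [sp_config()].
#' @param grid a [patch_grid()] used for model prediction.
#' @return List with `chains` (per channel), `adjusted` (final rendered
#'   channels, 8-bit), `map` (final predicted [class_map()]) and `trace`
#'   (one row per iteration: per-channel distances and chain lengths).
#' @export
bsp_iterate <- function(nuclear, lectin, model, target,
                        cfg = sp_config(), grid = patch_grid()) {
  check_same_shape(as_pixels(nuclear), as_pixels(lectin), "channels")
  masks <- list(nuclear = otsu_binary(nuclear),
                lectin = otsu_binary(lectin))
  search <- if (cfg$use_std) gd_search else sp_gamma_search
  chains <- list(nuclear = adjust_chain(), lectin = adjust_chain())
  adjusted <- list(nuclear = nuclear, lectin = lectin)
  map <- NULL
  trace <- vector("list", cfg$bootstrap_iters)
  for (it in seq_len(cfg$bootstrap_iters)) {
    dists <- c(nuclear = NA_real_, lectin = NA_real_)
    for (ch in c("nuclear", "lectin")) {
      raw <- if (ch == "nuclear") nuclear else lectin
      chains[[ch]] <- search(raw, masks[[ch]], target[[ch]], cfg)
      adjusted[[ch]] <- render_chain(raw, chains[[ch]])
      dists[[ch]] <- metric_distance(
        extract_metric(adjusted[[ch]], masks[[ch]], use_std = cfg$use_std),
        target[[ch]])
    }
    map <- tryCatch(
      run_segmenter(model, adjusted$nuclear, adjusted$lectin, grid),
      error = function(e)
        stop(sprintf("segmenter failed at bootstrap iteration %d: %s",
                     it, conditionMessage(e))))
    masks <- masks_from_map(map)
    trace[[it]] <- tibble::tibble(
      iteration = it,
      nuclear_distance = dists[["nuclear"]],
      lectin_distance = dists[["lectin"]],
      nuclear_chain = format(chains$nuclear),
      lectin_chain = format(chains$lectin))
  }
  list(chains = chains, adjusted = adjusted, map = map,
       trace = do.call(rbind, trace))
}
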