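# The iterative active-deep-learning orchestrator: per-iteration fold
# training, least-overfit-fold selection, semantic (or benchmark)
# preprocessing of the active set, snapshot-ensemble voting, confidence
# thresholding, the simulated accept/reject expert, and run accounting.

#' Simulated expert accept/reject decision
#'
#' Stands in for the human reviewer on synthetic data: a candidate label
#' is accepted when its macro Dice against the withheld truth reaches the
#' acceptance bar (boundary inclusive).  Accepted reviews cost 5 minutes
#' (evaluation plus quick edits); rejections cost 1 minute.
#'
#' @param candidate predicted [class_map()].
#' @param truth withheld ground-truth [class_map()].
#' @param accept_dice macro-Dice acceptance bar.
#' @param accept_minutes,reject_minutes review cost model.
#' @return List with `verdict` (`"accept"`/`"reject"`), `minutes` and the
#'   measured `dice`.
#' @export
simulated_expert <- function(candidate, truth, accept_dice = 0.90,
                             accept_minutes = 5, reject_minutes = 1) {
  d <- macro_dice(candidate, truth)
  if (d >= accept_dice)
    list(verdict = "accept", minutes = accept_minutes, dice = d)
  else
    list(verdict = "reject", minutes = reject_minutes, dice = d)
}

#' Dataset size after acceptance, percent of base
#'
#' @param base_samples sample count of the base (labeled) dataset.
#' @param accepted_samples cumulative accepted sample count.
#' @return `round(100 * (base + accepted) / base)`.
#' @export
dataset_size_pct <- function(base_samples, accepted_samples) {
  if (base_samples <= 0) stop("base_samples must be positive")
  round(100 * (base_samples + accepted_samples) / base_samples)
}

#' Percent of the active set accepted
#'
#' @param accepted_sections,total_sections section counts.
#' @return `round(100 * accepted / total)`.
#' @export
acceptance_pct <- function(accepted_sections, total_sections) {
  if (total_sections <= 0) stop("total_sections must be positive")
  round(100 * accepted_sections / total_sections)
}

#' Cumulative expert review time in hours
#'
#' @param accept_decisions,reject_decisions decision counts.
#' @param accept_minutes,reject_minutes per-decision cost model (5 and 1
#'   minutes by default).
#' @return Hours.
#' @export
expert_time_hours <- function(accept_decisions, reject_decisions,
                              accept_minutes = 5, reject_minutes = 1) {
  (accept_minutes * accept_decisions +
     reject_minutes * reject_decisions) / 60
}

#' Expert time saved relative to manual labeling, percent
#'
#' @param expert_hours review hours actually spent.
#' @param manual_hours hours manual labeling of the same sections would
#'   have taken.
#' @return `round(100 * (1 - expert/manual))`.
#' @export
time_saved_pct <- function(expert_hours, manual_hours) {
  if (manual_hours <= 0) stop("manual_hours must be positive")
  round(100 * (1 - expert_hours / manual_hours))
}

#' Active-deep-learning run configuration
#'
#' @param method preprocessing method: `"raw"`, `"dog"`, `"he"`,
#'   `"ahe"`, `"hm"`, `"sp"`, `"bsp"` or `"gdbsp"`.
#' @param sp an [sp_config()]; `use_std` is forced on for `"gdbsp"`.
#' @param train a [train_config()].
#' @param grid a [patch_grid()] for prediction.
#' @param n_folds,val_size cross-validation layout over the base
#'   sections.
#' @param capacity,floor expert capacity and minimum confidence floor
#'   for [choose_threshold()] (the stricter 0.97 preset of the
#'   verification protocol can be set via `floor`).
#' @param accept_dice simulated-expert acceptance bar.
#' @param accept_minutes,reject_minutes,manual_hours_per_section expert
#'   time model (5 min/accept, 1 min/reject, 2 h manual equivalent).
#' @param model_width,model_depth segmenter geometry (desk-scale
#'   defaults; `build_model()`'s budget default applies when
#'   `model_width` is `NULL`).
#' @param train_offsets pixel offsets for shifted-grid crop augmentation
#'   of the training patches; `0` alone gives the plain non-overlapping
#'   grid.  Short desk-scale schedules use `c(0, window/2)` to supply
#'   enough optimizer updates.
#' @param reference_id expert-designated reference section supplying the
#'   target semantic metrics (default: first base section).
#' @param seed run seed; all derived randomness flows from it.
#' @return An `adl_config` object.
#' @export
adl_config <- function(method = "gdbsp", sp = sp_config(),
                       train = train_config(10L, c(8L, 9L, 10L), lr = 8),
                       grid = patch_grid(64L, 32L, 16L),
                       n_folds = 2L, val_size = 1L,
                       capacity = 12L, floor = 0.90,
                       accept_dice = 0.90,
                       accept_minutes = 5, reject_minutes = 1,
                       manual_hours_per_section = 2,
                       model_width = 4L, model_depth = 2L,
                       train_offsets = c(0L, 32L),
                       reference_id = NULL, seed = 1L) {
  method <- match.arg(method, c("raw", "dog", "he", "ahe", "hm",
                                "sp", "bsp", "gdbsp"))
  if (method == "gdbsp")
    sp <- sp_config(sp$gamma_step, sp$gd_initial_step,
                    sp$gd_step_decrement, sp$bootstrap_iters,
                    use_std = TRUE)
  structure(list(method = method, sp = sp, train = train, grid = grid,
                 n_folds = as.integer(n_folds),
                 val_size = as.integer(val_size),
                 capacity = as.integer(capacity), floor = floor,
                 accept_dice = accept_dice,
                 accept_minutes = accept_minutes,
                 reject_minutes = reject_minutes,
                 manual_hours_per_section = manual_hours_per_section,
                 model_width = model_width,
                 model_depth = as.integer(model_depth),
                 train_offsets = as.integer(train_offsets),
                 reference_id = reference_id, seed = as.integer(seed)),
            class = "adl_config")
}

# Benchmark preprocessing of a two-channel section.
preprocess_channels <- function(method, nuclear, lectin, ref) {
  switch(method,
    raw = list(nuclear = nuclear, lectin = lectin),
    dog = list(nuclear = difference_of_gaussians(nuclear),
               lectin = difference_of_gaussians(lectin)),
    he  = list(nuclear = hist_equalize(nuclear),
               lectin = hist_equalize(lectin)),
    ahe = list(nuclear = adaptive_hist_equalize(nuclear),
               lectin = adaptive_hist_equalize(lectin)),
    hm  = list(nuclear = hist_match(nuclear, ref$nuclear),
               lectin = hist_match(lectin, ref$lectin)),
    stop(sprintf("not a benchmark method: '%s'", method)))
}

#' Initialize an active-deep-learning run
#'
#' Fixes the fold plan over the labeled base sections, extracts the
#' reference semantic metrics, and sets up the active-set bookkeeping.
#'
#' @param dataset an `sp_dataset` from [generate_cohorts()] (cohort 1 is
#'   the base, cohorts 2 and 3 the active set).
#' @param cfg an [adl_config()].
#' @return An `adl_state` to be advanced with [adl_iteration()].
#' @export
adl_init <- function(dataset, cfg = adl_config()) {
  base_ids <- names(dataset$truths)
  if (length(base_ids) == 0) stop("dataset has no labeled base sections")
  active_ids <- setdiff(names(dataset$sections), base_ids)
  ref_id <- if (is.null(cfg$reference_id)) base_ids[[1]] else cfg$reference_id
  ref <- dataset$sections[[ref_id]]
  # Target metrics come from the reference's expert ground-truth regions
  # (nuclear = not-none, lectin = normal): the same region definitions
  # the bootstrap's prediction-derived masks use, keeping the metric
  # space consistent across iterations.
  ref_masks <- masks_from_map(dataset$truths[[ref_id]])
  target <- list(
    nuclear = extract_metric(ref$nuclear, ref_masks$nuclear,
                             use_std = cfg$sp$use_std),
    lectin = extract_metric(ref$lectin, ref_masks$lectin,
                            use_std = cfg$sp$use_std))
  plan <- fold_plan(base_ids, cfg$n_folds, cfg$val_size, seed = cfg$seed)
  n_base_samples <- sum(vapply(base_ids, function(id)
    length(grid_patches(dataset$sections[[id]]$nuclear,
                        cfg$grid$window)$patches), numeric(1)))
  structure(list(
    plan = plan, reference = ref, target = target,
    active = tibble::tibble(section_id = active_ids, state = "pending"),
    extra = list(),           # accepted adjusted sections + voted labels
    iteration = 0L,
    n_base_samples = n_base_samples,
    n_active_total = length(active_ids),
    expert_minutes = 0, accepted_samples = 0,
    ledger = NULL), class = "adl_state")
}

# Cut a (possibly preprocessed) labeled section into training pairs.
# `offsets` shifts the non-overlapping grid by the given pixel amounts in
# both axes (shifted-grid crop augmentation for short desk-scale
# schedules); offset 0 alone reproduces the plain grid.
section_training_pairs <- function(nuclear, lectin, truth, window,
                                   offsets = 0L) {
  npx <- as_pixels(nuclear); lpx <- as_pixels(lectin)
  tlb <- as_labels(truth)
  inputs <- list(); labels <- list()
  for (dy in offsets) for (dx in offsets) {
    rows <- (1L + dy):nrow(npx); cols <- (1L + dx):ncol(npx)
    gn <- grid_patches(npx[rows, cols, drop = FALSE], window)
    gl <- grid_patches(lpx[rows, cols, drop = FALSE], window)
    gt <- grid_patches(tlb[rows, cols, drop = FALSE], window)
    for (k in seq_along(gn$patches)) {
      inputs[[length(inputs) + 1L]] <-
        window_input(gn$patches[[k]], gl$patches[[k]])
      labels[[length(labels) + 1L]] <- gt$patches[[k]]
    }
  }
  list(inputs = inputs, labels = labels)
}

#' Run one active-deep-learning iteration
#'
#' Trains every fold's snapshot ensemble on the base sections (plus all
#' previously accepted sections), cross-validates, selects the
#' least-overfit fold, preprocesses and predicts the pending active-set
#' sections with that fold's ensemble (bootstrapped semantic
#' preprocessing driven by the most-trained snapshot for the semantic
#' methods; the remaining snapshots then vote on the adjusted inputs),
#' thresholds the per-section confidences, submits qualifying sections
#' to the simulated expert, and folds accepted sections -- adjusted
#' images as inputs, voted ensemble maps as labels -- into every
#' training set.
#'
#' @param state an `adl_state`.
#' @param dataset the `sp_dataset` the state was initialized from.
#' @param cfg the run's [adl_config()].
#' @return The updated `adl_state`; `state$ledger` gains one row.
#' @export
adl_iteration <- function(state, dataset, cfg = adl_config()) {
  it <- state$iteration + 1L
  window <- cfg$grid$window
  semantic <- cfg$method %in% c("sp", "bsp", "gdbsp")

  # --- train all folds, record test Dice -----------------------------------
  ensembles <- list(); fold_dice <- numeric(0)
  for (fi in seq_along(state$plan$folds)) {
    fold <- state$plan$folds[[fi]]
    inputs <- list(); labels <- list()
    for (id in fold$train_ids) {
      sec <- dataset$sections[[id]]
      chans <- if (semantic) list(nuclear = sec$nuclear, lectin = sec$lectin)
               else preprocess_channels(cfg$method, sec$nuclear,
                                        sec$lectin, state$reference)
      pr <- section_training_pairs(chans$nuclear, chans$lectin,
                                   dataset$truths[[id]], window,
                                   cfg$train_offsets)
      inputs <- c(inputs, pr$inputs); labels <- c(labels, pr$labels)
    }
    for (ex in state$extra) {
      pr <- section_training_pairs(ex$nuclear, ex$lectin, ex$label, window,
                                   cfg$train_offsets)
      inputs <- c(inputs, pr$inputs); labels <- c(labels, pr$labels)
    }
    model <- build_model(width = cfg$model_width, depth = cfg$model_depth,
                         seed = cfg$seed * 100L + it * 10L + fi)
    tcfg <- cfg$train
    tcfg$seed <- cfg$seed * 1000L + it * 10L + fi
    ens <- train_snapshots(model, inputs, labels, tcfg)
    ensembles[[fi]] <- ens
    dtest <- vapply(fold$test_ids, function(id) {
      sec <- dataset$sections[[id]]
      chans <- if (semantic) list(nuclear = sec$nuclear, lectin = sec$lectin)
               else preprocess_channels(cfg$method, sec$nuclear,
                                        sec$lectin, state$reference)
      maps <- lapply(ens$members, function(m)
        predict_section(m, chans$nuclear, chans$lectin, cfg$grid)$map)
      macro_dice(ensemble_vote(maps)$map, dataset$truths[[id]])
    }, numeric(1))
    fold_dice[names(state$plan$folds)[fi]] <- mean(dtest)
  }
  work_fold <- least_overfit_fold(fold_dice)
  ens <- ensembles[[match(work_fold, names(state$plan$folds))]]

  # --- preprocess + predict the pending active set -------------------------
  pending <- state$active$section_id[state$active$state != "accepted"]
  evals <- list()
  for (id in pending) {
    sec <- dataset$sections[[id]]
    if (semantic) {
      spcfg <- cfg$sp
      if (cfg$method == "sp") spcfg$bootstrap_iters <- 1L
      bs <- bsp_iterate(sec$nuclear, sec$lectin, ens$final, state$target,
                        spcfg, cfg$grid)
      adj <- bs$adjusted
    } else {
      adj <- preprocess_channels(cfg$method, sec$nuclear, sec$lectin,
                                 state$reference)
    }
    maps <- lapply(ens$members, function(m)
      predict_section(m, adj$nuclear, adj$lectin, cfg$grid)$map)
    vote <- ensemble_vote(maps)
    evals[[id]] <- list(adj = adj, map = vote$map,
                        f = vote$conf$mean_confidence)
  }
  f_values <- vapply(evals, function(e) e$f, numeric(1))
  f_thresh <- choose_threshold(f_values, cfg$capacity, cfg$floor)

  # --- expert review -------------------------------------------------------
  n_acc <- 0L; n_rej <- 0L; minutes <- 0
  for (id in names(f_values)[f_values >= f_thresh]) {
    dec <- simulated_expert(evals[[id]]$map, expert_truth(dataset, id),
                            cfg$accept_dice, cfg$accept_minutes,
                            cfg$reject_minutes)
    minutes <- minutes + dec$minutes
    if (dec$verdict == "accept") {
      n_acc <- n_acc + 1L
      state$active$state[state$active$section_id == id] <- "accepted"
      state$extra[[id]] <- list(nuclear = evals[[id]]$adj$nuclear,
                                lectin = evals[[id]]$adj$lectin,
                                label = evals[[id]]$map)
      state$accepted_samples <- state$accepted_samples +
        length(grid_patches(evals[[id]]$adj$nuclear, window)$patches)
    } else {
      n_rej <- n_rej + 1L
      state$active$state[state$active$section_id == id] <- "rejected"
    }
  }
  state$expert_minutes <- state$expert_minutes + minutes
  state$iteration <- it
  cum_acc <- sum(state$active$state == "accepted")
  manual_hours <- cum_acc * cfg$manual_hours_per_section
  row <- tibble::tibble(
    iteration = it, method = cfg$method, work_fold = work_fold,
    mean_fold_dice = mean(fold_dice),
    n_pending = length(pending), n_presented = sum(f_values >= f_thresh),
    n_accepted = n_acc, n_rejected = n_rej,
    f_thresh = f_thresh, mean_active_conf = mean(f_values),
    cum_accepted_sections = cum_acc,
    cum_accepted_samples = state$accepted_samples,
    pct_active_accepted_original =
      acceptance_pct(cum_acc, state$n_active_total),
    dataset_size_pct =
      dataset_size_pct(state$n_base_samples, state$accepted_samples),
    expert_hours = state$expert_minutes / 60,
    manual_hours_equiv = manual_hours,
    time_saved_pct = if (manual_hours > 0)
      time_saved_pct(state$expert_minutes / 60, manual_hours) else NA_real_)
  state$ledger <- rbind(state$ledger, row)
  state
}

#' Run several active-deep-learning iterations
#'
#' @param dataset an `sp_dataset`.
#' @param cfg an [adl_config()].
#' @param n_iterations iterations to run.
#' @return The final `adl_state` (see [adl_iteration()]); the per-
#'   iteration accounting lives in `$ledger`.
#' @export
adl_run <- function(dataset, cfg = adl_config(), n_iterations = 3L) {
  state <- adl_init(dataset, cfg)
  for (i in seq_len(n_iterations))
    state <- adl_iteration(state, dataset, cfg)
  state
}
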