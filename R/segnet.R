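# The compact encoder-decoder segmenter (~2M parameters at full-scale
# defaults), snapshot training with Adadelta, ensemble plurality voting
# with confidence maps, and cross-validation fold bookkeeping.

#' Training configuration
#'
#' Adadelta with decay 0.9 and epsilon 1e-6, categorical cross-entropy
#' loss, global gradient-norm clipping at 1.0, inputs scaled to \[0, 1\].
#' Full-scale schedule: 110 epochs with snapshots at epochs 90, 100 and
#' 110; desk-scale runs use shorter schedules such as 10 epochs with
#' snapshots \{8, 9, 10\}.
#'
#' @param epochs total training epochs.
#' @param snapshot_epochs epochs at which ensemble members are saved;
#'   must all lie in `[1, epochs]`.
#' @param rho,eps Adadelta decay rate and numerical stability term.
#' @param grad_clip_norm global gradient-norm clip.
#' @param lr Adadelta step multiplier.
#' @param seed RNG seed for shuffling.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 110L, snapshot_epochs = c(90L, 100L, 110L),
                         rho = 0.9, eps = 1e-6, grad_clip_norm = 1.0,
                         lr = 1.0, seed = 1L) {
  epochs <- as.integer(epochs)
  snapshot_epochs <- sort(as.integer(snapshot_epochs))
  if (any(snapshot_epochs < 1L) || any(snapshot_epochs > epochs))
    stop("snapshot_epochs must lie within [1, epochs]")
  structure(list(epochs = epochs, snapshot_epochs = snapshot_epochs,
                 rho = rho, eps = eps, grad_clip_norm = grad_clip_norm,
                 lr = lr, seed = as.integer(seed)),
            class = "train_config")
}

#' Build the encoder-decoder segmenter
#'
#' A U-Net-style network: an encoder of 3x3 convolution pairs with 2x2
#' max pooling, a bottleneck, and a decoder with nearest-neighbour
#' upsampling and skip connections forwarding fine detail from the encode
#' path; a final 1x1 convolution emits three class logits per pixel.  The
#' channel width is chosen so the trainable parameter count lands as close
#' as possible to `params_budget` (default ~2 million); construction fails
#' if no width comes within 25% of the budget.
#'
#' @param params_budget target number of trainable parameters.
#' @param depth number of pooling levels (input windows must be divisible
#'   by `2^depth`).
#' @param width explicit base channel width; overrides the budget search.
#' @param in_ch,n_classes input channels (nuclear + lectin) and output
#'   classes.
#' @param seed RNG seed for weight initialization (He normal).
#' @return A `segnet` object; `predict()` on a `(H, W, 2)` array in
#'   \[0, 1\] returns per-pixel class probabilities summing to 1.
#' @export
build_model <- function(params_budget = 2e6, depth = 4L, width = NULL,
                        in_ch = 2L, n_classes = 3L, seed = 1L) {
  depth <- as.integer(depth)
  if (is.null(width)) {
    if (!is.numeric(params_budget) || params_budget <= 0)
      stop("params_budget must be positive")
    counts <- vapply(1:96, function(w)
      unet_count_formula(in_ch, n_classes, w, depth), numeric(1))
    width <- which.min(abs(counts - params_budget))
    if (abs(counts[width] - params_budget) > 0.25 * params_budget)
      stop(sprintf(
        "no width reaches within 25%% of a %.3g-parameter budget at depth %d",
        params_budget, depth))
  }
  width <- as.integer(width)
  params <- unet_init(in_ch, n_classes, width, depth, seed = seed)
  structure(list(params = params, depth = depth, width = width,
                 in_ch = as.integer(in_ch), n_classes = as.integer(n_classes),
                 seed = as.integer(seed), epoch = 0L),
            class = "segnet")
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf(
    "<segnet> depth %d, width %d, %s parameters%s\n", x$depth, x$width,
    format(unet_param_count(x$params), big.mark = ","),
    if (x$epoch > 0) sprintf(" (epoch %d)", x$epoch) else " (untrained)"))
  invisible(x)
}

#' Number of trainable parameters of a segmenter
#' @param model a `segnet`.
#' @return Integer count.
#' @export
n_parameters <- function(model) unet_param_count(model$params)

#' Per-pixel class probabilities for one window
#'
#' @param object a `segnet`.
#' @param x `(H, W, 2)` array scaled to \[0, 1\]; `H` and `W` must be
#'   divisible by `2^depth`.
#' @param ... unused.
#' @return `(H, W, 3)` array of class probabilities summing to 1 per
#'   pixel, classes ordered none, risk, normal.
#' @export
predict.segnet <- function(object, x, ...) {
  if (length(dim(x)) != 3L || dim(x)[3] != object$in_ch)
    stop(sprintf("expected a (H, W, %d) input array", object$in_ch))
  if (any(dim(x)[1:2] %% 2L^object$depth != 0L))
    stop(sprintf("window dims must be divisible by %d", 2L^object$depth))
  softmax3(unet_forward(object$params, x, object$depth))
}

# Stack the two 8-bit channels of a window into the normalized input.
window_input <- function(nuclear_px, lectin_px) {
  array(c(nuclear_px, lectin_px) / 255,
        c(nrow(nuclear_px), ncol(nuclear_px), 2L))
}

#' Train with snapshot capture
#'
#' Trains a segmenter by per-patch stochastic gradient descent under
#' Adadelta with categorical cross-entropy and global gradient-norm
#' clipping, saving a snapshot of the weights at each configured epoch.
#' The snapshots form the voting ensemble; the last one is the
#' most-trained member used for preprocessing and primary prediction.
#'
#' @param model an untrained or previously trained `segnet`.
#' @param inputs list of `(H, W, 2)` arrays in \[0, 1\].
#' @param labels list of integer label matrices (codes 0/1/2) matching
#'   `inputs`.
#' @param cfg a [train_config()].
#' @param val_inputs,val_labels optional validation set; macro Dice is
#'   tracked per epoch when supplied.
#' @return A `snapshot_ensemble`: list with `members` (named `segnet`s,
#'   e.g. `M90`), `final` (the last snapshot) and `metrics` (per-epoch
#'   tibble of mean training loss and validation Dice).
#' @export
train_snapshots <- function(model, inputs, labels, cfg = train_config(),
                            val_inputs = NULL, val_labels = NULL) {
  if (length(inputs) == 0L) stop("empty training set")
  stopifnot(length(inputs) == length(labels))
  set.seed(cfg$seed)
  params <- model$params
  state <- adadelta_state(params)
  members <- list()
  metrics <- vector("list", cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(inputs))
    losses <- numeric(length(ord))
    for (k in seq_along(ord)) {
      i <- ord[k]
      fw <- unet_forward(params, inputs[[i]], model$depth,
                         want_cache = TRUE)
      lg <- ce_loss_grad(fw$logits, labels[[i]])
      losses[k] <- lg$loss
      grads <- unet_backward(params, fw$cache, lg$dlogits, model$depth)
      upd <- adadelta_update(params, grads, state, rho = cfg$rho,
                             eps = cfg$eps, clip = cfg$grad_clip_norm,
                             lr = cfg$lr)
      params <- upd$params; state <- upd$state
    }
    val_dice <- NA_real_
    if (!is.null(val_inputs) && length(val_inputs) > 0) {
      snap <- model; snap$params <- params; snap$epoch <- epoch
      dices <- vapply(seq_along(val_inputs), function(i) {
        pr <- predict.segnet(snap, val_inputs[[i]])
        macro_dice(class_map(prob_argmax(pr)),
                   class_map(val_labels[[i]]))
      }, numeric(1))
      val_dice <- mean(dices)
    }
    metrics[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses), val_dice = val_dice)
    if (epoch %in% cfg$snapshot_epochs) {
      snap <- model; snap$params <- params; snap$epoch <- epoch
      members[[sprintf("M%d", epoch)]] <- snap
    }
  }
  structure(list(members = members,
                 final = members[[length(members)]],
                 metrics = do.call(rbind, metrics)),
            class = "snapshot_ensemble")
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble> %d members: %s\n", length(x$members),
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

# Argmax over the class axis with exact ties broken by class priority
# normal > risk > none (highest code wins).
prob_argmax <- function(probs) {
  d <- dim(probs)
  P <- matrix(probs, nrow = d[1] * d[2])
  matrix(max.col(P, ties.method = "last") - 1L, d[1], d[2])
}

#' Predict a whole section with patch-wise interpolation
#'
#' Cuts both channels into overlapping sliding windows, predicts each
#' window, keeps only the central stride-sized block of every output, and
#' stitches the blocks into a seam-free full-section map.
#'
#' @param model a `segnet` (or snapshot ensemble member), or a function
#'   mapping a `(H, W, 2)` window input in \[0, 1\] to a `(H, W, 3)`
#'   probability array (useful as an oracle stub).
#' @param nuclear,lectin the two channel images (`section_image` or
#'   matrices, 0--255).
#' @param grid a [patch_grid()]; the window must suit the model's
#'   downsampling factor.
#' @return List with `map` (a [class_map()]) and `probs` (`(H, W, 3)`
#'   array of stitched per-pixel class confidences).
#' @export
predict_section <- function(model, nuclear, lectin, grid = patch_grid()) {
  npx <- as_pixels(nuclear); lpx <- as_pixels(lectin)
  check_same_shape(npx, lpx, "channels")
  predict_window <- if (is.function(model)) model
                    else function(x) predict.segnet(model, x)
  wn <- sliding_windows(npx, grid)
  wl <- sliding_windows(lpx, grid)
  outs <- lapply(seq_along(wn$windows), function(k)
    predict_window(window_input(wn$windows[[k]], wl$windows[[k]])))
  prob_planes <- lapply(1:3, function(cl)
    stitch_centers(lapply(outs, function(o) o[, , cl]), grid,
                   wn$original_shape))
  probs <- array(unlist(prob_planes),
                 c(wn$original_shape, 3L))
  labels <- stitch_centers(lapply(outs, prob_argmax), grid,
                           wn$original_shape)
  sid <- if (inherits(nuclear, "section_image")) nuclear$section_id
         else "section"
  list(map = class_map(labels, sid), probs = probs)
}

#' Plurality vote of ensemble predictions
#'
#' Per pixel, the class receiving the most votes wins; the winner's vote
#' fraction forms the confidence map.  With three voters and three
#' classes a three-way split is possible despite the odd member count; it
#' is resolved in favour of the final (most-trained) snapshot's class,
#' with confidence 1/3.
#'
#' @param maps list of [class_map()]s (or label matrices), one per
#'   ensemble member, in training order (final snapshot last); the count
#'   must be odd.
#' @return List with `map` (the voted [class_map()]) and `conf` (a
#'   [confidence_map()] whose `mean_confidence` is the section score `f`).
#' @export
ensemble_vote <- function(maps) {
  n <- length(maps)
  if (n %% 2L == 0L) stop("ensemble must have an odd number of members")
  labs <- lapply(maps, as_labels)
  for (m in labs[-1]) check_same_shape(labs[[1]], m, "member maps")
  d <- dim(labs[[1]])
  counts <- lapply(0:2, function(k)
    Reduce(`+`, lapply(labs, function(L) (L == k) + 0L)))
  top <- pmax(counts[[1]], counts[[2]], counts[[3]])
  final <- labs[[n]]
  winner <- matrix(CLASS_NONE, d[1], d[2])
  # prefer the final snapshot's class wherever it is among the top-voted
  for (k in 0:2) winner[counts[[k + 1]] == top] <- k
  for (k in 0:2) {
    sel <- (final == k) & (counts[[k + 1]] == top)
    winner[sel] <- k
  }
  sid <- if (inherits(maps[[n]], "class_map")) maps[[n]]$section_id
         else "section"
  list(map = class_map(winner, sid),
       conf = confidence_map(top / n, sid))
}

#' Section-level confidence score
#'
#' The arithmetic mean of the per-pixel winning-vote proportions, the
#' acquisition score `f` that active deep learning thresholds.
#'
#' @param conf a [confidence_map()] or a numeric matrix of proportions.
#' @return Number in \[0, 1\].
#' @export
section_confidence <- function(conf) {
  if (inherits(conf, "confidence_map")) mean(conf$proportions)
  else mean(conf)
}

#' Choose the expert-capacity confidence threshold
#'
#' The threshold is the confidence of the `capacity`-th most confident
#' section (about one hour of expert work at 12 sections), but never
#' below the floor of 0.90 that filters unstable low-confidence
#' ensembles.
#'
#' @param f_values per-section confidence scores.
#' @param capacity number of sections the expert can review per
#'   iteration.
#' @param floor minimum admissible threshold.
#' @return The threshold `f_thresh`.
#' @export
choose_threshold <- function(f_values, capacity = 12L, floor = 0.90) {
  if (length(f_values) == 0L) stop("no confidence values supplied")
  srt <- sort(f_values, decreasing = TRUE)
  kth <- srt[min(length(srt), capacity)]
  max(floor, kth)
}

#' Pick the least-overfit cross-validation fold
#'
#' The fold with the lowest test Dice: an overfit fold would produce
#' high-confidence votes on poor labels, so the active set is evaluated
#' by the ensemble most likely to still improve.  Ties break in fold
#' order.
#'
#' @param fold_metrics named numeric vector of per-fold test Dice.
#' @return The name (or index, if unnamed) of the selected fold.
#' @export
least_overfit_fold <- function(fold_metrics) {
  if (length(fold_metrics) == 0L) stop("no fold metrics supplied")
  k <- which.min(fold_metrics)
  if (!is.null(names(fold_metrics))) names(fold_metrics)[k] else k
}

#' Cross-validation fold plan over section ids
#'
#' Shuffles the ids once and partitions them into near-equal test groups,
#' one per fold, so every section appears in exactly one test set; each
#' fold's remaining sections are split into validation and training.
#'
#' @param section_ids character vector of section identifiers.
#' @param n_folds number of folds.
#' @param val_size validation sections per fold.
#' @param seed split seed.
#' @return A `fold_plan`: list of folds, each with `train_ids`, `val_ids`,
#'   `test_ids`, plus the seed.
#' @export
fold_plan <- function(section_ids, n_folds, val_size = 1L, seed = 1L) {
  n <- length(section_ids)
  if (n_folds > n) stop("more folds than sections")
  if (n_folds * val_size >= n) stop("val_size too large for the fold count")
  set.seed(seed)
  shuffled <- sample(section_ids)
  test_groups <- split(shuffled, rep(seq_len(n_folds), length.out = n))
  folds <- lapply(seq_len(n_folds), function(i) {
    rest <- setdiff(shuffled, test_groups[[i]])
    list(test_ids = test_groups[[i]],
         val_ids = rest[seq_len(val_size)],
         train_ids = rest[-seq_len(val_size)])
  })
  names(folds) <- paste0("fold", seq_len(n_folds))
  structure(list(folds = folds, seed = as.integer(seed)),
            class = "fold_plan")
}
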