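# Readers and writers: 8-bit grayscale TIFF/PNG section channels, the
# strict false-color class-map codec (black/yellow/green), YAML run
# configuration, ledger CSV and JSON-lines traces.

CLASS_PALETTE <- matrix(c(0, 0, 0,       # none  = black
                          255, 255, 0,   # risk  = yellow
                          0, 255, 0),    # normal = green
                        nrow = 3, byrow = TRUE,
                        dimnames = list(CLASS_LEVELS, c("r", "g", "b")))

#' Read a grayscale section channel from TIFF or PNG
#'
#' Accepts 8-bit files directly; deeper bit depths are affinely rescaled
#' so the maximum value maps to 255, with a warning.  Non-grayscale files
#' are rejected.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param channel,section_id metadata for the resulting
#'   [section_image()].
#' @return A [section_image()].
#' @export
read_section <- function(path, channel = "nuclear",
                         section_id = sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L)
      stop(sprintf("'%s' is not grayscale (%d channels)", path,
                   dim(px)[3]))
    if (max(px) > 255) {
      warning(sprintf("'%s' has >8-bit depth; rescaling max %d to 255",
                      path, max(px)))
      px <- round(px / max(px) * 255)
    }
    px <- px + 0   # store doubles regardless of TIFF integer storage
  } else if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L)
      stop(sprintf("'%s' is not grayscale (%d channels)", path,
                   dim(x)[3]))
    px <- x * 255
    if (any(abs(px - round(px)) > 1e-6)) {
      warning(sprintf("'%s' has >8-bit depth; rescaling max to 255", path))
      px <- px / max(px) * 255
    }
    px <- round(px)
  } else stop(sprintf("unsupported image format: '%s'", ext))
  section_image(px, channel = channel, section_id = section_id)
}

#' Write a section channel as 8-bit grayscale
#'
#' @param img a [section_image()] or matrix (0--255).
#' @param path destination `.tif`/`.tiff` or `.png` path.
#' @return `path`, invisibly.
#' @export
write_section <- function(img, path) {
  px <- round(clip255(as_pixels(img)))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(px / 255, path, bits.per.sample = 8L)
  else if (ext == "png")
    png::writePNG(px / 255, path)
  else stop(sprintf("unsupported image format: '%s'", ext))
  invisible(path)
}

#' Write a class map as a false-color PNG
#'
#' Palette: none = black (0,0,0), risk = yellow (255,255,0), normal =
#' green (0,255,0).
#'
#' @param map a [class_map()].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
classmap_to_png <- function(map, path) {
  labels <- as_labels(map)
  rgb <- array(0, c(nrow(labels), ncol(labels), 3L))
  for (k in 0:2) for (ch in 1:3)
    rgb[, , ch][labels == k] <- CLASS_PALETTE[k + 1L, ch] / 255
  png::writePNG(rgb, path)
  invisible(path)
}

#' Read a false-color class-map PNG
#'
#' The inverse of [classmap_to_png()]; any pixel off the strict
#' black/yellow/green palette is an error reporting its coordinates.
#'
#' @param path PNG path.
#' @param section_id identifier for the resulting map.
#' @return A [class_map()].
#' @export
png_to_classmap <- function(path, section_id =
                              sub("\\.[^.]+$", "", basename(path))) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  x <- png::readPNG(path)
  if (length(dim(x)) != 3L || dim(x)[3] < 3L)
    stop(sprintf("'%s' is not an RGB class-map PNG", path))
  rgb <- round(x[, , 1:3] * 255)
  labels <- matrix(NA_integer_, dim(rgb)[1], dim(rgb)[2])
  for (k in 0:2) {
    hit <- rgb[, , 1] == CLASS_PALETTE[k + 1L, 1] &
           rgb[, , 2] == CLASS_PALETTE[k + 1L, 2] &
           rgb[, , 3] == CLASS_PALETTE[k + 1L, 3]
    labels[hit] <- k
  }
  if (anyNA(labels)) {
    bad <- which(is.na(labels), arr.ind = TRUE)
    stop(sprintf(
      "off-palette pixel(s) in '%s', first at (row %d, col %d): rgb(%d,%d,%d)",
      path, bad[1, 1], bad[1, 2],
      rgb[bad[1, 1], bad[1, 2], 1], rgb[bad[1, 1], bad[1, 2], 2],
      rgb[bad[1, 1], bad[1, 2], 3]))
  }
  class_map(labels, section_id)
}

#' Read and validate a YAML run configuration
#'
#' Known top-level keys: `method`, `seed`, `sp`, `train`, `grid`,
#' `thresholds` (`capacity`, `floor`), `expert` (`accept_dice`,
#' `accept_minutes`, `reject_minutes`, `manual_hours_per_section`),
#' `folds` (`n_folds`, `val_size`), `model` (`width`, `depth`),
#' `cohorts` (`n1`, `n2`, `n3`, `section_size`) and `paths`.  Unknown
#' keys are rejected.
#'
#' @param path YAML file.
#' @return An [adl_config()], with any `cohorts` settings attached as
#'   attribute `"cohorts"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  y <- yaml::read_yaml(path)
  known <- c("method", "seed", "sp", "train", "grid", "thresholds",
             "expert", "folds", "model", "cohorts", "paths")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste(extra, collapse = ", ")))
  pick <- function(lst, key, default) {
    v <- lst[[key]]
    if (is.null(v)) default else v
  }
  sp <- sp_config(
    gamma_step = pick(y$sp, "gamma_step", 0.05),
    gd_initial_step = pick(y$sp, "gd_initial_step", 0.10),
    gd_step_decrement = pick(y$sp, "gd_step_decrement", 0.01),
    bootstrap_iters = pick(y$sp, "bootstrap_iters", 5L),
    use_std = pick(y$sp, "use_std", FALSE))
  train <- train_config(
    epochs = pick(y$train, "epochs", 10L),
    snapshot_epochs = pick(y$train, "snapshot_epochs", c(8L, 9L, 10L)),
    seed = pick(y, "seed", 1L))
  grid <- patch_grid(
    window = pick(y$grid, "window", 64L),
    stride = pick(y$grid, "stride", 32L),
    trim = pick(y$grid, "trim", 16L),
    pad_mode = pick(y$grid, "pad_mode", "reflect"))
  cfg <- adl_config(
    method = pick(y, "method", "gdbsp"), sp = sp, train = train,
    grid = grid,
    n_folds = pick(y$folds, "n_folds", 2L),
    val_size = pick(y$folds, "val_size", 1L),
    capacity = pick(y$thresholds, "capacity", 12L),
    floor = pick(y$thresholds, "floor", 0.90),
    accept_dice = pick(y$expert, "accept_dice", 0.90),
    accept_minutes = pick(y$expert, "accept_minutes", 5),
    reject_minutes = pick(y$expert, "reject_minutes", 1),
    manual_hours_per_section =
      pick(y$expert, "manual_hours_per_section", 2),
    model_width = pick(y$model, "width", 4L),
    model_depth = pick(y$model, "depth", 2L),
    seed = pick(y, "seed", 1L))
  attr(cfg, "cohorts") <- y$cohorts
  attr(cfg, "paths") <- y$paths
  cfg
}

#' Write the run ledger as CSV
#'
#' One row per iteration, mirroring the acceptance-accounting columns
#' (confidence, threshold, accepted counts, dataset size, expert time).
#' An empty ledger yields a header-only file.
#'
#' @param ledger the `$ledger` tibble of an `adl_state` (or `NULL`).
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(ledger, path) {
  if (is.null(ledger))
    ledger <- tibble::tibble(
      iteration = integer(), method = character(),
      work_fold = character(), mean_fold_dice = numeric(),
      n_pending = integer(), n_presented = integer(),
      n_accepted = integer(), n_rejected = integer(),
      f_thresh = numeric(), mean_active_conf = numeric(),
      cum_accepted_sections = integer(), cum_accepted_samples = numeric(),
      pct_active_accepted_original = numeric(),
      dataset_size_pct = numeric(), expert_hours = numeric(),
      manual_hours_equiv = numeric(), time_saved_pct = numeric())
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}

#' Write a search or bootstrap trace as JSON lines
#'
#' @param trace data frame (e.g. the `"trace"` attribute of a search
#'   chain or the `$trace` of [bsp_iterate()]).
#' @param path destination `.jsonl` path.
#' @return `path`, invisibly.
#' @export
write_trace_jsonl <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(trace) && nrow(trace) > 0)
    for (i in seq_len(nrow(trace)))
      writeLines(jsonlite::toJSON(as.list(trace[i, ]), auto_unbox = TRUE),
                 con)
  invisible(path)
}
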