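# Grid decomposition of whole sections into network-sized patches, and
# the patch-wise "interpolation" stitcher: overlapping sliding windows are
# predicted but only each window's central block is kept, eliminating the
# grid pattern that patch-edge context starvation would otherwise leave.

#' Sliding-window geometry
#'
#' @param window window side length in pixels (full-scale default 512).
#' @param stride slide distance (default 256); also the side of the
#'   central block kept from each window.
#' @param trim buffer discarded on all four sides of each window output
#'   (default 128).  Must satisfy `window == stride + 2 * trim`.
#' @param pad_mode how the section is padded so edge windows get context:
#'   `"reflect"` (mirror, default) or `"zero"`.
#' @return A `patch_grid` object.
#' @export
patch_grid <- function(window = 512L, stride = 256L, trim = 128L,
                       pad_mode = c("reflect", "zero")) {
  pad_mode <- match.arg(pad_mode)
  window <- as.integer(window); stride <- as.integer(stride)
  trim <- as.integer(trim)
  if (window <= 2 * trim) stop("need window > 2 * trim")
  if (window != stride + 2L * trim)
    stop(sprintf("grid invariant violated: window (%d) != stride (%d) + 2*trim (%d)",
                 window, stride, 2L * trim))
  structure(list(window = window, stride = stride, trim = trim,
                 pad_mode = pad_mode),
            class = "patch_grid")
}

pad_matrix <- function(m, top, bottom, left, right, mode = "zero") {
  H <- nrow(m); W <- ncol(m)
  if (mode == "zero") {
    out <- matrix(0, H + top + bottom, W + left + right)
    out[top + seq_len(H), left + seq_len(W)] <- m
    out
  } else {  # symmetric reflection (edge row/col mirrored)
    if (top > H || bottom > H || left > W || right > W)
      stop("reflect padding wider than the image")
    ri <- c(rev(seq_len(top)), seq_len(H), H - seq_len(bottom) + 1L)
    ci <- c(rev(seq_len(left)), seq_len(W), W - seq_len(right) + 1L)
    m[ri, ci, drop = FALSE]
  }
}

#' Non-overlapping training patch grid
#'
#' Pads the section with zeros on the right/bottom to a window multiple
#' and tiles it exactly.  Used to cut training samples; prediction uses
#' [sliding_windows()] instead.
#'
#' @param section `section_image`, `class_map` or matrix.
#' @param window patch side length.
#' @return List with `patches` (list of window-sized matrices) and
#'   `coords` (0-based, half-open row/col intervals in the original
#'   section).
#' @export
grid_patches <- function(section, window = 512L) {
  m <- if (inherits(section, "class_map")) as_labels(section)
       else as_pixels(section)
  window <- as.integer(window)
  H <- nrow(m); W <- ncol(m)
  Hp <- ceiling(H / window) * window
  Wp <- ceiling(W / window) * window
  mp <- pad_matrix(m, 0L, Hp - H, 0L, Wp - W, mode = "zero")
  nby <- Hp %/% window; nbx <- Wp %/% window
  patches <- vector("list", nby * nbx)
  coords <- matrix(0L, nby * nbx, 4)
  k <- 1L
  for (bi in seq_len(nby) - 1L) for (bj in seq_len(nbx) - 1L) {
    patches[[k]] <- mp[bi * window + seq_len(window),
                       bj * window + seq_len(window), drop = FALSE]
    coords[k, ] <- c(bi * window, bj * window,
                     (bi + 1L) * window, (bj + 1L) * window)
    k <- k + 1L
  }
  colnames(coords) <- c("row0", "col0", "row1", "col1")
  list(patches = patches, coords = as.data.frame(coords))
}

# Number of stride blocks covering each axis.
stride_blocks <- function(shape, grid) {
  c(ceiling(shape[1] / grid$stride), ceiling(shape[2] / grid$stride))
}

#' Overlapping prediction windows
#'
#' Pads the section by `trim` on all four sides (per `pad_mode`) and with
#' zeros to a stride multiple on the right/bottom, then enumerates
#' window-sized views at every stride step.  The central `stride x stride`
#' blocks of the windows tile the original section exactly once.
#'
#' @param section `section_image` or matrix.
#' @param grid a [patch_grid()].
#' @return List with `windows` (list of matrices, row-major order),
#'   `centers` (0-based top-left coordinates of each center block in the
#'   original section), `grid` and `original_shape`.
#' @export
sliding_windows <- function(section, grid = patch_grid()) {
  stopifnot(inherits(grid, "patch_grid"))
  m <- as_pixels(section)
  H <- nrow(m); W <- ncol(m)
  nb <- stride_blocks(c(H, W), grid)
  Hp <- nb[1] * grid$stride; Wp <- nb[2] * grid$stride
  mp <- pad_matrix(m, 0L, Hp - H, 0L, Wp - W, mode = "zero")
  mp <- pad_matrix(mp, grid$trim, grid$trim, grid$trim, grid$trim,
                   mode = grid$pad_mode)
  windows <- vector("list", nb[1] * nb[2])
  centers <- matrix(0L, nb[1] * nb[2], 2)
  k <- 1L
  for (bi in seq_len(nb[1]) - 1L) for (bj in seq_len(nb[2]) - 1L) {
    windows[[k]] <- mp[bi * grid$stride + seq_len(grid$window),
                       bj * grid$stride + seq_len(grid$window),
                       drop = FALSE]
    centers[k, ] <- c(bi * grid$stride, bj * grid$stride)
    k <- k + 1L
  }
  colnames(centers) <- c("row0", "col0")
  list(windows = windows, centers = as.data.frame(centers), grid = grid,
       original_shape = c(H, W))
}

#' Stitch window outputs back into a full-section map
#'
#' Places the central `stride x stride` block of each window output at its
#' center coordinates and crops the stride padding, recovering a map of
#' the original section shape.  Outputs must be in the row-major order
#' produced by [sliding_windows()].
#'
#' @param outputs list of window-sized matrices, one per window.
#' @param grid the [patch_grid()] used to cut the windows.
#' @param original_shape integer vector `c(rows, cols)` of the section.
#' @return Matrix of shape `original_shape`.
#' @export
stitch_centers <- function(outputs, grid, original_shape) {
  stopifnot(inherits(grid, "patch_grid"))
  nb <- stride_blocks(original_shape, grid)
  expected <- nb[1] * nb[2]
  if (length(outputs) != expected) {
    want <- expand.grid(
      row0 = (seq_len(nb[1]) - 1L) * grid$stride,
      col0 = (seq_len(nb[2]) - 1L) * grid$stride)
    stop(sprintf(
      "expected %d window outputs for a %s section (centers at rows %s, cols %s), got %d",
      expected, paste(original_shape, collapse = "x"),
      paste(unique(want$row0), collapse = ","),
      paste(unique(want$col0), collapse = ","), length(outputs)))
  }
  canvas <- matrix(0, nb[1] * grid$stride, nb[2] * grid$stride)
  ctr <- grid$trim + seq_len(grid$stride)
  k <- 1L
  for (bi in seq_len(nb[1]) - 1L) for (bj in seq_len(nb[2]) - 1L) {
    out <- outputs[[k]]
    if (!all(dim(out) == grid$window))
      stop(sprintf("window output %d has shape %s, expected %dx%d",
                   k, paste(dim(out), collapse = "x"),
                   grid$window, grid$window))
    canvas[bi * grid$stride + seq_len(grid$stride),
           bj * grid$stride + seq_len(grid$stride)] <- out[ctr, ctr]
    k <- k + 1L
  }
  canvas[seq_len(original_shape[1]), seq_len(original_shape[2]),
         drop = FALSE]
}
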