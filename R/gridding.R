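# Line-wise gridding of the 1D receive signal onto a raw image.
#
# Raw-image layout (constructive convention, fixed by the pass/sweep labels
# of make_sequence): the raw image is a 2 x 2 block mosaic of sub-images of
# the FOV projection,
#   rows    1..nz      : positive-polarity FFL passes
#   rows nz+1..2*nz    : negative-polarity passes
#   cols    1..nx      : forward deflection sweeps (x increasing)
#   cols nx+1..2*nx    : backward sweeps, stored mirrored in x
# so one acquisition deposits the same tracer information four times
# (left/right sweep x FFL polarity), each convolved with the scanner PSF.

# Internal: precompute the sample -> raw-pixel assignment for a trajectory.
# Reused across system-matrix columns.
gridding_plan <- function(traj, shape = c(124, 128)) {
  stopifnot(inherits(traj, "mpi_trajectory"))
  if (length(shape) != 2 || any(shape < 2) || any(shape %% 2 != 0))
    stop("shape must be two even integers (rows, cols)")
  cfg <- traj$config
  nz <- shape[1] / 2
  nx <- shape[2] / 2
  col_in <- pmin(pmax(ceiling((traj$x + cfg$x_max) /
                                (2 * cfg$x_max) * nx), 1L), nx)
  row_in <- pmin(pmax(ceiling((traj$z + cfg$fov_z / 2) /
                                cfg$fov_z * nz), 1L), nz)
  col <- ifelse(traj$sweep > 0, col_in, 2L * nx + 1L - col_in)
  row <- ifelse(traj$sign > 0, row_in, nz + row_in)
  idx <- (col - 1L) * (2L * nz) + row
  hits <- tabulate(idx, nbins = 4L * nz * nx)
  submap <- matrix(0L, 2L * nz, 2L * nx)
  submap[seq_len(nz), seq_len(nx)] <- 1L              # +polarity, forward
  submap[seq_len(nz), nx + seq_len(nx)] <- 2L         # +polarity, backward
  submap[nz + seq_len(nz), seq_len(nx)] <- 3L         # -polarity, forward
  submap[nz + seq_len(nz), nx + seq_len(nx)] <- 4L    # -polarity, backward
  list(idx = idx, hits = hits, shape = c(2L * nz, 2L * nx), submap = submap)
}

#' Grid a signal frame onto a raw image
#'
#' Co-registers the 1D time signal point-by-point onto a 2D raw image using
#' the known FFL trajectory: each sample is accumulated (nearest neighbor) at
#' the pixel of its FFL position and every pixel is normalized by its hit
#' count. The raw image holds four redundant sub-images of the FOV (forward /
#' backward deflection sweep times positive / negative FFL polarity), laid
#' out as a 2 x 2 block mosaic with the backward-sweep blocks mirrored in x.
#'
#' @param frame a [signal_frame()] (typically fundamental-filtered and
#'   band-selected).
#' @param traj the matching [make_sequence()] trajectory.
#' @param shape raw-image dimensions `c(rows, cols)`, both even; each
#'   sub-image is `rows/2 x cols/2`.
#' @return An object of class `raw_image`: list with `grid` (hit-normalized),
#'   `hit_counts`, `subimage_map` (1..4 block labels) and `shape`.
#' @export
#' @examples
#' cfg <- scanner_config(fs = 49600)
#' traj <- make_sequence(cfg)
#' ph <- point_sample(c(0.01, 0.01), 1e-6, config = cfg, pixel_size = 0.004)
#' fr <- filter_fundamental(simulate_frame(ph, traj, tracer_model()), cfg)
#' raw <- grid_raw(fr, traj, shape = c(62, 64))
grid_raw <- function(frame, traj, shape = c(124, 128)) {
  stopifnot(inherits(frame, "signal_frame"), inherits(traj, "mpi_trajectory"))
  if (length(frame$samples) != length(traj$t))
    stop("frame and trajectory have different lengths")
  if (abs(frame$fs - traj$config$fs) > 1e-9)
    stop("frame and trajectory sampling rates differ")
  plan <- gridding_plan(traj, shape)
  sums <- numeric(length(plan$hits))
  acc <- rowsum(frame$samples, plan$idx)
  sums[as.integer(rownames(acc))] <- acc[, 1]
  grid <- matrix(ifelse(plan$hits > 0, sums / pmax(plan$hits, 1L), 0),
                 plan$shape[1], plan$shape[2])
  structure(list(grid = grid,
                 hit_counts = matrix(plan$hits, plan$shape[1], plan$shape[2]),
                 subimage_map = plan$submap, shape = plan$shape),
            class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %d x %d (4 sub-images of %d x %d), %d samples gridded\n",
              x$shape[1], x$shape[2], x$shape[1] / 2, x$shape[2] / 2,
              sum(x$hit_counts)))
  invisible(x)
}

#' @export
plot.raw_image <- function(x, ...) {
  graphics::image(t(x$grid), asp = nrow(x$grid) / ncol(x$grid),
                  xlab = "x blocks", ylab = "z blocks",
                  main = "raw image", useRaster = TRUE, ...)
  invisible(x)
}

#' Fold the four redundant sub-images
#'
#' Brings the four sub-images of a raw image into a common orientation
#' (un-mirroring the backward-sweep blocks in x; negating the
#' opposite-polarity blocks, whose induced signal has flipped sign) and
#' averages them with hit-count weights, enhancing the SNR by about the
#' square root of the number of folded copies.
#'
#' @param raw a [grid_raw()] result.
#' @return An object of class `folded_image`: list with `grid` (one FOV
#'   sub-image), `hit_counts` (summed weights) and `provenance` (which
#'   sub-images contributed).
#' @export
fold <- function(raw) {
  stopifnot(inherits(raw, "raw_image"))
  nz <- raw$shape[1] / 2
  nx <- raw$shape[2] / 2
  blocks <- list(
    list(rows = seq_len(nz),      cols = seq_len(nx),      mirror = FALSE, s = +1),
    list(rows = seq_len(nz),      cols = nx + seq_len(nx), mirror = TRUE,  s = +1),
    list(rows = nz + seq_len(nz), cols = seq_len(nx),      mirror = FALSE, s = -1),
    list(rows = nz + seq_len(nz), cols = nx + seq_len(nx), mirror = TRUE,  s = -1)
  )
  num <- matrix(0, nz, nx)
  den <- matrix(0, nz, nx)
  used <- integer(0)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    g <- raw$grid[bl$rows, bl$cols, drop = FALSE]
    h <- raw$hit_counts[bl$rows, bl$cols, drop = FALSE]
    if (bl$mirror) {
      g <- g[, rev(seq_len(nx)), drop = FALSE]
      h <- h[, rev(seq_len(nx)), drop = FALSE]
    }
    if (sum(h) == 0) next
    used <- c(used, b)
    num <- num + bl$s * g * h
    den <- den + h
  }
  if (length(used) < 4)
    warning(sprintf("folding over %d of 4 sub-images (others received no samples)",
                    length(used)))
  if (length(used) == 0) stop("no sub-image received any sample")
  structure(list(grid = ifelse(den > 0, num / pmax(den, 1), 0),
                 hit_counts = den, provenance = used),
            class = "folded_image")
}

#' @export
print.folded_image <- function(x, ...) {
  cat(sprintf("<folded_image> %d x %d from sub-images {%s}\n",
              nrow(x$grid), ncol(x$grid), paste(x$provenance, collapse = ",")))
  invisible(x)
}

#' @export
plot.folded_image <- function(x, ...) {
  graphics::image(t(x$grid), asp = nrow(x$grid) / ncol(x$grid),
                  xlab = "x", ylab = "z", main = "folded image",
                  useRaster = TRUE, ...)
  invisible(x)
}
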