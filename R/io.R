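#' Write / read a scanner configuration file
#'
#' Flat YAML key/value document mirroring the [scanner_config()] fields.
#' Reading validates through the constructor; unknown keys are rejected.
#'
#' @param config a [scanner_config()].
#' @param path file path (`.yaml`).
#' @return `write_scanner_config` returns `path` invisibly;
#'   `read_scanner_config` returns the validated [scanner_config()].
#' @export
write_scanner_config <- function(config, path) {
  stopifnot(inherits(config, "scanner_config"))
  keep <- setdiff(names(config), c("gradient", "commensurate"))
  yaml::write_yaml(config[keep], path, precision = 15)
  invisible(path)
}

#' @rdname write_scanner_config
#' @export
read_scanner_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(scanner_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown scanner configuration keys: ", paste(unknown, collapse = ", "))
  do.call(scanner_config, vals)
}

#' Export an image array as 16-bit grayscale TIFF with sidecar metadata
#'
#' The array is linearly scaled to the 16-bit range; the scale, pixel size
#' and provenance metadata go into a YAML sidecar (`<path>.yaml`) so the
#' array round-trips quantitatively to 16-bit precision.
#'
#' @param grid numeric matrix (rows = z, increasing upward; written so the
#'   image top row is the highest z).
#' @param path output TIFF path.
#' @param pixel_size pixel size in m (metadata).
#' @param meta named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(grid, path, pixel_size = NA, meta = list()) {
  if (!is.matrix(grid)) stop("grid must be a matrix")
  lo <- min(grid); hi <- max(grid)
  scaled <- if (hi > lo) (grid - lo) / (hi - lo) else grid * 0
  tiff::writeTIFF(scaled[rev(seq_len(nrow(scaled))), , drop = FALSE], path,
                  bits.per.sample = 16L)
  side <- c(list(min = lo, max = hi, pixel_size = pixel_size,
                 rows = nrow(grid), cols = ncol(grid),
                 package = "fflmpi",
                 version = as.character(utils::packageVersion("fflmpi"))),
            meta)
  yaml::write_yaml(side, paste0(path, ".yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  grid <- img[rev(seq_len(nrow(img))), , drop = FALSE]
  grid <- grid * (side$max - side$min) + side$min
  attr(grid, "meta") <- side
  grid
}

#' Write / read a phantom (16-bit TIFF + sidecar)
#'
#' @param ph an [phantom()].
#' @param path output TIFF path.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` the
#'   [phantom()].
#' @export
write_phantom <- function(ph, path) {
  stopifnot(inherits(ph, "mpi_phantom"))
  write_image_tiff(ph$grid, path, pixel_size = ph$pixel_size,
                  meta = list(total_iron_mol = sum(ph$grid),
                              origin = as.list(ph$origin), label = ph$label))
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  grid <- read_image_tiff(path)
  meta <- attr(grid, "meta")
  attr(grid, "meta") <- NULL
  grid[grid < 0] <- 0
  phantom(grid, pixel_size = meta$pixel_size,
          origin = unlist(meta$origin), label = meta$label %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / restore a system matrix
#'
#' The matrix is stored as an RDS container together with its build-parameter
#' fingerprint; `load_system_matrix` refuses a matrix whose fingerprint does
#' not match the supplied configuration and tracer.
#'
#' @param sm a [build_system_matrix()] result.
#' @param path file path (`.rds`).
#' @param config,tracer optional: when given, the stored fingerprint is
#'   checked against a rebuild fingerprint for these objects.
#' @return `save_system_matrix` returns `path` invisibly;
#'   `load_system_matrix` the `system_matrix`.
#' @export
save_system_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "system_matrix"))
  saveRDS(sm, path)
  invisible(path)
}

#' @rdname save_system_matrix
#' @export
load_system_matrix <- function(path, config = NULL, tracer = NULL) {
  sm <- readRDS(path)
  if (!inherits(sm, "system_matrix")) stop("file does not hold a system matrix")
  if (!is.null(config) && !is.null(tracer)) {
    want <- .sm_fingerprint(config, tracer, sm$grid, sm$shape, sm$n_set, sm$k_max)
    if (!identical(want, sm$build_params))
      stop("system-matrix fingerprint does not match the configuration; rebuild it")
  }
  sm
}
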