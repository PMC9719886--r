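# Simple 2-D parameter-map phantoms: a uniform background with a circular
# lesion disk, optional additive Gaussian noise, and an optional excluded
# core emulating the necrotic/cystic portions that ROIs must avoid.

#' Specification of a 2-D parameter-map phantom
#'
#' @param grid_shape Integer \code{c(rows, cols)} in pixels.
#' @param background_value Named (or unnamed) numeric vector: one background
#'   level per parameter map to generate.
#' @param lesion_center \code{c(row, col)}, 0-based pixel coordinates.
#' @param lesion_radius Lesion disk radius in pixels.
#' @param lesion_value Numeric vector parallel to \code{background_value}:
#'   the disk's level in each map.
#' @param excluded_core_radius Radius (pixels) of a central core flagged as
#'   excluded in the companion mask; 0 means none.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise.
#' @param seed Integer RNG seed.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L), background_value = 50,
                         lesion_center = c(31, 31), lesion_radius = 12,
                         lesion_value = 240, excluded_core_radius = 0,
                         noise_sd = 0, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L)) {
    stop("grid_shape must be two positive integers", call. = FALSE)
  }
  if (length(background_value) != length(lesion_value)) {
    stop("background_value and lesion_value must have the same length", call. = FALSE)
  }
  if (lesion_radius <= 0) stop("lesion_radius must be > 0", call. = FALSE)
  if (excluded_core_radius < 0 || excluded_core_radius >= lesion_radius) {
    stop("excluded_core_radius must satisfy 0 <= core < lesion_radius", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (lesion_center[1L] - lesion_radius < 0 ||
      lesion_center[2L] - lesion_radius < 0 ||
      lesion_center[1L] + lesion_radius > grid_shape[1L] - 1L ||
      lesion_center[2L] + lesion_radius > grid_shape[2L] - 1L) {
    stop("lesion disk must lie fully inside the grid", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, background_value = background_value,
                 lesion_center = lesion_center, lesion_radius = lesion_radius,
                 lesion_value = lesion_value,
                 excluded_core_radius = excluded_core_radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate phantom parameter maps and their exclusion mask
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list with \code{maps} (named list of numeric matrices, one per
#'   entry of \code{background_value}) and \code{mask} (logical matrix,
#'   \code{TRUE} = excluded pixel), class \code{phantom}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_shape[1L]
  nc <- spec$grid_shape[2L]
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(rep(seq_len(nc) - 1L, each = nr), nr, nc)
  d2 <- (rows - spec$lesion_center[1L])^2 + (cols - spec$lesion_center[2L])^2
  disk <- d2 <= spec$lesion_radius^2
  core <- if (spec$excluded_core_radius > 0) {
    d2 <= spec$excluded_core_radius^2
  } else {
    matrix(FALSE, nr, nc)
  }
  nm <- names(spec$background_value)
  if (is.null(nm)) nm <- paste0("map", seq_along(spec$background_value))
  maps <- vector("list", length(nm))
  names(maps) <- nm
  for (i in seq_along(nm)) {
    m <- matrix(spec$background_value[i], nr, nc)
    m[disk] <- spec$lesion_value[i]
    if (spec$noise_sd > 0) m <- m + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    maps[[i]] <- m
  }
  structure(list(maps = maps, mask = core, spec = spec), class = "phantom")
}

#' Write / read phantom maps as plain CSV matrices
#'
#' Each map is written as \code{<prefix>_<name>.csv}; the exclusion mask as
#' \code{<prefix>_mask.csv} (0/1).
#'
#' @param phantom A \code{phantom} from \code{\link{generate_phantom}}.
#' @param prefix Path prefix for the output files.
#' @return \code{write_phantom} returns the written paths invisibly;
#'   \code{read_phantom} returns a list with \code{maps} and \code{mask}.
#' @export
write_phantom <- function(phantom, prefix) {
  paths <- character(0)
  for (nm in names(phantom$maps)) {
    p <- paste0(prefix, "_", nm, ".csv")
    utils::write.table(phantom$maps[[nm]], p, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_mask.csv")
  utils::write.table(phantom$mask * 1L, p, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(paths, p))
}

#' @rdname write_phantom
#' @param map_names Names of the maps to read back.
#' @export
read_phantom <- function(prefix, map_names) {
  read_mat <- function(p) {
    if (!file.exists(p)) stop("phantom file not found: ", p, call. = FALSE)
    as.matrix(utils::read.table(p, sep = ",", header = FALSE))
  }
  maps <- lapply(map_names, function(nm) {
    m <- read_mat(paste0(prefix, "_", nm, ".csv"))
    dimnames(m) <- NULL
    m
  })
  names(maps) <- map_names
  mask <- read_mat(paste0(prefix, "_mask.csv")) == 1
  dimnames(mask) <- NULL
  list(maps = maps, mask = mask)
}
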