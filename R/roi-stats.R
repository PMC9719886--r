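#' Circular region of interest on a 2-D parameter map
#'
#' A pixel belongs to the ROI iff its center lies at Euclidean distance
#' \code{<= radius} from the ROI center; there is no partial-pixel
#' weighting.  Coordinates are 0-based \code{(row, col)} with pixel centers
#' at integer positions.
#'
#' @param center \code{c(row, col)}, 0-based pixel coordinates.
#' @param radius Radius in pixels, > 0.
#' @param pixel_spacing Isotropic pixel size in mm/pixel.
#' @return An object of class \code{circular_roi}.
#' @export
circular_roi <- function(center, radius, pixel_spacing = 1) {
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("center must be c(row, col)", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("pixel_spacing must be > 0", call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius,
                 pixel_spacing = pixel_spacing),
            class = "circular_roi")
}

#' Nominal (geometric) area of a circular ROI
#'
#' @param roi A \code{\link{circular_roi}}.
#' @return Area in mm^2: \code{pi * (radius * pixel_spacing)^2}.
#' @export
roi_area <- function(roi) {
  stopifnot(inherits(roi, "circular_roi"))
  pi * (roi$radius * roi$pixel_spacing)^2
}

#' Mean map value inside a circular ROI
#'
#' Averages the pixels whose centers fall inside the disk, excluding any
#' pixel flagged in \code{exclusion_mask} (the counterpart of avoiding
#' necrotic or cystic portions when placing a clinical ROI).
#'
#' @param map Numeric matrix (one parameter map).
#' @param roi A \code{\link{circular_roi}}.
#' @param exclusion_mask Optional logical matrix of \code{dim(map)};
#'   \code{TRUE} pixels are excluded.
#' @return List with \code{mean}, \code{n_pixels} and \code{area_mm2}
#'   (pixel count times squared pixel spacing).
#' @export
roi_mean <- function(map, roi, exclusion_mask = NULL) {
  stopifnot(is.matrix(map), inherits(roi, "circular_roi"))
  if (!is.null(exclusion_mask) && !identical(dim(exclusion_mask), dim(map))) {
    stop("exclusion_mask dimensions must match the map", call. = FALSE)
  }
  inside <- roi_pixels(dim(map), roi)
  if (!any(inside)) {
    stop("ROI lies fully outside the grid (no pixel center inside the disk)",
         call. = FALSE)
  }
  keep <- inside
  if (!is.null(exclusion_mask)) keep <- keep & !exclusion_mask
  if (!any(keep)) {
    stop("ROI is empty after applying the exclusion mask", call. = FALSE)
  }
  n <- sum(keep)
  list(mean = mean(map[keep]), n_pixels = n,
       area_mm2 = n * roi$pixel_spacing^2)
}

roi_pixels <- function(grid_dim, roi) {
  nr <- grid_dim[1L]
  nc <- grid_dim[2L]
  rows <- matrix(seq_len(nr) - 1L, nr, nc)
  cols <- matrix(rep(seq_len(nc) - 1L, each = nr), nr, nc)
  (rows - roi$center[1L])^2 + (cols - roi$center[2L])^2 <= roi$radius^2
}

#' Measure a lesion-node pair of co-registered parameter maps
#'
#' Applies \code{\link{roi_mean}} to the five parameter maps of each site and
#' assembles the two \code{\link{spectral_measurement}} objects with
#' \code{roi_area} set from the pixel count.
#'
#' @param lesion_maps,node_maps Named lists of matrices with elements
#'   \code{att40}, \code{att70}, \code{ic}, \code{wc}, \code{effz}; all maps
#'   of one site must share dimensions.
#' @param lesion_roi,node_roi \code{\link{circular_roi}} objects.
#' @param lesion_mask,node_mask Optional exclusion masks per site.
#' @return List with elements \code{lesion} and \code{node}, each a
#'   \code{spectral_measurement}.
#' @export
measure_pair <- function(lesion_maps, node_maps, lesion_roi, node_roi,
                         lesion_mask = NULL, node_mask = NULL) {
  measure_site <- function(maps, roi, mask, site) {
    need <- c("att40", "att70", "ic", "wc", "effz")
    if (!all(need %in% names(maps))) {
      stop("maps for the ", site, " must be named att40/att70/ic/wc/effz",
           call. = FALSE)
    }
    dims <- lapply(maps[need], dim)
    if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
      stop("mismatched grid shapes across the ", site, "'s parameter maps",
           call. = FALSE)
    }
    means <- lapply(need, function(p) roi_mean(maps[[p]], roi, mask))
    spectral_measurement(att40 = means[[1L]]$mean, att70 = means[[2L]]$mean,
                         ic = means[[3L]]$mean, wc = means[[4L]]$mean,
                         effz = means[[5L]]$mean,
                         roi_area = means[[1L]]$area_mm2)
  }
  list(lesion = measure_site(lesion_maps, lesion_roi, lesion_mask, "lesion"),
       node = measure_site(node_maps, node_roi, node_mask, "node"))
}
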