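#' Spectral slope of the Hounsfield-unit curve
#'
#' The spectral slope (lambda-HU) is the drop in CT attenuation between the
#' 40-keV and 70-keV virtual monochromatic images divided by the 30-keV
#' energy difference.  It is a proxy for iodine content of the tissue.
#'
#' @param att40 Attenuation at 40 keV (HU).
#' @param att70 Attenuation at 70 keV (HU).
#' @return Spectral slope in HU/keV. Vectorised over its arguments.
#' @examples
#' compute_lambda_hu(288, 108) # 6.0 HU/keV
#' @export
compute_lambda_hu <- function(att40, att70) {
  if (!is.numeric(att40) || !is.numeric(att70)) {
    stop("attenuations must be numeric", call. = FALSE)
  }
  if (any(!is.finite(att40)) || any(!is.finite(att70))) {
    stop("attenuations must be finite", call. = FALSE)
  }
  (att40 - att70) / 30
}

#' Rate of difference (ROD) between a lymph-node and a primary-lesion value
#'
#' The ROD is |node - lesion| / |lesion|: the relative discrepancy of a
#' quantitative parameter between an axillary lymph node and the primary
#' breast lesion.  Zero means the two sites are identical on that parameter;
#' the closer to zero, the more similar.
#'
#' The denominator uses the absolute lesion value so that the statistic is
#' nonnegative even for parameters that can be negative in other tissues
#' (e.g. attenuation); for all quantities encountered in a contrast-enhanced
#' breast study the lesion value is positive and the two conventions agree.
#'
#' @param node_value Value measured in the lymph node.
#' @param lesion_value Value measured in the primary lesion; must be nonzero.
#' @return Nonnegative dimensionless ROD. Vectorised.
#' @examples
#' compute_rod(288, 284) # 0.014 to 2 s.f.
#' @export
compute_rod <- function(node_value, lesion_value) {
  if (!is.numeric(node_value) || !is.numeric(lesion_value)) {
    stop("ROD inputs must be numeric", call. = FALSE)
  }
  if (any(!is.finite(node_value)) || any(!is.finite(lesion_value))) {
    stop("ROD inputs must be finite", call. = FALSE)
  }
  if (any(lesion_value == 0)) {
    stop("ROD is undefined: primary-lesion value is zero", call. = FALSE)
  }
  abs(node_value - lesion_value) / abs(lesion_value)
}

#' Construct one ROI's spectral measurement
#'
#' Bundles the five quantitative dual-energy CT parameters measured in one
#' circular ROI: attenuation at 40 and 70 keV (HU), iodine and water
#' concentration (mg/cm^3) and effective atomic number, plus an optional
#' ROI area (mm^2).
#'
#' @param att40,att70 Attenuation at 40 / 70 keV (HU).
#' @param ic Iodine concentration (mg/cm^3), nonnegative.
#' @param wc Water concentration (mg/cm^3), positive.
#' @param effz Effective atomic number, positive.
#' @param roi_area Optional ROI area (mm^2), positive when given.
#' @return An object of class \code{spectral_measurement} (named list).
#' @export
spectral_measurement <- function(att40, att70, ic, wc, effz, roi_area = NA_real_) {
  vals <- c(att40 = att40, att70 = att70, ic = ic, wc = wc, effz = effz)
  if (!all(is.finite(vals))) stop("spectral measurement must be finite", call. = FALSE)
  if (ic < 0) stop("iodine concentration must be >= 0", call. = FALSE)
  if (wc <= 0) stop("water concentration must be > 0", call. = FALSE)
  if (effz <= 0) stop("effective atomic number must be > 0", call. = FALSE)
  if (!is.na(roi_area) && roi_area <= 0) stop("roi_area must be > 0", call. = FALSE)
  structure(list(att40 = att40, att70 = att70, ic = ic, wc = wc, effz = effz,
                 roi_area = roi_area),
            class = "spectral_measurement")
}

#' Construct an aorta reference measurement
#'
#' Aortic IC, WC and Eff-Z measured in the same phase; used to normalise the
#' lesion and node values and so remove inter-patient differences in cardiac
#' output and contrast-bolus dynamics.
#'
#' @param ic,wc,effz Aortic iodine concentration, water concentration and
#'   effective atomic number; all strictly positive.
#' @return An object of class \code{aorta_reference}.
#' @export
aorta_reference <- function(ic, wc, effz) {
  if (!all(is.finite(c(ic, wc, effz))) || any(c(ic, wc, effz) <= 0)) {
    stop("aorta reference values must be finite and > 0", call. = FALSE)
  }
  structure(list(ic = ic, wc = wc, effz = effz), class = "aorta_reference")
}

#' Normalise a measurement by the aortic reference
#'
#' Divides the ROI's IC, WC and Eff-Z by the corresponding aortic value,
#' yielding dimensionless normalised parameters.
#'
#' @param measurement A \code{spectral_measurement} (or list with
#'   \code{ic}, \code{wc}, \code{effz}).
#' @param aorta An \code{aorta_reference} (or list with the same fields).
#' @return Named numeric vector \code{c(norm_ic, norm_wc, norm_effz)}.
#' @export
normalize_by_aorta <- function(measurement, aorta) {
  a <- c(aorta$ic, aorta$wc, aorta$effz)
  if (!all(is.finite(a)) || any(a <= 0)) {
    stop("aorta reference values must be finite and > 0", call. = FALSE)
  }
  c(norm_ic   = measurement$ic   / aorta$ic,
    norm_wc   = measurement$wc   / aorta$wc,
    norm_effz = measurement$effz / aorta$effz)
}

#' Per-parameter ROD similarity profile of a lesion-node pair
#'
#' Applies \code{\link{compute_rod}} element-wise to the six quantitative
#' parameters (attenuation at 40 and 70 keV, spectral slope, IC, WC, Eff-Z)
#' of a primary lesion and an axillary node.  If a site's \code{lambda_hu}
#' is not supplied it is derived from the attenuations; supplying it allows
#' reproducing printed worked examples from rounded slopes.
#'
#' @param lesion,node Lists (e.g. \code{spectral_measurement}) with fields
#'   \code{att40}, \code{att70}, \code{ic}, \code{wc}, \code{effz} and
#'   optionally \code{lambda_hu}.
#' @return An object of class \code{similarity_profile}: named numeric vector
#'   with elements \code{rod_att40}, \code{rod_att70}, \code{rod_lambda},
#'   \code{rod_ic}, \code{rod_wc}, \code{rod_effz}.
#' @export
similarity_profile <- function(lesion, node) {
  get_lambda <- function(m) {
    if (!is.null(m$lambda_hu)) m$lambda_hu else compute_lambda_hu(m$att40, m$att70)
  }
  params <- c("att40", "att70", "lambda", "ic", "wc", "effz")
  lv <- c(lesion$att40, lesion$att70, get_lambda(lesion), lesion$ic, lesion$wc, lesion$effz)
  nv <- c(node$att40, node$att70, get_lambda(node), node$ic, node$wc, node$effz)
  if (any(lv == 0)) {
    stop("ROD is undefined: primary-lesion value is zero for parameter '",
         params[which(lv == 0)[1L]], "'", call. = FALSE)
  }
  out <- compute_rod(nv, lv)
  names(out) <- paste0("rod_", params)
  structure(out, class = c("similarity_profile", "numeric"))
}

#' @export
print.similarity_profile <- function(x, ...) {
  cat("Lesion-node ROD similarity profile (0 = identical):\n")
  print(signif(unclass(x), 2), ...)
  invisible(x)
}

#' Add derived DECT columns to a cohort data frame
#'
#' Computes, for every patient row: the spectral slope of lesion and node,
#' the aorta-normalised IC/WC/Eff-Z of both sites, and the six lesion-node
#' ROD similarity parameters.
#'
#' @param cohort A cohort data frame in the standard schema
#'   (see \code{\link{generate_cohort}}).
#' @return The cohort with additional columns \code{lesion_lambda_hu},
#'   \code{node_lambda_hu}, \code{lesion_norm_*}, \code{node_norm_*} and
#'   \code{rod_*}.
#' @export
derive_cohort_parameters <- function(cohort) {
  need <- c("lesion_att40_hu", "lesion_att70_hu", "lesion_ic_mgcm3",
            "lesion_wc_mgcm3", "lesion_effz",
            "node_att40_hu", "node_att70_hu", "node_ic_mgcm3",
            "node_wc_mgcm3", "node_effz",
            "aorta_ic_mgcm3", "aorta_wc_mgcm3", "aorta_effz")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cohort$lesion_lambda_hu <- compute_lambda_hu(cohort$lesion_att40_hu, cohort$lesion_att70_hu)
  cohort$node_lambda_hu   <- compute_lambda_hu(cohort$node_att40_hu, cohort$node_att70_hu)

  if (any(cohort$aorta_ic_mgcm3 <= 0 | cohort$aorta_wc_mgcm3 <= 0 | cohort$aorta_effz <= 0)) {
    stop("aorta reference values must be > 0", call. = FALSE)
  }
  cohort$lesion_norm_ic   <- cohort$lesion_ic_mgcm3 / cohort$aorta_ic_mgcm3
  cohort$lesion_norm_wc   <- cohort$lesion_wc_mgcm3 / cohort$aorta_wc_mgcm3
  cohort$lesion_norm_effz <- cohort$lesion_effz     / cohort$aorta_effz
  cohort$node_norm_ic     <- cohort$node_ic_mgcm3 / cohort$aorta_ic_mgcm3
  cohort$node_norm_wc     <- cohort$node_wc_mgcm3 / cohort$aorta_wc_mgcm3
  cohort$node_norm_effz   <- cohort$node_effz     / cohort$aorta_effz

  pairs <- list(
    rod_att40  = c("node_att40_hu",   "lesion_att40_hu"),
    rod_att70  = c("node_att70_hu",   "lesion_att70_hu"),
    rod_lambda = c("node_lambda_hu",  "lesion_lambda_hu"),
    rod_ic     = c("node_ic_mgcm3",   "lesion_ic_mgcm3"),
    rod_wc     = c("node_wc_mgcm3",   "lesion_wc_mgcm3"),
    rod_effz   = c("node_effz",       "lesion_effz")
  )
  for (nm in names(pairs)) {
    lesion_vals <- cohort[[pairs[[nm]][2L]]]
    if (any(lesion_vals == 0, na.rm = TRUE)) {
      stop("ROD is undefined: zero primary-lesion value for '", nm, "'", call. = FALSE)
    }
    cohort[[nm]] <- compute_rod(cohort[[pairs[[nm]][1L]]], lesion_vals)
  }
  cohort
}
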