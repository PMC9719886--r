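# Cohort simulation: one latent-Gaussian factor per patient links the five
# lesion and five node DECT parameters; site factors add the extra
# correlation shared by parameters measured in the same ROI.  Marginals are
# Gaussian with rejection resampling for physical constraints.

#' Generate a synthetic cohort of paired lesion-node DECT records
#'
#' Draws \code{n_patients} patient records with the joint structure of the
#' published cohort: within each metastasis group the five node parameters
#' and five lesion parameters follow a latent-Gaussian (copula) factor model
#' with a configurable lesion-node rank correlation; morphology, pathology
#' and the aortic reference are drawn independently per group.  Physically
#' impossible draws (nonpositive concentrations/diameters, 40-keV attenuation
#' not exceeding 70-keV) are rejected and resampled, never clipped.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param n_patients Optional override of \code{config$n_patients}.
#' @return A data frame (one row per patient) in the standard cohort schema;
#'   see \code{\link{cohort_schema}}.
#' @export
generate_cohort <- function(config = cohort_config(), n_patients = NULL) {
  validate_cohort_config(config)
  n <- if (is.null(n_patients)) config$n_patients else as.integer(n_patients)
  if (is.na(n) || n <= 0L) {
    stop("configuration error: n_patients must be a positive integer", call. = FALSE)
  }

  set.seed(config$seed)
  group <- stats::rbinom(n, 1L, config$metastasis_fraction)

  aorta <- data.frame(
    aorta_ic_mgcm3 = rnorm_reject(n, config$aorta_params$ic, function(x) x > 0),
    aorta_wc_mgcm3 = rnorm_reject(n, config$aorta_params$wc, function(x) x > 0),
    aorta_effz     = rnorm_reject(n, config$aorta_params$effz, function(x) x > 0)
  )

  out <- vector("list", 2L)
  for (g in c(1L, 0L)) {
    gname <- if (g == 1L) "metastasis" else "non_metastasis"
    idx <- which(group == g)
    m <- length(idx)
    if (m == 0L) next
    dect <- draw_dect_block(
      m,
      marginals = config$group_marginals[[gname]],
      rank_rho = config$lesion_node_rank_correlation[[gname]],
      within = config$within_site_correlation
    )
    mo <- config$morphology_params[[gname]]
    pa <- config$pathology_params[[gname]]
    short <- rnorm_reject(m, mo$short, function(x) x > 0)
    long <- draw_long_diameter(m, mo$long, short)
    hilum <- stats::rbinom(m, 1L, 1 - mo$hilum_absent)
    er <- stats::rbinom(m, 1L, pa$er_positive)
    grade_draw <- sample.int(4L, m, replace = TRUE, prob = pa$nuclear_grade)
    grade <- ifelse(grade_draw == 4L, NA_integer_, grade_draw)
    ki67 <- 100 * stats::plogis(stats::rnorm(m, pa$ki67_logit[1L], pa$ki67_logit[2L]))
    size <- rnorm_reject(m, pa$lesion_size, function(x) x > 0)
    out[[2L - g]] <- data.frame(
      idx = idx, group = g, dect,
      node_short_mm = short, node_long_mm = long, hilum_present = hilum,
      er_positive = er, nuclear_grade = grade, ki67_pct = ki67,
      lesion_size_mm = size
    )
  }
  df <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  df <- df[order(df$idx), , drop = FALSE]
  cohort <- cbind(
    data.frame(patient_id = sprintf("P%05d", seq_len(n)), group = df$group),
    df[, !(names(df) %in% c("idx", "group")), drop = FALSE],
    aorta
  )
  rownames(cohort) <- NULL
  cohort[, cohort_schema()$column, drop = FALSE]
}

# Draw m patients' 5 lesion + 5 node parameters from the latent factor
# model.  Latent loadings: a patient factor L (variance share a, common to
# all ten variables), a site factor S_site (share b, completing the
# within-site correlation w = a + b), and per-parameter factors F_j shared
# by the two sites (share d, completing the cross-site same-parameter
# correlation c1 = a + d derived from the target Spearman rho).  The
# per-parameter factors are what lets a contrast like the spectral slope
# inherit the configured lesion-node correlation; a single shared factor
# would cancel out of it.  a is taken as small as the variance budget
# allows, max(0, c1 - (1 - w)).  Rows violating physical constraints are
# redrawn in full so the copula is preserved.
draw_dect_block <- function(m, marginals, rank_rho, within) {
  c1 <- latent_cross_correlation(rank_rho)
  load_patient <- max(0, c1 - (1 - within))
  load_site <- within - load_patient
  load_param <- c1 - load_patient
  stopifnot(load_site >= 0, load_param >= 0,
            load_patient + load_site + load_param <= 1 + 1e-12)
  resid <- max(0, 1 - load_patient - load_site - load_param)
  p <- param_names()

  draw_rows <- function(k) {
    L <- stats::rnorm(k)
    site <- list(lesion = stats::rnorm(k), node = stats::rnorm(k))
    f <- matrix(stats::rnorm(k * 5L), k, 5L)
    vals <- list()
    for (s in c("lesion", "node")) {
      z <- sqrt(load_patient) * L + sqrt(load_site) * site[[s]] +
        sqrt(load_param) * f +
        sqrt(resid) * matrix(stats::rnorm(k * 5L), k, 5L)
      for (j in seq_along(p)) {
        ls <- marginals[[s]][[p[j]]]
        vals[[paste(s, p[j], sep = "_")]] <- ls[1L] + ls[2L] * z[, j]
      }
    }
    as.data.frame(vals)
  }

  ok_rows <- function(d) {
    d$lesion_att40 > d$lesion_att70 & d$node_att40 > d$node_att70 &
      d$lesion_ic > 0 & d$node_ic > 0 &
      d$lesion_wc > 0 & d$node_wc > 0 &
      d$lesion_effz > 0 & d$node_effz > 0
  }

  d <- draw_rows(m)
  bad <- which(!ok_rows(d))
  guard <- 0L
  while (length(bad)) {
    d[bad, ] <- draw_rows(length(bad))
    bad <- bad[!ok_rows(d[bad, , drop = FALSE])]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("rejection sampling failed to satisfy physical constraints; ",
           "check the configured marginals", call. = FALSE)
    }
  }
  names(d) <- c("lesion_att40_hu", "lesion_att70_hu", "lesion_ic_mgcm3",
                "lesion_wc_mgcm3", "lesion_effz",
                "node_att40_hu", "node_att70_hu", "node_ic_mgcm3",
                "node_wc_mgcm3", "node_effz")
  d
}

rnorm_reject <- function(m, loc_scale, accept) {
  x <- stats::rnorm(m, loc_scale[1L], loc_scale[2L])
  bad <- which(!accept(x))
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), loc_scale[1L], loc_scale[2L])
    bad <- bad[!accept(x[bad])]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("rejection sampling failed; check the configured marginals", call. = FALSE)
    }
  }
  x
}

# Longest diameter, constrained to exceed that node's shortest diameter.
draw_long_diameter <- function(m, loc_scale, short) {
  x <- stats::rnorm(m, loc_scale[1L], loc_scale[2L])
  bad <- which(x <= short)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), loc_scale[1L], loc_scale[2L])
    bad <- bad[x[bad] <= short[bad]]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("rejection sampling failed for longest diameter; shortest-diameter ",
           "marginal may exceed the longest-diameter marginal", call. = FALSE)
    }
  }
  x
}

#' Standard cohort CSV schema
#'
#' One row per patient.  \code{group} is 1 for pathologically confirmed nodal
#' metastasis, 0 otherwise; missing values are written as empty CSV fields.
#'
#' @return Data frame with columns \code{column} and \code{type}
#'   (\code{"character"}, \code{"integer"} or \code{"numeric"}).
#' @export
cohort_schema <- function() {
  data.frame(
    column = c("patient_id", "group",
               "lesion_att40_hu", "lesion_att70_hu", "lesion_ic_mgcm3",
               "lesion_wc_mgcm3", "lesion_effz",
               "node_att40_hu", "node_att70_hu", "node_ic_mgcm3",
               "node_wc_mgcm3", "node_effz",
               "aorta_ic_mgcm3", "aorta_wc_mgcm3", "aorta_effz",
               "node_short_mm", "node_long_mm", "hilum_present",
               "er_positive", "nuclear_grade", "ki67_pct", "lesion_size_mm"),
    type = c("character", "integer",
             rep("numeric", 13L),
             "numeric", "numeric", "integer",
             "integer", "integer", "numeric", "numeric"),
    stringsAsFactors = FALSE
  )
}
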