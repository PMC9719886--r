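#' Configuration of the synthetic DECT cohort generator
#'
#' Builds the full parameter set for \code{\link{generate_cohort}}.  The
#' defaults emulate the published summary statistics of a 137-patient breast
#' cancer cohort: per-group node marginals for the five delayed-phase DECT
#' parameters, node morphology (shortest/longest diameter, hilum), pathology
#' covariates (ER status, nuclear grade, Ki67, lesion size), aortic reference
#' values, a metastasis prevalence of 39/137, and the contrast in lesion-node
#' rank correlation between the metastasis group (moderate, ~0.65) and the
#' non-metastasis group (negligible, ~0.14).
#'
#' Location/scale pairs are Gaussian mean and SD in the parameter's units
#' (HU for attenuations, mg/cm^3 for concentrations, mm for diameters).
#' Positivity and the 40-keV > 70-keV ordering are enforced by rejection
#' resampling, not clipping.  Ki67 is logit-normal on (0, 100)%.
#'
#' @param n_patients Number of patients to simulate.
#' @param metastasis_fraction Prevalence of nodal metastasis in (0, 1).
#' @param group_marginals Per-group (\code{metastasis}, \code{non_metastasis})
#'   per-site (\code{node}, \code{lesion}) list of \code{c(mean, sd)} for
#'   \code{att40}, \code{att70}, \code{ic}, \code{wc}, \code{effz}.
#' @param lesion_node_rank_correlation Named vector: target Spearman
#'   correlation between lesion and node parameters, per group, in (-1, 1).
#' @param within_site_correlation Latent correlation shared by the five
#'   parameters measured in the same site (same ROI, same tissue); all five
#'   quantities reflect the same local iodine uptake, so this is high.
#' @param morphology_params Per-group list: \code{short} and \code{long}
#'   diameter \code{c(mean, sd)} (mm) and \code{hilum_absent} probability.
#' @param pathology_params Per-group list: \code{er_positive} probability,
#'   \code{nuclear_grade} probabilities over categories 1/2/3/missing,
#'   \code{ki67_logit} \code{c(mean, sd)} on the logit scale of Ki67/100,
#'   and \code{lesion_size} \code{c(mean, sd)} (mm).
#' @param aorta_params \code{c(mean, sd)} for aortic \code{ic}, \code{wc},
#'   \code{effz}.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return An object of class \code{cohort_config} (validated list).
#' @export
cohort_config <- function(n_patients = 137L,
                          metastasis_fraction = 39 / 137,
                          group_marginals = default_group_marginals(),
                          lesion_node_rank_correlation = c(metastasis = 0.65,
                                                           non_metastasis = 0.14),
                          within_site_correlation = 0.8,
                          morphology_params = default_morphology_params(),
                          pathology_params = default_pathology_params(),
                          aorta_params = default_aorta_params(),
                          seed = 1L) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    metastasis_fraction = metastasis_fraction,
    group_marginals = group_marginals,
    lesion_node_rank_correlation = lesion_node_rank_correlation,
    within_site_correlation = within_site_correlation,
    morphology_params = morphology_params,
    pathology_params = pathology_params,
    aorta_params = aorta_params,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_group_marginals <- function() {
  list(
    metastasis = list(
      node   = list(att40 = c(247, 38), att70 = c(99, 14), ic = c(25.8, 4.8),
                    wc = c(1031, 8.4), effz = c(9.1, 0.23)),
      lesion = list(att40 = c(247, 25), att70 = c(99, 10), ic = c(25.8, 3.4),
                    wc = c(1031, 7), effz = c(9.1, 0.17))
    ),
    non_metastasis = list(
      node   = list(att40 = c(204, 45), att70 = c(81, 16), ic = c(21.6, 5.6),
                    wc = c(1027, 12), effz = c(8.9, 0.29)),
      lesion = list(att40 = c(260, 30), att70 = c(103, 12), ic = c(26.5, 4.5),
                    wc = c(1031, 9), effz = c(9.12, 0.22))
    )
  )
}

#' @rdname cohort_config
#' @export
default_morphology_params <- function() {
  list(
    metastasis     = list(short = c(7.6, 4.0), long = c(14.1, 5.0),
                          hilum_absent = 24 / 39),
    non_metastasis = list(short = c(3.4, 1.1), long = c(9.7, 3.0),
                          hilum_absent = 10 / 98)
  )
}

#' @rdname cohort_config
#' @export
default_pathology_params <- function() {
  list(
    metastasis = list(
      er_positive = 23 / 39,
      nuclear_grade = c(g1 = 12, g2 = 7, g3 = 17, missing = 3) / 39,
      ki67_logit = c(-0.2, 1.3),
      lesion_size = c(30.7, 14)
    ),
    non_metastasis = list(
      er_positive = 82 / 98,
      nuclear_grade = c(g1 = 45, g2 = 10, g3 = 19, missing = 24) / 98,
      ki67_logit = c(-1.6, 1.2),
      lesion_size = c(19.5, 12)
    )
  )
}

#' @rdname cohort_config
#' @export
default_aorta_params <- function() {
  list(ic = c(51.6, 6), wc = c(1030, 12), effz = c(10.2, 0.4))
}

param_names <- function() c("att40", "att70", "ic", "wc", "effz")

validate_loc_scale <- function(x, what) {
  if (!is.numeric(x) || length(x) != 2L || !all(is.finite(x))) {
    stop("configuration error: ", what, " must be a finite c(mean, sd) pair",
         call. = FALSE)
  }
  if (x[2L] <= 0) {
    stop("configuration error: scale parameter of ", what,
         " must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

validate_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("configuration error: ", what, " must be a probability in [0, 1]",
         call. = FALSE)
  }
  invisible(p)
}

validate_cohort_config <- function(cfg) {
  if (!is.integer(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      is.na(cfg$n_patients) || cfg$n_patients <= 0L) {
    stop("configuration error: n_patients must be a positive integer", call. = FALSE)
  }
  if (cfg$metastasis_fraction <= 0 || cfg$metastasis_fraction >= 1) {
    stop("configuration error: metastasis_fraction must lie in (0, 1)", call. = FALSE)
  }
  for (g in c("metastasis", "non_metastasis")) {
    gm <- cfg$group_marginals[[g]]
    if (is.null(gm)) stop("configuration error: group_marginals lacks '", g, "'",
                          call. = FALSE)
    for (site in c("node", "lesion")) {
      for (p in param_names()) {
        validate_loc_scale(gm[[site]][[p]], paste(g, site, p))
      }
    }
    rs <- cfg$lesion_node_rank_correlation[[g]]
    if (is.null(rs) || !is.finite(rs) || abs(rs) >= 1) {
      stop("configuration error: lesion_node_rank_correlation for '", g,
           "' must lie strictly inside (-1, 1)", call. = FALSE)
    }
    mo <- cfg$morphology_params[[g]]
    validate_loc_scale(mo$short, paste(g, "shortest diameter"))
    validate_loc_scale(mo$long, paste(g, "longest diameter"))
    validate_prob(mo$hilum_absent, paste(g, "hilum_absent"))
    pa <- cfg$pathology_params[[g]]
    validate_prob(pa$er_positive, paste(g, "er_positive"))
    if (length(pa$nuclear_grade) != 4L || any(pa$nuclear_grade < 0) ||
        abs(sum(pa$nuclear_grade) - 1) > 1e-8) {
      stop("configuration error: ", g, " nuclear_grade probabilities must be ",
           "4 nonnegative values summing to 1", call. = FALSE)
    }
    validate_loc_scale(pa$ki67_logit, paste(g, "ki67_logit"))
    validate_loc_scale(pa$lesion_size, paste(g, "lesion_size"))
  }
  if (cfg$within_site_correlation < 0 || cfg$within_site_correlation >= 1) {
    stop("configuration error: within_site_correlation must lie in [0, 1)",
         call. = FALSE)
  }
  for (p in c("ic", "wc", "effz")) {
    validate_loc_scale(cfg$aorta_params[[p]], paste("aorta", p))
  }
  if (!is.integer(cfg$seed) || is.na(cfg$seed)) {
    stop("configuration error: seed must be an integer", call. = FALSE)
  }
  invisible(cfg)
}

# Spearman rho of a bivariate Gaussian copula with latent Pearson correlation r
# is (6/pi) * asin(r/2); this inverts that relation.
latent_cross_correlation <- function(rank_rho) 2 * sin(pi * rank_rho / 6)

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic DECT cohort configuration\n")
  cat(sprintf("  n_patients: %d, metastasis fraction: %.3f, seed: %d\n",
              x$n_patients, x$metastasis_fraction, x$seed))
  cat(sprintf("  lesion-node rank correlation: %.2f (metastasis) / %.2f (non-metastasis)\n",
              x$lesion_node_rank_correlation[["metastasis"]],
              x$lesion_node_rank_correlation[["non_metastasis"]]))
  invisible(x)
}
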