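# Logistic modelling of nodal metastasis: univariable screening, the
# similarity-score transform that puts ROD predictors on a workable scale,
# maximum-likelihood logistic fits with Wald intervals, and forward
# selection with a likelihood-ratio stay test.

#' Similarity-score transform of a ROD predictor
#'
#' Raw ROD values are small (often < 0.3), which makes logistic odds ratios
#' per unit ROD unwieldy; the similarity score \code{10 * (1 - rod)} rescales
#' them so that higher values mean greater lesion-node similarity and a unit
#' step is a 0.1 change in ROD.
#'
#' @param rod Nonnegative ROD value(s).
#' @return \code{10 * (1 - rod)}.
#' @export
rod_transform <- function(rod) {
  if (!is.numeric(rod) || any(!is.finite(rod) & !is.na(rod))) {
    stop("rod must be numeric and finite", call. = FALSE)
  }
  if (any(rod < 0, na.rm = TRUE)) stop("rod must be >= 0", call. = FALSE)
  10 * (1 - rod)
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binary logistic model by iteratively reweighted least squares,
#' with Wald standard errors from the observed information.  Odds ratios are
#' \code{exp(beta)} with 95\% Wald intervals \code{exp(beta +/- 1.96 se)}.
#' Collinear predictors raise an error naming the aliased columns; complete
#' or quasi-complete separation is flagged on the returned object rather
#' than silently reported.
#'
#' @param formula Model formula with a binary (0/1 or two-level) outcome.
#' @param data Data frame; rows with missing values in the model variables
#'   are dropped (complete-case).
#' @return An object of class \code{logistic_fit}: list with
#'   \code{coefficients} (term, estimate, se, odds_ratio, ci_low, ci_high,
#'   p_value), \code{log_lik}, \code{converged}, \code{separation},
#'   \code{n} and the underlying \code{glm} object.
#' @export
fit_logistic <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  pred_cols <- setdiff(colnames(X), "(Intercept)")
  if (length(pred_cols)) {
    constant <- pred_cols[apply(X[, pred_cols, drop = FALSE], 2L,
                                function(col) length(unique(col)) == 1L)]
    if (length(constant)) {
      stop("constant predictor: ", paste(constant, collapse = ", "), call. = FALSE)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("collinear predictors: ", paste(aliased, collapse = ", "),
         " are linearly dependent on the remaining columns", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial(), data = data,
               na.action = stats::na.omit,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  mu <- stats::fitted(fit)
  separation <- any(mu < 1e-8 | mu > 1 - 1e-8) && max(abs(stats::coef(fit))) > 10
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, 1L],
    se = sm[, 2L],
    odds_ratio = exp(sm[, 1L]),
    ci_low = exp(sm[, 1L] - 1.96 * sm[, 2L]),
    ci_high = exp(sm[, 1L] + 1.96 * sm[, 2L]),
    p_value = sm[, 4L],
    row.names = NULL
  )
  structure(list(coefficients = coefs,
                 log_lik = as.numeric(stats::logLik(fit)),
                 converged = fit$converged && !separation,
                 separation = separation,
                 n = length(mu),
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.3f%s)\n", x$n, x$log_lik,
              if (x$separation) ", WARNING: separation detected" else ""))
  tab <- x$coefficients
  tab$odds_ratio <- signif(tab$odds_ratio, 3)
  tab$ci_low <- signif(tab$ci_low, 3)
  tab$ci_high <- signif(tab$ci_high, 3)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab[, c("term", "odds_ratio", "ci_low", "ci_high", "p_value")], ...)
  invisible(x)
}

#' Candidate specification for forward logistic modelling
#'
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of candidate predictor columns.
#' @param transforms Named character vector tagging predictors with
#'   \code{"identity"} (default) or \code{"rod_transform"}; ROD predictors
#'   always enter the model through \code{\link{rod_transform}}.
#' @param enter_threshold Univariable screening p-value threshold.
#' @param stay_threshold Likelihood-ratio p-value below which an entered
#'   candidate is retained.
#' @return An object of class \code{logistic_model_spec}.
#' @export
logistic_model_spec <- function(outcome = "group", predictors,
                                transforms = NULL,
                                enter_threshold = 0.001,
                                stay_threshold = 0.05) {
  if (anyDuplicated(predictors)) stop("predictors must be distinct", call. = FALSE)
  if (enter_threshold <= 0 || enter_threshold > 1 ||
      stay_threshold <= 0 || stay_threshold >= 1) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  tr <- stats::setNames(rep("identity", length(predictors)), predictors)
  if (!is.null(transforms)) {
    bad <- setdiff(names(transforms), predictors)
    if (length(bad)) stop("transforms name unknown predictors: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!all(transforms %in% c("identity", "rod_transform"))) {
      stop("transforms must be 'identity' or 'rod_transform'", call. = FALSE)
    }
    tr[names(transforms)] <- transforms
  }
  structure(list(outcome = outcome, predictors = predictors, transforms = tr,
                 enter_threshold = enter_threshold,
                 stay_threshold = stay_threshold),
            class = "logistic_model_spec")
}

#' Univariable screening of candidate predictors
#'
#' Each candidate is tested against the outcome with the same tests used for
#' the group-comparison tables: Mann-Whitney for numeric candidates, Fisher
#' exact (2x2) or chi-squared for categorical ones.  Candidates passing the
#' threshold are returned in ascending p-value order.
#'
#' @param cohort Cohort data frame with the outcome column.
#' @param candidates Character vector of candidate columns.
#' @param threshold Screening p-value threshold.
#' @param outcome Binary outcome column name (default \code{"group"}).
#' @return Data frame with \code{variable}, \code{test}, \code{p_value} for
#'   the candidates passing the screen, ordered by p-value; attribute
#'   \code{"all"} holds the unfiltered table.
#' @export
univariable_screen <- function(cohort, candidates, threshold = 0.001,
                               outcome = "group") {
  missing_cols <- setdiff(c(outcome, candidates), names(cohort))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort
  if (outcome != "group") dat$group <- dat[[outcome]]
  rows <- lapply(candidates, function(v) {
    is_cat <- !is.numeric(dat[[v]]) || length(unique(stats::na.omit(dat[[v]]))) <= 3L
    cmp <- compare_groups(dat, v, type = if (is_cat) "categorical" else "continuous")
    data.frame(variable = v, test = cmp$test, p_value = cmp$p_value)
  })
  all_tab <- do.call(rbind, rows)
  all_tab <- all_tab[order(all_tab$p_value), , drop = FALSE]
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$p_value < threshold, , drop = FALSE]
  attr(out, "all") <- all_tab
  out
}

#' Forward selection of a multivariable logistic model
#'
#' Candidates passing the univariable screen enter in ascending p-value
#' order; a candidate is retained if its likelihood-ratio test against the
#' current model has p below the stay threshold.  The number of retained
#' terms is capped at \code{floor(events / 10)} (events = size of the rarer
#' outcome class), the usual events-per-variable rule.  Candidates whose
#' addition makes the design rank-deficient are recorded as collinear and
#' skipped.
#'
#' @param spec A \code{\link{logistic_model_spec}}.
#' @param cohort Cohort data frame; rows with a missing value in any
#'   candidate or the outcome are dropped before selection so that all
#'   likelihoods are comparable.
#' @return An object of class \code{forward_selection}: list with
#'   \code{selected} (character), \code{fit} (a \code{logistic_fit}, or
#'   \code{NULL} when no candidate passes the screen), \code{trace}
#'   (data frame recording every decision) and \code{screen}.
#' @export
forward_select <- function(spec, cohort) {
  stopifnot(inherits(spec, "logistic_model_spec"))
  vars <- c(spec$outcome, spec$predictors)
  missing_cols <- setdiff(vars, names(cohort))
  if (length(missing_cols)) {
    stop("unknown variable(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[stats::complete.cases(cohort[, vars, drop = FALSE]),
                vars, drop = FALSE]
  for (v in spec$predictors) {
    if (spec$transforms[[v]] == "rod_transform") {
      dat[[v]] <- rod_transform(dat[[v]])
    }
  }
  y <- dat[[spec$outcome]]
  events <- min(sum(y == 1), sum(y == 0))
  max_terms <- max(1L, floor(events / 10))

  screen <- univariable_screen(dat, spec$predictors,
                               threshold = spec$enter_threshold,
                               outcome = spec$outcome)
  trace <- data.frame(variable = character(0), univariable_p = numeric(0),
                      lrt_p = numeric(0), action = character(0))
  if (nrow(screen) == 0L) {
    return(structure(list(selected = character(0), fit = NULL,
                          trace = trace, screen = screen),
                     class = "forward_selection"))
  }

  selected <- character(0)
  current <- fit_logistic(stats::reformulate("1", response = spec$outcome), dat)
  for (i in seq_len(nrow(screen))) {
    v <- screen$variable[i]
    if (length(selected) >= max_terms) {
      trace <- rbind(trace, data.frame(variable = v,
                                       univariable_p = screen$p_value[i],
                                       lrt_p = NA_real_,
                                       action = "skipped: events-per-variable cap"))
      next
    }
    cand_fit <- try(
      fit_logistic(stats::reformulate(c(selected, v), response = spec$outcome), dat),
      silent = TRUE
    )
    if (inherits(cand_fit, "try-error")) {
      trace <- rbind(trace, data.frame(variable = v,
                                       univariable_p = screen$p_value[i],
                                       lrt_p = NA_real_,
                                       action = "skipped: collinear or degenerate"))
      next
    }
    lrt_stat <- 2 * (cand_fit$log_lik - current$log_lik)
    df <- nrow(cand_fit$coefficients) - nrow(current$coefficients)
    lrt_p <- stats::pchisq(lrt_stat, df = df, lower.tail = FALSE)
    if (lrt_p < spec$stay_threshold) {
      selected <- c(selected, v)
      current <- cand_fit
      action <- "retained"
    } else {
      action <- "rejected: stay test"
    }
    trace <- rbind(trace, data.frame(variable = v,
                                     univariable_p = screen$p_value[i],
                                     lrt_p = lrt_p, action = action))
  }
  structure(list(selected = selected,
                 fit = if (length(selected)) current else NULL,
                 trace = trace, screen = screen),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Forward selection: no candidate passed the univariable screen.\n")
  } else {
    cat("Forward selection retained:", paste(x$selected, collapse = ", "), "\n")
    print(x$fit, ...)
  }
  invisible(x)
}
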