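# ROC analysis of the diagnostic markers: AUC as the normalised
# Mann-Whitney statistic (midranks, ties half-counted) and the Youden
# operating point over midpoint thresholds.

#' Area under the ROC curve
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, with ties counted one half; computed from midranks.  For
#' markers where a \emph{lower} value indicates disease (the ROD similarity
#' parameters), pass \code{orientation = "lower"}.
#'
#' @param scores Numeric marker values.
#' @param labels Binary 0/1 labels (1 = positive class).
#' @param orientation \code{"higher"} (default) if larger scores indicate
#'   the positive class, \code{"lower"} otherwise.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- if (orientation == "lower") -scores else scores
  r <- rank(s)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Youden-optimal operating threshold
#'
#' Candidate thresholds are the midpoints between adjacent distinct observed
#' scores; the threshold maximising Youden's J = sensitivity + specificity -
#' 1 is returned, with ties broken toward higher specificity.  The
#' classification rule is score >= threshold for \code{"higher"} orientation
#' and score <= threshold for \code{"lower"}.
#'
#' @inheritParams roc_auc
#' @return List with \code{threshold} (marker units), \code{sensitivity}
#'   and \code{specificity} (percent), and \code{youden_j}.
#' @export
optimal_threshold <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) stop("both classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    # degenerate constant marker: every cut classifies all subjects alike
    return(list(threshold = u, sensitivity = 100, specificity = 0,
                youden_j = 0, degenerate = TRUE))
  }
  cuts <- (u[-1L] + u[-length(u)]) / 2
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    pred_pos <- if (orientation == "higher") scores >= cuts[i] else scores <= cuts[i]
    sens[i] <- sum(pred_pos & labels == 1) / npos
    spec[i] <- sum(!pred_pos & labels == 0) / nneg
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  list(threshold = cuts[best], sensitivity = 100 * sens[best],
       specificity = 100 * spec[best], youden_j = j[best], degenerate = FALSE)
}

#' Evaluate diagnostic markers in the full cohort and the small-node subgroup
#'
#' For each marker, computes AUC and the Youden operating point in the full
#' cohort and, when requested, in the subgroup of small nodes (shortest
#' diameter below \code{subgroup_cut_mm}).  ROD similarity markers use the
#' lower-is-positive orientation; simple parameters higher-is-positive.
#'
#' @param cohort Cohort data frame (with derived columns as needed) and a
#'   binary \code{group} column.
#' @param markers Data frame with columns \code{name} and \code{orientation}
#'   (\code{"higher"}/\code{"lower"}), or a character vector of column names
#'   (orientation inferred: names starting with \code{"rod_"} are
#'   \code{"lower"}).
#' @param subgroup Logical; also evaluate the small-node subgroup.
#' @param subgroup_cut_mm Shortest-diameter cutoff in mm (default 5).
#' @return Data frame of class \code{diagnostic_result}: one row per marker
#'   per stratum with \code{marker}, \code{stratum}, \code{orientation},
#'   \code{auc}, \code{threshold}, \code{sensitivity}, \code{specificity},
#'   \code{n_pos}, \code{n_neg}, \code{flag}.
#' @export
evaluate_markers <- function(cohort, markers, subgroup = TRUE,
                             subgroup_cut_mm = 5) {
  if (is.character(markers)) {
    markers <- data.frame(
      name = markers,
      orientation = ifelse(startsWith(markers, "rod_"), "lower", "higher")
    )
  }
  missing_cols <- setdiff(markers$name, names(cohort))
  if (length(missing_cols)) {
    stop("unknown marker(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  strata <- list(full_cohort = rep(TRUE, nrow(cohort)))
  if (subgroup) {
    strata$small_nodes <- cohort$node_short_mm < subgroup_cut_mm
  }
  rows <- list()
  for (st in names(strata)) {
    sub <- cohort[strata[[st]], , drop = FALSE]
    for (i in seq_len(nrow(markers))) {
      nm <- markers$name[i]
      orient <- markers$orientation[i]
      sc <- sub[[nm]]
      lb <- sub$group
      npos <- sum(lb == 1, na.rm = TRUE)
      nneg <- sum(lb == 0, na.rm = TRUE)
      if (npos == 0L || nneg == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker = nm, stratum = st, orientation = orient,
          auc = NA_real_, threshold = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_, n_pos = npos, n_neg = nneg,
          flag = "unevaluable: one class absent"
        )
        next
      }
      auc <- roc_auc(sc, lb, orient)
      op <- optimal_threshold(sc, lb, orient)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = nm, stratum = st, orientation = orient,
        auc = auc, threshold = op$threshold, sensitivity = op$sensitivity,
        specificity = op$specificity, n_pos = npos, n_neg = nneg,
        flag = if (isTRUE(op$degenerate)) "degenerate: constant marker" else ""
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diagnostic_result", "data.frame")
  out
}

#' @export
print.diagnostic_result <- function(x, ...) {
  y <- as.data.frame(x)
  y$auc <- round(y$auc, 2)
  y$threshold <- signif(y$threshold, 3)
  y$sensitivity <- round(y$sensitivity, 1)
  y$specificity <- round(y$specificity, 1)
  print(y, ...)
  invisible(x)
}
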