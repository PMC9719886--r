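#' Write / read a cohort CSV
#'
#' The on-disk format is a plain CSV in the standard schema
#' (\code{\link{cohort_schema}}); missing values are empty fields.  Numeric
#' columns are written with enough digits to round-trip exactly.
#'
#' @param cohort Cohort data frame containing at least the schema columns.
#' @param path File path.
#' @return \code{write_cohort} returns \code{path} invisibly;
#'   \code{read_cohort} returns the cohort data frame with schema types
#'   restored (missing fields become \code{NA}).
#' @export
write_cohort <- function(cohort, path) {
  schema <- cohort_schema()
  missing_cols <- setdiff(schema$column, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing schema columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data.table::fwrite(cohort[, schema$column, drop = FALSE], path,
                     na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  schema <- cohort_schema()
  raw <- data.table::fread(path, colClasses = "character", na.strings = NULL,
                           data.table = FALSE)
  missing_cols <- setdiff(schema$column, names(raw))
  if (length(missing_cols)) {
    stop("cohort file does not match the schema; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[, schema$column, drop = FALSE]
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    type <- schema$type[i]
    if (type == "character") next
    v <- out[[col]]
    v[v == ""] <- NA_character_
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(conv) & !is.na(v))
    if (length(bad)) {
      stop(sprintf("parse error in cohort file: non-numeric value '%s' at row %d, column '%s'",
                   v[bad[1L]], bad[1L], col), call. = FALSE)
    }
    out[[col]] <- if (type == "integer") as.integer(round(conv)) else conv
  }
  out
}

#' Serialise a cohort configuration to / from JSON
#'
#' @param config A \code{\link{cohort_config}}.
#' @param path JSON file path.
#' @return \code{read_cohort_config} returns a validated
#'   \code{cohort_config}.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  x <- unclass(config)
  # named vectors must become JSON objects, not bare arrays
  x$lesion_node_rank_correlation <- as.list(x$lesion_node_rank_correlation)
  for (g in names(x$pathology_params)) {
    x$pathology_params[[g]]$nuclear_grade <-
      as.list(x$pathology_params[[g]]$nuclear_grade)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  num_pair <- function(v) as.numeric(v)
  for (g in names(x$group_marginals)) {
    for (s in names(x$group_marginals[[g]])) {
      x$group_marginals[[g]][[s]] <- lapply(x$group_marginals[[g]][[s]], num_pair)
    }
  }
  cohort_config(
    n_patients = x$n_patients,
    metastasis_fraction = x$metastasis_fraction,
    group_marginals = x$group_marginals,
    lesion_node_rank_correlation = unlist(x$lesion_node_rank_correlation),
    within_site_correlation = x$within_site_correlation,
    morphology_params = lapply(x$morphology_params, function(g) {
      list(short = num_pair(g$short), long = num_pair(g$long),
           hilum_absent = g$hilum_absent)
    }),
    pathology_params = lapply(x$pathology_params, function(g) {
      list(er_positive = g$er_positive,
           nuclear_grade = unlist(g$nuclear_grade),
           ki67_logit = num_pair(g$ki67_logit),
           lesion_size = num_pair(g$lesion_size))
    }),
    aorta_params = lapply(x$aorta_params, num_pair),
    seed = x$seed
  )
}
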