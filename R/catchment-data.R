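#' Validate a catchment frame
#'
#' A catchment frame is a plain `data.frame` describing the landscape: one
#' row per catchment with its nested hydrologic-unit codes, centroid
#' coordinates, optional state label, and per-catchment survey count.
#' Validation enforces unique catchment ids and consistency of the nesting
#' (each HUC12 belongs to exactly one HUC10, each HUC10 to one HUC8).
#'
#' @param frame data.frame with columns `catchment_id`, `huc12`, `huc10`,
#'   `huc8`, `centroid_x`, `centroid_y`, `survey_count` and optionally
#'   `state`.
#' @return the frame, invisibly, if valid; otherwise an error.
#' @export
validate_catchment_frame <- function(frame) {
  need <- c("catchment_id", "huc12", "huc10", "huc8",
            "centroid_x", "centroid_y", "survey_count")
  miss <- setdiff(need, names(frame))
  if (length(miss) > 0L) {
    stop("catchment frame missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(frame$catchment_id)) {
    stop("catchment_id values must be unique")
  }
  n10 <- tapply(frame$huc10, frame$huc12, function(x) length(unique(x)))
  if (any(n10 > 1L)) stop("nesting violated: a huc12 maps to multiple huc10s")
  n8 <- tapply(frame$huc8, frame$huc10, function(x) length(unique(x)))
  if (any(n8 > 1L)) stop("nesting violated: a huc10 maps to multiple huc8s")
  if (any(frame$survey_count < 0)) stop("survey_count must be nonnegative")
  invisible(frame)
}

#' Construct a covariate table
#'
#' Per-catchment environmental values with per-column metadata: each
#' covariate is tagged `continuous` or `binary` and carries a declared
#' spatial scale label (`catchment`, `watershed`, `riparian`, `huc12` or
#' `huc8`).  Constant columns are rejected at load with a clear error, as
#' are non-finite values, duplicate catchment ids, and binary columns with
#' values outside {0, 1}.
#'
#' @param df data.frame whose first-class column `catchment_id` keys the
#'   rows; every other column is a covariate.
#' @param types character vector (`"continuous"`/`"binary"`), one per
#'   covariate column, recycled names from the columns.
#' @param scales character vector of spatial-scale labels, one per column.
#' @return the data.frame with `cov_type` and `cov_scale` attributes.
#' @export
covariate_table <- function(df, types = NULL, scales = NULL) {
  if (!"catchment_id" %in% names(df)) stop("covariate table needs catchment_id")
  if (anyDuplicated(df$catchment_id)) stop("duplicate catchment ids")
  vars <- setdiff(names(df), "catchment_id")
  if (is.null(types)) {
    types <- vapply(vars, function(v) {
      if (all(df[[v]] %in% c(0, 1))) "binary" else "continuous"
    }, "")
  }
  if (is.null(scales)) scales <- rep("catchment", length(vars))
  types <- stats::setNames(rep(types, length.out = length(vars)), vars)
  scales <- stats::setNames(rep(scales, length.out = length(vars)), vars)
  for (v in vars) {
    x <- df[[v]]
    if (!is.numeric(x)) stop("covariate ", v, " is not numeric")
    if (any(!is.finite(x))) stop("covariate ", v, " has non-finite values")
    if (length(unique(x)) < 2L) {
      stop("covariate ", v, " is constant; constant columns are rejected")
    }
    if (types[[v]] == "binary" && !all(x %in% c(0, 1))) {
      stop("binary covariate ", v, " has values outside {0, 1}")
    }
  }
  attr(df, "cov_type") <- types
  attr(df, "cov_scale") <- scales
  df
}

#' Names of covariates of a given type
#' @param covariates a [covariate_table()].
#' @param type `"continuous"`, `"binary"`, or `"all"`.
#' @return character vector of column names.
#' @export
covariate_names <- function(covariates, type = c("all", "continuous", "binary")) {
  type <- match.arg(type)
  vars <- setdiff(names(covariates), "catchment_id")
  if (type == "all") return(vars)
  tp <- attr(covariates, "cov_type")
  if (is.null(tp)) {
    tp <- vapply(vars, function(v) {
      if (all(covariates[[v]] %in% c(0, 1))) "binary" else "continuous"
    }, "")
  }
  vars[tp[vars] == type]
}

#' Read the pipeline's input CSV set
#'
#' Loads `catchments.csv`, `covariates.csv`, `occurrences.csv`,
#' `surveys.csv` and (when present) `aux_covariates.csv` and `species.csv`
#' from a directory, validating the frame and covariate table on the way in.
#'
#' @param dir directory containing the CSVs.
#' @return list with `catchments`, `covariates`, `occurrences`, `surveys`,
#'   and optional `aux`, `species_table`.
#' @export
read_landscape_csv <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  frame <- rd("catchments.csv")
  validate_catchment_frame(frame)
  out <- list(
    catchments = frame,
    covariates = covariate_table(rd("covariates.csv")),
    occurrences = rd("occurrences.csv"),
    surveys = rd("surveys.csv")
  )
  if (file.exists(file.path(dir, "aux_covariates.csv"))) out$aux <- rd("aux_covariates.csv")
  if (file.exists(file.path(dir, "species.csv"))) out$species_table <- rd("species.csv")
  out
}

#' Filter occurrence or survey records by year
#'
#' Keeps records with `year >= cutoff_year`.  The modelling dataset uses a
#' 1952 cutoff (mussels are long-lived, so decades-old records can still
#' represent living individuals); the survey-priority binary uses a 1992
#' cutoff (surveys in the last thirty years).
#'
#' @param records data.frame with a `year` column.
#' @param cutoff_year integer cutoff; records strictly before it are dropped.
#' @return the filtered data.frame.
#' @export
filter_records_by_year <- function(records, cutoff_year) {
  records[records$year >= cutoff_year, , drop = FALSE]
}

#' Consolidate occurrence records to presence-only catchment sets
#'
#' Collapses duplicate records: the result is, per species, the set of
#' catchments with at least one record.  Records referencing unknown
#' catchments are a referential-integrity error.
#'
#' @param records occurrence records (`species_id`, `catchment_id`, ...).
#' @param frame optional catchment frame used for the integrity check.
#' @return named list mapping species_id to a character vector of catchment
#'   ids (sorted for reproducibility).
#' @export
consolidate_presences <- function(records, frame = NULL) {
  if (!is.null(frame)) {
    bad <- setdiff(unique(records$catchment_id), frame$catchment_id)
    if (length(bad) > 0L) {
      stop("occurrence records reference unknown catchment(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  lapply(split(records$catchment_id, records$species_id),
         function(x) sort(unique(x)))
}

#' Species-specific HUC8 occurrence layer
#'
#' A binary covariate marking every catchment whose encompassing HUC8
#' contains at least one recorded presence of the focal species.  It stands
#' in for historical distribution and dispersal limitation, and is excluded
#' from collinearity screening because it differs across species.
#'
#' @param presences character vector of presence catchment ids for the focal
#'   species (or the list from [consolidate_presences()] plus `species_id`).
#' @param frame catchment frame.
#' @param species_id focal species, required when `presences` is a list.
#' @return integer vector of 0/1 aligned with `frame$catchment_id`.
#' @export
huc8_occurrence_layer <- function(presences, frame, species_id = NULL) {
  if (is.list(presences) && !is.data.frame(presences)) {
    if (is.null(species_id)) stop("species_id required with a presence list")
    presences <- presences[[species_id]] %||% character(0)
  }
  occ_huc8 <- unique(frame$huc8[frame$catchment_id %in% presences])
  as.integer(frame$huc8 %in% occ_huc8)
}
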