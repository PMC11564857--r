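# Plain-text I/O for cohorts: long-format tract panels, subject profiles,
# norms, and the wide per-subject layout tractometry tools emit.

#' Write / read a cohort as CSV
#'
#' `write_cohort()` writes `tract_metrics.csv` (long format: `subject_id`,
#' `group`, `metric`, `tract_id`, `value`) and `profiles.csv` into a
#' directory; `read_cohort()` reads them back and validates.  The round trip
#' is exact in decimal text representation (values written with full
#' precision).
#'
#' @param cohort list with elements `panel` and `profiles`, as returned by
#'   [generate_cohort()].
#' @param dir directory (created if needed).
#' @return `write_cohort()`: character vector of file paths, invisibly.
#'   `read_cohort()`: list with `panel` and `profiles`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- cohort$panel
  panel$value <- formatC(panel$value, format = "g", digits = 17)
  paths <- c(
    tract_metrics = file.path(dir, "tract_metrics.csv"),
    profiles = file.path(dir, "profiles.csv")
  )
  utils::write.csv(panel, paths[["tract_metrics"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$profiles, paths[["profiles"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pf <- file.path(dir, "tract_metrics.csv")
  sf <- file.path(dir, "profiles.csv")
  if (!file.exists(pf)) stop("missing tract_metrics.csv in ", dir)
  panel <- utils::read.csv(pf, stringsAsFactors = FALSE)
  validate_panel(panel)
  profiles <- if (file.exists(sf)) {
    utils::read.csv(sf, stringsAsFactors = FALSE)
  } else NULL
  if (!is.null(profiles)) validate_profiles(profiles)
  list(panel = panel, profiles = profiles)
}

#' Validate a long-format tract panel
#'
#' Checks required columns, known group labels, finite values, FA range, and
#' uniqueness of (subject, metric, tract) keys; violations are reported with
#' the offending key or row numbers.
#'
#' @param panel long-format data.frame.
#' @return the panel, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  need <- c("subject_id", "group", "metric", "tract_id", "value")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel is missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_grp <- which(!panel$group %in% c("athlete", "control"))
  if (length(bad_grp)) {
    stop("unknown group label(s) '",
         paste(unique(panel$group[bad_grp]), collapse = "', '"),
         "' at row(s) ", paste(utils::head(bad_grp, 5), collapse = ", "))
  }
  bad_val <- which(!is.finite(panel$value))
  if (length(bad_val)) {
    stop("non-finite value(s) at row(s) ",
         paste(utils::head(bad_val, 5), collapse = ", "))
  }
  key <- paste(panel$subject_id, panel$metric, panel$tract_id, sep = "|")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (subject, metric, tract) key '", key[dup[1]],
         "' at row ", dup[1])
  }
  fa <- is_fa_metric(panel$metric)
  bad_fa <- which(fa & (panel$value < 0 | panel$value > 1))
  if (length(bad_fa)) {
    stop("FA-type value outside [0, 1] at row(s) ",
         paste(utils::head(bad_fa, 5), collapse = ", "))
  }
  invisible(panel)
}

validate_profiles <- function(profiles) {
  need <- c("subject_id", "group")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profiles missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(profiles$subject_id)) {
    stop("duplicate subject_id in profiles: ",
         profiles$subject_id[duplicated(profiles$subject_id)][1])
  }
  if ("SCAT5_severity" %in% names(profiles) &&
      any(profiles$SCAT5_severity > 132, na.rm = TRUE)) {
    stop("SCAT5_severity exceeds the instrument maximum of 132")
  }
  if ("SCAT5_nsymptoms" %in% names(profiles) &&
      any(profiles$SCAT5_nsymptoms > 22, na.rm = TRUE)) {
    stop("SCAT5_nsymptoms exceeds the instrument maximum of 22")
  }
  invisible(profiles)
}

#' Read a per-subject wide tractometry CSV
#'
#' Loader for the per-subject layout tract-segmentation tools emit: a
#' `metric` column followed by one column per tract.  Tract columns may be
#' named arbitrarily; they are assigned `tract_id` 1..T in column order
#' unless the names are already integers.
#'
#' @param file path to the CSV.
#' @param subject_id subject identifier to stamp on the rows.
#' @param group group label (`"athlete"` or `"control"`).
#' @return long-format panel data.frame for this subject.
#' @export
read_tractseg_subject <- function(file, subject_id, group) {
  wide <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"metric" %in% names(wide)) {
    stop("wide tractometry file must have a 'metric' column: ", file)
  }
  tract_cols <- setdiff(names(wide), "metric")
  ids <- suppressWarnings(as.integer(tract_cols))
  if (anyNA(ids)) ids <- seq_along(tract_cols)
  out <- data.frame(
    subject_id = subject_id, group = group,
    metric = rep(wide$metric, length(tract_cols)),
    tract_id = rep(ids, each = nrow(wide)),
    value = as.vector(as.matrix(wide[, tract_cols])),
    stringsAsFactors = FALSE
  )
  validate_panel(out)
}

#' Write / read a norms table
#' @param norms data.frame as from [default_norms()].
#' @param file CSV path.
#' @return `read_norms()`: validated norms data.frame.
#' @export
write_norms <- function(norms, file) {
  utils::write.csv(norms, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_norms
#' @export
read_norms <- function(file) {
  norms <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("test", "norm_mean", "norm_sd", "higher_is_better")
  miss <- setdiff(need, names(norms))
  if (length(miss)) stop("norms missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(norms$norm_sd <= 0)) stop("norm_sd must be positive")
  norms
}
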