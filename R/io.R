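#' Write a cohort to its four-CSV on-disk form
#'
#' Writes `encounters.csv`, `observations.csv`, `doses.csv` and `troughs.csv`
#' plus a `cohort_meta.json` sidecar recording the generator configuration and
#' seed. Integer sets (KRT hours, continuous-infusion days) are stored as
#' semicolon-separated fields.
#'
#' @param cohort An `icu_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "icu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in c("encounters", "observations", "doses", "troughs")) {
    utils::write.csv(cohort[[f]], file.path(dir, paste0(f, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(seed = cohort$seed, config = unclass(cohort$config))
  jsonlite::write_json(meta, file.path(dir, "cohort_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read and validate a cohort from its four-CSV form
#'
#' Checks header schemas and referential integrity: every observation, dose
#' and trough row must join to an encounter, timestamps must be finite
#' non-negative numbers, and dose amounts positive. Violations raise an error
#' naming the file and row.
#'
#' @param dir Directory holding the four CSV files.
#' @return An `icu_cohort`.
#' @export
read_cohort <- function(dir) {
  need <- c("encounters", "observations", "doses", "troughs")
  paths <- file.path(dir, paste0(need, ".csv"))
  missing <- need[!file.exists(paths)]
  if (length(missing)) stop("missing cohort files: ", paste(missing, collapse = ", "))
  tabs <- lapply(paths, utils::read.csv, stringsAsFactors = FALSE)
  names(tabs) <- need

  required_cols <- list(
    encounters = c("patient_id", "age", "sex", "weight", "baseline_scr",
                   "icu_admit", "icu_discharge", "krt_hours",
                   "cont_infusion_days"),
    observations = c("patient_id", "variable_id", "t_hours", "value"),
    doses = c("patient_id", "t_start", "amount_mg", "duration_h"),
    troughs = c("patient_id", "t_hours", "value_mg_per_L", "range_lower",
                "range_upper")
  )
  for (f in need) {
    absent <- setdiff(required_cols[[f]], names(tabs[[f]]))
    if (length(absent)) {
      stop(sprintf("%s.csv is missing columns: %s", f,
                   paste(absent, collapse = ", ")))
    }
  }
  # integer-set fields: empty cells come back from read.csv as NA
  for (col in c("krt_hours", "cont_infusion_days")) {
    v <- as.character(tabs$encounters[[col]])
    v[is.na(v)] <- ""
    tabs$encounters[[col]] <- v
  }
  ids <- tabs$encounters$patient_id
  check_join <- function(f, tcol) {
    tab <- tabs[[f]]
    orphan <- which(!(tab$patient_id %in% ids))
    if (length(orphan)) {
      stop(sprintf("%s.csv row %d: unknown patient_id '%s'", f, orphan[1],
                   tab$patient_id[orphan[1]]))
    }
    bad <- which(!is.finite(tab[[tcol]]) | tab[[tcol]] < 0)
    if (length(bad)) {
      stop(sprintf("%s.csv row %d: invalid timestamp in %s", f, bad[1], tcol))
    }
  }
  check_join("observations", "t_hours")
  check_join("doses", "t_start")
  check_join("troughs", "t_hours")
  if (nrow(tabs$doses) && any(tabs$doses$amount_mg <= 0)) {
    stop("doses.csv: amount_mg must be positive")
  }
  if (nrow(tabs$troughs) && any(tabs$troughs$range_lower >= tabs$troughs$range_upper)) {
    stop("troughs.csv: range_lower must be below range_upper")
  }

  meta_path <- file.path(dir, "cohort_meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  structure(c(tabs, list(config = meta$config, seed = meta$seed)),
            class = "icu_cohort")
}
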