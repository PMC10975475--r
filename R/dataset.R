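#' Concentration-time study datasets
#'
#' The package's lingua franca for in-vivo data is a long-format table of
#' concentration records with dosing metadata, one row per (subject, matrix,
#' time) observation. Units are fixed package-wide: time in hours,
#' concentration in ng/mL, dose in mg/kg (or mg, with the basis recorded in
#' `dose_units`). Conversions happen only at I/O boundaries.
#'
#' Required columns: `subject_id`, `species`, `sex` (`M`/`F`), `group`,
#' `route` (`iv_bolus`/`oral`), `dose`, `dose_units` (`mg/kg` or `mg`),
#' `matrix`, `time_h`, `conc_ng_per_ml`. An optional logical column `blq`
#' flags below-quantification-limit records; these are retained but excluded
#' from AUC and regression computations downstream.
#'
#' @param records data.frame with the columns above.
#' @param label study label stored in the dataset metadata.
#' @param lloq lower limit of quantification, ng/mL; records with
#'   concentration below `lloq` are flagged `blq` (not dropped).
#' @return object of class `study_dataset` (a validated data.frame with
#'   attributes `label` and `lloq`).
#' @examples
#' d <- study_dataset(data.frame(
#'   subject_id = "r1", species = "rat", sex = "M", group = "iv",
#'   route = "iv_bolus", dose = 1, dose_units = "mg/kg", matrix = "plasma",
#'   time_h = c(0.25, 1, 4), conc_ng_per_ml = c(400, 250, 60)))
#' nrow(d)
#' @export
study_dataset <- function(records, label = "study", lloq = NA_real_) {
  required <- c("subject_id", "species", "sex", "group", "route", "dose",
                "dose_units", "matrix", "time_h", "conc_ng_per_ml")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    abort_schema(paste0("missing mandatory column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) abort_validation("dataset has no records")

  bad_species <- setdiff(unique(records$species),
                         c("mouse", "rat", "dog", "monkey", "human"))
  if (length(bad_species)) {
    abort_validation(paste0("unknown species: ", paste(bad_species, collapse = ", ")))
  }
  if (!all(records$sex %in% c("M", "F"))) {
    abort_validation("sex must be 'M' or 'F'")
  }
  if (!all(records$route %in% c("iv_bolus", "oral"))) {
    abort_validation("route must be 'iv_bolus' or 'oral'")
  }
  if (!all(records$dose_units %in% c("mg/kg", "mg"))) {
    abort_validation("dose_units must be 'mg/kg' or 'mg'")
  }
  bad_time <- which(!is.finite(records$time_h) | records$time_h < 0)
  if (length(bad_time)) {
    abort_validation(sprintf("negative or non-finite time at row %d", bad_time[1]))
  }
  bad_conc <- which(!is.finite(records$conc_ng_per_ml) | records$conc_ng_per_ml < 0)
  if (length(bad_conc)) {
    abort_validation(sprintf("negative or non-finite concentration at row %d",
                             bad_conc[1]))
  }
  # dose basis must be consistent within a group
  mixed <- tapply(records$dose_units, records$group,
                  function(u) length(unique(u)) > 1L)
  if (any(unlist(mixed))) {
    abort_validation("dose_units differ within a dosing group")
  }
  # time strictly increasing within (subject, matrix)
  key <- interaction(records$subject_id, records$matrix, drop = TRUE)
  dup <- unlist(tapply(records$time_h, key,
                       function(tt) anyDuplicated(tt) > 0L), use.names = FALSE)
  if (any(dup)) {
    abort_validation("duplicate sampling times within a (subject, matrix) series")
  }

  records <- records[order(records$subject_id, records$matrix, records$time_h), ,
                     drop = FALSE]
  rownames(records) <- NULL
  if (is.null(records$blq)) records$blq <- FALSE
  if (is.finite(lloq)) {
    records$blq <- records$blq | (records$conc_ng_per_ml < lloq &
                                    records$conc_ng_per_ml > 0)
  }
  structure(records, label = label, lloq = lloq,
            class = c("study_dataset", "data.frame"))
}

#' Read a concentration-time CSV into a study dataset
#'
#' Expects a comma-separated, UTF-8, dot-decimal file with a mandatory header
#' row holding the columns documented in [study_dataset()].
#'
#' @param path path to the CSV file.
#' @param label study label; defaults to the file name.
#' @param lloq lower limit of quantification, ng/mL (optional).
#' @return a validated `study_dataset`.
#' @export
read_dataset <- function(path, label = basename(path), lloq = NA_real_) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  study_dataset(df, label = label, lloq = lloq)
}

#' Write a study dataset to CSV
#'
#' @param dataset a `study_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset '%s': %d records, %d subject(s), %d matrix(es)>\n",
              attr(x, "label"), nrow(x), length(unique(x$subject_id)),
              length(unique(x$matrix))))
  NextMethod()
}

#' Write result tables as TSV reports
#'
#' Renders a named list of result tables to tab-separated files with a
#' deterministic column order and numeric values rounded to 3 significant
#' figures (the package's reporting precision).
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @return character vector of file paths written, invisibly.
#' @export
write_report <- function(tables, dir) {
  if (!is.list(tables) || length(tables) == 0L ||
      is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort_validation("`tables` must be a non-empty named list of data.frames")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) abort_io(paste0("cannot create directory: ", dir))
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) abort_validation(sprintf("table '%s' is not a data.frame", nm))
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], signif, digits = 3)
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
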