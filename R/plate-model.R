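#' @title Plate data model and CSV I/O
#' @description
#' Long-format tables keyed by `(plate_id, well)` are the canonical
#' representation for multi-plate screens: measurements carry
#' `(plate_id, well, time_h, od600)`, annotations carry strain, medium,
#' compound and role for every well, and the compound library carries the
#' formulation flags that drive exclusions downstream. Wells use plate-reader
#' convention: letter rows A-H, 1-based columns 1-12 (96-well grid).
#' @name plate_model
NULL

#' Parse well labels into row letters and column numbers
#'
#' @param well character vector of labels such as `"A1"` or `"H12"`.
#' @return data.frame with columns `row` (letter) and `column` (integer).
#' @examples
#' parse_well(c("A1", "H12"))
#' @export
parse_well <- function(well) {
  well <- toupper(as.character(well))
  ok <- grepl("^[A-H](1[0-2]|[1-9])$", well)
  if (any(!ok)) {
    ss_stop("invalid well label(s) for a 96-well plate: ",
            paste(unique(well[!ok]), collapse = ", "))
  }
  data.frame(row = substr(well, 1, 1),
             column = as.integer(substring(well, 2)),
             stringsAsFactors = FALSE)
}

#' Compose well labels from row letters and column numbers
#'
#' @param row letter row A-H.
#' @param column integer column 1-12.
#' @return character vector of well labels.
#' @export
well_label <- function(row, column) {
  stopifnot(all(row %in% LETTERS[1:8]), all(column %in% 1:12))
  paste0(row, column)
}

ss_require_columns <- function(df, cols, what, path = NULL) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    ss_stop(sprintf("%s%s is missing required column(s): %s",
                    what, if (is.null(path)) "" else paste0(" '", path, "'"),
                    paste(missing, collapse = ", ")))
  }
}

#' Validate a measurement table
#'
#' Enforces the measurement invariants: valid 96-well addresses, non-negative
#' OD600, no duplicate `(plate_id, well, time_h)` key, and times sorted
#' non-decreasing within each well (rows are reordered to guarantee this).
#'
#' @param measurements data.frame with columns `plate_id`, `well`, `time_h`,
#'   `od600`.
#' @return the validated (and time-ordered) measurement table.
#' @export
validate_measurements <- function(measurements) {
  ss_require_columns(measurements, c("plate_id", "well", "time_h", "od600"),
                     "measurement table")
  parse_well(measurements$well)
  bad <- which(!is.finite(measurements$od600) | measurements$od600 < 0)
  if (length(bad)) {
    b <- measurements[bad[1], ]
    ss_stop(sprintf(
      "negative or non-finite od600 at plate %s well %s time %g h (%d offending row(s))",
      b$plate_id, b$well, b$time_h, length(bad)))
  }
  if (any(!is.finite(measurements$time_h) | measurements$time_h < 0)) {
    ss_stop("time_h must be finite and >= 0")
  }
  key <- paste(measurements$plate_id, measurements$well, measurements$time_h,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- measurements[duplicated(key), c("plate_id", "well", "time_h")]
    ss_stop("duplicate (plate, well, time) measurement(s): ",
            paste(unique(sprintf("%s/%s@%gh", dup$plate_id, dup$well,
                                 dup$time_h)), collapse = ", "))
  }
  measurements <- measurements[order(measurements$plate_id,
                                     measurements$well,
                                     measurements$time_h), , drop = FALSE]
  rownames(measurements) <- NULL
  measurements
}

#' Read a long-format OD600 measurement CSV
#'
#' The canonical layout is one row per well per timepoint with header
#' `plate_id,well,time_h,od600`. A dialect list maps differently named
#' columns and converts minute-based time columns to hours.
#'
#' @param path CSV file path.
#' @param dialect optional list with any of `plate_id`, `well`, `time`, `od`
#'   (source column names) and `time_unit` (`"hours"`, the default, or
#'   `"minutes"`).
#' @return validated measurement data.frame (see [validate_measurements()]).
#' @export
read_measurements <- function(path, dialect = list()) {
  if (!file.exists(path)) ss_stop("measurement file not found: ", path)
  cols <- list(plate_id = dialect$plate_id %||% "plate_id",
               well = dialect$well %||% "well",
               time = dialect$time %||% "time_h",
               od = dialect$od %||% "od600")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ss_require_columns(df, unlist(cols), "measurement file", path)
  out <- data.frame(plate_id = as.character(df[[cols$plate_id]]),
                    well = as.character(df[[cols$well]]),
                    time_h = as.numeric(df[[cols$time]]),
                    od600 = as.numeric(df[[cols$od]]),
                    stringsAsFactors = FALSE)
  if (identical(dialect$time_unit %||% "hours", "minutes")) {
    out$time_h <- out$time_h / 60
  }
  if (nrow(out) == 0L) {
    warning("measurement file '", path, "' contains no data rows",
            call. = FALSE)
    return(out)
  }
  validate_measurements(out)
}

#' Read a wide plate-grid CSV (read-only convenience)
#'
#' One 8 x 12 grid of OD values for a single plate at a single timepoint,
#' with row letters in the first column and column numbers in the header.
#'
#' @param path CSV path.
#' @param plate_id plate identifier to assign.
#' @param time_h timepoint (hours) of the grid.
#' @return long-format measurement data.frame.
#' @export
read_plate_grid <- function(path, plate_id, time_h) {
  if (!file.exists(path)) ss_stop("plate grid file not found: ", path)
  g <- utils::read.csv(path, stringsAsFactors = FALSE, row.names = 1,
                       check.names = FALSE)
  if (nrow(g) != 8L || ncol(g) != 12L) {
    ss_stop("plate grid must be 8 rows x 12 columns, got ",
            nrow(g), " x ", ncol(g))
  }
  long <- data.frame(
    plate_id = plate_id,
    well = well_label(rep(rownames(g), times = 12L),
                      rep(1:12, each = 8L)),
    time_h = time_h,
    od600 = as.numeric(as.matrix(g)),
    stringsAsFactors = FALSE)
  validate_measurements(long)
}

#' Write a measurement table as canonical long-format CSV
#'
#' @param measurements measurement data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  ss_require_columns(measurements, c("plate_id", "well", "time_h", "od600"),
                     "measurement table")
  # shortest decimal representation that round-trips the double exactly
  fmt <- function(x) {
    s <- sprintf("%.15g", x)
    bad <- as.numeric(s) != x
    s[bad] <- sprintf("%.17g", x[bad])
    s
  }
  out <- data.frame(plate_id = measurements$plate_id,
                    well = measurements$well,
                    time_h = fmt(measurements$time_h),
                    od600 = fmt(measurements$od600),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a well-annotation table
#'
#' Checks the role/compound invariants: a `negative_control` well is vehicle
#' only (no compound), and `concentration_uM` is zero exactly when no
#' compound is present.
#'
#' @param annotations data.frame with columns `plate_id`, `well`, `strain`,
#'   `medium`, `compound_id` (`NA` for none), `concentration_uM`, `role`.
#' @return the validated table.
#' @export
validate_annotations <- function(annotations) {
  ss_require_columns(annotations,
                     c("plate_id", "well", "strain", "medium",
                       "compound_id", "concentration_uM", "role"),
                     "annotation table")
  parse_well(annotations$well)
  annotations$compound_id[which(annotations$compound_id %in% "")] <- NA
  if (!all(annotations$strain %in% ss_strains())) {
    ss_stop("unknown strain(s): ",
            paste(setdiff(unique(annotations$strain), ss_strains()),
                  collapse = ", "))
  }
  if (!all(annotations$medium %in% ss_media())) {
    ss_stop("unknown medium(s): ",
            paste(setdiff(unique(annotations$medium), ss_media()),
                  collapse = ", "))
  }
  if (!all(annotations$role %in% ss_roles())) {
    ss_stop("unknown role(s): ",
            paste(setdiff(unique(annotations$role), ss_roles()),
                  collapse = ", "))
  }
  key <- paste(annotations$plate_id, annotations$well, sep = "\r")
  if (anyDuplicated(key)) {
    ss_stop("duplicate well annotation(s): ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  nc <- annotations$role == "negative_control"
  if (any(nc & !is.na(annotations$compound_id))) {
    ss_stop("negative_control wells must be vehicle only (compound_id none)")
  }
  has_cmp <- !is.na(annotations$compound_id)
  if (any(has_cmp & annotations$concentration_uM <= 0)) {
    ss_stop("wells with a compound must have concentration_uM > 0")
  }
  if (any(!has_cmp & annotations$concentration_uM != 0)) {
    ss_stop("wells without a compound must have concentration_uM = 0")
  }
  annotations
}

#' Read a well-annotation CSV
#' @param path CSV path with the columns of [validate_annotations()].
#' @return validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) ss_stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(compound_id = "character"))
  validate_annotations(df)
}

#' Validate a compound-library table
#' @param library data.frame with columns `compound_id`, `name`,
#'   `contains_sulfate`, `colored_solution`, `stock_mM`.
#' @return the validated table.
#' @export
validate_library <- function(library) {
  ss_require_columns(library,
                     c("compound_id", "name", "contains_sulfate",
                       "colored_solution", "stock_mM"), "compound library")
  if (anyDuplicated(library$compound_id)) {
    ss_stop("duplicate compound_id(s) in library: ",
            paste(unique(library$compound_id[duplicated(library$compound_id)]),
                  collapse = ", "))
  }
  if (any(!is.finite(library$stock_mM) | library$stock_mM <= 0)) {
    ss_stop("stock_mM must be > 0 for every compound")
  }
  library$contains_sulfate <- as.logical(library$contains_sulfate)
  library$colored_solution <- as.logical(library$colored_solution)
  library
}

#' Read a compound-library CSV
#' @param path CSV path with the columns of [validate_library()].
#' @return validated library data.frame.
#' @export
read_library <- function(path) {
  if (!file.exists(path)) ss_stop("library file not found: ", path)
  validate_library(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = c(compound_id = "character")))
}

#' Join measurements with well annotations and the compound library
#'
#' The join is lossless: exactly one output row per measurement row. Every
#' measured well must be annotated and every annotated compound must exist
#' in the library.
#'
#' @param measurements measurement data.frame.
#' @param annotations annotation data.frame.
#' @param library compound-library data.frame (optional; `NULL` to join
#'   annotations only).
#' @return data.frame of measurements with annotation (and library) columns.
#' @export
join_annotations <- function(measurements, annotations, library = NULL) {
  measurements <- validate_measurements(measurements)
  annotations <- validate_annotations(annotations)
  mkey <- paste(measurements$plate_id, measurements$well, sep = "\r")
  akey <- paste(annotations$plate_id, annotations$well, sep = "\r")
  orphan <- setdiff(unique(mkey), akey)
  if (length(orphan)) {
    ss_stop("measured well(s) lack annotation: ",
            paste(gsub("\r", "/", orphan), collapse = ", "))
  }
  idx <- match(mkey, akey)
  joined <- cbind(measurements,
                  annotations[idx, c("strain", "medium", "compound_id",
                                     "concentration_uM", "role")])
  rownames(joined) <- NULL
  if (!is.null(library)) {
    library <- validate_library(library)
    used <- unique(stats::na.omit(joined$compound_id))
    unknown <- setdiff(used, library$compound_id)
    if (length(unknown)) {
      ss_stop("compound id(s) absent from library: ",
              paste(unknown, collapse = ", "))
    }
    lidx <- match(joined$compound_id, library$compound_id)
    joined$compound_name <- library$name[lidx]
    joined$contains_sulfate <- library$contains_sulfate[lidx]
    joined$colored_solution <- library$colored_solution[lidx]
  }
  stopifnot(nrow(joined) == nrow(measurements))
  joined
}
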