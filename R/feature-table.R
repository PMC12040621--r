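#' Validate a per-patient feature table
#'
#' A feature table has one row per patient: an identifier column, numeric
#' feature columns, optional clinical covariates, a binary subtype label
#' (0 = luminal, 1 = non-luminal) and, optionally, a `split` assignment.
#'
#' @param table A data frame.
#' @param id Name of the patient identifier column.
#' @param label Name of the binary label column (or `NULL` to skip the check).
#' @return The table as a tibble, invisibly checked.
#' @export
validate_feature_table <- function(table, id = "patient_id", label = "label") {
  table <- tibble::as_tibble(table)
  if (anyDuplicated(names(table))) stop("duplicate column names: ",
                                        paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  if (id %in% names(table) && anyDuplicated(table[[id]])) {
    stop("duplicate patient identifiers in column '", id, "'")
  }
  if (!is.null(label) && label %in% names(table)) {
    lv <- table[[label]]
    if (!all(lv %in% c(0, 1))) stop("label column '", label, "' must be binary 0/1")
  }
  num <- vapply(table, is.numeric, logical(1))
  for (cn in names(table)[num]) {
    bad <- which(!is.finite(table[[cn]]))
    if (length(bad)) stop("non-finite value in column '", cn, "', row ", bad[1])
  }
  table
}

#' Write / read a feature table as CSV
#'
#' Plain UTF-8 CSV with a header row and `.` decimal separator; numeric
#' values are written with 15 significant digits so a write/read round trip
#' is lossless to beyond 12 significant digits.
#'
#' @param table A data frame (validated with [validate_feature_table()]).
#' @param path Output CSV path.
#' @param ... Passed to [validate_feature_table()].
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_feature_table <- function(table, path, ...) {
  table <- validate_feature_table(table, ...)
  out <- table
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  validate_feature_table(tibble::as_tibble(df), ...)
}

#' Read a per-patient case configuration
#'
#' A case config names, per patient, the NIfTI paths of the three dynamic
#' phases and the lesion mask. The three phases are supplied explicitly by
#' name, never inferred from timestamps. YAML and JSON are both accepted:
#' a top-level mapping of patient id to an entry with `pre`, `initial`,
#' `delayed` and `mask` keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @param base_dir Directory against which relative paths are resolved
#'   (default: the config's directory).
#' @return A tibble with columns `patient_id`, `pre`, `initial`, `delayed`,
#'   `mask`.
#' @export
read_case_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("pre", "initial", "delayed", "mask")
  rows <- purrr::imap(cfg, function(entry, id) {
    miss <- setdiff(need, names(entry))
    if (length(miss)) stop("patient '", id, "' is missing: ", paste(miss, collapse = ", "))
    p <- unname(vapply(entry[need], identity, character(1)))
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(base_dir, p[rel])
    tibble::tibble(patient_id = id, pre = p[1], initial = p[2],
                   delayed = p[3], mask = p[4])
  })
  dplyr::bind_rows(rows)
}
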