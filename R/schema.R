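#' Diagnosis labels
#'
#' The four diagnostic outcomes, in the fixed order used throughout the
#' package (confusion matrices, leaf-label tie-breaks): HF with reduced,
#' mid-range and preserved ejection fraction, and no heart failure.
#' The first three collapse to "HF" in binary analyses.
#'
#' @return Character vector of the four labels.
#' @export
#' @examples
#' hf_labels()
hf_labels <- function() {
  c("HFrEF", "HFmrEF", "HFpEF", "NoHF")
}

#' Default clinical attribute schema
#'
#' The 14 attributes a knowledge model may test: demographics (age, sex),
#' the cardinal HF findings (symptoms/signs, clinical history, physical
#' exam, abnormal ECG), the NT-proBNP biomarker, and echocardiographic
#' indices (LVEF, LAVI, LVMI, E/e', septal e', TRV, GLS).  Sex is encoded
#' as the binary attribute `male`; LVEF and GLS are stored in percent
#' (e.g. 27.1, not 0.271), GLS as a positive magnitude.
#'
#' @return A data frame with columns `name`, `kind` (`"continuous"` or
#'   `"binary"`), `units`, and for continuous attributes the closed valid
#'   range `lo`, `hi` (values outside it are rejected at load time).
#' @export
#' @examples
#' default_schema()
default_schema <- function() {
  data.frame(
    name = c("age", "male", "hf_symptoms_signs", "clinical_history",
             "physical_exam", "abnormal_ecg", "nt_probnp", "lvef", "lavi",
             "lvmi", "e_over_eprime", "septal_eprime", "trv", "gls"),
    kind = c("continuous", "binary", "binary", "binary", "binary", "binary",
             "continuous", "continuous", "continuous", "continuous",
             "continuous", "continuous", "continuous", "continuous"),
    units = c("years", "", "", "", "", "", "pg/L", "%", "mL/m2", "mg/m2",
              "", "cm/s", "m/s", "%"),
    lo = c(18, NA, NA, NA, NA, NA, 0.5, 0, 5, 20, 1, 0.5, 0.3, 0),
    hi = c(110, NA, NA, NA, NA, NA, 2e5, 100, 200, 400, 60, 25, 7, 40),
    stringsAsFactors = FALSE
  )
}

schema_attributes <- function(schema = default_schema()) schema$name

schema_kind <- function(attribute, schema = default_schema()) {
  i <- match(attribute, schema$name)
  if (anyNA(i)) stop("unknown attribute(s): ",
                     paste(attribute[is.na(i)], collapse = ", "), call. = FALSE)
  schema$kind[i]
}

#' Validate a patient cohort against the attribute schema
#'
#' Checks that every schema attribute is present as a column, that binary
#' attributes are logical (or 0/1 coercible), that continuous values lie
#' inside their valid range, and that `gold_diagnosis`, when present, uses
#' only the four labels (or NA).  `NA` cells denote Missing values and are
#' always allowed: Missing is a first-class value here, never imputed;
#' what a Missing value *means* is decided by the knowledge model that
#' tests the attribute.
#'
#' @param cohort Data frame with one row per patient.
#' @param schema Attribute schema, see [default_schema()].
#' @return The cohort, invisibly, with binary columns coerced to logical
#'   and `gold_diagnosis` to character.
#' @export
validate_cohort <- function(cohort, schema = default_schema()) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(schema$name, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks schema attribute(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"patient_id" %in% names(cohort))
    cohort$patient_id <- paste0("p", seq_len(nrow(cohort)))
  for (i in seq_len(nrow(schema))) {
    a <- schema$name[i]
    v <- cohort[[a]]
    if (schema$kind[i] == "binary") {
      if (is.numeric(v)) {
        bad <- !is.na(v) & !(v %in% c(0, 1))
        if (any(bad))
          stop(sprintf("attribute '%s': non-binary value in row %d",
                       a, which(bad)[1]), call. = FALSE)
        v <- as.logical(v)
      }
      if (!is.logical(v))
        stop(sprintf("attribute '%s' must be logical (binary)", a),
             call. = FALSE)
      cohort[[a]] <- v
    } else {
      if (!is.numeric(v))
        stop(sprintf("attribute '%s' must be numeric (continuous)", a),
             call. = FALSE)
      out <- !is.na(v) & (v < schema$lo[i] | v > schema$hi[i])
      if (any(out))
        stop(sprintf(
          "attribute '%s': value %g in row %d outside valid range [%g, %g]",
          a, v[which(out)[1]], which(out)[1], schema$lo[i], schema$hi[i]),
          call. = FALSE)
    }
  }
  if ("gold_diagnosis" %in% names(cohort)) {
    g <- as.character(cohort$gold_diagnosis)
    g[!is.na(g) & g == ""] <- NA_character_
    bad <- !is.na(g) & !(g %in% hf_labels())
    if (any(bad))
      stop(sprintf("unknown gold_diagnosis '%s' in row %d",
                   g[which(bad)[1]], which(bad)[1]), call. = FALSE)
    cohort$gold_diagnosis <- g
  }
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' The file must be comma-separated UTF-8 with a header row naming the
#' schema attributes; empty cells denote Missing.  A `gold_diagnosis`
#' column, when present, is parsed against the four diagnosis labels.
#' Columns other than `patient_id`, the schema attributes and
#' `gold_diagnosis` are rejected, as are continuous values outside their
#' valid range.
#'
#' @param path CSV file path.
#' @inheritParams validate_cohort
#' @return Data frame with `patient_id`, one column per attribute
#'   (logical for binary, numeric for continuous, `NA` = Missing) and
#'   `gold_diagnosis` (character or `NA`) if present in the file.
#' @export
load_cohort <- function(path, schema = default_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""), fileEncoding = "UTF-8",
                         colClasses = "character")
  extra <- setdiff(names(raw), c("patient_id", schema$name, "gold_diagnosis"))
  if (length(extra))
    stop("unknown column(s) in cohort file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(schema))) {
    a <- schema$name[i]
    if (!a %in% names(raw)) next
    v <- raw[[a]]
    if (schema$kind[i] == "binary") {
      parsed <- rep(NA, length(v))
      parsed[!is.na(v) & toupper(v) %in% c("TRUE", "T", "1")] <- TRUE
      parsed[!is.na(v) & toupper(v) %in% c("FALSE", "F", "0")] <- FALSE
      bad <- !is.na(v) & is.na(parsed)
      if (any(bad))
        stop(sprintf("attribute '%s': unparseable binary value '%s' in row %d",
                     a, v[which(bad)[1]], which(bad)[1]), call. = FALSE)
      raw[[a]] <- parsed
    } else {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & is.na(parsed)
      if (any(bad))
        stop(sprintf("attribute '%s': unparseable numeric value '%s' in row %d",
                     a, v[which(bad)[1]], which(bad)[1]), call. = FALSE)
      raw[[a]] <- parsed
    }
  }
  validate_cohort(raw, schema)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [load_cohort()]: Missing values become empty cells.  Output
#' is deterministic for a given cohort, so identically generated cohorts
#' serialize byte-for-byte identically.
#'
#' @param cohort Validated cohort data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
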