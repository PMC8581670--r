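#' Construct a cohort object
#'
#' Bundles per-subject covariates, the subjects x regions cortical-thickness
#' matrix, and the atlas into one validated container.
#'
#' @param subjects Data frame with at least `subject_id`, `group`, `age`,
#'   `sex` (`"M"`/`"F"`), `tiv` (total intracranial volume, mm^3). Optional:
#'   `dq` (developmental quotient) and global surface metrics `mean_ct` (mm),
#'   `fd`, `sd` (mm), `gi` (degrees).
#' @param ct Numeric matrix, one row per subject (same order as `subjects`),
#'   one column per atlas region; values in mm, strictly positive and finite.
#' @param atlas An `scn_atlas` data frame (default: [default_atlas()] sized to
#'   `ncol(ct)`).
#' @return An object of class `scn_cohort`: a list with elements `subjects`,
#'   `ct`, `atlas`.
#' @export
scn_cohort <- function(subjects, ct, atlas = default_atlas(ncol(ct))) {
  mandatory <- c("subject_id", "group", "age", "sex", "tiv")
  miss <- setdiff(mandatory, names(subjects))
  if (length(miss))
    stop("subjects table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id values", call. = FALSE)
  if (any(is.na(subjects$group)) || any(subjects$group == ""))
    stop("every subject needs a group label", call. = FALSE)
  if (!all(subjects$sex %in% c("M", "F")))
    stop("sex must be coded 'M'/'F'", call. = FALSE)
  ct <- as.matrix(ct)
  if (nrow(ct) != nrow(subjects))
    stop("ct rows must match subjects rows", call. = FALSE)
  if (ncol(ct) != nrow(atlas))
    stop(sprintf("ct has %d regions but atlas has %d", ncol(ct), nrow(atlas)),
         call. = FALSE)
  if (!all(is.finite(ct)) || any(ct <= 0))
    stop("regional CT must be finite and > 0 (use read_cohort for QC exclusion)",
         call. = FALSE)
  rownames(ct) <- subjects$subject_id
  colnames(ct) <- atlas$label
  structure(list(subjects = subjects, ct = ct, atlas = atlas),
            class = "scn_cohort")
}

#' @export
print.scn_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Structural covariance cohort\n")
  cat(sprintf("  %d subjects, %d regions (%d per hemisphere)\n",
              nrow(x$ct), ncol(x$ct), sum(x$atlas$hemisphere == "L")))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

# Columns that are numeric on disk, serialized at full double precision.
.cohort_covariate_cols <- c("age", "tiv", "dq", "mean_ct", "fd", "sd", "gi")

format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write a cohort to a delimited file
#'
#' One wide TSV: covariate columns first (subject_id leading), then one column
#' per atlas region, numeric values at full double precision so a
#' write-then-read round trip is lossless.
#'
#' @param cohort An `scn_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort$subjects
  out <- data.frame(lapply(df, format_full), stringsAsFactors = FALSE,
                    check.names = FALSE)
  ctc <- apply(cohort$ct, 2, format_full)
  if (nrow(cohort$ct) == 1L) ctc <- matrix(ctc, nrow = 1,
                                           dimnames = list(NULL, colnames(cohort$ct)))
  out <- cbind(out, as.data.frame(ctc, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' Accepts TSV or CSV (delimiter sniffed from the header line). Subjects with
#' any non-finite or non-positive regional CT value are excluded, and the
#' exclusions are reported by subject id (attribute `"exclusions"` and a
#' message), mirroring scan-quality rejection in morphometric studies.
#'
#' @param path Path to the table; header must contain all atlas labels plus
#'   `subject_id`, `group`, `age`, `sex`, `tiv`.
#' @param atlas Atlas defining the expected region columns.
#' @return An `scn_cohort`; excluded subject ids in `attr(, "exclusions")`.
#' @export
read_cohort <- function(path, atlas = default_atlas()) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("subject_id", "group", "age", "sex", "tiv")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("cohort file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss_reg <- setdiff(atlas$label, names(df))
  if (length(miss_reg))
    stop(sprintf("cohort file lacks %d atlas region column(s), e.g. %s",
                 length(miss_reg), miss_reg[1]), call. = FALSE)
  ct <- as.matrix(df[, atlas$label, drop = FALSE])
  storage.mode(ct) <- "double"
  bad <- !apply(ct, 1, function(r) all(is.finite(r)) && all(r > 0))
  excluded <- df$subject_id[bad]
  if (length(excluded)) {
    message("read_cohort: excluded ", length(excluded),
            " subject(s) with invalid regional CT: ",
            paste(excluded, collapse = ", "))
    df <- df[!bad, , drop = FALSE]
    ct <- ct[!bad, , drop = FALSE]
  }
  covars <- df[, setdiff(names(df), atlas$label), drop = FALSE]
  for (col in intersect(.cohort_covariate_cols, names(covars)))
    covars[[col]] <- as.numeric(covars[[col]])
  cohort <- scn_cohort(covars, ct, atlas)
  attr(cohort, "exclusions") <- excluded
  cohort
}

#' Write a clinical-score table to TSV
#' @param clinical Data frame with `subject_id` plus numeric score columns
#'   (ADOS-2 and Griffith domains); `NA` permitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- data.frame(lapply(clinical, format_full), stringsAsFactors = FALSE,
                    check.names = FALSE)
  out[is.na(clinical)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical-score table
#'
#' @param path TSV/CSV path with a `subject_id` column.
#' @param cohort Optional `scn_cohort`; if given, every clinical subject_id
#'   must exist in the cohort.
#' @return Data frame; missing values kept as `NA` (flagged in attribute
#'   `"n_missing"`).
#' @export
read_clinical <- function(path, cohort = NULL) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"subject_id" %in% names(df))
    stop("clinical file missing subject_id column", call. = FALSE)
  if (!is.null(cohort)) {
    unknown <- setdiff(df$subject_id, cohort$subjects$subject_id)
    if (length(unknown))
      stop("clinical subject_id not in cohort: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  attr(df, "n_missing") <- sum(is.na(df))
  df
}
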