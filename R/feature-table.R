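#' Construct a radiomic feature table
#'
#' A feature table is a numeric samples-by-features matrix tagged with the
#' MRI sequence (modality) it was extracted from. Sample identifiers and
#' feature names must be unique and every entry finite: downstream kernel
#' construction has no notion of missingness, so validation is strict.
#'
#' @param values numeric matrix (samples x features).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#' @param modality modality label, conventionally `"T1CE"` or `"T2FLAIR"`.
#' @return An object of class `feature_table`: the numeric matrix with
#'   `sample_ids` as rownames and a `modality` attribute.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          modality = "T1CE") {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L)
    stop("feature table must be a nonempty numeric matrix")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 sample_ids[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]))
  rownames(values) <- sample_ids
  structure(values, modality = modality, class = c("feature_table", "matrix"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> modality=%s: %d samples x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature names and a first column `sample_id`.
#' Rejects duplicate identifiers, non-numeric cells and missing values,
#' naming the offending row/column in the error.
#'
#' @param path path to a CSV (or TSV with `sep = "\t"`) file.
#' @param modality modality label to attach.
#' @param sep field separator.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, modality = "T1CE", sep = ",") {
  df <- read.csv(path, sep = sep, check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or headerless feature table: ", path)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing cell at sample '%s', feature '%s'",
                   ids[i], names(vals)[j]))
    }
    vals[[j]] <- v
  }
  ft <- feature_table(as.matrix(vals), ids, modality)
  message(sprintf("read %d samples x %d features [%s] from %s",
                  nrow(ft), ncol(ft), modality, path))
  ft
}

#' Write a feature table as CSV
#'
#' @param x a [feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a clinical table
#'
#' Checks the clinical covariates that the survival and contingency
#' analyses rely on: overall survival in days with an event indicator,
#' age, gender, WHO grade (2/3/4), tumor volume, IDH genotype and MGMT
#' promoter status.
#'
#' @param df data.frame with columns `sample_id`, `os_days`, `event`,
#'   `age_years`, `gender` (`female`/`male`), `grade` (2, 3, 4),
#'   `tumor_volume_cm3`, `idh` (`wild`/`mutant`), `mgmt`
#'   (`unmethylated`/`methylated`). Extra columns pass through.
#' @return The validated data.frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  req <- c("sample_id", "os_days", "event", "age_years", "gender",
           "grade", "tumor_volume_cm3", "idh", "mgmt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(df$os_days < 0)) stop("negative os_days")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  if (!all(df$gender %in% c("female", "male"))) stop("bad gender level")
  if (!all(df$grade %in% c(2, 3, 4))) stop("grade must be 2, 3 or 4")
  if (any(df$tumor_volume_cm3 <= 0)) stop("tumor volume must be positive")
  if (!all(df$idh %in% c("wild", "mutant"))) stop("bad idh level")
  if (!all(df$mgmt %in% c("unmethylated", "methylated"))) stop("bad mgmt level")
  class(df) <- c("clinical_table", class(df))
  df
}

#' Read a clinical table from CSV
#' @param path CSV path with the columns documented in [clinical_table()].
#' @return A validated `clinical_table`.
#' @export
read_clinical_table <- function(path) {
  clinical_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Align feature tables and clinical data to a common sample set
#'
#' Restricts every table to the intersection of sample ids, in one
#' canonical (sorted) order, so that fusion stages can assume identical
#' sample indexing. Dropped samples are reported via `message()`.
#'
#' @param tables list of [feature_table()]s (one per modality).
#' @param clinical optional [clinical_table()].
#' @return A list with elements `tables` (aligned feature tables),
#'   `clinical` (aligned or NULL) and `sample_ids`.
#' @export
align_cohort <- function(tables, clinical = NULL) {
  if (!length(tables)) stop("no feature tables supplied")
  id_sets <- lapply(tables, rownames)
  common <- Reduce(intersect, id_sets)
  if (!is.null(clinical)) common <- intersect(common, clinical$sample_id)
  if (length(common) == 0L) stop("empty sample-id intersection")
  common <- sort(common)
  dropped <- length(unique(unlist(id_sets))) - length(common)
  if (dropped > 0L) message(sprintf("align_cohort: dropped %d sample(s)", dropped))
  tables <- lapply(tables, function(t)
    feature_table(t[common, , drop = FALSE], common, attr(t, "modality")))
  if (!is.null(clinical)) {
    clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
    rownames(clinical) <- NULL
  }
  list(tables = tables, clinical = clinical, sample_ids = common)
}
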