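#' Cohort tables
#'
#' A cohort table is a data frame with one row per subject (columns
#' `subject_id`, `volume_path`, `age_years`, `sex`, `bmi`), a
#' `split_label` attribute (`train`, `validation`, `test` or `unsplit`)
#' and, optionally, in-memory volumes attached by the phantom generator
#' so that synthetic cohorts need not touch the filesystem.  `bmi` may
#' be `NA` for prediction-only cohorts; training and evaluation reject
#' such records.  `sex` is coded 0 for female and 1 for male; age is in
#' years (precision to the month).
#'
#' @param records data frame with the columns above.
#' @param volumes optional named list of [new_volume()] objects keyed by
#'   `subject_id`.
#' @param split_label one of `"train"`, `"validation"`, `"test"`,
#'   `"unsplit"`.
#' @return an object of class `cohort_table` (a data frame).
#' @export
cohort_table <- function(records, volumes = NULL, split_label = "unsplit") {
  required <- c("subject_id", "volume_path", "age_years", "sex", "bmi")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[required]
  records$subject_id <- as.character(records$subject_id)
  dup <- records$subject_id[duplicated(records$subject_id)]
  if (length(dup))
    stop("duplicate subject_id: ", paste(unique(dup), collapse = ", "))
  bad_sex <- !records$sex %in% c(0, 1)
  if (any(bad_sex))
    stop("sex must be coded 0 (female) or 1 (male); offending rows: ",
         paste(which(bad_sex), collapse = ", "))
  if (any(!is.na(records$age_years) & records$age_years < 0))
    stop("age_years must be non-negative")
  bad_bmi <- !is.na(records$bmi) & (records$bmi <= 0 | !is.finite(records$bmi))
  if (any(bad_bmi))
    stop("bmi must be positive and finite where present; offending rows: ",
         paste(which(bad_bmi), collapse = ", "))
  if (!split_label %in% c("train", "validation", "test", "unsplit"))
    stop("invalid split_label: ", split_label)
  if (!is.null(volumes)) {
    if (is.null(names(volumes)) ||
        !all(names(volumes) %in% records$subject_id))
      stop("`volumes` must be named by subject_id")
  }
  structure(records, volumes = volumes, split_label = split_label,
            class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with the exact header
#' `subject_id,volume_path,age_years,sex,bmi`; `bmi` entries may be
#' empty for prediction-only cohorts.
#'
#' @param csv_path path to the CSV file.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(csv_path) {
  if (!file.exists(csv_path)) stop("file not found: ", csv_path)
  raw <- utils::read.csv(csv_path, colClasses = "character",
                         na.strings = c("", "NA"))
  required <- c("subject_id", "volume_path", "age_years", "sex", "bmi")
  if (!identical(names(raw)[seq_along(required)], required))
    stop("cohort CSV must have header: ", paste(required, collapse = ","))
  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad))
      stop(sprintf("unparseable %s in row(s) %s of %s", col,
                   paste(bad, collapse = ", "), csv_path))
    out
  }
  records <- data.frame(
    subject_id = raw$subject_id,
    volume_path = raw$volume_path,
    age_years = parse_num(raw$age_years, "age_years"),
    sex = parse_num(raw$sex, "sex"),
    bmi = parse_num(raw$bmi, "bmi"),
    stringsAsFactors = FALSE
  )
  cohort_table(records)
}

#' Write a cohort table to CSV
#'
#' @param cohort a [cohort_table()].
#' @param csv_path output path.
#' @export
write_cohort_csv <- function(cohort, csv_path) {
  df <- as.data.frame(cohort)[c("subject_id", "volume_path", "age_years",
                                "sex", "bmi")]
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  invisible(csv_path)
}

#' Split a cohort into disjoint train/validation/test tables
#'
#' Validation and test sizes are the fractions rounded to the nearest
#' integer; any remainder goes to the training split (so 17,938 records
#' at fractions 13938/2000/2000 over 17,938 give sizes 13938, 2000 and
#' 2000).  The assignment is a seeded random permutation.
#'
#' @param cohort a [cohort_table()] with at least 3 records.
#' @param fractions non-negative numeric triple summing to 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  if (n < 3L) stop("need at least 3 records to split")
  if (length(fractions) != 3L || any(fractions < 0))
    stop("`fractions` must be three non-negative numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must sum to 1 (within 1e-9)")
  n_val <- as.integer(floor(fractions[2] * n + 0.5))
  n_test <- as.integer(floor(fractions[3] * n + 0.5))
  n_train <- n - n_val - n_test
  if (n_train < 0) stop("fractions leave no training records")
  perm <- with_seed(seed, sample.int(n))
  idx <- list(train = perm[seq_len(n_train)],
              validation = perm[n_train + seq_len(n_val)],
              test = perm[n_train + n_val + seq_len(n_test)])
  vols <- attr(cohort, "volumes")
  out <- lapply(names(idx), function(split) {
    rows <- sort(idx[[split]])
    sub <- as.data.frame(cohort)[rows, , drop = FALSE]
    rownames(sub) <- NULL
    v <- if (is.null(vols)) NULL else vols[sub$subject_id]
    cohort_table(sub, volumes = v,
                 split_label = if (split == "train") "train"
                               else if (split == "validation") "validation"
                               else "test")
  })
  names(out) <- names(idx)
  out
}

# Fetch subject i's volume: in-memory if attached, else from disk.
get_volume <- function(cohort, i) {
  vols <- attr(cohort, "volumes")
  id <- cohort$subject_id[i]
  if (!is.null(vols) && !is.null(vols[[id]])) return(vols[[id]])
  path <- cohort$volume_path[i]
  if (is.na(path) || !nzchar(path))
    stop("no volume available for subject ", id)
  read_volume(path)
}

# All volumes as plain 3D arrays (shape-checked against the first).
cohort_arrays <- function(cohort) {
  arrays <- lapply(seq_len(nrow(cohort)), function(i)
    as_volume_array(get_volume(cohort, i)))
  d1 <- dim(arrays[[1]])
  same <- vapply(arrays, function(a) identical(dim(a), d1), logical(1))
  if (!all(same)) stop("volumes in the cohort differ in shape")
  arrays
}

# Covariate matrix in network order (age, sex).
cohort_covariates <- function(cohort) {
  cbind(age = cohort$age_years, sex = cohort$sex)
}

require_targets <- function(cohort, what = "this operation") {
  if (any(is.na(cohort$bmi)))
    stop(what, " requires a bmi value for every record; missing for: ",
         paste(cohort$subject_id[is.na(cohort$bmi)], collapse = ", "))
  invisible(TRUE)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x), " subjects, split ",
      attr(x, "split_label"),
      if (!is.null(attr(x, "volumes"))) ", in-memory volumes" else "",
      "\n", sep = "")
  NextMethod()
}
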