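#' Regional measure table
#'
#' Subjects-by-regions matrix of a regional measure (ReHo, cortical
#' thickness, CBF, ...) joined to subject covariates, diagnosis and an
#' optional symptom-severity rating. Row order of `measures` matches
#' `subjects`; column order matches `region_ids`.
#'
#' @param subjects Data frame with columns `subject_id`, `age` (years),
#'   `sex` (0/1), `dx` (0 = control, 1 = case) and optionally `severity`
#'   (missing for subjects without a rating).
#' @param measures Numeric matrix, one row per subject, one column per
#'   region.
#' @param measure_name Short measure label, e.g. `"reho"`.
#' @return An object of class `regional_table`.
#' @export
regional_table <- function(subjects, measures, measure_name = "measure") {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  measures <- as.matrix(measures)
  need <- c("subject_id", "age", "sex", "dx")
  miss <- setdiff(need, names(subjects))
  if (length(miss))
    stop("subject table is missing columns: ", paste(miss, collapse = ", "))
  if (!"severity" %in% names(subjects)) subjects$severity <- NA_real_
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  if (nrow(measures) != nrow(subjects))
    stop("measures has ", nrow(measures), " rows but subjects has ",
         nrow(subjects))
  if (is.null(colnames(measures)))
    colnames(measures) <- sprintf("region_%02d", seq_len(ncol(measures)))
  if (!all(subjects$dx %in% c(0, 1)) || !all(subjects$sex %in% c(0, 1)))
    stop("dx and sex must be coded 0/1")
  structure(list(subjects = subjects, measures = measures,
                 region_ids = colnames(measures),
                 measure_name = measure_name),
            class = "regional_table")
}

#' @export
print.regional_table <- function(x, ...) {
  cat("regional_table [", x$measure_name, "]: ",
      nrow(x$measures), " subjects (", sum(x$subjects$dx == 1), " cases, ",
      sum(x$subjects$dx == 0), " controls) x ",
      length(x$region_ids), " regions\n", sep = "")
  invisible(x)
}

#' Read / write a regional table as TSV
#'
#' Canonical tabular interchange: tab-delimited UTF-8, `.` decimal,
#' missing values spelled `NA`; columns `subject_id`, `age`, `sex`,
#' `dx`, `severity`, then one column per region.
#'
#' @param table A [regional_table].
#' @param path File path.
#' @param measure_name Measure label to attach on read.
#' @return `read_regional_tsv` returns a [regional_table].
#' @export
write_regional_tsv <- function(table, path) {
  stopifnot(inherits(table, "regional_table"))
  out <- cbind(table$subjects[c("subject_id", "age", "sex", "dx", "severity")],
               as.data.frame(table$measures))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_regional_tsv
#' @export
read_regional_tsv <- function(path, measure_name = "measure") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  covar <- c("subject_id", "age", "sex", "dx", "severity")
  reg <- setdiff(names(df), covar)
  regional_table(df[intersect(covar, names(df))],
                 as.matrix(df[reg]), measure_name = measure_name)
}

#' Read / write a template effect-size vector as TSV
#'
#' Template TSV has columns `region` and `d` (per-region case - control
#' standardized effect, deficits negative).
#'
#' @param path File path.
#' @param template Named numeric vector of per-region effect sizes.
#' @return `read_template_tsv` returns a named numeric vector.
#' @export
read_template_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region", "d") %in% names(df)))
    stop("template TSV needs columns 'region' and 'd'")
  stats::setNames(as.numeric(df$d), df$region)
}

#' @rdname read_template_tsv
#' @export
write_template_tsv <- function(template, path) {
  utils::write.table(data.frame(region = names(template), d = as.numeric(template)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
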