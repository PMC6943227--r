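## Domain containers. These are deliberately lightweight: an abundance table is
## a validated numeric matrix (taxa x samples), the manifest and clinical
## tables are validated data frames, and an SNV table is a position-annotation
## data frame plus parallel coverage / allele-frequency matrices.

#' Construct a validated relative-abundance table
#'
#' An abundance table holds species-level (mOTU-style) relative abundances
#' with taxa as rows and samples as columns. Values must be nonnegative and
#' each sample column must sum to at most `1 + 1e-6`; columns are *not*
#' renormalized here (that is the caller's decision), and all-zero taxa are
#' retained.
#'
#' @param values Numeric matrix, taxa x samples, with unique row and column
#'   names.
#' @return The matrix with class `"abundance_table"`.
#' @export
abundance_table <- function(values) {
  values <- as.matrix(values)
  fmt_assert(is.numeric(values), "fmt_validation_error",
             "abundance values must be numeric")
  fmt_assert(!anyNA(values), "fmt_validation_error",
             "abundance values must not contain missing values")
  fmt_assert(all(values >= 0), "fmt_validation_error",
             "abundance values must be nonnegative")
  fmt_assert(!is.null(rownames(values)) && !is.null(colnames(values)),
             "fmt_validation_error", "abundance table needs taxon and sample names")
  fmt_assert(!anyDuplicated(rownames(values)), "fmt_validation_error",
             "duplicate taxon ids in abundance table")
  fmt_assert(!anyDuplicated(colnames(values)), "fmt_validation_error",
             "duplicate sample ids in abundance table")
  sums <- colSums(values)
  if (any(sums > 1 + 1e-6)) {
    bad <- colnames(values)[which.max(sums)]
    fmt_stop("fmt_validation_error",
             "column sum > 1 + 1e-6 (sample '%s' sums to %.6g)", bad, max(sums))
  }
  class(values) <- c("abundance_table", class(values))
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Normalize a time-point label to a day offset
#'
#' The cohort vocabulary (`baseline`, `day3`, `day7`, `day30`, ...) is stored
#' internally as integer day offsets (baseline = 0), which also accommodates
#' autologous-control schedules sampled on other days.
#'
#' @param x Character or numeric vector of time-point labels.
#' @return Integer vector of day offsets.
#' @export
normalize_timepoint <- function(x) {
  if (is.numeric(x)) {
    fmt_assert(all(!is.na(x)) && all(x >= 0) && all(x == floor(x)),
               "fmt_validation_error", "numeric timepoints must be nonnegative integers")
    return(as.integer(x))
  }
  x <- as.character(x)
  out <- rep(NA_integer_, length(x))
  out[x %in% c("baseline", "day0", "0")] <- 0L
  m <- grepl("^day[0-9]+$", x)
  out[m] <- as.integer(sub("^day", "", x[m]))
  num <- grepl("^[0-9]+$", x)
  out[num] <- as.integer(x[num])
  if (anyNA(out)) {
    fmt_stop("fmt_validation_error", "unrecognized timepoint label(s): %s",
             paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Construct a validated cohort manifest
#'
#' The manifest links every sequenced sample to a subject, a role (donor or
#' recipient), a treatment arm, a disease subtype, and a day offset, and
#' resolves each allogenic recipient to its donor.
#'
#' @param df Data frame with columns `sample_id`, `subject_id`, `role`
#'   (`donor`/`recipient`), `donor_id` (NA for donors), `subtype`
#'   (`CD`/`UC`/`healthy`/`metabolic`), `arm` (`allogenic`/`autologous`/`none`),
#'   and `timepoint` or `day`.
#' @return Data frame of class `"cohort_manifest"` with a normalized integer
#'   `day` column.
#' @export
cohort_manifest <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "role", "donor_id", "subtype", "arm")
  miss <- setdiff(need, names(df))
  fmt_assert(length(miss) == 0, "fmt_validation_error",
             "manifest missing column(s): %s", paste(miss, collapse = ", "))
  if (!"day" %in% names(df)) {
    fmt_assert("timepoint" %in% names(df), "fmt_validation_error",
               "manifest needs a 'timepoint' or 'day' column")
    df$day <- normalize_timepoint(df$timepoint)
    df$timepoint <- NULL
  } else {
    df$day <- normalize_timepoint(df$day)
  }
  df$donor_id[!is.na(df$donor_id) & df$donor_id == ""] <- NA_character_
  fmt_assert(!anyDuplicated(df$sample_id), "fmt_validation_error",
             "duplicate sample_id in manifest")
  fmt_assert(all(df$role %in% c("donor", "recipient")), "fmt_validation_error",
             "role must be 'donor' or 'recipient'")
  fmt_assert(all(df$arm %in% c("allogenic", "autologous", "none")),
             "fmt_validation_error", "arm must be allogenic, autologous, or none")
  fmt_assert(all(df$subtype %in% c("CD", "UC", "healthy", "metabolic")),
             "fmt_validation_error", "subtype must be CD, UC, healthy, or metabolic")
  donors <- unique(df$subject_id[df$role == "donor"])
  rec <- df[df$role == "recipient", , drop = FALSE]
  allo <- rec[rec$arm == "allogenic", , drop = FALSE]
  if (nrow(allo)) {
    fmt_assert(!anyNA(allo$donor_id), "fmt_validation_error",
               "allogenic recipient without donor_id")
    dangling <- setdiff(allo$donor_id, donors)
    fmt_assert(length(dangling) == 0, "fmt_validation_error",
               "donor_id without matching donor record: %s",
               paste(dangling, collapse = ", "))
  }
  auto <- rec[rec$arm == "autologous", , drop = FALSE]
  if (nrow(auto)) {
    fmt_assert(all(auto$donor_id == auto$subject_id), "fmt_validation_error",
               "autologous records must have donor_id equal to subject_id")
  }
  fmt_assert(!anyDuplicated(rec[, c("subject_id", "day")]), "fmt_validation_error",
             "duplicate (subject_id, timepoint) among recipients")
  df <- df[, c("sample_id", "subject_id", "role", "donor_id", "subtype", "arm", "day")]
  rownames(df) <- NULL
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Construct a validated per-position SNV table
#'
#' Holds biallelic single-nucleotide-variant observations per species and
#' reference position: an annotation frame plus two parallel matrices of
#' per-sample read coverage and alternative-allele frequency. Positions are
#' 0-based on the species reference; alleles are already resolved (no strand
#' handling). Where coverage is zero the allele frequency is undefined and is
#' coerced to `NA` (with a warning if a value was supplied).
#'
#' @param info Data frame with columns `species_id`, `position` (integer >= 0),
#'   `ref_allele`, `alt_allele`; `(species_id, position)` must be unique.
#' @param coverage Integer matrix, `nrow(info)` x samples, counts >= 0.
#' @param alt_freq Numeric matrix of the same shape, values in `[0, 1]` or NA.
#' @return List of class `"snv_table"` with elements `info`, `coverage`,
#'   `alt_freq`.
#' @export
snv_table <- function(info, coverage, alt_freq) {
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  need <- c("species_id", "position", "ref_allele", "alt_allele")
  fmt_assert(all(need %in% names(info)), "fmt_validation_error",
             "SNV info needs columns %s", paste(need, collapse = ", "))
  fmt_assert(all(info$position >= 0) && all(info$position == floor(info$position)),
             "fmt_validation_error", "positions must be nonnegative integers")
  fmt_assert(!anyDuplicated(info[, c("species_id", "position")]),
             "fmt_validation_error", "duplicated (species_id, position)")
  coverage <- as.matrix(coverage)
  alt_freq <- as.matrix(alt_freq)
  fmt_assert(nrow(coverage) == nrow(info) && nrow(alt_freq) == nrow(info),
             "fmt_validation_error", "coverage/alt_freq rows must match info")
  fmt_assert(identical(dim(coverage), dim(alt_freq)), "fmt_validation_error",
             "coverage and alt_freq must have identical dimensions")
  fmt_assert(!is.null(colnames(coverage)) &&
               identical(colnames(coverage), colnames(alt_freq)),
             "fmt_validation_error", "coverage/alt_freq need matching sample names")
  fmt_assert(!anyNA(coverage) && all(coverage >= 0), "fmt_validation_error",
             "coverage must be nonnegative and complete")
  ok <- is.na(alt_freq) | (alt_freq >= 0 & alt_freq <= 1)
  fmt_assert(all(ok), "fmt_validation_error",
             "alt_frequency outside [0, 1]")
  zero_cov <- coverage == 0
  if (any(zero_cov & !is.na(alt_freq))) {
    warning("alt_frequency given where coverage is 0; coerced to NA",
            call. = FALSE)
    alt_freq[zero_cov] <- NA_real_
  }
  info$position <- as.integer(info$position)
  rownames(info) <- NULL
  structure(list(info = info, coverage = coverage, alt_freq = alt_freq),
            class = "snv_table")
}

#' @export
print.snv_table <- function(x, ...) {
  cat(sprintf("snv_table: %d positions, %d species, %d samples\n",
              nrow(x$info), length(unique(x$info$species_id)),
              ncol(x$coverage)))
  invisible(x)
}

snv_samples <- function(snv) colnames(snv$coverage)

snv_species_rows <- function(snv, species) which(snv$info$species_id == species)

#' Construct a validated long-format clinical table
#'
#' One row per (subject, day, index); values may be missing.
#'
#' @param df Data frame with columns `subject_id`, `timepoint` or `day`,
#'   `index_name`, `value`.
#' @return Data frame of class `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"day" %in% names(df)) {
    fmt_assert("timepoint" %in% names(df), "fmt_validation_error",
               "clinical table needs a 'timepoint' or 'day' column")
    df$day <- normalize_timepoint(df$timepoint)
    df$timepoint <- NULL
  } else {
    df$day <- normalize_timepoint(df$day)
  }
  need <- c("subject_id", "day", "index_name", "value")
  miss <- setdiff(need, names(df))
  fmt_assert(length(miss) == 0, "fmt_validation_error",
             "clinical table missing column(s): %s", paste(miss, collapse = ", "))
  fmt_assert(is.numeric(df$value), "fmt_validation_error",
             "clinical values must be numeric")
  fmt_assert(!anyDuplicated(df[, c("subject_id", "day", "index_name")]),
             "fmt_validation_error", "duplicate (subject_id, timepoint, index_name)")
  df <- df[, need]
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}
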