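## TSV ingestion and emission. Canonical dialect: tab separator, '.' decimal,
## UTF-8, one header row. Missing values are written as the empty string and
## accepted as "", "NA", or "NaN" on read wherever a missing value is legal
## (clinical values, zero-coverage allele frequencies); abundance cells must
## always parse as numbers.

read_tsv_raw <- function(path, na = NULL) {
  fmt_assert(file.exists(path), "fmt_io_error", "file not found: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = na %||% character(0), quote = "",
                    comment.char = "")
}

write_tsv_raw <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.double(col)) {
      ## shortest representation that survives a read/parse round trip
      chr <- as.character(col)
      lossy <- !is.na(col) & suppressWarnings(as.numeric(chr)) != col
      chr[lossy] <- sprintf("%.17g", col[lossy])
      col <- chr
    } else {
      col <- as.character(col)
    }
    col[is.na(col)] <- ""
    df[[j]] <- col
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

parse_numeric_cells <- function(chr, row_ids, col_ids, what, na_ok = FALSE) {
  num <- suppressWarnings(as.numeric(chr))
  if (na_ok) {
    bad <- which(is.na(num) & !is.na(chr) & !(chr %in% c("", "NA", "NaN")))
    num[is.na(chr) | chr %in% c("", "NA", "NaN")] <- NA_real_
  } else {
    bad <- which(is.na(num))
  }
  if (length(bad)) {
    i <- bad[1]
    r <- ((i - 1) %% length(row_ids)) + 1
    c <- ((i - 1) %/% length(row_ids)) + 1
    fmt_stop("fmt_parse_error",
             "non-numeric %s value '%s' at row '%s', column '%s'",
             what, chr[i] %||% "", row_ids[r], col_ids[c])
  }
  num
}

#' Read a relative-abundance table from TSV
#'
#' The file has one header row; the first column holds row identifiers. The
#' `taxa_orientation` flag says whether taxa are the rows or the columns of
#' the file; internally taxa are always rows. Columns are not renormalized and
#' zero-only taxa are kept.
#'
#' @param path Path to a TSV file.
#' @param taxa_orientation `"rows"` (default) or `"columns"`.
#' @return An [abundance_table()].
#' @export
read_abundance_table <- function(path, taxa_orientation = c("rows", "columns")) {
  taxa_orientation <- match.arg(taxa_orientation)
  raw <- read_tsv_raw(path)
  fmt_assert(ncol(raw) >= 2, "fmt_parse_error",
             "abundance TSV needs an id column plus at least one data column")
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- parse_numeric_cells(as.vector(body), ids, colnames(raw)[-1],
                              "abundance")
  m <- matrix(vals, nrow = nrow(raw), dimnames = list(ids, colnames(raw)[-1]))
  if (taxa_orientation == "columns") m <- t(m)
  abundance_table(m)
}

#' Write a relative-abundance table to TSV
#'
#' Taxa are written as rows. Numeric values are printed with R's shortest
#' round-trippable representation, so `read_abundance_table()` reproduces the
#' table exactly.
#'
#' @param x An [abundance_table()] (or taxa x samples numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}

#' Read a cohort manifest from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `role`, `donor_id`,
#'   `subtype`, `arm`, `timepoint` (or `day`).
#' @return A [cohort_manifest()].
#' @export
read_manifest <- function(path) {
  raw <- read_tsv_raw(path, na = c("", "NA", "NaN"))
  cohort_manifest(raw)
}

#' Write a cohort manifest to TSV
#' @param x A [cohort_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' Read a long-format clinical table from TSV
#'
#' @param path TSV with columns `subject_id`, `timepoint` (or `day`),
#'   `index_name`, `value`. Values `""`, `"NA"`, `"NaN"` are read as missing.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  raw <- read_tsv_raw(path, na = c("", "NA", "NaN"))
  raw$value <- parse_numeric_cells(raw$value, seq_len(nrow(raw)), "value",
                                   "clinical", na_ok = TRUE)
  clinical_table(raw)
}

#' Write a clinical table to TSV
#' @param x A [clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' Read an SNV table from TSV
#'
#' Expected header: `species_id`, `position`, `ref_allele`, `alt_allele`, then
#' one `<sample>.cov` / `<sample>.freq` column pair per sample (a tabular
#' reduction of metaSNV-style per-position output). Rows with zero coverage
#' keep the allele frequency as missing.
#'
#' @param path Path to a TSV file.
#' @return An [snv_table()].
#' @export
read_snv_table <- function(path) {
  raw <- read_tsv_raw(path, na = c("", "NA", "NaN"))
  fixed <- c("species_id", "position", "ref_allele", "alt_allele")
  fmt_assert(identical(names(raw)[seq_along(fixed)], fixed), "fmt_parse_error",
             "SNV TSV must start with columns %s", paste(fixed, collapse = ", "))
  rest <- names(raw)[-seq_along(fixed)]
  cov_cols <- grep("\\.cov$", rest, value = TRUE)
  freq_cols <- grep("\\.freq$", rest, value = TRUE)
  samples <- sub("\\.cov$", "", cov_cols)
  fmt_assert(length(rest) == length(cov_cols) + length(freq_cols) &&
               setequal(paste0(samples, ".freq"), freq_cols),
             "fmt_parse_error",
             "per-sample columns must come in <sample>.cov / <sample>.freq pairs")
  info <- raw[, fixed]
  info$position <- parse_numeric_cells(info$position, seq_len(nrow(raw)),
                                       "position", "position")
  cov <- sapply(paste0(samples, ".cov"), function(cn)
    parse_numeric_cells(raw[[cn]], seq_len(nrow(raw)), cn, "coverage"))
  freq <- sapply(paste0(samples, ".freq"), function(cn)
    parse_numeric_cells(raw[[cn]], seq_len(nrow(raw)), cn, "frequency",
                        na_ok = TRUE))
  cov <- matrix(cov, nrow = nrow(raw), dimnames = list(NULL, samples))
  freq <- matrix(freq, nrow = nrow(raw), dimnames = list(NULL, samples))
  snv_table(info, cov, freq)
}

#' Write an SNV table to TSV
#' @param x An [snv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_table <- function(x, path) {
  samples <- snv_samples(x)
  df <- x$info
  for (s in samples) {
    df[[paste0(s, ".cov")]] <- x$coverage[, s]
    df[[paste0(s, ".freq")]] <- x$alt_freq[, s]
  }
  write_tsv_raw(df, path)
  invisible(path)
}

#' Export a correlation network to GraphML or SIF
#'
#' Accepts either the edge data frame produced by [correlate_cohort()] /
#' [bh_adjust()]-annotated pairs (columns `taxon_id`, `index_name`, `rho`,
#' `q`, `sign`) or an igraph object from [build_network()]. An empty edge set
#' yields a valid empty file.
#'
#' @param x Edge data frame or igraph graph.
#' @param path Output path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("graphml", "sif")) {
  if (!is.character(format) || length(format) != 1 ||
      !format %in% c("graphml", "sif")) {
    fmt_stop("fmt_usage_error", "unknown network format: %s",
             paste(format, collapse = "/"))
  }
  g <- if (inherits(x, "igraph")) x else build_network(x, q_max = Inf)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    lines <- if (nrow(el)) {
      rel <- ifelse(el$sign == "positive", "pos", "neg")
      sprintf("%s\t%s\t%s", el$from, rel, el$to)
    } else character(0)
    writeLines(lines, path)
  }
  invisible(path)
}
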