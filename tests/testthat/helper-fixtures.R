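## Small in-code fixtures shared across test files.

## One allogenic donor-recipient pair with baseline + post samples.
pair_manifest <- function(post_days = 3, subtype = "CD") {
  rows <- data.frame(
    sample_id = c("D1_d0", "R1_d0", sprintf("R1_d%d", post_days)),
    subject_id = c("D1", "R1", rep("R1", length(post_days))),
    role = c("donor", "recipient", rep("recipient", length(post_days))),
    donor_id = c(NA, "D1", rep("D1", length(post_days))),
    subtype = c("healthy", subtype, rep(subtype, length(post_days))),
    arm = c("none", "allogenic", rep("allogenic", length(post_days))),
    day = c(0L, 0L, as.integer(post_days)),
    stringsAsFactors = FALSE)
  cohort_manifest(rows)
}

## SNV table for one species built from explicit per-sample frequency
## vectors; coverage constant unless given.
make_snv <- function(freqs, coverage = 50, species = "spX") {
  samples <- names(freqs)
  P <- length(freqs[[1]])
  cov <- matrix(coverage, nrow = P, ncol = length(samples),
                dimnames = list(NULL, samples))
  fr <- do.call(cbind, freqs)
  colnames(fr) <- samples
  info <- data.frame(species_id = species, position = seq_len(P) - 1L,
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  snv_table(info, cov, fr)
}

## Random sparse relative-abundance vector, named.
rand_abund <- function(n, zero_frac = 0.4) {
  v <- stats::runif(n) * (stats::runif(n) > zero_frac)
  if (sum(v) == 0) v[1] <- 1
  v <- v / sum(v)
  names(v) <- sprintf("t%03d", seq_len(n))
  v
}

## delta_table wrapper around one (x, y) pair, for driving the Spearman path
## through the public interface.
delta_pair <- function(x, y, taxon = "tA", index = "ixB") {
  structure(list(
    taxa = matrix(x, ncol = 1, dimnames = list(names(x) %||%
                                                 seq_along(x), taxon)),
    clinical = matrix(y, ncol = 1, dimnames = list(names(y) %||%
                                                     seq_along(y), index)),
    recipients = seq_along(x)), class = "delta_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Synthetic feature set: sparse donor / pre-FMT abundance features plus
## pure-noise columns, with presence targets generated by the "present if
## present in donor OR in the pre-FMT recipient" rule.
rule_data <- function(n = 200, n_taxa = 5, n_noise = 10, seed = 4) {
  withr::with_seed(seed, {
    don <- matrix(stats::runif(n * n_taxa) * (stats::runif(n * n_taxa) < 0.4), n)
    pre <- matrix(stats::runif(n * n_taxa) * (stats::runif(n * n_taxa) < 0.4), n)
    noise <- matrix(stats::rnorm(n * n_noise), n)
    x <- as.data.frame(cbind(don, pre, noise))
    names(x) <- c(paste0("donor|t", seq_len(n_taxa)),
                  paste0("pre|t", seq_len(n_taxa)),
                  paste0("noise", seq_len(n_noise)))
    list(x = x, don = don, pre = pre)
  })
}

target_of <- function(rd, t) {
  factor(ifelse(rd$don[, t] > 0 | rd$pre[, t] > 0, "present", "absent"),
         levels = c("absent", "present"))
}
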