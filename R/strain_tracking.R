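## Strain-level displacement tracking. At baseline, each donor-recipient pair
## and species defines a determinant set: positions where the donor carries
## the alternative allele and the recipient does not (donor-specific), or the
## reverse (recipient-specific). Post-FMT samples are then scored by the
## fraction of each set still called present, and the joint pattern is
## classified as donor takeover, recipient persistence, or coexistence.

#' Presence call thresholds
#'
#' Bundles the three thresholds that turn (coverage, allele frequency) into a
#' presence / absence / unresolved call. Defaults: coverage of at least 5
#' reads to call at all; frequency of at least 0.10 to call an allele present
#' (at typical 20x coverage this demands two or more supporting reads, above
#' the expected reach of per-read sequencing error); frequency of at most
#' 0.05 to call it absent (a single stray read at 20x, frequency 1/20, still
#' counts as absent rather than inflating the unresolved class). Frequencies
#' between `absent_max` and `present_min` are unresolved.
#'
#' @param cov_min Minimum coverage for any call.
#' @param present_min Minimum frequency to call the allele present.
#' @param absent_max Maximum frequency to call the allele absent.
#' @return List of class `"presence_thresholds"`.
#' @export
presence_thresholds <- function(cov_min = 5, present_min = 0.10,
                                absent_max = 0.05) {
  fmt_assert(cov_min >= 0 && present_min > absent_max &&
               is_fraction(c(present_min, absent_max)),
             "fmt_validation_error",
             "need 0 <= absent_max < present_min <= 1 and cov_min >= 0")
  structure(list(cov_min = cov_min, present_min = present_min,
                 absent_max = absent_max), class = "presence_thresholds")
}

#' Call allele presence from coverage and frequency
#'
#' Vectorized. `present` if coverage >= `cov_min` and frequency >=
#' `present_min`; `absent` if coverage >= `cov_min` and frequency <=
#' `absent_max`; otherwise `unresolved` (including missing frequency at zero
#' coverage).
#'
#' @param coverage Nonnegative read counts.
#' @param alt_frequency Frequencies in `[0, 1]`, or NA where coverage is 0.
#' @param thresholds A [presence_thresholds()].
#' @return Character vector in `{present, absent, unresolved}`.
#' @export
call_presence <- function(coverage, alt_frequency,
                          thresholds = presence_thresholds()) {
  out <- rep("unresolved", length(coverage))
  ok <- coverage >= thresholds$cov_min & !is.na(alt_frequency)
  out[ok & alt_frequency >= thresholds$present_min] <- "present"
  out[ok & alt_frequency <= thresholds$absent_max] <- "absent"
  out
}

#' Build the determinant position set for one pair and species
#'
#' Donor-specific positions are present in the donor baseline sample and
#' absent in the recipient baseline; recipient-specific positions are the
#' reverse. Positions unresolved in either sample are excluded. Species whose
#' determinant set (union of both sides) has fewer than `min_positions`
#' members are excluded with a logged reason and `NULL` is returned — this
#' operationalizes the requirement that tracked species be consistently and
#' sufficiently detected in the pair, and makes identical donor/recipient
#' baselines (the autologous control) yield no determinant set at all.
#'
#' @param snv An [snv_table()].
#' @param donor_sample,recipient_sample Sample ids of the two baselines.
#' @param species Species id to assess.
#' @param thresholds A [presence_thresholds()].
#' @param min_positions Inclusion floor for the determinant set size.
#' @return List of class `"determinant_set"` (`species_id`, `donor_sample`,
#'   `recipient_sample`, `donor_specific`, `recipient_specific`,
#'   `n_total_assessed`), or `NULL` if the species is excluded.
#' @export
build_determinant_set <- function(snv, donor_sample, recipient_sample, species,
                                  thresholds = presence_thresholds(),
                                  min_positions = 20) {
  rows <- snv_species_rows(snv, species)
  if (length(rows) == 0) {
    fmt_stop("fmt_notfound_error", "species '%s' absent from SNV table", species)
  }
  fmt_assert(all(c(donor_sample, recipient_sample) %in% snv_samples(snv)),
             "fmt_validation_error", "sample missing from SNV table")
  dcall <- call_presence(snv$coverage[rows, donor_sample],
                         snv$alt_freq[rows, donor_sample], thresholds)
  rcall <- call_presence(snv$coverage[rows, recipient_sample],
                         snv$alt_freq[rows, recipient_sample], thresholds)
  resolved <- dcall != "unresolved" & rcall != "unresolved"
  pos <- snv$info$position[rows]
  donor_specific <- pos[resolved & dcall == "present" & rcall == "absent"]
  recipient_specific <- pos[resolved & rcall == "present" & dcall == "absent"]
  n_det <- length(donor_specific) + length(recipient_specific)
  if (n_det < min_positions) {
    message(sprintf(
      "species '%s' excluded: %d informative position(s) < floor of %d",
      species, n_det, min_positions))
    return(NULL)
  }
  structure(list(species_id = species,
                 donor_sample = donor_sample,
                 recipient_sample = recipient_sample,
                 donor_specific = donor_specific,
                 recipient_specific = recipient_specific,
                 n_total_assessed = sum(resolved)),
            class = "determinant_set")
}

#' Retention of determinant alleles in a post-FMT sample
#'
#' For each side of the determinant set, the retention fraction is the number
#' of positions called present in the post-FMT sample divided by the number
#' of positions not unresolved there; unresolved positions drop out of both
#' numerator and denominator. If every position on a side is unresolved that
#' retention is `NA` with a reason attribute.
#'
#' @param dset A [build_determinant_set()] result.
#' @param snv An [snv_table()].
#' @param post_sample Post-FMT sample id.
#' @param thresholds A [presence_thresholds()].
#' @return List `donor_retention`, `recipient_retention`, `n_evaluable`
#'   (total evaluable positions across both sides).
#' @export
retention_fraction <- function(dset, snv, post_sample,
                               thresholds = presence_thresholds()) {
  fmt_assert(inherits(dset, "determinant_set"), "fmt_validation_error",
             "dset must be a determinant_set")
  fmt_assert(post_sample %in% snv_samples(snv), "fmt_validation_error",
             "post sample '%s' missing from SNV table", post_sample)
  rows <- snv_species_rows(snv, dset$species_id)
  pos <- snv$info$position[rows]
  calls <- call_presence(snv$coverage[rows, post_sample],
                         snv$alt_freq[rows, post_sample], thresholds)
  side <- function(positions) {
    idx <- match(positions, pos)
    cl <- calls[idx]
    ev <- cl != "unresolved"
    if (!any(ev)) return(list(ret = NA_real_, n = 0L))
    list(ret = sum(cl[ev] == "present") / sum(ev), n = sum(ev))
  }
  d <- side(dset$donor_specific)
  r <- side(dset$recipient_specific)
  out <- list(donor_retention = d$ret, recipient_retention = r$ret,
              n_evaluable = d$n + r$n)
  if (out$n_evaluable == 0) {
    attr(out, "reason") <- "all determinant positions unresolved in post sample"
  }
  out
}

#' Classify the post-FMT strain state
#'
#' `coexistence` if both retentions are at least `lo`; `donor_takeover` if the
#' donor retention is at least `hi` while the recipient side fell below `lo`;
#' `recipient_persistence` in the mirrored case; otherwise `indeterminate`.
#' Missing retention gives `indeterminate`.
#'
#' @param donor_retention,recipient_retention Retention fractions in `[0, 1]`.
#' @param hi,lo Classification thresholds (defaults 0.8 and 0.2).
#' @return One of `donor_takeover`, `recipient_persistence`, `coexistence`,
#'   `indeterminate`.
#' @export
classify_state <- function(donor_retention, recipient_retention,
                           hi = 0.8, lo = 0.2) {
  if (is.na(donor_retention) || is.na(recipient_retention)) {
    return("indeterminate")
  }
  if (donor_retention >= lo && recipient_retention >= lo) return("coexistence")
  if (donor_retention >= hi && recipient_retention < lo) return("donor_takeover")
  if (recipient_retention >= hi && donor_retention < lo) {
    return("recipient_persistence")
  }
  "indeterminate"
}

#' Rate of newly arising SNVs relative to baseline
#'
#' Fraction of positions that were called absent at baseline and present in
#' the post-FMT sample, over all positions evaluable (not unresolved) in both
#' samples; reported per species and pooled.
#'
#' @param snv An [snv_table()].
#' @param baseline_sample,post_sample Sample ids.
#' @param thresholds A [presence_thresholds()].
#' @return List with `per_species` data frame (`species_id`, `n_evaluable`,
#'   `n_new`, `rate`) and `pooled` rate (`NA` if nothing is evaluable).
#' @export
new_snv_rate <- function(snv, baseline_sample, post_sample,
                         thresholds = presence_thresholds()) {
  fmt_assert(all(c(baseline_sample, post_sample) %in% snv_samples(snv)),
             "fmt_validation_error", "sample missing from SNV table")
  base <- call_presence(snv$coverage[, baseline_sample],
                        snv$alt_freq[, baseline_sample], thresholds)
  post <- call_presence(snv$coverage[, post_sample],
                        snv$alt_freq[, post_sample], thresholds)
  ev <- base != "unresolved" & post != "unresolved"
  new <- ev & base == "absent" & post == "present"
  per <- do.call(rbind, lapply(split(seq_along(ev), snv$info$species_id),
    function(idx) {
      n_ev <- sum(ev[idx])
      data.frame(n_evaluable = n_ev, n_new = sum(new[idx]),
                 rate = if (n_ev > 0) sum(new[idx]) / n_ev else NA_real_)
    }))
  per <- data.frame(species_id = rownames(per), per, stringsAsFactors = FALSE)
  rownames(per) <- NULL
  pooled <- if (sum(ev) > 0) sum(new) / sum(ev) else NA_real_
  list(per_species = per, pooled = pooled)
}

#' Track strain retention across a cohort
#'
#' For every allogenic donor-recipient pair and every species in the SNV
#' table, builds the determinant set from the two baseline samples and scores
#' each post-FMT sample of that recipient. Species below the determinant
#' floor are skipped (see [build_determinant_set()]).
#'
#' @param snv An [snv_table()].
#' @param manifest A [cohort_manifest()].
#' @param thresholds A [presence_thresholds()].
#' @param min_positions Determinant-set inclusion floor.
#' @param hi,lo Classification thresholds for [classify_state()].
#' @return Data frame of class `"retention_series"`: one row per
#'   (pair, species, post day).
#' @export
track_strains <- function(snv, manifest, thresholds = presence_thresholds(),
                          min_positions = 20, hi = 0.8, lo = 0.2) {
  rec <- manifest[manifest$role == "recipient" & manifest$arm == "allogenic", ,
                  drop = FALSE]
  species <- unique(snv$info$species_id)
  samples <- snv_samples(snv)
  rows <- list()
  for (subj in unique(rec$subject_id)) {
    sub <- rec[rec$subject_id == subj, , drop = FALSE]
    base <- sub$sample_id[sub$day == 0]
    donor_sample <- manifest$sample_id[manifest$role == "donor" &
                                         manifest$subject_id == sub$donor_id[1]]
    posts <- sub[sub$day > 0, , drop = FALSE]
    if (length(base) != 1 || length(donor_sample) != 1 || nrow(posts) == 0) next
    if (!all(c(base, donor_sample) %in% samples)) next
    for (sp in species) {
      dset <- build_determinant_set(snv, donor_sample, base, sp,
                                    thresholds, min_positions)
      if (is.null(dset)) next
      for (i in seq_len(nrow(posts))) {
        ps <- posts$sample_id[i]
        if (!ps %in% samples) next
        ret <- retention_fraction(dset, snv, ps, thresholds)
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = subj, donor_id = sub$donor_id[1], species_id = sp,
          subtype = posts$subtype[i], day = posts$day[i],
          donor_retention = ret$donor_retention,
          recipient_retention = ret$recipient_retention,
          n_evaluable = ret$n_evaluable,
          classification = classify_state(ret$donor_retention,
                                          ret$recipient_retention, hi, lo),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_id = character(0), donor_id = character(0),
               species_id = character(0), subtype = character(0),
               day = integer(0), donor_retention = numeric(0),
               recipient_retention = numeric(0), n_evaluable = integer(0),
               classification = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("retention_series", "data.frame")
  out
}

#' Cohort-level retention summary
#'
#' Two-level averaging: each recipient's species retentions are averaged
#' first, then recipients are averaged within each (subtype, day) cell, so
#' recipients with many tracked species do not dominate. Mean and sample SD
#' across recipients; cells with one recipient report `sd = NA`. Empty cells
#' are omitted.
#'
#' @param series A [track_strains()] result.
#' @param value `"donor_retention"` or `"recipient_retention"`.
#' @return Data frame `subtype`, `day`, `n_recipients`, `mean`, `sd`.
#' @export
cohort_retention_summary <- function(series,
                                     value = c("donor_retention",
                                               "recipient_retention")) {
  value <- match.arg(value)
  s <- series[!is.na(series[[value]]), , drop = FALSE]
  if (nrow(s) == 0) {
    return(data.frame(subtype = character(0), day = integer(0),
                      n_recipients = integer(0), mean = numeric(0),
                      sd = numeric(0)))
  }
  per_rec <- stats::aggregate(s[[value]],
                              by = list(subtype = s$subtype, day = s$day,
                                        pair_id = s$pair_id), FUN = mean)
  out <- do.call(rbind, lapply(
    split(per_rec, list(per_rec$subtype, per_rec$day), drop = TRUE),
    function(g) data.frame(
      subtype = g$subtype[1], day = g$day[1], n_recipients = nrow(g),
      mean = mean(g$x), sd = if (nrow(g) > 1) stats::sd(g$x) else NA_real_,
      stringsAsFactors = FALSE)))
  out <- out[order(out$subtype, out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
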