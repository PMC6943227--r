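## Source partitioning of post-FMT communities. Each taxon detected in a
## post-FMT sample is classified against the paired donor and pre-FMT
## baseline profiles: donor_specific (detected in donor, not at baseline),
## recipient_specific (the reverse), common (both), or new (neither). One
## detection gate applies uniformly to all three profiles.

PARTITION_CATEGORIES <- c("donor_specific", "recipient_specific", "common", "new")

#' Detect taxa above the relative-abundance gate
#'
#' A taxon counts as detected when its relative abundance is at least
#' `threshold` (the boundary is inclusive).
#'
#' @param profile Named abundance vector.
#' @param threshold Detection gate in `(0, 1)`, default `0.001`.
#' @return Character vector of detected taxon names (possibly empty).
#' @export
detect_taxa <- function(profile, threshold = 0.001) {
  fmt_assert(is.numeric(threshold) && length(threshold) == 1 &&
               threshold > 0 && threshold < 1,
             "fmt_validation_error", "threshold must lie in (0, 1)")
  fmt_assert(!is.null(names(profile)), "fmt_validation_error",
             "profile must be a named vector")
  names(profile)[profile >= threshold]
}

#' Partition one post-FMT sample by source
#'
#' @param donor,pre,post Abundance vectors on the same taxon index (donor,
#'   recipient baseline, recipient post-FMT).
#' @param threshold Detection gate applied to all three vectors.
#' @param sample_id Optional label carried into the result.
#' @return List of class `"species_partition"`: `categories` (named character
#'   vector over detected post-FMT taxa), `count_fractions` and
#'   `abundance_fractions` (each a 4-vector over
#'   donor_specific / recipient_specific / common / new, summing to 1;
#'   abundance fractions are renormalized to the detected mass),
#'   `detection_threshold`, `n_detected`.
#' @export
partition_sample <- function(donor, pre, post, threshold = 0.001,
                             sample_id = NULL) {
  fmt_assert(length(donor) == length(pre) && length(pre) == length(post),
             "fmt_validation_error", "vectors must share one taxon index")
  fmt_assert(identical(names(donor), names(post)) &&
               identical(names(pre), names(post)),
             "fmt_validation_error", "vectors must share taxon names")
  d_set <- detect_taxa(donor, threshold)
  p_set <- detect_taxa(pre, threshold)
  post_set <- detect_taxa(post, threshold)
  if (length(post_set) == 0) {
    fmt_stop("fmt_input_error",
             "no taxon detected in the post-FMT sample at threshold %g", threshold)
  }
  in_donor <- post_set %in% d_set
  in_pre <- post_set %in% p_set
  cat_of <- ifelse(in_donor & in_pre, "common",
            ifelse(in_donor, "donor_specific",
            ifelse(in_pre, "recipient_specific", "new")))
  names(cat_of) <- post_set
  counts <- vapply(PARTITION_CATEGORIES, function(k) sum(cat_of == k), 1L)
  mass <- vapply(PARTITION_CATEGORIES, function(k)
    sum(post[post_set[cat_of == k]]), 1.0)
  structure(list(
    sample_id = sample_id,
    categories = cat_of,
    count_fractions = counts / sum(counts),
    abundance_fractions = mass / sum(mass),
    detection_threshold = threshold,
    n_detected = length(post_set)
  ), class = "species_partition")
}

#' Partition every post-FMT sample of a cohort
#'
#' Runs [partition_sample()] for each recipient sample with `day > 0`,
#' against that recipient's baseline and (for allogenic arms) donor profile.
#' Autologous recipients are compared against their own baseline as "donor".
#'
#' @param abundance An [abundance_table()].
#' @param manifest A [cohort_manifest()].
#' @param threshold Detection gate.
#' @return List with `partitions` (named list of `species_partition`) and
#'   `table`: one row per post-FMT sample with both fraction kinds.
#' @export
partition_cohort <- function(abundance, manifest, threshold = 0.001) {
  rec <- manifest[manifest$role == "recipient", , drop = FALSE]
  rows <- list(); parts <- list()
  for (subj in unique(rec$subject_id)) {
    sub <- rec[rec$subject_id == subj, , drop = FALSE]
    base <- sub$sample_id[sub$day == 0]
    posts <- sub[sub$day > 0, , drop = FALSE]
    if (length(base) != 1 || nrow(posts) == 0) next
    donor_subject <- sub$donor_id[1]
    donor_sample <- manifest$sample_id[manifest$role == "donor" &
                                         manifest$subject_id == donor_subject]
    if (sub$arm[1] == "autologous") donor_sample <- base
    if (length(donor_sample) != 1) next
    have <- colnames(abundance)
    if (!base %in% have || !donor_sample %in% have) next
    for (i in seq_len(nrow(posts))) {
      ps <- posts$sample_id[i]
      if (!ps %in% have) next
      part <- partition_sample(abundance[, donor_sample], abundance[, base],
                               abundance[, ps], threshold, sample_id = ps)
      parts[[ps]] <- part
      rows[[ps]] <- data.frame(
        sample_id = ps, subject_id = subj, donor_id = donor_subject,
        subtype = posts$subtype[i], arm = posts$arm[i], day = posts$day[i],
        n_detected = part$n_detected,
        count_donor_specific = part$count_fractions[["donor_specific"]],
        count_recipient_specific = part$count_fractions[["recipient_specific"]],
        count_common = part$count_fractions[["common"]],
        count_new = part$count_fractions[["new"]],
        ab_donor_specific = part$abundance_fractions[["donor_specific"]],
        ab_recipient_specific = part$abundance_fractions[["recipient_specific"]],
        ab_common = part$abundance_fractions[["common"]],
        ab_new = part$abundance_fractions[["new"]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(partitions = parts, table = tab)
}

#' Summarize donor gain per disease subtype
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' donor-specific fraction per subtype and overall. Count-based and
#' abundance-weighted fractions are both first-class; choose with `kind`.
#' Groups with a single observation report `sd = 0` and are flagged.
#'
#' @param partition_table The `table` element of [partition_cohort()].
#' @param kind `"count"` (fraction of detected taxa) or `"abundance"`
#'   (fraction of detected mass).
#' @return Data frame with columns `group`, `n`, `mean`, `sd`,
#'   `single_observation`.
#' @export
donor_gain_summary <- function(partition_table, kind = c("count", "abundance")) {
  kind <- match.arg(kind)
  fmt_assert(is.data.frame(partition_table) && nrow(partition_table) >= 1,
             "fmt_validation_error", "need at least one partition")
  col <- if (kind == "count") "count_donor_specific" else "ab_donor_specific"
  groups <- split(partition_table[[col]], partition_table$subtype)
  groups <- c(groups, list(overall = partition_table[[col]]))
  empty <- vapply(groups, length, 1L) == 0
  if (any(empty)) {
    warning("empty subtype group(s) omitted: ",
            paste(names(groups)[empty], collapse = ", "), call. = FALSE)
    groups <- groups[!empty]
  }
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 1L),
    mean = vapply(groups, mean, 1.0),
    sd = vapply(groups, function(v) if (length(v) > 1) stats::sd(v) else 0, 1.0),
    single_observation = vapply(groups, length, 1L) == 1,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
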