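## Synthetic donor/recipient cohorts with known ground truth. The generator
## encodes the study conditions the pipeline is validated under: a shared
## taxon pool with log-normal(0, 1) magnitudes, per-subject sparsification,
## post-FMT profiles as an explicit donor/recipient/environment mixture, and
## biallelic determinant SNVs with binomial read sampling. It produces the
## same containers the readers produce, so every downstream stage can be
## exercised without sequencing data.

#' Specification for a simulated species-level cohort
#'
#' @param n_pairs Number of donor-recipient pairs (default 15, split 11 CD /
#'   4 UC as in a typical IBD FMT cohort of this size).
#' @param n_taxa Taxon pool size (>= 4).
#' @param d Per-pair fraction of post-FMT mass drawn from the donor
#'   (engraftment), scalar or length `n_pairs`.
#' @param g Fraction of post-FMT mass from environmental taxa seen in neither
#'   donor nor recipient; `d + g <= 1`.
#' @param sparsity Expected fraction of pool taxa absent from any one subject.
#' @param timepoints Post-FMT day offsets sampled per recipient.
#' @param subtypes Optional character vector of disease subtypes per pair.
#' @param n_donors Number of distinct donors, shared round-robin (default
#'   scales as 6 donors per 15 pairs).
#' @param seed RNG seed (required; the spec + seed fully determine the cohort).
#' @return List of class `"cohort_sim_spec"`.
#' @export
cohort_sim_spec <- function(n_pairs = 15, n_taxa = 200, d = 0.3, g = 0.05,
                            sparsity = 0.5, timepoints = c(3, 7),
                            subtypes = NULL, n_donors = NULL, seed = 1) {
  fmt_assert(n_taxa >= 4, "fmt_spec_error", "n_taxa must be at least 4")
  fmt_assert(n_pairs >= 1, "fmt_spec_error", "n_pairs must be at least 1")
  d <- rep_len(d, n_pairs); g <- rep_len(g, n_pairs)
  fmt_assert(is_fraction(d) && is_fraction(g) && is_fraction(sparsity),
             "fmt_spec_error", "d, g, sparsity must lie in [0, 1]")
  fmt_assert(all(d + g <= 1), "fmt_spec_error", "d + g must not exceed 1")
  fmt_assert(all(timepoints > 0), "fmt_spec_error",
             "post-FMT timepoints must be positive day offsets")
  if (is.null(subtypes)) {
    n_cd <- round(n_pairs * 11 / 15)
    subtypes <- c(rep("CD", n_cd), rep("UC", n_pairs - n_cd))
  }
  fmt_assert(length(subtypes) == n_pairs && all(subtypes %in% c("CD", "UC")),
             "fmt_spec_error", "subtypes must be CD/UC, one per pair")
  n_donors <- n_donors %||% max(1L, ceiling(n_pairs * 6 / 15))
  structure(list(n_pairs = n_pairs, n_taxa = n_taxa, d = d, g = g,
                 sparsity = sparsity, timepoints = as.integer(timepoints),
                 subtypes = subtypes, n_donors = as.integer(n_donors),
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

## One sparse compositional profile over the pool: lognormal magnitudes,
## Bernoulli inclusion, renormalized. At least one taxon is always included.
rand_profile <- function(n_taxa, include_prob) {
  incl <- stats::rbinom(n_taxa, 1, include_prob)
  if (sum(incl) == 0) incl[sample.int(n_taxa, 1)] <- 1
  mag <- exp(stats::rnorm(n_taxa)) * incl
  mag / sum(mag)
}

#' Simulate a species-level FMT cohort with known engraftment
#'
#' Donor and recipient baseline profiles are drawn independently on a shared
#' taxon pool; the post-FMT profile at every timepoint is the renormalized
#' mixture `d * donor + (1 - d - g) * recipient + g * environment`, where the
#' environmental component lives on taxa detected in neither the donor nor
#' the recipient baseline. The returned truth record carries, per pair, the
#' planted `d` and `g` and the realized post-FMT mass on donor-exclusive taxa
#' (the generator's own bookkeeping, used by recovery tests).
#'
#' @param spec A [cohort_sim_spec()].
#' @return List of class `"species_cohort_sim"`: `abundance`
#'   ([abundance_table()]), `manifest` ([cohort_manifest()]), `truth` (data
#'   frame, one row per pair).
#' @export
simulate_species_cohort <- function(spec) {
  fmt_assert(inherits(spec, "cohort_sim_spec"), "fmt_spec_error",
             "spec must be a cohort_sim_spec")
  withr::with_seed(spec$seed, {
    taxa <- sprintf("taxon_%04d", seq_len(spec$n_taxa))
    include_prob <- 1 - spec$sparsity
    donor_ids <- sprintf("D%d", seq_len(spec$n_donors))
    donor_of_pair <- rep_len(donor_ids, spec$n_pairs)
    donor_prof <- sapply(donor_ids, function(i) rand_profile(spec$n_taxa,
                                                             include_prob))
    subj_num <- stats::ave(seq_len(spec$n_pairs), spec$subtypes,
                           FUN = seq_along)
    recipients <- sprintf("%s-%d", spec$subtypes, subj_num)
    cols <- list(); manifest_rows <- list(); truth_rows <- list()
    for (j in seq_along(donor_ids)) {
      sid <- paste0(donor_ids[j], "_d0")
      cols[[sid]] <- donor_prof[, j]
      manifest_rows[[sid]] <- data.frame(
        sample_id = sid, subject_id = donor_ids[j], role = "donor",
        donor_id = NA_character_, subtype = "healthy", arm = "none", day = 0L)
    }
    for (p in seq_len(spec$n_pairs)) {
      rid <- recipients[p]
      donor <- donor_prof[, donor_of_pair[p]]
      recip <- rand_profile(spec$n_taxa, include_prob)
      d <- spec$d[p]; g <- spec$g[p]
      env <- rep(0, spec$n_taxa)
      if (g > 0) {
        free <- which(donor == 0 & recip == 0)
        fmt_assert(length(free) > 0, "fmt_spec_error",
                   "no environmental taxa available for pair %s", rid)
        incl <- free[stats::rbinom(length(free), 1, 0.5) == 1]
        if (length(incl) == 0) incl <- free[sample.int(length(free), 1)]
        env[incl] <- exp(stats::rnorm(length(incl)))
        env <- env / sum(env)
      }
      post <- d * donor + (1 - d - g) * recip + g * env
      post <- post / sum(post)
      base_id <- paste0(rid, "_d0")
      cols[[base_id]] <- recip
      manifest_rows[[base_id]] <- data.frame(
        sample_id = base_id, subject_id = rid, role = "recipient",
        donor_id = donor_of_pair[p], subtype = spec$subtypes[p],
        arm = "allogenic", day = 0L)
      for (tp in spec$timepoints) {
        sid <- sprintf("%s_d%d", rid, tp)
        cols[[sid]] <- post
        manifest_rows[[sid]] <- data.frame(
          sample_id = sid, subject_id = rid, role = "recipient",
          donor_id = donor_of_pair[p], subtype = spec$subtypes[p],
          arm = "allogenic", day = tp)
      }
      donor_excl <- donor > 0 & recip == 0
      truth_rows[[rid]] <- data.frame(
        subject_id = rid, donor_id = donor_of_pair[p],
        subtype = spec$subtypes[p], d = d, g = g,
        donor_exclusive_mass = sum(post[donor_excl]),
        stringsAsFactors = FALSE)
    }
    values <- do.call(cbind, cols)
    rownames(values) <- taxa
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    structure(list(abundance = abundance_table(values),
                   manifest = cohort_manifest(do.call(rbind, manifest_rows)),
                   truth = truth),
              class = "species_cohort_sim")
  })
}

#' Specification for a simulated strain-level (SNV) cohort
#'
#' @param n_species Number of tracked species (assigned round-robin to the
#'   manifest's allogenic pairs).
#' @param positions_per_species Determinant candidate positions per species
#'   (>= 20, the tracking inclusion floor).
#' @param f Fraction of donor-specific determinant alleles established
#'   post-FMT (displacement), scalar or per species.
#' @param r Fraction of recipient-specific alleles retained post-FMT.
#' @param mean_coverage Expected reads per position (Poisson).
#' @param error_rate Per-read miscall probability; a miscall produces the
#'   specific alternative allele with probability `error_rate / 3`.
#' @param seed RNG seed.
#' @return List of class `"strain_sim_spec"`.
#' @export
strain_sim_spec <- function(n_species = 10, positions_per_species = 100,
                            f = 0.6, r = 0.9, mean_coverage = 20,
                            error_rate = 0.01, seed = 1) {
  fmt_assert(positions_per_species >= 20, "fmt_spec_error",
             "positions_per_species must be >= 20 (the tracking inclusion floor)")
  f <- rep_len(f, n_species); r <- rep_len(r, n_species)
  fmt_assert(is_fraction(f) && is_fraction(r) && is_fraction(error_rate),
             "fmt_spec_error", "f, r, error_rate must lie in [0, 1]")
  fmt_assert(mean_coverage > 0, "fmt_spec_error", "mean_coverage must be positive")
  structure(list(n_species = as.integer(n_species),
                 positions_per_species = as.integer(positions_per_species),
                 f = f, r = r, mean_coverage = mean_coverage,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "strain_sim_spec")
}

#' Simulate an SNV cohort with known strain displacement
#'
#' Each species is attached to one allogenic donor-recipient pair of the
#' manifest. Half of its positions are donor-specific (the donor carries the
#' alternative allele, the recipient baseline does not), half are
#' recipient-specific. Post-FMT, each donor-specific allele is established
#' with probability `f` and each recipient-specific allele retained with
#' probability `r` — one Bernoulli draw per position, shared across post
#' timepoints (engraftment as a persistent state). Read counts are Poisson
#' around `mean_coverage`; alternative-allele reads are Binomial with success
#' probability `1 - error_rate` where the allele is carried and
#' `error_rate / 3` where it is not. Samples from other pairs get zero
#' coverage for that species.
#'
#' @param spec A [strain_sim_spec()].
#' @param manifest A [cohort_manifest()] with at least one allogenic pair.
#' @return List of class `"snv_cohort_sim"`: `snv` ([snv_table()]) and
#'   `truth` (per species: planted `f`, `r` and realized establishment
#'   fractions).
#' @export
simulate_snv_cohort <- function(spec, manifest) {
  fmt_assert(inherits(spec, "strain_sim_spec"), "fmt_spec_error",
             "spec must be a strain_sim_spec")
  rec <- manifest[manifest$role == "recipient" & manifest$arm == "allogenic", ,
                  drop = FALSE]
  pairs <- unique(rec$subject_id)
  fmt_assert(length(pairs) >= 1, "fmt_validation_error",
             "manifest has no allogenic pair")
  withr::with_seed(spec$seed, {
    all_samples <- manifest$sample_id
    P <- spec$positions_per_species
    e_alt <- spec$error_rate / 3
    info_list <- list(); cov_list <- list(); freq_list <- list()
    truth_rows <- list()
    pair_of_species <- rep_len(pairs, spec$n_species)
    for (s in seq_len(spec$n_species)) {
      sp <- sprintf("species_%03d", s)
      subj <- pair_of_species[s]
      sub <- rec[rec$subject_id == subj, , drop = FALSE]
      base <- sub$sample_id[sub$day == 0]
      donor_sample <- manifest$sample_id[manifest$role == "donor" &
                                           manifest$subject_id == sub$donor_id[1]]
      posts <- sub$sample_id[sub$day > 0]
      fmt_assert(length(base) == 1 && length(donor_sample) == 1,
                 "fmt_validation_error",
                 "pair %s lacks donor or baseline sample", subj)
      ds <- sort(sample.int(P, P %/% 2))          # donor-specific positions
      is_ds <- seq_len(P) %in% ds
      alleles <- t(sapply(seq_len(P), function(i) sample(c("A", "C", "G", "T"), 2)))
      established <- stats::rbinom(P, 1, spec$f[s]) == 1   # for donor side
      retained <- stats::rbinom(P, 1, spec$r[s]) == 1      # for recipient side
      carrier_of <- function(sample_kind) {
        switch(sample_kind,
               donor = is_ds,
               baseline = !is_ds,
               post = (is_ds & established) | (!is_ds & retained))
      }
      cov <- matrix(0L, nrow = P, ncol = length(all_samples),
                    dimnames = list(NULL, all_samples))
      freq <- matrix(NA_real_, nrow = P, ncol = length(all_samples),
                     dimnames = list(NULL, all_samples))
      emit <- function(sample_id, kind) {
        cv <- stats::rpois(P, spec$mean_coverage)
        carrier <- carrier_of(kind)
        p_alt <- ifelse(carrier, 1 - spec$error_rate, e_alt)
        alt <- stats::rbinom(P, cv, p_alt)
        cov[, sample_id] <<- cv
        freq[, sample_id] <<- ifelse(cv > 0, alt / cv, NA_real_)
      }
      emit(donor_sample, "donor")
      emit(base, "baseline")
      for (ps in posts) emit(ps, "post")
      info_list[[s]] <- data.frame(
        species_id = sp, position = seq_len(P) - 1L,
        ref_allele = alleles[, 1], alt_allele = alleles[, 2],
        stringsAsFactors = FALSE)
      cov_list[[s]] <- cov
      freq_list[[s]] <- freq
      truth_rows[[s]] <- data.frame(
        species_id = sp, subject_id = subj, donor_id = sub$donor_id[1],
        f = spec$f[s], r = spec$r[s],
        n_donor_specific = sum(is_ds), n_recipient_specific = sum(!is_ds),
        f_realized = mean(established[is_ds]),
        r_realized = mean(retained[!is_ds]),
        stringsAsFactors = FALSE)
    }
    snv <- suppressWarnings(snv_table(do.call(rbind, info_list),
                                      do.call(rbind, cov_list),
                                      do.call(rbind, freq_list)))
    truth <- do.call(rbind, truth_rows)
    rownames(truth) <- NULL
    structure(list(snv = snv, truth = truth), class = "snv_cohort_sim")
  })
}

#' Simulate a clinical table with planted taxon-index associations
#'
#' Generates baseline and follow-up clinical values for every recipient that
#' has both abundance samples. For each planted `(taxon, index, rho)` effect,
#' the change in that index across recipients is drawn from a Gaussian copula
#' against the recipient's change in that taxon's abundance, giving
#' approximately the requested rank correlation; all other indexes change
#' independently.
#'
#' @param manifest A [cohort_manifest()].
#' @param abundance An [abundance_table()] covering baseline and day `t2`.
#' @param effects `NULL` (fully null) or a data frame with columns
#'   `taxon_id`, `index_name`, `rho` in `[-1, 1]`.
#' @param n_indexes Number of clinical indexes to emit (planted indexes are
#'   added if not among the first `n_indexes` default names).
#' @param index_names Optional index names; defaults to a standard IBD panel.
#' @param t2 Follow-up day for the planted association (default 3).
#' @param seed RNG seed.
#' @return A [clinical_table()].
#' @export
simulate_clinical <- function(manifest, abundance, effects = NULL,
                              n_indexes = 8, index_names = NULL, t2 = 3,
                              seed = 1) {
  if (!is.null(effects)) {
    fmt_assert(all(abs(effects$rho) <= 1), "fmt_spec_error",
               "planted |rho| must not exceed 1")
  }
  defaults <- c("hbi", "mayo", "cd4_cd8_ratio", "iga", "defecation_score",
                "crp", "tsc", "th_cell_induced", "bmi", "abdominal_pain")
  index_names <- index_names %||% defaults[seq_len(min(n_indexes,
                                                       length(defaults)))]
  if (length(index_names) < n_indexes) {
    index_names <- c(index_names,
                     sprintf("index_%02d", seq_len(n_indexes -
                                                     length(index_names))))
  }
  if (!is.null(effects)) {
    index_names <- union(index_names, effects$index_name)
  }
  rec <- manifest[manifest$role == "recipient", , drop = FALSE]
  subjects <- intersect(
    rec$subject_id[rec$day == 0 & rec$sample_id %in% colnames(abundance)],
    rec$subject_id[rec$day == t2 & rec$sample_id %in% colnames(abundance)])
  fmt_assert(length(subjects) >= 1, "fmt_validation_error",
             "no recipient with both baseline and day %d samples", t2)
  sample_at <- function(subj, day)
    rec$sample_id[rec$subject_id == subj & rec$day == day]
  withr::with_seed(seed, {
    n <- length(subjects)
    rows <- list()
    for (ix in index_names) {
      planted <- if (!is.null(effects)) {
        effects[effects$index_name == ix, , drop = FALSE]
      } else effects
      delta <- stats::rnorm(n)
      if (!is.null(planted) && nrow(planted)) {
        fmt_assert(nrow(planted) == 1, "fmt_spec_error",
                   "at most one planted taxon per index ('%s')", ix)
        taxon <- planted$taxon_id[1]
        fmt_assert(taxon %in% rownames(abundance), "fmt_spec_error",
                   "planted taxon '%s' not in abundance table", taxon)
        dx <- vapply(subjects, function(s)
          abundance[taxon, sample_at(s, t2)] -
            abundance[taxon, sample_at(s, 0)], 1.0)
        z <- stats::qnorm((rank(dx, ties.method = "average") - 0.375) /
                            (n + 0.25))
        rho <- planted$rho[1]
        delta <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      }
      baseline <- stats::rnorm(n, mean = 50, sd = 5)
      rows[[ix]] <- data.frame(
        subject_id = rep(subjects, 2),
        day = rep(c(0L, as.integer(t2)), each = n),
        index_name = ix,
        value = c(baseline, baseline + delta),
        stringsAsFactors = FALSE)
    }
    clinical_table(do.call(rbind, rows))
  })
}
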