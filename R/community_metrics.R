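## Alpha diversity and pairwise community comparison. All comparisons that use
## a log transform share one TransformSpec so the pseudo-count convention is
## stated in exactly one place.

#' Log-transform specification for abundance comparisons
#'
#' Community distances on relative abundances are computed after a log
#' transform with pseudo-count `x0`. The default variant,
#' `shifted_log = log(1 + x/x0)`, is zero at zero abundance and monotone, so
#' Bray-Curtis stays within `[0, 1]`. The `raw_log = log(x + x0)` variant is
#' retained for fidelity experiments; it maps zero abundance to `log(x0)`
#' (about -13.8 at the default), which makes Bray-Curtis ill-behaved and is
#' not the default for that reason.
#'
#' @param x0 Positive pseudo-count, default `1e-6`.
#' @param variant `"shifted_log"` or `"raw_log"`.
#' @return List of class `"transform_spec"`.
#' @export
transform_spec <- function(x0 = 1e-6, variant = c("shifted_log", "raw_log")) {
  fmt_assert(is.numeric(x0) && length(x0) == 1 && x0 > 0,
             "fmt_validation_error", "x0 must be a positive number")
  variant <- match.arg(variant)
  structure(list(x0 = x0, variant = variant), class = "transform_spec")
}

#' Apply a log-transform specification to abundances
#' @param x Numeric vector or matrix of relative abundances.
#' @param spec A [transform_spec()].
#' @return Transformed values, same shape as `x`.
#' @export
apply_transform <- function(x, spec = transform_spec()) {
  switch(spec$variant,
         shifted_log = log1p(x / spec$x0),
         raw_log = log(x + spec$x0))
}

#' Shannon diversity index (natural log)
#'
#' `H = -sum(p_i * log(p_i))` over strictly positive proportions, in nats.
#' The vector is renormalized internally, so unnormalized profiles are fine.
#'
#' @param profile Nonnegative abundance vector with positive sum.
#' @return Nonnegative real.
#' @export
shannon_index <- function(profile) {
  fmt_assert(is.numeric(profile) && all(profile >= 0), "fmt_validation_error",
             "profile must be nonnegative")
  if (sum(profile) <= 0) {
    fmt_stop("fmt_input_error", "Shannon index undefined for an all-zero profile")
  }
  as.numeric(vegan::diversity(profile, index = "shannon"))
}

#' Bray-Curtis dissimilarity on log-transformed abundances
#'
#' `BC = sum(|a' - b'|) / sum(a' + b')` on transformed values. With the
#' default `shifted_log` transform the inputs stay nonnegative and the result
#' lies in `[0, 1]`; under `raw_log` the formula is evaluated directly on the
#' (possibly negative) transformed values.
#'
#' @param a,b Equal-length nonnegative abundance vectors on the same taxa.
#' @param transform A [transform_spec()].
#' @return Dissimilarity in `[0, 1]` for nonnegative transforms.
#' @export
bray_curtis <- function(a, b, transform = transform_spec()) {
  fmt_assert(length(a) == length(b), "fmt_validation_error",
             "vectors must have equal length")
  fmt_assert(all(a >= 0) && all(b >= 0), "fmt_validation_error",
             "abundances must be nonnegative")
  if (sum(a) == 0 && sum(b) == 0) {
    fmt_stop("fmt_input_error", "Bray-Curtis undefined for two all-zero vectors")
  }
  ta <- apply_transform(a, transform)
  tb <- apply_transform(b, transform)
  if (any(ta < 0) || any(tb < 0)) {
    return(sum(abs(ta - tb)) / sum(ta + tb))
  }
  as.numeric(vegan::vegdist(rbind(ta, tb), method = "bray"))
}

#' Cosine similarity of two abundance vectors
#'
#' Computed on raw (untransformed) relative abundances:
#' `dot(a, b) / (||a|| * ||b||)`. For nonnegative inputs the value lies in
#' `[0, 1]`.
#'
#' @param a,b Equal-length numeric vectors, each with nonzero norm.
#' @return Real in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  fmt_assert(length(a) == length(b), "fmt_validation_error",
             "vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    fmt_stop("fmt_input_error", "cosine similarity undefined for a zero vector")
  }
  sum(a * b) / (na * nb)
}

#' Euclidean distances among baseline, post-FMT, and donor profiles
#'
#' Returns the three pairwise Euclidean distances on log-transformed vectors;
#' callers interpret direction (movement toward the donor versus back toward
#' baseline).
#'
#' @param pre,post,donor Abundance vectors on the same taxon index.
#' @param transform A [transform_spec()].
#' @return Named list `d_pre_post`, `d_post_donor`, `d_pre_donor`.
#' @export
euclidean_shift <- function(pre, post, donor, transform = transform_spec()) {
  fmt_assert(length(pre) == length(post) && length(post) == length(donor),
             "fmt_validation_error", "vectors must have equal length")
  m <- apply_transform(rbind(pre = pre, post = post, donor = donor), transform)
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  list(d_pre_post = d["pre", "post"],
       d_post_donor = d["post", "donor"],
       d_pre_donor = d["pre", "donor"])
}

#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with a chi-square reference on `k - 1` degrees of
#' freedom. The degenerate case where every observation is identical is
#' reported as `H = 0`, `p = 1`.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 1 observation.
#' @return List with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  fmt_assert(is.list(groups) && length(groups) >= 2, "fmt_validation_error",
             "need at least two groups")
  fmt_assert(all(vapply(groups, length, 1L) >= 1), "fmt_validation_error",
             "every group needs at least one observation")
  all_vals <- unlist(groups)
  if (length(unique(all_vals)) == 1) {
    return(list(statistic = 0, p.value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
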