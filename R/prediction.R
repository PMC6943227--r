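## Per-taxon engraftment prediction. For every sufficiently prevalent taxon,
## one random-forest classifier predicts its presence in the post-FMT
## recipient and one random-forest regressor predicts its abundance, from the
## donor profile, the pre-FMT recipient profile, and the recipient's baseline
## clinical indexes. With cohorts of ~15 recipients no held-out split is
## defensible, so all evaluation is out-of-bag: classifier AUC from OOB class
## votes, regression performance from pooled OOB predictions.

#' Drop taxa detected in too few samples
#'
#' Removes taxa detected (relative abundance >= `threshold`) in fewer than
#' `min_samples` samples, the class-imbalance guard applied before model
#' fitting.
#'
#' @param abundance An [abundance_table()].
#' @param min_samples Minimum number of samples with detection (default 3).
#' @param threshold Detection gate (default 0.001).
#' @return Filtered [abundance_table()] (may be empty, with a warning).
#' @export
filter_rare_taxa <- function(abundance, min_samples = 3, threshold = 0.001) {
  keep <- rowSums(unclass(abundance) >= threshold) >= min_samples
  if (!any(keep)) warning("no taxon passes the prevalence filter", call. = FALSE)
  abundance_table(unclass(abundance)[keep, , drop = FALSE])
}

#' Assemble the per-recipient feature matrix
#'
#' One row per post-FMT recipient sample at `predict_day`; columns are the
#' donor's taxon abundances (`donor|`), the recipient's baseline abundances
#' (`pre|`), and the recipient's baseline clinical indexes (`clin|`). Missing
#' clinical values are median-imputed; indexes missing everywhere are
#' dropped. Column provenance is recorded in the `provenance` attribute.
#'
#' @param abundance An [abundance_table()].
#' @param manifest A [cohort_manifest()].
#' @param clinical Optional [clinical_table()].
#' @param predict_day Post-FMT day to predict (default 3).
#' @return List: `features` (data frame), `post` (taxa x samples matrix of
#'   observed post-FMT abundances), `recipients` (data frame), `provenance`
#'   (named character vector over feature columns).
#' @export
build_feature_matrix <- function(abundance, manifest, clinical = NULL,
                                 predict_day = 3) {
  rec <- manifest[manifest$role == "recipient" & manifest$arm == "allogenic", ,
                  drop = FALSE]
  have <- colnames(abundance)
  rows <- list()
  for (subj in unique(rec$subject_id)) {
    sub <- rec[rec$subject_id == subj, , drop = FALSE]
    base <- sub$sample_id[sub$day == 0]
    post <- sub$sample_id[sub$day == predict_day]
    donor_sample <- manifest$sample_id[manifest$role == "donor" &
                                         manifest$subject_id == sub$donor_id[1]]
    if (length(base) != 1 || length(post) != 1 || length(donor_sample) != 1) next
    if (!all(c(base, post, donor_sample) %in% have)) next
    rows[[subj]] <- data.frame(subject_id = subj, base = base, post = post,
                               donor = donor_sample, stringsAsFactors = FALSE)
  }
  fmt_assert(length(rows) >= 2, "fmt_validation_error",
             "need at least two recipients with baseline, post, and donor samples")
  recipients <- do.call(rbind, rows)
  taxa <- rownames(abundance)
  donor_f <- t(unclass(abundance)[, recipients$donor, drop = FALSE])
  pre_f <- t(unclass(abundance)[, recipients$base, drop = FALSE])
  colnames(donor_f) <- paste0("donor|", taxa)
  colnames(pre_f) <- paste0("pre|", taxa)
  features <- cbind(donor_f, pre_f)
  provenance <- c(rep("donor_profile", length(taxa)),
                  rep("recipient_profile", length(taxa)))
  if (!is.null(clinical)) {
    cl <- clinical[clinical$day == 0, , drop = FALSE]
    for (ix in unique(cl$index_name)) {
      v <- cl$value[cl$index_name == ix][
        match(recipients$subject_id, cl$subject_id[cl$index_name == ix])]
      if (all(is.na(v))) next
      v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      features <- cbind(features, v)
      colnames(features)[ncol(features)] <- paste0("clin|", ix)
      provenance <- c(provenance, "recipient_clinical")
    }
  }
  names(provenance) <- colnames(features)
  rownames(features) <- recipients$post
  list(features = as.data.frame(features),
       post = unclass(abundance)[, recipients$post, drop = FALSE],
       recipients = recipients,
       provenance = provenance)
}

make_folds <- function(y, k) {
  n <- length(y)
  fold <- integer(n)
  if (is.factor(y)) {
    small <- any(table(y) < k)
    if (small) {
      warning("a class has fewer members than folds; folds rebalanced",
              call. = FALSE)
    }
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

#' Choose mtry by k-fold cross-validation over a halving grid
#'
#' Candidate feature-subset sizes are `p, p/2, p/4, ..., 1`; each is scored
#' by k-fold cross-validated error (misclassification rate for a factor
#' target, mean squared error otherwise) and the size with the lowest mean
#' error wins, ties going to the smaller value. A single-feature matrix
#' returns 1 without cross-validation. Folds are stratified for
#' classification.
#'
#' @param features Data frame or matrix of predictors.
#' @param target Factor (classification) or numeric (regression) target.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @param n_trees Trees per cross-validation fit (default 100).
#' @return The selected `mtry`.
#' @export
select_mtry <- function(features, target, k = 5, seed = 1, n_trees = 100) {
  p <- ncol(features)
  if (p == 1) return(1L)
  grid <- integer(0); m <- p
  while (m >= 1) { grid <- c(grid, m); m <- m %/% 2 }
  grid <- sort(unique(grid))
  x <- as.data.frame(features)
  withr::with_seed(seed, {
    fold <- make_folds(target, k)
    err <- vapply(grid, function(mtry) {
      fe <- vapply(seq_len(k), function(f) {
        tr <- fold != f; te <- fold == f
        if (!any(te) || length(unique(target[tr])) < 2) return(NA_real_)
        fit <- randomForest::randomForest(x = x[tr, , drop = FALSE],
                                          y = target[tr], mtry = mtry,
                                          ntree = n_trees)
        pred <- stats::predict(fit, x[te, , drop = FALSE])
        if (is.factor(target)) mean(pred != target[te])
        else mean((as.numeric(pred) - target[te])^2)
      }, 1.0)
      mean(fe, na.rm = TRUE)
    }, 1.0)
    grid[which.min(err)]   # which.min takes the first (smallest) on ties
  })
}

#' Fit the per-taxon presence classifier
#'
#' A random forest on the feature matrix with OOB evaluation: AUC from the
#' OOB vote fraction for the positive class (with the fixed direction
#' "higher vote, more likely present", so an uninformative model scores near
#' 0.5) and per-feature permutation importance (mean decrease in OOB
#' accuracy). A single-class target is skipped with a message (`NULL`).
#'
#' @param features Predictors (rows = post-FMT recipient samples).
#' @param target Factor with levels `c("absent", "present")` (or any two
#'   levels; the second is treated as positive).
#' @param mtry Features tried per split.
#' @param n_trees Trees (default 500).
#' @param seed RNG seed.
#' @param taxon_id Optional label.
#' @return List of class `"per_taxon_model"` with `taxon_id`, `task`,
#'   `auc`, `oob_error`, `mtry`, `n_positive`, `importance`, `votes`,
#'   `response`, or `NULL` if skipped.
#' @export
fit_presence_model <- function(features, target, mtry, n_trees = 500,
                               seed = 1, taxon_id = NULL) {
  target <- as.factor(target)
  if (nlevels(droplevels(target)) < 2) {
    message(sprintf("taxon %s skipped: single-class presence target",
                    taxon_id %||% "?"))
    return(NULL)
  }
  x <- as.data.frame(features)
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = x, y = target, mtry = mtry,
                               ntree = n_trees, importance = TRUE))
  pos <- levels(target)[2]
  votes <- fit$votes[, pos]
  ## samples that were never out-of-bag have no OOB vote (possible at very
  ## small n); they cannot enter the ROC, and if a whole class vanishes the
  ## AUC is undefined
  ok <- is.finite(votes)
  auc <- if (length(unique(target[ok])) == 2) {
    roc <- pROC::roc(response = target[ok], predictor = votes[ok],
                     levels = levels(target), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(roc))
  } else {
    message(sprintf("taxon %s: AUC undefined (a class has no OOB votes)",
                    taxon_id %||% "?"))
    NA_real_
  }
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  structure(list(taxon_id = taxon_id, task = "presence",
                 auc = auc,
                 oob_error = unname(fit$err.rate[n_trees, "OOB"]),
                 mtry = mtry, n_positive = sum(target == pos),
                 importance = imp, votes = votes, response = target),
            class = "per_taxon_model")
}

#' Fit the per-taxon abundance regressor
#'
#' A random-forest regressor; OOB predictions are retained so performance can
#' be pooled across taxa. Importance is the permutation increase in OOB mean
#' squared error. Targets with fewer than three distinct values are skipped
#' with a message (`NULL`).
#'
#' @inheritParams fit_presence_model
#' @param target Numeric post-FMT abundances.
#' @return List of class `"per_taxon_model"` with OOB `predicted` and
#'   `observed`, or `NULL` if skipped.
#' @export
fit_abundance_model <- function(features, target, mtry, n_trees = 500,
                                seed = 1, taxon_id = NULL) {
  if (length(unique(target)) < 3) {
    message(sprintf("taxon %s skipped: near-constant abundance target",
                    taxon_id %||% "?"))
    return(NULL)
  }
  x <- as.data.frame(features)
  ## randomForest warns about near-discrete regression targets; expected for
  ## small cohorts, so muffled here specifically
  fit <- withCallingHandlers(
    withr::with_seed(seed,
      randomForest::randomForest(x = x, y = target, mtry = mtry,
                                 ntree = n_trees, importance = TRUE)),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  structure(list(taxon_id = taxon_id, task = "abundance", auc = NA_real_,
                 oob_error = fit$mse[n_trees], mtry = mtry,
                 n_positive = NA_integer_, importance = imp,
                 predicted = unname(fit$predicted), observed = target),
            class = "per_taxon_model")
}

#' Pool regression performance across taxa
#'
#' Spearman rank correlation of OOB-predicted versus observed abundances,
#' pooled over all regression models and samples, with an asymptotic
#' two-sided p-value and, optionally, a permutation p-value.
#'
#' @param results List of `per_taxon_model` objects (regression results are
#'   selected automatically).
#' @param n_perm Number of permutations for the permutation p-value
#'   (0 disables it).
#' @param seed RNG seed for the permutations.
#' @return List `rho`, `p`, `n`, and `p_perm` (NA unless requested).
#' @export
pool_regression_performance <- function(results, n_perm = 0, seed = 1) {
  reg <- Filter(function(r) !is.null(r) && r$task == "abundance", results)
  pred <- unlist(lapply(reg, `[[`, "predicted"))
  obs <- unlist(lapply(reg, `[[`, "observed"))
  fmt_assert(length(pred) >= 2, "fmt_validation_error",
             "need at least two pooled (predicted, observed) pairs")
  if (length(unique(pred)) == 1 || length(unique(obs)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = length(pred),
                p_perm = NA_real_))
  }
  ct <- suppressWarnings(stats::cor.test(pred, obs, method = "spearman",
                                         exact = FALSE))
  p_perm <- NA_real_
  if (n_perm > 0) {
    obs_rho <- unname(ct$estimate)
    perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i)
      stats::cor(sample(pred), obs, method = "spearman"), 1.0))
    p_perm <- (1 + sum(abs(perm) >= abs(obs_rho))) / (n_perm + 1)
  }
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(pred),
       p_perm = p_perm)
}

#' Aggregate feature importance across well-performing classifiers
#'
#' Restricted to presence models with AUC strictly greater than `auc_min`.
#' Each qualifying model's importance vector is rank-normalized to `[0, 1]`
#' (so models contribute comparably regardless of scale), scores are averaged
#' per feature, and the `top_k` features are returned with their provenance
#' labels.
#'
#' @param results List of `per_taxon_model` objects.
#' @param provenance Named character vector mapping feature to provenance
#'   (from [build_feature_matrix()]).
#' @param auc_min AUC qualification bar (default 0.9).
#' @param top_k Number of features to return (default 40).
#' @return Data frame `feature`, `provenance`, `score`, `n_models`, ranked by
#'   score; empty (with a warning) if no model qualifies.
#' @export
aggregate_importance <- function(results, provenance = NULL, auc_min = 0.9,
                                 top_k = 40) {
  cls <- Filter(function(r) !is.null(r) && r$task == "presence" &&
                  !is.na(r$auc) && r$auc > auc_min, results)
  if (length(cls) == 0) {
    warning("no model qualifies (AUC > ", auc_min, ")", call. = FALSE)
    return(data.frame(feature = character(0), provenance = character(0),
                      score = numeric(0), n_models = integer(0)))
  }
  feats <- names(cls[[1]]$importance)
  for (r in cls) {
    fmt_assert(identical(names(r$importance), feats), "fmt_validation_error",
               "models were fit on different feature matrices")
  }
  scores <- sapply(cls, function(r)
    rank(r$importance, ties.method = "average") / length(r$importance))
  agg <- rowMeans(scores)
  ord <- order(agg, decreasing = TRUE)
  out <- data.frame(feature = feats[ord],
                    provenance = if (is.null(provenance)) NA_character_
                                 else unname(provenance[feats[ord]]),
                    score = unname(agg[ord]),
                    n_models = length(cls), stringsAsFactors = FALSE)
  utils::head(out, top_k)
}

#' Per-taxon engraftment prediction across a cohort
#'
#' The end-to-end driver: filters rare taxa, assembles the feature matrix,
#' then per taxon selects `mtry` (optionally), fits the presence classifier
#' and abundance regressor, and pools regression performance. Cohorts with
#' fewer than 20 recipients are flagged as small-sample (OOB estimates are
#' then noisy, which is the operative regime for FMT cohorts of this size).
#'
#' @param abundance An [abundance_table()].
#' @param manifest A [cohort_manifest()].
#' @param clinical Optional [clinical_table()].
#' @param threshold Detection gate.
#' @param min_samples Prevalence filter (default 3).
#' @param predict_day Post-FMT day to predict.
#' @param n_trees Trees per final model.
#' @param tune_mtry Tune mtry by cross-validation (otherwise the usual
#'   `sqrt(p)` / `p/3` defaults are used).
#' @param k Cross-validation folds for tuning.
#' @param n_perm Permutations for the pooled-rho p-value.
#' @param seed RNG seed.
#' @return List of class `"engraftment_prediction"`: `results` (per-taxon
#'   model list), `summary` (data frame), `pooled` (from
#'   [pool_regression_performance()]), `provenance`, `n_samples`,
#'   `small_sample` flag.
#' @export
predict_engraftment <- function(abundance, manifest, clinical = NULL,
                                threshold = 0.001, min_samples = 3,
                                predict_day = 3, n_trees = 500,
                                tune_mtry = TRUE, k = 5, n_perm = 199,
                                seed = 1) {
  filt <- filter_rare_taxa(abundance, min_samples, threshold)
  fm <- build_feature_matrix(filt, manifest, clinical, predict_day)
  n <- nrow(fm$features)
  small <- n < 20
  if (small) {
    message(sprintf("small-sample regime: %d recipients; OOB estimates are noisy", n))
  }
  p <- ncol(fm$features)
  taxa <- rownames(filt)
  results <- list()
  for (ti in seq_along(taxa)) {
    taxon <- taxa[ti]
    y_abund <- fm$post[taxon, ]
    y_pres <- factor(ifelse(y_abund >= threshold, "present", "absent"),
                     levels = c("absent", "present"))
    sd_cls <- derive_seed(seed, 2 * ti)
    sd_reg <- derive_seed(seed, 2 * ti + 1)
    if (nlevels(droplevels(y_pres)) == 2) {
      m_cls <- if (tune_mtry) select_mtry(fm$features, y_pres, k, sd_cls)
               else max(1L, floor(sqrt(p)))
      res <- fit_presence_model(fm$features, y_pres, m_cls, n_trees, sd_cls,
                                taxon_id = taxon)
      if (!is.null(res)) results[[paste0(taxon, ".presence")]] <- res
    }
    if (length(unique(y_abund)) >= 3) {
      m_reg <- if (tune_mtry) select_mtry(fm$features, y_abund, k, sd_reg)
               else max(1L, floor(p / 3))
      res <- fit_abundance_model(fm$features, y_abund, m_reg, n_trees, sd_reg,
                                 taxon_id = taxon)
      if (!is.null(res)) results[[paste0(taxon, ".abundance")]] <- res
    }
  }
  summary <- do.call(rbind, lapply(results, function(r) data.frame(
    taxon_id = r$taxon_id, task = r$task, auc = r$auc,
    oob_error = r$oob_error, mtry = r$mtry, n_positive = r$n_positive,
    stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  pooled <- if (any(vapply(results, function(r) r$task == "abundance", TRUE)))
    pool_regression_performance(results, n_perm = n_perm,
                                seed = derive_seed(seed, 999))
  else list(rho = NA_real_, p = NA_real_, n = 0L, p_perm = NA_real_)
  structure(list(results = results, summary = summary, pooled = pooled,
                 provenance = fm$provenance, n_samples = n,
                 small_sample = small),
            class = "engraftment_prediction")
}
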