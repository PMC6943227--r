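test_that("the prevalence filter keeps taxa detected in >= min_samples samples", {
  m <- matrix(0, 3, 15, dimnames = list(c("rare", "boundary", "ubiquitous"),
                                        paste0("s", 1:15)))
  m["rare", 1:2] <- 0.01
  m["boundary", 1:3] <- 0.01
  m["ubiquitous", ] <- 0.01
  filt <- filter_rare_taxa(abundance_table(m))
  expect_setequal(rownames(filt), c("boundary", "ubiquitous"))
  all_in <- abundance_table(m["ubiquitous", , drop = FALSE])
  expect_identical(rownames(filter_rare_taxa(all_in)), "ubiquitous")
  ## detection uses the 0.001 gate, not mere positivity
  m["rare", ] <- 0.0009
  expect_false("rare" %in% rownames(filter_rare_taxa(abundance_table(m))))
})

test_that("mtry selection is deterministic, grid-bound, and degenerate-safe", {
  rd <- rule_data(n = 60, seed = 8)
  y <- target_of(rd, 1)
  m1 <- select_mtry(rd$x, y, k = 5, seed = 9, n_trees = 50)
  m2 <- select_mtry(rd$x, y, k = 5, seed = 9, n_trees = 50)
  expect_identical(m1, m2)
  grid <- c(1, 2, 5, 10, 20)  # halving grid for p = 20
  expect_true(m1 %in% grid)
  expect_identical(select_mtry(rd$x[, 1, drop = FALSE], y, seed = 9), 1L)
  ## pure-noise target: still deterministic under the seed
  ynoise <- withr::with_seed(10, factor(sample(c("a", "b"), 60, TRUE)))
  expect_identical(select_mtry(rd$x, ynoise, k = 5, seed = 11, n_trees = 25),
                   select_mtry(rd$x, ynoise, k = 5, seed = 11, n_trees = 25))
})

test_that("a perfectly separable target reaches AUC 1 and flipping inverts it", {
  rd <- rule_data(n = 100, seed = 12)
  y <- factor(ifelse(rd$x[["noise1"]] > 0, "present", "absent"),
              levels = c("absent", "present"))
  fit <- fit_presence_model(rd$x, y, mtry = 4, n_trees = 300, seed = 13)
  ## OOB votes separate the classes essentially perfectly
  expect_gte(fit$auc, 0.99)
  expect_equal(fit$n_positive, sum(y == "present"))

  ## anti-predictor: scoring the same votes against flipped labels
  flipped <- factor(ifelse(y == "present", "absent", "present"),
                    levels = c("absent", "present"))
  roc <- pROC::roc(response = flipped, predictor = fit$votes,
                   levels = c("absent", "present"), direction = "<",
                   quiet = TRUE)
  expect_equal(as.numeric(pROC::auc(roc)), 1 - fit$auc)

  ## single-class target is skipped with a message
  expect_message(
    out <- fit_presence_model(rd$x,
                              factor(rep("present", 100),
                                     levels = c("absent", "present")),
                              mtry = 4, seed = 13),
    "single-class")
  expect_null(out)
})

test_that("learnable presence rules score high; regression tracks its target", {
  rd <- rule_data(n = 200, seed = 4)
  fit <- fit_presence_model(rd$x, target_of(rd, 1), mtry = 4, n_trees = 500,
                            seed = 14)
  expect_gte(fit$auc, 0.9)

  ## abundance regressor on a self-predictable (continuous) target
  y <- rd$x[["noise1"]]
  reg <- fit_abundance_model(rd$x, y, mtry = 10, n_trees = 300, seed = 15)
  rho <- suppressWarnings(cor(reg$predicted, reg$observed, method = "spearman"))
  expect_gte(rho, 0.9)
  expect_message(
    out <- fit_abundance_model(rd$x, rep(0, 200), mtry = 7, seed = 15),
    "constant")
  expect_null(out)
})

test_that("pooled regression performance matches the rank-formula oracle", {
  mk <- function(pred, obs) structure(
    list(task = "abundance", predicted = pred, observed = obs),
    class = "per_taxon_model")
  r <- pool_regression_performance(list(mk(1:10, 1:10)))
  expect_equal(r$rho, 1)
  r2 <- pool_regression_performance(list(mk(1:10, 10:1)))
  expect_equal(r2$rho, -1)
  set.seed(16)
  pred <- round(runif(10), 1); obs <- round(runif(10), 1)
  r3 <- pool_regression_performance(list(mk(pred, obs)))
  ok <- oracle_spearman(pred, obs)
  expect_equal(r3$rho, ok$rho)
  expect_equal(r3$p, ok$p)
  ## permutation p-value is small for a strong monotone association
  r4 <- pool_regression_performance(list(mk(1:30, (1:30)^2)), n_perm = 99,
                                    seed = 17)
  expect_lt(r4$p_perm, 0.05)
})

test_that("importance aggregation ranks a planted predictor first", {
  ## several taxa whose presence is driven by one shared clinical feature
  withr::with_seed(18, {
    n <- 120
    x <- as.data.frame(matrix(rnorm(n * 8), n))
    names(x) <- c(paste0("pre|t", 1:7), "clin|driver")
    prov <- c(rep("recipient_profile", 7), "recipient_clinical")
    names(prov) <- names(x)
    results <- lapply(1:4, function(t) {
      y <- factor(ifelse(x[["clin|driver"]] + 0.2 * rnorm(n) > 0,
                         "present", "absent"),
                  levels = c("absent", "present"))
      fit_presence_model(x, y, mtry = 3, n_trees = 300, seed = 18 + t,
                         taxon_id = paste0("t", t))
    })
  })
  imp <- aggregate_importance(results, prov, auc_min = 0.9, top_k = 5)
  expect_identical(imp$feature[1], "clin|driver")
  expect_identical(imp$provenance[1], "recipient_clinical")

  ## a single qualifying model returns its own ranking
  one <- aggregate_importance(results[1], prov, auc_min = 0.9, top_k = 8)
  expect_identical(one$feature[1],
                   names(which.max(results[[1]]$importance)))
  expect_true(all(diff(one$score) <= 0))
  expect_warning(none <- aggregate_importance(results, prov, auc_min = 1.01),
                 "no model qualifies")
  expect_equal(nrow(none), 0)
})

test_that("the cohort driver flags small samples and reports both tasks", {
  co <- simulate_species_cohort(cohort_sim_spec(n_pairs = 8, n_taxa = 30,
                                                timepoints = 3, seed = 19))
  cl <- simulate_clinical(co$manifest, co$abundance, seed = 20)
  expect_message(
    fit <- predict_engraftment(co$abundance, co$manifest, cl,
                               n_trees = 100, tune_mtry = FALSE, n_perm = 19,
                               seed = 21),
    "small-sample")
  expect_true(fit$small_sample)
  expect_true(all(c("presence", "abundance") %in% fit$summary$task))
  ## AUC is NA where a singleton class never goes out of bag; defined values
  ## stay within [0, 1]
  aucs <- fit$summary$auc[fit$summary$task == "presence"]
  expect_true(any(!is.na(aucs)))
  expect_true(all(aucs[!is.na(aucs)] >= 0 & aucs[!is.na(aucs)] <= 1))
  expect_true(all(c("donor_profile", "recipient_profile",
                    "recipient_clinical") %in% fit$provenance))
  ## determinism of the whole driver under a fixed seed
  fit2 <- suppressMessages(
    predict_engraftment(co$abundance, co$manifest, cl, n_trees = 100,
                        tune_mtry = FALSE, n_perm = 19, seed = 21))
  expect_identical(fit$summary, fit2$summary)
  expect_identical(fit$pooled, fit2$pooled)
})
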