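## Orchestration: one declarative config drives simulate -> community metrics
## -> species partitioning -> strain tracking -> prediction -> correlation,
## and produces one consolidated report. A stage whose inputs are missing is
## skipped with a recorded reason rather than failing the run; hard errors
## (unreadable files, invariant violations) still stop.

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to the abundance / manifest / SNV /
#' clinical TSVs) or `simulate` (simulation settings) must be given. The
#' seed is mandatory and drives every stochastic stage through derived
#' sub-seeds.
#'
#' @param inputs `NULL`, or a list with elements `abundance`, `manifest`, and
#'   optionally `snv`, `clinical` (file paths).
#' @param simulate `NULL`, or a list with optional elements matching
#'   [cohort_sim_spec()] arguments, plus optional `strain` (a list matching
#'   [strain_sim_spec()] arguments) and `clinical` (`TRUE`/`FALSE`/effects
#'   data frame for [simulate_clinical()]).
#' @param threshold Detection gate for species-level analyses.
#' @param transform A [transform_spec()].
#' @param strain List of strain-tracking settings: `thresholds`
#'   ([presence_thresholds()]), `min_positions`, `hi`, `lo`.
#' @param prediction List of prediction settings: `n_trees`, `tune_mtry`,
#'   `k`, `n_perm`, `auc_min`, `top_k`, `predict_day`.
#' @param correlation List of correlation settings: `t1`, `t2`, `min_n`,
#'   `q_max`.
#' @param seed Integer seed (mandatory).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(inputs = NULL, simulate = NULL, threshold = 0.001,
                            transform = transform_spec(),
                            strain = list(), prediction = list(),
                            correlation = list(), seed) {
  fmt_assert(!missing(seed) && is.numeric(seed) && length(seed) == 1,
             "fmt_usage_error", "a single integer seed is mandatory")
  if (is.null(inputs) == is.null(simulate)) {
    fmt_stop("fmt_usage_error",
             "provide exactly one of input paths or a simulation spec")
  }
  if (!is.null(inputs)) {
    fmt_assert(all(c("abundance", "manifest") %in% names(inputs)),
               "fmt_usage_error", "inputs need at least abundance and manifest")
  }
  strain <- utils::modifyList(
    list(thresholds = presence_thresholds(), min_positions = 20,
         hi = 0.8, lo = 0.2), strain)
  prediction <- utils::modifyList(
    list(n_trees = 500, tune_mtry = TRUE, k = 5, n_perm = 199,
         auc_min = 0.9, top_k = 40, predict_day = 3, min_samples = 3),
    prediction)
  correlation <- utils::modifyList(
    list(t1 = 0, t2 = 3, min_n = 4, q_max = 0.05), correlation)
  structure(list(inputs = inputs, simulate = simulate, threshold = threshold,
                 transform = transform, strain = strain,
                 prediction = prediction, correlation = correlation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [pipeline_config()] arguments (`inputs`,
#' `simulate`, `threshold`, `transform`, `strain`, `prediction`,
#' `correlation`, `seed`).
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tf <- if (is.null(y$transform)) transform_spec() else
    transform_spec(x0 = y$transform$x0 %||% 1e-6,
                   variant = y$transform$variant %||% "shifted_log")
  st <- y$strain %||% list()
  if (!is.null(st$thresholds)) st$thresholds <- do.call(presence_thresholds,
                                                        st$thresholds)
  pipeline_config(inputs = y$inputs, simulate = y$simulate,
                  threshold = y$threshold %||% 0.001, transform = tf,
                  strain = st, prediction = y$prediction %||% list(),
                  correlation = y$correlation %||% list(),
                  seed = y$seed %||% fmt_stop("fmt_usage_error",
                                              "config must set a seed"))
}

config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

load_pipeline_tables <- function(config) {
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    list(
      abundance = read_abundance_table(inp$abundance),
      manifest = read_manifest(inp$manifest),
      snv = if (!is.null(inp$snv)) read_snv_table(inp$snv),
      clinical = if (!is.null(inp$clinical)) read_clinical(inp$clinical),
      truth = NULL)
  } else {
    sim <- config$simulate
    strain_args <- sim$strain
    clin_arg <- sim$clinical %||% TRUE
    base_args <- sim[setdiff(names(sim), c("strain", "clinical"))]
    base_args$seed <- base_args$seed %||% config$seed
    spec <- do.call(cohort_sim_spec, base_args)
    cohort <- simulate_species_cohort(spec)
    snv <- NULL
    if (!is.null(strain_args)) {
      strain_args$seed <- strain_args$seed %||% derive_seed(config$seed, 1)
      sspec <- do.call(strain_sim_spec, strain_args)
      snv <- simulate_snv_cohort(sspec, cohort$manifest)$snv
    }
    clinical <- NULL
    if (!isFALSE(clin_arg)) {
      effects <- if (is.data.frame(clin_arg) || is.list(clin_arg) &&
                     !isTRUE(clin_arg)) as.data.frame(clin_arg) else NULL
      if (!is.null(effects) && nrow(effects) == 0) effects <- NULL
      clinical <- simulate_clinical(cohort$manifest, cohort$abundance,
                                    effects = effects,
                                    t2 = config$correlation$t2,
                                    seed = derive_seed(config$seed, 2))
    }
    list(abundance = cohort$abundance, manifest = cohort$manifest,
         snv = snv, clinical = clinical, truth = cohort$truth)
  }
}

skipped_section <- function(reason) list(skipped = TRUE, reason = reason)

community_section <- function(abundance, manifest, transform) {
  shannon <- data.frame(
    sample_id = colnames(abundance),
    shannon = apply(unclass(abundance), 2, shannon_index),
    stringsAsFactors = FALSE)
  shannon <- merge(shannon, as.data.frame(manifest), by = "sample_id",
                   sort = TRUE)
  rec <- manifest[manifest$role == "recipient", , drop = FALSE]
  rows <- list()
  for (subj in unique(rec$subject_id)) {
    sub <- rec[rec$subject_id == subj, , drop = FALSE]
    base <- sub$sample_id[sub$day == 0]
    donor_sample <- manifest$sample_id[manifest$role == "donor" &
                                         manifest$subject_id == sub$donor_id[1]]
    posts <- sub[sub$day > 0, , drop = FALSE]
    if (length(base) != 1 || length(donor_sample) != 1) next
    for (i in seq_len(nrow(posts))) {
      ps <- posts$sample_id[i]
      pre_v <- abundance[, base]; post_v <- abundance[, ps]
      donor_v <- abundance[, donor_sample]
      eu <- euclidean_shift(pre_v, post_v, donor_v, transform)
      rows[[ps]] <- data.frame(
        subject_id = subj, subtype = posts$subtype[i], day = posts$day[i],
        bray_curtis_pre_post = bray_curtis(pre_v, post_v, transform),
        cosine_pre_post = cosine_similarity(pre_v, post_v),
        cosine_post_donor = cosine_similarity(post_v, donor_v),
        d_pre_post = eu$d_pre_post, d_post_donor = eu$d_post_donor,
        d_pre_donor = eu$d_pre_donor, stringsAsFactors = FALSE)
    }
  }
  comparisons <- do.call(rbind, rows)
  rownames(comparisons) <- NULL
  ## Alpha-diversity contrast: healthy donors vs CD vs UC baselines.
  base_groups <- list(
    healthy = shannon$shannon[shannon$role == "donor"],
    CD = shannon$shannon[shannon$role == "recipient" & shannon$day == 0 &
                           shannon$subtype == "CD"],
    UC = shannon$shannon[shannon$role == "recipient" & shannon$day == 0 &
                           shannon$subtype == "UC"])
  base_groups <- base_groups[vapply(base_groups, length, 1L) > 0]
  kw <- if (length(base_groups) >= 2) kruskal_wallis(base_groups) else
    list(statistic = NA_real_, p.value = NA_real_)
  med <- function(x) if (length(x)) stats::median(x) else NA_real_
  cos_median <- do.call(rbind, lapply(
    split(comparisons, comparisons$subtype),
    function(g) data.frame(subtype = g$subtype[1],
                           cosine_pre_post = med(g$cosine_pre_post),
                           cosine_post_donor = med(g$cosine_post_donor))))
  rownames(cos_median) <- NULL
  list(shannon = shannon, comparisons = comparisons,
       shannon_kruskal_wallis = kw, cosine_medians = cos_median)
}

#' Run the full engraftment analysis pipeline
#'
#' Loads (or simulates) the cohort tables and executes every stage whose
#' inputs are available: community metrics, species-source partitioning,
#' strain tracking (needs an SNV table), per-taxon prediction, and
#' delta-delta clinical correlation (needs a clinical table). Unavailable
#' stages are recorded as skipped. Identical configs (including seed)
#' reproduce the report exactly.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"engraftment_report"` with sections `community`,
#'   `species`, `strain`, `prediction`, `correlation`, and a `provenance`
#'   block (config fingerprint, seed, package version).
#' @export
run_pipeline <- function(config) {
  fmt_assert(inherits(config, "pipeline_config"), "fmt_usage_error",
             "config must be a pipeline_config")
  tabs <- load_pipeline_tables(config)
  community <- community_section(tabs$abundance, tabs$manifest,
                                 config$transform)
  parts <- partition_cohort(tabs$abundance, tabs$manifest, config$threshold)
  species <- if (is.null(parts$table)) {
    skipped_section("no recipient with baseline, post-FMT, and donor samples")
  } else {
    list(table = parts$table,
         gain_count = donor_gain_summary(parts$table, "count"),
         gain_abundance = donor_gain_summary(parts$table, "abundance"))
  }
  strain <- if (is.null(tabs$snv)) {
    skipped_section("no SNV table provided")
  } else {
    series <- suppressMessages(track_strains(
      tabs$snv, tabs$manifest, config$strain$thresholds,
      config$strain$min_positions, config$strain$hi, config$strain$lo))
    if (nrow(series) == 0) skipped_section("no species passed the determinant floor")
    else list(series = series,
              summary = cohort_retention_summary(series),
              classification = as.list(table(series$classification)))
  }
  pr <- config$prediction
  prediction <- tryCatch({
    fit <- suppressMessages(predict_engraftment(
      tabs$abundance, tabs$manifest, tabs$clinical,
      threshold = config$threshold, min_samples = pr$min_samples,
      predict_day = pr$predict_day, n_trees = pr$n_trees,
      tune_mtry = pr$tune_mtry, k = pr$k, n_perm = pr$n_perm,
      seed = derive_seed(config$seed, 101)))
    imp <- suppressWarnings(aggregate_importance(
      fit$results, fit$provenance, pr$auc_min, pr$top_k))
    auc <- fit$summary$auc[fit$summary$task == "presence"]
    list(summary = fit$summary, pooled = fit$pooled, importance = imp,
         n_samples = fit$n_samples, small_sample = fit$small_sample,
         auc_mean = if (length(auc)) mean(auc, na.rm = TRUE) else NA_real_,
         auc_median = if (length(auc)) stats::median(auc, na.rm = TRUE)
                      else NA_real_)
  }, fmtengraft_error = function(e) skipped_section(conditionMessage(e)))
  co <- config$correlation
  correlation <- if (is.null(tabs$clinical)) {
    skipped_section("no clinical table provided")
  } else {
    edges <- correlate_cohort(tabs$abundance, tabs$clinical, tabs$manifest,
                              co$t1, co$t2, co$min_n, co$q_max)
    list(edges = edges, n_tested = nrow(edges),
         n_significant = sum(edges$significant))
  }
  structure(list(
    community = community, species = species, strain = strain,
    prediction = prediction, correlation = correlation,
    provenance = list(config_md5 = config_fingerprint(config),
                      seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("fmtengraft")))),
    class = "engraftment_report")
}

#' Write a consolidated report to disk
#'
#' Emits `report.json` (the full report; numbers at full precision so reruns
#' are byte-identical) plus flat TSVs for the main tables and, when
#' significant correlation edges exist, `network.graphml`.
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  fmt_assert(inherits(report, "engraftment_report"), "fmt_usage_error",
             "report must be an engraftment_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
  if (!isTRUE(report$species$skipped)) {
    write_tsv_raw(report$species$table, file.path(dir, "partitions.tsv"))
  }
  if (!isTRUE(report$strain$skipped)) {
    write_tsv_raw(report$strain$series, file.path(dir, "retention.tsv"))
  }
  if (!isTRUE(report$prediction$skipped) &&
      !is.null(report$prediction$summary)) {
    write_tsv_raw(report$prediction$summary, file.path(dir, "models.tsv"))
  }
  if (!isTRUE(report$correlation$skipped)) {
    write_tsv_raw(report$correlation$edges, file.path(dir, "edges.tsv"))
    sig <- report$correlation$edges[report$correlation$edges$significant, ,
                                    drop = FALSE]
    if (nrow(sig)) {
      export_network(build_network(sig, q_max = Inf),
                     file.path(dir, "network.graphml"), "graphml")
    }
  }
  invisible(dir)
}
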