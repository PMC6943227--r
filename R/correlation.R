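## Delta-delta correlation analysis: per-recipient changes in taxon abundance
## between baseline and an early follow-up are correlated (Spearman) with
## changes in clinical indexes over the same interval, with Benjamini-Hochberg
## control, and the significant pairs form a bipartite network.

#' Build the per-recipient delta table
#'
#' For every recipient with abundance samples at both `t1` and `t2`, the
#' taxon delta is `abundance(t2) - abundance(t1)`; clinical deltas are
#' computed per index wherever both visits have a value and are `NA`
#' otherwise (pairwise-complete handling happens downstream).
#'
#' @param abundance An [abundance_table()].
#' @param clinical A [clinical_table()].
#' @param manifest A [cohort_manifest()].
#' @param t1,t2 Day offsets (defaults 0 and 3).
#' @return List of class `"delta_table"`: `taxa` (recipients x taxa),
#'   `clinical` (recipients x indexes, may contain NA), `recipients`.
#' @export
build_deltas <- function(abundance, clinical, manifest, t1 = 0, t2 = 3) {
  rec <- manifest[manifest$role == "recipient", , drop = FALSE]
  have <- colnames(abundance)
  at <- function(subj, day) {
    s <- rec$sample_id[rec$subject_id == subj & rec$day == day]
    if (length(s) == 1 && s %in% have) s else NA_character_
  }
  subjects <- unique(rec$subject_id)
  s1 <- vapply(subjects, at, "", day = t1)
  s2 <- vapply(subjects, at, "", day = t2)
  keep <- !is.na(s1) & !is.na(s2)
  if (!any(keep)) {
    fmt_stop("fmt_input_error",
             "no recipient has samples at both day %d and day %d", t1, t2)
  }
  subjects <- subjects[keep]
  taxa_d <- t(unclass(abundance)[, s2[keep], drop = FALSE] -
                unclass(abundance)[, s1[keep], drop = FALSE])
  rownames(taxa_d) <- subjects
  idx <- unique(clinical$index_name)
  clin_d <- sapply(idx, function(ix) {
    cl <- clinical[clinical$index_name == ix, , drop = FALSE]
    v1 <- cl$value[cl$day == t1][match(subjects, cl$subject_id[cl$day == t1])]
    v2 <- cl$value[cl$day == t2][match(subjects, cl$subject_id[cl$day == t2])]
    v2 - v1
  })
  clin_d <- matrix(clin_d, nrow = length(subjects),
                   dimnames = list(subjects, idx))
  structure(list(taxa = taxa_d, clinical = clin_d, recipients = subjects),
            class = "delta_table")
}

#' Spearman correlation for every taxon-index delta pair
#'
#' Tie-corrected Spearman rho with a two-sided asymptotic p-value for each
#' (taxon, clinical index) pair, on pairwise-complete observations. Pairs
#' with fewer than `min_n` complete observations, or with a constant column,
#' are skipped; skipped pairs and reasons are attached as the `"skipped"`
#' attribute.
#'
#' @param deltas A [build_deltas()] result.
#' @param min_n Minimum complete observations per pair (default 4; rank
#'   p-values below that are vacuous).
#' @return Data frame `taxon_id`, `index_name`, `n`, `rho`, `p`.
#' @export
spearman_all_pairs <- function(deltas, min_n = 4) {
  fmt_assert(min_n >= 2, "fmt_validation_error", "min_n must be at least 2")
  taxa <- colnames(deltas$taxa)
  idx <- colnames(deltas$clinical)
  rows <- list(); skipped <- list()
  for (ix in idx) {
    y_all <- deltas$clinical[, ix]
    for (tx in taxa) {
      x_all <- deltas$taxa[, tx]
      ok <- !is.na(x_all) & !is.na(y_all)
      key <- paste(tx, ix, sep = "~")
      if (sum(ok) < min_n) {
        skipped[[key]] <- "fewer complete observations than min_n"
        next
      }
      x <- x_all[ok]; y <- y_all[ok]
      if (length(unique(x)) == 1 || length(unique(y)) == 1) {
        skipped[[key]] <- "constant column"
        next
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      rows[[key]] <- data.frame(taxon_id = tx, index_name = ix, n = sum(ok),
                                rho = unname(ct$estimate), p = ct$p.value,
                                stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon_id = character(0), index_name = character(0),
               n = integer(0), rho = numeric(0), p = numeric(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped))
    data.frame(pair = names(skipped), reason = unlist(skipped),
               row.names = NULL, stringsAsFactors = FALSE)
  else NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with the usual monotonicity
#' enforcement (cumulative minimum from the largest rank).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  fmt_assert(length(p) >= 1, "fmt_validation_error", "need at least one p-value")
  fmt_assert(is.numeric(p) && all(!is.na(p)) && all(p >= 0) && all(p <= 1),
             "fmt_validation_error", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bipartite taxon-index correlation network
#'
#' Keeps edges with `q` strictly below `q_max` and builds a bipartite graph:
#' taxon vertices (`type = FALSE`) and clinical-index vertices
#' (`type = TRUE`); edges carry `rho`, `q`, `sign`, and `weight = |rho|`.
#' An empty graph is valid.
#'
#' @param edges Data frame with columns `taxon_id`, `index_name`, `rho`, `q`.
#' @param q_max Strict q-value cutoff (default 0.05).
#' @return An igraph graph.
#' @export
build_network <- function(edges, q_max = 0.05) {
  fmt_assert(all(c("taxon_id", "index_name", "rho", "q") %in% names(edges)),
             "fmt_validation_error", "edges need taxon_id, index_name, rho, q")
  keep <- edges[edges$q < q_max, , drop = FALSE]
  verts <- data.frame(
    name = c(unique(keep$taxon_id), unique(keep$index_name)),
    type = c(rep(FALSE, length(unique(keep$taxon_id))),
             rep(TRUE, length(unique(keep$index_name)))),
    stringsAsFactors = FALSE)
  el <- data.frame(from = keep$taxon_id, to = keep$index_name,
                   rho = keep$rho, q = keep$q,
                   sign = ifelse(keep$rho >= 0, "positive", "negative"),
                   weight = abs(keep$rho), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Delta-delta correlation analysis for a cohort
#'
#' Convenience driver: [build_deltas()], [spearman_all_pairs()],
#' [bh_adjust()], and edge annotation in one call.
#'
#' @inheritParams build_deltas
#' @param min_n Minimum complete observations per pair.
#' @param q_max Strict q-value cutoff for the `significant` flag.
#' @return Data frame of all tested pairs with `q`, `sign`, and
#'   `significant`; the network of significant edges is available via
#'   [build_network()].
#' @export
correlate_cohort <- function(abundance, clinical, manifest, t1 = 0, t2 = 3,
                             min_n = 4, q_max = 0.05) {
  deltas <- build_deltas(abundance, clinical, manifest, t1, t2)
  pairs <- spearman_all_pairs(deltas, min_n)
  if (nrow(pairs) == 0) {
    pairs$q <- numeric(0); pairs$sign <- character(0)
    pairs$significant <- logical(0)
    return(pairs)
  }
  pairs$q <- bh_adjust(pairs$p)
  pairs$sign <- ifelse(pairs$rho >= 0, "positive", "negative")
  pairs$significant <- pairs$q < q_max
  pairs
}
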