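test_that("delta tables subtract baseline from follow-up per recipient", {
  m <- matrix(c(0.10, 0.90,   # R1 d0
                0.25, 0.75,   # R1 d3
                0.40, 0.60,   # R2 d0
                0.40, 0.60),  # R2 d3
              nrow = 2,
              dimnames = list(c("tA", "tB"),
                              c("R1_d0", "R1_d3", "R2_d0", "R2_d3")))
  man <- cohort_manifest(data.frame(
    sample_id = colnames(m),
    subject_id = rep(c("R1", "R2"), each = 2),
    role = "recipient", donor_id = rep(c("R1", "R2"), each = 2),
    subtype = "CD", arm = "autologous", day = rep(c(0L, 3L), 2)))
  cl <- clinical_table(data.frame(
    subject_id = rep(c("R1", "R2"), each = 2), day = rep(c(0L, 3L), 2),
    index_name = "hbi", value = c(8, 5, 7, NA)))
  d <- build_deltas(m, cl, man)
  expect_equal(d$taxa["R1", "tA"], 0.15)
  expect_equal(d$taxa["R2", "tA"], 0)
  expect_equal(d$clinical["R1", "hbi"], -3)
  expect_true(is.na(d$clinical["R2", "hbi"]))  # missing visit propagates

  ## recipient without the follow-up sample is dropped entirely
  man2 <- man[man$sample_id != "R2_d3", ]
  d2 <- build_deltas(m[, colnames(m) != "R2_d3"], cl, man2)
  expect_identical(rownames(d2$taxa), "R1")
  expect_error(build_deltas(m[, 1:2, drop = FALSE], cl, man2, t2 = 30),
               class = "fmt_input_error")
})

test_that("pairwise Spearman matches the rank oracle, with skip rules", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_all_pairs(delta_pair(x, x * 2))$rho, 1)
  expect_equal(spearman_all_pairs(delta_pair(x, -x))$rho, -1)
  ## six points with a tie
  y <- c(2, 2, 5, 1, 7, 9)
  got <- spearman_all_pairs(delta_pair(x, y))
  ok <- oracle_spearman(x, y)
  expect_equal(got$rho, ok$rho)
  expect_equal(got$p, ok$p)
  ## monotone-transform invariance
  got2 <- spearman_all_pairs(delta_pair(exp(x), y^3 - 2))
  expect_equal(got2$rho, got$rho)
  expect_equal(got2$p, got$p)
  ## below min_n and constant columns are skipped with reasons
  short <- spearman_all_pairs(delta_pair(1:3, c(3, 1, 2)))
  expect_equal(nrow(short), 0)
  expect_match(attr(short, "skipped")$reason, "min_n")
  const <- spearman_all_pairs(delta_pair(rep(1, 6), y))
  expect_match(attr(const, "skipped")$reason, "constant")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "fmt_validation_error")
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the network keeps only q strictly below the cutoff", {
  edges <- data.frame(taxon_id = c("tA", "tB", "tC"),
                      index_name = c("hbi", "iga", "crp"),
                      rho = c(0.9, -0.7, 0.6),
                      q = c(0.01, 0.05, 0.49))
  g <- build_network(edges, q_max = 0.05)
  expect_equal(igraph::ecount(g), 1)   # q = 0.05 exactly is excluded
  el <- igraph::as_data_frame(g)
  expect_identical(el$from, "tA")
  expect_identical(el$sign, "positive")
  expect_equal(el$weight, 0.9)
  expect_equal(igraph::ecount(build_network(edges, q_max = 0.001)), 0)
})

test_that("a planted association is recovered as exactly one strong edge", {
  co <- simulate_species_cohort(cohort_sim_spec(n_pairs = 40, n_taxa = 50,
                                                timepoints = 3, seed = 24))
  rec <- co$manifest[co$manifest$role == "recipient", ]
  dvar <- apply(co$abundance[, rec$sample_id[rec$day == 3]] -
                  co$abundance[, rec$sample_id[rec$day == 0]], 1, var)
  taxon <- names(which.max(dvar))
  cl <- simulate_clinical(co$manifest, co$abundance,
                          effects = data.frame(taxon_id = taxon,
                                               index_name = "hbi", rho = 0.9),
                          n_indexes = 10, seed = 25)
  e <- correlate_cohort(co$abundance, cl, co$manifest)
  hit <- e[e$significant & e$taxon_id == taxon & e$index_name == "hbi", ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$rho, 0.5)
  expect_true(all(e$q >= e$p))
})
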