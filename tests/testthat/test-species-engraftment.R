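test_that("detection gate is inclusive at the boundary", {
  prof <- c(a = 0.001, b = 0.0009, c = 0, d = 0.5)
  expect_setequal(detect_taxa(prof), c("a", "d"))
  expect_identical(detect_taxa(c(x = 0, y = 0)), character(0))
  expect_error(detect_taxa(prof, threshold = 0), class = "fmt_validation_error")
})

test_that("partition_sample applies the four-source rule", {
  taxa <- c("A", "B", "C", "D")
  donor <- c(A = 0.5, B = 0.5, C = 0, D = 0)
  pre <- c(A = 0, B = 0.6, C = 0.4, D = 0)
  post <- c(A = 0.3, B = 0.3, C = 0, D = 0.4)
  p <- partition_sample(donor, pre, post)
  expect_identical(p$categories[["A"]], "donor_specific")
  expect_identical(p$categories[["B"]], "common")
  expect_identical(p$categories[["D"]], "new")
  expect_false("C" %in% names(p$categories))
  expect_equal(unname(p$abundance_fractions), c(0.3, 0, 0.3, 0.4))
  expect_equal(unname(p$count_fractions), c(1, 0, 1, 1) / 3)

  ## identical donor and baseline leave no source-specific taxa
  p2 <- partition_sample(donor, donor, post)
  expect_equal(p2$count_fractions[["donor_specific"]], 0)
  expect_equal(p2$count_fractions[["recipient_specific"]], 0)

  ## post drawn entirely from the donor, disjoint from baseline
  p3 <- partition_sample(donor, c(A = 0, B = 0, C = 1, D = 0),
                         c(A = 0.6, B = 0.4, C = 0, D = 0))
  expect_equal(p3$abundance_fractions[["donor_specific"]], 1)

  expect_error(partition_sample(donor, pre, c(A = 0, B = 0, C = 0, D = 0)),
               class = "fmt_input_error")
})

test_that("the four categories always partition the detected post taxa", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(10:80, 1)
    donor <- rand_abund(n); pre <- rand_abund(n); post <- rand_abund(n)
    p <- partition_sample(donor, pre, post)
    expect_setequal(names(p$categories), detect_taxa(post))
    expect_equal(sum(p$count_fractions), 1, tolerance = 1e-9)
    expect_equal(sum(p$abundance_fractions), 1, tolerance = 1e-9)
  }
})

test_that("donor gain summaries use mean and sample SD per subtype", {
  tab <- data.frame(subtype = c("CD", "CD"), count_donor_specific = c(0.2, 0.4),
                    ab_donor_specific = c(0.2, 0.4))
  s <- donor_gain_summary(tab, "count")
  cd <- s[s$group == "CD", ]
  expect_equal(cd$mean, 0.3)
  expect_equal(cd$sd, stats::sd(c(0.2, 0.4)))
  one <- donor_gain_summary(
    data.frame(subtype = "UC", count_donor_specific = 0.3,
               ab_donor_specific = 0.3), "abundance")
  expect_equal(one$sd[one$group == "UC"], 0)
  expect_true(one$single_observation[one$group == "UC"])
})

test_that("simulated donor fractions are recovered and respond to d", {
  co <- simulate_species_cohort(cohort_sim_spec(n_pairs = 10, n_taxa = 200,
                                                d = 0.3, g = 0.1, seed = 11))
  tab <- partition_cohort(co$abundance, co$manifest)$table
  t3 <- tab[tab$day == 3, ]
  truth <- co$truth$donor_exclusive_mass[match(t3$subject_id,
                                               co$truth$subject_id)]
  expect_true(all(abs(t3$ab_donor_specific - truth) < 0.05))

  means <- vapply(seq(0.1, 0.9, by = 0.2), function(d) {
    coh <- simulate_species_cohort(cohort_sim_spec(n_pairs = 6, n_taxa = 500,
                                                   d = d, g = 0.05, seed = 5))
    mean(partition_cohort(coh$abundance, coh$manifest)$table$ab_donor_specific)
  }, 1.0)
  expect_true(all(diff(means) > 0))
})

test_that("the category depends only on the detection pattern of the triple", {
  ## exhaustive presence combinations at boundary abundances; the filler
  ## taxon keeps the post-FMT sample nonempty
  vals <- c(absent = 0.0009, at = 0.001, above = 0.0011)
  for (d_in in c(FALSE, TRUE)) for (p_in in c(FALSE, TRUE)) {
    for (dv in vals) for (pv in vals) {
      donor <- c(x = if (d_in) unname(dv) else 0.0009, fill = 0.9)
      pre <- c(x = if (p_in) unname(pv) else 0.0009, fill = 0.9)
      post <- c(x = 0.1, fill = 0.9)
      part <- partition_sample(donor, pre, post)
      d_det <- d_in && dv >= 0.001
      p_det <- p_in && pv >= 0.001
      want <- if (d_det && p_det) "common" else if (d_det) "donor_specific"
              else if (p_det) "recipient_specific" else "new"
      expect_identical(part$categories[["x"]], want)
    }
  }
})
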