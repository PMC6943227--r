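test_that("presence calls follow the thresholds, including boundaries", {
  th <- presence_thresholds(cov_min = 5, present_min = 0.10, absent_max = 0.05)
  expect_identical(call_presence(20, 0.5, th), "present")
  expect_identical(call_presence(20, 0.0, th), "absent")
  expect_identical(call_presence(3, 0.5, th), "unresolved")
  expect_identical(call_presence(20, 0.10, th), "present")   # inclusive
  expect_identical(call_presence(20, 0.05, th), "absent")    # inclusive
  expect_identical(call_presence(20, 0.07, th), "unresolved")
  expect_identical(call_presence(0, NA_real_, th), "unresolved")
  expect_identical(call_presence(c(20, 20, 0), c(1, 0, NA), th),
                   c("present", "absent", "unresolved"))
  expect_error(presence_thresholds(present_min = 0.05, absent_max = 0.1),
               class = "fmt_validation_error")
})

test_that("determinant sets come from baseline contrasts only", {
  ## 30 clean donor-specific positions
  snv <- make_snv(list(D1_d0 = rep(1, 30), R1_d0 = rep(0, 30),
                       R1_d3 = rep(1, 30)))
  dset <- build_determinant_set(snv, "D1_d0", "R1_d0", "spX")
  expect_s3_class(dset, "determinant_set")
  expect_length(dset$donor_specific, 30)
  expect_length(dset$recipient_specific, 0)

  ## identical baselines (the autologous situation) yield no set
  snv2 <- make_snv(list(D1_d0 = runif(40), R1_d0 = NA))
  snv2$alt_freq[, "R1_d0"] <- snv2$alt_freq[, "D1_d0"]
  expect_message(
    out <- build_determinant_set(snv2, "D1_d0", "R1_d0", "spX"),
    "excluded")
  expect_null(out)

  ## below the inclusion floor
  snv3 <- make_snv(list(D1_d0 = c(rep(1, 10), rep(0, 20)),
                        R1_d0 = rep(0, 30)))
  expect_message(out3 <- build_determinant_set(snv3, "D1_d0", "R1_d0", "spX",
                                               min_positions = 20), "excluded")
  expect_null(out3)
  expect_s3_class(build_determinant_set(snv3, "D1_d0", "R1_d0", "spX",
                                        min_positions = 10),
                  "determinant_set")

  expect_error(build_determinant_set(snv, "D1_d0", "R1_d0", "nope"),
               class = "fmt_notfound_error")
})

test_that("retention counts present positions over evaluable positions", {
  ## 20 donor-specific + 20 recipient-specific; post keeps 6 of the first 10
  ## donor positions, the rest absent, 10 donor positions unresolved
  donor <- c(rep(1, 20), rep(0, 20))
  recip <- c(rep(0, 20), rep(1, 20))
  post <- c(rep(1, 6), rep(0, 4), rep(0.07, 10), rep(1, 20))
  snv <- make_snv(list(D1_d0 = donor, R1_d0 = recip, R1_d3 = post))
  dset <- build_determinant_set(snv, "D1_d0", "R1_d0", "spX")
  ret <- retention_fraction(dset, snv, "R1_d3")
  expect_equal(ret$donor_retention, 0.6)
  expect_equal(ret$recipient_retention, 1.0)
  expect_equal(ret$n_evaluable, 30)

  ## post identical to the donor sample: full donor retention
  snv2 <- make_snv(list(D1_d0 = donor, R1_d0 = recip, R1_d3 = donor))
  ret2 <- retention_fraction(dset, snv2, "R1_d3")
  expect_equal(ret2$donor_retention, 1.0)
  expect_equal(ret2$recipient_retention, 0.0)
})

test_that("classification is total over the unit square with pinned boundaries", {
  expect_identical(classify_state(0.9, 0.1), "donor_takeover")
  expect_identical(classify_state(0.1, 0.9), "recipient_persistence")
  expect_identical(classify_state(0.5, 0.5), "coexistence")
  expect_identical(classify_state(0.1, 0.1), "indeterminate")
  expect_identical(classify_state(0.2, 0.2), "coexistence")     # lo inclusive
  expect_identical(classify_state(0.8, 0.19), "donor_takeover") # hi inclusive
  expect_identical(classify_state(0.79, 0.19), "indeterminate")
  expect_identical(classify_state(NA, 0.5), "indeterminate")
  states <- c("donor_takeover", "recipient_persistence", "coexistence",
              "indeterminate")
  for (d in seq(0, 1, by = 0.1)) for (r in seq(0, 1, by = 0.1)) {
    expect_true(classify_state(d, r) %in% states)
  }
})

test_that("new SNV rate counts baseline-absent, post-present positions", {
  base <- c(rep(0, 50), rep(1, 50))
  snv <- make_snv(list(R1_d0 = base, R1_d3 = base))
  expect_equal(new_snv_rate(snv, "R1_d0", "R1_d3")$pooled, 0)

  post <- base; post[1:7] <- 1
  snv2 <- make_snv(list(R1_d0 = base, R1_d3 = post))
  out <- new_snv_rate(snv2, "R1_d0", "R1_d3")
  expect_equal(out$pooled, 0.07)
  expect_equal(out$per_species$n_evaluable, 100L)
})

test_that("retention recovers the planted displacement fraction", {
  man <- pair_manifest()
  sim <- simulate_snv_cohort(
    strain_sim_spec(n_species = 1, positions_per_species = 1000, f = 0.6,
                    r = 0.9, mean_coverage = 20, error_rate = 0.01, seed = 42),
    man)
  dset <- suppressMessages(
    build_determinant_set(sim$snv, "D1_d0", "R1_d0", "species_001"))
  ret <- retention_fraction(dset, sim$snv, "R1_d3")
  expect_lt(abs(ret$donor_retention - 0.6), 0.04)
  expect_lt(abs(ret$recipient_retention - 0.9), 0.04)
})

test_that("cohort summaries average species within recipients first", {
  series <- data.frame(
    pair_id = c("R1", "R2", "R3"), donor_id = "D1",
    species_id = "sp1", subtype = "CD", day = 3L,
    donor_retention = c(0.2, 0.4, 0.6), recipient_retention = 0.9,
    n_evaluable = 100L, classification = "coexistence")
  s <- cohort_retention_summary(series)
  expect_equal(s$mean, 0.4)
  expect_equal(s$sd, 0.2)

  ## a recipient with many species must not dominate the cell
  series2 <- rbind(series,
                   data.frame(pair_id = "R1", donor_id = "D1",
                              species_id = paste0("sp", 2:9), subtype = "CD",
                              day = 3L, donor_retention = 1,
                              recipient_retention = 0.9, n_evaluable = 100L,
                              classification = "coexistence"))
  per_rec_means <- c(mean(c(0.2, rep(1, 8))), 0.4, 0.6)
  expect_equal(cohort_retention_summary(series2)$mean, mean(per_rec_means))
})

test_that("a UC arm with stronger displacement outranks the CD arm", {
  co <- simulate_species_cohort(cohort_sim_spec(
    n_pairs = 6, n_taxa = 50, timepoints = 3,
    subtypes = rep(c("CD", "UC"), each = 3), seed = 21))
  ## species are assigned round-robin, so the first three land on the CD
  ## pairs and the last three on the UC pairs
  sim <- simulate_snv_cohort(
    strain_sim_spec(n_species = 6, positions_per_species = 200,
                    f = c(0.1, 0.1, 0.1, 0.6, 0.6, 0.6), r = 0.9, seed = 22),
    co$manifest)
  expect_identical(sim$truth$subject_id,
                   c("CD-1", "CD-2", "CD-3", "UC-1", "UC-2", "UC-3"))
  series <- suppressMessages(track_strains(sim$snv, co$manifest))
  s <- cohort_retention_summary(series)
  expect_gt(s$mean[s$subtype == "UC"], s$mean[s$subtype == "CD"])
})
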