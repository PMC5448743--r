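test_that("simulation is deterministic given the seed and preserves RNG state", {
  p <- simulation_params(n_per_group = 5, n_mirnas = 60, n_reference = 4,
                         n_differential = 6, seed = 101)
  set.seed(1); before <- rnorm(1)
  set.seed(1)
  s1 <- simulate_cohort(p)
  after <- rnorm(1)
  s2 <- simulate_cohort(p)
  expect_identical(s1$panel$ct, s2$panel$ct)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$truth, s2$truth)
  expect_identical(before, after)  # caller RNG untouched
  s3 <- simulate_cohort(simulation_params(n_per_group = 5, n_mirnas = 60,
                                          n_reference = 4, n_differential = 6,
                                          seed = 102))
  expect_false(identical(s1$panel$ct, s3$panel$ct))
})

test_that("default-sized panel is 754 miRNAs by 2 x 8 samples", {
  sim <- simulate_cohort(simulation_params(n_per_group = 8, seed = 1))
  expect_identical(dim(sim$panel$ct), c(754L, 16L))
  expect_identical(sum(sim$panel$panel_of == "A"), 377L)
  expect_identical(table(sim$cohort$group)[["atherosclerotic"]], 8L)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params(n_mirnas = 10, n_reference = 8,
                                 n_differential = 8), "exceed")
  expect_error(simulation_params(ct_sd = 0), "positive")
  expect_error(simulation_params(dropout_ct = 45), "<= 40")
  expect_error(simulation_params(n_per_group = 1), ">= 2")
  expect_error(simulation_params(hemolysis_fraction = 1), "hemolysis_fraction")
})

test_that("planted truth ids are disjoint and carry the requested effects", {
  p <- simulation_params(n_per_group = 6, n_mirnas = 80, n_reference = 5,
                         n_differential = 4, effect_log2fc = c(2, -1.5),
                         seed = 7)
  sim <- simulate_cohort(p)
  expect_length(intersect(sim$truth$reference_ids,
                          sim$truth$differential_ids), 0)
  expect_equal(unname(sim$truth$log2fc), c(2, -1.5, 2, -1.5))  # recycled
})

test_that("planted differential miRNAs shift Ct by minus the log2 fold change", {
  p <- simulation_params(n_per_group = 200, n_mirnas = 40, n_reference = 5,
                         n_differential = 5, effect_log2fc = 2,
                         ct_sd = 0.8, seed = 8)
  sim <- simulate_cohort(p)
  ath <- sim$cohort$group == "atherosclerotic"
  d <- sim$truth$differential_ids[1]
  shift <- mean(sim$panel$ct[d, ath]) - mean(sim$panel$ct[d, !ath])
  expect_equal(shift, -2, tolerance = 0.2)   # SE ~ 0.08 at n = 200
})

test_that("low-variance planted references pass the candidate criteria", {
  p <- simulation_params(n_per_group = 10, n_mirnas = 100, n_reference = 8,
                         n_differential = 5, reference_sd = 0.02, seed = 9)
  sim <- simulate_cohort(p)
  panel <- impute_undetermined(sim$panel)
  cand <- candidate_reference_filter(panel, sim$cohort$group)
  expect_true(all(sim$truth$reference_ids %in% cand))
})

test_that("null planted effects reject at the nominal t-test rate", {
  ps <- unlist(lapply(1:15, function(s) {
    sim <- simulate_cohort(simulation_params(
      n_per_group = 10, n_mirnas = 120, n_reference = 5, n_differential = 10,
      effect_log2fc = 0, seed = 200 + s))
    panel <- impute_undetermined(sim$panel)
    expr <- delta_ct(panel, sim$truth$reference_ids)
    differential_candidates(expr, sim$cohort$group)$p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("hemolysed samples appear at the requested fraction and fail QC", {
  sim <- simulate_cohort(simulation_params(n_per_group = 20, n_mirnas = 30,
                                           n_reference = 3, n_differential = 3,
                                           hemolysis_fraction = 0.2,
                                           seed = 10))
  expect_identical(sum(sim$cohort$absorbance_415 >= 0.2), 8L)  # 20% of 40
  kept <- hemolysis_filter(sim$cohort)
  expect_identical(nrow(kept), 32L)
})

test_that("clinical covariates follow the group means of the specification", {
  sim <- simulate_cohort(simulation_params(n_per_group = 400, n_mirnas = 10,
                                           n_reference = 3, n_differential = 3,
                                           seed = 11))
  ath <- sim$cohort$group == "atherosclerotic"
  spec <- default_clinical_spec()$continuous
  for (v in c("hba1c", "hdl_c", "lipoprotein_a")) {
    row <- spec[spec$name == v, ]
    expect_equal(mean(sim$cohort[[v]][ath]), row$mean_ath,
                 tolerance = 4 * row$sd_ath / sqrt(400))
    expect_equal(mean(sim$cohort[[v]][!ath]), row$mean_non,
                 tolerance = 4 * row$sd_non / sqrt(400))
  }
  expect_gt(mean(sim$cohort$diabetes[ath] == "yes"),
            mean(sim$cohort$diabetes[!ath] == "yes"))
})

test_that("simulated studies round-trip through the CSV/JSON writers", {
  sim <- simulate_cohort(simulation_params(n_per_group = 4, n_mirnas = 20,
                                           n_reference = 3, n_differential = 3,
                                           seed = 12))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  p2 <- read_ct_wide(file.path(dir, "ct_panel.csv"))
  expect_equal(p2$ct, sim$panel$ct)
  c2 <- read_cohort_csv(file.path(dir, "cohort.csv"))
  expect_identical(c2$sample_id, sim$cohort$sample_id)
  expect_identical(as.character(c2$group), as.character(sim$cohort$group))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_identical(truth$reference_ids, sim$truth$reference_ids)
})
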