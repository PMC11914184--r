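test_that("cohort_config validates probabilities, counts and weights", {
  expect_s3_class(tiny_config(), "cohort_config")
  expect_error(tiny_config(n_patients = 0L), "positive integer")
  expect_error(tiny_config(n_true_variants = -1L), "non-negative")
  expect_error(tiny_config(artifact_reject_prob = 1.2), "\\[0, 1\\]")
  expect_error(tiny_config(signature_mix = c(S1 = 0.6, S2 = 0.3)),
               "sum to 1")
  expect_error(tiny_config(telomere_scenarios = "weird"),
               "unknown telomere scenario")
})

test_that("caller simulation honours degenerate limits", {
  cfg <- tiny_config(n_artifact_variants = 0L,
                     caller_sensitivity = c(vardict = 1, strelka2 = 1,
                                            mutect2 = 1))
  calls <- simulate_caller_calls(cfg)
  status <- as.matrix(calls$observations[, cfg$callers])
  expect_true(all(status == "pass"))
  expect_equal(nrow(calls$normal_support), 0L)
  expect_length(calls$truth$artifact_ids, 0L)
})

test_that("generators are deterministic under an identical seed + config", {
  a <- simulate_caller_calls(tiny_config(seed = 11L))
  b <- simulate_caller_calls(tiny_config(seed = 11L))
  expect_identical(a, b)
  expect_false(identical(
    a$observations,
    simulate_caller_calls(tiny_config(seed = 12L))$observations
  ))
  segs <- simulate_cn_segments(tiny_config(seed = 11L))
  expect_identical(segs, simulate_cn_segments(tiny_config(seed = 11L)))
  r1 <- simulate_clonal_reads(tiny_config(seed = 11L),
                              diploid_segments(c("S1", "S2")))
  r2 <- simulate_clonal_reads(tiny_config(seed = 11L),
                              diploid_segments(c("S1", "S2")))
  expect_identical(r1$matrix$alt, r2$matrix$alt)
  expect_identical(simulate_telomere_profiles(tiny_config(seed = 11L)),
                   simulate_telomere_profiles(tiny_config(seed = 11L)))
})

test_that("configured artifact fraction lands inside exact binomial bounds", {
  # 500/500 split: the emitted id ratio is fixed by configuration, so it
  # must sit inside the central 99% binomial band for f = 0.5, n = 1000
  cfg <- cohort_config(seed = 5L, n_patients = 4L,
                       n_true_variants = 500L, n_artifact_variants = 500L,
                       n_normals = 10L)
  calls <- simulate_caller_calls(cfg)
  n_art <- length(calls$truth$artifact_ids)
  n_tot <- n_art + length(calls$truth$true_variant_ids)
  lo <- qbinom(0.005, 1000L, 0.5) / 1000
  hi <- qbinom(0.995, 1000L, 0.5) / 1000
  expect_gte(n_art / n_tot, lo)
  expect_lte(n_art / n_tot, hi)
})

test_that("ground-truth bookkeeping is complete and disjoint", {
  calls <- simulate_caller_calls(tiny_config(seed = 3L))
  truth <- calls$truth
  expect_length(intersect(truth$true_variant_ids, truth$artifact_ids), 0L)
  expect_setequal(unique(calls$observations$variant_id),
                  c(truth$true_variant_ids, truth$artifact_ids))
  expect_true(all(calls$normal_support$variant_id %in% truth$artifact_ids))
  expect_true(all(truth$panel_artifact_ids %in% truth$artifact_ids))
})

test_that("clonal read simulation follows the binomial model", {
  # phi = 1, diploid omega = 0.5, huge depth: VAF concentrates at 0.5
  cfg <- tiny_config(seed = 9L, depth_mean = 10000)
  sim <- simulate_clonal_reads(cfg, diploid_segments("S1"),
                               phi = matrix(1, 1, 1,
                                            dimnames = list(NULL, "S1")),
                               n_variants = 50L)
  vaf <- sim$matrix$alt / sim$matrix$total
  expect_true(all(abs(vaf - 0.5) < 0.02))
  expect_true(all(sim$matrix$vrp == 0.5))

  # a phi = 0 clone contributes no alt reads
  phi <- matrix(c(0.8, 0), 2, 1, dimnames = list(NULL, "S1"))
  sim0 <- simulate_clonal_reads(tiny_config(seed = 9L),
                                diploid_segments("S1"), phi = phi,
                                n_variants = 60L)
  zero_clone <- sim0$truth$assignment == 2L
  expect_true(any(zero_clone))
  expect_true(all(sim0$matrix$alt[zero_clone, ] == 0L))

  # a second sample whose segments do not cover the drawn positions is a
  # generation error
  short <- diploid_segments("S2")
  short$end <- 10L
  expect_error(
    simulate_clonal_reads(tiny_config(seed = 9L),
                          rbind(diploid_segments("S1"), short),
                          n_variants = 5L),
    "generation error"
  )
})

test_that("telomere scenarios hit their configured expectations", {
  # 100 patients x 2 samples, all normal: mean log2 ratio ~ 0 (CLT bound)
  cfg <- cohort_config(seed = 21L, n_patients = 100L,
                       samples_per_patient = 2L, n_normals = 5L,
                       n_true_variants = 10L, n_artifact_variants = 0L,
                       telomere_scenarios = "normal")
  prof <- simulate_telomere_profiles(cfg)
  tum <- prof[prof$role == "tumour", ]
  blo <- prof[prof$role == "blood", ]
  ratio <- log2(tum$intratelomeric_reads / blo$intratelomeric_reads)
  expect_equal(nrow(tum), 200L)
  expect_lt(abs(mean(ratio)), 0.05)

  # enriched at the default target of 1.0: >95% flagged downstream
  cfg_e <- cohort_config(seed = 22L, n_patients = 100L,
                         samples_per_patient = 1L, n_normals = 5L,
                         n_true_variants = 10L, n_artifact_variants = 0L,
                         telomere_scenarios = "enriched")
  pe <- simulate_telomere_profiles(cfg_e)
  te <- pe[pe$role == "tumour", ]
  be <- pe[pe$role == "blood", ]
  enr <- enrichment_ratio(
    telomere_content(te$intratelomeric_reads, te$gc_matched_total_reads),
    telomere_content(be$intratelomeric_reads, be$gc_matched_total_reads)
  )
  expect_gt(mean(enr$enriched), 0.95)

  # zero-noise configuration recovers the configured ratio exactly
  cfg_z <- tiny_config(seed = 23L, telomere_scenarios = "enriched",
                       telomere_noise = FALSE)
  pz <- simulate_telomere_profiles(cfg_z)
  tz <- pz[pz$role == "tumour", "intratelomeric_reads"]
  bz <- pz[pz$role == "blood", "intratelomeric_reads"]
  expect_equal(log2(tz / bz), rep(1, length(tz)))

  # alt_like reduces the canonical proportion by the configured factor
  cfg_a <- tiny_config(seed = 24L, telomere_scenarios = "alt_like",
                       telomere_noise = FALSE)
  pa <- simulate_telomere_profiles(cfg_a)
  ta <- pa[pa$role == "tumour", ]
  ba <- pa[pa$role == "blood", ]
  expect_lt(max(ta$tvr_TTAGGG / ta$intratelomeric_reads), 0.7)
  expect_equal(unique(ta$ccircle_status), "positive")
  expect_gt(min(ba$tvr_TTAGGG / ba$intratelomeric_reads), 0.85)
})

test_that("signature catalog simulation records exact ground truth", {
  S <- synthetic_signature_matrix(k = 3L, seed = 1L)
  pure <- simulate_signature_catalog(S, c(S1 = 1), n = 500L, seed = 2L)
  expect_equal(sum(pure$catalog), 500L)
  expect_equal(pure$true_exposures, c(S1 = 500))
  empty <- simulate_signature_catalog(S, c(S2 = 1), n = 0L, seed = 2L)
  expect_true(all(empty$catalog == 0L))
  expect_error(
    simulate_signature_catalog(S, c(S1 = 1.2, S2 = -0.2), 10L, 1L),
    "negative"
  )
  # all generated counts are non-negative integers
  mixed <- simulate_signature_catalog(S, c(S1 = 0.5, S3 = 0.5), 1000L, 3L)
  expect_true(all(mixed$catalog >= 0L))
  expect_identical(unname(mixed$catalog), as.integer(mixed$catalog))
})
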