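grid_for <- function(alt, total = 100L) {
  # alt: named list variant -> per-sample alt read counts
  samples <- sprintf("S%d", seq_along(alt[[1]]))
  do.call(rbind, lapply(names(alt), function(v) {
    data.frame(variant_id = v, sample_id = samples, alt = alt[[v]],
               total = total, stringsAsFactors = FALSE)
  }))
}

test_that("unify_and_exclude drops the 1..3 read ambiguity band cohort-wide", {
  grid <- grid_for(list(clean = c(40L, 0L), banded = c(40L, 2L),
                        edge = c(4L, 4L), at3 = c(40L, 3L)))
  mat <- unify_and_exclude(grid)
  expect_setequal(mat$variant_ids, c("clean", "edge"))
  expect_setequal(mat$excluded$variant_id, c("banded", "at3"))
  # symmetric under sample reordering
  flipped <- grid
  flipped$sample_id <- ifelse(grid$sample_id == "S1", "S2", "S1")
  expect_setequal(unify_and_exclude(flipped)$variant_ids,
                  mat$variant_ids)
  # ragged grids are rejected
  expect_error(unify_and_exclude(grid[-1L, ]), "ragged")
})

test_that("variant read probabilities reproduce the rule table", {
  # diploid: 0.5 for any purity or VAF
  expect_equal(variant_read_probability(0.3, 0.8, 1, 1), 0.5)
  expect_equal(variant_read_probability(0.9, 0.2, 1, 1), 0.5)
  # single copy loss with VAF above half purity: 1
  expect_equal(variant_read_probability(0.45, 0.8, 1, 0), 1)
  # CN-LOH below half purity: 1 / major
  expect_equal(variant_read_probability(0.2, 0.8, 2, 0), 0.5)
  # CN-LOH above half purity: 1
  expect_equal(variant_read_probability(0.5, 0.8, 2, 0), 1)
  # other regions: 1 / total
  expect_equal(variant_read_probability(0.3, 0.8, 2, 1), 1 / 3)
  expect_equal(variant_read_probability(0.3, 0.8, 2, 2), 1 / 4)
  # VAF exactly half purity in CN-LOH takes the conservative 1/major branch
  expect_equal(variant_read_probability(0.4, 0.8, 2, 0), 0.5)
  expect_error(variant_read_probability(0.3, 0.8, 0, 0), "undefined-region")
})

test_that("rule table agrees with the prose oracle on the exhaustive grid", {
  for (major in 0:4) {
    for (minor in 0:major) {
      if (major + minor == 0) next
      for (vaf in seq(0, 1, by = 0.05)) {
        for (purity in c(0.2, 0.5, 0.8)) {
          expect_identical(
            variant_read_probability(vaf, purity, major, minor),
            vrp_prose_oracle(vaf, purity, major, minor)
          )
        }
      }
    }
  }
})

test_that("add_vrp looks up the covering segment per sample", {
  grid <- grid_for(list(v1 = c(50L, 40L)))
  mat <- unify_and_exclude(grid)
  positions <- data.frame(variant_id = "v1", chrom = "chr1", pos = 500L)
  segs <- rbind(diploid_segments("S1"), diploid_segments("S2"))
  segs$major_cn[2] <- 2
  segs$minor_cn[2] <- 0
  mat <- add_vrp(mat, positions, segs)
  expect_equal(mat$vrp[1, "S1"], 0.5)
  # S2 is CN-LOH with VAF 0.4 = purity/2 exactly: conservative 1/major
  expect_equal(mat$vrp[1, "S2"], 0.5)
  expect_error(add_vrp(unify_and_exclude(grid), positions,
                       within(segs, chrom <- "chr9")),
               "not covered")
})

test_that("binomial-mixture EM recovers frequencies and is monotone", {
  # k = 1, omega = 0.5, true phi = 0.8, depth 1000: MLE concentration
  withr::with_seed(41L, {
    n <- 80L
    alt <- matrix(rbinom(n, 1000L, 0.5 * 0.8), n, 1,
                  dimnames = list(sprintf("v%02d", 1:n), "S1"))
    total <- matrix(1000L, n, 1, dimnames = dimnames(alt))
  })
  mat <- clonal_variant_matrix(alt, total,
                               vrp = matrix(0.5, n, 1,
                                            dimnames = dimnames(alt)),
                               purity = 0.8)
  model <- cluster_frequencies(mat, k = 1L, seed = 1L)
  expect_lt(abs(model$phi[1, 1] - 0.8), 0.02)
  expect_true(all(diff(model$loglik_trace) > -1e-6))

  # k = 1 with zero alt reads everywhere: phi = 0
  zero <- clonal_variant_matrix(total * 0L, total,
                                vrp = matrix(0.5, n, 1,
                                             dimnames = dimnames(alt)))
  expect_equal(unname(cluster_frequencies(zero, 1L, seed = 1L)$phi[1, 1]),
               0)

  expect_error(cluster_frequencies(mat, k = n + 1L, seed = 1L), "k must")
})

test_that("EM is deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 51L, depth_mean = 100)
  sim <- simulate_clonal_reads(cfg, diploid_segments(c("S1", "S2")),
                               phi = matrix(c(0.9, 0.3, 0.9, 0.3), 2, 2,
                                            dimnames = list(NULL,
                                                            c("S1", "S2"))),
                               n_variants = 60L)
  m1 <- cluster_frequencies(sim$matrix, 2L, seed = 5L)
  m2 <- cluster_frequencies(sim$matrix, 2L, seed = 5L)
  expect_identical(m1$phi, m2$phi)
  expect_identical(m1$assignment, m2$assignment)
})

test_that("shared/private partition matches clone membership", {
  grid <- grid_for(list(s1 = c(40L, 38L), s2 = c(50L, 45L),
                        pa = c(40L, 0L), pb = c(0L, 44L)))
  mat <- unify_and_exclude(grid)
  part <- partition_shared_private(mat)
  expect_equal(part$shared, 2L)
  expect_equal(part$private_a, 1L)
  expect_equal(part$private_b, 1L)
  expect_equal(unname(part$category[c("pa", "pb")]),
               c("private_a", "private_b"))
  expect_error(partition_shared_private(
    unify_and_exclude(grid_for(list(v = c(10L, 10L, 10L))))
  ), "two samples")

  # seeded two-clone fixture: private variants are exactly the ones from
  # the clone absent in the other sample
  phi <- matrix(c(1, 1, 1, 0), 2, 2,
                dimnames = list(NULL, c("S1", "S2")))
  sim <- simulate_clonal_reads(tiny_config(seed = 52L, depth_mean = 200),
                               diploid_segments(c("S1", "S2")),
                               phi = phi, n_variants = 80L)
  part2 <- partition_shared_private(sim$matrix)
  clone2 <- sim$truth$assignment == 2L
  expect_equal(part2$shared, sum(!clone2))
  expect_equal(part2$private_a, sum(clone2))
  expect_equal(part2$private_b, 0L)
})
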