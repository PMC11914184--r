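test_that("two-of-three consensus follows the acceptance rule", {
  expect_true(consensus_accept(c(vardict = "pass", strelka2 = "pass",
                                 mutect2 = "not_called")))
  expect_false(consensus_accept(c(vardict = "pass", strelka2 = "not_called",
                                  mutect2 = "not_called")))
  expect_true(consensus_accept(c(vardict = "pass", strelka2 = "pass",
                                 mutect2 = "pass")))
  # reject does not count towards the consensus
  expect_false(consensus_accept(c(vardict = "pass", strelka2 = "reject",
                                  mutect2 = "reject")))
  expect_error(consensus_accept(c(gatk = "pass", strelka2 = "pass",
                                  mutect2 = "pass")),
               "unknown caller")
  expect_error(consensus_accept(c(vardict = "maybe", strelka2 = "pass",
                                  mutect2 = "pass")))
})

test_that("normal-panel blacklist uses >= 3 reads in > 2 normals", {
  sup <- function(reads) {
    data.frame(variant_id = rep("v1", length(reads)),
               normal_id = sprintf("n%d", seq_along(reads)),
               reads = reads, stringsAsFactors = FALSE)
  }
  expect_equal(build_normal_panel_blacklist(sup(c(3, 3, 3)))$variant_id,
               "v1")
  # exactly two supporting normals: kept (rule is strictly more than two)
  expect_equal(nrow(build_normal_panel_blacklist(sup(c(3, 3)))), 0L)
  # no normal reaches three reads
  expect_equal(nrow(build_normal_panel_blacklist(sup(c(2, 2, 2, 2)))), 0L)
  expect_error(build_normal_panel_blacklist(sup(c(-1, 3, 3))), "negative")
  expect_equal(nrow(build_normal_panel_blacklist(sup(integer(0)))), 0L)
})

test_that("reject:pass blacklist is strict at ratio one and infinite at P=0", {
  mk <- function(n_pass, n_reject) {
    # spread statuses over single-caller observations
    n <- n_pass + n_reject
    data.frame(
      variant_id = rep("v1", n),
      vardict = c(rep("pass", n_pass), rep("reject", n_reject)),
      strelka2 = rep("not_called", n), mutect2 = rep("not_called", n),
      stringsAsFactors = FALSE
    )
  }
  expect_equal(build_reject_ratio_blacklist(mk(4, 5))$variant_id, "v1")
  expect_equal(nrow(build_reject_ratio_blacklist(mk(4, 4))), 0L)
  expect_equal(nrow(build_reject_ratio_blacklist(mk(10, 0))), 0L)
  expect_equal(build_reject_ratio_blacklist(mk(0, 1))$variant_id, "v1")
  expect_equal(nrow(build_reject_ratio_blacklist(mk(0, 0)[0, ])), 0L)
})

test_that("apply_filters removes blacklist hits with provenance", {
  accepted <- sprintf("v%02d", 1:10)
  panel <- data.frame(variant_id = c("v01", "v02", "v03"),
                      source = "normal_panel")
  ratio <- data.frame(variant_id = "v04", source = "reject_ratio")
  res <- apply_filters(accepted, list(panel, ratio))
  expect_length(res$kept, 6L)
  expect_setequal(res$removed$variant_id, c("v01", "v02", "v03", "v04"))

  # empty blacklists are the identity
  expect_equal(apply_filters(accepted, list())$kept, accepted)

  # a variant on both lists is removed once, provenance lists both
  both <- apply_filters("v01", list(panel,
                                    data.frame(variant_id = "v01",
                                               source = "reject_ratio")))
  expect_length(both$kept, 0L)
  expect_equal(both$removed$sources, "normal_panel,reject_ratio")

  # idempotence
  again <- apply_filters(res$kept, list(panel, ratio))
  expect_equal(again$kept, res$kept)
})

test_that("tumour mutation burden is count over megabases", {
  expect_equal(tumour_mutation_burden(3200, 3200), 1.0)
  expect_equal(tumour_mutation_burden(0), 0.0)
  expect_equal(tumour_mutation_burden(992), 0.32)
  expect_error(tumour_mutation_burden(10, 0), "positive")
})

test_that("variant keys normalize shared bases and left-shift position", {
  # shared suffix trimmed
  expect_equal(normalize_variant_key("chr1", 100L, "CTT", "CT")$key,
               "chr1:100:CT:C")
  # shared prefix trimmed, position advances
  n <- normalize_variant_key("chr1", 100L, "ACG", "ATG")
  expect_equal(n$pos, 101L)
  expect_equal(n$ref, "C")
  expect_equal(n$alt, "T")
  # SNV is a fixed point
  expect_equal(normalize_variant_key("chr2", 5L, "G", "T")$key,
               "chr2:5:G:T")
  expect_error(normalize_variant_key("chr1", 1L, "A", "A"), "differ")
})

test_that("panel blacklist grows monotonically with panel size", {
  calls <- simulate_caller_calls(tiny_config(seed = 31L))
  sup <- calls$normal_support
  normals <- sort(unique(sup$normal_id))
  prev <- character()
  for (k in seq_along(normals)) {
    sub <- sup[sup$normal_id %in% normals[seq_len(k)], , drop = FALSE]
    bl <- build_normal_panel_blacklist(sub)$variant_id
    expect_true(all(prev %in% bl))
    prev <- bl
  }
})

test_that("filtering matches the brute-force oracle on small cohorts", {
  for (seed in c(1L, 2L, 3L)) {
    cfg <- cohort_config(seed = seed, n_patients = 3L,
                         n_true_variants = 25L, n_artifact_variants = 25L,
                         n_normals = 8L, artifact_reject_prob = 0.5)
    calls <- simulate_caller_calls(cfg)
    obs <- calls$observations
    status <- as.matrix(obs[, cfg$callers])
    accepted <- unique(obs$variant_id[rowSums(status == "pass") >= 2L])
    res <- apply_filters(accepted, list(
      build_normal_panel_blacklist(calls$normal_support),
      build_reject_ratio_blacklist(obs, cfg$callers)
    ))
    expect_setequal(res$kept,
                    brute_force_filter(obs, calls$normal_support,
                                       cfg$callers))
  }
})

test_that("blacklist recall of artifacts rises with the reject probability", {
  recall_at <- function(p) {
    hits <- vapply(1:3, function(seed) {
      cfg <- cohort_config(seed = seed, n_patients = 5L,
                           n_true_variants = 50L,
                           n_artifact_variants = 80L, n_normals = 10L,
                           artifact_reject_prob = p,
                           artifact_panel_frac = 0.3)
      calls <- simulate_caller_calls(cfg)
      bl <- unique(c(
        build_normal_panel_blacklist(calls$normal_support)$variant_id,
        build_reject_ratio_blacklist(calls$observations,
                                     cfg$callers)$variant_id
      ))
      mean(calls$truth$artifact_ids %in% bl)
    }, numeric(1))
    mean(hits)
  }
  recalls <- vapply(c(0.2, 0.5, 0.8), recall_at, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_gt(recalls[3], recalls[1])
})
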