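## Seeded synthetic-cohort generator.
##
## Every pipeline stage consumes fixtures produced here, with ground truth
## recorded so recovery tests can score the filters and estimators exactly.
## A single root seed is expanded into fixed per-stream substreams (calls,
## reads, telomere, catalog, sv, cn, msi) so adding one generator does not
## shift the draws of another.

.default_callers <- c("vardict", "strelka2", "mutect2")

.tvr_patterns <- c(
  "TTAGGG", "TGAGGG", "TCAGGG", "TTGGGG", "GTAGGG",
  "GTTGGG", "TAAGGG", "TTCGGG", "TTTGGG", "CATGGG"
)

# Baseline telomere-repeat composition: canonical TTAGGG dominates, the nine
# variant repeats share the remainder.
.tvr_base_props <- c(
  TTAGGG = 0.900, TGAGGG = 0.030, TCAGGG = 0.015, TTGGGG = 0.015,
  GTAGGG = 0.010, GTTGGG = 0.010, TAAGGG = 0.007, TTCGGG = 0.006,
  TTTGGG = 0.004, CATGGG = 0.003
)

#' Cohort generator configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. Defaults describe a small multi-sample cohort:
#' patients carry one primary and one metastasis, three callers observe each
#' variant independently, technical artifacts recur in a panel of normals,
#' and tumour purity/ploidy vary per sample.
#'
#' @param seed integer root seed; expanded internally into independent
#'   per-generator streams.
#' @param n_patients number of patients.
#' @param samples_per_patient tumour samples per patient (>= 1).
#' @param n_true_variants number of genuine somatic variants in the cohort.
#' @param n_artifact_variants number of recurrent technical artifacts.
#' @param n_normals size of the panel of normals.
#' @param caller_sensitivity named probabilities that each of the three
#'   callers detects a variant present in a sample.
#' @param artifact_reject_prob probability that a caller labels a detected
#'   artifact `reject` rather than `pass`.
#' @param artifact_panel_frac fraction of artifacts that recur with >= 3
#'   supporting reads in more than two panel normals.
#' @param artifact_sample_rate probability an artifact is observed in any
#'   given tumour sample (artifacts recur across samples; true variants are
#'   private to one patient).
#' @param depth_mean mean sequencing depth; per-site depth is
#'   Poisson(`depth_mean`) truncated at 1.
#' @param purity_range tumour purity interval, each sample drawn uniformly.
#' @param ploidy_choices tumour ploidies sampled per sample.
#' @param clone_tree_depth number of clones on the simulated linear clone
#'   chain (child fraction <= parent fraction in every sample).
#' @param signature_mix named weights (summing to 1) over columns of the
#'   signature matrix used by [simulate_signature_catalog()].
#' @param n_catalog_mutations mutations per simulated catalog.
#' @param telomere_scenarios scenario labels recycled over tumour samples;
#'   each must be one of `"normal"`, `"enriched"`, `"alt_like"`.
#' @param telomere_log2_target expected tumour:blood log2 content ratio for
#'   the `enriched` and `alt_like` scenarios (must exceed the 0.5 calling
#'   threshold to be detectable).
#' @param telomere_canonical_reduction multiplicative reduction of the
#'   canonical TTAGGG proportion in `alt_like` samples.
#' @param telomere_rate expected intratelomeric reads per million GC-matched
#'   reads in blood.
#' @param telomere_noise logical; `FALSE` replaces Poisson/multinomial draws
#'   with their expectations (exact ratio recovery).
#' @param gc_matched_total GC-matched read total per sample (fixed).
#' @param total_reads total read count per sample (fixed).
#' @param msi_rate_range microsatellite indels-per-megabase interval.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 6L,
                          samples_per_patient = 2L,
                          n_true_variants = 600L,
                          n_artifact_variants = 400L,
                          n_normals = 20L,
                          caller_sensitivity = c(vardict = 0.95,
                                                 strelka2 = 0.95,
                                                 mutect2 = 0.95),
                          artifact_reject_prob = 0.6,
                          artifact_panel_frac = 0.6,
                          artifact_sample_rate = 0.5,
                          depth_mean = 60,
                          purity_range = c(0.3, 0.9),
                          ploidy_choices = c(2, 2, 2, 3.6),
                          clone_tree_depth = 3L,
                          signature_mix = c(S1 = 0.7, S2 = 0.3),
                          n_catalog_mutations = 10000L,
                          telomere_scenarios = c("normal", "enriched",
                                                 "alt_like"),
                          telomere_log2_target = 1.0,
                          telomere_canonical_reduction = 0.7,
                          telomere_rate = 300,
                          telomere_noise = TRUE,
                          gc_matched_total = 2e6,
                          total_reads = 6e8,
                          msi_rate_range = c(0.1, 1.5)) {
  cfg <- list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    samples_per_patient = as.integer(samples_per_patient),
    n_true_variants = as.integer(n_true_variants),
    n_artifact_variants = as.integer(n_artifact_variants),
    n_normals = as.integer(n_normals),
    callers = names(caller_sensitivity),
    caller_sensitivity = caller_sensitivity,
    artifact_reject_prob = artifact_reject_prob,
    artifact_panel_frac = artifact_panel_frac,
    artifact_sample_rate = artifact_sample_rate,
    depth_mean = depth_mean,
    purity_range = purity_range,
    ploidy_choices = ploidy_choices,
    clone_tree_depth = as.integer(clone_tree_depth),
    signature_mix = signature_mix,
    n_catalog_mutations = as.integer(n_catalog_mutations),
    telomere_scenarios = telomere_scenarios,
    telomere_log2_target = telomere_log2_target,
    telomere_canonical_reduction = telomere_canonical_reduction,
    telomere_rate = telomere_rate,
    telomere_noise = isTRUE(telomere_noise),
    gc_matched_total = gc_matched_total,
    total_reads = total_reads,
    msi_rate_range = msi_rate_range
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  assert_that(inherits(config, "cohort_config"), "not a cohort_config")
  counts_pos <- c("n_patients", "samples_per_patient", "n_normals",
                  "clone_tree_depth")
  for (f in counts_pos) {
    assert_that(is_count(config[[f]]) && config[[f]] >= 1L,
                sprintf("configuration error: %s must be a positive integer", f))
  }
  for (f in c("n_true_variants", "n_artifact_variants",
              "n_catalog_mutations")) {
    assert_that(is_count(config[[f]]) && config[[f]] >= 0L,
                sprintf("configuration error: %s must be a non-negative integer", f))
  }
  assert_that(length(config$caller_sensitivity) == 3L &&
                !is.null(names(config$caller_sensitivity)),
              "configuration error: exactly three named caller sensitivities required")
  for (f in c("caller_sensitivity", "artifact_reject_prob",
              "artifact_panel_frac", "artifact_sample_rate")) {
    assert_that(is_prob(config[[f]]),
                sprintf("configuration error: %s must be in [0, 1]", f))
  }
  assert_that(config$depth_mean > 0,
              "configuration error: depth_mean must be positive")
  assert_that(length(config$purity_range) == 2L &&
                is_prob(config$purity_range) &&
                diff(config$purity_range) >= 0,
              "configuration error: purity_range must be an interval in [0, 1]")
  assert_that(all(config$ploidy_choices > 0),
              "configuration error: ploidy_choices must be positive")
  assert_that(all(config$signature_mix >= 0) &&
                abs(sum(config$signature_mix) - 1) < 1e-9,
              "configuration error: signature_mix weights must be >= 0 and sum to 1")
  assert_that(all(config$telomere_scenarios %in%
                    c("normal", "enriched", "alt_like")),
              "configuration error: unknown telomere scenario label")
  assert_that(length(config$msi_rate_range) == 2L &&
                all(config$msi_rate_range >= 0) &&
                diff(config$msi_rate_range) >= 0,
              "configuration error: msi_rate_range must be a non-negative interval")
  config
}

cohort_sample_ids <- function(config) {
  patients <- sprintf("E%03d", seq_len(config$n_patients))
  samples <- unlist(lapply(patients, function(p) {
    suffix <- c("P1", if (config$samples_per_patient > 1L)
      sprintf("M%d", seq_len(config$samples_per_patient - 1L)))
    paste0(p, "-", suffix)
  }))
  data.frame(sample_id = samples,
             patient_id = rep(patients, each = config$samples_per_patient),
             stringsAsFactors = FALSE)
}

rdepth <- function(n, mean) {
  d <- rpois(n, mean)
  pmax(d, 1L)
}

random_variant_table <- function(n, prefix) {
  if (n == 0L) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  data.frame(
    variant_id = sprintf("%s%05d", prefix, seq_len(n)),
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(1e8L, n, replace = TRUE),
    ref = ref,
    alt = unname(alt),
    stringsAsFactors = FALSE
  )
}

#' Simulate multi-caller somatic call sets with artifact contamination
#'
#' Emits one observation per (variant, tumour sample) carrying the status
#' each of the three callers assigned, together with a panel-of-normals
#' read-support table. True variants are private to one patient and always
#' labelled `pass` when detected; artifacts recur across samples, are
#' labelled `reject` with probability `artifact_reject_prob`, and a
#' configurable fraction of them receive >= 3 supporting reads in more than
#' two panel normals — so both blacklists have exactly computable targets.
#'
#' @param config a [cohort_config()].
#' @return list with elements `observations` (data frame: variant identity,
#'   sample, per-caller status, tumour alt/depth), `normal_support` (data
#'   frame: variant_id, normal_id, reads; absent rows mean zero support),
#'   `samples`, and `truth` (id sets and panel bookkeeping).
#' @export
simulate_caller_calls <- function(config) {
  validate_cohort_config(config)
  samples <- cohort_sample_ids(config)
  with_stream(config$seed, "calls", {
    truevar <- random_variant_table(config$n_true_variants, "TV")
    artvar <- random_variant_table(config$n_artifact_variants, "AR")

    obs <- list()
    # True variants: one patient each, observed in every sample of that
    # patient, pass when detected.
    if (nrow(truevar) > 0L) {
      owner <- sample(unique(samples$patient_id), nrow(truevar), replace = TRUE)
      for (i in seq_len(nrow(truevar))) {
        sids <- samples$sample_id[samples$patient_id == owner[i]]
        for (sid in sids) {
          detected <- runif(3) < config$caller_sensitivity
          status <- ifelse(detected, "pass", "not_called")
          depth <- rdepth(1L, config$depth_mean)
          obs[[length(obs) + 1L]] <- data.frame(
            truevar[i, ], sample_id = sid,
            as.list(setNames(status, config$callers)),
            alt_reads = rbinom(1L, depth, 0.35), depth = depth,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    # Artifacts: recur across samples; reject with stated probability.
    if (nrow(artvar) > 0L) {
      for (i in seq_len(nrow(artvar))) {
        seen <- samples$sample_id[runif(nrow(samples)) <
                                    config$artifact_sample_rate]
        if (length(seen) == 0L)
          seen <- sample(samples$sample_id, 1L)
        for (sid in seen) {
          detected <- runif(3) < config$caller_sensitivity
          status <- ifelse(detected,
                           ifelse(runif(3) < config$artifact_reject_prob,
                                  "reject", "pass"),
                           "not_called")
          depth <- rdepth(1L, config$depth_mean)
          obs[[length(obs) + 1L]] <- data.frame(
            artvar[i, ], sample_id = sid,
            as.list(setNames(status, config$callers)),
            alt_reads = rbinom(1L, depth, 0.08), depth = depth,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    observations <- if (length(obs)) do.call(rbind, obs) else
      data.frame()

    # Panel of normals: a fraction of artifacts recur with >= 3 reads in
    # more than two normals; everything else gets at most sporadic 1-2 read
    # noise so the read-count boundary is exercised.
    support <- list()
    panel_ids <- character()
    if (nrow(artvar) > 0L && config$n_normals >= 3L) {
      in_panel <- runif(nrow(artvar)) < config$artifact_panel_frac
      panel_ids <- artvar$variant_id[in_panel]
      for (vid in panel_ids) {
        k <- sample(3:min(8L, config$n_normals), 1L)
        normals <- sample(config$n_normals, k)
        support[[length(support) + 1L]] <- data.frame(
          variant_id = vid,
          normal_id = sprintf("N%03d", normals),
          reads = 3L + rpois(k, 2),
          stringsAsFactors = FALSE
        )
      }
    }
    # low-level (1-2 read) noise stays confined to artifacts so true
    # variants never appear in the panel and blacklist recall is exact
    off_panel <- setdiff(artvar$variant_id, panel_ids)
    if (length(off_panel)) {
      noisy <- off_panel[runif(length(off_panel)) < 0.25]
      for (vid in noisy) {
        support[[length(support) + 1L]] <- data.frame(
          variant_id = vid,
          normal_id = sprintf("N%03d", sample(config$n_normals, 1L)),
          reads = sample(1:2, 1L),
          stringsAsFactors = FALSE
        )
      }
    }
    normal_support <- if (length(support)) do.call(rbind, support) else
      data.frame(variant_id = character(), normal_id = character(),
                 reads = integer(), stringsAsFactors = FALSE)
    rownames(observations) <- NULL
    rownames(normal_support) <- NULL
    list(
      observations = observations,
      normal_support = normal_support,
      samples = samples,
      truth = list(
        true_variant_ids = truevar$variant_id,
        artifact_ids = artvar$variant_id,
        panel_artifact_ids = panel_ids
      )
    )
  })
}

.cn_states <- list(
  c(1, 1), c(1, 1), c(1, 1), c(2, 1), c(2, 0), c(1, 0), c(2, 2), c(3, 1)
)

#' Simulate allele-specific copy-number segments
#'
#' Tiles six synthetic chromosomes per sample with non-overlapping segments
#' whose (major, minor) states favour the diploid (1, 1) configuration but
#' include losses, copy-neutral LOH, and gains. Purity is drawn uniformly
#' from `purity_range` and ploidy sampled from `ploidy_choices` per sample.
#' Some segments fall under 50 markers so segment joining is exercised.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns sample_id, chrom, start, end, n_markers,
#'   major_cn, minor_cn, purity, sample_ploidy.
#' @export
simulate_cn_segments <- function(config) {
  validate_cohort_config(config)
  samples <- cohort_sample_ids(config)
  with_stream(config$seed, "cn", {
    out <- list()
    for (i in seq_len(nrow(samples))) {
      purity <- runif(1, config$purity_range[1], config$purity_range[2])
      ploidy <- sample(config$ploidy_choices, 1L)
      for (chrom in paste0("chr", 1:6)) {
        n_seg <- sample(1:4, 1L)
        cuts <- sort(sample.int(1e8L - 1L, n_seg - 1L))
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, 1e8L)
        for (j in seq_len(n_seg)) {
          state <- .cn_states[[sample(length(.cn_states), 1L)]]
          out[[length(out) + 1L]] <- data.frame(
            sample_id = samples$sample_id[i],
            chrom = chrom, start = starts[j], end = ends[j],
            n_markers = sample(c(10:49, 50:5000), 1L,
                               prob = c(rep(0.002, 40), rep(1, 4951))),
            major_cn = state[1], minor_cn = state[2],
            purity = purity, sample_ploidy = ploidy,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate clonal read counts for one patient
#'
#' Builds a linear clone chain (child fraction <= parent fraction in every
#' sample), assigns variants to clones, and draws alt reads as
#' Binomial(depth, omega * phi) where omega is the variant read probability
#' implied by the covering copy-number segment (variants are simulated as
#' fully clonal events on the retained allele, so the VAF handed to the
#' rule table exceeds half the purity) and phi is the assigned clone's
#' fraction in the sample. Depth is Poisson(`depth_mean`) truncated at 1.
#'
#' @param config a [cohort_config()]; `samples_per_patient` samples are
#'   generated with ids S1, S2, ...
#' @param segments copy-number segments covering the simulated positions,
#'   with one set per sample (columns as [simulate_cn_segments()]); a
#'   variant outside every segment of a sample is a generation error.
#' @param phi optional clone-by-sample fraction matrix overriding the
#'   simulated clone chain.
#' @param n_variants number of variants (defaults to `n_true_variants`).
#' @return list with `matrix` (a [clonal_variant_matrix()]) and `truth`
#'   (phi matrix, variant clone assignment).
#' @export
simulate_clonal_reads <- function(config, segments, phi = NULL,
                                  n_variants = config$n_true_variants) {
  validate_cohort_config(config)
  sample_ids <- unique(segments$sample_id)
  assert_that(length(sample_ids) >= 1L, "segments carry no samples")
  with_stream(config$seed, "reads", {
    k <- if (is.null(phi)) config$clone_tree_depth else nrow(phi)
    if (is.null(phi)) {
      phi <- matrix(0, k, length(sample_ids),
                    dimnames = list(NULL, sample_ids))
      for (s in seq_along(sample_ids)) {
        phi[1, s] <- runif(1, 0.6, 1)
        for (c in seq_len(k)[-1]) {
          phi[c, s] <- phi[c - 1, s] * runif(1, 0.25, 0.9)
        }
      }
    }
    assignment <- sample.int(k, n_variants, replace = TRUE)
    # positions drawn inside the first sample's segments
    seg1 <- segments[segments$sample_id == sample_ids[1], ]
    pick <- sample.int(nrow(seg1), n_variants, replace = TRUE)
    pos <- seg1$start[pick] +
      floor(runif(n_variants) * (seg1$end[pick] - seg1$start[pick] + 1))
    chrom <- seg1$chrom[pick]
    variant_ids <- sprintf("CV%05d", seq_len(n_variants))

    alt <- total <- vrp <-
      matrix(0, n_variants, length(sample_ids),
             dimnames = list(variant_ids, sample_ids))
    purity <- numeric(length(sample_ids))
    names(purity) <- sample_ids
    for (s in seq_along(sample_ids)) {
      segs <- segments[segments$sample_id == sample_ids[s], ]
      purity[s] <- segs$purity[1]
      for (v in seq_len(n_variants)) {
        hit <- which(segs$chrom == chrom[v] & segs$start <= pos[v] &
                       segs$end >= pos[v])
        assert_that(length(hit) >= 1L,
                    "generation error: variant outside all segments")
        seg <- segs[hit[1], ]
        vrp[v, s] <- variant_read_probability(
          vaf = purity[s], purity = purity[s],
          major = seg$major_cn, minor = seg$minor_cn
        )
        depth <- rdepth(1L, config$depth_mean)
        total[v, s] <- depth
        alt[v, s] <- rbinom(1L, depth, vrp[v, s] * phi[assignment[v], s])
      }
    }
    list(
      matrix = clonal_variant_matrix(alt, total, vrp, purity),
      positions = data.frame(variant_id = variant_ids, chrom = chrom,
                             pos = pos, stringsAsFactors = FALSE),
      truth = list(phi = phi, assignment = assignment,
                   variant_ids = variant_ids)
    )
  })
}

tvr_scenario_props <- function(config, scenario) {
  props <- .tvr_base_props
  if (scenario == "alt_like") {
    canon <- props[["TTAGGG"]] * config$telomere_canonical_reduction
    freed <- props[["TTAGGG"]] - canon
    others <- props[names(props) != "TTAGGG"]
    props <- c(TTAGGG = canon, others + freed * others / sum(others))
  }
  props[.tvr_patterns]
}

#' Simulate telomere read-class count tables
#'
#' Produces a tumour and blood profile per tumour sample. Blood
#' intratelomeric counts follow Poisson draws at `telomere_rate` reads per
#' million GC-matched reads; `enriched` and `alt_like` tumours scale the
#' rate by `2 ^ telomere_log2_target` so the expected log2 tumour:blood
#' content ratio equals the configured target, and `alt_like` additionally
#' reduces the canonical TTAGGG proportion of the telomere-repeat
#' composition. GC-matched and total read counts are fixed per sample.
#' `alt_like` tumours are annotated C-circle positive, all others negative.
#'
#' @param config a [cohort_config()]; scenarios recycled over samples.
#' @return data frame, one row per (sample, role in tumour/blood), with
#'   intratelomeric/GC-matched/total read counts and one `tvr_<pattern>`
#'   column per six-mer repeat.
#' @export
simulate_telomere_profiles <- function(config) {
  validate_cohort_config(config)
  samples <- cohort_sample_ids(config)
  scenarios <- rep_len(config$telomere_scenarios, nrow(samples))
  with_stream(config$seed, "telomere", {
    rows <- list()
    base_mu <- config$telomere_rate * config$gc_matched_total / 1e6
    for (i in seq_len(nrow(samples))) {
      scen <- scenarios[i]
      mult <- if (scen == "normal") 1 else 2^config$telomere_log2_target
      mus <- c(tumour = base_mu * mult, blood = base_mu)
      ccircle <- if (scen == "alt_like") "positive" else "negative"
      for (role in c("tumour", "blood")) {
        tel <- if (config$telomere_noise) rpois(1L, mus[[role]]) else
          round(mus[[role]])
        props <- if (role == "tumour") tvr_scenario_props(config, scen) else
          .tvr_base_props[.tvr_patterns]
        counts <- if (config$telomere_noise)
          as.integer(rmultinom(1L, tel, props)) else round(tel * props)
        row <- data.frame(
          sample_id = samples$sample_id[i],
          patient_id = samples$patient_id[i],
          role = role, scenario = scen, ccircle_status = ccircle,
          intratelomeric_reads = tel,
          gc_matched_total_reads = config$gc_matched_total,
          total_reads = config$total_reads,
          stringsAsFactors = FALSE
        )
        row[paste0("tvr_", .tvr_patterns)] <- as.list(counts)
        rows[[length(rows) + 1L]] <- row
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Simulate a mutation catalog from a signature mixture
#'
#' Draws `n` mutations multinomially from the context-class distribution
#' `signatures %*% mix` and records the ground-truth exposures `n * mix`.
#'
#' @param signatures signature matrix (context classes x signatures, each
#'   column a probability distribution).
#' @param mix named non-negative weights over signature columns, summing
#'   to 1.
#' @param n number of mutations (>= 0).
#' @param seed integer seed.
#' @return list with `catalog` (named integer vector over context classes)
#'   and `true_exposures` (`n * mix`).
#' @export
simulate_signature_catalog <- function(signatures, mix, n, seed) {
  assert_that(all(mix >= 0), "negative signature weights")
  assert_that(abs(sum(mix) - 1) < 1e-9, "signature weights must sum to 1")
  assert_that(is_count(n) && n >= 0, "n must be a non-negative integer")
  assert_that(all(names(mix) %in% colnames(signatures)),
              "mix names must match signature columns")
  p <- as.vector(signatures[, names(mix), drop = FALSE] %*% mix)
  catalog <- withr::with_seed(as.integer(seed), {
    if (n == 0L) rep(0L, nrow(signatures)) else
      as.integer(rmultinom(1L, n, p))
  })
  names(catalog) <- rownames(signatures)
  list(catalog = catalog, true_exposures = n * mix)
}

#' Simulate structural-variant calls
#'
#' Generates per-sample breakpoint pairs with split/paired read support.
#' True SVs are private to a patient and well supported; artifact SVs share
#' exact coordinates across more than two patients (some rejected, some
#' passed) and carry weak support, so the recurrence and read-support
#' filters have computable targets.
#'
#' @param config a [cohort_config()].
#' @param n_true,n_artifact number of true and artifact SVs.
#' @return data frame of SV calls plus a `truth` attribute with id sets.
#' @export
simulate_sv_calls <- function(config, n_true = 40L, n_artifact = 15L) {
  validate_cohort_config(config)
  samples <- cohort_sample_ids(config)
  with_stream(config$seed, "sv", {
    mk_bp <- function(n) {
      data.frame(
        chrom1 = paste0("chr", sample(1:22, n, replace = TRUE)),
        pos1 = sample.int(1e8L, n, replace = TRUE),
        strand1 = sample(c("+", "-"), n, replace = TRUE),
        chrom2 = paste0("chr", sample(1:22, n, replace = TRUE)),
        pos2 = sample.int(1e8L, n, replace = TRUE),
        strand2 = sample(c("+", "-"), n, replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    rows <- list()
    truebp <- mk_bp(n_true)
    true_owner <- sample(unique(samples$patient_id), n_true, replace = TRUE)
    for (i in seq_len(n_true)) {
      sids <- samples$sample_id[samples$patient_id == true_owner[i]]
      for (sid in sids) {
        rows[[length(rows) + 1L]] <- data.frame(
          sv_id = sprintf("SV%04d", i), class = "true",
          patient_id = true_owner[i], sample_id = sid, truebp[i, ],
          split_reads = 2L + rpois(1L, 6), paired_reads = 1L + rpois(1L, 5),
          caller_status = "pass", stringsAsFactors = FALSE
        )
      }
    }
    artbp <- mk_bp(n_artifact)
    patients <- unique(samples$patient_id)
    for (i in seq_len(n_artifact)) {
      n_hit <- sample(3:min(6L, length(patients)), 1L)
      hit <- sample(patients, n_hit)
      for (p in hit) {
        sid <- sample(samples$sample_id[samples$patient_id == p], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          sv_id = sprintf("AS%04d", i), class = "artifact",
          patient_id = p, sample_id = sid, artbp[i, ],
          split_reads = sample(0:2, 1L), paired_reads = sample(0:2, 1L),
          caller_status = sample(c("pass", "reject"), 1L),
          stringsAsFactors = FALSE
        )
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    attr(res, "truth") <- list(
      true_ids = sprintf("SV%04d", seq_len(n_true)),
      artifact_ids = sprintf("AS%04d", seq_len(n_artifact))
    )
    res
  })
}

#' Simulate microsatellite indel burdens
#'
#' Per-sample microsatellite indel rates drawn uniformly from
#' `msi_rate_range` over a fixed callable genome size.
#'
#' @param config a [cohort_config()].
#' @param callable_megabases callable genome size.
#' @return data frame with sample_id, microsatellite_indel_count,
#'   callable_megabases.
#' @export
simulate_msi_inputs <- function(config, callable_megabases = 2800) {
  validate_cohort_config(config)
  samples <- cohort_sample_ids(config)
  with_stream(config$seed, "msi", {
    rate <- runif(nrow(samples), config$msi_rate_range[1],
                  config$msi_rate_range[2])
    data.frame(
      sample_id = samples$sample_id,
      microsatellite_indel_count = as.integer(round(rate *
                                                      callable_megabases)),
      callable_megabases = callable_megabases,
      stringsAsFactors = FALSE
    )
  })
}
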