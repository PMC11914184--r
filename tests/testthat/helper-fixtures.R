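# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures exist on disk.

tiny_config <- function(seed = 42L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_patients = 4L, samples_per_patient = 2L,
         n_true_variants = 40L, n_artifact_variants = 30L,
         n_normals = 10L),
    list(...)
  )
  do.call(cohort_config, args)
}

# single diploid segment covering one chromosome for one or more samples
diploid_segments <- function(sample_ids, purity = 0.8, ploidy = 2) {
  do.call(rbind, lapply(sample_ids, function(s) {
    data.frame(sample_id = s, chrom = "chr1", start = 1L, end = 1e8L,
               n_markers = 1000L, major_cn = 1, minor_cn = 1,
               purity = purity, sample_ploidy = ploidy,
               stringsAsFactors = FALSE)
  }))
}

# literal transcription of the variant-read-probability prose, used as the
# independent oracle for the rule-table implementation
vrp_prose_oracle <- function(vaf, purity, major, minor) {
  total <- major + minor
  if (major == 1 && minor == 1) return(0.5)                  # diploid
  if (total == 1 && vaf > purity / 2) return(1)              # single loss
  if (minor == 0 && total >= 2) {                            # CN-LOH
    if (vaf > purity / 2) return(1)
    return(1 / major)
  }
  1 / total                                                  # other regions
}

# Benjamini-Hochberg step-up written out explicitly (independent of
# stats::p.adjust): adjusted p_i = min over j >= i of m * p_(j) / j
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# exact NNLS oracle by subset enumeration: the NNLS optimum is the least
# feasible unconstrained solution over some support set
nnls_subset_oracle <- function(A, b) {
  n <- ncol(A)
  best <- list(x = numeric(n), residual = sqrt(sum(b^2)))
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    coef <- tryCatch(qr.coef(qr(A[, idx, drop = FALSE]), b),
                     error = function(e) NULL)
    if (is.null(coef) || anyNA(coef) || any(coef < 0)) next
    x <- numeric(n)
    x[idx] <- coef
    r <- sqrt(sum((b - A %*% x)^2))
    if (r < best$residual) best <- list(x = x, residual = r)
  }
  best
}

# brute-force evaluation of consensus + both blacklists, one variant at a
# time, used as the oracle for the filtering stack
brute_force_filter <- function(observations, normal_support,
                               callers = c("vardict", "strelka2", "mutect2"),
                               min_reads = 3L, min_normals = 2L) {
  ids <- unique(observations$variant_id)
  kept <- character()
  for (vid in ids) {
    rows <- observations[observations$variant_id == vid, , drop = FALSE]
    accepted <- FALSE
    n_pass <- 0L
    n_reject <- 0L
    for (i in seq_len(nrow(rows))) {
      st <- unlist(rows[i, callers])
      if (sum(st == "pass") >= 2L) accepted <- TRUE
      n_pass <- n_pass + sum(st == "pass")
      n_reject <- n_reject + sum(st == "reject")
    }
    sup <- normal_support[normal_support$variant_id == vid, , drop = FALSE]
    n_strong <- length(unique(sup$normal_id[sup$reads >= min_reads]))
    panel_hit <- n_strong > min_normals
    ratio_hit <- n_reject > n_pass
    if (accepted && !panel_hit && !ratio_hit) kept <- c(kept, vid)
  }
  kept
}
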