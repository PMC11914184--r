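## Clonal reconstruction preparation: per-patient variant unification with
## the low-support exclusion band, the copy-number-aware variant read
## probability (VRP) rule table, a binomial-mixture EM over clone
## frequencies (a deliberately simplified stand-in for full tree search),
## and shared/private partitioning of paired samples.

#' Clonal variant matrix
#'
#' Container for one patient's variant x sample read counts with per-entry
#' variant read probabilities and per-sample purity.
#'
#' @param alt,total integer matrices (variant x sample), alt <= total.
#' @param vrp matrix of variant read probabilities in (0, 1].
#' @param purity named per-sample purity in (0, 1].
#' @param excluded optional data frame recording variants dropped by the
#'   exclusion band.
#' @return object of class `clonal_variant_matrix`.
#' @export
clonal_variant_matrix <- function(alt, total, vrp = NULL, purity = NULL,
                                  excluded = NULL) {
  alt <- as.matrix(alt)
  total <- as.matrix(total)
  assert_that(all(dim(alt) == dim(total)), "dimension mismatch")
  assert_that(all(alt >= 0) && all(total >= 0) && all(alt <= total),
              "need 0 <= alt <= total elementwise")
  if (!is.null(vrp)) {
    assert_that(all(dim(vrp) == dim(alt)), "vrp dimension mismatch")
    assert_that(all(vrp > 0) && all(vrp <= 1), "vrp must lie in (0, 1]")
  }
  if (!is.null(purity)) {
    assert_that(length(purity) == ncol(alt), "purity length mismatch")
    assert_that(all(purity > 0) && all(purity <= 1),
                "purity must lie in (0, 1]")
  }
  structure(
    list(alt = alt, total = total, vrp = vrp, purity = purity,
         variant_ids = rownames(alt), sample_ids = colnames(alt),
         excluded = excluded),
    class = "clonal_variant_matrix"
  )
}

#' @export
print.clonal_variant_matrix <- function(x, ...) {
  cat(sprintf("clonal_variant_matrix: %d variants x %d samples (%d excluded)\n",
              nrow(x$alt), ncol(x$alt),
              if (is.null(x$excluded)) 0L else nrow(x$excluded)))
  invisible(x)
}

#' Unify recalled variants and apply the low-support exclusion band
#'
#' Takes the complete per-patient recall grid (every variant recalled in
#' every sample of the patient) and excludes a variant from ALL samples
#' when any sample supports it with an ambiguous 1..`min_reads` alt reads:
#' zero reads is unambiguous absence and more than `min_reads` reads is
#' confident presence, but the band between cannot be distinguished from
#' sequencing artifacts.
#'
#' @param grid data frame with columns variant_id, sample_id, alt, total;
#'   every variant x sample combination must be present (ragged grids are
#'   an error).
#' @param min_reads upper edge of the exclusion band (default 3; the band
#'   is inclusive of this value).
#' @return a [clonal_variant_matrix()] of the retained variants, with the
#'   excluded variants recorded in `$excluded`.
#' @export
unify_and_exclude <- function(grid, min_reads = 3L) {
  variants <- sort(unique(grid$variant_id))
  samples <- sort(unique(grid$sample_id))
  assert_that(nrow(grid) == length(variants) * length(samples) &&
                !anyDuplicated(grid[c("variant_id", "sample_id")]),
              "ragged grid: every variant must be recalled in every sample")
  alt <- matrix(0L, length(variants), length(samples),
                dimnames = list(variants, samples))
  total <- alt
  alt[cbind(match(grid$variant_id, variants),
            match(grid$sample_id, samples))] <- grid$alt
  total[cbind(match(grid$variant_id, variants),
              match(grid$sample_id, samples))] <- grid$total
  in_band <- alt >= 1L & alt <= min_reads
  drop <- rowSums(in_band) > 0L
  excluded <- data.frame(
    variant_id = variants[drop],
    reason = rep(sprintf("alt reads in 1..%d in >=1 sample", min_reads),
                 sum(drop)),
    stringsAsFactors = FALSE
  )
  clonal_variant_matrix(alt[!drop, , drop = FALSE],
                        total[!drop, , drop = FALSE],
                        excluded = excluded)
}

#' Copy-number-aware variant read probability
#'
#' The expected allele fraction of a fully clonal variant given the local
#' allele-specific copy number and sample purity:
#' \itemize{
#'   \item diploid segment (major = 1, minor = 1): 0.5;
#'   \item single copy loss (total = 1) with VAF > purity / 2: 1;
#'   \item copy-neutral LOH (minor = 0, total >= 2) with
#'     VAF > purity / 2: 1;
#'   \item copy-neutral LOH with VAF <= purity / 2: 1 / major;
#'   \item every other region type: 1 / total copy number.
#' }
#' A VAF exactly equal to half the purity takes the 1 / major branch (the
#' more conservative, lower probability). Results are clamped to (0, 1].
#'
#' @param vaf observed variant allele fraction (alt / total reads).
#' @param purity sample purity in (0, 1].
#' @param major,minor allele-specific copy numbers (major >= minor >= 0);
#'   total = major + minor must be positive.
#' @return variant read probability in (0, 1] (vectorized).
#' @export
variant_read_probability <- function(vaf, purity, major, minor) {
  n <- max(length(vaf), length(purity), length(major), length(minor))
  vaf <- rep_len(vaf, n)
  purity <- rep_len(purity, n)
  major <- rep_len(major, n)
  minor <- rep_len(minor, n)
  assert_that(all(major >= minor) && all(minor >= 0),
              "need major >= minor >= 0")
  assert_that(all(purity > 0) && all(purity <= 1),
              "purity must lie in (0, 1]")
  assert_that(all(vaf >= 0) && all(vaf <= 1), "VAF must lie in [0, 1]")
  total <- major + minor
  if (any(total <= 0)) {
    stop("undefined-region error: total copy number must be positive",
         call. = FALSE)
  }
  omega <- 1 / total
  high_vaf <- vaf > purity / 2
  loss <- total == 1 & high_vaf
  cnloh <- minor == 0 & total >= 2
  omega[cnloh] <- ifelse(high_vaf[cnloh], 1, 1 / major[cnloh])
  omega[loss] <- 1
  omega[major == 1 & minor == 1] <- 0.5
  pmin(pmax(omega, .Machine$double.eps), 1)
}

#' Attach variant read probabilities from copy-number segments
#'
#' Looks up each variant's covering segment per sample and evaluates
#' [variant_read_probability()] at the observed VAF.
#'
#' @param mat a [clonal_variant_matrix()].
#' @param positions data frame with variant_id, chrom, pos.
#' @param segments per-sample segments (as [simulate_cn_segments()]).
#' @return the matrix with `$vrp` and `$purity` filled.
#' @export
add_vrp <- function(mat, positions, segments) {
  vrp <- matrix(NA_real_, nrow(mat$alt), ncol(mat$alt),
                dimnames = dimnames(mat$alt))
  purity <- setNames(numeric(ncol(mat$alt)), mat$sample_ids)
  pos <- positions[match(mat$variant_ids, positions$variant_id), ]
  for (s in mat$sample_ids) {
    segs <- segments[segments$sample_id == s, ]
    assert_that(nrow(segs) > 0L, paste0("no segments for sample ", s))
    purity[s] <- segs$purity[1]
    for (i in seq_along(mat$variant_ids)) {
      hit <- which(segs$chrom == pos$chrom[i] & segs$start <= pos$pos[i] &
                     segs$end >= pos$pos[i])
      assert_that(length(hit) >= 1L,
                  "variant not covered by any segment")
      seg <- segs[hit[1], ]
      vaf <- if (mat$total[i, s] > 0) mat$alt[i, s] / mat$total[i, s] else 0
      vrp[i, s] <- variant_read_probability(vaf, purity[s], seg$major_cn,
                                            seg$minor_cn)
    }
  }
  clonal_variant_matrix(mat$alt, mat$total, vrp, purity,
                        excluded = mat$excluded)
}

## log-likelihood of variant rows under clone frequencies phi (k x s)
.cluster_loglik_matrix <- function(mat, phi) {
  k <- nrow(phi)
  eps <- 1e-12
  ll <- matrix(0, nrow(mat$alt), k)
  for (c in seq_len(k)) {
    p <- sweep(mat$vrp, 2L, phi[c, ], "*")
    p <- pmin(pmax(p, eps), 1 - eps)
    ll[, c] <- rowSums(dbinom(mat$alt, mat$total, p, log = TRUE))
  }
  ll
}

## weighted binomial MLE for one (cluster, sample) frequency: maximize
## sum_v r_v [a_v log(w_v phi) + (n_v - a_v) log(1 - w_v phi)] over [0, 1]
.fit_phi_one <- function(alt, total, vrp, weights) {
  if (sum(weights * alt) <= 0) return(0)
  if (all(alt == total)) return(1)
  obj <- function(phi) {
    p <- pmin(pmax(vrp * phi, 1e-12), 1 - 1e-12)
    sum(weights * (alt * log(p) + (total - alt) * log1p(-p)))
  }
  opt <- optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-9)
  # optimize() never evaluates the endpoints; keep them in contention
  cand <- c(opt$maximum, 0, 1)
  cand[which.max(vapply(cand, obj, numeric(1)))]
}

#' Binomial-mixture clustering of clone frequencies
#'
#' Expectation-maximization over the mixture
#' `alt[v, s] ~ Binomial(total[v, s], vrp[v, s] * phi[c(v), s])`: a
#' simplified, recovery-validated stand-in for full clone-tree inference.
#' The E-step computes variant-to-cluster responsibilities; the M-step
#' refits each cluster-sample frequency by one-dimensional weighted
#' binomial maximum likelihood. The observed-data log-likelihood is
#' non-decreasing across iterations. A fixed multi-start schedule derived
#' from `seed` makes the result deterministic.
#'
#' @param mat a [clonal_variant_matrix()] with `$vrp` populated.
#' @param k number of clusters (1 <= k <= number of variants).
#' @param seed integer seed for the multi-start schedule.
#' @param n_starts random restarts (default 5).
#' @param max_iter,tol EM stopping controls.
#' @return list of class `clone_model`: `phi` (k x samples), `assignment`
#'   (hard max-responsibility labels), `pi` (mixing weights), `loglik`,
#'   `loglik_trace` of the best start.
#' @export
cluster_frequencies <- function(mat, k, seed = 1L, n_starts = 5L,
                                max_iter = 200L, tol = 1e-8) {
  assert_that(inherits(mat, "clonal_variant_matrix"), "need a clonal_variant_matrix")
  assert_that(!is.null(mat$vrp), "vrp must be populated (see add_vrp)")
  n <- nrow(mat$alt)
  s <- ncol(mat$alt)
  assert_that(is_count(k) && k >= 1L && k <= n,
              "k must lie in 1..number of variants")
  best <- NULL
  for (start in seq_len(n_starts)) {
    phi <- withr::with_seed(
      as.integer((as.numeric(seed) * 131 + start) %% 2147483647),
      matrix(runif(k * s, 0.05, 0.95), k, s)
    )
    pi_c <- rep(1 / k, k)
    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      ll <- .cluster_loglik_matrix(mat, phi)
      lw <- sweep(ll, 2L, log(pi_c), "+")
      norm <- apply(lw, 1L, logsumexp)
      loglik <- sum(norm)
      trace <- c(trace, loglik)
      resp <- exp(lw - norm)
      pi_c <- pmax(colMeans(resp), 1e-12)
      pi_c <- pi_c / sum(pi_c)
      for (c in seq_len(k)) {
        for (j in seq_len(s)) {
          phi[c, j] <- .fit_phi_one(mat$alt[, j], mat$total[, j],
                                    mat$vrp[, j], resp[, c])
        }
      }
      if (loglik - prev < tol && iter > 1L) break
      prev <- loglik
    }
    ll <- .cluster_loglik_matrix(mat, phi)
    lw <- sweep(ll, 2L, log(pi_c), "+")
    final <- sum(apply(lw, 1L, logsumexp))
    if (is.null(best) || final > best$loglik) {
      best <- list(phi = phi, pi = pi_c,
                   assignment = apply(lw, 1L, which.max),
                   loglik = final, loglik_trace = trace)
    }
  }
  colnames(best$phi) <- mat$sample_ids
  names(best$assignment) <- mat$variant_ids
  class(best) <- "clone_model"
  best
}

#' @export
print.clone_model <- function(x, ...) {
  cat(sprintf("clone_model: %d clusters, loglik %.3f\n", nrow(x$phi),
              x$loglik))
  print(round(x$phi, 3))
  invisible(x)
}

#' Shared/private variant partition for a sample pair
#'
#' After unification, a variant is detected in a sample when its alt reads
#' strictly exceed `min_reads` (consistent with the exclusion band, which
#' removed every in-between case); shared variants are detected in both
#' samples, private variants in exactly one.
#'
#' @param mat a two-sample [clonal_variant_matrix()].
#' @param min_reads detection threshold (strict; default 3).
#' @return list with counts `shared`, `private_a`, `private_b` and a
#'   per-variant `category` vector.
#' @export
partition_shared_private <- function(mat, min_reads = 3L) {
  assert_that(ncol(mat$alt) == 2L, "exactly two samples required")
  det <- mat$alt > min_reads
  category <- ifelse(det[, 1] & det[, 2], "shared",
                     ifelse(det[, 1], "private_a",
                            ifelse(det[, 2], "private_b", "absent")))
  names(category) <- mat$variant_ids
  list(
    shared = sum(category == "shared"),
    private_a = sum(category == "private_a"),
    private_b = sum(category == "private_b"),
    category = category
  )
}
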