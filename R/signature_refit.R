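## Mutational signature refitting: SBS-96 catalog construction from variant
## lists plus a reference sequence, non-negative least-squares fitting of
## catalogs against a signature matrix, and the cohort reporting thresholds.

.sbs_substitutions <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.dna_bases <- c("A", "C", "G", "T")

#' SBS-96 context class labels
#'
#' The 96 pyrimidine-centric trinucleotide classes in the conventional
#' order: substitutions C>A, C>G, C>T, T>A, T>C, T>G, each with 5' and 3'
#' flanking bases cycling alphabetically.
#'
#' @return character vector of 96 labels like `"A[C>A]A"`.
#' @export
sbs96_classes <- function() {
  unlist(lapply(.sbs_substitutions, function(sub) {
    unlist(lapply(.dna_bases, function(five) {
      paste0(five, "[", sub, "]", .dna_bases)
    }))
  }))
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), character(1)))
}

#' SBS-96 context class of a single-base substitution
#'
#' Extracts the trinucleotide context around `pos` from the reference
#' sequence and maps purine-centred substitutions onto the reverse
#' complement strand so the mutated base is always C or T.
#'
#' @param chrom chromosome name (must index `reference`).
#' @param pos 1-based position of the substituted base.
#' @param ref,alt single reference and alternate bases (ref != alt).
#' @param reference named character vector (or anything coercible with
#'   `as.character`, e.g. a `DNAStringSet`) of chromosome sequences.
#' @return one SBS-96 class label.
#' @export
sbs96_context <- function(chrom, pos, ref, alt, reference) {
  assert_that(!identical(ref, alt), "ref and alt must differ")
  assert_that(nchar(ref) == 1L && nchar(alt) == 1L,
              "single-base substitution required")
  seqs <- vapply(as.list(reference), as.character, character(1))
  assert_that(chrom %in% names(seqs), "chromosome absent from reference")
  seq <- seqs[[chrom]]
  assert_that(pos >= 2L && pos <= nchar(seq) - 1L,
              "position too close to the contig edge for a trinucleotide")
  context <- substr(seq, pos - 1L, pos + 1L)
  assert_that(substr(context, 2L, 2L) == ref,
              "data error: ref allele does not match reference sequence")
  if (ref %in% c("A", "G")) {
    context <- unname(revcomp(context))
    ref <- chartr("ACGT", "TGCA", ref)
    alt <- chartr("ACGT", "TGCA", alt)
  }
  paste0(substr(context, 1L, 1L), "[", ref, ">", alt, "]",
         substr(context, 3L, 3L))
}

#' Build an SBS-96 catalog from a variant table
#'
#' @param variants data frame with columns chrom, pos, ref, alt (single
#'   base substitutions only).
#' @param reference named character vector of chromosome sequences.
#' @return named integer vector over [sbs96_classes()].
#' @export
build_sbs96_catalog <- function(variants, reference) {
  classes <- sbs96_classes()
  counts <- setNames(integer(length(classes)), classes)
  if (nrow(variants) > 0L) {
    labels <- vapply(seq_len(nrow(variants)), function(i) {
      sbs96_context(variants$chrom[i], variants$pos[i], variants$ref[i],
                    variants$alt[i], reference)
    }, character(1))
    tab <- table(factor(labels, levels = classes))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Minimizes `||A x - b||_2` subject to `x >= 0`. Deterministic; the active
#' set update uses the standard gradient tolerance.
#'
#' @param A matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol gradient tolerance for entering the passive set.
#' @return list with `x` (solution) and `residual` (Euclidean norm).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- as.vector(crossprod(A, b))
  outer_iter <- 0L
  max_outer <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol &&
           outer_iter < max_outer) {
    outer_iter <- outer_iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      sol <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      sol[is.na(sol)] <- 0
      z[passive] <- sol
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      infeasible <- passive & z <= tol
      alpha <- min(x[infeasible] / (x[infeasible] - z[infeasible]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Refit a mutation catalog against reference signatures
#'
#' Estimates the optimal non-negative linear combination of signature
#' columns reconstructing the observed catalog (non-negative least
#' squares). Exposures are on the mutation-count scale.
#'
#' @param catalog named count vector over context classes (or a one-column
#'   matrix).
#' @param signatures signature matrix, context classes x signatures; each
#'   column a probability distribution (sums to 1 within 1e-6).
#' @return list with `exposures` (named, >= 0), `residual` (Euclidean norm
#'   of the reconstruction error) and `fitted` (reconstructed catalog).
#' @export
fit_exposures <- function(catalog, signatures) {
  signatures <- as.matrix(signatures)
  m <- as.numeric(drop(as.matrix(catalog)))
  assert_that(length(m) == nrow(signatures),
              "scheme mismatch: catalog and signature classes differ")
  if (!is.null(names(catalog)) && !is.null(rownames(signatures))) {
    assert_that(identical(names(catalog), rownames(signatures)),
                "scheme mismatch: class labels differ or are reordered")
  }
  colsum <- colSums(signatures)
  assert_that(all(colsum > 0), "all-zero signature column")
  assert_that(all(abs(colsum - 1) < 1e-6),
              "signature columns must each sum to 1")
  assert_that(all(signatures >= 0) && all(m >= 0),
              "negative entries not allowed")
  fit <- nnls_fit(signatures, m)
  exposures <- setNames(fit$x, colnames(signatures))
  list(exposures = exposures, residual = fit$residual,
       fitted = drop(signatures %*% fit$x))
}

#' Refit every sample of a catalog matrix
#'
#' @param catalogs matrix, context classes x samples.
#' @param signatures signature matrix as in [fit_exposures()].
#' @return matrix of exposures, signatures x samples, with residuals in
#'   attribute `residuals`.
#' @export
fit_exposures_matrix <- function(catalogs, signatures) {
  catalogs <- as.matrix(catalogs)
  fits <- lapply(seq_len(ncol(catalogs)), function(j) {
    fit_exposures(catalogs[, j], signatures)
  })
  exposures <- vapply(fits, `[[`, numeric(ncol(signatures)), "exposures")
  exposures <- matrix(exposures, ncol = ncol(catalogs),
                      dimnames = list(colnames(signatures),
                                      colnames(catalogs)))
  attr(exposures, "residuals") <- vapply(fits, `[[`, numeric(1), "residual")
  exposures
}

.scheme_min_mutations <- c(SBS96 = 500, ID83 = 50, DBS78 = 10)

#' Cohort-level signature reporting
#'
#' A signature is reported when, in at least one sample, its fitted
#' exposure reaches 15% of that sample's total fitted exposure AND the
#' scheme-specific absolute minimum (500 mutations for SBS, 50 for ID, 10
#' for DBS). Reported signatures are ranked by mean proportional
#' contribution across samples, ties broken by signature id.
#'
#' @param exposures matrix, signatures x samples, of fitted exposures.
#' @param scheme one of `"SBS96"`, `"ID83"`, `"DBS78"`.
#' @param min_proportion per-sample proportion threshold (default 0.15).
#' @return data frame of reported signatures with mean proportions, ranked.
#' @export
report_signatures <- function(exposures, scheme = c("SBS96", "ID83",
                                                    "DBS78"),
                              min_proportion = 0.15) {
  scheme <- match.arg(scheme)
  min_count <- .scheme_min_mutations[[scheme]]
  exposures <- as.matrix(exposures)
  totals <- colSums(exposures)
  props <- sweep(exposures, 2L, ifelse(totals > 0, totals, 1), "/")
  qualifies <- (props >= min_proportion) & (exposures >= min_count)
  reported <- rownames(exposures)[rowSums(qualifies) > 0L]
  mean_prop <- rowMeans(props)[reported]
  ord <- order(-mean_prop, reported)
  data.frame(signature = reported[ord],
             mean_proportion = unname(mean_prop[ord]),
             stringsAsFactors = FALSE)
}

#' Synthetic reference signature matrix
#'
#' Deterministically constructs `k` synthetic signature columns over the
#' SBS-96 classes (Dirichlet-like draws from a fixed seed, each column
#' normalized to sum to 1). This stands in for a reference signature
#' database so tests and demos need no external download; it is labelled
#' synthetic and carries no biological meaning.
#'
#' @param k number of signatures.
#' @param seed integer seed.
#' @param concentration sparsity of each column (smaller = spikier).
#' @return matrix, 96 x k, columns named S1..Sk.
#' @export
synthetic_signature_matrix <- function(k = 5L, seed = 20260909L,
                                       concentration = 0.3) {
  classes <- sbs96_classes()
  withr::with_seed(as.integer(seed), {
    g <- matrix(stats::rgamma(length(classes) * k, shape = concentration),
                nrow = length(classes))
    S <- sweep(g, 2L, colSums(g), "/")
    dimnames(S) <- list(classes, paste0("S", seq_len(k)))
    S
  })
}

#' Load the bundled synthetic signature matrix
#'
#' @return matrix, 96 classes x 5 synthetic signatures.
#' @export
load_synthetic_signatures <- function() {
  path <- system.file("extdata", "synthetic_signatures_sbs96.tsv",
                      package = "pcpgsomatics")
  tab <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(tab)
}
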