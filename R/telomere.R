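## Telomere content, tumour:blood enrichment, telomere-variant-repeat (TVR)
## differential usage between C-circle positive and negative tumours, and
## TERRA quantitation (same content formula applied to transcriptome counts).

#' Telomere content
#'
#' Intratelomeric read count times one million divided by the number of
#' reads with telomere-like GC composition. The same formula serves WGS
#' telomere content and WTS TERRA content.
#'
#' @param intratelomeric_reads intratelomeric (telomere-sequence) reads.
#' @param gc_matched_total_reads GC-matched read total (> 0).
#' @return content in reads per GC-matched million (vectorized).
#' @export
telomere_content <- function(intratelomeric_reads, gc_matched_total_reads) {
  assert_that(all(gc_matched_total_reads > 0),
              "zero GC-matched denominator")
  assert_that(all(intratelomeric_reads >= 0), "negative read counts")
  intratelomeric_reads * 1e6 / gc_matched_total_reads
}

#' Tumour:blood telomere enrichment
#'
#' Telomeric enrichment is a log2 ratio of tumour to blood telomere
#' content strictly greater than the threshold (default 0.5); a ratio of
#' exactly 0.5 is not enriched.
#'
#' @param content_tumour,content_blood telomere contents (> 0).
#' @param threshold log2-ratio calling threshold.
#' @return list with `log2_ratio` and `enriched` (vectorized).
#' @export
enrichment_ratio <- function(content_tumour, content_blood,
                             threshold = 0.5) {
  assert_that(all(content_blood > 0) && all(content_tumour > 0),
              "undefined ratio: telomere content must be positive")
  ratio <- log2(content_tumour / content_blood)
  list(log2_ratio = ratio, enriched = ratio > threshold)
}

#' Proportion of canonical TTAGGG repeats
#'
#' @param ttaggg_count reads assigned to the canonical TTAGGG repeat.
#' @param intratelomeric_reads total intratelomeric reads (> 0).
#' @return proportion in \[0, 1\] (vectorized).
#' @export
canonical_tvr_proportion <- function(ttaggg_count, intratelomeric_reads) {
  assert_that(all(intratelomeric_reads > 0), "zero telomeric reads")
  assert_that(all(ttaggg_count >= 0) &&
                all(ttaggg_count <= intratelomeric_reads),
              "TTAGGG count must lie in [0, intratelomeric_reads]")
  ttaggg_count / intratelomeric_reads
}

#' TVR differential usage between C-circle groups
#'
#' For every TVR pattern: per-sample counts are normalized against either
#' the intratelomeric or the total read count, the tumour/blood ratio of
#' normalized counts is formed per pair, and the ratios of C-circle
#' positive tumours are compared to those of C-circle negative tumours
#' with a two-tailed two-sample t-test (Welch by default; set
#' `var_equal = TRUE` for the pooled-variance test). Raw p-values are
#' flagged at p < 0.05 and Benjamini-Hochberg adjusted p-values at
#' p_BH < 0.1. Candidate TVRs are conventionally selected on the
#' total-read normalization.
#'
#' @param profiles data frame as produced by
#'   [simulate_telomere_profiles()]: one row per (sample, role) with
#'   `tvr_<pattern>` columns, `intratelomeric_reads`, `total_reads` and
#'   `ccircle_status`; tumour and blood rows paired by `sample_id`.
#' @param normalization `"total"` or `"intratelomeric"` denominator.
#' @param var_equal passed to [stats::t.test()].
#' @return data frame: tvr, normalization, group means, t, p, p_bh,
#'   sig_raw (p < 0.05), sig_bh (p_BH < 0.1). Degenerate comparisons
#'   (constant values) yield NA statistics.
#' @export
tvr_differential <- function(profiles,
                             normalization = c("total", "intratelomeric"),
                             var_equal = FALSE) {
  normalization <- match.arg(normalization)
  tvr_cols <- grep("^tvr_", names(profiles), value = TRUE)
  assert_that(length(tvr_cols) > 0L, "no tvr_ columns in profiles")
  tum <- profiles[profiles$role == "tumour", ]
  blo <- profiles[profiles$role == "blood", ]
  blo <- blo[match(tum$sample_id, blo$sample_id), ]
  assert_that(!anyNA(blo$sample_id), "unpaired tumour sample")
  denom <- function(x) {
    if (normalization == "intratelomeric") x$intratelomeric_reads else
      x$total_reads
  }
  pos <- tum$ccircle_status == "positive"
  assert_that(sum(pos) >= 2L && sum(!pos) >= 2L,
              "need at least two pairs per C-circle group")
  rows <- lapply(tvr_cols, function(col) {
    ratio <- (tum[[col]] / denom(tum)) / (blo[[col]] / denom(blo))
    a <- ratio[pos]
    b <- ratio[!pos]
    tt <- tryCatch(
      t.test(a, b, var.equal = var_equal),
      error = function(e) NULL
    )
    data.frame(
      tvr = sub("^tvr_", "", col),
      normalization = normalization,
      mean_ccircle_pos = mean(a),
      mean_ccircle_neg = mean(b),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res$p_bh <- p.adjust(res$p, method = "BH")
  res$sig_raw <- !is.na(res$p) & res$p < 0.05
  res$sig_bh <- !is.na(res$p_bh) & res$p_bh < 0.1
  res
}
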