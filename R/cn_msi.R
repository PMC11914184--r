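## Copy-number derived metrics: GISTIC input transform and small-segment
## joining, percent genome altered relative to sample ploidy, and
## microsatellite-instability scoring.

#' GISTIC input transform
#'
#' Log2 of the segmental total copy number incremented by a small offset,
#' minus one, centring the diploid state near zero:
#' `log2(CN + 0.01) - 1`. CN = 0 is valid and maps to about -7.644.
#'
#' @param total_cn total copy number (major + minor), >= 0 (vectorized).
#' @param offset the small offset (default 0.01).
#' @return transformed value(s).
#' @export
gistic_transform <- function(total_cn, offset = 0.01) {
  assert_that(all(total_cn >= 0), "negative copy number")
  log2(total_cn + offset) - 1
}

#' Join small copy-number segments
#'
#' Repeatedly merges the smallest below-threshold segment of each
#' (sample, chromosome) into the flanking neighbour whose total copy
#' number is closer (ties go to the left neighbour). The merged segment
#' spans the union of coordinates, sums markers, and carries the
#' marker-weighted mean major/minor copy numbers — so total marker count
#' and the marker-weighted mean CN per chromosome are conserved. A
#' chromosome whose entire marker count is below threshold collapses to a
#' single segment and is retained.
#'
#' @param segments data frame with sample_id, chrom, start, end,
#'   n_markers, major_cn, minor_cn (sorted by coordinate within
#'   chromosome; other columns carried from the first constituent).
#' @param min_markers joining threshold (default 50).
#' @return joined data frame.
#' @export
join_small_segments <- function(segments, min_markers = 50L) {
  if (nrow(segments) == 0L) return(segments)
  pieces <- split(segments,
                  list(segments$sample_id, segments$chrom), drop = TRUE)
  joined <- lapply(pieces, function(seg) {
    assert_that(!is.unsorted(seg$start),
                "unsorted input: segments must be ordered by start")
    while (nrow(seg) > 1L && min(seg$n_markers) < min_markers) {
      i <- which.min(seg$n_markers)
      cn <- seg$major_cn + seg$minor_cn
      left <- if (i > 1L) abs(cn[i - 1L] - cn[i]) else Inf
      right <- if (i < nrow(seg)) abs(cn[i + 1L] - cn[i]) else Inf
      j <- if (left <= right) i - 1L else i + 1L
      lo <- min(i, j)
      hi <- max(i, j)
      w <- seg$n_markers[c(lo, hi)]
      merged <- seg[lo, ]
      merged$start <- min(seg$start[c(lo, hi)])
      merged$end <- max(seg$end[c(lo, hi)])
      merged$n_markers <- sum(w)
      merged$major_cn <- sum(seg$major_cn[c(lo, hi)] * w) / sum(w)
      merged$minor_cn <- sum(seg$minor_cn[c(lo, hi)] * w) / sum(w)
      seg <- rbind(
        if (lo > 1L) seg[seq_len(lo - 1L), ],
        merged,
        if (hi < nrow(seg)) seg[seq(hi + 1L, nrow(seg)), ]
      )
    }
    seg
  })
  res <- do.call(rbind, joined)
  rownames(res) <- NULL
  res
}

#' Percent genome altered relative to sample ploidy
#'
#' Fraction (as a percentage) of the covered autosomal genome whose total
#' copy number deviates from the sample's rounded ploidy by more than 0.5
#' — so a tetraploid sample's CN-4 segments count as unaltered. Gains and
#' losses are judged relative to ploidy, not to the diploid state.
#'
#' @param segments one sample's segments with major_cn, minor_cn, start,
#'   end, chrom and sample_ploidy columns.
#' @param autosomes_only drop chrX/chrY before scoring (default TRUE).
#' @return percentage in \[0, 100\].
#' @export
percent_genome_altered <- function(segments, autosomes_only = TRUE) {
  if (autosomes_only) {
    segments <- segments[!segments$chrom %in%
                           c("chrX", "chrY", "X", "Y"), , drop = FALSE]
  }
  len <- segments$end - segments$start + 1
  assert_that(sum(len) > 0, "zero covered length")
  ploidy <- segments$sample_ploidy[1]
  total_cn <- segments$major_cn + segments$minor_cn
  altered <- abs(total_cn - round(ploidy)) > 0.5
  100 * sum(len[altered]) / sum(len)
}

#' Microsatellite instability score
#'
#' Microsatellite indels per callable megabase; samples strictly above the
#' threshold (default 4 indels/Mb, the caller's default) are MSI.
#'
#' @param microsatellite_indel_count indel count in microsatellite regions.
#' @param callable_megabases callable genome size in Mb (> 0).
#' @param threshold indels/Mb cutoff (strict inequality).
#' @return list with `score` (indels/Mb) and `msi` (logical), vectorized.
#' @export
msi_score <- function(microsatellite_indel_count, callable_megabases,
                      threshold = 4.0) {
  assert_that(all(callable_megabases > 0), "zero callable denominator")
  assert_that(all(microsatellite_indel_count >= 0), "negative indel count")
  score <- microsatellite_indel_count / callable_megabases
  list(score = score, msi = score > threshold)
}

#' Write segments as a GISTIC-ready SEG file
#'
#' Applies [join_small_segments()] then [gistic_transform()] and writes the
#' six-column SEG layout (sample, chromosome, start, end, marker count,
#' transformed value).
#'
#' @param segments data frame of per-sample segments.
#' @param path output path.
#' @param min_markers joining threshold.
#' @return the written data frame, invisibly.
#' @export
write_gistic_seg <- function(segments, path, min_markers = 50L) {
  joined <- join_small_segments(segments, min_markers)
  out <- data.frame(
    Sample = joined$sample_id,
    Chromosome = joined$chrom,
    Start = joined$start,
    End = joined$end,
    Num_Probes = joined$n_markers,
    Segment_Mean = gistic_transform(joined$major_cn + joined$minor_cn),
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
  invisible(out)
}
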