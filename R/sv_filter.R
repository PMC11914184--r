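## Structural-variant artifact filters: cohort recurrence blacklist (exact
## breakpoint coordinates, counted per patient) and a minimum read-support
## rule on split/paired evidence.

#' Canonical breakpoint-pair key for an SV call
#'
#' Orders the two breakends so the lower coordinate comes first and joins
#' chromosome, position and orientation of both ends into a single string.
#' Exact-coordinate matching (including orientation) is intentional: the
#' recurrence filter targets alignment artifacts that reproduce byte-level
#' identical calls, not biological events in a fuzzy window.
#'
#' @param calls data frame with columns chrom1, pos1, strand1, chrom2,
#'   pos2, strand2.
#' @return character vector of keys.
#' @export
sv_key <- function(calls) {
  flip <- calls$chrom2 < calls$chrom1 |
    (calls$chrom2 == calls$chrom1 & calls$pos2 < calls$pos1)
  a <- ifelse(flip,
              paste(calls$chrom2, calls$pos2, calls$strand2, sep = ":"),
              paste(calls$chrom1, calls$pos1, calls$strand1, sep = ":"))
  b <- ifelse(flip,
              paste(calls$chrom1, calls$pos1, calls$strand1, sep = ":"),
              paste(calls$chrom2, calls$pos2, calls$strand2, sep = ":"))
  paste(a, b, sep = "|")
}

#' SV recurrence blacklist
#'
#' An SV key observed — whether ultimately rejected or passed — in strictly
#' more than `max_samples` unrelated samples (distinct patients; multiple
#' samples from one patient count once) is blacklisted.
#'
#' @param calls data frame of SV calls including rejected records, with
#'   breakpoint columns (see [sv_key()]) and `patient_id`.
#' @param max_samples blacklist when distinct patients strictly exceed
#'   this count (default 2).
#' @return character vector of blacklisted SV keys.
#' @export
build_sv_recurrence_blacklist <- function(calls, max_samples = 2L) {
  if (nrow(calls) == 0L) return(character())
  keys <- sv_key(calls)
  per_patient <- unique(data.frame(key = keys,
                                   patient = calls$patient_id,
                                   stringsAsFactors = FALSE))
  counts <- table(per_patient$key)
  names(counts)[counts > max_samples]
}

#' SV read-support filter
#'
#' A call passes with a minimum of three supporting split reads, or three
#' paired reads, or a combination of at least one split and one paired
#' read.
#'
#' @param split_reads,paired_reads non-negative read counts (vectorized).
#' @return logical vector.
#' @export
sv_support_filter <- function(split_reads, paired_reads) {
  assert_that(all(split_reads >= 0) && all(paired_reads >= 0),
              "negative read counts")
  split_reads >= 3L | paired_reads >= 3L |
    (split_reads >= 1L & paired_reads >= 1L)
}

#' Apply both SV filters
#'
#' @param calls data frame of SV calls (pass-filter candidates).
#' @param blacklist keys from [build_sv_recurrence_blacklist()].
#' @return `calls` restricted to rows passing the support filter and not on
#'   the recurrence blacklist, with a `filter` column recording the fate of
#'   removed rows in the attribute `removed`.
#' @export
apply_sv_filters <- function(calls, blacklist = character()) {
  if (nrow(calls) == 0L) return(calls)
  keys <- sv_key(calls)
  support_ok <- sv_support_filter(calls$split_reads, calls$paired_reads)
  recurrent <- keys %in% blacklist
  kept <- calls[support_ok & !recurrent, , drop = FALSE]
  removed <- calls[!(support_ok & !recurrent), , drop = FALSE]
  if (nrow(removed)) {
    removed$filter <- paste0(
      ifelse(!support_ok[!(support_ok & !recurrent)], "min_support", ""),
      ifelse(recurrent[!(support_ok & !recurrent)], ",recurrent", "")
    )
    removed$filter <- sub("^,", "", removed$filter)
  }
  attr(kept, "removed") <- removed
  kept
}
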