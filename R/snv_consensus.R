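## Somatic SNV/indel consensus and cohort blacklists.
##
## Acceptance rule: a variant is somatic if at least two of the three
## configured callers flag it pass. Two cohort-level blacklists then remove
## recurrent technical artifacts: (1) variants supported by >= 3 reads in
## more than two panel normals, and (2) variants whose pooled reject:pass
## ratio across all samples and callers exceeds one.

#' Normalize a variant key
#'
#' Collapses equivalent representations of the same allele so observations
#' from different callers match: shared trailing bases are trimmed first,
#' then shared leading bases (advancing the position), leaving a minimal
#' left-aligned (chrom, pos, ref, alt) key. Multi-allelic records must be
#' decomposed to biallelic observations before this is applied.
#'
#' @param chrom chromosome.
#' @param pos 1-based position.
#' @param ref,alt reference and alternate alleles (ref != alt).
#' @return list with normalized chrom, pos, ref, alt and a `key` string
#'   `"chrom:pos:ref:alt"`.
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt) {
  assert_that(pos >= 1, "pos must be >= 1")
  assert_that(!identical(ref, alt), "ref and alt must differ")
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  ref <- paste(r, collapse = "")
  alt <- paste(a, collapse = "")
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = paste(chrom, pos, ref, alt, sep = ":"))
}

#' Two-of-three caller consensus
#'
#' A candidate variant is accepted as somatic if it was flagged `pass` by
#' at least two of the three callers; `reject` and `not_called` statuses do
#' not count towards the consensus.
#'
#' @param statuses named character vector of per-caller status, each one of
#'   `"pass"`, `"reject"`, `"not_called"`.
#' @param callers the configured caller names (exactly three).
#' @return logical scalar.
#' @export
consensus_accept <- function(statuses,
                             callers = c("vardict", "strelka2", "mutect2")) {
  assert_that(length(callers) == 3L, "exactly three callers must be configured")
  if (!is.null(names(statuses))) {
    unknown <- setdiff(names(statuses), callers)
    assert_that(length(unknown) == 0L,
                paste0("configuration error: unknown caller ",
                       paste(unknown, collapse = ", ")))
  }
  assert_that(length(statuses) == 3L, "three caller statuses required")
  assert_that(all(statuses %in% c("pass", "reject", "not_called")),
              "status must be pass, reject or not_called")
  sum(statuses == "pass") >= 2L
}

#' Panel-of-normals blacklist
#'
#' A variant is blacklisted when it is supported by at least `min_reads`
#' reads in strictly more than `min_normals` normal controls. With the
#' defaults this is the "three or more reads in more than two normals"
#' rule; exactly two supporting normals is therefore kept.
#'
#' @param normal_support data frame with columns `variant_id` (or
#'   `variant_key`), `normal_id`, `reads`; variants with no rows have zero
#'   support everywhere.
#' @param min_reads minimum supporting reads per normal (default 3).
#' @param min_normals blacklist when supporting normals strictly exceed
#'   this count (default 2).
#' @return data frame of blacklist entries: variant_id, source
#'   (`"normal_panel"`), n_normals_supporting.
#' @export
build_normal_panel_blacklist <- function(normal_support, min_reads = 3L,
                                         min_normals = 2L) {
  idcol <- if ("variant_id" %in% names(normal_support)) "variant_id" else
    "variant_key"
  empty <- data.frame(variant_id = character(), source = character(),
                      n_normals_supporting = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(normal_support) == 0L) return(empty)
  assert_that(all(normal_support$reads >= 0), "negative read counts")
  strong <- normal_support[normal_support$reads >= min_reads, ]
  if (nrow(strong) == 0L) return(empty)
  counts <- table(strong[[idcol]])
  hit <- counts[counts > min_normals]
  if (length(hit) == 0L) return(empty)
  data.frame(variant_id = names(hit), source = "normal_panel",
             n_normals_supporting = as.integer(hit),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reject:pass ratio blacklist
#'
#' Pools every observation of a variant over all samples and callers —
#' including caller-rejected observations — and blacklists the variant when
#' rejects strictly outnumber passes (ratio > 1). A variant never passed
#' anywhere but rejected at least once has infinite ratio and is
#' blacklisted; a ratio of exactly one is kept.
#'
#' @param observations data frame with `variant_id` (or `variant_key`) and
#'   one status column per caller (statuses pass/reject/not_called), one
#'   row per (variant, sample).
#' @param callers caller status column names.
#' @return data frame of blacklist entries: variant_id, source
#'   (`"reject_ratio"`), n_pass, n_reject.
#' @export
build_reject_ratio_blacklist <- function(observations,
                                         callers = c("vardict", "strelka2",
                                                     "mutect2")) {
  empty <- data.frame(variant_id = character(), source = character(),
                      n_pass = integer(), n_reject = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(observations) == 0L) return(empty)
  idcol <- if ("variant_id" %in% names(observations)) "variant_id" else
    "variant_key"
  status <- as.matrix(observations[, callers, drop = FALSE])
  n_pass <- rowSums(status == "pass")
  n_reject <- rowSums(status == "reject")
  p <- tapply(n_pass, observations[[idcol]], sum)
  r <- tapply(n_reject, observations[[idcol]], sum)
  bad <- r > p  # covers P = 0, R > 0 (infinite ratio)
  if (!any(bad)) return(empty)
  data.frame(variant_id = names(p)[bad], source = "reject_ratio",
             n_pass = as.integer(p[bad]), n_reject = as.integer(r[bad]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply consensus and blacklists
#'
#' Removes from the consensus-accepted set every variant present on any
#' supplied blacklist, annotating removed variants with all triggering
#' rules. Filtering is idempotent.
#'
#' @param accepted character vector of consensus-accepted variant ids.
#' @param blacklists list of blacklist data frames (as produced by the
#'   `build_*_blacklist` functions).
#' @return list with `kept` (character vector) and `removed` (data frame:
#'   variant_id, sources — comma-separated triggering rules).
#' @export
apply_filters <- function(accepted, blacklists = list()) {
  entries <- do.call(rbind, lapply(blacklists, function(b) {
    if (is.null(b) || nrow(b) == 0L) return(NULL)
    b[, c("variant_id", "source")]
  }))
  if (is.null(entries) || nrow(entries) == 0L) {
    return(list(kept = accepted,
                removed = data.frame(variant_id = character(),
                                     sources = character(),
                                     stringsAsFactors = FALSE)))
  }
  hit <- intersect(accepted, entries$variant_id)
  sources <- vapply(hit, function(v) {
    paste(sort(unique(entries$source[entries$variant_id == v])),
          collapse = ",")
  }, character(1))
  list(
    kept = setdiff(accepted, entries$variant_id),
    removed = data.frame(variant_id = hit, sources = unname(sources),
                         stringsAsFactors = FALSE)
  )
}

#' Tumour mutation burden
#'
#' Filtered somatic SNV + indel count divided by the effective genome size
#' in megabases. The default denominator of 3100 Mb approximates the
#' GRCh38 genome; it is configurable because burden is only comparable
#' across cohorts using the same denominator.
#'
#' @param n_variants number of filtered somatic variants in one sample.
#' @param effective_genome_mb effective genome size in megabases (> 0).
#' @return mutations per megabase.
#' @export
tumour_mutation_burden <- function(n_variants, effective_genome_mb = 3100) {
  assert_that(effective_genome_mb > 0,
              "effective_genome_mb must be positive")
  assert_that(all(n_variants >= 0), "negative variant count")
  n_variants / effective_genome_mb
}
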