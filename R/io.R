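## Minimal VCF 4.2 reading and writing for the multi-caller call sets.
## The on-disk format carries the per-caller status in INFO/CALLS and the
## tumour read support in the sample column (AD:DP); it is deliberately
## minimal — one record per biallelic observation, no genotypes.

#' Write one sample's caller observations as a minimal VCF 4.2
#'
#' @param obs data frame for a single sample with columns variant_id,
#'   chrom, pos, ref, alt, one status column per caller, alt_reads, depth.
#' @param path output path.
#' @param callers caller status column names.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(obs, path,
                             callers = c("vardict", "strelka2",
                                         "mutect2")) {
  sample_id <- unique(obs$sample_id)
  assert_that(length(sample_id) <= 1L, "one sample per VCF")
  if (length(sample_id) == 0L) sample_id <- "NA"
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VID,Number=1,Type=String,Description=\"Variant identifier\">",
    "##INFO=<ID=CALLS,Number=1,Type=String,Description=\"Per-caller status caller:status,...\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(obs) > 0L) {
    calls <- apply(as.matrix(obs[, callers, drop = FALSE]), 1L, function(s) {
      paste(paste0(callers, ":", s), collapse = ",")
    })
    body <- paste(
      obs$chrom, obs$pos, obs$variant_id, obs$ref, obs$alt, ".", ".",
      paste0("VID=", obs$variant_id, ";CALLS=", calls),
      "AD:DP",
      paste0(obs$depth - obs$alt_reads, ",", obs$alt_reads, ":", obs$depth),
      sep = "\t"
    )
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal caller VCF back into an observation table
#'
#' @param path VCF written by [write_caller_vcf()].
#' @param callers caller names expected in INFO/CALLS.
#' @return data frame matching the [simulate_caller_calls()] observation
#'   layout.
#' @export
read_caller_vcf <- function(path,
                            callers = c("vardict", "strelka2", "mutect2")) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#CHROM")]
  assert_that(length(hdr) == 1L, "malformed VCF: missing column header")
  sample_id <- utils::tail(strsplit(hdr, "\t")[[1]], 1L)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    out <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      sample_id = character(), stringsAsFactors = FALSE)
    for (cl in callers) out[[cl]] <- character()
    out$alt_reads <- integer()
    out$depth <- integer()
    return(out)
  }
  fields <- do.call(rbind, strsplit(body, "\t"))
  info <- fields[, 8L]
  calls <- sub(".*CALLS=([^;]*).*", "\\1", info)
  status <- t(vapply(strsplit(calls, ","), function(parts) {
    kv <- strsplit(parts, ":")
    setNames(vapply(kv, `[`, character(1), 2L),
             vapply(kv, `[`, character(1), 1L))[callers]
  }, character(length(callers))))
  gt <- strsplit(fields[, 10L], ":")
  ad <- strsplit(vapply(gt, `[`, character(1), 1L), ",")
  out <- data.frame(
    variant_id = fields[, 3L],
    chrom = fields[, 1L],
    pos = as.integer(fields[, 2L]),
    ref = fields[, 4L],
    alt = fields[, 5L],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  out[callers] <- as.data.frame(status, stringsAsFactors = FALSE)
  out$alt_reads <- as.integer(vapply(ad, `[`, character(1), 2L))
  out$depth <- as.integer(vapply(gt, `[`, character(1), 2L))
  out
}
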