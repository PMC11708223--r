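#' Read per-genome variant calls from VCF
#'
#' Loads SNP and InDel calls for one resequenced genome and applies the
#' call-level read-depth filter: SNP and insertion records with a read depth
#' below `min_depth` are dropped. Deletion records are exempt from this filter
#' by default (the rule names only SNPs and insertions); set
#' `filter_deletions = TRUE` for the stricter behaviour.
#'
#' Multi-allelic records are split into one call per alternative allele.
#' Heterozygous calls are retained and flagged in `zygosity`; downstream
#' allele-frequency counting treats a het line as carrying the alternative
#' allele (see [select_target_allele()]).
#'
#' @param path VCF file (plain text or bgzip), one sample per file.
#' @param genome_id Identifier for the genome; defaults to the VCF sample name.
#' @param min_depth Minimum read depth for SNP/insertion calls (default 5:
#'   records with depth < 5 are removed).
#' @param filter_deletions Apply the depth filter to deletions too.
#' @param reference Optional [reference_genome]; when supplied, records whose
#'   position lies beyond the chromosome end raise an error.
#' @return Tibble with columns `genome_id`, `chrom`, `pos` (1-based anchor),
#'   `ref`, `alt`, `class` (`"SNP"`, `"INS"`, `"DEL"`), `depth`, `zygosity`
#'   (`"hom"`/`"het"`).
#' @export
read_variant_calls <- function(path, genome_id = NULL, min_depth = 5,
                               filter_deletions = FALSE, reference = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  # v@fix stays a matrix even for single-record files
  fix <- tibble::as_tibble(as.data.frame(v@fix[, 1:5, drop = FALSE],
                                         stringsAsFactors = FALSE))
  if (nrow(fix) == 0) {
    return(variant_call_tibble())
  }
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(genome_id)) genome_id <- colnames(v@gt)[2] %||% "sample"
  dp1 <- if (!is.null(dp)) as.numeric(dp[, 1]) else rep(NA_real_, nrow(fix))
  gt1 <- if (!is.null(gt)) as.character(gt[, 1]) else rep(NA_character_, nrow(fix))

  rows <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    depth = as.integer(round(dp1)),
    gt = gt1
  ) %>%
    tidyr::separate_rows("alt", sep = ",") %>%
    dplyr::filter(.data$alt != "", .data$alt != ".")

  zyg <- ifelse(!is.na(rows$gt) & grepl("0", rows$gt), "het", "hom")
  out <- rows %>%
    dplyr::mutate(
      genome_id = genome_id,
      class = classify_variant(.data$ref, .data$alt),
      zygosity = zyg
    ) %>%
    dplyr::filter(!is.na(.data$class)) %>%
    dplyr::select("genome_id", "chrom", "pos", "ref", "alt", "class",
                  "depth", "zygosity")

  if (!is.null(reference)) {
    for (cc in unique(out$chrom)) {
      if (any(out$pos[out$chrom == cc] > ref_length(reference, cc))) {
        stop("variant position beyond end of chromosome ", cc)
      }
    }
  }

  keep <- !(out$class %in% c("SNP", "INS")) |
    (!is.na(out$depth) & out$depth >= min_depth)
  if (filter_deletions) {
    keep <- keep & (out$class != "DEL" | (!is.na(out$depth) & out$depth >= min_depth))
  }
  out[keep, , drop = FALSE]
}

variant_call_tibble <- function() {
  tibble::tibble(
    genome_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), class = character(),
    depth = integer(), zygosity = character()
  )
}

# SNP: single differing base; INS: alt longer; DEL: ref longer; anything else
# (MNP, symbolic allele) is unsupported and returns NA
classify_variant <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1 & nchar(alt) == 1 & ref != alt ~ "SNP",
    nchar(alt) > nchar(ref) ~ "INS",
    nchar(ref) > nchar(alt) ~ "DEL",
    TRUE ~ NA_character_
  )
}

#' Write variant calls as a minimal single-sample VCF
#'
#' Emits a plain-text VCF 4.2 file with `GT:DP` per-sample fields, suitable
#' for round-tripping through [read_variant_calls()].
#'
#' @param calls Tibble as returned by [read_variant_calls()] (one genome).
#' @param path Output path.
#' @export
write_variant_calls <- function(calls, path) {
  stopifnot(length(unique(calls$genome_id)) <= 1)
  gid <- if (nrow(calls) > 0) calls$genome_id[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", gid)
  )
  ord <- order(calls$chrom, calls$pos)
  calls <- calls[ord, , drop = FALSE]
  gtf <- ifelse(calls$zygosity == "het", "0/1", "1/1")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP\t%s:%d",
                  calls$chrom, calls$pos, calls$ref, calls$alt, gtf,
                  ifelse(is.na(calls$depth), 0L, calls$depth))
  writeLines(c(hdr, body), path)
  invisible(path)
}
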