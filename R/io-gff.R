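#' Read gene models from GFF3
#'
#' Assembles a flat, tidy gene-model table from a GFF3 file containing
#' `gene`, `mRNA`, `exon` and `CDS` features linked by `ID`/`Parent`
#' attributes. When UTR features are absent they are derived as exon minus
#' CDS, split into 5' and 3' parts by strand.
#'
#' @param path GFF3 file.
#' @return Tibble with one row per feature interval: `gene_id`,
#'   `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `feature` (`"exon"`,
#'   `"CDS"`, `"UTR5"`, `"UTR3"`), `start`, `end` (1-based inclusive),
#'   `phase` (CDS only).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID),
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p) == 0) NA_character_ else p[[1]], character(1)),
    phase = if ("phase" %in% names(S4Vectors::mcols(gr)))
      as.integer(as.character(gr$phase)) else NA_integer_
  )
  build_gene_models(df)
}

# df: chrom,start,end,strand,type,id,parent,phase
build_gene_models <- function(df) {
  genes <- df[df$type == "gene", , drop = FALSE]
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  sub <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
            drop = FALSE]
  if (any(is.na(sub$parent))) stop("exon/CDS feature with no mRNA parent")
  if (!all(sub$parent %in% mrna$id)) {
    stop("orphan feature(s): parent transcript not found: ",
         paste(utils::head(setdiff(sub$parent, mrna$id), 3), collapse = ", "))
  }
  tx2gene <- stats::setNames(mrna$parent, mrna$id)
  if (any(is.na(tx2gene)) || !all(tx2gene %in% genes$id)) {
    stop("mRNA feature with no gene parent")
  }
  out <- tibble::tibble(
    gene_id = unname(tx2gene[sub$parent]),
    transcript_id = sub$parent,
    chrom = sub$chrom,
    strand = sub$strand,
    feature = dplyr::recode(sub$type,
                            five_prime_UTR = "UTR5", three_prime_UTR = "UTR3"),
    start = as.integer(sub$start),
    end = as.integer(sub$end),
    phase = sub$phase
  )
  # validate CDS within exons per transcript, then derive missing UTRs
  parts <- split(out, out$transcript_id)
  parts <- lapply(parts, derive_utrs)
  res <- dplyr::bind_rows(parts) %>%
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)
  tibble::as_tibble(res)
}

derive_utrs <- function(tx) {
  ex <- tx[tx$feature == "exon", , drop = FALSE]
  cds <- tx[tx$feature == "CDS", , drop = FALSE]
  if (nrow(ex) == 0) stop("transcript ", tx$transcript_id[1], " has no exons")
  ex <- dplyr::arrange(ex, .data$start)
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("overlapping exons in ", tx$transcript_id[1])
  }
  if (nrow(cds) > 0) {
    covered <- unlist(Map(seq.int, ex$start, ex$end))
    cdspos <- unlist(Map(seq.int, cds$start, cds$end))
    if (!all(cdspos %in% covered)) {
      stop("CDS outside exons in ", tx$transcript_id[1])
    }
  }
  if (any(tx$feature %in% c("UTR5", "UTR3")) || nrow(cds) == 0) {
    return(tx)
  }
  # exon minus CDS span, attributed 5'/3' by strand
  lo <- min(cds$start); hi <- max(cds$end)
  strand <- tx$strand[1]
  utr <- list()
  for (i in seq_len(nrow(ex))) {
    s <- ex$start[i]; e <- ex$end[i]
    if (s < lo) {
      piece <- c(s, min(e, lo - 1))
      utr[[length(utr) + 1]] <- c(piece, if (strand == "+") 5 else 3)
    }
    if (e > hi) {
      piece <- c(max(s, hi + 1), e)
      utr[[length(utr) + 1]] <- c(piece, if (strand == "+") 3 else 5)
    }
  }
  if (length(utr) > 0) {
    um <- do.call(rbind, utr)
    utr_tbl <- tibble::tibble(
      gene_id = tx$gene_id[1], transcript_id = tx$transcript_id[1],
      chrom = tx$chrom[1], strand = strand,
      feature = ifelse(um[, 3] == 5, "UTR5", "UTR3"),
      start = as.integer(um[, 1]), end = as.integer(um[, 2]),
      phase = NA_integer_
    )
    tx <- dplyr::bind_rows(tx, utr_tbl)
  }
  tx
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` records (UTRs are re-derivable and
#' not written) with `ID`/`Parent` links, via rtracklayer.
#'
#' @param models Gene-model tibble as from [read_gene_models()].
#' @param path Output GFF3 path.
#' @export
write_gene_models <- function(models, path) {
  sub <- models[models$feature %in% c("exon", "CDS"), , drop = FALSE]
  tx <- sub %>%
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom, .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  gn <- tx %>%
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  mk <- function(chrom, start, end, strand, type, id, parent, phase) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
    gr$type <- type
    gr$ID <- id
    gr$Parent <- ifelse(is.na(parent), NA_character_, parent)
    gr$phase <- phase
    gr
  }
  gr <- c(
    mk(gn$chrom, gn$start, gn$end, gn$strand, "gene", gn$gene_id,
       NA_character_, NA_integer_),
    mk(tx$chrom, tx$start, tx$end, tx$strand, "mRNA", tx$transcript_id,
       tx$gene_id, NA_integer_),
    mk(sub$chrom, sub$start, sub$end, sub$strand, sub$feature,
       NA_character_, sub$transcript_id, sub$phase)
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
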