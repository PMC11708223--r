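#' Predicted functional effect of a target variant
#'
#' Classifies a variant against every transcript of a gene-model table.
#' Region is one of `intergenic`, `UTR5`, `UTR3`, `intron`, `CDS`. For CDS
#' SNPs the affected codon is reconstructed strand- and phase-aware from the
#' reference, mutated, and translated with the standard genetic code:
#' `synonymous`, `nonsynonymous`, `premature_stop` (new stop before the
#' annotated stop), `stop_loss` (annotated stop destroyed) or `start_loss`
#' (start codon destroyed). CDS-overlapping indels are `frameshift` when the
#' number of inserted/deleted coding bases is not a multiple of 3, else
#' `nonframeshift`; indels removing the start or stop codon are reported as
#' `start_loss`/`stop_loss`. A variant is *functional* when its effect is
#' any of nonsynonymous, premature_stop, stop_loss, start_loss, frameshift
#' or nonframeshift.
#'
#' @param models Gene-model tibble from [read_gene_models()].
#' @param reference The [reference_genome] the models annotate.
#' @param chrom,pos Variant position (1-based; indels left-anchored).
#' @param ref,alt Reference and alternative alleles (VCF style).
#' @param class `"SNP"`, `"INS"` or `"DEL"`.
#' @return Tibble with one row per overlapping transcript (or a single
#'   `intergenic` row): `transcript_id`, `gene_id`, `region`, `effect`,
#'   `functional`.
#' @export
annotate_variant <- function(models, reference, chrom, pos, ref, alt, class) {
  if (pos < 1 || pos > ref_length(reference, chrom)) {
    stop("variant outside reference bounds")
  }
  span <- variant_span(pos, ref, class)
  tx_ids <- unique(models$transcript_id[models$chrom == chrom])
  rows <- list()
  for (tid in tx_ids) {
    tx <- models[models$transcript_id == tid, , drop = FALSE]
    tspan <- c(min(tx$start), max(tx$end))
    if (span[2] < tspan[1] || span[1] > tspan[2]) next
    rows[[length(rows) + 1]] <- annotate_in_transcript(
      tx, reference, chrom, pos, ref, alt, class, span)
  }
  if (length(rows) == 0) {
    return(tibble::tibble(transcript_id = NA_character_,
                          gene_id = NA_character_, region = "intergenic",
                          effect = "none", functional = FALSE))
  }
  dplyr::bind_rows(rows)
}

functional_effects <- c("nonsynonymous", "premature_stop", "stop_loss",
                        "start_loss", "frameshift", "nonframeshift")

# genomic bases affected by the variant: SNP the base itself; DEL the
# deleted bases (anchor excluded); INS the two bases around the insertion
# point
variant_span <- function(pos, ref, class) {
  switch(class,
    SNP = c(pos, pos),
    DEL = c(pos + 1, pos + nchar(ref) - 1),
    INS = c(pos, pos + 1),
    stop("unknown variant class: ", class)
  )
}

overlaps <- function(span, start, end) span[1] <= end & span[2] >= start

annotate_in_transcript <- function(tx, reference, chrom, pos, ref, alt,
                                   class, span) {
  cds <- dplyr::arrange(tx[tx$feature == "CDS", , drop = FALSE], .data$start)
  out <- tibble::tibble(transcript_id = tx$transcript_id[1],
                        gene_id = tx$gene_id[1], region = "intron",
                        effect = "none", functional = FALSE)
  in_cds <- nrow(cds) > 0 && any(overlaps(span, cds$start, cds$end))
  if (!in_cds && class == "INS" && nrow(cds) > 0) {
    # insertion strictly inside one CDS interval (between two coding bases)
    in_cds <- any(pos >= cds$start & pos + 1 <= cds$end)
  }
  if (in_cds) {
    out$region <- "CDS"
    out$effect <- if (class == "SNP") {
      classify_cds_snp(cds, reference, chrom, pos, alt, tx$strand[1])
    } else {
      classify_cds_indel(cds, pos, ref, alt, class, tx$strand[1], span)
    }
    out$functional <- out$effect %in% functional_effects
    return(out)
  }
  for (feat in c("UTR5", "UTR3")) {
    ft <- tx[tx$feature == feat, , drop = FALSE]
    if (nrow(ft) > 0 && any(overlaps(span, ft$start, ft$end))) {
      out$region <- feat
      return(out)
    }
  }
  out  # inside the transcript span but in no exon feature: intron
}

# spliced CDS sequence (5'->3') and the CDS coordinate of each genomic
# position, strand aware
cds_geometry <- function(cds, reference, chrom, strand) {
  gpos <- unlist(Map(seq.int, cds$start, cds$end))
  seq <- paste(vapply(seq_len(nrow(cds)), function(i)
    ref_subseq(reference, chrom, cds$start[i], cds$end[i]), character(1)),
    collapse = "")
  if (strand == "-") {
    seq <- revcomp(seq)
    gpos <- rev(gpos)
  }
  list(seq = seq, gpos = gpos)  # gpos[i] = genomic position of CDS base i
}

classify_cds_snp <- function(cds, reference, chrom, pos, alt, strand) {
  geo <- cds_geometry(cds, reference, chrom, strand)
  ci <- match(pos, geo$gpos)
  base <- if (strand == "-") revcomp(alt) else alt
  n_codon <- nchar(geo$seq) %/% 3
  codon_idx <- (ci - 1) %/% 3 + 1
  if (codon_idx > n_codon) return("none")  # trailing partial codon
  off <- (ci - 1) %% 3 + 1
  codon <- substr(geo$seq, (codon_idx - 1) * 3 + 1, codon_idx * 3)
  mut <- codon
  substr(mut, off, off) <- base
  aa0 <- translate_codon(codon)
  aa1 <- translate_codon(mut)
  if (codon_idx == 1 && aa0 == "M" && mut != "ATG") return("start_loss")
  if (aa0 == "*" && aa1 != "*") return("stop_loss")
  if (aa1 == "*" && aa0 != "*" && codon_idx < n_codon) return("premature_stop")
  if (aa1 == "*" && aa0 != "*") return("premature_stop")
  if (aa0 == aa1) return("synonymous")
  "nonsynonymous"
}

classify_cds_indel <- function(cds, pos, ref, alt, class, strand, span) {
  # coding bases inserted or deleted
  if (class == "INS") {
    len <- nchar(alt) - nchar(ref)
  } else {
    del <- seq.int(span[1], span[2])
    len <- sum(vapply(del, function(p) any(p >= cds$start & p <= cds$end),
                      logical(1)))
    # start/stop codon removal
    first3 <- if (strand == "+") utils::head(cds_positions(cds), 3)
              else utils::tail(cds_positions(cds), 3)
    last3 <- if (strand == "+") utils::tail(cds_positions(cds), 3)
             else utils::head(cds_positions(cds), 3)
    if (any(del %in% first3)) return("start_loss")
    if (any(del %in% last3)) return("stop_loss")
  }
  if (len %% 3 != 0) "frameshift" else "nonframeshift"
}

cds_positions <- function(cds) unlist(Map(seq.int, cds$start, cds$end))

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Annotate all designs against one assembly's gene models
#'
#' Runs [annotate_variant()] for every passing design and collapses the
#' per-isoform records to a design-level `functional` flag (true when any
#' isoform shows a functional effect).
#'
#' @param designs Output of [build_designs()].
#' @param models Gene-model tibble.
#' @param reference The matching [reference_genome].
#' @return List of two tibbles: `by_transcript` (pKey x transcript records)
#'   and `by_design` (`pKey`, `region`, `effect`, `functional`) where
#'   `region`/`effect` are taken from the first functional record when one
#'   exists, else the first record.
#' @export
annotate_designs <- function(designs, models, reference) {
  d <- designs[designs$verdict == "pass", , drop = FALSE]
  recs <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    a <- annotate_variant(models, reference, d$chrom[i], d$pos[i],
                          d$ref[i], d$target_alt[i], d$class[i])
    a$pKey <- d$pKey[i]
    recs[[i]] <- a
  }
  by_tx <- dplyr::bind_rows(recs) %>% dplyr::relocate("pKey")
  by_design <- by_tx %>%
    dplyr::group_by(.data$pKey) %>%
    dplyr::summarise(
      functional = any(.data$functional),
      region = if (any(.data$functional)) .data$region[.data$functional][1]
               else .data$region[1],
      effect = if (any(.data$functional)) .data$effect[.data$functional][1]
               else .data$effect[1],
      .groups = "drop"
    )
  list(by_transcript = by_tx, by_design = by_design)
}
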