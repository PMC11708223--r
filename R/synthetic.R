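#' Generate a synthetic reference genome with gene models
#'
#' Random nucleotide sequence at a specified GC content, seeded with
#' realistic trouble spots for the design filters: microsatellite tracts
#' (tandem repeats), AT-rich tracts (GC-window failures) and one duplicated
#' segment per chromosome (placement ties). Non-overlapping multi-exon
#' protein-coding genes with valid CDS (ATG start, in-frame stop, no
#' internal stop) are planted on both strands.
#'
#' All generators in this file are deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Length of each chromosome (bp).
#' @param gc Target GC fraction of background sequence.
#' @param n_genes Genes per chromosome.
#' @param n_microsat Microsatellite tracts per chromosome.
#' @param n_at_tracts AT-rich tracts per chromosome.
#' @param dup_len Length of the duplicated segment (0 disables).
#' @return List: `reference` ([reference_genome]), `models` (gene-model
#'   tibble), `features` (tibble of planted tracts/duplications with
#'   `chrom`, `start`, `end`, `what`).
#' @export
sim_reference <- function(seed = 1, n_chrom = 2, chrom_len = 100000,
                          gc = 0.43, n_genes = 25, n_microsat = 12,
                          n_at_tracts = 6, dup_len = 400) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- list()
  feats <- list()
  models <- list()
  gi <- 0
  for (cc in chroms) {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    ch <- sample(names(p), chrom_len, replace = TRUE, prob = p)
    used <- rep(FALSE, chrom_len)  # regions reserved by planted features

    reserve <- function(s, e) {
      s <- max(1, s); e <- min(chrom_len, e)
      if (any(used[s:e])) return(FALSE)
      used[s:e] <<- TRUE
      TRUE
    }
    place <- function(len, margin = 120, tries = 50) {
      for (t in seq_len(tries)) {
        s <- sample.int(chrom_len - len - 2 * margin, 1) + margin
        if (reserve(s - margin, s + len - 1 + margin)) return(s)
      }
      NA_integer_
    }

    # microsatellite tracts: unit 1-4 nt repeated 7-12 times
    for (i in seq_len(n_microsat)) {
      unit <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                           replace = TRUE), collapse = "")
      reps <- sample(7:12, 1)
      tract <- strrep(unit, reps)
      s <- place(nchar(tract))
      if (is.na(s)) next
      ch[s:(s + nchar(tract) - 1)] <- strsplit(tract, "")[[1]]
      feats[[length(feats) + 1]] <- tibble::tibble(
        chrom = cc, start = s, end = s + nchar(tract) - 1, what = "microsat")
    }
    # AT-rich tracts (~95% AT over 250 bp)
    for (i in seq_len(n_at_tracts)) {
      len <- 250
      s <- place(len)
      if (is.na(s)) next
      ch[s:(s + len - 1)] <- sample(c("A", "T", "G", "C"), len, replace = TRUE,
                                    prob = c(0.475, 0.475, 0.025, 0.025))
      feats[[length(feats) + 1]] <- tibble::tibble(
        chrom = cc, start = s, end = s + len - 1, what = "at_tract")
    }
    # genes
    for (i in seq_len(n_genes)) {
      g <- sim_gene_layout()
      s <- place(g$len, margin = 200)
      if (is.na(s)) next
      gi <- gi + 1
      strand <- sample(c("+", "-"), 1)
      gene_seq <- g$seq
      if (strand == "-") gene_seq <- chartr("ACGT", "TGCA",
                                            paste(rev(strsplit(gene_seq, "")[[1]]),
                                                  collapse = ""))
      ch[s:(s + g$len - 1)] <- strsplit(gene_seq, "")[[1]]
      fl <- g$features
      if (strand == "-") {
        # mirror intervals within the gene; each segment keeps its identity
        # (the 5' UTR of a minus-strand gene sits at the genomic right end)
        ns <- g$len - fl$end + 1
        ne <- g$len - fl$start + 1
        fl$start <- ns; fl$end <- ne
      }
      gene_id <- sprintf("G%03d", gi)
      models[[length(models) + 1]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = paste0(gene_id, ".1"),
        chrom = cc, strand = strand, feature = fl$feature,
        start = as.integer(s + fl$start - 1), end = as.integer(s + fl$end - 1),
        phase = ifelse(fl$feature == "CDS", 0L, NA_integer_)
      )
    }
    # duplicated segment: copy one clean block elsewhere on the chromosome
    if (dup_len > 0) {
      src <- place(dup_len)
      dst <- place(dup_len)
      if (!is.na(src) && !is.na(dst)) {
        ch[dst:(dst + dup_len - 1)] <- ch[src:(src + dup_len - 1)]
        feats[[length(feats) + 1]] <- tibble::tibble(
          chrom = cc, start = src, end = src + dup_len - 1, what = "dup_src")
        feats[[length(feats) + 1]] <- tibble::tibble(
          chrom = cc, start = dst, end = dst + dup_len - 1, what = "dup_copy")
      }
    }
    seqs[[cc]] <- paste(ch, collapse = "")
  }
  list(
    reference = reference_genome(unlist(seqs), "simref"),
    models = if (length(models)) dplyr::bind_rows(models) else NULL,
    features = if (length(feats)) dplyr::bind_rows(feats) else
      tibble::tibble(chrom = character(), start = integer(),
                     end = integer(), what = character())
  )
}

# one plus-strand gene layout: UTR5 exon part, 2-3 CDS exons with introns,
# UTR3; returns total length, sequence, and feature intervals relative to 1
sim_gene_layout <- function() {
  n_codons <- sample(50:110, 1)
  stops <- c("TAA", "TAG", "TGA")
  codons <- names(Biostrings::GENETIC_CODE)
  internal <- sample(setdiff(codons, stops), n_codons - 2, replace = TRUE)
  cds <- paste0("ATG", paste(internal, collapse = ""),
                sample(stops, 1))
  n_ex <- sample(2:3, 1)
  # split CDS into n_ex chunks (each >= 20 bp)
  L <- nchar(cds)
  cuts <- sort(sample(seq(21, L - 21), n_ex - 1))
  bounds <- c(0, cuts, L)
  utr5 <- sample(15:40, 1)
  utr3 <- sample(15:40, 1)
  introns <- sample(40:80, n_ex - 1, replace = TRUE)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  seq <- rnd(utr5)
  featrows <- list(tibble::tibble(feature = "UTR5", start = 1, end = utr5))
  pos <- utr5
  ex_start <- utr5 + 1
  for (e in seq_len(n_ex)) {
    chunk <- substr(cds, bounds[e] + 1, bounds[e + 1])
    seq <- paste0(seq, chunk)
    featrows[[length(featrows) + 1]] <- tibble::tibble(
      feature = "CDS", start = pos + 1, end = pos + nchar(chunk))
    featrows[[length(featrows) + 1]] <- tibble::tibble(
      feature = "exon", start = if (e == 1) 1 else pos + 1,
      end = pos + nchar(chunk))
    pos <- pos + nchar(chunk)
    if (e < n_ex) {
      seq <- paste0(seq, rnd(introns[e]))
      pos <- pos + introns[e]
    }
  }
  seq <- paste0(seq, rnd(utr3))
  featrows[[length(featrows) + 1]] <- tibble::tibble(
    feature = "UTR3", start = pos + 1, end = pos + utr3)
  fl <- dplyr::bind_rows(featrows)
  # extend last exon over the 3' UTR and first exon over the 5' UTR
  fl$end[fl$feature == "exon" & fl$end == pos] <- pos + utr3
  list(len = pos + utr3, seq = seq, features = fl)
}
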