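# Functional-effect classification against gene models.

# a two-exon gene on the requested strand with a fully specified CDS
mk_gene <- function(cds, strand = "+", chrom_len = 1500, utr = 20,
                    intron = 50, seed = 2) {
  stopifnot(nchar(cds) %% 3 == 0)
  half <- (nchar(cds) %/% 6) * 3
  ex1 <- substr(cds, 1, half)
  ex2 <- substr(cds, half + 1, nchar(cds))
  gene_seq <- paste0(strrep("T", utr), ex1, bg_seq(intron, seed = seed + 1),
                     ex2, strrep("T", utr))
  if (strand == "-") gene_seq <- oracle_rc(gene_seq)
  pre <- bg_seq(300, seed = seed)
  post <- bg_seq(chrom_len - 300 - nchar(gene_seq), seed = seed + 2)
  seq <- paste0(pre, gene_seq, post)
  g0 <- 300  # gene starts at g0 + 1
  lay <- list(
    utr5 = c(1, utr), ex1 = c(utr + 1, utr + nchar(ex1)),
    ex2 = c(utr + nchar(ex1) + intron + 1,
            utr + nchar(ex1) + intron + nchar(ex2)),
    utr3 = c(utr + nchar(ex1) + intron + nchar(ex2) + 1, nchar(gene_seq) / 1)
  )
  lay$utr3[2] <- lay$utr3[1] + utr - 1
  glen <- lay$utr3[2]
  tolocal <- function(iv) if (strand == "+") g0 + iv else g0 + glen - rev(iv) + 1
  u5 <- tolocal(lay$utr5); e1 <- tolocal(lay$ex1); e2 <- tolocal(lay$ex2)
  u3 <- tolocal(lay$utr3)
  feat <- function(f, iv) tibble::tibble(
    gene_id = "g1", transcript_id = "t1", chrom = "chr1", strand = strand,
    feature = f, start = as.integer(iv[1]), end = as.integer(iv[2]),
    phase = if (f == "CDS") 0L else NA_integer_)
  # mirroring the whole gene keeps each segment's identity: the 5' UTR of a
  # minus-strand gene simply lands at the genomic right end
  models <- dplyr::bind_rows(
    feat("UTR5", u5),
    feat("exon", range(c(u5, e1))), feat("CDS", e1),
    feat("CDS", e2), feat("exon", range(c(e2, u3))), feat("UTR3", u3))
  ref <- reference_genome(c(chr1 = seq), "ann")
  # genomic position of CDS base i (1-based along the coding sequence)
  cds_gpos <- function(i) {
    if (strand == "+") {
      if (i <= nchar(ex1)) e1[1] + i - 1 else e2[1] + (i - nchar(ex1)) - 1
    } else {
      if (i <= nchar(ex1)) e1[2] - i + 1 else e2[2] - (i - nchar(ex1)) + 1
    }
  }
  list(ref = ref, models = models, cds = cds, cds_gpos = cds_gpos,
       strand = strand)
}

demo_cds <- function() {
  paste0("ATG", "GGA", "TAC", "CTT", "AAA", "GGG", "CCT", "TCA", "TAA")
}

test_that("intergenic, UTR and intron regions are assigned correctly", {
  g <- mk_gene(demo_cds())
  far <- annotate_variant(g$models, g$ref, "chr1", 50, "A", "G", "SNP")
  expect_equal(far$region, "intergenic")
  expect_false(far$functional)
  u5 <- annotate_variant(g$models, g$ref, "chr1", 305, "T", "C", "SNP")
  expect_equal(u5$region, "UTR5")
  intr <- annotate_variant(g$models, g$ref, "chr1",
                           g$cds_gpos(12) + 5, "A", "G", "SNP")
  expect_equal(intr$region, "intron")
})

test_that("CDS SNPs classify by codon against the translation table", {
  g <- mk_gene(demo_cds())
  # GGA -> GGG at codon 2 position 3: synonymous (both glycine)
  p <- g$cds_gpos(6)
  out <- annotate_variant(g$models, g$ref, "chr1", p, "A", "G", "SNP")
  expect_equal(out$region, "CDS")
  expect_equal(out$effect, "synonymous")
  expect_false(out$functional)
  # TAC -> TAA at codon 3: premature stop
  p2 <- g$cds_gpos(9)
  out2 <- annotate_variant(g$models, g$ref, "chr1", p2, "C", "A", "SNP")
  expect_equal(out2$effect, "premature_stop")
  expect_true(out2$functional)
  # TAA -> CAA at the annotated stop: stop loss
  p3 <- g$cds_gpos(25)
  out3 <- annotate_variant(g$models, g$ref, "chr1", p3, "T", "C", "SNP")
  expect_equal(out3$effect, "stop_loss")
  # ATG -> GTG: start loss
  p4 <- g$cds_gpos(1)
  out4 <- annotate_variant(g$models, g$ref, "chr1", p4, "A", "G", "SNP")
  expect_equal(out4$effect, "start_loss")
})

test_that("CDS indels split into frameshift and nonframeshift by length mod 3", {
  g <- mk_gene(demo_cds())
  p <- g$cds_gpos(4)  # codon 2: well inside the first CDS exon
  ref2 <- ref_subseq(g$ref, "chr1", p, p + 2)
  del2 <- annotate_variant(g$models, g$ref, "chr1", p, ref2,
                           substr(ref2, 1, 1), "DEL")
  expect_equal(del2$effect, "frameshift")
  ref3 <- ref_subseq(g$ref, "chr1", p, p + 3)
  del3 <- annotate_variant(g$models, g$ref, "chr1", p, ref3,
                           substr(ref3, 1, 1), "DEL")
  expect_equal(del3$effect, "nonframeshift")
  ins1 <- annotate_variant(g$models, g$ref, "chr1", p,
                           substr(ref2, 1, 1), paste0(substr(ref2, 1, 1), "T"),
                           "INS")
  expect_equal(ins1$effect, "frameshift")
  expect_true(all(c(del2$functional, del3$functional, ins1$functional)))
})

test_that("minus-strand variants classify on the reverse-complement codon", {
  cds <- demo_cds()
  gp <- mk_gene(cds, strand = "+")
  gm <- mk_gene(cds, strand = "-")
  for (ci in c(1, 6, 9, 14, 25)) {
    pp <- gp$cds_gpos(ci)
    pm <- gm$cds_gpos(ci)
    refp <- ref_subseq(gp$ref, "chr1", pp, pp)
    alt <- setdiff(c("A", "C", "G", "T"), refp)[1]
    outp <- annotate_variant(gp$models, gp$ref, "chr1", pp, refp, alt, "SNP")
    refm <- ref_subseq(gm$ref, "chr1", pm, pm)
    expect_equal(refm, oracle_rc(refp))  # mirrored construction sanity
    outm <- annotate_variant(gm$models, gm$ref, "chr1", pm, refm,
                             oracle_rc(alt), "SNP")
    expect_equal(outm$effect, outp$effect, info = paste("cds base", ci))
  }
})

test_that("random CDS SNPs agree with the whole-protein translation oracle", {
  withr::with_seed(91, {
    stops <- c("TAA", "TAG", "TGA")
    codons <- setdiff(names(Biostrings::GENETIC_CODE), stops)
    for (rep in 1:6) {
      cds <- paste0("ATG", paste(sample(codons, 30, replace = TRUE),
                                 collapse = ""), sample(stops, 1))
      strand <- sample(c("+", "-"), 1)
      g <- mk_gene(cds, strand = strand, seed = 400 + rep)
      for (i in 1:25) {
        ci <- sample(nchar(cds), 1)
        base_ref <- substr(cds, ci, ci)
        alt_cds <- sample(setdiff(c("A", "C", "G", "T"), base_ref), 1)
        p <- g$cds_gpos(ci)
        ref_g <- ref_subseq(g$ref, "chr1", p, p)
        alt_g <- if (strand == "+") alt_cds else oracle_rc(alt_cds)
        got <- annotate_variant(g$models, g$ref, "chr1", p, ref_g, alt_g,
                                "SNP")
        expect_equal(got$effect, oracle_snp_effect(cds, ci, alt_cds),
                     info = paste(strand, ci))
      }
    }
  })
})

test_that("synonymous verdicts never change the translated protein", {
  sim <- shared_sim()
  tx <- sim$ann$by_transcript
  syn <- tx[!is.na(tx$effect) & tx$effect == "synonymous", ]
  d <- sim$designs
  models <- sim$ro$models
  ref <- sim$ro$reference
  for (i in seq_len(min(nrow(syn), 25))) {
    row <- d[d$pKey == syn$pKey[i] & !is.na(d$pKey), ]
    cds <- models[models$transcript_id == syn$transcript_id[i] &
                    models$feature == "CDS", ]
    cds <- cds[order(cds$start), ]
    seqs <- paste(vapply(seq_len(nrow(cds)), function(j)
      ref_subseq(ref, cds$chrom[j], cds$start[j], cds$end[j]), character(1)),
      collapse = "")
    gpos <- unlist(Map(seq.int, cds$start, cds$end))
    if (cds$strand[1] == "-") { seqs <- oracle_rc(seqs); gpos <- rev(gpos) }
    ci <- match(row$pos, gpos)
    mut <- seqs
    base <- if (cds$strand[1] == "-") oracle_rc(row$target_alt) else row$target_alt
    substr(mut, ci, ci) <- base
    n3 <- (nchar(seqs) %/% 3) * 3
    expect_equal(
      as.character(Biostrings::translate(Biostrings::DNAString(substr(mut, 1, n3)))),
      as.character(Biostrings::translate(Biostrings::DNAString(substr(seqs, 1, n3)))))
  }
})

test_that("every variant receives exactly one region per transcript", {
  sim <- shared_sim()
  tx <- sim$ann$by_transcript
  expect_true(all(tx$region %in% c("intergenic", "UTR5", "UTR3", "intron",
                                   "CDS")))
  # one record per design x transcript
  expect_equal(anyDuplicated(paste(tx$pKey, tx$transcript_id)), 0)
  # region counts partition the annotated designs
  expect_equal(nrow(tx), sum(table(tx$region)))
})
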