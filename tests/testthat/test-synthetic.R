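# The synthetic-data generators: determinism, realised composition, and the
# behaviours later stages rely on.

test_that("generators are byte-identical under a fixed seed", {
  a <- sim_reference(seed = 9, n_chrom = 1, chrom_len = 15000, n_genes = 4)
  b <- sim_reference(seed = 9, n_chrom = 1, chrom_len = 15000, n_genes = 4)
  expect_identical(as.character(a$reference$seq), as.character(b$reference$seq))
  expect_identical(as.data.frame(a$models), as.data.frame(b$models))
  pa <- sim_panel(a, seed = 10, n_genomes = 8, n_sites = 60)
  pb <- sim_panel(b, seed = 10, n_genomes = 8, n_sites = 60)
  expect_identical(as.data.frame(pa$panel$calls), as.data.frame(pb$panel$calls))
  expect_identical(as.data.frame(pa$truth), as.data.frame(pb$truth))
  ga <- sim_genotyping(sprintf("K%02d", 1:30), seed = 11, n_samples = 40)
  gb <- sim_genotyping(sprintf("K%02d", 1:30), seed = 11, n_samples = 40)
  expect_identical(as.data.frame(ga$gm), as.data.frame(gb$gm))
  # different seeds give different data
  pc <- sim_panel(a, seed = 12, n_genomes = 8, n_sites = 60)
  expect_false(identical(as.data.frame(pa$panel$calls),
                         as.data.frame(pc$panel$calls)))
})

test_that("realised GC content concentrates around the requested value", {
  ro <- sim_reference(seed = 13, n_chrom = 1, chrom_len = 100000, gc = 0.5,
                      n_genes = 0, n_microsat = 0, n_at_tracts = 0,
                      dup_len = 0)
  ch <- strsplit(as.character(ro$reference$seq[[1]]), "")[[1]]
  gc <- mean(ch %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.02)  # binomial concentration at n = 100k
})

test_that("planted genes translate cleanly: ATG start, single terminal stop", {
  ro <- sim_reference(seed = 14, n_chrom = 1, chrom_len = 40000, n_genes = 10,
                      n_microsat = 0, n_at_tracts = 0, dup_len = 0)
  ref <- ro$reference
  for (tid in unique(ro$models$transcript_id)) {
    tx <- ro$models[ro$models$transcript_id == tid, ]
    cds <- tx[tx$feature == "CDS", ]
    cds <- cds[order(cds$start), ]
    seq <- paste(vapply(seq_len(nrow(cds)), function(i)
      ref_subseq(ref, cds$chrom[i], cds$start[i], cds$end[i]), character(1)),
      collapse = "")
    if (tx$strand[1] == "-") seq <- oracle_rc(seq)
    expect_equal(nchar(seq) %% 3, 0)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(seq)))
    expect_equal(substr(prot, 1, 1), "M")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("planted carrier counts cover both sides of every frequency rule", {
  sim <- shared_sim()
  tr <- sim$sp$truth
  expect_true(all(c("rare_allele", "monomorphic", "target_coverage",
                    "flank_coverage", "flank_variation", "repeat", "gc",
                    "none") %in% tr$failed_rule))
  # carrier fractions of passing sites spread over the admissible range
  pass <- tr[tr$verdict == "pass", ]
  expect_gt(nrow(pass), 30)
})

test_that("realised pass-scenario carrier counts match the declared uniform draw", {
  ro <- sim_reference(seed = 15, n_chrom = 1, chrom_len = 60000, n_genes = 0,
                      n_microsat = 0, n_at_tracts = 0, dup_len = 0)
  sp <- sim_panel(ro, seed = 16, n_genomes = 20, n_sites = 400)
  calls <- sp$panel$calls
  tr <- sp$truth[sp$truth$scenario == "pass", ]
  carriers <- vapply(seq_len(nrow(tr)), function(i) {
    at <- calls[calls$chrom == tr$chrom[i] & calls$pos == tr$pos[i] &
                  calls$alt == tr$alt[i], ]
    length(unique(at$genome_id))
  }, integer(1))
  # declared draw: 2..18 uniformly, thinned only by the depth filter
  expect_gte(min(carriers), 1)
  expect_lte(max(carriers), 18)
  # uniform mean 10 with sd ~4.9; depth thinning shifts it down slightly
  se <- stats::sd(carriers) / sqrt(length(carriers))
  expect_lt(abs(mean(carriers) - 10), 0.5 + 3 * se)
  # all magnitudes are represented, not clumped
  expect_gt(length(unique(carriers)), 12)
})

test_that("a zero failure rate yields a 100% call rate everywhere", {
  g <- sim_genotyping(sprintf("K%02d", 1:25), seed = 17, n_samples = 50,
                      all_fail_rate = 0, shaky_rate = 0, mono_rate = 0,
                      call_fail_rate = 0)
  crs <- call_rate_summary(g$gm)
  expect_true(all(crs$markers$call_rate == 1))
})

test_that("a drifted design line shows the planted discordance rate", {
  markers <- sprintf("K%03d", 1:300)
  pred <- tidyr::crossing(sample = sprintf("L%02d", 1:3), marker = markers) %>%
    dplyr::mutate(predicted = sample(c("reference", "target"), dplyr::n(),
                                     replace = TRUE))
  g <- sim_genotyping(markers, seed = 18, n_samples = 20,
                      all_fail_rate = 0, shaky_rate = 0, mono_rate = 0,
                      call_fail_rate = 0, design_predicted = pred,
                      discord_rates = c(L01 = 0.5, L02 = 0.05, L03 = 0))
  cc <- concordance(g$gm[grepl("^L", g$gm$sample), ], pred)
  line <- tidy(cc)
  # binomial expectation within 3 SD: 0.5 +- 3*sqrt(0.25/300)
  expect_lt(abs(line$pct_match[line$sample == "L01"] / 100 - 0.5),
            3 * sqrt(0.25 / 300))
  expect_equal(line$pct_match[line$sample == "L03"], 100)
})

test_that("failure codes are injected at the requested rate and split", {
  markers <- sprintf("K%03d", 1:200)
  g <- sim_genotyping(markers, seed = 19, n_samples = 100,
                      all_fail_rate = 0, shaky_rate = 0, mono_rate = 0,
                      call_fail_rate = 0.1)
  frac <- mean(g$gm$call %in% c("?", "Bad", "Uncallable"))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / nrow(g$gm)))
  codes <- table(g$gm$call[g$gm$call %in% c("?", "Bad", "Uncallable")])
  expect_gt(codes[["?"]], codes[["Bad"]])
})

test_that("written scenario files reload into the same panel", {
  ro <- sim_reference(seed = 23, n_chrom = 1, chrom_len = 12000, n_genes = 3,
                      n_microsat = 2, n_at_tracts = 1)
  sp <- sim_panel(ro, seed = 24, n_genomes = 6, n_sites = 40)
  dir <- withr::local_tempdir()
  paths <- sim_write_all(ro, sp, targets = NULL, dir = dir)
  ref2 <- read_reference(paths$reference)
  expect_identical(as.character(ref2$seq), as.character(ro$reference$seq))
  g1 <- sp$panel$genomes[1]
  back <- read_variant_calls(file.path(paths$vcf_dir, paste0(g1, ".vcf")),
                             genome_id = g1)
  orig <- sp$panel$calls[sp$panel$calls$genome_id == g1, ]
  orig <- dplyr::arrange(orig, chrom, pos, alt)
  back <- dplyr::arrange(back, chrom, pos, alt)
  expect_equal(back$pos, orig$pos)
  expect_equal(back$alt, orig$alt)
  tr2 <- read_depth_track(file.path(paths$depth_dir,
                                    paste0(g1, ".depth.tsv")))
  expect_equal(attr(tr2, "mean_depth"),
               attr(sp$panel$depth_tracks[[g1]], "mean_depth"))
})
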