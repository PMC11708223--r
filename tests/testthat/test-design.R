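# Filter 4, degenerate sequence construction, repeat and GC screens.

test_that("admissible flank structure passes; each inadmissible case fails", {
  seq <- bg_seq(1200, seed = 9)
  ok <- design_panel(list(flank_call(510, seq, "DEL", 3),
                          flank_call(480, seq), flank_call(530, seq)))
  prof <- assess_flank_variation(ok, "chr1", 500)
  expect_equal(prof$verdict, "pass")
  expect_equal(nrow(prof$snp_sites), 2)
  expect_equal(prof$indel$len, 3)

  # indel within 5 bp of the target
  close <- design_panel(list(flank_call(504, seq, "INS", 2)))
  expect_equal(assess_flank_variation(close, "chr1", 500)$failed_rule,
               "flank_variation")
  # offset boundary: 5 fails, 6 passes
  at5 <- design_panel(list(flank_call(505, seq, "INS", 2)))
  expect_equal(assess_flank_variation(at5, "chr1", 500)$verdict, "fail")
  at6 <- design_panel(list(flank_call(506, seq, "INS", 2)))
  expect_equal(assess_flank_variation(at6, "chr1", 500)$verdict, "pass")

  # length boundary: 10 passes, 11+ fails
  len10 <- design_panel(list(flank_call(520, seq, "INS", 10)))
  expect_equal(assess_flank_variation(len10, "chr1", 500)$verdict, "pass")
  len12 <- design_panel(list(flank_call(520, seq, "INS", 12)))
  expect_equal(assess_flank_variation(len12, "chr1", 500)$verdict, "fail")

  # two distinct indel sites
  two <- design_panel(list(flank_call(515, seq, "INS", 2),
                           flank_call(470, seq, "DEL", 2, g = "G03")))
  expect_equal(assess_flank_variation(two, "chr1", 500)$verdict, "fail")

  # six SNP sites in one flank (five passes)
  five <- design_panel(lapply(c(460, 470, 480, 490, 494), flank_call,
                              seq = seq))
  expect_equal(assess_flank_variation(five, "chr1", 500)$verdict, "pass")
  six <- design_panel(lapply(c(455, 460, 470, 480, 490, 494), flank_call,
                             seq = seq))
  expect_equal(assess_flank_variation(six, "chr1", 500)$failed_rule,
               "flank_variation")
  # the strict-total reading caps across both flanks
  both3 <- design_panel(lapply(c(460, 470, 480, 510, 520, 530), flank_call,
                               seq = seq))
  expect_equal(assess_flank_variation(both3, "chr1", 500)$verdict, "pass")
  expect_equal(assess_flank_variation(both3, "chr1", 500, max_flank_snps = 5,
                                      per_flank = FALSE)$verdict, "fail")

  # unequal deletion lengths at one site
  uneq <- design_panel(list(flank_call(520, seq, "DEL", 2, g = "G02"),
                            flank_call(520, seq, "DEL", 3, g = "G03")))
  expect_equal(assess_flank_variation(uneq, "chr1", 500)$verdict, "fail")
})

test_that("design sequences encode flank variation as IUPAC letters and N runs", {
  seq <- bg_seq(1200, seed = 9)
  # SNP at +13: minimal covering code
  p <- design_panel(list(flank_call(513, seq)))
  prof <- assess_flank_variation(p, "chr1", 500)
  built <- build_design_sequence(p$reference, "chr1", 500, prof)
  expect_equal(nchar(built$design_seq), 101)
  ref_b <- substr(seq, 513, 513)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  expect_equal(substr(built$design_seq, 64, 64), iupac_code(c(ref_b, alt_b)))
  # target base stays the reference allele
  expect_equal(substr(built$design_seq, 51, 51), substr(seq, 500, 500))

  # 3-bp deletion becomes NNN over the deleted bases, length unchanged
  pd <- design_panel(list(flank_call(510, seq, "DEL", 3)))
  profd <- assess_flank_variation(pd, "chr1", 500)
  bd <- build_design_sequence(pd$reference, "chr1", 500, profd)
  expect_equal(nchar(bd$design_seq), 101)
  expect_equal(substr(bd$design_seq, 62, 64), "NNN")

  # 4-bp insertion: Ns inserted after the anchor, length 105
  pi <- design_panel(list(flank_call(490, seq, "INS", 4)))
  profi <- assess_flank_variation(pi, "chr1", 500)
  bi <- build_design_sequence(pi$reference, "chr1", 500, profi)
  expect_equal(nchar(bi$design_seq), 105)
  expect_equal(substr(bi$design_seq, 42, 45), "NNNN")
  expect_equal(bi$target_index, 55)
  expect_equal(substr(bi$design_seq, 55, 55), substr(seq, 500, 500))

  # no flank variation: the literal reference window
  p0 <- design_panel(list())
  b0 <- build_design_sequence(p0$reference, "chr1", 500,
                              assess_flank_variation(p0, "chr1", 500))
  expect_equal(b0$design_seq, substr(seq, 450, 550))

  # two alternatives at one site: code covers ref and both alts
  refb <- substr(seq, 530, 530)
  alts <- setdiff(c("A", "C", "G", "T"), refb)[1:2]
  pv <- design_panel(list(
    call_row("G02", 530, refb, alts[1]),
    call_row("G03", 530, refb, alts[2])))
  bv <- build_design_sequence(pv$reference, "chr1", 500,
                              assess_flank_variation(pv, "chr1", 500))
  expect_equal(substr(bv$design_seq, 81, 81), iupac_code(c(refb, alts)))
})

test_that("tandem-repeat screen counts maximal copies over all resolutions", {
  pad <- function(core) paste0(bg_seq(40, seed = 31), core,
                               bg_seq(40, seed = 32))
  expect_equal(check_tandem_repeats(pad(strrep("AT", 6)))$failed_rule,
               "repeat")
  expect_equal(check_tandem_repeats(pad("CAAAAAG"))$verdict, "pass")
  expect_equal(check_tandem_repeats(pad(strrep("CGT", 6)))$failed_rule,
               "repeat")
  # ambiguity letter whose A-resolution creates an 11-base homopolymer
  amb <- paste0(bg_seq(30, seed = 33), "AAAAARAAAAA", bg_seq(30, seed = 34))
  out <- check_tandem_repeats(amb)
  expect_equal(out$failed_rule, "repeat")
  # Ns are stripped before scanning, so an N run can join two half-runs
  withN <- paste0(bg_seq(30, seed = 35), "AAANNNAAA", bg_seq(30, seed = 36))
  expect_equal(check_tandem_repeats(withN)$failed_rule, "repeat")
})

test_that("repeat counting agrees with a naive per-start oracle", {
  withr::with_seed(55, {
    for (i in 1:300) {
      s <- paste(sample(c("A", "C", "G", "T"), sample(15:40, 1),
                        replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4)),
                 collapse = "")
      expect_equal(kaspforge:::max_tandem_copies(s), oracle_max_copies(s),
                   info = s)
    }
  })
})

test_that("GC window is centred, inclusive at both bounds, and skips Ns", {
  mk101 <- function(win55) paste0(strrep("A", 23), win55, strrep("A", 23))
  # all-A/T window: 0% GC, extreme failure
  expect_equal(check_gc_window(substr(strrep("AT", 51), 1, 101),
                               51)$failed_rule, "gc")
  # 27 G/C of 55 -> 49.1%: pass, percentage by direct count
  w49 <- paste(c(rep("G", 27), rep("A", 28)), collapse = "")
  gc <- check_gc_window(mk101(w49), 51)
  expect_equal(gc$verdict, "pass")
  expect_equal(gc$gc_window_pct, 100 * 27 / 55)
  # ambiguity letters contribute their mean GC: 16 G + 13 R = 22.5/55
  wamb <- paste(c(rep("G", 16), rep("R", 13), rep("A", 26)), collapse = "")
  expect_equal(check_gc_window(mk101(wamb), 51)$gc_window_pct,
               100 * 22.5 / 55)
  # N positions drop out of numerator and denominator: 14 G + 26 A + 15 N
  # gives exactly 35.0% of the 40 informative bases -> inclusive pass
  w35 <- paste(c(rep("G", 14), rep("A", 26), rep("N", 15)), collapse = "")
  out <- check_gc_window(mk101(w35), 51)
  expect_equal(out$gc_window_pct, 35)
  expect_equal(out$verdict, "pass")
  # exactly 65%: 26 G/C of 40 informative -> inclusive pass; one more fails
  w65 <- paste(c(rep("G", 26), rep("A", 14), rep("N", 15)), collapse = "")
  expect_equal(check_gc_window(mk101(w65), 51)$gc_window_pct, 65)
  expect_equal(check_gc_window(mk101(w65), 51)$verdict, "pass")
  w66 <- paste(c(rep("G", 27), rep("A", 13), rep("N", 15)), collapse = "")
  expect_equal(check_gc_window(mk101(w66), 51)$failed_rule, "gc")
})

test_that("every emitted design satisfies all admissibility constraints at once", {
  sim <- shared_sim()
  d <- sim$designs[sim$designs$verdict == "pass", ]
  expect_gt(nrow(d), 50)
  for (i in seq_len(nrow(d))) {
    ch <- strsplit(d$design_seq[i], "")[[1]]
    amb <- ch %in% c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
    sn <- d$flank_snps[[i]]
    # bijection between degenerate letters and SNP flank sites
    expect_equal(sum(amb), nrow(sn))
    expect_lte(sum(sn$offset < 0), 5)
    expect_lte(sum(sn$offset > 0), 5)
    # at most one N run, bounded length and offset
    r <- rle(ch == "N")
    nruns <- sum(r$values)
    expect_lte(nruns, 1)
    if (nruns == 1) {
      expect_lte(max(r$lengths[r$values]), 10)
      expect_gt(abs(d$indel_offset[i]), 5)
    }
    expect_equal(check_tandem_repeats(d$design_seq[i])$verdict, "pass")
    gw <- check_gc_window(d$design_seq[i], d$target_index[i])
    expect_equal(gw$verdict, "pass")
  }
})

test_that("resolving every degenerate letter to its reference base recovers the reference", {
  sim <- shared_sim()
  d <- sim$designs[sim$designs$verdict == "pass", ]
  ref <- sim$sp$panel$reference
  for (i in seq_len(min(nrow(d), 120))) {
    ch <- strsplit(d$design_seq[i], "")[[1]]
    # drop inserted Ns / restore deleted bases, then substitute reference
    win <- strsplit(ref_subseq(ref, d$chrom[i], d$pos[i] - 50,
                               d$pos[i] + 50), "")[[1]]
    if (!is.na(d$indel_kind[i]) && d$indel_kind[i] == "INS") {
      ch <- ch[ch != "N"]
    } else if (!is.na(d$indel_kind[i])) {
      ch[ch == "N"] <- win[which(ch == "N")]
    }
    amb <- which(!ch %in% c("A", "C", "G", "T"))
    for (j in amb) {
      expect_true(win[j] %in% iupac_bases(ch[j]))
      ch[j] <- win[j]
    }
    expect_equal(paste(ch, collapse = ""), paste(win, collapse = ""))
  }
})
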