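# Design-property battery, success/failure comparison, cutoff sweep.

mk_design_row <- function(pKey, offsets_left, offsets_right, seq = NULL,
                          indel_len = NA_integer_, indel_offset = NA_integer_,
                          indel_kind = NA_character_) {
  snp <- tibble::tibble(
    offset = as.integer(c(offsets_left, offsets_right)),
    pos = 1000L + as.integer(c(offsets_left, offsets_right)),
    ref_base = "A", alts = replicate(length(c(offsets_left, offsets_right)),
                                     "G", simplify = FALSE))
  tibble::tibble(
    pKey = pKey, chrom = "chr1", pos = 1000L, ref = "A", target_alt = "G",
    class = "SNP", verdict = "pass", failed_rule = "none", detail = "",
    design_seq = seq %||% bg_seq(101, seed = pKey),
    target_index = 51L,
    n_amb_left = length(offsets_left), n_amb_right = length(offsets_right),
    indel_kind = indel_kind, indel_len = indel_len,
    indel_offset = indel_offset, gc_window_pct = 50,
    flank_snps = list(snp))
}

test_that("ambiguity counts and nth distances enumerate the flank structure", {
  d <- mk_design_row(1, offsets_left = -12, offsets_right = 7)
  p <- design_properties(d)
  expect_equal(p$n_amb, 2)
  expect_equal(p$n_amb_left, 1)
  expect_equal(p$n_amb_right, 1)
  expect_equal(p$n_amb_least, 1)
  expect_equal(p$n_amb_most, 1)
  expect_equal(p$dist_left_1, 12)
  expect_equal(p$dist_right_1, 7)
  expect_equal(p$dist_shortest_1, 7)
  expect_equal(p$dist_longest_1, 12)
  expect_true(is.na(p$dist_left_2))
  expect_true(is.na(p$dist_shortest_2))

  # multiple per flank: nth-closest ordering
  d2 <- mk_design_row(2, offsets_left = c(-3, -20, -44),
                      offsets_right = c(8, 15))
  p2 <- design_properties(d2)
  expect_equal(unlist(p2[paste0("dist_left_", 1:3)], use.names = FALSE),
               c(3, 20, 44))
  expect_equal(p2$dist_shortest_2, 15)
  expect_equal(p2$dist_longest_2, 20)
  expect_true(is.na(p2$dist_longest_1) == FALSE)
  # longest requires both flanks: with an empty right flank it is undefined
  d3 <- mk_design_row(3, offsets_left = c(-5, -9), offsets_right = integer(0))
  p3 <- design_properties(d3)
  expect_true(is.na(p3$dist_longest_1))
  expect_equal(p3$dist_shortest_1, 5)
  expect_equal(p3$n_amb_most, 2)
})

test_that("designs without ambiguity have zero counts and undefined distances", {
  d <- mk_design_row(1, integer(0), integer(0))
  p <- design_properties(d)
  expect_equal(p$n_amb, 0)
  dist_cols <- grep("^dist_", names(p), value = TRUE)
  expect_true(all(is.na(unlist(p[dist_cols]))))
})

test_that("flank GC splits at the target and the battery spans 29 properties", {
  seq <- paste0(strrep("G", 50), "A", strrep("T", 50))
  d <- mk_design_row(1, integer(0), integer(0), seq = seq)
  p <- design_properties(d)
  expect_equal(p$gc_left, 100)
  expect_equal(p$gc_right, 0)
  expect_equal(p$gc_lowest, 0)
  expect_equal(p$gc_highest, 100)
  expect_equal(p$gc_total, 100 * 50 / 101)
  expect_equal(ncol(p) - 1, 29)  # pKey plus the 29 properties
})

test_that("identical groups show no shift while planted shifts are detected", {
  withr::with_seed(81, {
    d <- dplyr::bind_rows(lapply(1:40, function(i)
      mk_design_row(i, offsets_left = -sample(50, 2), offsets_right = sample(50, 1))))
    props <- design_properties(d)
    half <- rep(c(TRUE, FALSE), 20)
    cmp <- compare_properties(props, half)
    expect_true(all(cmp$p_value > 0.001))
    expect_s3_class(cmp, "kasp_property_comparison")

    # planted shift in ambiguity counts mirroring the observed 1.86 vs 2.5
    n <- 400
    succ <- lapply(seq_len(n), function(i) mk_design_row(
      i, offsets_left = -sample(50, min(5, stats::rpois(1, 0.9))),
      offsets_right = sample(50, min(5, stats::rpois(1, 0.9)))))
    fail <- lapply(seq_len(n), function(i) mk_design_row(
      n + i, offsets_left = -sample(50, min(5, stats::rpois(1, 1.3))),
      offsets_right = sample(50, min(5, stats::rpois(1, 1.2)))))
    props2 <- design_properties(dplyr::bind_rows(c(succ, fail)))
    cmp2 <- compare_properties(props2, c(rep(TRUE, n), rep(FALSE, n)))
    row <- cmp2[cmp2$property == "n_amb", ]
    expect_lt(row$p_value, 0.001)
    expect_lt(row$mean_success, row$mean_failure)
    expect_equal(row$stars, "***")
  })
})

test_that("degenerate groups are skipped rather than tested", {
  d <- dplyr::bind_rows(mk_design_row(1, -5, 10), mk_design_row(2, -6, 12),
                        mk_design_row(3, -7, 14))
  props <- design_properties(d)
  cmp <- compare_properties(props, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(cmp), 0)  # single design in the failure group
})

test_that("the rank-sum test agrees with an exact permutation oracle at small n", {
  withr::with_seed(83, {
    for (i in 1:10) {
      x <- stats::runif(sample(4:7, 1), 0, 10)
      y <- stats::runif(sample(4:7, 1), 2, 12)
      got <- suppressWarnings(stats::wilcox.test(x, y))$p.value
      expect_equal(got, oracle_wilcox_p(x, y), tolerance = 1e-8)
    }
  })
})

test_that("cutoff sweep shrinks the design set and stretches marker spacing", {
  sim <- shared_sim()
  d <- sim$designs[!is.na(sim$designs$pKey), ]
  d$marker <- paste0("K", d$pKey)
  sw <- cutoff_sweep(d, cutoffs = c(5, 4, 3, 2, 1, 0))
  expect_equal(sw$n_designs, sort(sw$n_designs, decreasing = TRUE))
  sp <- sw$median_spacing[!is.na(sw$median_spacing)]
  expect_true(all(diff(sp) >= 0))
  expect_equal(sw$n_designs[1], nrow(d))  # cutoff 5 admits every design
  # order-statistics oracle for the spacing of one subset
  sub <- d[pmax(d$n_amb_left, d$n_amb_right) <= 2, ]
  gaps <- unlist(lapply(split(sub$pos, sub$chrom),
                        function(p) diff(sort(p))))
  expect_equal(sw$median_spacing[sw$cutoff == 2], stats::median(gaps))
})

test_that("cutoff sweep reports genotyping outcomes for the tested subset", {
  sim <- shared_sim()
  d <- sim$designs[!is.na(sim$designs$pKey), ]
  d$marker <- paste0("K", d$pKey)
  g <- sim_genotyping(d$marker, seed = 44, n_samples = 60)
  sw <- cutoff_sweep(d, gm = g$gm, cutoffs = c(4, 2, 0))
  expect_true(all(sw$n_tested <= nrow(d)))
  expect_true(all(sw$pct_successful <= sw$pct_producing_results + 1e-9))
  expect_true(all(sw$pct_successful >= 0 & sw$pct_successful <= 100))
})
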