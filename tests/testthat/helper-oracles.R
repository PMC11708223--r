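# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (masks are rebuilt locally, scanning is exhaustive).

oracle_mask <- function(seq) {
  tab <- c(A = 1L, C = 2L, G = 4L, T = 8L,
           R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
           B = 14L, D = 11L, H = 7L, V = 13L, N = 15L)
  m <- tab[strsplit(toupper(seq), "")[[1]]]
  m[is.na(m)] <- 0L
  unname(m)
}

oracle_rc <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# exhaustive sliding-window best-hit set over every start and both strands
oracle_best_hits <- function(query, ref_seqs) {
  L <- nchar(query)
  hits <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else oracle_rc(query)
    qm <- oracle_mask(qs)
    for (cc in names(ref_seqs)) {
      gm <- oracle_mask(ref_seqs[[cc]])
      G <- length(gm)
      if (G < L) next
      n_start <- G - L + 1
      score <- integer(n_start)
      for (j in seq_len(L)) {
        compat <- bitwAnd(qm[j], gm[j:(G - L + j)]) > 0
        score <- score + ifelse(compat, 1L, -1L)
      }
      hits[[length(hits) + 1]] <- tibble::tibble(
        chrom = cc, start = seq_len(n_start), strand = strand, score = score)
    }
  }
  all <- dplyr::bind_rows(hits)
  best <- all[all$score == max(all$score), , drop = FALSE]
  best[order(best$chrom, best$start, best$strand), ]
}

# naive tandem-repeat maximum copy count: every start, every unit length,
# count copies forward by direct substring comparison
oracle_max_copies <- function(s, max_unit = 5) {
  n <- nchar(s)
  best <- 1L
  for (k in seq_len(min(max_unit, n %/% 2))) {
    for (i in seq_len(n - 2 * k + 1)) {
      unit <- substr(s, i, i + k - 1)
      copies <- 1L
      j <- i + k
      while (j + k - 1 <= n && substr(s, j, j + k - 1) == unit) {
        copies <- copies + 1L
        j <- j + k
      }
      best <- max(best, copies)
    }
  }
  best
}

# effect classification by whole-protein comparison (translate full CDS
# before and after the SNP; classify from the protein difference)
oracle_snp_effect <- function(cds_ref, cds_pos, alt_base) {
  mut <- cds_ref
  substr(mut, cds_pos, cds_pos) <- alt_base
  n_codon <- nchar(cds_ref) %/% 3
  p0 <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_ref, 1, 3 * n_codon))))
  p1 <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mut, 1, 3 * n_codon)),
    if.fuzzy.codon = "solve"))
  idx <- (cds_pos - 1) %/% 3 + 1
  if (idx > n_codon) return("none")
  a0 <- substr(p0, idx, idx); a1 <- substr(p1, idx, idx)
  if (idx == 1 && a0 == "M" && substr(mut, 1, 3) != "ATG") return("start_loss")
  if (a0 == "*" && a1 != "*") return("stop_loss")
  if (a1 == "*" && a0 != "*") return("premature_stop")
  if (p0 == p1) return("synonymous")
  "nonsynonymous"
}

# exact Wilcoxon rank-sum p-value by full permutation enumeration (small n)
oracle_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  all <- c(x, y)
  r <- rank(all)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  ew <- nx * ny / 2
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}
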