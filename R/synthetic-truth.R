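# Analytic ground truth for sim_panel: a deliberately plain, self-contained
# reimplementation of the design rules, kept independent of the pipeline
# code so that truth-table agreement is a genuine double-entry check.

sim_truth <- function(site_tbl, kept, depth, means, refchars, clen, feats,
                      models, n_genomes) {
  chroms <- names(clen)
  # per-chromosome count of genomes low-covered at each base
  nlow <- stats::setNames(lapply(chroms, function(cc) {
    acc <- integer(clen[[cc]])
    for (g in names(depth)) {
      acc <- acc + (depth[[g]][[cc]] < 0.1 * means[[g]])
    }
    acc
  }), chroms)

  loc_iupac <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  loc_gcw <- c(A = 0, C = 1, G = 1, T = 0, R = 0.5, Y = 0.5, S = 1, W = 0,
               K = 0.5, M = 0.5, B = 2 / 3, D = 1 / 3, H = 1 / 3, V = 2 / 3)

  kept_by_chrom <- split(kept, kept$chrom)

  n <- nrow(site_tbl)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cc <- site_tbl$chrom[i]; p <- site_tbl$pos[i]
    rec <- list(chrom = cc, pos = p, scenario = site_tbl$scenario[i],
                ref = NA_character_, alt = NA_character_,
                class = NA_character_, verdict = "fail",
                failed_rule = NA_character_, design_seq = NA_character_,
                target_index = NA_integer_, region = NA_character_,
                effect = NA_character_, functional = NA)
    kc <- kept_by_chrom[[cc]]
    at <- kc[kc$pos == p, , drop = FALSE]
    if (nrow(at) == 0) { rec$failed_rule <- "no_call"; out[[i]] <- as_row(rec); next }

    # rule 1: modal alternative, rare-allele and monomorphic screens
    key <- paste0(at$class, ":", at$ref, ">", at$alt)
    tab <- table(key)
    best <- max(tab)
    modal <- sort(names(tab)[tab == best])[1]
    j <- match(modal, key)
    rec$ref <- at$ref[j]; rec$alt <- at$alt[j]; rec$class <- at$class[j]
    n_other <- sum(tab) - tab[[modal]]
    if (n_other / n_genomes > 0.10) {
      rec$failed_rule <- "rare_allele"; out[[i]] <- as_row(rec); next
    }
    if (length(unique(at$genome_id[key == modal])) >= n_genomes) {
      rec$failed_rule <- "monomorphic"; out[[i]] <- as_row(rec); next
    }
    # rule 2: target-site coverage
    if (nlow[[cc]][p] / n_genomes > 0.10) {
      rec$failed_rule <- "target_coverage"; out[[i]] <- as_row(rec); next
    }
    # rule 3: flank coverage
    if (p - 50 < 1 || p + 50 > clen[[cc]]) {
      rec$failed_rule <- "flank_coverage"; out[[i]] <- as_row(rec); next
    }
    fidx <- setdiff((p - 50):(p + 50), p)
    if (any(nlow[[cc]][fidx] / n_genomes > 0.10)) {
      rec$failed_rule <- "flank_coverage"; out[[i]] <- as_row(rec); next
    }
    # rule 4: flanking variation admissibility
    fv <- kc[kc$pos >= p - 50 & kc$pos <= p + 50 & kc$pos != p, , drop = FALSE]
    fv <- unique(fv[, c("pos", "ref", "alt", "class")])
    ind <- fv[fv$class != "SNP", , drop = FALSE]
    snp <- fv[fv$class == "SNP", , drop = FALSE]
    bad4 <- FALSE
    ind1 <- NULL
    if (nrow(ind) > 0) {
      if (length(unique(ind$pos)) > 1) bad4 <- TRUE
      lens <- abs(nchar(ind$alt) - nchar(ind$ref))
      if (!bad4 && length(unique(ind$class)) > 1) bad4 <- TRUE
      if (!bad4 && length(unique(lens)) > 1) bad4 <- TRUE
      if (!bad4) {
        off <- ind$pos[1] - p
        if (abs(off) <= 5 || lens[1] > 10) bad4 <- TRUE
        if (!bad4 && ind$class[1] == "DEL" && off < 0 &&
            ind$pos[1] + lens[1] >= p) bad4 <- TRUE
        if (!bad4) ind1 <- list(off = off, len = lens[1], kind = ind$class[1])
      }
    }
    if (!bad4 && nrow(snp) > 0) {
      if (!all(snp$alt %in% c("A", "C", "G", "T"))) bad4 <- TRUE
      nl <- length(unique(snp$pos[snp$pos < p]))
      nr <- length(unique(snp$pos[snp$pos > p]))
      if (max(nl, nr) > 5) bad4 <- TRUE
    }
    if (bad4) {
      rec$failed_rule <- "flank_variation"; out[[i]] <- as_row(rec); next
    }
    # design sequence
    ch <- refchars[[cc]][(p - 50):(p + 50)]
    tgt <- 51L
    if (nrow(snp) > 0) {
      for (sp in unique(snp$pos)) {
        jd <- sp - p + 51
        un <- sort(unique(c(ch[jd], snp$alt[snp$pos == sp])))
        ch[jd] <- loc_iupac[[paste(un, collapse = "")]]
      }
    }
    if (!is.null(ind1)) {
      jd <- ind1$off + 51
      if (ind1$kind == "DEL") {
        span <- (jd + 1):(jd + ind1$len)
        span <- span[span >= 1 & span <= 101 & span != 51]
        ch[span] <- "N"
      } else {
        ch <- append(ch, rep("N", ind1$len), after = jd)
        if (jd < tgt) tgt <- tgt + ind1$len
      }
    }
    rec$design_seq <- paste(ch, collapse = "")
    rec$target_index <- as.integer(tgt)
    # repeat screen: any resolution with >5 consecutive copies of a 1-5mer
    core <- gsub("N", "", rec$design_seq, fixed = TRUE)
    if (any(grepl("(.{1,5})\\1{5,}", loc_expand(core), perl = TRUE))) {
      rec$failed_rule <- "repeat"; out[[i]] <- as_row(rec); next
    }
    # placement: windows wholly inside a duplicated segment tie between copies
    dups <- feats[feats$chrom == cc & feats$what %in% c("dup_src", "dup_copy"), ,
                  drop = FALSE]
    if (nrow(dups) > 0 &&
        any(p - 50 >= dups$start & p + 50 <= dups$end)) {
      rec$failed_rule <- "alignment"; out[[i]] <- as_row(rec); next
    }
    # GC window
    w <- loc_gcw[ch[(tgt - 27):(tgt + 27)]]
    pct <- 100 * mean(w, na.rm = TRUE)
    if (is.nan(pct) || pct < 35 || pct > 65) {
      rec$failed_rule <- "gc"; out[[i]] <- as_row(rec); next
    }
    rec$verdict <- "pass"; rec$failed_rule <- "none"
    eff <- loc_effect(models, refchars, cc, p, rec$ref, rec$alt, rec$class)
    rec$region <- eff$region; rec$effect <- eff$effect
    rec$functional <- eff$functional
    out[[i]] <- as_row(rec)
  }
  dplyr::bind_rows(out)
}

as_row <- function(rec) tibble::as_tibble(rec)

# plain recursive ambiguity expansion (truth-side)
loc_expand <- function(s) {
  sets <- list(R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"))
  ch <- strsplit(s, "")[[1]]
  amb <- which(ch %in% names(sets))
  if (length(amb) == 0) return(s)
  fixed <- ch
  combos <- expand.grid(lapply(amb, function(a) sets[[ch[a]]]),
                        stringsAsFactors = FALSE)
  vapply(seq_len(nrow(combos)), function(r) {
    fixed[amb] <- as.character(unlist(combos[r, ], use.names = FALSE))
    paste(fixed, collapse = "")
  }, character(1))
}

# truth-side effect classification (first functional transcript wins)
loc_effect <- function(models, refchars, cc, p, ref, alt, class) {
  none <- list(region = "intergenic", effect = "none", functional = FALSE)
  if (is.null(models)) return(none)
  span <- switch(class, SNP = c(p, p), INS = c(p, p + 1),
                 DEL = c(p + 1, p + nchar(ref) - 1))
  mods <- models[models$chrom == cc, , drop = FALSE]
  recs <- list()
  for (tid in unique(mods$transcript_id)) {
    tx <- mods[mods$transcript_id == tid, , drop = FALSE]
    if (span[2] < min(tx$start) || span[1] > max(tx$end)) next
    cds <- tx[tx$feature == "CDS", , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    hit_cds <- nrow(cds) > 0 &&
      (any(span[1] <= cds$end & span[2] >= cds$start) ||
         (class == "INS" && any(p >= cds$start & p + 1 <= cds$end)))
    if (hit_cds) {
      eff <- loc_cds_effect(cds, refchars[[cc]], p, ref, alt, class,
                            tx$strand[1], span)
      recs[[length(recs) + 1]] <- list(
        region = "CDS", effect = eff,
        functional = eff %in% c("nonsynonymous", "premature_stop",
                                "stop_loss", "start_loss", "frameshift",
                                "nonframeshift"))
      next
    }
    reg <- "intron"
    for (feat in c("UTR5", "UTR3")) {
      ft <- tx[tx$feature == feat, , drop = FALSE]
      if (nrow(ft) > 0 && any(span[1] <= ft$end & span[2] >= ft$start)) {
        reg <- feat
        break
      }
    }
    recs[[length(recs) + 1]] <- list(region = reg, effect = "none",
                                     functional = FALSE)
  }
  if (length(recs) == 0) return(none)
  fun <- vapply(recs, function(r) r$functional, logical(1))
  pick <- if (any(fun)) recs[[which(fun)[1]]] else recs[[1]]
  pick
}

loc_cds_effect <- function(cds, chrom_chars, p, ref, alt, class, strand, span) {
  gpos <- unlist(Map(seq.int, cds$start, cds$end))
  seq <- paste(chrom_chars[gpos], collapse = "")
  if (strand == "-") {
    seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                 collapse = "")
    gpos <- rev(gpos)
  }
  code <- Biostrings::GENETIC_CODE
  if (class == "SNP") {
    ci <- match(p, gpos)
    base <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
    n_codon <- nchar(seq) %/% 3
    idx <- (ci - 1) %/% 3 + 1
    if (idx > n_codon) return("none")
    off <- (ci - 1) %% 3 + 1
    codon <- substr(seq, (idx - 1) * 3 + 1, idx * 3)
    mut <- codon
    substr(mut, off, off) <- base
    aa0 <- code[[codon]]; aa1 <- code[[mut]]
    if (idx == 1 && aa0 == "M" && mut != "ATG") return("start_loss")
    if (aa0 == "*" && aa1 != "*") return("stop_loss")
    if (aa1 == "*" && aa0 != "*") return("premature_stop")
    if (aa0 == aa1) return("synonymous")
    return("nonsynonymous")
  }
  if (class == "INS") {
    len <- nchar(alt) - nchar(ref)
  } else {
    del <- seq.int(span[1], span[2])
    len <- sum(del %in% gpos)
    if (any(del %in% utils::head(if (strand == "+") sort(gpos) else sort(gpos, decreasing = TRUE), 3)))
      return("start_loss")
    if (any(del %in% utils::tail(if (strand == "+") sort(gpos) else sort(gpos, decreasing = TRUE), 3)))
      return("stop_loss")
  }
  if (len %% 3 != 0) "frameshift" else "nonframeshift"
}
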