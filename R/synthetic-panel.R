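#' Generate a synthetic resequenced-genome panel with analytic ground truth
#'
#' Plants target variants, flanking SNPs/indels and depth deserts in a panel
#' of `n_genomes` genomes so that every design rule is exercised on both
#' sides of its boundary, and records the expected verdict of every planted
#' site by applying the rules analytically at generation time. The truth
#' verdicts are computed by an independent straight-line reimplementation of
#' the rules inside this generator (not by calling the pipeline), so tests
#' against them are a genuine double-entry check.
#'
#' @param ref_obj Output of [sim_reference()].
#' @param seed Integer seed.
#' @param n_genomes Panel size (default 20).
#' @param n_sites Number of planted target sites (default 2000).
#' @param legacy_divergence Per-base substitution rate used to derive the
#'   second ("legacy") assembly from the primary (default 0.005).
#' @return List: `panel` (a [genome_panel] holding the depth-filtered
#'   calls), `calls_all` (pre-filter calls, for VCF emission), `legacy`
#'   (diverged [reference_genome]), and `truth` (tibble per planted site:
#'   coordinates and alleles, `scenario`, `verdict`, `failed_rule`,
#'   `design_seq`, `target_index`, `region`, `effect`, `functional`).
#' @export
sim_panel <- function(ref_obj, seed = 1, n_genomes = 20, n_sites = 2000,
                      legacy_divergence = 0.005) {
  set.seed(seed)
  ref <- ref_obj$reference
  models <- ref_obj$models
  feats <- ref_obj$features
  chroms <- names(ref$seq)
  clen <- stats::setNames(Biostrings::width(ref$seq), chroms)
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  means <- stats::setNames(round(stats::runif(n_genomes, 6, 90), 1), genomes)

  refchars <- lapply(chroms, function(cc) strsplit(as.character(ref$seq[[cc]]), "")[[1]])
  names(refchars) <- chroms

  # --- depth vectors -------------------------------------------------------
  depth <- list()  # depth[[genome]][[chrom]] integer vector
  for (g in genomes) {
    depth[[g]] <- list()
    for (cc in chroms) {
      v <- integer(clen[[cc]])
      pos <- 1L
      while (pos <= clen[[cc]]) {
        seg <- sample(2000:5000, 1)
        v[pos:min(clen[[cc]], pos + seg - 1)] <-
          max(1L, as.integer(round(means[[g]] * stats::runif(1, 0.6, 1.4))))
        pos <- pos + seg
      }
      # background low-coverage deserts
      lowmax <- max(0L, as.integer(ceiling(0.1 * means[[g]])) - 1L)
      for (i in seq_len(3)) {
        s <- sample.int(clen[[cc]] - 500, 1)
        v[s:(s + sample(100:400, 1))] <- sample(0:lowmax, 1)
      }
      depth[[g]][[cc]] <- v
    }
  }

  # --- position bookkeeping ------------------------------------------------
  occ <- lapply(chroms, function(cc) rep(FALSE, clen[[cc]]))
  names(occ) <- chroms
  take <- function(cc, s, e) {
    s <- max(1L, s); e <- min(clen[[cc]], e)
    if (any(occ[[cc]][s:e])) return(FALSE)
    occ[[cc]][s:e] <<- TRUE
    TRUE
  }

  # --- choose site positions ----------------------------------------------
  scen_pool <- c(pass = 0.44, boundary_pass = 0.05, rare_allele = 0.08,
                 monomorphic = 0.04, tcov = 0.06, fcov = 0.05,
                 indel_close = 0.04, indel_long = 0.03, two_indels = 0.03,
                 six_snps = 0.04, unequal_indels = 0.03, mixed_kind = 0.02,
                 cds = 0.09)
  sites <- list()
  add_site <- function(cc, p, scenario) {
    sites[[length(sites) + 1]] <<- list(chrom = cc, pos = as.integer(p),
                                        scenario = scenario)
  }
  # tract-anchored sites (repeat / GC / alignment behaviour emerges there)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    mid <- as.integer((f$start + f$end) / 2)
    if (f$what == "dup_src") next  # keep source copy variant-free
    if (mid > 60 && mid < clen[[f$chrom]] - 60 && take(f$chrom, mid - 3, mid + 3)) {
      add_site(f$chrom, mid, "pass")
    }
  }
  # truncated-flank sites near chromosome ends
  for (cc in chroms) {
    for (p in c(25L, clen[[cc]] - 20L)) {
      if (take(cc, p - 3, p + 3)) add_site(cc, p, "edge")
    }
  }
  # CDS sites for effect-class coverage
  if (!is.null(models)) {
    cdsint <- models[models$feature == "CDS", , drop = FALSE]
    n_cds <- min(round(unname(scen_pool["cds"]) * n_sites), nrow(cdsint) * 4)
    for (i in seq_len(n_cds)) {
      r <- cdsint[sample.int(nrow(cdsint), 1), ]
      p <- sample(r$start:r$end, 1)
      if (p > 60 && p < clen[[r$chrom]] - 60 && take(r$chrom, p - 3, p + 3)) {
        add_site(r$chrom, p, "pass")
      }
    }
  }
  # bulk sites
  scen_rest <- scen_pool[setdiff(names(scen_pool), "cds")]
  while (length(sites) < n_sites) {
    cc <- sample(chroms, 1)
    p <- sample.int(clen[[cc]] - 120, 1) + 60
    if (!take(cc, p - 3, p + 3)) next
    add_site(cc, p, sample(names(scen_rest), 1, prob = scen_rest))
  }

  # --- plant calls ---------------------------------------------------------
  calls <- list()
  emit <- function(g, cc, p, refa, alta, class, dp, zyg) {
    calls[[length(calls) + 1]] <<- list(g, cc, as.integer(p), refa, alta,
                                        class, as.integer(dp), zyg)
  }
  rand_depth <- function(n, force_first = TRUE) {
    d <- ifelse(stats::runif(n) < 0.04, sample(1:4, n, replace = TRUE),
                sample(5:60, n, replace = TRUE))
    if (force_first && n > 0) d[1] <- max(d[1], 5L)
    as.integer(d)
  }
  other_base <- function(b, exclude = character(0)) {
    sample(setdiff(c("A", "C", "G", "T"), c(b, exclude)), 1)
  }
  rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

  floorN <- floor(0.10 * n_genomes)        # carriers at exactly 10% pass
  site_meta <- vector("list", length(sites))
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    cc <- s$chrom; p <- s$pos
    refb <- refchars[[cc]][p]
    scenario <- s$scenario
    # target allele
    cls <- sample(c("SNP", "INS", "DEL"), 1, prob = c(0.8, 0.1, 0.1))
    if (p + 6 > clen[[cc]]) cls <- "SNP"
    if (cls == "SNP") {
      refa <- refb; alta <- other_base(refb)
    } else if (cls == "INS") {
      refa <- refb; alta <- paste0(refb, rnd_seq(sample(1:3, 1)))
    } else {
      # deleted span stays inside the site's own reserved zone (p-3..p+3)
      L <- sample(1:3, 1)
      refa <- paste(refchars[[cc]][p:(p + L)], collapse = "")
      alta <- refb
    }
    # carriers
    if (scenario == "monomorphic") {
      m <- n_genomes; o <- 0
    } else if (scenario == "rare_allele") {
      o <- sample((floorN + 1):max(floorN + 1, floor(0.25 * n_genomes)), 1)
      m <- sample((o + 1):max(o + 1, n_genomes - o - 1), 1)
    } else if (scenario == "boundary_pass") {
      o <- floorN                           # exactly 10%: passes
      m <- sample((o + 1):(n_genomes - o - 1), 1)
    } else {
      m <- sample(2:(n_genomes - 2), 1)
      o <- if (stats::runif(1) < 0.15) sample(0:floorN, 1) else 0
      o <- min(o, n_genomes - m - 1)
    }
    carriers <- sample(genomes, m)
    others <- if (o > 0) sample(setdiff(genomes, carriers), o) else character(0)
    dpc <- rand_depth(m)
    zygc <- ifelse(stats::runif(m) < 0.1, "het", "hom")
    for (j in seq_along(carriers)) emit(carriers[j], cc, p, refa, alta, cls,
                                        dpc[j], zygc[j])
    if (o > 0) {
      # a second, different alternative allele at the same site
      if (cls == "SNP") { alt2 <- other_base(refb, alta) }
      else if (cls == "INS") { alt2 <- paste0(refb, rnd_seq(nchar(alta) - 1 + 1)) }
      else { alt2 <- refb; }
      if (cls == "DEL") {
        # use a SNP as the competing allele to avoid span bookkeeping
        for (g in others) emit(g, cc, p, refb, other_base(refb), "SNP",
                               max(5L, sample(5:60, 1)), "hom")
      } else {
        for (g in others) emit(g, cc, p, refa, alt2, cls,
                               max(5L, sample(5:60, 1)), "hom")
      }
    }
    # coverage scenarios
    if (scenario == "tcov") {
      k <- sample((floorN + 1):max(floorN + 1, floorN + 3), 1)
      for (g in sample(genomes, k)) {
        lv <- max(0L, as.integer(ceiling(0.1 * means[[g]])) - 1L)
        depth[[g]][[cc]][max(1, p - 2):min(clen[[cc]], p + 2)] <- lv
      }
    } else if (scenario == "fcov") {
      off <- sample(c(-50:-6, 6:50), 1)
      k <- sample((floorN + 1):max(floorN + 1, floorN + 3), 1)
      for (g in sample(genomes, k)) {
        lv <- max(0L, as.integer(ceiling(0.1 * means[[g]])) - 1L)
        fp <- p + off
        depth[[g]][[cc]][max(1, fp - 1):min(clen[[cc]], fp + 1)] <- lv
      }
    }
    # flanking variation scenarios
    plant_flank_snp <- function(off, n_carr = sample(1:3, 1)) {
      fp <- p + off
      if (fp < 1 || fp > clen[[cc]]) return(FALSE)
      if (!take(cc, fp, fp)) return(FALSE)
      fb <- refchars[[cc]][fp]
      fa <- other_base(fb)
      for (g in sample(genomes, n_carr)) emit(g, cc, fp, fb, fa, "SNP",
                                              max(5L, sample(5:60, 1)), "hom")
      TRUE
    }
    plant_flank_indel <- function(off, len, kind) {
      fp <- p + off
      if (fp < 2 || fp + len + 1 > clen[[cc]]) return(FALSE)
      if (!take(cc, fp, fp + len)) return(FALSE)
      fb <- refchars[[cc]][fp]
      if (kind == "INS") {
        fa <- paste0(fb, rnd_seq(len)); fr <- fb
      } else {
        fr <- paste(refchars[[cc]][fp:(fp + len)], collapse = ""); fa <- fb
      }
      for (g in sample(genomes, sample(1:3, 1))) emit(g, cc, fp, fr, fa, kind,
                                                      max(5L, sample(5:60, 1)), "hom")
      TRUE
    }
    if (scenario %in% c("pass", "boundary_pass", "cds")) {
      # light, admissible flank structure
      nsnp <- sample(0:5, 1, prob = c(0.35, 0.3, 0.15, 0.1, 0.05, 0.05))
      for (j in seq_len(nsnp)) plant_flank_snp(sample(c(-50:-1, 1:50), 1))
      if (stats::runif(1) < 0.12) {
        plant_flank_indel(sample(c(-50:-16, 6:40), 1), sample(1:10, 1),
                          sample(c("INS", "DEL"), 1))
      }
    } else if (scenario == "six_snps") {
      sgn <- sample(c(-1, 1), 1)
      offs <- sample(1:50, 6) * sgn
      for (off in offs) plant_flank_snp(off)
    } else if (scenario == "indel_close") {
      plant_flank_indel(sample(c(-5:-2, 2:5), 1), sample(1:4, 1),
                        sample(c("INS", "DEL"), 1))
    } else if (scenario == "indel_long") {
      plant_flank_indel(sample(c(-40:-16, 6:38), 1), sample(11:12, 1),
                        sample(c("INS", "DEL"), 1))
    } else if (scenario == "two_indels") {
      plant_flank_indel(sample(6:30, 1), sample(1:6, 1), "INS")
      plant_flank_indel(-sample(7:30, 1), sample(1:6, 1), "DEL")
    } else if (scenario == "unequal_indels") {
      fp <- p + sample(c(-30:-16, 6:30), 1)
      if (fp >= 2 && fp + 5 <= clen[[cc]] && take(cc, fp, fp + 5)) {
        fb <- refchars[[cc]][fp]
        g2 <- sample(genomes, 2)
        emit(g2[1], cc, fp, paste(refchars[[cc]][fp:(fp + 2)], collapse = ""),
             fb, "DEL", sample(5:60, 1), "hom")
        emit(g2[2], cc, fp, paste(refchars[[cc]][fp:(fp + 3)], collapse = ""),
             fb, "DEL", sample(5:60, 1), "hom")
      }
    } else if (scenario == "mixed_kind") {
      fp <- p + sample(c(-30:-16, 6:30), 1)
      if (fp >= 2 && fp + 4 <= clen[[cc]] && take(cc, fp, fp + 4)) {
        fb <- refchars[[cc]][fp]
        g2 <- sample(genomes, 2)
        emit(g2[1], cc, fp, paste(refchars[[cc]][fp:(fp + 2)], collapse = ""),
             fb, "DEL", sample(5:60, 1), "hom")
        emit(g2[2], cc, fp, fb, paste0(fb, rnd_seq(2)), "INS",
             sample(5:60, 1), "hom")
      }
    }
    site_meta[[si]] <- list(cc, p, scenario, refa, alta, cls)
  }
  col <- function(rows, i, cast = identity) cast(vapply(rows, function(r)
    as.character(r[[i]]), character(1)))
  calls_all <- tibble::tibble(
    genome_id = col(calls, 1), chrom = col(calls, 2),
    pos = col(calls, 3, as.integer), ref = col(calls, 4),
    alt = col(calls, 5), class = col(calls, 6),
    depth = col(calls, 7, as.integer), zygosity = col(calls, 8))
  site_tbl <- tibble::tibble(
    chrom = col(site_meta, 1), pos = col(site_meta, 2, as.integer),
    scenario = col(site_meta, 3), ref = col(site_meta, 4),
    alt = col(site_meta, 5), class = col(site_meta, 6))

  # --- depth-filter view (generator's own rule) ---------------------------
  kept <- calls_all[!(calls_all$class %in% c("SNP", "INS") & calls_all$depth < 5), ,
                    drop = FALSE]

  # --- depth tracks for the panel -----------------------------------------
  tracks <- list()
  for (g in genomes) {
    ivs <- list()
    for (cc in chroms) {
      r <- rle(depth[[g]][[cc]])
      e <- cumsum(r$lengths)
      s <- e - r$lengths + 1
      nz <- r$values > 0
      ivs[[length(ivs) + 1]] <- tibble::tibble(chrom = cc, start = s[nz],
                                               end = e[nz], depth = r$values[nz])
    }
    tracks[[g]] <- depth_track(dplyr::bind_rows(ivs), g, means[[g]])
  }
  panel <- genome_panel(ref, kept, tracks)

  # --- legacy assembly -----------------------------------------------------
  legacy_seqs <- character(0)
  for (cc in chroms) {
    ch <- refchars[[cc]]
    nmut <- stats::rbinom(1, clen[[cc]], legacy_divergence)
    at <- sample.int(clen[[cc]], nmut)
    ch[at] <- vapply(ch[at], other_base, character(1))
    legacy_seqs[[cc]] <- paste(ch, collapse = "")
  }
  legacy <- reference_genome(legacy_seqs, "simlegacy")

  truth <- sim_truth(site_tbl, kept, depth, means, refchars, clen, feats,
                     models, n_genomes)
  list(panel = panel, calls_all = calls_all, legacy = legacy, truth = truth)
}
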