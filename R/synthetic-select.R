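#' Generate trait targets for a synthetic reference
#'
#' Anchors roughly half the targets at planted gene positions and the rest
#' at random loci, mimicking breeder-specified gene and SSR targets.
#'
#' @param ref_obj Output of [sim_reference()].
#' @param seed Integer seed.
#' @param n_targets Number of targets.
#' @return Tibble `target_id`, `name`, `chrom`, `start`, `end`, `kind`.
#' @export
sim_targets <- function(ref_obj, seed = 1, n_targets = 30) {
  set.seed(seed)
  ref <- ref_obj$reference
  chroms <- names(ref$seq)
  clen <- stats::setNames(Biostrings::width(ref$seq), chroms)
  rows <- list()
  models <- ref_obj$models
  gene_tbl <- if (!is.null(models)) {
    models %>%
      dplyr::group_by(.data$gene_id, .data$chrom) %>%
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop")
  } else NULL
  for (i in seq_len(n_targets)) {
    if (!is.null(gene_tbl) && i <= min(nrow(gene_tbl), ceiling(n_targets / 2))) {
      g <- gene_tbl[i, ]
      rows[[i]] <- tibble::tibble(
        target_id = sprintf("T%03d", i), name = g$gene_id, chrom = g$chrom,
        start = as.integer(g$start), end = as.integer(g$end), kind = "gene")
    } else {
      cc <- sample(chroms, 1)
      pp <- sample.int(clen[[cc]] - 200, 1) + 100
      rows[[i]] <- tibble::tibble(
        target_id = sprintf("T%03d", i), name = sprintf("SSR%03d", i),
        chrom = cc, start = as.integer(pp), end = as.integer(pp),
        kind = "SSR")
    }
  }
  dplyr::bind_rows(rows)
}

# Generator-side reimplementation of the candidate search, per-target
# selection and quota trimming, used as the independent expectation for
# panel-membership truth. Returns list(selected = tibble(target_id, chrom,
# pos), panel = tibble(chrom, pos) distinct).
sim_selection_truth <- function(targets, truth, kept_calls, genomes,
                                k = 5, quota = Inf, max_dist = 20000,
                                dedup_bp = 100) {
  pass <- truth[truth$verdict == "pass", , drop = FALSE]
  pass <- pass[order(pass$chrom, pass$pos), , drop = FALSE]
  pass$ord <- seq_len(nrow(pass))  # stands in for the pKey tie-break

  # predicted-genotype signature per passing site, from the kept calls
  sig <- character(nrow(pass))
  for (i in seq_len(nrow(pass))) {
    at <- kept_calls[kept_calls$chrom == pass$chrom[i] &
                       kept_calls$pos == pass$pos[i], , drop = FALSE]
    st <- stats::setNames(rep("reference", length(genomes)), sort(genomes))
    is_t <- at$alt == pass$alt[i] & at$ref == pass$ref[i] &
      at$class == pass$class[i]
    st[at$genome_id[!is_t]] <- "unknown"
    tg <- at[is_t, , drop = FALSE]
    st[tg$genome_id] <- ifelse(tg$zygosity == "het", "het", "target")
    sig[i] <- paste(st[sort(names(st))], collapse = "|")
  }
  pass$sig <- sig

  sel <- list()
  for (t in seq_len(nrow(targets))) {
    tg <- targets[t, ]
    cand <- pass[pass$chrom == tg$chrom, , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- pmax(0L, pmax(tg$start - cand$pos, cand$pos - tg$end))
    cand <- cand[d <= max_dist, , drop = FALSE]
    d <- d[d <= max_dist]
    cand$distance <- d
    cand <- cand[order(!cand$functional, cand$distance, cand$ord), , drop = FALSE]
    chosen <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= k) break
      dup <- FALSE
      for (j in chosen) {
        if (abs(cand$pos[i] - cand$pos[j]) <= dedup_bp &&
            cand$sig[i] == cand$sig[j]) { dup <- TRUE; break }
      }
      if (!dup) chosen <- c(chosen, i)
    }
    if (length(chosen) > 0) {
      cs <- cand[chosen, , drop = FALSE]
      cs$target_id <- tg$target_id
      sel[[length(sel) + 1]] <- cs
    }
  }
  seltab <- dplyr::bind_rows(sel)
  # quota trim
  repeat {
    keyset <- unique(paste(seltab$chrom, seltab$pos))
    if (length(keyset) <= quota) break
    counts <- sort(table(seltab$target_id), decreasing = TRUE)
    maxt <- sort(names(counts)[counts == counts[[1]]])
    pick <- NULL
    for (tid in maxt) {
      rows <- seltab[seltab$target_id == tid & !seltab$functional, , drop = FALSE]
      if (nrow(rows) > 0) {
        rows <- rows[order(-rows$distance, -rows$ord), , drop = FALSE]
        pick <- rows[1, ]; break
      }
    }
    if (is.null(pick)) {
      rows <- seltab[seltab$target_id == maxt[1], , drop = FALSE]
      rows <- rows[order(-rows$distance, -rows$ord), , drop = FALSE]
      pick <- rows[1, ]
    }
    seltab <- seltab[!(seltab$target_id == pick$target_id &
                         seltab$pos == pick$pos &
                         seltab$chrom == pick$chrom), , drop = FALSE]
  }
  list(selected = seltab[, c("target_id", "chrom", "pos", "distance",
                             "functional")],
       panel = dplyr::distinct(seltab[, c("chrom", "pos")]))
}

#' Write a full synthetic scenario to disk
#'
#' Emits the primary and legacy reference FASTAs, one VCF and one depth TSV
#' per genome, the gene models GFF3, the targets TSV and the truth table
#' TSV, so the whole pipeline can be driven from files.
#'
#' @param ref_obj Output of [sim_reference()].
#' @param panel_obj Output of [sim_panel()].
#' @param targets Optional targets tibble from [sim_targets()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
sim_write_all <- function(ref_obj, panel_obj, targets = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$reference <- file.path(dir, "reference.fa")
  write_reference(ref_obj$reference, paths$reference)
  paths$legacy <- file.path(dir, "legacy.fa")
  write_reference(panel_obj$legacy, paths$legacy)
  if (!is.null(ref_obj$models)) {
    paths$gff <- file.path(dir, "genes.gff3")
    write_gene_models(ref_obj$models, paths$gff)
  }
  vcf_dir <- file.path(dir, "vcf"); dir.create(vcf_dir, showWarnings = FALSE)
  depth_dir <- file.path(dir, "depth"); dir.create(depth_dir, showWarnings = FALSE)
  panel <- panel_obj$panel
  for (g in panel$genomes) {
    cg <- panel_obj$calls_all[panel_obj$calls_all$genome_id == g, , drop = FALSE]
    write_variant_calls(cg, file.path(vcf_dir, paste0(g, ".vcf")))
    write_depth_track(panel$depth_tracks[[g]],
                      file.path(depth_dir, paste0(g, ".depth.tsv")))
  }
  paths$vcf_dir <- vcf_dir; paths$depth_dir <- depth_dir
  if (!is.null(targets)) {
    paths$targets <- file.path(dir, "targets.tsv")
    utils::write.table(as.data.frame(targets), paths$targets, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(as.data.frame(panel_obj$truth), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
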