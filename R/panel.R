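#' Assemble a multi-genome variant panel
#'
#' A genome panel couples one reference assembly with the variant calls and
#' depth tracks of N resequenced genomes. It is the input to the sequential
#' design filters: rare-allele removal, target-site coverage and flank-site
#' coverage.
#'
#' @param reference A [reference_genome].
#' @param calls Tibble of variant calls for all genomes (rows as returned by
#'   [read_variant_calls()]).
#' @param depth_tracks Named list of [depth_track] objects, one per genome;
#'   names are genome ids. Every genome appearing in `calls` must have a
#'   track.
#' @return An object of class `genome_panel`.
#' @export
genome_panel <- function(reference, calls, depth_tracks) {
  stopifnot(inherits(reference, "reference_genome"))
  genomes <- names(depth_tracks)
  if (length(genomes) < 2) stop("a panel needs at least 2 genomes")
  missing <- setdiff(unique(calls$genome_id), genomes)
  if (length(missing) > 0) {
    stop("genomes with calls but no depth track: ", paste(missing, collapse = ", "))
  }
  structure(
    list(reference = reference, genomes = genomes,
         calls = tibble::as_tibble(calls), depth_tracks = depth_tracks),
    class = "genome_panel"
  )
}

#' @export
print.genome_panel <- function(x, ...) {
  cat("<genome_panel> ", length(x$genomes), " genomes vs ",
      x$reference$assembly_id, "; ", nrow(x$calls), " calls\n", sep = "")
  invisible(x)
}

#' @rdname genome_panel
#' @param panel A `genome_panel`.
#' @export
n_genomes <- function(panel) length(panel$genomes)

# allele key: class + ref + alt uniquely identifies an alternative allele at
# a site; ties between equally common alleles are broken lexicographically
# on this key
allele_key <- function(class, ref, alt) paste0(class, ":", ref, ">", alt)

#' Candidate target sites of a panel
#'
#' Every distinct (chrom, pos, ref, alt) with at least one passing call is a
#' candidate for KASP design.
#'
#' @param panel A [genome_panel].
#' @return Tibble `chrom`, `pos` with one row per candidate site (alleles are
#'   resolved later by [select_target_allele()]).
#' @export
candidate_sites <- function(panel) {
  dplyr::distinct(panel$calls, .data$chrom, .data$pos) %>%
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Filter 1: choose the target allele, removing rare-allele and monomorphic
#' sites
#'
#' At each candidate site the most common alternative allele becomes the
#' target. The site fails `rare_allele` when the lines carrying neither the
#' reference allele nor that modal alternative exceed 10% of the panel
#' (strictly more than `max_other_frac`), and fails `monomorphic` when every
#' line carries the same non-reference allele (no polymorphism left to
#' assay). Lines with no call at the site count as reference carriers; a
#' heterozygous line counts as carrying its alternative allele (set
#' `het_weight = 0.5` to count het lines as half a carrier).
#'
#' @param site_calls Calls at one site: tibble with `genome_id`, `ref`,
#'   `alt`, `class`, `zygosity`.
#' @param n_genomes Panel size N.
#' @param max_other_frac Strict threshold on the non-ref/non-target fraction
#'   (default 0.10).
#' @param het_weight Carrier weight of a heterozygous line (1 or 0.5).
#' @return A one-row tibble: `verdict` (`"pass"`/`"fail"`), `failed_rule`
#'   (`"none"`, `"rare_allele"`, `"monomorphic"`), and for passing sites
#'   `ref`, `target_alt`, `class`, `n_carriers`, plus `detail`.
#' @export
select_target_allele <- function(site_calls, n_genomes,
                                 max_other_frac = 0.10, het_weight = 1) {
  if (nrow(site_calls) == 0) stop("no alternative allele at site (caller bug)")
  w <- ifelse(site_calls$zygosity == "het", het_weight, 1)
  key <- allele_key(site_calls$class, site_calls$ref, site_calls$alt)
  counts <- tapply(w, key, sum)
  counts <- counts[order(-counts, names(counts))]  # modal, lexicographic ties
  target_key <- names(counts)[1]
  n_target <- counts[[1]]
  n_other <- sum(counts) - n_target
  i <- match(target_key, key)
  mk <- function(verdict, rule, detail = "") tibble::new_tibble(list(
    verdict = verdict, failed_rule = rule, detail = detail,
    ref = site_calls$ref[i], target_alt = site_calls$alt[i],
    class = site_calls$class[i], n_carriers = n_target
  ), nrow = 1L)
  if (n_other / n_genomes > max_other_frac) {
    return(mk("fail", "rare_allele",
              sprintf("%.3g of lines carry other alternatives", n_other / n_genomes)))
  }
  # count distinct lines carrying the target allele (weights only affect the
  # rare-allele fraction); monomorphic means every line is a target carrier
  n_lines_target <- length(unique(site_calls$genome_id[key == target_key]))
  if (n_lines_target >= n_genomes) {
    return(mk("fail", "monomorphic", "all lines carry the non-reference allele"))
  }
  mk("pass", "none")
}

# per-chromosome count of genomes whose depth is below 0.1 x their mean, at
# every base (internal work-horse for filters 2 and 3)
low_coverage_counts <- function(panel, low_depth_frac = 0.10) {
  ref <- panel$reference
  out <- stats::setNames(
    lapply(names(ref$seq), function(cc) rep(0L, ref_length(ref, cc))),
    names(ref$seq)
  )
  for (gid in panel$genomes) {
    tr <- panel$depth_tracks[[gid]]
    thr <- low_depth_frac * attr(tr, "mean_depth")
    dv <- depth_vectors(tr, ref)
    for (cc in names(out)) {
      out[[cc]] <- out[[cc]] + (dv[[cc]] < thr)
    }
  }
  out
}

#' Filter 2: reject targets with low coverage at the target site
#'
#' A genome is "low" at a base when its read depth there is strictly below
#' `low_depth_frac` (default 0.1) times that genome's mean read depth. The
#' site fails when low genomes exceed `max_low_genomes_frac` of the panel
#' (strictly; exactly 10% passes).
#'
#' @param panel A [genome_panel].
#' @param chrom,pos Site coordinates.
#' @param low_depth_frac Fraction of the genome mean below which a base is
#'   low-covered.
#' @param max_low_genomes_frac Strict threshold on the fraction of low
#'   genomes.
#' @param nlow Optional precomputed per-chromosome low-genome count vectors
#'   (internal fast path used by `filter_sites()`).
#' @return One-row tibble `verdict`, `failed_rule` (`"target_coverage"` or
#'   `"none"`), `detail`.
#' @export
check_target_coverage <- function(panel, chrom, pos, low_depth_frac = 0.10,
                                  max_low_genomes_frac = 0.10, nlow = NULL) {
  if (is.null(nlow)) nlow <- low_coverage_counts(panel, low_depth_frac)
  n <- n_genomes(panel)
  k <- nlow[[chrom]][pos]
  if (k / n > max_low_genomes_frac) {
    tibble::new_tibble(list(verdict = "fail", failed_rule = "target_coverage",
                            detail = sprintf("low coverage in %d/%d genomes",
                                             k, n)), nrow = 1L)
  } else {
    tibble::new_tibble(list(verdict = "pass", failed_rule = "none",
                            detail = ""), nrow = 1L)
  }
}

#' Filter 3: reject targets with low coverage anywhere in the flanks
#'
#' Each of the 100 flanking positions (50 bp either side of the target) is
#' subjected to the filter-2 criterion; a single failing flank base rejects
#' the target. Targets closer than `flank_bp` to a chromosome end fail with
#' detail `"truncated flank"`. Setting `any_genome = TRUE` applies the
#' stricter reading in which one low genome at any flank base suffices to
#' reject.
#'
#' @inheritParams check_target_coverage
#' @param flank_bp Flank width (default 50).
#' @param any_genome Stricter aggregation: any single low genome at a flank
#'   base rejects.
#' @return One-row tibble `verdict`, `failed_rule` (`"flank_coverage"` or
#'   `"none"`), `detail`.
#' @export
check_flank_coverage <- function(panel, chrom, pos, flank_bp = 50,
                                 low_depth_frac = 0.10,
                                 max_low_genomes_frac = 0.10,
                                 any_genome = FALSE, nlow = NULL) {
  L <- ref_length(panel$reference, chrom)
  if (pos - flank_bp < 1 || pos + flank_bp > L) {
    return(tibble::new_tibble(list(verdict = "fail",
                                   failed_rule = "flank_coverage",
                                   detail = "truncated flank"), nrow = 1L))
  }
  if (is.null(nlow)) nlow <- low_coverage_counts(panel, low_depth_frac)
  n <- n_genomes(panel)
  idx <- c((pos - flank_bp):(pos - 1), (pos + 1):(pos + flank_bp))
  k <- nlow[[chrom]][idx]
  thr <- if (any_genome) 0 else max_low_genomes_frac * n
  bad <- which(k > thr)
  if (length(bad) > 0) {
    tibble::new_tibble(list(verdict = "fail", failed_rule = "flank_coverage",
                            detail = sprintf("%d flank base(s) low-covered",
                                             length(bad))), nrow = 1L)
  } else {
    tibble::new_tibble(list(verdict = "pass", failed_rule = "none",
                            detail = ""), nrow = 1L)
  }
}

#' Run filters 1-3 over all candidate sites of a panel
#'
#' Applies rare-allele/monomorphic selection, target-site coverage and
#' flank-site coverage in fixed order; each site receives at most one failed
#' rule (the first that rejects it).
#'
#' @param panel A [genome_panel].
#' @param sites Optional tibble `chrom`, `pos` restricting evaluation to
#'   those sites (default: all [candidate_sites()]).
#' @param max_other_frac,het_weight See [select_target_allele()].
#' @param low_depth_frac,max_low_genomes_frac See [check_target_coverage()].
#' @param flank_bp,any_genome See [check_flank_coverage()].
#' @return Tibble, one row per site: `chrom`, `pos`, `verdict`,
#'   `failed_rule`, `detail`, and for sites passing filter 1 the chosen
#'   `ref`, `target_alt`, `class`, `n_carriers`.
#' @export
filter_sites <- function(panel, sites = NULL,
                         max_other_frac = 0.10, het_weight = 1,
                         low_depth_frac = 0.10, max_low_genomes_frac = 0.10,
                         flank_bp = 50, any_genome = FALSE) {
  if (is.null(sites)) sites <- candidate_sites(panel)
  nlow <- low_coverage_counts(panel, low_depth_frac)
  n <- n_genomes(panel)
  calls <- panel$calls
  key <- paste(calls$chrom, calls$pos)
  by_site <- split(seq_len(nrow(calls)), key)

  res <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    cc <- sites$chrom[i]; p <- sites$pos[i]
    idx <- by_site[[paste(cc, p)]]
    if (is.null(idx)) {
      res[[i]] <- tibble::tibble(verdict = "fail", failed_rule = "monomorphic",
                                 detail = "no calls at site", ref = NA_character_,
                                 target_alt = NA_character_, class = NA_character_,
                                 n_carriers = NA_real_)
      next
    }
    f1 <- select_target_allele(calls[idx, , drop = FALSE], n,
                               max_other_frac = max_other_frac,
                               het_weight = het_weight)
    if (f1$verdict == "fail") { res[[i]] <- f1; next }
    f2 <- check_target_coverage(panel, cc, p, low_depth_frac,
                                max_low_genomes_frac, nlow = nlow)
    if (f2$verdict == "fail") {
      res[[i]] <- dplyr::mutate(f1, verdict = "fail",
                                failed_rule = f2$failed_rule, detail = f2$detail)
      next
    }
    f3 <- check_flank_coverage(panel, cc, p, flank_bp, low_depth_frac,
                               max_low_genomes_frac, any_genome, nlow = nlow)
    if (f3$verdict == "fail") {
      res[[i]] <- dplyr::mutate(f1, verdict = "fail",
                                failed_rule = f3$failed_rule, detail = f3$detail)
      next
    }
    res[[i]] <- f1
  }
  dplyr::bind_cols(sites, dplyr::bind_rows(res))
}
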