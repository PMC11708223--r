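# GC percent of a character span under the ambiguity-weight convention
span_gc <- function(ch) {
  w <- iupac_gc_weight(ch)
  if (all(is.na(w))) return(NA_real_)
  100 * mean(w, na.rm = TRUE)
}

nth_dist <- function(offsets, n) {
  d <- sort(abs(offsets))
  if (length(d) >= n) d[n] else NA_real_
}

#' The 29 per-design properties
#'
#' Computes, for every passing design, the property battery used to compare
#' successful and failing assays: flank-indel size and distance, ambiguous
#' base counts (total, per flank, flank-with-least/most), distances from the
#' target to the 1st-5th ambiguous base per flank plus the shortest (either
#' flank) and longest (both flanks) variants for n = 1, 2, and GC
#' percentages (whole design, each flank, lowest/highest flank).
#'
#' An nth-distance property is `NA` when the relevant flank has fewer than n
#' ambiguous bases; the shortest-distance variant needs at least one flank
#' with n or more, the longest-distance variant needs both.
#'
#' @param designs Output of [build_designs()] (passing rows used).
#' @return Tibble, one row per design, `pKey` plus 29 property columns.
#' @export
design_properties <- function(designs) {
  d <- designs[designs$verdict == "pass", , drop = FALSE]
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    sn <- d$flank_snps[[i]]
    left <- sn$offset[sn$offset < 0]
    right <- sn$offset[sn$offset > 0]
    nl <- length(left); nr <- length(right)
    ch <- strsplit(d$design_seq[i], "")[[1]]
    ti <- d$target_index[i]
    gl <- span_gc(ch[seq_len(ti - 1)])
    gr <- span_gc(ch[(ti + 1):length(ch)])
    row <- tibble::tibble(
      pKey = d$pKey[i],
      n_indel_bases = as.numeric(d$indel_len[i]),
      indel_distance = as.numeric(abs(d$indel_offset[i])),
      n_amb = nl + nr, n_amb_left = nl, n_amb_right = nr,
      n_amb_least = min(nl, nr), n_amb_most = max(nl, nr),
      gc_total = span_gc(ch), gc_left = gl, gc_right = gr,
      gc_lowest = min(gl, gr), gc_highest = max(gl, gr)
    )
    for (n in 1:5) {
      dl <- nth_dist(left, n); dr <- nth_dist(right, n)
      row[[paste0("dist_left_", n)]] <- dl
      row[[paste0("dist_right_", n)]] <- dr
      row[[paste0("dist_shortest_", n)]] <-
        if (all(is.na(c(dl, dr)))) NA_real_ else min(dl, dr, na.rm = TRUE)
      if (n <= 2) {
        row[[paste0("dist_longest_", n)]] <-
          if (any(is.na(c(dl, dr)))) NA_real_ else max(dl, dr)
      }
    }
    out[[i]] <- row
  }
  dplyr::bind_rows(out)
}

#' Wilcoxon rank-sum comparison of design properties by assay outcome
#'
#' For every property column, a two-sided Wilcoxon rank-sum test between the
#' designs whose assays succeeded and those that failed, with per-property
#' inclusion rules applied through the `NA` pattern of
#' [design_properties()]. Properties with fewer than 2 eligible designs in
#' either group are skipped.
#'
#' @param props Property tibble from [design_properties()].
#' @param success Logical vector along `props` rows (or vector of successful
#'   pKeys) marking designs whose assay succeeded.
#' @return Tibble of class `kasp_property_comparison`: `property`, `W`,
#'   `p_value`, `mean_success`, `mean_failure`, `n_success`, `n_failure`,
#'   `stars` (`*` < 0.05, `**` < 0.01, `***` < 0.001).
#' @export
compare_properties <- function(props, success) {
  if (!is.logical(success)) success <- props$pKey %in% success
  stopifnot(length(success) == nrow(props))
  cols <- setdiff(names(props), "pKey")
  rows <- list()
  for (cl in cols) {
    x <- props[[cl]][success]
    y <- props[[cl]][!success]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    p <- wt$p.value
    if (is.na(p)) p <- 1  # fully tied groups carry no evidence of a shift
    rows[[length(rows) + 1]] <- tibble::tibble(
      property = cl, W = unname(wt$statistic), p_value = p,
      mean_success = mean(x), mean_failure = mean(y),
      n_success = length(x), n_failure = length(y),
      stars = dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**",
                               p < 0.05 ~ "*", TRUE ~ "")
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kasp_property_comparison", class(out))
  out
}

#' Ambiguous-base cutoff sweep
#'
#' Restricts the design set to designs whose per-flank ambiguous-base count
#' does not exceed each cutoff, reporting how the design inventory, the
#' median distance between consecutive retained designs, and (when a
#' genotyping run is supplied) the genotyping outcome percentages respond.
#'
#' @param designs Positioned design tibble with `pKey`, `chrom`, `pos`,
#'   `n_amb_left`, `n_amb_right` and, for the genotyping columns, `marker`.
#' @param gm Optional long genotype tibble whose `marker` ids match
#'   `designs$marker`.
#' @param cutoffs Integer cutoffs to sweep (default `c(4, 3, 2, 1, 0)`).
#' @param threshold Validation call-rate threshold (default 0.90).
#' @return Tibble of class `kasp_cutoff_sweep`: `cutoff`, `n_designs`,
#'   `median_spacing`, and with `gm`: `n_tested`, `pct_producing_results`
#'   (call rate > 0), `pct_successful` (validated).
#' @export
cutoff_sweep <- function(designs, gm = NULL, cutoffs = c(4, 3, 2, 1, 0),
                         threshold = 0.90) {
  d <- designs[!is.na(designs$pKey), , drop = FALSE]
  crs <- if (!is.null(gm)) call_rate_summary(gm, threshold)$markers else NULL
  rows <- list()
  for (co in cutoffs) {
    keep <- pmax(d$n_amb_left, d$n_amb_right) <= co
    sub <- d[keep, , drop = FALSE]
    spacing <- sub %>%
      dplyr::arrange(.data$chrom, .data$pos) %>%
      dplyr::group_by(.data$chrom) %>%
      dplyr::mutate(gap = .data$pos - dplyr::lag(.data$pos)) %>%
      dplyr::pull(.data$gap)
    row <- tibble::tibble(cutoff = co, n_designs = nrow(sub),
                          median_spacing = stats::median(spacing, na.rm = TRUE))
    if (!is.null(crs) && "marker" %in% names(sub)) {
      tested <- crs[crs$marker %in% sub$marker, , drop = FALSE]
      row$n_tested <- nrow(tested)
      row$pct_producing_results <- 100 * mean(!tested$failed_all)
      row$pct_successful <- 100 * mean(tested$validated)
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kasp_cutoff_sweep", class(out))
  out
}
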