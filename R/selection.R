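#' Find candidate designs near trait targets
#'
#' Candidates for a target locus are all positioned designs whose target
#' variant lies within `max_dist` bp of the target position or interval
#' (distance 0 inside the interval; otherwise distance to the nearest edge),
#' sorted by distance.
#'
#' @param targets Tibble of trait targets: `target_id`, `chrom`, `start`,
#'   `end` (point targets use `start == end`), optional `name`, `kind`.
#' @param designs Tibble of positioned designs with at least `pKey`,
#'   `chrom`, `pos`, `functional` (logical).
#' @param max_dist Maximum distance in bp (default 20000).
#' @return Tibble `target_id`, `pKey`, `chrom`, `pos`, `distance`,
#'   `functional`, `rank` (1 = nearest), sorted by target then distance
#'   (ties by pKey).
#' @export
find_candidates <- function(targets, designs, max_dist = 20000) {
  d <- designs[!is.na(designs$pKey), , drop = FALSE]
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    t <- targets[i, ]
    dd <- d[d$chrom == t$chrom, , drop = FALSE]
    if (nrow(dd) == 0) { out[[i]] <- NULL; next }
    dist <- pmax(0L, pmax(t$start - dd$pos, dd$pos - t$end))
    keep <- dist <= max_dist
    if (!any(keep)) next
    cand <- tibble::tibble(target_id = t$target_id, pKey = dd$pKey[keep],
                           chrom = dd$chrom[keep], pos = dd$pos[keep],
                           distance = as.integer(dist[keep]),
                           functional = dd$functional[keep]) %>%
      dplyr::arrange(.data$distance, .data$pKey)
    cand$rank <- seq_len(nrow(cand))
    out[[i]] <- cand
  }
  dplyr::bind_rows(out)
}

# genotype signature per design: one string over genomes in fixed order
genotype_signatures <- function(predicted) {
  predicted %>%
    dplyr::arrange(.data$pKey, .data$genome_id) %>%
    dplyr::group_by(.data$pKey) %>%
    dplyr::summarise(signature = paste(.data$predicted, collapse = "|"),
                     .groups = "drop")
}

#' Select up to k designs per target
#'
#' Functional designs are chosen first (nearest first), then nonfunctional
#' (nearest first), until `k` designs are selected. A candidate is skipped
#' when it lies within `dedup_bp` of an already-selected design *and* has
#' the identical predicted genotype across all panel lines (the skipped one
#' is replaced by the next candidate in order). Targets with fewer than `k`
#' candidates keep them all.
#'
#' @param candidates Output of [find_candidates()] (any number of targets).
#' @param predicted Long predicted-genotype tibble from
#'   [predicted_genotypes()] (used for the duplicate rule; may be `NULL` to
#'   disable deduplication).
#' @param k Designs per target (default 5).
#' @param dedup_bp Proximity radius of the duplicate rule (default 100).
#' @return Tibble like `candidates` with the selected rows only, plus a
#'   `removal log` attribute (`attr(x, "removed")`): tibble `target_id`,
#'   `pKey`, `rule`.
#' @export
select_per_target <- function(candidates, predicted = NULL, k = 5,
                              dedup_bp = 100) {
  sig <- if (is.null(predicted)) NULL else genotype_signatures(predicted)
  removed <- list()
  sel <- list()
  for (tid in unique(candidates$target_id)) {
    cand <- candidates[candidates$target_id == tid, , drop = FALSE]
    ord <- order(!cand$functional, cand$distance, cand$pKey)
    cand <- cand[ord, , drop = FALSE]
    chosen <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (length(chosen) >= k) break
      dup <- FALSE
      if (!is.null(sig) && length(chosen) > 0) {
        si <- sig$signature[match(cand$pKey[i], sig$pKey)]
        for (j in chosen) {
          sj <- sig$signature[match(cand$pKey[j], sig$pKey)]
          if (abs(cand$pos[i] - cand$pos[j]) <= dedup_bp &&
              identical(si, sj)) { dup <- TRUE; break }
        }
      }
      if (dup) {
        removed[[length(removed) + 1]] <- tibble::tibble(
          target_id = tid, pKey = cand$pKey[i], rule = "proximity_duplicate")
      } else {
        chosen <- c(chosen, i)
      }
    }
    sel[[length(sel) + 1]] <- cand[chosen, , drop = FALSE]
  }
  out <- dplyr::bind_rows(sel)
  attr(out, "removed") <- dplyr::bind_rows(removed)
  out
}

#' Trim a selection to a global quota
#'
#' Iteratively removes, from the lexicographically first target among those
#' currently holding the most selected markers, its nonfunctional marker
#' farthest from the target, until the number of distinct selected designs
#' equals `quota`. When no max-count target holds a nonfunctional marker the
#' farthest functional marker is removed instead and logged as a deviation.
#' Ties break on target id then pKey, making the result deterministic.
#'
#' @param selection Output of [select_per_target()].
#' @param quota Final panel size.
#' @return The trimmed selection tibble, with attribute `removed` extended
#'   by rows with rule `"quota_nonfunctional"` or `"quota_functional"`.
#' @export
trim_to_quota <- function(selection, quota) {
  removed <- attr(selection, "removed") %||%
    tibble::tibble(target_id = character(), pKey = integer(), rule = character())
  sel <- selection
  repeat {
    n_distinct <- length(unique(sel$pKey))
    if (n_distinct <= quota) break
    counts <- sort(table(sel$target_id), decreasing = TRUE)
    max_n <- counts[[1]]
    max_targets <- sort(names(counts)[counts == max_n])
    pick <- NULL
    for (tid in max_targets) {
      rows <- sel[sel$target_id == tid & !sel$functional, , drop = FALSE]
      if (nrow(rows) > 0) {
        rows <- rows[order(-rows$distance, -rows$pKey), , drop = FALSE]
        pick <- list(tid = tid, pKey = rows$pKey[1], rule = "quota_nonfunctional")
        break
      }
    }
    if (is.null(pick)) {
      tid <- max_targets[1]
      rows <- sel[sel$target_id == tid, , drop = FALSE]
      rows <- rows[order(-rows$distance, -rows$pKey), , drop = FALSE]
      pick <- list(tid = tid, pKey = rows$pKey[1], rule = "quota_functional")
    }
    sel <- sel[!(sel$target_id == pick$tid & sel$pKey == pick$pKey), ,
               drop = FALSE]
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      target_id = pick$tid, pKey = pick$pKey, rule = pick$rule))
  }
  attr(sel, "removed") <- removed
  sel
}

#' Query designs by region or by named anchor
#'
#' Search-tool-style lookup: either every design inside a genomic region, or
#' every design within `distance` bp of a named target (gene, SSR or array
#' SNP) from a targets table.
#'
#' @param designs Positioned design tibble (`pKey`, `chrom`, `pos`, ...).
#' @param chrom,start,end Region query (all three given).
#' @param name Anchor name; looked up in `targets$name` then
#'   `targets$target_id`.
#' @param targets Targets tibble (required for name queries).
#' @param distance Search radius for name queries (default 10000).
#' @return Tibble of matching design rows (with `distance` for name
#'   queries), sorted by position or distance.
#' @export
query_designs <- function(designs, chrom = NULL, start = NULL, end = NULL,
                          name = NULL, targets = NULL, distance = 10000) {
  if (!is.null(name)) {
    if (is.null(targets)) stop("name queries need a targets table")
    hit <- targets[(!is.null(targets$name) & targets$name == name) |
                     targets$target_id == name, , drop = FALSE]
    hit <- hit[!is.na(hit$target_id), , drop = FALSE]
    if (nrow(hit) == 0) stop("unknown anchor name: ", name)
    cand <- find_candidates(hit[1, , drop = FALSE], designs,
                            max_dist = distance)
    return(dplyr::left_join(cand,
                            dplyr::select(designs, -dplyr::any_of(c("chrom", "pos"))),
                            by = "pKey"))
  }
  if (is.null(chrom) || is.null(start) || is.null(end)) {
    stop("give either a region (chrom/start/end) or a name")
  }
  d <- designs[!is.na(designs$pKey) & designs$chrom == chrom &
                 designs$pos >= start & designs$pos <= end, , drop = FALSE]
  dplyr::arrange(d, .data$pos)
}
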