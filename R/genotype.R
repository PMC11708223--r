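#' Read a genotyping result table
#'
#' Long TSV `sample<TAB>marker<TAB>call` with calls in `ref_hom`, `alt_hom`,
#' `het`, `?`, `Bad`, `Uncallable` or `NA`. `?`, `Bad`, `Uncallable` and
#' missing cells all count as failed calls.
#'
#' @param path TSV path (comment lines start `#`).
#' @return Long tibble `sample`, `marker`, `call`.
#' @export
read_genotype_calls <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           header = TRUE, colClasses = "character",
                           na.strings = c("NA", ""))
  names(tab) <- c("sample", "marker", "call")[seq_along(names(tab))]
  tibble::as_tibble(tab)
}

#' @rdname read_genotype_calls
#' @param calls Long genotype tibble to write.
#' @export
write_genotype_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# sample\tmarker\tcall", con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

failed_codes <- c("?", "Bad", "Uncallable")
success_codes <- c("ref_hom", "alt_hom", "het")

is_successful_call <- function(call) !is.na(call) & call %in% success_codes

#' Per-marker and per-sample call-rate summary
#'
#' A marker is *validated* when its call rate is strictly above `threshold`
#' (default 0.90: successful calls in more than 90% of samples). Markers
#' with no successful call at all are flagged `failed_all`; markers whose
#' successful calls are all identical are flagged `monomorphic`.
#'
#' @param gm Long genotype tibble (`sample`, `marker`, `call`).
#' @param threshold Validation call-rate threshold (strict; default 0.90).
#' @return Object of class `call_rate_summary`: list with tibbles `markers`
#'   (`marker`, `n`, `n_called`, `call_rate`, `validated`, `failed_all`,
#'   `monomorphic`) and `samples` (`sample`, `n`, `n_called`, `call_rate`),
#'   plus `threshold`. `tidy()` returns the marker table; `glance()` the
#'   headline counts.
#' @export
call_rate_summary <- function(gm, threshold = 0.90) {
  if (nrow(gm) == 0) stop("empty genotype table")
  ok <- is_successful_call(gm$call)
  markers <- gm %>%
    dplyr::mutate(ok = ok) %>%
    dplyr::group_by(marker = .data$marker) %>%
    dplyr::summarise(
      n = dplyr::n(),
      n_called = sum(.data$ok),
      call_rate = .data$n_called / .data$n,
      monomorphic = .data$n_called > 0 &&
        length(unique(.data$call[.data$ok])) == 1,
      .groups = "drop"
    ) %>%
    dplyr::mutate(validated = .data$call_rate > threshold,
                  failed_all = .data$n_called == 0)
  samples <- gm %>%
    dplyr::mutate(ok = ok) %>%
    dplyr::group_by(sample = .data$sample) %>%
    dplyr::summarise(n = dplyr::n(), n_called = sum(.data$ok),
                     call_rate = .data$n_called / .data$n, .groups = "drop")
  structure(list(markers = markers, samples = samples, threshold = threshold),
            class = "call_rate_summary")
}

#' @export
print.call_rate_summary <- function(x, ...) {
  g <- glance(x)
  cat("<call_rate_summary> ", g$n_markers, " markers x ", g$n_samples,
      " samples\n  validated (rate > ", x$threshold, "): ", g$n_validated,
      "; failed in all: ", g$n_failed_all, "; monomorphic: ",
      g$n_monomorphic, "\n", sep = "")
  invisible(x)
}

#' @method tidy call_rate_summary
#' @export
tidy.call_rate_summary <- function(x, ...) x$markers

#' @method glance call_rate_summary
#' @export
glance.call_rate_summary <- function(x, ...) {
  m <- x$markers
  tibble::tibble(
    n_markers = nrow(m), n_samples = nrow(x$samples),
    n_validated = sum(m$validated), n_failed_all = sum(m$failed_all),
    n_monomorphic = sum(m$validated & m$monomorphic),
    n_polymorphic_validated = sum(m$validated & !m$monomorphic),
    median_sample_rate = stats::median(x$samples$call_rate)
  )
}

#' Convert genotype calls to a numeric matrix
#'
#' Cells are coded 1 for the reference-allele homozygote, 0 for the target
#' variant and, for heterozygotes, either 0.5 (`het_mode = "half"`) or the
#' marker's most common homozygous code (`het_mode = "majority"`). Failed
#' calls are imputed with the marker mean. Intended for validated,
#' polymorphic markers (subset with `markers`).
#'
#' @param gm Long genotype tibble.
#' @param het_mode `"half"` or `"majority"`.
#' @param markers Optional character vector restricting the columns.
#' @return Numeric matrix, samples in rows, markers in columns.
#' @export
to_numeric_matrix <- function(gm, het_mode = c("half", "majority"),
                              markers = NULL) {
  het_mode <- match.arg(het_mode)
  if (!is.null(markers)) gm <- gm[gm$marker %in% markers, , drop = FALSE]
  wide <- gm %>%
    dplyr::mutate(v = dplyr::case_when(
      .data$call == "ref_hom" ~ 1,
      .data$call == "alt_hom" ~ 0,
      .data$call == "het" ~ 0.5,
      TRUE ~ NA_real_
    )) %>%
    dplyr::select("sample", "marker", "v") %>%
    tidyr::pivot_wider(names_from = "marker", values_from = "v")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  if (het_mode == "majority") {
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      hom <- col[!is.na(col) & col != 0.5]
      if (any(col == 0.5, na.rm = TRUE)) {
        maj <- if (length(hom) == 0) 0.5 else if (mean(hom == 1) >= 0.5) 1 else 0
        col[!is.na(col) & col == 0.5] <- maj
        m[, j] <- col
      }
    }
  }
  called <- colSums(!is.na(m))
  if (any(called == 0)) {
    stop("marker(s) with no successful calls: ",
         paste(utils::head(colnames(m)[called == 0], 3), collapse = ", "))
  }
  for (j in which(colSums(is.na(m)) > 0)) {
    m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  m
}

#' Hierarchical clustering of a genotype matrix
#'
#' Pairwise Euclidean distances and average-linkage (UPGMA) agglomeration,
#' cut at `k` groups. Deterministic given the input row order.
#'
#' @param m Numeric genotype matrix (samples x markers), complete.
#' @param k Number of groups to cut at.
#' @return Object of class `kasp_clusters`: list with the `hclust` tree,
#'   `k`, and `labels` (named integer vector of group assignments).
#'   `tidy()` returns a `sample`/`cluster` tibble; `glance()` sizes and
#'   heights. [as_newick()] serialises the dendrogram.
#' @export
hierarchical_clusters <- function(m, k = 4) {
  if (nrow(m) < k) stop("fewer samples than k")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, k = k, labels = labels),
            class = "kasp_clusters")
}

#' @export
print.kasp_clusters <- function(x, ...) {
  cat("<kasp_clusters> ", length(x$labels), " samples in ", x$k,
      " groups (sizes: ", paste(table(x$labels), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' @method tidy kasp_clusters
#' @export
tidy.kasp_clusters <- function(x, ...) {
  tibble::tibble(sample = names(x$labels), cluster = unname(x$labels))
}

#' @method glance kasp_clusters
#' @export
glance.kasp_clusters <- function(x, ...) {
  tibble::tibble(n_samples = length(x$labels), k = x$k,
                 max_height = max(x$hclust$height))
}

#' @rdname hierarchical_clusters
#' @param x A `kasp_clusters` object.
#' @param path Optional file to write the Newick string to.
#' @export
as_newick <- function(x, path = NULL) {
  phy <- ape::as.phylo(x$hclust)
  if (is.null(path)) ape::write.tree(phy) else {
    ape::write.tree(phy, file = path)
    invisible(path)
  }
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on which two clusterings agree (both together or
#' both apart); 1 means identical partitions.
#'
#' @param a,b Cluster label vectors over the same samples.
#' @return A number in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

#' Concordance of genotype calls with design-time predictions
#'
#' A datapoint matches when the called genotype equals the predicted one
#' (`reference` -> `ref_hom`, `target` -> `alt_hom`, `het` -> `het`);
#' failed calls (`?`, `Bad`, `Uncallable`, missing) always count as
#' nonmatching, as do `unknown` predictions.
#'
#' @param gm Long genotype tibble for the lines in `predicted`.
#' @param predicted Tibble `genome_id` (or `sample`), `marker`, `predicted`
#'   with values in `reference`/`target`/`het`/`unknown`.
#' @return Object of class `kasp_concordance`: list with `by_line`
#'   (`sample`, `n`, `n_match`, `pct_match`), `by_marker` (`marker`, `n`,
#'   `n_nonmatch`, plus `complete_agreement`), `mismatch_distribution`
#'   (`n_nonmatching_lines`, `n_markers`), and `n_datapoints`.
#' @export
concordance <- function(gm, predicted) {
  if ("genome_id" %in% names(predicted) && !"sample" %in% names(predicted)) {
    predicted <- dplyr::rename(predicted, sample = "genome_id")
  }
  joined <- dplyr::inner_join(gm, predicted, by = c("sample", "marker"))
  if (nrow(joined) == 0) stop("no sample/marker ids shared between datasets")
  expected <- dplyr::recode(joined$predicted, reference = "ref_hom",
                            target = "alt_hom", het = "het",
                            .default = NA_character_)
  match <- !is.na(joined$call) & !is.na(expected) & joined$call == expected
  joined$match <- match
  by_line <- joined %>%
    dplyr::group_by(sample = .data$sample) %>%
    dplyr::summarise(n = dplyr::n(), n_match = sum(.data$match),
                     pct_match = 100 * .data$n_match / .data$n,
                     .groups = "drop")
  by_marker <- joined %>%
    dplyr::group_by(marker = .data$marker) %>%
    dplyr::summarise(n = dplyr::n(), n_nonmatch = sum(!.data$match),
                     .groups = "drop") %>%
    dplyr::mutate(complete_agreement = .data$n_nonmatch == 0)
  dist <- by_marker %>%
    dplyr::count(n_nonmatching_lines = .data$n_nonmatch, name = "n_markers")
  structure(list(by_line = by_line, by_marker = by_marker,
                 mismatch_distribution = dist, n_datapoints = nrow(joined)),
            class = "kasp_concordance")
}

#' @export
print.kasp_concordance <- function(x, ...) {
  cat("<kasp_concordance> ", x$n_datapoints, " datapoints; overall match ",
      sprintf("%.1f%%", 100 * sum(x$by_line$n_match) / x$n_datapoints),
      "; markers in complete agreement: ",
      sum(x$by_marker$complete_agreement), "\n", sep = "")
  invisible(x)
}

#' @method tidy kasp_concordance
#' @export
tidy.kasp_concordance <- function(x, ...) x$by_line

#' @method glance kasp_concordance
#' @export
glance.kasp_concordance <- function(x, ...) {
  tibble::tibble(
    n_datapoints = x$n_datapoints,
    n_nonmatching = sum(x$by_marker$n_nonmatch),
    pct_match = 100 * (1 - sum(x$by_marker$n_nonmatch) / x$n_datapoints),
    n_complete_agreement = sum(x$by_marker$complete_agreement),
    min_line_pct = min(x$by_line$pct_match),
    max_line_pct = max(x$by_line$pct_match)
  )
}
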