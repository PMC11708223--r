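#' Place a query sequence in a reference assembly
#'
#' Deterministic seed-and-extend search: exact seeds (default 15-mers) are
#' tiled over the unambiguous stretches of the query and matched exactly
#' against both strands of every chromosome; each seed hit nominates one
#' full-length ungapped alignment, scored match +1 / mismatch -1 with IUPAC
#' ambiguity letters (and N) matching any base in their set. Identity is
#' reported over the full query length. All best-scoring loci are returned;
#' callers reject queries whose best score is tied across loci.
#'
#' @param query Query sequence (may contain IUPAC ambiguity letters and N).
#' @param reference A [reference_genome].
#' @param seed_len Exact-seed length (default 15).
#' @return Tibble of best-scoring hits: `assembly_id`, `chrom`, `start`
#'   (1-based), `strand`, `score`, `identity_pct`. Zero rows when no seed
#'   matches anywhere.
#' @export
align_query <- function(query, reference, seed_len = 15) {
  query <- toupper(query)
  L <- nchar(query)
  if (L < seed_len) stop("query shorter than seed length (", seed_len, ")")
  chrom_str <- reference$str %||% stats::setNames(as.character(reference$seq),
                                                  names(reference$seq))
  chroms <- names(chrom_str)
  clen <- nchar(chrom_str)

  rows <- list()
  for (strand in c("+", "-")) {
    qs <- if (strand == "+") query else revcomp(query)
    qmask <- seq_masks(qs)
    # tile exact seeds over unambiguous runs of the (oriented) query
    runs <- gregexpr("[ACGT]+", qs)[[1]]
    if (runs[1] == -1) next
    offs <- integer(0)
    for (r in seq_along(runs)) {
      s0 <- runs[r]; rl <- attr(runs, "match.length")[r]
      if (rl < seed_len) next
      offs <- c(offs, unique(c(seq(s0, s0 + rl - seed_len, by = seed_len),
                               s0 + rl - seed_len)))
    }
    if (length(offs) == 0) next
    for (ci in seq_along(chroms)) {
      starts <- integer(0)
      for (o in offs) {
        pat <- substr(qs, o, o + seed_len - 1)
        m <- stringi::stri_locate_all_fixed(
          chrom_str[[ci]], pat,
          opts_fixed = stringi::stri_opts_fixed(overlap = TRUE))[[1]][, 1]
        if (length(m) == 0 || is.na(m[1])) next
        starts <- c(starts, m - (o - 1L))
      }
      starts <- unique(starts)
      starts <- starts[starts >= 1 & starts + L - 1 <= clen[[ci]]]
      for (st in starts) {
        gmask <- seq_masks(substring(chrom_str[[ci]], st, st + L - 1))
        compat <- bitwAnd(qmask, gmask) > 0
        rows[[length(rows) + 1]] <- list(chroms[ci], as.integer(st), strand,
                                         sum(compat) - sum(!compat),
                                         100 * sum(compat) / L)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(assembly_id = character(), chrom = character(),
                          start = integer(), strand = character(),
                          score = integer(), identity_pct = numeric()))
  }
  all_hits <- tibble::tibble(
    assembly_id = reference$assembly_id,
    chrom = vapply(rows, `[[`, character(1), 1),
    start = vapply(rows, `[[`, integer(1), 2),
    strand = vapply(rows, `[[`, character(1), 3),
    score = as.integer(vapply(rows, `[[`, numeric(1), 4)),
    identity_pct = vapply(rows, `[[`, numeric(1), 5)
  )
  all_hits <- dplyr::distinct(all_hits)
  all_hits[all_hits$score == max(all_hits$score), , drop = FALSE]
}

#' Unique best placement of a design sequence
#'
#' A design is kept only when it has a single best alignment in the
#' assembly; two or more loci tying for the best score (for example a
#' duplicated context) yield `NULL` ("unknown").
#'
#' @inheritParams align_query
#' @param design_seq Design sequence (IUPAC letters and Ns allowed).
#' @return One-row tibble (as [align_query()]) or `NULL` when placement is
#'   ambiguous or absent.
#' @export
locate_design <- function(design_seq, reference, seed_len = 15) {
  best <- align_query(design_seq, reference, seed_len)
  if (nrow(best) != 1) return(NULL)
  best
}

#' Cross-reference a design in a legacy assembly
#'
#' As [locate_design()], with the additional rule that a unique best hit
#' whose full-length identity is below `min_identity` percent is still
#' reported as unknown. Informational: a failed cross-reference does not
#' reject the design.
#'
#' @inheritParams locate_design
#' @param min_identity Minimum full-length identity percent (default 90;
#'   exactly 90 is accepted).
#' @export
crossref_legacy <- function(design_seq, reference, min_identity = 90,
                            seed_len = 15) {
  best <- align_query(design_seq, reference, seed_len)
  if (nrow(best) != 1) return(NULL)
  if (best$identity_pct < min_identity) return(NULL)
  best
}

#' Position an SSR marker by its primer pair
#'
#' Each primer is aligned independently; hits below `min_identity` percent
#' full-length identity are discarded before best-hit selection. All
#' combinations of surviving best hits are considered and the marker is
#' positioned in an assembly only when exactly one forward/reverse pair
#' lies on one chromosome within `max_pair_span` bp; the marker position is
#' the interval spanned by the pair.
#'
#' @param forward,reverse Primer sequences (>= 15 bp).
#' @param assemblies Named list of [reference_genome] objects.
#' @param min_identity Minimum full-length primer identity percent
#'   (default 95).
#' @param max_pair_span Maximum distance between paired primer placements
#'   (default 10000).
#' @param seed_len Seed length for the aligner.
#' @return Tibble with one row per assembly: `assembly_id`, `known`,
#'   `chrom`, `start`, `end` (`NA` when unknown).
#' @export
position_ssr <- function(forward, reverse, assemblies, min_identity = 95,
                         max_pair_span = 10000, seed_len = 15) {
  if (nchar(forward) < 15 || nchar(reverse) < 15) {
    stop("primer shorter than 15 bp")
  }
  out <- vector("list", length(assemblies))
  for (a in seq_along(assemblies)) {
    ref <- assemblies[[a]]
    hf <- align_query(forward, ref, seed_len)
    hr <- align_query(reverse, ref, seed_len)
    hf <- hf[hf$identity_pct >= min_identity, , drop = FALSE]
    hr <- hr[hr$identity_pct >= min_identity, , drop = FALSE]
    row <- tibble::tibble(assembly_id = ref$assembly_id, known = FALSE,
                          chrom = NA_character_, start = NA_integer_,
                          end = NA_integer_)
    if (nrow(hf) > 0 && nrow(hr) > 0) {
      pairs <- tidyr::crossing(f = seq_len(nrow(hf)), r = seq_len(nrow(hr)))
      ok <- purrr::map_lgl(seq_len(nrow(pairs)), function(i) {
        f <- hf[pairs$f[i], ]; r <- hr[pairs$r[i], ]
        f$chrom == r$chrom && abs(f$start - r$start) <= max_pair_span
      })
      if (sum(ok) == 1) {
        i <- which(ok)
        f <- hf[pairs$f[i], ]; r <- hr[pairs$r[i], ]
        fe <- f$start + nchar(forward) - 1L
        re <- r$start + nchar(reverse) - 1L
        row$known <- TRUE
        row$chrom <- f$chrom
        row$start <- min(f$start, r$start)
        row$end <- max(fe, re)
      }
    }
    out[[a]] <- row
  }
  dplyr::bind_rows(out)
}

#' Position an array-SNP context sequence
#'
#' Applies the [crossref_legacy()] contract (unique best hit with at least
#' `min_identity` percent full-length identity) to a fixed-array SNP's
#' flanking context sequence in each assembly.
#'
#' @param context_seq Context sequence around the array SNP.
#' @param assemblies Named list of [reference_genome] objects.
#' @param min_identity Minimum identity percent (default 90).
#' @param seed_len Seed length.
#' @return Tibble with one row per assembly: `assembly_id`, `known`,
#'   `chrom`, `start`, `strand`.
#' @export
position_array_snp <- function(context_seq, assemblies, min_identity = 90,
                               seed_len = 15) {
  out <- vector("list", length(assemblies))
  for (a in seq_along(assemblies)) {
    hit <- crossref_legacy(context_seq, assemblies[[a]], min_identity, seed_len)
    out[[a]] <- tibble::tibble(
      assembly_id = assemblies[[a]]$assembly_id,
      known = !is.null(hit),
      chrom = if (is.null(hit)) NA_character_ else hit$chrom,
      start = if (is.null(hit)) NA_integer_ else hit$start,
      strand = if (is.null(hit)) NA_character_ else hit$strand
    )
  }
  dplyr::bind_rows(out)
}
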