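#' Per-genome read-depth tracks
#'
#' Depth tracks are run-length encoded as sorted, non-overlapping 1-based
#' inclusive intervals (`chrom`, `start`, `end`, `depth`) with a per-genome
#' mean read depth attached. Positions not covered by any interval have
#' depth 0. The mean is the genome-wide average read depth reported by the
#' upstream coverage computation and drives the 0.1x low-coverage rule; it is
#' not recomputed from the intervals.
#'
#' @param intervals Tibble with columns `chrom`, `start`, `end`, `depth`.
#' @param genome_id Genome identifier.
#' @param mean_depth Genome-wide mean read depth (> 0).
#' @return A tibble of class `depth_track` with attributes `genome_id` and
#'   `mean_depth`.
#' @export
depth_track <- function(intervals, genome_id, mean_depth) {
  stopifnot(mean_depth > 0)
  intervals <- tibble::as_tibble(intervals)[, c("chrom", "start", "end", "depth")]
  if (any(intervals$depth < 0)) stop("negative depth")
  if (any(intervals$end < intervals$start)) stop("interval end before start")
  intervals <- dplyr::arrange(intervals, .data$chrom, .data$start)
  by_chrom <- split(intervals, intervals$chrom)
  for (iv in by_chrom) {
    if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      stop("overlapping depth intervals on ", iv$chrom[1])
    }
  }
  structure(intervals, class = c("depth_track", class(intervals)),
            genome_id = genome_id, mean_depth = mean_depth)
}

#' @rdname depth_track
#' @param track A `depth_track`.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based positions.
#' @return `depth_at()` returns an integer vector of point depths (0 where
#'   uncovered).
#' @export
depth_at <- function(track, chrom, pos) {
  iv <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(iv) == 0) return(rep(0L, length(pos)))
  idx <- findInterval(pos, iv$start)
  out <- rep(0L, length(pos))
  hit <- idx > 0
  hit[hit] <- pos[hit] <= iv$end[idx[hit]]
  out[hit] <- as.integer(iv$depth[idx[hit]])
  out
}

#' Read / write a depth track TSV
#'
#' The file format is `chrom<TAB>start<TAB>end<TAB>depth` with 1-based
#' inclusive coordinates. Header comment lines (starting `#`) carry the
#' genome id and mean depth, e.g. `# genome_id=G01 mean_depth=32.5`; the
#' `mean` argument overrides the header value.
#'
#' @param path TSV path.
#' @param genome_id Override the header genome id.
#' @param mean Override the header mean depth.
#' @return A [depth_track].
#' @export
read_depth_track <- function(path, genome_id = NULL, mean = NULL) {
  first <- readLines(path, n = 5)
  hdr <- grep("^#", first, value = TRUE)
  hid <- stringr::str_match(paste(hdr, collapse = " "), "genome_id=(\\S+)")[, 2]
  hmean <- stringr::str_match(paste(hdr, collapse = " "), "mean_depth=([0-9.eE+-]+)")[, 2]
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("chrom", "start", "end", "depth"),
                           colClasses = c("character", "integer", "integer", "numeric"))
  na_null <- function(x) if (is.null(x) || all(is.na(x))) NULL else x
  mean_depth <- mean %||% na_null(as.numeric(hmean))
  if (is.null(mean_depth)) stop("no mean_depth in header of ", path,
                                " and none supplied")
  depth_track(tibble::as_tibble(tab),
              genome_id = genome_id %||% na_null(hid) %||% basename(path),
              mean_depth = mean_depth)
}

#' @rdname read_depth_track
#' @param track A [depth_track] to write.
#' @export
write_depth_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# genome_id=%s mean_depth=%g  (chrom\tstart\tend\tdepth; 1-based inclusive)",
                     attr(track, "genome_id"), attr(track, "mean_depth")), con)
  utils::write.table(as.data.frame(track)[, c("chrom", "start", "end", "depth")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# expand a depth track into per-chromosome integer vectors up to the
# chromosome lengths of `ref` (internal; used for fast panel-wide filters)
depth_vectors <- function(track, ref) {
  out <- list()
  for (cc in names(ref$seq)) {
    v <- rep(0L, ref_length(ref, cc))
    iv <- track[track$chrom == cc, , drop = FALSE]
    if (nrow(iv) > 0) {
      for (i in seq_len(nrow(iv))) {
        v[iv$start[i]:min(iv$end[i], length(v))] <- as.integer(iv$depth[i])
      }
    }
    out[[cc]] <- v
  }
  out
}
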