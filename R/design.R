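#' Filter 4: flanking-variation admissibility
#'
#' Collects every alternative allele observed in the panel within the 50 bp
#' flanks of a target site and decides whether the flanking polymorphism can
#' be encoded in a degenerate design sequence. A site passes only when:
#'
#' * every indel-bearing flank site carries indels of one kind and one
#'   length, there is at most one indel site in total, its anchor lies more
#'   than `min_indel_offset` bp from the target, its length is at most
#'   `max_indel_len` bases, and (for deletions) the deleted span does not
#'   reach the target base; and
#' * every other variant site is a SNP site, with at most `max_flank_snps`
#'   SNP sites per flank (or in total, with `per_flank = FALSE`).
#'
#' @param panel A [genome_panel].
#' @param chrom,pos Target site.
#' @param flank_bp Flank width (default 50).
#' @param max_flank_snps Maximum SNP sites per flank (default 5).
#' @param per_flank Apply the SNP cap per flank (default) or to the total.
#' @param max_indel_len Maximum inserted/deleted bases (default 10).
#' @param min_indel_offset Minimum anchor distance of an indel from the
#'   target (strict; default 5, so offset 6 is the nearest admissible).
#' @param window_calls Optional pre-sliced tibble of the panel calls inside
#'   the flank window (internal fast path used by [build_designs()]).
#' @return A list of class `flank_assessment`: `verdict`, `failed_rule`
#'   (`"flank_variation"` or `"none"`), `detail`, `snp_sites` (tibble
#'   `offset`, `pos`, `ref_base`, `alts` list-column) and `indel` (0- or
#'   1-row tibble `offset`, `pos`, `kind`, `len`).
#' @export
assess_flank_variation <- function(panel, chrom, pos, flank_bp = 50,
                                   max_flank_snps = 5, per_flank = TRUE,
                                   max_indel_len = 10, min_indel_offset = 5,
                                   window_calls = NULL) {
  fl <- window_calls
  if (is.null(fl)) {
    calls <- panel$calls
    fl <- calls[calls$chrom == chrom &
                  calls$pos >= pos - flank_bp & calls$pos <= pos + flank_bp &
                  calls$pos != pos, , drop = FALSE]
  }
  fl <- fl[!duplicated(paste(fl$pos, fl$ref, fl$alt, fl$class)), ,
           drop = FALSE]

  fail <- function(detail) {
    structure(list(verdict = "fail", failed_rule = "flank_variation",
                   detail = detail, snp_sites = empty_snp_sites(),
                   indel = empty_indel()), class = "flank_assessment")
  }

  ind <- fl[fl$class %in% c("INS", "DEL"), , drop = FALSE]
  snp <- fl[fl$class == "SNP", , drop = FALSE]

  indel_tbl <- empty_indel()
  if (nrow(ind) > 0) {
    sites <- unique(ind$pos)
    if (length(sites) > 1) return(fail("more than one indel site in flanks"))
    lens <- abs(nchar(ind$alt) - nchar(ind$ref))
    if (length(unique(ind$class)) > 1) {
      return(fail("insertion and deletion at the same flank site"))
    }
    if (length(unique(lens)) > 1) {
      return(fail("indels of unequal length at one flank site"))
    }
    off <- sites - pos
    len <- lens[1]
    if (abs(off) <= min_indel_offset) {
      return(fail(sprintf("indel within %d bp of target (offset %+d)",
                          min_indel_offset, off)))
    }
    if (len > max_indel_len) {
      return(fail(sprintf("indel of %d bases exceeds %d", len, max_indel_len)))
    }
    if (ind$class[1] == "DEL" && off < 0 && sites + len >= pos) {
      return(fail("deletion spans target"))
    }
    indel_tbl <- tibble::tibble(offset = off, pos = sites,
                                kind = ind$class[1], len = len)
  }

  snp_tbl <- empty_snp_sites()
  if (nrow(snp) > 0) {
    bad <- !snp$alt %in% c("A", "C", "G", "T")
    if (any(bad)) return(fail("flank SNP with non-ACGT alternative"))
    upos <- sort(unique(snp$pos))
    snp_tbl <- tibble::new_tibble(list(
      offset = as.integer(upos - pos),
      pos = as.integer(upos),
      ref_base = snp$ref[match(upos, snp$pos)],
      alts = lapply(upos, function(sp) sort(unique(snp$alt[snp$pos == sp])))
    ), nrow = length(upos))
    n_left <- sum(snp_tbl$offset < 0)
    n_right <- sum(snp_tbl$offset > 0)
    over <- if (per_flank) max(n_left, n_right) > max_flank_snps
            else (n_left + n_right) > max_flank_snps
    if (over) {
      return(fail(sprintf("%d left / %d right SNP flank sites exceed cap %d",
                          n_left, n_right, max_flank_snps)))
    }
  }

  structure(list(verdict = "pass", failed_rule = "none", detail = "",
                 snp_sites = snp_tbl, indel = indel_tbl),
            class = "flank_assessment")
}

empty_snp_sites <- function() tibble::tibble(
  offset = integer(), pos = integer(), ref_base = character(), alts = list()
)
empty_indel <- function() tibble::tibble(
  offset = integer(), pos = integer(), kind = character(), len = integer()
)

#' Build the degenerate design sequence
#'
#' The design sequence is the 101 bp reference window centred on the target
#' (the target base keeps the reference allele; the assay interrogates
#' reference vs target). Each SNP flank site becomes the minimal IUPAC code
#' covering the reference base and all observed alternatives. A flank
#' deletion of L bases is rendered by replacing the L deleted reference
#' bases with Ns (design length stays 101 and coordinates stay aligned to
#' the reference); an insertion of L bases is rendered by inserting L Ns
#' after the anchor base (design length 101 + L).
#'
#' @param reference A [reference_genome].
#' @param chrom,pos Target site.
#' @param profile A passing `flank_assessment` from
#'   [assess_flank_variation()].
#' @param flank_bp Flank width (default 50).
#' @return List: `design_seq` (string), `target_index` (1-based position of
#'   the target base within `design_seq`), `n_amb_left`, `n_amb_right`.
#' @export
build_design_sequence <- function(reference, chrom, pos, profile,
                                  flank_bp = 50) {
  stopifnot(inherits(profile, "flank_assessment"), profile$verdict == "pass")
  win <- ref_subseq(reference, chrom, pos - flank_bp, pos + flank_bp)
  ch <- strsplit(win, "")[[1]]
  tgt <- flank_bp + 1L

  sn <- profile$snp_sites
  for (i in seq_len(nrow(sn))) {
    j <- tgt + sn$offset[i]
    ch[j] <- iupac_code(c(ch[j], sn$alts[[i]]))
  }
  ind <- profile$indel
  if (nrow(ind) == 1) {
    j <- tgt + ind$offset
    if (ind$kind == "DEL") {
      span <- (j + 1):(j + ind$len)
      span <- span[span >= 1 & span <= length(ch) & span != tgt]
      ch[span] <- "N"
    } else {
      ch <- append(ch, rep("N", ind$len), after = j)
      if (j < tgt) tgt <- tgt + ind$len
    }
  }
  list(design_seq = paste(ch, collapse = ""), target_index = as.integer(tgt),
       n_amb_left = sum(sn$offset < 0), n_amb_right = sum(sn$offset > 0))
}

# maximal number of consecutive exact copies of any 1-5 nt unit in a plain
# ACGT string
max_tandem_copies <- function(s, max_unit = 5) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  best <- 1L
  for (k in seq_len(min(max_unit, n - 1))) {
    eq <- ch[(k + 1):n] == ch[1:(n - k)]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs) > 0) {
      best <- max(best, as.integer(max(runs) %/% k) + 1L)
    }
  }
  best
}

#' Tandem-repeat screen on a degenerate design sequence
#'
#' Ns are removed, every resolution of every ambiguity letter is enumerated
#' (cartesian product, capped at `max_resolutions`), and each resolved string
#' is scanned at every start position for maximal consecutive exact copies
#' of 1-5 nucleotide units. The design fails when any resolution contains a
#' run of more than `max_copies` copies (exactly 5 copies passes).
#'
#' @param design_seq Degenerate design sequence.
#' @param max_copies Maximum permitted copy number (default 5).
#' @param max_unit Longest repeat unit scanned (default 5).
#' @param max_resolutions Cap on the ambiguity expansion (default `4^10`,
#'   the worst admissible design); exceeding it is an internal error.
#' @return One-row tibble `verdict`, `failed_rule` (`"repeat"` or `"none"`),
#'   `detail`, `max_copies_found`.
#' @export
check_tandem_repeats <- function(design_seq, max_copies = 5, max_unit = 5,
                                 max_resolutions = 4^10) {
  s <- gsub("N", "", toupper(design_seq), fixed = TRUE)
  variants <- expand_ambiguity(s, max_resolutions = max_resolutions)
  found <- max(vapply(variants, max_tandem_copies, integer(1),
                      max_unit = max_unit))
  if (found > max_copies) {
    tibble::tibble(verdict = "fail", failed_rule = "repeat",
                   detail = sprintf("tandem run of %d copies", found),
                   max_copies_found = found)
  } else {
    tibble::tibble(verdict = "pass", failed_rule = "none", detail = "",
                   max_copies_found = found)
  }
}

#' GC-content window check
#'
#' GC fraction of the `window` bp (default 55) of the design sequence
#' centred on the target base must lie within `[lo, hi]` percent, bounds
#' inclusive. Ambiguity letters contribute the mean GC of their base set
#' (S = 1, W = 0, R/Y/K/M = 0.5, ...); N positions are excluded from both
#' numerator and denominator.
#'
#' @param design_seq Degenerate design sequence.
#' @param target_index 1-based index of the target base in `design_seq`.
#' @param lo,hi Inclusive GC percentage bounds (defaults 35 and 65).
#' @param window Window width in bp (default 55; must be odd).
#' @return One-row tibble `verdict`, `failed_rule` (`"gc"` or `"none"`),
#'   `detail`, `gc_window_pct`.
#' @export
check_gc_window <- function(design_seq, target_index, lo = 35, hi = 65,
                            window = 55) {
  ch <- strsplit(toupper(design_seq), "")[[1]]
  if (length(ch) < window) stop("design shorter than GC window")
  half <- (window - 1) %/% 2
  i0 <- max(1L, target_index - half)
  i1 <- min(length(ch), target_index + half)
  w <- iupac_gc_weight(ch[i0:i1])
  pct <- 100 * mean(w, na.rm = TRUE)
  if (is.nan(pct)) pct <- NA_real_
  ok <- !is.na(pct) && pct >= lo && pct <= hi
  tibble::tibble(
    verdict = if (ok) "pass" else "fail",
    failed_rule = if (ok) "none" else "gc",
    detail = if (ok) "" else sprintf("GC %.1f%% outside [%g, %g]", pct, lo, hi),
    gc_window_pct = pct
  )
}

#' Build KASP designs from filtered sites
#'
#' Runs the design stage over every site that survived filters 1-3: flank
#' variation admissibility, degenerate sequence construction, tandem-repeat
#' screen, optional unique-placement screen against one or more assemblies,
#' and the GC window check (in that order; a site is attributed the first
#' rule that rejects it). Surviving designs receive sequential `pKey`
#' identifiers.
#'
#' @param panel A [genome_panel].
#' @param filtered Output of [filter_sites()] (only rows with
#'   `verdict == "pass"` are considered).
#' @param assemblies Optional named list of [reference_genome] objects; when
#'   given, designs must have a single best alignment in every assembly
#'   (rule `alignment`). The panel's own reference is always checked first.
#' @param flank_bp,max_flank_snps,per_flank,max_indel_len,min_indel_offset
#'   See [assess_flank_variation()].
#' @param repeat_max_copies,gc_lo,gc_hi,gc_window Check parameters.
#' @param check_alignment Also require unique placement in the panel's own
#'   reference (default TRUE when `assemblies` is non-NULL, else FALSE).
#' @return Tibble with one row per evaluated site: site columns, `verdict`,
#'   `failed_rule` (`flank_variation`, `repeat`, `alignment`, `gc` or
#'   `none`), `detail`, and for survivors `pKey`, `design_seq`,
#'   `target_index`, `n_amb_left`, `n_amb_right`, `indel_kind`, `indel_len`,
#'   `indel_offset`, `gc_window_pct`, plus the list-column `flank_snps`
#'   (per-design SNP-site tibble).
#' @export
build_designs <- function(panel, filtered, assemblies = NULL,
                          flank_bp = 50, max_flank_snps = 5, per_flank = TRUE,
                          max_indel_len = 10, min_indel_offset = 5,
                          repeat_max_copies = 5, gc_lo = 35, gc_hi = 65,
                          gc_window = 55,
                          check_alignment = !is.null(assemblies)) {
  cand <- filtered[filtered$verdict == "pass", , drop = FALSE]
  # canonical genomic order so pKeys (and their tie-breaks) are reproducible
  # whatever order the sites arrived in
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  n <- nrow(cand)
  rows <- vector("list", n)
  # calls sorted by position per chromosome for O(log n) window slicing
  ord <- order(panel$calls$chrom, panel$calls$pos)
  cs <- panel$calls[ord, , drop = FALSE]
  pos_by_chrom <- split(seq_len(nrow(cs)), cs$chrom)
  for (i in seq_len(n)) {
    cc <- cand$chrom[i]; p <- cand$pos[i]
    idx <- pos_by_chrom[[cc]]
    win <- if (is.null(idx)) cs[0, , drop = FALSE] else {
      pv <- cs$pos[idx]
      i1 <- findInterval(p - flank_bp - 0.5, pv) + 1L
      i2 <- findInterval(p + flank_bp + 0.5, pv)
      w <- if (i1 > i2) cs[0, , drop = FALSE] else cs[idx[i1:i2], , drop = FALSE]
      w[w$pos != p, , drop = FALSE]
    }
    base <- tibble::tibble(
      chrom = cc, pos = p, ref = cand$ref[i], target_alt = cand$target_alt[i],
      class = cand$class[i], n_carriers = cand$n_carriers[i],
      verdict = "pass", failed_rule = "none", detail = "",
      design_seq = NA_character_, target_index = NA_integer_,
      n_amb_left = NA_integer_, n_amb_right = NA_integer_,
      indel_kind = NA_character_, indel_len = NA_integer_,
      indel_offset = NA_integer_, gc_window_pct = NA_real_,
      flank_snps = list(empty_snp_sites())
    )
    prof <- assess_flank_variation(panel, cc, p, flank_bp, max_flank_snps,
                                   per_flank, max_indel_len, min_indel_offset,
                                   window_calls = win)
    if (prof$verdict == "fail") {
      base$verdict <- "fail"; base$failed_rule <- prof$failed_rule
      base$detail <- prof$detail
      rows[[i]] <- base; next
    }
    built <- build_design_sequence(panel$reference, cc, p, prof, flank_bp)
    base$design_seq <- built$design_seq
    base$target_index <- built$target_index
    base$n_amb_left <- built$n_amb_left
    base$n_amb_right <- built$n_amb_right
    base$flank_snps <- list(prof$snp_sites)
    if (nrow(prof$indel) == 1) {
      base$indel_kind <- prof$indel$kind
      base$indel_len <- prof$indel$len
      base$indel_offset <- prof$indel$offset
    }
    rep_chk <- check_tandem_repeats(built$design_seq,
                                    max_copies = repeat_max_copies)
    if (rep_chk$verdict == "fail") {
      base$verdict <- "fail"; base$failed_rule <- "repeat"
      base$detail <- rep_chk$detail
      rows[[i]] <- base; next
    }
    if (check_alignment) {
      refs <- c(list(panel$reference), assemblies)
      unique_everywhere <- TRUE
      for (ref in refs) {
        hit <- locate_design(built$design_seq, ref)
        if (is.null(hit)) { unique_everywhere <- FALSE; break }
      }
      if (!unique_everywhere) {
        base$verdict <- "fail"; base$failed_rule <- "alignment"
        base$detail <- "no single best alignment in all assemblies"
        rows[[i]] <- base; next
      }
    }
    gc_chk <- check_gc_window(built$design_seq, built$target_index,
                              lo = gc_lo, hi = gc_hi, window = gc_window)
    base$gc_window_pct <- gc_chk$gc_window_pct
    if (gc_chk$verdict == "fail") {
      base$verdict <- "fail"; base$failed_rule <- "gc"
      base$detail <- gc_chk$detail
    }
    rows[[i]] <- base
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$pKey <- NA_integer_
  ok <- out$verdict == "pass"
  out$pKey[ok] <- seq_len(sum(ok))
  dplyr::relocate(out, "pKey")
}

#' Predicted per-line genotypes for designs
#'
#' For every design and panel genome: lines carrying the target allele are
#' predicted `"target"` (or `"het"` when the source call was heterozygous),
#' lines carrying a different alternative allele are `"unknown"` (the assay
#' cannot resolve them), and all other lines are `"reference"`.
#'
#' @param panel A [genome_panel].
#' @param designs Output of [build_designs()] (passing rows used).
#' @return Long tibble `pKey`, `genome_id`, `predicted` with one row per
#'   design x genome.
#' @export
predicted_genotypes <- function(panel, designs) {
  d <- designs[designs$verdict == "pass", , drop = FALSE]
  calls <- panel$calls
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    at <- calls[calls$chrom == d$chrom[i] & calls$pos == d$pos[i], , drop = FALSE]
    is_target <- at$alt == d$target_alt[i] & at$ref == d$ref[i] &
      at$class == d$class[i]
    state <- stats::setNames(rep("reference", length(panel$genomes)),
                             panel$genomes)
    state[at$genome_id[!is_target]] <- "unknown"
    tg <- at[is_target, , drop = FALSE]
    state[tg$genome_id] <- ifelse(tg$zygosity == "het", "het", "target")
    out[[i]] <- tibble::tibble(pKey = d$pKey[i], genome_id = names(state),
                               predicted = unname(state))
  }
  dplyr::bind_rows(out)
}
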