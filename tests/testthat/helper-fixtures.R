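# Small in-code fixtures shared across test files.

# deterministic background sequence
bg_seq <- function(n, seed = 1, gc = 0.45) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
}

# a panel with explicit per-genome calls and flat depth tracks
mk_panel <- function(ref_seq, calls, n_genomes = 10, mean_depth = 30,
                     depth_overrides = NULL, chrom = "chr1") {
  ref <- reference_genome(stats::setNames(ref_seq, chrom), "test")
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  L <- nchar(ref_seq)
  tracks <- lapply(genomes, function(g) {
    iv <- tibble::tibble(chrom = chrom, start = 1L, end = L,
                         depth = mean_depth)
    ov <- depth_overrides[[g]]
    if (!is.null(ov)) {
      # ov: tibble(start, end, depth); split the flat interval around it
      iv <- flatten_overrides(L, chrom, mean_depth, ov)
    }
    depth_track(iv, g, mean_depth)
  })
  names(tracks) <- genomes
  genome_panel(ref, calls, tracks)
}

flatten_overrides <- function(L, chrom, base_depth, ov) {
  d <- rep(base_depth, L)
  for (i in seq_len(nrow(ov))) d[ov$start[i]:ov$end[i]] <- ov$depth[i]
  r <- rle(d)
  e <- cumsum(r$lengths)
  tibble::tibble(chrom = chrom, start = e - r$lengths + 1, end = e,
                 depth = r$values)
}

mk_calls <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(genome_id = r$g, chrom = r$chrom %||% "chr1",
                   pos = as.integer(r$pos), ref = r$ref, alt = r$alt,
                   class = r$class %||% "SNP",
                   depth = as.integer(r$depth %||% 30L),
                   zygosity = r$zyg %||% "hom")
  }))
}

call_row <- function(g, pos, ref, alt, class = "SNP", depth = 30, zyg = "hom",
                     chrom = "chr1") {
  list(g = g, pos = pos, ref = ref, alt = alt, class = class, depth = depth,
       zyg = zyg, chrom = chrom)
}

# one shared mid-size synthetic scenario, built once per test run
shared_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(shared_env$sim)) {
    ro <- sim_reference(seed = 301, n_chrom = 2, chrom_len = 30000,
                        n_genes = 10, n_microsat = 5, n_at_tracts = 3)
    sp <- sim_panel(ro, seed = 302, n_genomes = 16, n_sites = 250)
    filtered <- filter_sites(sp$panel, sites = sp$truth[, c("chrom", "pos")])
    designs <- build_designs(sp$panel, filtered,
                             assemblies = list(legacy = sp$legacy))
    ann <- annotate_designs(designs, ro$models, ro$reference)
    designs <- dplyr::left_join(designs, ann$by_design, by = "pKey")
    shared_env$sim <- list(ro = ro, sp = sp, filtered = filtered,
                           designs = designs, ann = ann)
  }
  shared_env$sim
}

# panel whose only variation is what each test plants around position 500
design_panel <- function(extra_calls, seqlen = 1200, n_genomes = 10,
                         ref_seq = NULL) {
  target <- call_row("G01", 500, NA, NA)
  seq <- ref_seq %||% bg_seq(seqlen, seed = 9)
  rb <- substr(seq, 500, 500)
  target$ref <- rb
  target$alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  mk_panel(seq, do.call(mk_calls, c(list(target), extra_calls)),
           n_genomes = n_genomes)
}

flank_call <- function(pos, seq, kind = "SNP", len = 2, g = "G02") {
  b <- substr(seq, pos, pos)
  if (kind == "SNP") {
    call_row(g, pos, b, setdiff(c("A", "C", "G", "T"), b)[1])
  } else if (kind == "INS") {
    call_row(g, pos, b, paste0(b, strrep("T", len)), class = "INS")
  } else {
    call_row(g, pos, substr(seq, pos, pos + len), b, class = "DEL")
  }
}

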