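#' Run the full design pipeline from a configuration
#'
#' Chains the stages in their canonical order — load inputs, assemble the
#' panel, filters 1-3, design build (filter 4, degenerate encoding, repeat,
#' placement, GC), functional annotation, legacy cross-reference and
#' trait-target panel selection — and writes stage outputs plus a run
#' manifest with per-rule counts to `out_dir`. Every threshold is a named
#' config key defaulting to the pipeline's canonical value.
#'
#' @param config Named list (or path to a YAML/TSV-free R list is not
#'   supported; pass a list) with keys: `reference` (FASTA), `vcf_dir`,
#'   `depth_dir`, `out_dir`; optional `gff`, `legacy` (FASTA), `targets`
#'   (TSV), `quota`, `k_per_target`, `max_dist`, `min_depth`,
#'   `max_other_frac`, `low_depth_frac`, `max_low_genomes_frac`,
#'   `flank_bp`, `max_flank_snps`, `max_indel_len`, `min_indel_offset`,
#'   `repeat_max_copies`, `gc_lo`, `gc_hi`, `gc_window`, `crossref`.
#' @return List: `designs`, `filtered`, `annotation`, `selection`,
#'   `manifest` (tibble of stage/rule counts). Outputs are also written as
#'   TSVs under `out_dir`.
#' @export
run_pipeline <- function(config) {
  required <- c("reference", "vcf_dir", "depth_dir", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  }
  cfg <- function(key, default) config[[key]] %||% default
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ref <- read_reference(config$reference, assembly_id = "primary")
  vcfs <- sort(list.files(config$vcf_dir, pattern = "\\.vcf(\\.gz)?$",
                          full.names = TRUE))
  if (length(vcfs) == 0) stop("no VCF files in ", config$vcf_dir)
  gid <- function(path) sub("\\.(vcf)(\\.gz)?$", "", basename(path))
  calls <- dplyr::bind_rows(lapply(vcfs, function(v)
    read_variant_calls(v, genome_id = gid(v),
                       min_depth = cfg("min_depth", 5))))
  depth_files <- sort(list.files(config$depth_dir, pattern = "\\.tsv$",
                                 full.names = TRUE))
  tracks <- lapply(depth_files, read_depth_track)
  names(tracks) <- vapply(tracks, function(t) attr(t, "genome_id"), character(1))
  panel <- genome_panel(ref, calls, tracks)

  filtered <- filter_sites(
    panel,
    max_other_frac = cfg("max_other_frac", 0.10),
    low_depth_frac = cfg("low_depth_frac", 0.10),
    max_low_genomes_frac = cfg("max_low_genomes_frac", 0.10),
    flank_bp = cfg("flank_bp", 50))

  assemblies <- NULL
  if (!is.null(config$legacy)) {
    assemblies <- list(legacy = read_reference(config$legacy, "legacy"))
  }
  designs <- build_designs(
    panel, filtered, assemblies = assemblies,
    flank_bp = cfg("flank_bp", 50),
    max_flank_snps = cfg("max_flank_snps", 5),
    max_indel_len = cfg("max_indel_len", 10),
    min_indel_offset = cfg("min_indel_offset", 5),
    repeat_max_copies = cfg("repeat_max_copies", 5),
    gc_lo = cfg("gc_lo", 35), gc_hi = cfg("gc_hi", 65),
    gc_window = cfg("gc_window", 55))

  annotation <- NULL
  if (!is.null(config$gff)) {
    models <- read_gene_models(config$gff)
    annotation <- annotate_designs(designs, models, ref)
    designs <- dplyr::left_join(designs, annotation$by_design, by = "pKey")
  } else {
    designs$functional <- FALSE
  }

  selection <- NULL
  if (!is.null(config$targets)) {
    targets <- tibble::as_tibble(
      utils::read.table(config$targets, sep = "\t", header = TRUE,
                        colClasses = c(start = "integer", end = "integer")))
    predicted <- predicted_genotypes(panel, designs)
    cand <- find_candidates(targets, designs,
                            max_dist = cfg("max_dist", 20000))
    sel <- select_per_target(cand, predicted, k = cfg("k_per_target", 5))
    selection <- trim_to_quota(sel, cfg("quota", Inf))
  }

  manifest <- pipeline_manifest(filtered, designs, selection)

  ddump <- dplyr::select(designs, -dplyr::any_of("flank_snps"))
  write_tsv_c <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(config$out_dir, name),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_c(filtered, "filtered_sites.tsv")
  write_tsv_c(ddump, "designs.tsv")
  if (!is.null(annotation)) write_tsv_c(annotation$by_transcript,
                                        "annotation.tsv")
  if (!is.null(selection)) write_tsv_c(selection, "panel_selection.tsv")
  write_tsv_c(manifest, "manifest.tsv")

  list(panel = panel, filtered = filtered, designs = designs,
       annotation = annotation, selection = selection, manifest = manifest)
}

# per-rule accounting; candidates_in = survivors + sum of failures per stage
pipeline_manifest <- function(filtered, designs, selection = NULL) {
  f_counts <- filtered %>%
    dplyr::count(stage = "site_filters", rule = .data$failed_rule)
  d_counts <- designs %>%
    dplyr::count(stage = "design_build", rule = .data$failed_rule)
  rows <- dplyr::bind_rows(
    tibble::tibble(stage = "site_filters", rule = "candidates_in",
                   n = nrow(filtered)),
    f_counts,
    tibble::tibble(stage = "design_build", rule = "candidates_in",
                   n = nrow(designs)),
    d_counts
  )
  if (!is.null(selection)) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      stage = "selection", rule = "selected",
      n = length(unique(selection$pKey))))
  }
  rows
}
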