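#' Reference genome container
#'
#' A reference assembly is held as a [Biostrings::DNAStringSet] (one entry per
#' chromosome, uppercase, alphabet restricted to A/C/G/T/N) plus an assembly
#' identifier. External coordinates are 1-based inclusive throughout the
#' package, matching FASTA/VCF/GFF3 conventions; any internal 0-based
#' arithmetic is confined to private helpers.
#'
#' @param seqs Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param assembly_id Assembly name, e.g. `"R498"`.
#' @return An object of class `reference_genome`: a list with elements
#'   `assembly_id` and `seq` (a `DNAStringSet`).
#' @examples
#' ref <- reference_genome(c(chr1 = "ACGTACGT"), "toy")
#' ref_length(ref, "chr1")
#' @export
reference_genome <- function(seqs, assembly_id = "assembly") {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(names(seqs) == "")) {
      stop("duplicate or empty chromosome names")
    }
    if (any(grepl("[^ACGTNacgtn]", seqs))) {
      stop("reference sequences may contain only A/C/G/T/N")
    }
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names")
  if (any(Biostrings::width(seqs) == 0)) stop("zero-length chromosome")
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  if (any(rowSums(bad) != Biostrings::width(seqs))) {
    stop("reference sequences may contain only A/C/G/T/N")
  }
  # plain-character shadow copy for fast substring and seed search
  str <- stats::setNames(as.character(seqs), names(seqs))
  structure(list(assembly_id = assembly_id, seq = seqs, str = str),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$assembly_id, ": ", length(x$seq),
      " chromosome(s), ", sum(Biostrings::width(x$seq)), " bp\n", sep = "")
  invisible(x)
}

#' @rdname reference_genome
#' @param ref A `reference_genome`.
#' @param chrom Chromosome name.
#' @export
ref_length <- function(ref, chrom) {
  stopifnot(inherits(ref, "reference_genome"))
  if (!chrom %in% names(ref$seq)) stop("unknown chromosome: ", chrom)
  length(ref$seq[[chrom]])
}

#' @rdname reference_genome
#' @param start,end 1-based inclusive bounds.
#' @export
ref_subseq <- function(ref, chrom, start, end) {
  L <- ref_length(ref, chrom)
  if (start < 1 || end > L || start > end) {
    stop("subsequence ", start, "-", end, " out of bounds for ", chrom,
         " (length ", L, ")")
  }
  substring(ref$str[[chrom]], start, end)
}

#' Read / write a reference genome FASTA
#'
#' Sequences are uppercased on load; any character outside A/C/G/T/N and
#' duplicate record ids are rejected.
#'
#' @param path FASTA file path.
#' @param assembly_id Assembly name to attach.
#' @return A [reference_genome].
#' @export
read_reference <- function(path, assembly_id = tools::file_path_sans_ext(basename(path))) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA: ", path)
  # readDNAStringSet accepts the full IUPAC alphabet; restrict and uppercase
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  reference_genome(stats::setNames(as.character(seqs), names(seqs)), assembly_id)
}

#' @rdname read_reference
#' @param ref A [reference_genome] to write.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_genome"))
  Biostrings::writeXStringSet(ref$seq, path)
  invisible(path)
}
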