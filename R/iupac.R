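#' IUPAC degenerate nucleotide codes
#'
#' Helpers for converting between sets of unambiguous bases (A/C/G/T) and the
#' IUPAC single-letter ambiguity codes used to encode flanking polymorphism in
#' KASP design sequences.
#'
#' @name iupac
NULL

# canonical code -> base set table (N included; used for matching, never
# emitted for a SNP site)
.iupac_tab <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# base-set string (sorted) -> code
.iupac_rev <- stats::setNames(names(.iupac_tab), unname(.iupac_tab))

# 4-bit base masks: A=1, C=2, G=4, T=8; ambiguity codes are unions
.iupac_mask <- vapply(.iupac_tab, function(s) {
  b <- strsplit(s, "")[[1]]
  sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b])
}, integer(1))

#' @describeIn iupac Minimal IUPAC letter covering a set of bases.
#' @param bases Character vector of unambiguous bases (any order, duplicates
#'   allowed), e.g. `c("C", "T")`.
#' @return `iupac_code()` returns a single letter; `iupac_bases()` a character
#'   vector of the bases a letter stands for.
#' @examples
#' iupac_code(c("C", "T"))  # "Y"
#' iupac_bases("V")         # A C G
#' @export
iupac_code <- function(bases) {
  bases <- unique(toupper(bases))
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("iupac_code() only covers unambiguous bases A/C/G/T, got: ",
         paste(setdiff(bases, c("A", "C", "G", "T")), collapse = ", "))
  }
  unname(.iupac_rev[paste(sort(bases), collapse = "")])
}

#' @describeIn iupac Bases covered by one IUPAC letter.
#' @param code A single IUPAC letter.
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  if (!code %in% names(.iupac_tab)) stop("not an IUPAC nucleotide code: ", code)
  strsplit(unname(.iupac_tab[code]), "")[[1]]
}

#' @describeIn iupac GC weight of a letter: fraction of its base set that is
#'   G or C (`S` = 1, `W` = 0, `R` = 0.5, ...). `N` returns `NA` because N
#'   positions are excluded from GC calculations altogether.
#' @export
iupac_gc_weight <- function(code) {
  vapply(toupper(code), function(cc) {
    if (cc == "N") return(NA_real_)
    b <- iupac_bases(cc)
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# integer compatibility masks for a sequence string (vector of 4-bit masks);
# characters outside the IUPAC alphabet get mask 0 (match nothing)
seq_masks <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  m <- .iupac_mask[ch]
  m[is.na(m)] <- 0L
  unname(m)
}

# reverse complement preserving IUPAC letters
revcomp <- function(seq) {
  comp <- chartr("ACGTRYKMBDHVSWN", "TGCAYRMKVHDBSWN", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# all resolutions of a degenerate string into plain ACGT strings, with a cap
# on the cartesian product size
expand_ambiguity <- function(seq, max_resolutions = 4^10) {
  ch <- strsplit(toupper(seq), "")[[1]]
  sets <- lapply(ch, function(cc) {
    if (cc %in% c("A", "C", "G", "T")) cc else iupac_bases(cc)
  })
  n <- prod(lengths(sets))
  if (n > max_resolutions) {
    stop("ambiguity expansion would produce ", n, " resolutions (cap ",
         max_resolutions, ")")
  }
  if (n == 1) return(paste(ch, collapse = ""))
  amb <- which(lengths(sets) > 1)
  grid <- expand.grid(sets[amb], stringsAsFactors = FALSE)
  out <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ch2 <- ch
    ch2[amb] <- as.character(unlist(grid[i, ], use.names = FALSE))
    out[i] <- paste(ch2, collapse = "")
  }
  out
}
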