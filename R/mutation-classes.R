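# Canonical algebra of trinucleotide-context mutation classes and k-mer
# changes. All vectors and files use the conventional COSMIC ordering of the
# 96 classes (substitution type C>A, C>G, C>T, T>A, T>C, T>G, then
# alphabetical 5'/3' context) and the "XYZ>XWZ" string dialect, e.g.
# "TCA>TTA" for a central C>T flanked by T and A.

DNA_BASES_ <- c("A", "C", "G", "T")
SUBSTITUTION_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement for plain character vectors of A/C/G/T
#' strings (any length).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("AGC", "TTCCGGATTTT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x) | is.na(x)
  if (any(bad)) {
    rlang::abort(sprintf(
      "%s must contain only A/C/G/T; offending value(s): %s",
      what, paste(utils::head(unique(x[bad]), 3), collapse = ", ")
    ))
  }
  invisible(x)
}

#' The 96 canonical mutation classes
#'
#' Single-base substitutions in trinucleotide context are strand-collapsed so
#' that the central (mutated) base is a pyrimidine (C or T); there are
#' 4 x 2 x 3 x 4 = 96 such classes. Returned in COSMIC order: grouped by
#' substitution type (C>A, C>G, C>T, T>A, T>C, T>G), then alphabetical by 5'
#' and 3' flanking base.
#'
#' @return Character vector of length 96, e.g. `"ACA>AAA"`, `"TCA>TTA"`.
#' @export
#' @examples
#' head(mutation_classes())
mutation_classes <- function() {
  out <- character(0)
  for (type in SUBSTITUTION_TYPES) {
    ref <- substr(type, 1, 1)
    alt <- substr(type, 3, 3)
    for (p5 in DNA_BASES_) for (p3 in DNA_BASES_) {
      out <- c(out, paste0(p5, ref, p3, ">", p5, alt, p3))
    }
  }
  out
}

#' Substitution type of a mutation class
#'
#' @param class Character vector of class labels (`"TCA>TTA"` style).
#' @return Character vector of pyrimidine substitution types (`"C>T"` etc.).
#' @export
substitution_type <- function(class) {
  paste0(substr(class, 2, 2), ">", substr(class, 6, 6))
}

#' Collapse a trinucleotide substitution to its canonical mutation class
#'
#' Mutation classes do not distinguish the DNA strand of the mutated base: a
#' substitution whose central base is a purine (A or G) is reported as the
#' reverse complement of both the trinucleotide and the alternate base, so
#' that the central base of every class is C or T. For example AGC>ATC is
#' grouped with GCT>GAT.
#'
#' @param ref_tri Character vector of reference trinucleotides.
#' @param alt Character vector of alternate central bases (recycled).
#' @return Character vector of canonical class labels.
#' @export
#' @examples
#' canonical_class("AGC", "T") # "GCT>GAT"
#' canonical_class("ACA", "A") # "ACA>AAA"
canonical_class <- function(ref_tri, alt) {
  n <- max(length(ref_tri), length(alt))
  ref_tri <- rep_len(ref_tri, n)
  alt <- rep_len(alt, n)
  check_dna(ref_tri, "ref_tri")
  check_dna(alt, "alt")
  if (any(nchar(ref_tri) != 3L)) rlang::abort("ref_tri must be length-3 strings")
  if (any(nchar(alt) != 1L)) rlang::abort("alt must be single bases")
  center <- substr(ref_tri, 2, 2)
  if (any(alt == center)) {
    rlang::abort("alt must differ from the central reference base")
  }
  purine <- center %in% c("A", "G")
  tri <- ref_tri
  if (any(purine)) {
    tri[purine] <- revcomp(ref_tri[purine])
    alt[purine] <- comp_base(alt[purine])
  }
  paste0(tri, ">", substr(tri, 1, 1), alt, substr(tri, 3, 3))
}

#' Canonicalise a k-mer change
#'
#' Extends the pyrimidine-strand convention of [canonical_class()] to changes
#' of the central base of an odd-length k-mer (the assayed tables use
#' 11-mers): when the central base is a purine, both the k-mer and the
#' alternate base are reverse-complemented. Idempotent.
#'
#' @param kmer Character vector of odd-length A/C/G/T strings (all the same
#'   width).
#' @param alt Character vector of alternate central bases.
#' @return A tibble with columns `kmer`, `alt` (canonical form) and `class`
#'   (the canonical class of the central trinucleotide change).
#' @export
#' @examples
#' canonical_change("TTCCGGATTTT", "A") # center G -> reverse complemented
canonical_change <- function(kmer, alt) {
  n <- max(length(kmer), length(alt))
  kmer <- rep_len(kmer, n)
  alt <- rep_len(alt, n)
  check_dna(kmer, "kmer")
  check_dna(alt, "alt")
  w <- unique(nchar(kmer))
  if (length(w) != 1L || w < 3L || w %% 2L == 0L) {
    rlang::abort("kmer must be odd-length strings of a single common width (>= 3)")
  }
  c0 <- (w + 1L) %/% 2L
  center <- substr(kmer, c0, c0)
  if (any(alt == center)) {
    rlang::abort("alt must differ from the central base of kmer")
  }
  purine <- center %in% c("A", "G")
  if (any(purine)) {
    kmer[purine] <- revcomp(kmer[purine])
    alt[purine] <- comp_base(alt[purine])
  }
  tri <- substr(kmer, c0 - 1L, c0 + 1L)
  tibble::tibble(
    kmer = kmer, alt = alt,
    class = paste0(tri, ">", substr(tri, 1, 1), alt, substr(tri, 3, 3))
  )
}

all_kmers <- function(width) {
  if (width == 0L) return("")
  Biostrings::mkAllStrings(DNA_BASES_, width)
}

#' Enumerate all canonical k-mer changes of one mutation class
#'
#' For a class with central trinucleotide XYZ there are `4^(width - 3)`
#' k-mers containing XYZ at the centre, each contributing one change to the
#' given alternate base: 65,536 changes per class at the assay width of 11.
#' The 96 enumerations partition the full space of `96 * 4^(width - 3)`
#' canonical changes (6,291,456 at width 11).
#'
#' @param class A single canonical class label, e.g. `"TCA>TTA"`.
#' @param width Odd k-mer width (default 11, the assay width).
#' @return Tibble with columns `kmer`, `alt`, `class`.
#' @export
#' @examples
#' nrow(enumerate_changes("TCA>TTA", width = 5)) # 4^2 = 16
enumerate_changes <- function(class, width = 11L) {
  stopifnot(length(class) == 1L)
  if (!class %in% mutation_classes()) {
    rlang::abort(sprintf("'%s' is not one of the 96 canonical mutation classes", class))
  }
  if (width < 3L || width %% 2L == 0L) rlang::abort("width must be odd and >= 3")
  flank <- (width - 3L) %/% 2L
  tri <- substr(class, 1, 3)
  alt <- substr(class, 6, 6)
  left <- all_kmers(flank)
  right <- all_kmers(flank)
  grid <- expand.grid(right = right, left = left,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    kmer = paste0(grid$left, tri, grid$right),
    alt = alt,
    class = class
  )
}

#' Enumerate all canonical k-mer changes
#'
#' @param width Odd k-mer width.
#' @return Tibble with columns `kmer`, `alt`, `class`; `96 * 4^(width - 3)`
#'   rows.
#' @export
enumerate_all_changes <- function(width = 7L) {
  dplyr::bind_rows(lapply(mutation_classes(), enumerate_changes, width = width))
}
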