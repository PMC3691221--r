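#' The vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial code (NCBI translation table 2) as a
#' list with the codon table and the start-codon set used throughout the
#' package. Relative to the standard code, AGA and AGG are stop codons, ATA
#' encodes methionine and TGA encodes tryptophan, leaving 60 sense codons and
#' 4 stops (TAA, TAG, AGA, AGG). Mitochondrial open reading frames initiate
#' at ATG or, in some genes (e.g. COX1 in many fishes), GTG.
#'
#' @param start_codons Character vector of accepted initiation codons.
#' @return A list of class `mito_code` with elements `table` (named character
#'   vector codon -> one-letter amino acid, `"*"` for stop), `start_codons`,
#'   `stop_codons` and `sense_codons` (the 60 sense codons in alphabetical
#'   order, the fixed column order of codon-usage matrices).
#' @export
#' @examples
#' code <- mito_genetic_code()
#' code$table[c("ATA", "TGA", "AGA")]
mito_genetic_code <- function(start_codons = c("ATG", "GTG")) {
  tab <- Biostrings::getGeneticCode("2")  # Vertebrate Mitochondrial
  names(tab) <- gsub("U", "T", names(tab))
  tab <- tab[order(names(tab))]
  structure(
    list(
      table = tab,
      start_codons = toupper(start_codons),
      stop_codons = sort(names(tab)[tab == "*"]),
      sense_codons = names(tab)[tab != "*"]
    ),
    class = "mito_code"
  )
}

# Split a sequence into in-frame codons (complete triplets only).
split_codons <- function(x) {
  x <- clean_seq(x)
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a mitochondrial coding sequence
#'
#' Translates an in-frame nucleotide sequence under the vertebrate
#' mitochondrial code. Translation stops at the first in-frame stop codon;
#' the stop symbol itself is not returned. An incomplete terminal codon
#' (1 or 2 trailing bases, as left by truncated TA+/T++ stops) is ignored.
#' Codons containing a base outside ACGT (e.g. `N` or an alignment gap) are
#' rendered as `X`.
#'
#' @param cds Nucleotide string, length >= 3, read from position 1.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Amino-acid string (possibly empty if the CDS opens with a stop).
#' @export
#' @examples
#' translate_mito("ATGTTTTAA")  # "MF"
#' translate_mito("ATGAGA")     # "M" (AGA is a mitochondrial stop)
translate_mito <- function(cds, code = mito_genetic_code()) {
  cds <- clean_seq(cds)
  if (nchar(cds) < 3L) abort("coding sequence shorter than one codon")
  codons <- split_codons(cds)
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

# Two-base codon prefixes that are fourfold degenerate: the amino acid is
# determined by the first two bases for every third base, and no third base
# yields a stop. Computed from the code table, not hard-coded.
fourfold_prefixes <- function(code = mito_genetic_code()) {
  bases <- c("A", "C", "G", "T")
  pre <- as.vector(outer(bases, bases, paste0))
  keep <- vapply(pre, function(p) {
    aas <- code$table[paste0(p, bases)]
    !any(aas == "*") && length(unique(aas)) == 1L
  }, logical(1))
  pre[keep]
}
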