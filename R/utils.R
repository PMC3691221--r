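#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join inner_join bind_rows
#'   group_by summarise ungroup across n rename row_number pull distinct count
#' @importFrom stats setNames
NULL

# Uppercase a sequence and strip whitespace. All internal sequence handling is
# on plain uppercase character strings; Biostrings objects appear only at the
# I/O and alignment boundaries.
clean_seq <- function(x) {
  toupper(gsub("[[:space:]]", "", x))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' IUPAC ambiguity codes (including `N`) are handled.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(clean_seq(x))))
}

# Coerce an alignment to a named character vector of equal-length rows.
# Accepted inputs: named character vector, tibble/data.frame with columns
# `taxon` and `sequence`, or a Biostrings XStringSet.
as_alignment <- function(x) {
  if (inherits(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.data.frame(x)) {
    need <- c("taxon", "sequence")
    if (!all(need %in% names(x))) {
      abort("alignment data frame needs columns `taxon` and `sequence`")
    }
    x <- setNames(x$sequence, x$taxon)
  }
  if (!is.character(x)) abort("cannot interpret input as an alignment")
  x <- setNames(clean_seq(x), names(x))
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("seq", seq_along(x))
  }
  if (length(unique(nchar(x))) > 1) {
    abort("alignment rows differ in length")
  }
  x
}

# Alignment as a character matrix, rows = taxa, columns = sites.
alignment_matrix <- function(aln) {
  aln <- as_alignment(aln)
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

matrix_alignment <- function(m) {
  setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
}

alignment_tibble <- function(aln) {
  aln <- as_alignment(aln)
  tibble(taxon = names(aln), sequence = unname(aln))
}

# Single genome sequence from a string, tibble(taxon, sequence) row, or list.
as_genome_seq <- function(genome) {
  if (is.list(genome) && !is.data.frame(genome) && !is.null(genome$sequence)) {
    genome <- genome$sequence
  }
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1L) abort("expected a single genome (one row)")
    genome <- genome$sequence
  }
  if (!is.character(genome) || length(genome) != 1L) {
    abort("cannot interpret input as a single genome sequence")
  }
  clean_seq(genome)
}
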