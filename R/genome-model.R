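#' Length of a (possibly origin-spanning) feature on a circular genome
#'
#' Coordinates are 1-based and inclusive on the H-strand reference, the
#' convention of published mitogenome feature tables. A feature whose stop
#' coordinate is smaller than its start wraps across the origin of the
#' circular molecule.
#'
#' @param start,stop 1-based inclusive coordinates (vectorized).
#' @param genome_length Genome size in nucleotides.
#' @return Integer vector of feature lengths in nucleotides.
#' @export
#' @examples
#' feature_length(7985, 8152, 16588)  # ATP8: 168
#' feature_length(16580, 5, 16588)    # wraps the origin: 14
feature_length <- function(start, stop, genome_length) {
  start <- as.integer(start)
  stop <- as.integer(stop)
  if (any(start < 1L | stop < 1L | start > genome_length | stop > genome_length)) {
    abort("coordinates outside [1, genome_length]")
  }
  ifelse(stop >= start, stop - start + 1L, genome_length - start + 1L + stop)
}

#' Intergenic spacing between consecutive features
#'
#' The number of nucleotides between the stop of the upstream feature and the
#' start of the next, as printed in mitogenome organization tables. Negative
#' values signal an overlap of that many nucleotides and are a normal property
#' of compact mitochondrial genomes (e.g. ATP8/ATP6 overlap by 10 nt).
#'
#' @param prev_stop Stop coordinate of the upstream feature (vectorized).
#' @param next_start Start coordinate of the downstream feature.
#' @return Integer vector of gaps (negative = overlap, 0 = abutting).
#' @export
#' @examples
#' intergenic_gap(3825, 3829)  # ND1 -> tRNA-Ile: 3
#' intergenic_gap(8152, 8143)  # ATP8/ATP6 overlap: -10
intergenic_gap <- function(prev_stop, next_start) {
  as.integer(next_start) - as.integer(prev_stop) - 1L
}

#' Base composition of a nucleotide sequence
#'
#' Counts A, C, G and T; `N` and other ambiguity codes are excluded from the
#' denominator, so the four fractions always sum to one over counted bases.
#'
#' @param sequence Nucleotide string.
#' @return A tibble with columns `base`, `count`, `fraction` and `percent`.
#' @export
#' @examples
#' base_composition("GGGT")
base_composition <- function(sequence) {
  sequence <- clean_seq(sequence)
  if (nchar(sequence) == 0L) abort("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::BString(sequence), c("A", "C", "G", "T"))
  total <- sum(counts)
  if (total == 0L) abort("sequence contains no unambiguous A/C/G/T base")
  tibble(
    base = c("A", "C", "G", "T"),
    count = as.integer(counts),
    fraction = as.numeric(counts) / total,
    percent = 100 * as.numeric(counts) / total
  )
}

#' Classify the stop codon of a mitochondrial CDS
#'
#' Mitochondrial protein genes frequently end in a non-triplet 3' end that is
#' completed to a functional TAA stop by post-transcriptional polyadenylation.
#' A CDS of triplet length must end in one of the four vertebrate
#' mitochondrial stops (TAA, TAG, AGA, AGG); a CDS with 2 trailing bases
#' reading `TA`, or 1 trailing base reading `T`, immediately adjacent to the
#' downstream feature is classified as the truncated stop `TA+` or `T++`.
#' Anything else signals a misannotation.
#'
#' @param cds_sequence Nucleotide string of the annotated CDS (H-strand genes
#'   as-is, L-strand genes already reverse-complemented to coding orientation).
#' @param adjacent_downstream Logical; is the CDS immediately followed by the
#'   next feature (intergenic gap <= 0)? Required for truncated stops.
#' @return One of `"TAA"`, `"TAG"`, `"AGA"`, `"AGG"`, `"TA+"`, `"T++"`.
#' @export
#' @examples
#' classify_stop_codon("ATGCCCTAA", FALSE)
classify_stop_codon <- function(cds_sequence, adjacent_downstream = TRUE) {
  cds_sequence <- clean_seq(cds_sequence)
  n <- nchar(cds_sequence)
  if (n < 3L) abort("coding sequence shorter than one codon")
  phase <- n %% 3L
  if (phase == 0L) {
    last <- substr(cds_sequence, n - 2L, n)
    stops <- mito_genetic_code()$stop_codons
    if (last %in% stops) return(last)
    abort(paste0("triplet CDS ends in non-stop codon ", last, " (misannotation?)"))
  }
  tail_bases <- substr(cds_sequence, n - phase + 1L, n)
  if (phase == 2L && tail_bases == "TA" && adjacent_downstream) return("TA+")
  if (phase == 1L && tail_bases == "T" && adjacent_downstream) return("T++")
  abort(paste0(
    "non-triplet CDS end `", tail_bases, "`",
    if (!adjacent_downstream) " not adjacent to a downstream feature" else "",
    " cannot be classified as a truncated stop"
  ))
}

#' Extract a feature sequence from a circular genome
#'
#' Returns the feature subsequence in coding orientation: H-strand features
#' as the genome substring `start..stop`, L-strand features as its reverse
#' complement. `stop < start` denotes a feature wrapping the origin.
#'
#' @param genome Genome sequence (string, or one-row tibble with `sequence`).
#' @param start,stop 1-based inclusive H-strand coordinates.
#' @param strand `"H"` or `"L"`.
#' @return Nucleotide string in coding orientation.
#' @export
#' @examples
#' extract_feature_seq("ACGTACGT", 2, 4)            # "CGT"
#' extract_feature_seq("ACGTACGT", 2, 4, strand = "L")  # "ACG"
#' extract_feature_seq("ACGTACGT", 7, 2)            # wraps: "GTAC"
extract_feature_seq <- function(genome, start, stop, strand = "H") {
  genome <- as_genome_seq(genome)
  L <- nchar(genome)
  start <- as.integer(start); stop <- as.integer(stop)
  if (start < 1L || stop < 1L || start > L || stop > L) {
    abort("feature coordinates outside the genome")
  }
  s <- if (stop >= start) {
    substr(genome, start, stop)
  } else {
    paste0(substr(genome, start, L), substr(genome, 1L, stop))
  }
  if (identical(strand, "L")) revcomp(s) else s
}

#' Extract every feature of a feature table
#'
#' @param genome Genome sequence (see [extract_feature_seq()]).
#' @param features Feature table tibble with columns `name`, `start`, `stop`,
#'   `strand` (as read by [read_feature_table()]).
#' @return The feature table with an added `sequence` column (coding
#'   orientation).
#' @export
extract_feature_seqs <- function(genome, features) {
  genome <- as_genome_seq(genome)
  features$sequence <- purrr::pmap_chr(
    list(features$start, features$stop, features$strand),
    function(start, stop, strand) extract_feature_seq(genome, start, stop, strand)
  )
  features
}

#' Consequence of a single-base deletion in a coding sequence
#'
#' Models the downstream effect of a frameshifting one-base deletion (as seen
#' in heteroplasmic indel variants): the base at `deletion_pos` is removed,
#' the sequence is re-read from position 1, and the first in-frame stop codon
#' after the shift is located.
#'
#' @param cds Nucleotide string of the intact CDS.
#' @param deletion_pos 1-based position of the deleted base within the CDS.
#' @param code Genetic code from [mito_genetic_code()].
#' @return A one-row tibble with `stop_found` (logical), `new_stop_start`
#'   (1-based position of the first stop codon in post-deletion coordinates,
#'   NA if none), `stop_codon`, and `truncated_protein_length` (amino acids
#'   preceding the stop; the full translated length if no stop is found).
#' @export
#' @examples
#' frameshift_consequence("ATGCTAACGG", 4)  # stop TAA at position 4, 1 aa
frameshift_consequence <- function(cds, deletion_pos, code = mito_genetic_code()) {
  cds <- clean_seq(cds)
  n <- nchar(cds)
  if (deletion_pos < 1L || deletion_pos > n) abort("deletion position outside the CDS")
  mutated <- paste0(substr(cds, 1L, deletion_pos - 1L), substr(cds, deletion_pos + 1L, n))
  codons <- split_codons(mutated)
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  stop_idx <- which(aa == "*")
  if (length(stop_idx)) {
    i <- stop_idx[1L]
    tibble(
      stop_found = TRUE,
      new_stop_start = 3L * (i - 1L) + 1L,
      stop_codon = codons[i],
      truncated_protein_length = i - 1L
    )
  } else {
    tibble(
      stop_found = FALSE,
      new_stop_start = NA_integer_,
      stop_codon = NA_character_,
      truncated_protein_length = length(aa)
    )
  }
}

#' Published mitogenome feature tables shipped with the package
#'
#' The complete mitochondrial feature tables of the two Lake Tanganyika
#' cichlids *Petrochromis trewavasae* (`"PT"`, 16,588 bp) and *Tropheus
#' moorii* (`"TM"`, 16,590 bp): 13 protein-coding genes, 22 tRNAs, 2 rRNAs,
#' the control region and the light-strand replication origin, with the
#' published size and intergenic columns retained for validation.
#'
#' @param species `"PT"` or `"TM"`.
#' @return Feature table tibble (see [read_feature_table()]).
#' @export
#' @examples
#' ft <- example_feature_table("PT")
#' dplyr::count(ft, class)
example_feature_table <- function(species = c("PT", "TM")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("feature_table_", species, ".tsv"),
                      package = "mitocomp", mustWork = TRUE)
  read_feature_table(path)
}

#' Validate a mitogenome feature table
#'
#' Recomputes the size of every feature and the intergenic spacing between
#' consecutive features (the last feature wraps to the first on the circular
#' genome) and, where the table carries published `size`/`intergenic`
#' columns, flags every disagreement. Also tallies features per class and
#' strand and sums the protein-coding nucleotides.
#'
#' @param features Feature table tibble sorted by start coordinate.
#' @param genome_length Genome size; defaults to the maximum stop coordinate
#'   (exact when the control region ends at the origin, as in the shipped
#'   tables).
#' @return An object of class `mito_validation`: a list with `table` (the
#'   input plus `size_calc`, `intergenic_calc`, `size_mismatch`,
#'   `intergenic_mismatch`), `n_mismatches`, `genome_length`, `class_counts`,
#'   `strand_counts`, `cds_total_bp`, `cds_fraction_percent` and `warnings`.
#' @export
#' @examples
#' report <- validate_genome_table(example_feature_table("PT"))
#' report$n_mismatches
validate_genome_table <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L)
  warnings <- character(0)
  if (is.unsorted(features$start)) {
    warnings <- c(warnings, "feature table not sorted by start coordinate; sorting")
    features <- dplyr::arrange(features, .data$start)
  }
  genome_length <- genome_length %||% max(features$stop)
  tab <- features
  tab$size_calc <- feature_length(tab$start, tab$stop, genome_length)
  nxt <- c(tab$start[-1L], tab$start[1L] + genome_length)
  tab$intergenic_calc <- as.integer(nxt - tab$stop - 1L)
  tab$size_mismatch <- if ("size" %in% names(tab)) {
    !is.na(tab$size) & tab$size != tab$size_calc
  } else rep(FALSE, nrow(tab))
  tab$intergenic_mismatch <- if ("intergenic" %in% names(tab)) {
    !is.na(tab$intergenic) & tab$intergenic != tab$intergenic_calc
  } else rep(FALSE, nrow(tab))

  big_overlap <- tab$intergenic_calc < -60L
  if (any(big_overlap)) {
    warnings <- c(warnings, paste0(
      "overlap beyond 60 nt at: ", paste(tab$name[big_overlap], collapse = ", ")
    ))
  }
  cds_total <- sum(tab$size_calc[tab$class == "CDS"])
  structure(
    list(
      table = tab,
      n_mismatches = sum(tab$size_mismatch) + sum(tab$intergenic_mismatch),
      genome_length = genome_length,
      class_counts = c(table(tab$class)),
      strand_counts = c(table(tab$strand)),
      cds_total_bp = cds_total,
      cds_fraction_percent = 100 * cds_total / genome_length,
      warnings = warnings
    ),
    class = "mito_validation"
  )
}

#' @export
print.mito_validation <- function(x, ...) {
  cat("Mitogenome feature-table validation\n")
  cat("  genome length:", x$genome_length, "bp\n")
  cat("  features:", nrow(x$table), "(",
      paste(names(x$class_counts), as.integer(x$class_counts), collapse = ", "), ")\n")
  cat("  size/intergenic mismatches:", x$n_mismatches, "\n")
  cat(sprintf("  CDS total: %d bp (%.2f%% of genome)\n",
              x$cds_total_bp, x$cds_fraction_percent))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
tidy.mito_validation <- function(x, ...) {
  as_tibble(x$table)
}

#' @export
glance.mito_validation <- function(x, ...) {
  tibble(
    genome_length = x$genome_length,
    n_features = nrow(x$table),
    n_mismatches = x$n_mismatches,
    cds_total_bp = x$cds_total_bp,
    cds_fraction_percent = x$cds_fraction_percent
  )
}

# Canonical feature-class inference from conventional mitochondrial gene
# names, used when alignments are keyed by gene label only.
infer_feature_class <- function(name) {
  cds <- c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
           "COX1", "COX2", "COX3", "ATP6", "ATP8", "CYTB")
  dplyr::case_when(
    toupper(name) %in% cds ~ "CDS",
    grepl("12S|16S|RRN", toupper(name)) ~ "rRNA",
    grepl("^TRNA|^TRN", toupper(name)) ~ "tRNA",
    grepl("D-?LOOP|^CR$|CONTROL", toupper(name)) ~ "CR",
    grepl("^OL$", toupper(name)) ~ "OL",
    TRUE ~ NA_character_
  )
}
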