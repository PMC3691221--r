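#' Gap-weighted p-distance between two aligned sequences
#'
#' The proportion of differing columns between two rows of an alignment. With
#' `gap_mode = "full_weight"` (the default, the "fully weighted gaps"
#' convention) a gap aligned to a base counts as a full difference, so
#' insertions and deletions contribute to divergence; columns where both rows
#' are gapped carry no signal and are excluded from numerator and
#' denominator. `N` (or any ambiguity symbol) never matches anything,
#' including another `N`. With `gap_mode = "ignore"` every column containing
#' a gap is excluded.
#'
#' @param row_a,row_b Aligned sequences of equal length over A/C/G/T/N/-.
#' @param gap_mode `"full_weight"` or `"ignore"`.
#' @return Distance in `[0, 1]`, with attribute `n_sites` (counted columns).
#' @export
#' @examples
#' p_distance("AA-A", "AATA")                      # 0.25
#' p_distance("AA-A", "AATA", gap_mode = "ignore") # 0
p_distance <- function(row_a, row_b, gap_mode = c("full_weight", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  a <- seq_chars(clean_seq(row_a))
  b <- seq_chars(clean_seq(row_b))
  if (length(a) != length(b)) abort("aligned sequences differ in length")
  gap_a <- a == "-"
  gap_b <- b == "-"
  counted <- if (gap_mode == "full_weight") !(gap_a & gap_b) else !(gap_a | gap_b)
  a <- a[counted]; b <- b[counted]
  if (length(a) == 0L) abort("undefined distance: no counted columns")
  plain <- c("A", "C", "G", "T")
  same <- a == b & a %in% plain
  d <- 1 - sum(same) / length(a)
  structure(d, n_sites = length(a))
}

#' Plurality consensus sequence of an alignment
#'
#' Per-column plurality symbol, with the gap character competing as an
#' ordinary symbol. Ties are broken toward the symbol most frequent in the
#' whole alignment, then alphabetically.
#'
#' @param alignment Alignment (named character vector, tibble with
#'   `taxon`/`sequence`, or XStringSet); >= 2 rows.
#' @return The consensus as a single aligned sequence (string).
#' @export
#' @examples
#' consensus_sequence(c(a = "AAT", b = "AAT", c = "AAA"))
consensus_sequence <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) abort("consensus needs at least 2 rows")
  overall <- table(m)
  # symbols in tie-break precedence: overall frequency desc, then alphabetical
  symbols <- names(overall)[order(-as.integer(overall), names(overall))]
  counts <- vapply(symbols, function(s) colSums(m == s),
                   numeric(ncol(m)))
  counts <- matrix(counts, ncol = length(symbols),
                   dimnames = list(NULL, symbols))
  pick <- symbols[max.col(counts, ties.method = "first")]
  paste(pick, collapse = "")
}

#' Per-gene distance table
#'
#' Computes gap-weighted p-distances for one gene alignment, either for all
#' unordered taxon pairs (`mode = "pairwise"`) or for each taxon against the
#' plurality consensus (`mode = "vs_consensus"`).
#'
#' @param alignment Gene alignment (>= 2 rows; >= 3 for downstream regression).
#' @param mode `"pairwise"` or `"vs_consensus"`.
#' @param gap_mode Passed to [p_distance()].
#' @param gene Optional gene label recorded in the table.
#' @return Tibble of class `mito_dist_table`: columns `gene`, `taxon_a`,
#'   `taxon_b` (`"consensus"` in vs_consensus mode), `distance`, `n_sites`.
#' @export
gene_distances <- function(alignment, mode = c("pairwise", "vs_consensus"),
                           gap_mode = c("full_weight", "ignore"),
                           gene = NA_character_) {
  mode <- match.arg(mode)
  gap_mode <- match.arg(gap_mode)
  aln <- as_alignment(alignment)
  taxa <- names(aln)
  if (mode == "pairwise") {
    pairs <- utils::combn(taxa, 2L)
    d <- purrr::map(seq_len(ncol(pairs)), function(k) {
      dd <- p_distance(aln[[pairs[1L, k]]], aln[[pairs[2L, k]]], gap_mode)
      tibble(taxon_a = pairs[1L, k], taxon_b = pairs[2L, k],
             distance = as.numeric(dd), n_sites = attr(dd, "n_sites"))
    })
    out <- dplyr::bind_rows(d)
  } else {
    cons <- consensus_sequence(aln)
    out <- purrr::map_dfr(taxa, function(t) {
      dd <- p_distance(aln[[t]], cons, gap_mode)
      tibble(taxon_a = t, taxon_b = "consensus",
             distance = as.numeric(dd), n_sites = attr(dd, "n_sites"))
    })
  }
  out <- dplyr::mutate(out, gene = gene, .before = 1L)
  class(out) <- c("mito_dist_table", class(out))
  attr(out, "mode") <- mode
  out
}

#' Split a codon alignment into the three codon-position partitions
#'
#' @param codon_alignment In-frame codon alignment whose length is divisible
#'   by 3 (e.g. from back-translation).
#' @return Named list of three alignments (`pos1`, `pos2`, `pos3`), column
#'   order preserved within each partition.
#' @export
codon_position_split <- function(codon_alignment) {
  m <- alignment_matrix(codon_alignment)
  if (ncol(m) %% 3L != 0L) abort("alignment length not divisible by 3 (frame error)")
  idx <- ((seq_len(ncol(m)) - 1L) %% 3L) + 1L
  lapply(setNames(1:3, paste0("pos", 1:3)), function(p) {
    matrix_alignment(m[, idx == p, drop = FALSE])
  })
}

#' Fourfold-degenerate third-codon-position sites
#'
#' A codon column-triple contributes its third position when, in every taxon
#' with a complete unambiguous codon there, the first two bases determine the
#' amino acid for all four third bases under the vertebrate mitochondrial
#' code (and no third base yields a stop). A taxon whose codon contains a gap
#' or `N` abstains; the site is kept only if all non-missing taxa qualify and
#' at least one taxon votes.
#'
#' @param codon_alignment In-frame codon alignment (length divisible by 3).
#' @param code Genetic code from [mito_genetic_code()].
#' @return Integer vector of alignment column indices (third positions).
#' @export
fourfold_degenerate_sites <- function(codon_alignment, code = mito_genetic_code()) {
  m <- alignment_matrix(codon_alignment)
  if (ncol(m) %% 3L != 0L) abort("alignment length not divisible by 3 (frame error)")
  prefixes <- fourfold_prefixes(code)
  n_codons <- ncol(m) %/% 3L
  keep <- vapply(seq_len(n_codons), function(k) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    codons <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    complete <- grepl("^[ACGT]{3}$", codons)
    if (!any(complete)) return(FALSE)
    all(substr(codons[complete], 1L, 2L) %in% prefixes)
  }, logical(1))
  which(keep) * 3L
}

#' Drop gap-rich alignment columns
#'
#' Removes every column whose gap fraction exceeds `max_gap_fraction`; with
#' the default 0 every column containing a gap is removed. This is the
#' package's documented stand-in for external block-filtering tools when
#' indel-rich regions (e.g. the D-loop) are to be compared with and without
#' insertions/deletions.
#'
#' @param alignment Alignment.
#' @param max_gap_fraction Highest tolerated per-column gap fraction in
#'   `[0, 1]` (default 0).
#' @return The filtered alignment (named character vector), column order
#'   preserved. Errors if no column survives.
#' @export
gap_column_filter <- function(alignment, max_gap_fraction = 0) {
  stopifnot(max_gap_fraction >= 0, max_gap_fraction <= 1)
  m <- alignment_matrix(alignment)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_fraction
  if (!any(keep)) abort("gap filter removed every column")
  matrix_alignment(m[, keep, drop = FALSE])
}
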