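#' Default control-region motif set
#'
#' The seven conserved control-region elements (TAS, CSB-F, CSB-E, OH, CSB1,
#' CSB2, CSB3) of the *P. trewavasae* D-loop, shipped as the default motif
#' set for control-region partitioning. The per-motif mismatch budget
#' defaults to `ceiling(0.1 * nchar(sequence))`, which accommodates the <=3
#' substitutions observed between the two study species on a 45-mer.
#'
#' @param species Reference species for the motif sequences (`"PT"` default).
#' @return Tibble with columns `motif`, `sequence`, `max_mismatches`.
#' @export
default_motif_set <- function(species = c("PT", "TM")) {
  species <- match.arg(species)
  tab <- dloop_motif_table()
  tab <- tab[tab$species == species & !is.na(tab$sequence), ]
  tibble(
    motif = tab$item,
    sequence = tab$sequence,
    max_mismatches = as.integer(ceiling(0.1 * nchar(tab$sequence)))
  )
}

#' Approximate motif search by Hamming-window scan
#'
#' Reports every window of the sequence whose Hamming distance to the motif
#' is within the mismatch budget (no indels). Matching is performed with
#' [Biostrings::matchPattern()].
#'
#' @param sequence Nucleotide string to scan.
#' @param motif Motif string over A/C/G/T.
#' @param max_mismatches Maximum Hamming distance (default 0).
#' @return Tibble with `position` (1-based window start, ascending) and
#'   `mismatches`.
#' @export
#' @examples
#' find_motif_approx("AAACCC", "ACC", 0)
find_motif_approx <- function(sequence, motif, max_mismatches = 0L) {
  sequence <- clean_seq(sequence); motif <- clean_seq(motif)
  if (nchar(motif) > nchar(sequence)) abort("motif longer than sequence")
  if (!grepl("^[ACGT]+$", motif)) abort("motif alphabet must be A/C/G/T")
  hits <- Biostrings::matchPattern(
    motif, Biostrings::DNAString(sequence),
    max.mismatch = max_mismatches, with.indels = FALSE, fixed = TRUE
  )
  pos <- Biostrings::start(hits)
  # matchPattern may report hits running off the sequence ends; only complete
  # windows count
  pos <- pos[pos >= 1L & pos <= nchar(sequence) - nchar(motif) + 1L]
  if (length(pos) == 0L) return(tibble(position = integer(0), mismatches = integer(0)))
  mm <- vapply(pos, function(p) {
    w <- substr(sequence, p, p + nchar(motif) - 1L)
    sum(seq_chars(w) != seq_chars(motif))
  }, integer(1))
  tibble(position = as.integer(sort(pos)), mismatches = mm[order(pos)])
}

#' Partition a control region into its three canonical domains
#'
#' The vertebrate mitochondrial control region divides into (1) a
#' hypervariable domain containing the termination-associated sequence (TAS),
#' (2) a central conserved domain opening at CSB-F and containing CSB-E and
#' the heavy-strand replication origin, and (3) a variable domain opening at
#' CSB1 and containing CSB2 and CSB3. Domain 2 is anchored at the CSB-F hit,
#' domain 3 at the CSB1 hit; every motif hit is reported relative to the
#' control-region start.
#'
#' @param cr_sequence Control-region sequence (5' to 3' on the H strand).
#' @param motifs Motif set tibble (see [default_motif_set()]).
#' @return List of class `mito_cr_partition`: `domains` (tibble `domain`,
#'   `start`, `end`), `hits` (tibble `motif`, `position`, `end`,
#'   `mismatches`; best hit per motif, NA rows for missing optional motifs).
#' @export
partition_control_region <- function(cr_sequence, motifs = default_motif_set()) {
  cr_sequence <- clean_seq(cr_sequence)
  if (nchar(cr_sequence) < max(nchar(motifs$sequence))) {
    abort("control region shorter than the longest motif")
  }
  hits <- purrr::pmap_dfr(
    list(motifs$motif, motifs$sequence, motifs$max_mismatches),
    function(m, s, k) {
      h <- find_motif_approx(cr_sequence, s, k)
      if (nrow(h) == 0L) {
        return(tibble(motif = m, position = NA_integer_, end = NA_integer_,
                      mismatches = NA_integer_))
      }
      h <- h[order(h$mismatches, h$position), ][1L, ]
      tibble(motif = m, position = h$position,
             end = h$position + nchar(s) - 1L, mismatches = h$mismatches)
    }
  )
  anchor <- function(name) hits$position[hits$motif == name]
  csbf <- anchor("CSB-F"); csb1 <- anchor("CSB1")
  if (length(csbf) == 0L || is.na(csbf) || length(csb1) == 0L || is.na(csb1)) {
    found <- hits$motif[!is.na(hits$position)]
    abort(paste0(
      "cannot partition control region: anchor motif ",
      paste(setdiff(c("CSB-F", "CSB1"),
                    hits$motif[!is.na(hits$position)]), collapse = " and "),
      " not found within the mismatch budget (found: ",
      if (length(found)) paste(found, collapse = ", ") else "none", ")"
    ))
  }
  if (csbf <= 1L || csb1 <= csbf) {
    abort("anchor motifs out of order; cannot partition control region")
  }
  domains <- tibble(
    domain = c("Domain1", "Domain2", "Domain3"),
    start = c(1L, as.integer(csbf), as.integer(csb1)),
    end = c(as.integer(csbf) - 1L, as.integer(csb1) - 1L, nchar(cr_sequence))
  )
  structure(list(domains = domains, hits = hits), class = "mito_cr_partition")
}

#' @export
print.mito_cr_partition <- function(x, ...) {
  cat("Control-region partition\n")
  print(x$domains)
  cat("Motif hits (positions relative to control-region start):\n")
  print(x$hits)
  invisible(x)
}

#' @export
tidy.mito_cr_partition <- function(x, ...) x$hits

#' @export
glance.mito_cr_partition <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(
      dplyr::mutate(x$domains, length = .data$end - .data$start + 1L),
      "domain", "length"
    ),
    names_from = "domain", values_from = "length"
  )
}
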