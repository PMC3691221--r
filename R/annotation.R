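#' Optimal local alignment of two nucleotide sequences
#'
#' Smith-Waterman-style local alignment used as the homology-search engine of
#' the annotation-transfer pipeline, so no external search binary is needed.
#' Built on [Biostrings::pairwiseAlignment()] with affine gap costs.
#'
#' @param query,target Nucleotide strings (query = reference feature).
#' @param match,mismatch Match/mismatch scores (defaults +2/-3).
#' @param gap_open,gap_extend Gap opening/extension penalties (positive
#'   costs; defaults 5 and 2).
#' @return One-row tibble with `query_start`, `query_end`, `target_start`,
#'   `target_end`, `score`, `identity` (matches / alignment columns) and
#'   `coverage` (aligned query span / query length).
#' @export
#' @examples
#' local_align("ACGTACGT", "TTACGTACGTTT")
local_align <- function(query, target, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2) {
  query <- clean_seq(query); target <- clean_seq(target)
  if (nchar(query) == 0L || nchar(target) == 0L) abort("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA"
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = target, type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  width <- nchar(as.character(pat))  # alignment columns incl. gaps
  tibble(
    query_start = Biostrings::start(pat),
    query_end = Biostrings::end(pat),
    target_start = Biostrings::start(sub),
    target_end = Biostrings::end(sub),
    score = Biostrings::score(aln),
    identity = Biostrings::nmatch(aln) / width,
    coverage = (Biostrings::end(pat) - Biostrings::start(pat) + 1) / nchar(query)
  )
}

#' Place a reference feature sequence on a target genome
#'
#' Searches both strands of a circular genome (via a doubled-sequence search
#' across the origin) for the best-scoring local alignment of a reference
#' feature and reports it as a placement with percent identity and length
#' coverage. Placements below the identity/coverage thresholds are dropped.
#'
#' @param ref_seq Reference feature sequence in coding orientation.
#' @param genome Target genome sequence (string or one-row tibble).
#' @param feature_name,ref_taxon Labels carried into the placement.
#' @param both_strands Search the L strand too (default TRUE).
#' @param circular Search across the origin (default TRUE).
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.6).
#' @param ... Scoring parameters passed to [local_align()].
#' @return Tibble with zero rows (not found) or one row: `feature_name`,
#'   `ref_taxon`, `start`, `stop` (1-based H-strand, `stop < start` denotes an
#'   origin-spanning feature), `strand`, `percent_identity`,
#'   `length_coverage`, `score` (identity x coverage).
#' @export
place_feature <- function(ref_seq, genome, feature_name = NA_character_,
                          ref_taxon = NA_character_, both_strands = TRUE,
                          circular = TRUE, min_identity = 0.6,
                          min_coverage = 0.6, ...) {
  ref_seq <- clean_seq(ref_seq)
  genome <- as_genome_seq(genome)
  if (nchar(ref_seq) < 20L) abort("reference sequence shorter than 20 nt")
  L <- nchar(genome)
  target <- if (circular) {
    paste0(genome, substr(genome, 1L, min(L - 1L, nchar(ref_seq) + 100L)))
  } else genome
  strands <- if (both_strands) c("H", "L") else "H"
  hits <- purrr::map(strands, function(s) {
    q <- if (s == "L") revcomp(ref_seq) else ref_seq
    hit <- local_align(q, target, ...)
    hit$strand <- s
    hit
  })
  hits <- dplyr::bind_rows(hits)
  hits <- dplyr::filter(hits, .data$identity >= min_identity,
                        .data$coverage >= min_coverage)
  if (nrow(hits) == 0L) {
    return(tibble(
      feature_name = character(0), ref_taxon = character(0),
      start = integer(0), stop = integer(0), strand = character(0),
      percent_identity = numeric(0), length_coverage = numeric(0),
      score = numeric(0)
    ))
  }
  best <- hits[order(-(hits$identity * hits$coverage), hits$target_start), ][1L, ]
  start <- ((best$target_start - 1L) %% L) + 1L
  stop <- ((best$target_end - 1L) %% L) + 1L
  tibble(
    feature_name = feature_name, ref_taxon = ref_taxon,
    start = as.integer(start), stop = as.integer(stop), strand = best$strand,
    percent_identity = best$identity, length_coverage = best$coverage,
    score = best$identity * best$coverage
  )
}

# Majority vote over integer candidates with optional near-miss window.
# Ties between values go to the supporting placement with the highest score.
majority_vote <- function(values, scores, window = 0L) {
  cand <- sort(unique(values))
  support <- vapply(cand, function(v) sum(abs(values - v) <= window), integer(1))
  top <- cand[support == max(support)]
  if (length(top) == 1L) return(list(value = top, support = max(support)))
  best_scores <- vapply(top, function(v) max(scores[values == v]), numeric(1))
  winners <- top[best_scores == max(best_scores)]
  list(value = min(winners), support = max(support))
}

#' Majority-rule consensus over reference placements
#'
#' Collapses the placements of one feature from several reference genomes
#' into a single consensus annotation: start and stop are chosen by strict
#' plurality over the exact candidate coordinates (optionally with a
#' near-miss window), ties are broken toward the highest-scoring placement,
#' and the strand must have a majority.
#'
#' @param placements Tibble of placements (rows as returned by
#'   [place_feature()]) for a single feature.
#' @param near_window Integer; votes also count for coordinates within
#'   `near_window` nt (default 0 = exact-match vote).
#' @return One-row tibble: `feature_name`, `start`, `stop`, `strand`,
#'   `support` (placements backing the winning start), `n_placements`,
#'   `mean_identity`.
#' @export
consensus_annotation <- function(placements, near_window = 0L) {
  if (is.null(placements) || nrow(placements) == 0L) {
    abort("not found: no placement passed the thresholds")
  }
  strand_tab <- table(placements$strand)
  top_strand <- names(strand_tab)[strand_tab == max(strand_tab)]
  if (length(top_strand) > 1L) {
    abort("ambiguous strand: no majority across placements")
  }
  v_start <- majority_vote(placements$start, placements$score, near_window)
  v_stop <- majority_vote(placements$stop, placements$score, near_window)
  tibble(
    feature_name = placements$feature_name[1L],
    start = as.integer(v_start$value),
    stop = as.integer(v_stop$value),
    strand = top_strand,
    support = as.integer(v_start$support),
    n_placements = nrow(placements),
    mean_identity = mean(placements$percent_identity)
  )
}

#' Read a reference feature set
#'
#' Accepts either a directory of per-feature FASTA files (file name = feature
#' label, record headers = reference taxa) or a single multi-FASTA whose
#' headers read `taxon|feature`.
#'
#' @param path Directory or FASTA file.
#' @return Tibble with columns `taxon`, `feature`, `class` (inferred from the
#'   feature name), `sequence`.
#' @export
read_reference_set <- function(path) {
  recs <- if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (length(files) == 0L) abort(paste0("no FASTA files in ", path))
    purrr::map_dfr(files, function(f) {
      r <- read_fasta(f)
      r$feature <- sub("\\.(fa|fasta|fna)$", "", basename(f))
      r
    })
  } else {
    r <- read_fasta(path)
    parts <- stringr::str_split_fixed(r$taxon, stringr::fixed("|"), 2L)
    if (any(parts[, 2] == "")) abort("multi-FASTA headers must read `taxon|feature`")
    r$taxon <- parts[, 1]
    r$feature <- parts[, 2]
    r
  }
  recs$class <- infer_feature_class(recs$feature)
  recs[, c("taxon", "feature", "class", "sequence")]
}

#' Homology-transfer annotation of a mitogenome
#'
#' Places every reference feature on the target genome ([place_feature()]),
#' collapses placements per feature by majority rule
#' ([consensus_annotation()]), sorts by start coordinate and fills in CDS
#' codon metadata (start codon from the placed sequence; stop class from
#' [classify_stop_codon()] using the recomputed adjacency to the next
#' feature).
#'
#' @param genome Target genome sequence.
#' @param refs Reference set tibble (`taxon`, `feature`, `class`, `sequence`,
#'   optional `anticodon`), e.g. from [read_reference_set()].
#' @param min_identity,min_coverage Placement thresholds (defaults 0.6).
#' @param near_window Near-miss window for the majority vote (default 0).
#' @param ... Passed to [place_feature()].
#' @return Feature table tibble with consensus `support` and `n_placements`
#'   columns; features with no accepted placement are dropped with a warning.
#' @export
annotate_genome <- function(genome, refs, min_identity = 0.6,
                            min_coverage = 0.6, near_window = 0L, ...) {
  genome <- as_genome_seq(genome)
  L <- nchar(genome)
  rows <- list()
  for (feat in unique(refs$feature)) {
    sub <- refs[refs$feature == feat, ]
    placements <- purrr::pmap_dfr(
      list(sub$sequence, sub$taxon),
      function(s, taxon) {
        place_feature(s, genome, feature_name = feat, ref_taxon = taxon,
                      min_identity = min_identity,
                      min_coverage = min_coverage, ...)
      }
    )
    if (nrow(placements) == 0L) {
      warn(paste0("feature not found on target genome: ", feat))
      next
    }
    cons <- consensus_annotation(placements, near_window = near_window)
    cons$class <- sub$class[1L]
    cons$anticodon <- if ("anticodon" %in% names(sub)) {
      ac <- sub$anticodon[!is.na(sub$anticodon)]
      if (length(ac)) ac[1L] else NA_character_
    } else NA_character_
    rows[[feat]] <- cons
  }
  if (length(rows) == 0L) abort("no feature could be placed on the target genome")
  tab <- dplyr::bind_rows(rows)
  tab <- dplyr::arrange(tab, .data$start)
  tab <- dplyr::rename(tab, name = "feature_name")
  # CDS codon metadata from the placed sequences
  nxt_start <- c(tab$start[-1L], tab$start[1L] + L)
  adjacent <- (nxt_start - tab$stop - 1L) <= 0L
  meta <- purrr::pmap_dfr(
    list(tab$start, tab$stop, tab$strand, tab$class, adjacent),
    function(start, stop, strand, class, adj) {
      if (!identical(class, "CDS")) {
        return(tibble(start_codon = NA_character_, stop_class = NA_character_))
      }
      s <- extract_feature_seq(genome, start, stop, strand)
      sc <- substr(s, 1L, 3L)
      code <- mito_genetic_code()
      tibble(
        start_codon = if (sc %in% code$start_codons) sc else NA_character_,
        stop_class = tryCatch(classify_stop_codon(s, adj),
                              error = function(e) NA_character_)
      )
    }
  )
  tab$start_codon <- meta$start_codon
  tab$stop_class <- meta$stop_class
  tab[, c("name", "class", "start", "stop", "strand", "start_codon",
          "stop_class", "anticodon", "support", "n_placements",
          "mean_identity")]
}

#' Scan a circular genome for open reading frames
#'
#' Finds all maximal open reading frames on both strands, initiating at ATG
#' or GTG and terminating at a vertebrate mitochondrial stop codon (TAA, TAG,
#' AGA, AGG), reading through the origin of the circular molecule. An ORF is
#' maximal when it starts at the first start codon following the previous
#' in-frame stop. Reported lengths include the stop codon.
#'
#' @param genome Genome sequence.
#' @param code Genetic code from [mito_genetic_code()].
#' @param min_length Minimum ORF length in nucleotides (default 150).
#' @param both_strands Scan the L strand too (default TRUE).
#' @param circular Read through the origin (default TRUE).
#' @return Tibble sorted by start: `start`, `stop` (H-strand, 1-based
#'   inclusive, `stop < start` = wraps the origin), `strand`, `start_codon`,
#'   `length`.
#' @export
scan_orfs <- function(genome, code = mito_genetic_code(), min_length = 150L,
                      both_strands = TRUE, circular = TRUE) {
  genome <- as_genome_seq(genome)
  L <- nchar(genome)
  strands <- if (both_strands) c("H", "L") else "H"
  out <- list()
  for (s in strands) {
    seq_s <- if (s == "L") revcomp(genome) else genome
    scan_seq <- if (circular) paste0(seq_s, seq_s) else seq_s
    n_cod_total <- nchar(scan_seq) %/% 3L
    for (frame in 0:2) {
      offset <- frame
      n_cod <- (nchar(scan_seq) - offset) %/% 3L
      if (n_cod < 2L) next
      pos <- offset + 3L * (seq_len(n_cod) - 1L) + 1L
      codons <- substring(scan_seq, pos, pos + 2L)
      is_stop <- codons %in% code$stop_codons
      is_start <- codons %in% code$start_codons
      stop_idx <- which(is_stop)
      prev_stop <- 0L
      for (si in stop_idx) {
        starts <- which(is_start[(prev_stop + 1L):si])
        if (length(starts)) {
          st <- prev_stop + starts[1L]
          orf_start <- pos[st]
          orf_stop <- pos[si] + 2L
          len <- orf_stop - orf_start + 1L
          if (len >= min_length && len <= L && orf_start <= L) {
            # canonical circular coordinates on this strand's sequence
            a <- orf_start
            b <- ((orf_stop - 1L) %% L) + 1L
            if (s == "H") {
              h_start <- a; h_stop <- b
            } else {
              h_start <- L - b + 1L; h_stop <- L - a + 1L
            }
            out[[length(out) + 1L]] <- tibble(
              start = h_start, stop = h_stop, strand = s,
              start_codon = codons[st], length = len
            )
          }
        }
        prev_stop <- si
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(0), stop = integer(0), strand = character(0),
                  start_codon = character(0), length = integer(0)))
  }
  res <- dplyr::distinct(dplyr::bind_rows(out))
  dplyr::arrange(res, .data$start, .data$stop)
}
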