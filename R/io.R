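#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return A tibble with columns `taxon` (full description line) and
#'   `sequence` (uppercased). An empty file yields a zero-row tibble with a
#'   warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warn(paste0("empty FASTA file: ", path))
    return(tibble(taxon = character(0), sequence = character(0)))
  }
  tibble(taxon = names(set), sequence = unname(toupper(as.character(set))))
}

#' Write sequences to a FASTA file
#'
#' @param records Tibble with columns `taxon` and `sequence`, or a named
#'   character vector.
#' @param path Output path. Sequences wrap at 70 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.data.frame(records)) {
    records <- tibble(taxon = names(records), sequence = unname(records))
  }
  set <- Biostrings::BStringSet(setNames(toupper(records$sequence), records$taxon))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

feature_classes <- c("CDS", "tRNA", "rRNA", "CR", "OL")

#' Read a mitogenome feature table
#'
#' Reads the tab-separated feature-table dialect with header columns
#' `name class start stop strand start_codon stop_class anticodon`
#' (published `size` and `intergenic` columns, when present, are kept for
#' validation). Files with a `##gff-version 3` header are dispatched to
#' [read_gff3()].
#'
#' @param path Path to a TSV feature table or GFF3 file.
#' @return Tibble with one row per feature, 1-based inclusive coordinates.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L)
  if (grepl("^##gff-version", first)) return(read_gff3(path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    class = readr::col_character(),
    start = readr::col_integer(),
    stop = readr::col_integer(),
    strand = readr::col_character(),
    .default = readr::col_guess()
  ))
  need <- c("name", "class", "start", "stop", "strand")
  if (!all(need %in% names(tab))) {
    abort(paste0("feature table lacks required columns: ",
                 paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  for (col in c("start_codon", "stop_class", "anticodon")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
    tab[[col]] <- as.character(tab[[col]])
    tab[[col]][!is.na(tab[[col]]) & tab[[col]] == ""] <- NA_character_
  }
  bad_class <- which(!tab$class %in% feature_classes)
  if (length(bad_class)) {
    abort(paste0("row ", bad_class[1L], " (", tab$name[bad_class[1L]],
                 "): unknown feature class `", tab$class[bad_class[1L]], "`"))
  }
  bad_strand <- which(!tab$strand %in% c("H", "L"))
  if (length(bad_strand)) {
    abort(paste0("row ", bad_strand[1L], " (", tab$name[bad_strand[1L]],
                 "): strand must be H or L"))
  }
  if (anyNA(tab$start) || anyNA(tab$stop) || any(tab$start < 1L) || any(tab$stop < 1L)) {
    abort("malformed coordinates in feature table")
  }
  tab
}

#' Write a feature table to TSV
#'
#' @param features Feature table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("name", "class", "start", "stop", "strand",
            "start_codon", "stop_class", "anticodon")
  extra <- intersect(c("size", "intergenic"), names(features))
  out <- features[, c(cols[cols %in% names(features)], extra)]
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

gff3_type_map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   CR = "D_loop", OL = "rep_origin")

#' Read features from GFF3
#'
#' Accepts GFF3 with feature types `CDS`, `tRNA`, `rRNA`, `D_loop` and
#' `rep_origin` (mapped to classes CDS/tRNA/rRNA/CR/OL). Uses rtracklayer.
#'
#' @param path Path to a GFF3 file.
#' @return Feature table tibble (1-based inclusive coordinates, as in GFF3).
#' @export
read_gff3 <- function(path) {
  rlang::check_installed("rtracklayer")
  gr <- rtracklayer::import(path, format = "gff3")
  cls_map <- setNames(names(gff3_type_map), gff3_type_map)
  type <- as.character(gr$type)
  keep <- type %in% names(cls_map)
  gr <- gr[keep]
  type <- type[keep]
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  tibble(
    name = nm,
    class = unname(cls_map[type]),
    start = as.integer(GenomicRanges::start(gr)),
    stop = as.integer(GenomicRanges::end(gr)),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "L", "H"),
    start_codon = NA_character_,
    stop_class = NA_character_,
    anticodon = NA_character_
  )
}

#' Write a feature table as GFF3
#'
#' @param features Feature table tibble.
#' @param path Output path.
#' @param seqid Sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqid = "mitogenome") {
  rlang::check_installed(c("rtracklayer", "GenomicRanges", "IRanges"))
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(start = features$start, end = features$stop),
    strand = ifelse(features$strand == "L", "-", "+")
  )
  gr$source <- "mitocomp"
  gr$type <- unname(gff3_type_map[features$class])
  gr$phase <- ifelse(features$class == "CDS", 0L, NA_integer_)
  gr$ID <- features$name
  gr$Name <- features$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a phylogenetic tree in newick format
#'
#' Trees are consumed, never inferred: simulation and rate analyses take the
#' topology and branch lengths as given.
#'
#' @param path Path to a newick file (single tree).
#' @param require_lengths Error if branch lengths are missing (they are
#'   required for simulation use, where they are expected substitutions per
#'   site on the reference partition).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, require_lengths = TRUE) {
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) abort(paste0("cannot parse newick file: ", path))
  if (require_lengths && is.null(tree$edge.length)) {
    abort("tree has no branch lengths (required)")
  }
  tree
}

#' Read a directory of per-gene alignments
#'
#' Loads one aligned FASTA per gene (file name = gene label) into the named
#' list consumed by [rate_table()]. This is the entry point for analysing an
#' externally aligned multi-genome data set.
#'
#' @param path Directory containing `.fa`/`.fasta` alignment files.
#' @return Named list of alignments (named character vectors keyed by taxon).
#' @export
read_gene_alignments <- function(path) {
  if (!dir.exists(path)) {
    abort(paste0("alignment directory not found: ", path,
                 " (expected one aligned FASTA per gene)"))
  }
  files <- list.files(path, pattern = "\\.(fa|fasta|fna|aln)$", full.names = TRUE)
  if (length(files) == 0L) abort(paste0("no alignment FASTA files in ", path))
  alns <- lapply(files, function(f) {
    r <- read_fasta(f)
    setNames(r$sequence, r$taxon)
  })
  names(alns) <- sub("\\.(fa|fasta|fna|aln)$", "", basename(files))
  alns
}

#' The published control-region motif table
#'
#' Termination-associated sequence (TAS), conserved sequence blocks (CSB-F,
#' CSB-E, CSB1-3), the heavy-strand replication origin (OH) and the three
#' D-loop domain spans for the two study species, with positions relative to
#' the control-region start.
#'
#' @return Tibble with columns `species`, `item`, `sequence`, `start`, `end`.
#' @export
dloop_motif_table <- function() {
  path <- system.file("extdata", "dloop_motifs.tsv", package = "mitocomp",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    item = readr::col_character(),
    sequence = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer()
  ))
}
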