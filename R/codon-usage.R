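#' Count sense codons in coding sequences
#'
#' Counts in-frame codons from position 1 over a set of coding sequences
#' (e.g. all protein-coding genes of one genome, already in coding
#' orientation). Stop codons, incomplete terminal codons (as left by
#' truncated TA+/T++ stops) and codons containing `N` or a gap are excluded.
#'
#' @param cds_list Character vector (or list) of CDS nucleotide strings.
#' @param code Genetic code from [mito_genetic_code()].
#' @return Named integer vector of counts over the 60 sense codons
#'   (alphabetical codon order).
#' @export
#' @examples
#' count_codons("ATGGCCGCCTAA")[c("ATG", "GCC")]
count_codons <- function(cds_list, code = mito_genetic_code()) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  codons <- unlist(lapply(cds_list, split_codons), use.names = FALSE)
  codons <- codons[codons %in% code$sense_codons]
  counts <- table(factor(codons, levels = code$sense_codons))
  setNames(as.integer(counts), code$sense_codons)
}

#' Normalize codon counts to uniform-usage units
#'
#' Scales counts so that a uniformly used codon scores 1 (one observation per
#' 60 codons): `value = count / total * 60`. The mean over the 60 sense
#' codons is exactly 1 for every profile, which makes deviations readable as
#' factors above/below uniform expectation.
#'
#' @param counts Named count vector from [count_codons()].
#' @return Named numeric vector over the 60 sense codons.
#' @export
normalize_usage <- function(counts) {
  total <- sum(counts)
  if (total == 0) abort("empty usage row: no countable codon")
  counts / total * length(counts)
}

#' Codon-usage matrix for a set of taxa
#'
#' Builds the taxa x 60-sense-codon matrix of normalized usage from per-taxon
#' coding sequences (gene-wise rows are obtained by passing a single gene per
#' taxon; merged rows by passing all genes).
#'
#' @param cds Tibble with columns `taxon` and `sequence` (one row per CDS,
#'   coding orientation), or a named list taxon -> character vector of CDS.
#' @param code Genetic code.
#' @return Tibble of class `mito_usage`: column `taxon` plus one column per
#'   sense codon.
#' @export
codon_usage_matrix <- function(cds, code = mito_genetic_code()) {
  if (is.data.frame(cds)) {
    cds <- split(cds$sequence, cds$taxon)
  }
  rows <- purrr::imap(cds, function(seqs, taxon) {
    vals <- normalize_usage(count_codons(seqs, code))
    dplyr::bind_cols(tibble(taxon = taxon), as_tibble(as.list(vals)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mito_usage", class(out))
  out
}

usage_values <- function(usage) {
  m <- as.matrix(usage[, setdiff(names(usage), "taxon")])
  rownames(m) <- usage$taxon
  m
}

#' Distance between two codon-usage profiles
#'
#' @param row_a,row_b Normalized usage vectors (same codon order).
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return Single distance value.
#' @export
usage_distance <- function(row_a, row_b, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (length(row_a) != length(row_b)) abort("profiles differ in length")
  d <- row_a - row_b
  if (metric == "euclidean") sqrt(sum(d^2)) else sum(abs(d))
}

#' Distance matrix between usage profiles
#'
#' @param usage A `mito_usage` tibble from [codon_usage_matrix()].
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return A symmetric `matrix` of pairwise distances.
#' @export
usage_dist_matrix <- function(usage, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  as.matrix(stats::dist(usage_values(usage), method = metric))
}

lw_params <- function(method, ni, nj) {
  switch(method,
    average = c(ai = ni / (ni + nj), aj = nj / (ni + nj), b = 0, g = 0),
    single = c(ai = 0.5, aj = 0.5, b = 0, g = -0.5),
    complete = c(ai = 0.5, aj = 0.5, b = 0, g = 0.5),
    median = c(ai = 0.5, aj = 0.5, b = -0.25, g = 0)
  )
}

#' Agglomerative clustering via the Lance-Williams recurrence
#'
#' Hierarchical clustering of a distance matrix using the Lance-Williams
#' update formula, which expresses average (UPGMA), single, complete and
#' median linkage as one recurrence over merged-cluster distances. At every
#' step the pair at minimal distance is merged (ties resolved toward the
#' smallest cluster-label order, so the result is deterministic). Heights are
#' the merge distances; under median linkage they may decrease (dendrogram
#' inversions), which is reported via a warning rather than suppressed.
#'
#' @param dist Symmetric distance matrix with zero diagonal (or a `dist`).
#' @param method `"average"` (default), `"median"`, `"single"`, `"complete"`.
#' @return An object of class `hclust` (plottable, convertible with
#'   [ape::as.phylo()]).
#' @export
#' @examples
#' m <- usage_dist_matrix(codon_usage_matrix(
#'   c(a = "ATGGCC", b = "ATGGCG", c = "TTAGCC")))
#' lance_williams_cluster(m)
lance_williams_cluster <- function(dist,
                                   method = c("average", "median", "single",
                                              "complete")) {
  method <- match.arg(method)
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    abort("distance input must be a square matrix or dist object")
  }
  if (max(abs(dist - t(dist))) > 1e-12 || any(diag(dist) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  n <- nrow(dist)
  if (n < 2L) abort("need at least two items to cluster")
  labels <- rownames(dist) %||% as.character(seq_len(n))
  D <- dist
  active <- seq_len(n)          # column indices into D of live clusters
  code <- -seq_len(n)           # hclust encoding: -leaf or +merge-row
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    # first pair attaining the minimum, scanning in label order
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d_ij <- D[active[i], active[j]]
        if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    ci <- active[i]; cj <- active[j]
    pair <- code[c(i, j)]
    merge[step, ] <- if (all(pair < 0L)) {
      -sort(-pair)                         # singletons by original label order
    } else if (all(pair > 0L)) {
      sort(pair)
    } else {
      c(pair[pair < 0L], pair[pair > 0L])  # singleton before merged cluster
    }
    height[step] <- best_d
    p <- lw_params(method, sizes[ci], sizes[cj])
    others <- active[-c(i, j)]
    if (length(others)) {
      d_new <- p["ai"] * D[ci, others] + p["aj"] * D[cj, others] +
        p["b"] * best_d + p["g"] * abs(D[ci, others] - D[cj, others])
      D[ci, others] <- d_new
      D[others, ci] <- d_new
    }
    sizes[ci] <- sizes[ci] + sizes[cj]
    code[i] <- step
    active <- active[-j]
    code <- code[-j]
  }
  if (any(diff(height) < -1e-12)) {
    warn(paste0("dendrogram inversions: heights decrease at merge(s) ",
                paste(which(diff(height) < -1e-12) + 1L, collapse = ", ")))
  }
  hc <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = paste0("lance-williams/", method),
         call = match.call(), dist.method = "user"),
    class = "hclust"
  )
  hc
}

# Leaf order for plotting: left-to-right expansion of the merge matrix.
hclust_order <- function(merge) {
  expand <- function(i) {
    if (i < 0L) return(-i)
    c(expand(merge[i, 1L]), expand(merge[i, 2L]))
  }
  expand(nrow(merge))
}

#' Serialize a dendrogram as newick
#'
#' @param hc An `hclust` object (e.g. from [lance_williams_cluster()]).
#' @param path Optional output file; when NULL the newick string is returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
cluster_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Codon-usage heatmap
#'
#' @param object A `mito_usage` tibble.
#' @param cluster_taxa Order taxa by average-linkage Lance-Williams
#'   clustering of the usage profiles (default TRUE).
#' @param ... Unused.
#' @return A ggplot tile map: taxa x codons, fill = normalized usage
#'   (1 = uniform expectation).
#' @export
autoplot.mito_usage <- function(object, cluster_taxa = TRUE, ...) {
  long <- tidyr::pivot_longer(object, -"taxon", names_to = "codon",
                              values_to = "usage")
  if (cluster_taxa && nrow(object) > 2L) {
    hc <- lance_williams_cluster(usage_dist_matrix(object))
    long$taxon <- factor(long$taxon, levels = hc$labels[hc$order])
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$codon, y = .data$taxon,
                                     fill = .data$usage)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue3", mid = "green4",
                                  high = "red3") +
    ggplot2::labs(x = NULL, y = NULL, fill = "usage\n(1 = uniform)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5))
}
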