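canonical_pairs <- function(d) {
  dplyr::mutate(
    d,
    key_a = pmin(.data$taxon_a, .data$taxon_b),
    key_b = pmax(.data$taxon_a, .data$taxon_b)
  )
}

#' Distance-regression (DR) relative rate
#'
#' The relative substitution rate of a gene is estimated as the slope of a
#' linear least-squares regression of its distances on the distances of a
#' reference gene over the same taxa (or taxon pairs). Because both axes are
#' raw gap-weighted p-distances, insertions and deletions contribute to the
#' estimate, which model-based rate estimators cannot do. A zero reference
#' distance implies a zero gene distance under a rate-ratio reading, so the
#' regression is through the origin by default; a free intercept is available.
#'
#' @param y Distance table of the gene of interest ([gene_distances()]).
#' @param x Distance table of the reference gene, same mode.
#' @param through_origin Logical; default TRUE (slope = sum(xy)/sum(x^2)).
#' @return One-row tibble: `slope`, `intercept` (0 when through the origin),
#'   `r_squared`, `n_points`.
#' @export
#' @examples
#' a <- c(t1 = "AAAA", t2 = "AATA", t3 = "TTAA")
#' relative_rate_regression(gene_distances(a), gene_distances(a))  # slope 1
relative_rate_regression <- function(y, x, through_origin = TRUE) {
  keys <- c("key_a", "key_b")
  merged <- dplyr::inner_join(
    dplyr::select(canonical_pairs(x), dplyr::all_of(keys), x = "distance"),
    dplyr::select(canonical_pairs(y), dplyr::all_of(keys), y = "distance"),
    by = keys
  )
  n <- nrow(merged)
  if (n < 3L) abort("insufficient data: fewer than 3 shared taxa/pairs")
  xs <- merged$x; ys <- merged$y
  if (through_origin) {
    sxx <- sum(xs^2)
    if (sxx == 0) abort("degenerate regression: reference distances all zero")
    slope <- sum(xs * ys) / sxx
    intercept <- 0
    ss_tot <- sum(ys^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum((ys - slope * xs)^2) / ss_tot
  } else {
    if (stats::var(xs) == 0) abort("degenerate regression: zero variance in reference")
    slope <- stats::cov(xs, ys) / stats::var(xs)
    intercept <- mean(ys) - slope * mean(xs)
    ss_tot <- sum((ys - mean(ys))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum((ys - intercept - slope * xs)^2) / ss_tot
  }
  tibble(slope = slope, intercept = intercept, r_squared = r2, n_points = n)
}

trim_to_frame <- function(aln) {
  aln <- as_alignment(aln)
  L <- nchar(aln[[1L]])
  L3 <- (L %/% 3L) * 3L
  if (L3 == L) return(aln)
  setNames(substr(aln, 1L, L3), names(aln))
}

# Concatenate selected columns of several alignments (same taxa) into one.
pool_columns <- function(alignments, site_lists) {
  taxa <- names(alignments[[1L]])
  pieces <- purrr::map2(alignments, site_lists, function(aln, sites) {
    if (length(sites) == 0L) return(setNames(rep("", length(taxa)), taxa))
    m <- alignment_matrix(aln)[taxa, sites, drop = FALSE]
    matrix_alignment(m)
  })
  setNames(
    vapply(taxa, function(t) paste(vapply(pieces, `[[`, character(1), t),
                                   collapse = ""), character(1)),
    taxa
  )
}

#' Relative-rate table across all mitogenome partitions
#'
#' Runs the distance-regression estimator for every gene, for the three
#' codon-position partitions of every protein-coding gene, for the
#' fourfold-degenerate third positions pooled over all protein-coding genes
#' (an approximation of the neutral mutation rate), and for the control
#' region both raw and gap-column-filtered. All taxa are restricted to the
#' intersection across alignments; outgroups should be removed by the caller.
#'
#' @param alignments Named list of gene alignments (names = gene labels).
#' @param reference Reference gene label (default `"12S"`; the reference's
#'   own slope is 1 by construction).
#' @param classes Optional named character vector gene -> feature class;
#'   inferred from conventional gene names when NULL.
#' @param mode Distance mode, `"pairwise"` (default) or `"vs_consensus"`.
#' @param gap_mode Passed to [p_distance()] (default `"full_weight"`).
#' @param through_origin Passed to [relative_rate_regression()].
#' @param cr_gap_fraction Gap-fraction threshold used for the filtered
#'   control-region partition (default 0 = all gap-containing columns out).
#' @param code Genetic code for the codon partitions.
#' @return Tibble of class `mito_rate_table`: `partition`, `gene`, `group`
#'   (one of CDS/rRNA/tRNA/CR/1st/2nd/3rd/4-fold), `slope`, `intercept`,
#'   `r_squared`, `n_points`, with a `group_means` attribute (see
#'   [glance.mito_rate_table()]).
#' @export
rate_table <- function(alignments, reference = "12S", classes = NULL,
                       mode = c("pairwise", "vs_consensus"),
                       gap_mode = c("full_weight", "ignore"),
                       through_origin = TRUE, cr_gap_fraction = 0,
                       code = mito_genetic_code()) {
  mode <- match.arg(mode)
  gap_mode <- match.arg(gap_mode)
  if (!reference %in% names(alignments)) {
    abort(paste0("reference gene `", reference, "` not among the alignments"))
  }
  alignments <- purrr::map(alignments, as_alignment)
  classes <- classes %||%
    setNames(infer_feature_class(names(alignments)), names(alignments))
  taxa <- Reduce(intersect, purrr::map(alignments, names))
  if (length(taxa) < 3L) abort("fewer than 3 taxa shared across alignments")
  alignments <- purrr::map(alignments, function(a) a[taxa])

  dist_of <- function(aln) gene_distances(aln, mode = mode, gap_mode = gap_mode)
  x <- dist_of(alignments[[reference]])
  fit <- function(aln) {
    relative_rate_regression(dist_of(aln), x, through_origin = through_origin)
  }
  safe_row <- function(partition, gene, group, aln) {
    est <- tryCatch(fit(aln), error = function(e) {
      warn(paste0("skipping partition ", partition, ": ", conditionMessage(e)))
      NULL
    })
    if (is.null(est)) return(NULL)
    dplyr::bind_cols(tibble(partition = partition, gene = gene, group = group), est)
  }

  rows <- list()
  for (g in names(alignments)) {
    rows[[g]] <- safe_row(g, g, classes[[g]], alignments[[g]])
  }
  cds_genes <- names(alignments)[classes[names(alignments)] == "CDS"]
  pos_groups <- c(pos1 = "1st", pos2 = "2nd", pos3 = "3rd")
  for (g in cds_genes) {
    framed <- trim_to_frame(alignments[[g]])
    parts <- codon_position_split(framed)
    for (p in names(parts)) {
      id <- paste0(g, ":", p)
      rows[[id]] <- safe_row(id, g, pos_groups[[p]], parts[[p]])
    }
  }
  if (length(cds_genes)) {
    framed <- purrr::map(alignments[cds_genes], trim_to_frame)
    sites <- purrr::map(framed, fourfold_degenerate_sites, code = code)
    pooled <- pool_columns(framed, sites)
    if (nchar(pooled[[1L]]) > 0L) {
      rows[["fourfold"]] <- safe_row("fourfold", NA_character_, "4-fold", pooled)
    }
  }
  cr_genes <- names(alignments)[classes[names(alignments)] == "CR"]
  for (g in cr_genes) {
    filtered <- tryCatch(gap_column_filter(alignments[[g]], cr_gap_fraction),
                         error = function(e) NULL)
    if (!is.null(filtered)) {
      id <- paste0(g, ":gapfiltered")
      rows[[id]] <- safe_row(id, g, "CR", filtered)
    }
  }

  out <- dplyr::bind_rows(rows)
  means <- out |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_slope = mean(.data$slope), n_partitions = dplyr::n(),
                     .groups = "drop")
  class(out) <- c("mito_rate_table", class(out))
  attr(out, "group_means") <- means
  attr(out, "reference") <- reference
  attr(out, "mode") <- mode
  out
}

#' @export
tidy.mito_rate_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mito_rate_table")
  as_tibble(out)
}

#' Group-mean relative rates
#'
#' @param x A `mito_rate_table` from [rate_table()].
#' @param ... Unused.
#' @return Tibble of per-group mean slopes (CDS, rRNA, tRNA, CR, 1st, 2nd,
#'   3rd, 4-fold), mirroring the horizontal group-mean lines of a
#'   relative-rate bar chart.
#' @export
glance.mito_rate_table <- function(x, ...) {
  attr(x, "group_means")
}

#' Bar chart of relative rates
#'
#' @param object A `mito_rate_table`.
#' @param ... Unused.
#' @return A ggplot: one bar per partition, coloured by group, dashed
#'   horizontal line at the per-group mean, solid line at the reference
#'   slope 1.
#' @export
autoplot.mito_rate_table <- function(object, ...) {
  df <- tidy(object)
  df$partition <- factor(df$partition, levels = df$partition[order(df$group, df$partition)])
  means <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$partition, y = .data$slope,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.3) +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$mean_slope,
                                     colour = .data$group),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "relative rate (slope vs reference)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}
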