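#' Amino-acid accessibility scale
#'
#' Per-residue propensity values used for sliding-window profiles. The
#' default `"janin"` scale is Janin's (1979) accessibility table (molar
#' percentage of residues found accessible in globular protein structures);
#' higher values mean the residue type is more often solvent-exposed.
#'
#' @param name Scale name; currently `"janin"`.
#' @return Named numeric vector over the 20 standard amino acids (one-letter
#'   codes).
#' @export
aa_scale <- function(name = "janin") {
  scales <- list(
    janin = c(
      A = 6.6, R = 4.5, N = 6.7, D = 7.7, C = 0.9, Q = 5.2, E = 5.7,
      G = 6.7, H = 2.5, I = 2.8, L = 4.8, K = 10.3, M = 1.0, F = 2.4,
      P = 4.8, S = 9.4, T = 7.0, W = 1.4, Y = 5.1, V = 4.5
    )
  )
  if (!name %in% names(scales)) abort(paste0("unknown scale: ", name))
  scales[[name]]
}

window_means <- function(vals, window, edge_mode) {
  n <- length(vals)
  h <- (window - 1L) %/% 2L
  positions <- if (edge_mode == "interior_only") {
    if (n < window) integer(0) else (h + 1L):(n - h)
  } else seq_len(n)
  scores <- vapply(positions, function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    w <- vals[lo:hi]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  list(positions = positions, scores = scores)
}

#' Sliding-window amino-acid-scale profile
#'
#' Scores each residue position as the unweighted mean of the scale values in
#' a window centred on it. With the default `edge_mode =
#' "full_weight_truncated"` (the fully-weighted-edges convention) windows at
#' the sequence ends truncate to the available residues, every included
#' residue weighing 1; `"interior_only"` omits positions without a complete
#' window. Residues read `X` are skipped with the window mean renormalized
#' over the remaining residues (reported via a warning); any other residue
#' absent from the scale is an error.
#'
#' @param proteins A single amino-acid string, or a tibble with columns
#'   `taxon` and `sequence` (e.g. from [read_fasta()]).
#' @param scale Named per-residue values (default [aa_scale()] `"janin"`).
#' @param window Odd window size >= 1 (default 9).
#' @param edge_mode `"full_weight_truncated"` (default) or `"interior_only"`.
#' @return Tibble of class `mito_profile`: `taxon`, `position`, `residue`,
#'   `score`.
#' @export
#' @examples
#' windowed_profile("MFTTKEELS", window = 3)
windowed_profile <- function(proteins, scale = aa_scale("janin"), window = 9L,
                             edge_mode = c("full_weight_truncated",
                                           "interior_only")) {
  edge_mode <- match.arg(edge_mode)
  if (window < 1L || window %% 2L == 0L) abort("window must be odd and >= 1")
  if (!is.data.frame(proteins)) {
    proteins <- tibble(taxon = names(proteins) %||% "protein",
                       sequence = unname(proteins))
  }
  out <- purrr::pmap_dfr(
    list(proteins$taxon, proteins$sequence),
    function(taxon, sequence) {
      chars <- seq_chars(toupper(gsub("[[:space:]*]", "", sequence)))
      if (length(chars) == 0L) abort(paste0("empty protein for ", taxon))
      unknown <- setdiff(unique(chars), c(names(scale), "X"))
      if (length(unknown)) {
        abort(paste0("residue(s) absent from scale: ",
                     paste(unknown, collapse = ", "), " in ", taxon))
      }
      vals <- unname(scale[chars])  # X -> NA
      if (any(chars == "X")) {
        warn(paste0(sum(chars == "X"), " X residue(s) in ", taxon,
                    " skipped; window means renormalized"))
      }
      wm <- window_means(vals, window, edge_mode)
      tibble(taxon = taxon, position = wm$positions,
             residue = chars[wm$positions], score = wm$scores)
    }
  )
  class(out) <- c("mito_profile", class(out))
  out
}

#' Min-max normalization of profile scores to \[0, 1\]
#'
#' Rescales scores so the minimum maps to 0 and the maximum to 1. Applied to
#' a profile tibble the normalization is per taxon by default (each profile
#' spans the full (0,1) range); `per_taxon = FALSE` normalizes jointly across
#' all taxa for multi-sequence panels. A constant profile has no extent to
#' normalize and is an error.
#'
#' @param scores Numeric score vector, or a profile tibble from
#'   [windowed_profile()].
#' @param per_taxon Logical (tibble input only); default TRUE.
#' @return Normalized numeric vector, or the profile tibble with an added
#'   `score_norm` column.
#' @export
#' @examples
#' normalize_profile(c(2, 4, 6))
normalize_profile <- function(scores, per_taxon = TRUE) {
  norm1 <- function(s) {
    rng <- range(s, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0) {
      abort("degenerate profile: scores are constant, nothing to normalize")
    }
    (s - rng[1L]) / diff(rng)
  }
  if (is.data.frame(scores)) {
    if (per_taxon) {
      scores <- dplyr::mutate(dplyr::group_by(scores, .data$taxon),
                              score_norm = norm1(.data$score))
      return(dplyr::ungroup(scores))
    }
    scores$score_norm <- norm1(scores$score)
    return(scores)
  }
  norm1(scores)
}

#' Accessibility profile plot
#'
#' @param object A `mito_profile` tibble.
#' @param normalized Plot min-max normalized scores (default TRUE).
#' @param ... Unused.
#' @return A ggplot of score against residue position, one line per taxon.
#' @export
autoplot.mito_profile <- function(object, normalized = TRUE, ...) {
  df <- if (normalized) normalize_profile(object) else
    dplyr::mutate(object, score_norm = .data$score)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score_norm,
                                   colour = .data$taxon)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue position",
                  y = if (normalized) "accessibility (min-max normalized)"
                      else "accessibility score") +
    ggplot2::theme_minimal()
}
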