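# Shared generators for property-style tests. Everything is built in code at
# test time; seeds are fixed inside each test block.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_alignment <- function(n_taxa, len, gap_prob = 0, n_prob = 0) {
  alphabet <- c("A", "C", "G", "T")
  rows <- vapply(seq_len(n_taxa), function(i) {
    chars <- sample(alphabet, len, replace = TRUE)
    if (gap_prob > 0) {
      gaps <- runif(len) < gap_prob
      chars[gaps] <- "-"
    }
    if (n_prob > 0) {
      ns <- runif(len) < n_prob
      chars[ns] <- "N"
    }
    paste(chars, collapse = "")
  }, character(1))
  setNames(rows, paste0("t", seq_len(n_taxa)))
}

# Independent column-counting oracle for the gap-weighted p-distance.
p_distance_oracle <- function(a, b, gap_mode = "full_weight") {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  diffs <- 0L; counted <- 0L
  for (i in seq_along(a)) {
    both_gap <- a[i] == "-" && b[i] == "-"
    any_gap <- a[i] == "-" || b[i] == "-"
    if (gap_mode == "full_weight" && both_gap) next
    if (gap_mode == "ignore" && any_gap) next
    counted <- counted + 1L
    match <- a[i] == b[i] && a[i] %in% c("A", "C", "G", "T")
    if (!match) diffs <- diffs + 1L
  }
  diffs / counted
}

# Star tree used for the rate-recovery simulations: 20 taxa, branch lengths
# calibrated under JC so the expected pairwise p-distance on the reference
# partition is 0.10 (2b solves p = 3/4 (1 - exp(-4 t / 3))).
dr_recovery_tree <- function() {
  p <- 0.10
  t_pair <- -3 / 4 * log(1 - 4 * p / 3)
  tree <- ape::stree(20, type = "star")
  tree$tip.label <- paste0("t", 1:20)
  tree$edge.length <- rep(t_pair / 2, 20)
  tree
}

dr_recovery_partitions <- function() {
  tibble::tibble(
    label = c("12S", "g025", "g05", "g1", "g2", "g4"),
    length = c(943L, rep(900L, 5)),
    class = "rRNA", strand = "H",
    rate_multiplier = c(1, 0.25, 0.5, 1, 2, 4)
  )
}

# One recovery replicate: estimated DR slopes for the five test partitions.
dr_recovery_slopes <- function(seed) {
  cfg <- sim_config(dr_recovery_tree(), dr_recovery_partitions(),
                    model = "JC", seed = seed)
  sim <- simulate_alignment(cfg)
  x <- gene_distances(sim$alignments[["12S"]], mode = "vs_consensus")
  vapply(c("g025", "g05", "g1", "g2", "g4"), function(g) {
    y <- gene_distances(sim$alignments[[g]], mode = "vs_consensus")
    relative_rate_regression(y, x)$slope
  }, numeric(1))
}
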