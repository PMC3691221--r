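test_that("count_codons counts in-frame sense codons only", {
  counts <- count_codons("ATGGCCGCCTAA")
  expect_equal(unname(counts["ATG"]), 1L)
  expect_equal(unname(counts["GCC"]), 2L)
  expect_equal(sum(counts), 3L)  # TAA (stop) not counted
  expect_false("TAA" %in% names(counts))

  counts2 <- count_codons("ATGGT")  # trailing incomplete codon ignored
  expect_equal(sum(counts2), 1L)
  expect_equal(unname(counts2["ATG"]), 1L)

  # codons containing N or gaps are excluded
  counts3 <- count_codons("ATGN--TTT")
  expect_equal(sum(counts3), 2L)
})

test_that("count_codons agrees with the simulator's own codon tally", {
  tree <- ape::read.tree(text = "(A:0.02,B:0.02,C:0.02);")
  parts <- tibble::tibble(label = c("cds1", "cds2"), length = c(300L, 450L),
                          class = "CDS", strand = "H", rate_multiplier = 1)
  set <- simulate_mitogenome_set(sim_config(tree, parts, seed = 55))
  for (tx in c("A", "B", "C")) {
    cds <- dplyr::filter(set$features, taxon == tx, class == "CDS")
    g <- set$genomes$sequence[set$genomes$taxon == tx]
    seqs <- extract_feature_seqs(g, cds)$sequence
    expect_equal(count_codons(seqs), set$truth$codon_tally[[tx]])
  }
})

test_that("normalize_usage puts uniform usage at exactly 1", {
  code <- mito_genetic_code()
  uniform <- setNames(rep(1L, 60), code$sense_codons)
  expect_true(all(normalize_usage(uniform) == 1))

  solo <- setNames(c(60L, rep(0L, 59)), code$sense_codons)
  ns <- normalize_usage(solo)
  expect_equal(unname(ns[1]), 60)
  expect_true(all(ns[-1] == 0))

  set.seed(108)
  for (i in 1:20) {
    counts <- setNames(rpois(60, 5), code$sense_codons)
    counts[1] <- counts[1] + 1L  # guard against all-zero draws
    expect_equal(mean(normalize_usage(counts)), 1, tolerance = 1e-12)
  }
  expect_error(normalize_usage(setNames(rep(0L, 60), code$sense_codons)), "empty")
})

test_that("codon_usage_matrix rows all have mean 1", {
  set.seed(109)
  cds <- tibble::tibble(
    taxon = rep(c("a", "b", "c"), each = 2),
    sequence = replicate(6, paste0("ATG", random_seq(297)))
  )
  um <- codon_usage_matrix(cds)
  vals <- as.matrix(um[, -1])
  expect_equal(ncol(vals), 60L)
  expect_equal(unname(rowMeans(vals)), rep(1, 3), tolerance = 1e-12)
})

test_that("usage_distance matches the direct formula", {
  a <- c(1, 1, 1); b <- c(1, 3, 1)
  expect_equal(usage_distance(a, b), 2)
  expect_equal(usage_distance(a, a), 0)
  set.seed(110)
  for (i in 1:20) {
    x <- runif(60); y <- runif(60)
    expect_equal(usage_distance(x, y), sqrt(sum((x - y)^2)))
    expect_equal(usage_distance(x, y, "manhattan"), sum(abs(x - y)))
  }
})

test_that("lance_williams_cluster handles minimal and tied configurations", {
  m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- lance_williams_cluster(m2)
  expect_equal(hc2$height, 3)
  expect_equal(nrow(hc2$merge), 1L)

  # three equidistant items: first merge by label order, second at same height
  m3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3])); diag(m3) <- 0
  hc3 <- lance_williams_cluster(m3)
  expect_equal(hc3$merge[1, ], c(-1L, -2L))
  expect_equal(hc3$height, c(2, 2))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(lance_williams_cluster(bad), "symmetric")
})

test_that("average-linkage heights equal stats::hclust UPGMA to 1e-10", {
  set.seed(111)
  for (i in 1:50) {
    pts <- matrix(rnorm(8 * 4), 8)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(paste0("s", 1:8), paste0("s", 1:8))
    mine <- lance_williams_cluster(d, "average")
    ref <- stats::hclust(as.dist(d), method = "average")
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
    # same partitions at every merge height
    expect_equal(unname(cutree(mine, k = 3)[order(rownames(d))] |> table() |> sort()),
                 unname(cutree(ref, k = 3)[order(rownames(d))] |> table() |> sort()))
  }
})

test_that("single and complete linkage match their hclust counterparts", {
  set.seed(112)
  for (method in c("single", "complete")) {
    d <- as.matrix(dist(matrix(rnorm(7 * 3), 7)))
    dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
    mine <- lance_williams_cluster(d, method)
    ref <- stats::hclust(as.dist(d), method = method)
    expect_equal(sort(mine$height), sort(ref$height), tolerance = 1e-10)
  }
})

test_that("clustering is invariant to input label permutation", {
  set.seed(113)
  d <- as.matrix(dist(matrix(rnorm(6 * 5), 6)))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  ref <- lance_williams_cluster(d)
  ref_nwk <- cluster_newick(ref)
  for (i in 1:5) {
    perm <- sample.int(6)
    dp <- d[perm, perm]
    hc <- lance_williams_cluster(dp)
    expect_equal(sort(hc$height), sort(ref$height), tolerance = 1e-12)
    # identical tree up to relabeling: compare via topology distance
    t1 <- ape::as.phylo(ref); t2 <- ape::as.phylo(hc)
    expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  }
})

test_that("median linkage reports inversions instead of suppressing them", {
  # near-equilateral configuration: the merged pair's midpoint lies closer to
  # the third point than the first merge height
  d <- matrix(c(0, 2, 2.1,
                2, 0, 2.1,
                2.1, 2.1, 0), 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(lance_williams_cluster(d, "median"), "inversion")
})

test_that("sister taxa with shared codon-bias shifts cluster together", {
  tree <- ape::read.tree(text = paste0(
    "(((A:0.01,B:0.01):0.03,(C:0.01,D:0.01):0.03):0.01,",
    "((E:0.01,F:0.01):0.03,(G:0.01,H:0.01):0.03):0.01);"))
  parts <- tibble::tibble(label = c("cds1", "cds2"), length = c(900L, 900L),
                          class = "CDS", strand = "H", rate_multiplier = 1)
  bias <- tibble::tibble(taxon = LETTERS[1:8],
                         third_base = rep(c("A", "C", "G", "T"), each = 2),
                         strength = 0.5)
  pairs <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"))
  ok <- 0L
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(tree, parts, codon_bias = bias, seed = 7000 + r)
    sim <- simulate_alignment(cfg)
    cds <- tibble::tibble(
      taxon = rep(names(sim$alignments$cds1), 2),
      sequence = c(unname(sim$alignments$cds1), unname(sim$alignments$cds2))
    )
    hc <- lance_williams_cluster(usage_dist_matrix(codon_usage_matrix(cds)))
    phy <- ape::as.phylo(hc)
    if (all(vapply(pairs, function(p) ape::is.monophyletic(phy, p), logical(1)))) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("usage heatmap autoplot returns a ggplot", {
  set.seed(114)
  cds <- tibble::tibble(taxon = c("a", "b", "c"),
                        sequence = replicate(3, paste0("ATG", random_seq(300))))
  p <- autoplot(codon_usage_matrix(cds))
  expect_s3_class(p, "ggplot")
})
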