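small_parts <- function() {
  tibble::tibble(label = c("ref", "gene", "cr", "cds"),
                 length = c(300L, 300L, 200L, 300L),
                 class = c("rRNA", "rRNA", "CR", "CDS"),
                 strand = "H", rate_multiplier = c(1, 2, 3, 1))
}

test_that("identical config and seed reproduce outputs byte-identically", {
  tree <- ape::read.tree(text = "((A:0.02,B:0.02):0.01,(C:0.02,D:0.02):0.01);")
  cfg <- sim_config(tree, small_parts(), seed = 12, indel_rate = 0.2)
  s1 <- simulate_alignment(cfg)
  s2 <- simulate_alignment(cfg)
  expect_identical(s1$alignments, s2$alignments)
  g1 <- simulate_mitogenome_set(cfg)
  g2 <- simulate_mitogenome_set(cfg)
  expect_identical(g1$genomes, g2$genomes)
  expect_identical(g1$features, g2$features)
})

test_that("zero branch lengths and zero multipliers give invariant partitions", {
  tree <- ape::read.tree(text = "((A:0,B:0):0,(C:0,D:0):0);")
  cfg <- sim_config(tree, small_parts(), seed = 13, indel_rate = 0)
  sim <- simulate_alignment(cfg)
  for (aln in sim$alignments) {
    expect_equal(length(unique(unname(aln))), 1L)
  }
  d <- gene_distances(sim$alignments$gene)
  expect_true(all(d$distance == 0))

  parts0 <- small_parts()
  parts0$rate_multiplier[2] <- 0
  tree2 <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  sim2 <- simulate_alignment(sim_config(tree2, parts0, seed = 14, indel_rate = 0))
  expect_equal(length(unique(unname(sim2$alignments$gene))), 1L)
  expect_gt(max(gene_distances(sim2$alignments$ref)$distance), 0)
})

test_that("two-taxon JC distances match the closed form within Monte-Carlo error", {
  # p = 3/4 (1 - exp(-4t/3)) at total path length t = 0.05
  t_total <- 0.05
  expected <- 3 / 4 * (1 - exp(-4 * t_total / 3))
  tree <- ape::read.tree(text = "(A:0.025,B:0.025,C:0.0);")
  parts <- tibble::tibble(label = "ref", length = 500L, class = "rRNA",
                          strand = "H", rate_multiplier = 1)
  n_rep <- 200
  ps <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_alignment(sim_config(tree, parts, model = "JC", seed = 9000 + r))
    as.numeric(p_distance(sim$alignments$ref[["A"]], sim$alignments$ref[["B"]]))
  }, numeric(1))
  se <- sd(ps) / sqrt(n_rep)
  expect_lt(abs(mean(ps) - expected), 3 * se)
})

test_that("mean pairwise distance is non-decreasing in the rate multiplier", {
  tree <- dr_recovery_tree()
  sim <- simulate_alignment(sim_config(tree, dr_recovery_partitions(),
                                       model = "JC", seed = 31))
  mean_d <- vapply(c("g025", "g05", "g1", "g2", "g4"), function(g) {
    mean(gene_distances(sim$alignments[[g]])$distance)
  }, numeric(1))
  expect_true(all(diff(mean_d) > 0))
})

test_that("simulated CDS stay translatable with held start and stop codons", {
  tree <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  parts <- tibble::tibble(label = "cds", length = 300L, class = "CDS",
                          strand = "H", rate_multiplier = 2)
  sim <- simulate_alignment(sim_config(tree, parts, seed = 16))
  for (s in sim$alignments$cds) {
    expect_equal(substr(s, 1, 3), "ATG")
    prot <- translate_mito(s)
    expect_equal(nchar(prot), 300 / 3 - 1)  # stop is terminal, none internal
    expect_false(grepl("\\*", prot))
  }
})

test_that("round trip: translating an extracted simulated CDS matches its alignment row", {
  tree <- ape::read.tree(text = "(A:0.02,B:0.02,C:0.02);")
  parts <- tibble::tibble(label = c("cds1", "trn"), length = c(240L, 70L),
                          class = c("CDS", "tRNA"),
                          strand = c("L", "H"), rate_multiplier = 1)
  set <- simulate_mitogenome_set(sim_config(tree, parts, seed = 17))
  for (tx in c("A", "B", "C")) {
    f <- dplyr::filter(set$features, taxon == tx, name == "cds1")
    g <- set$genomes$sequence[set$genomes$taxon == tx]
    extracted <- extract_feature_seq(g, f$start, f$stop, f$strand)
    expect_equal(extracted, set$alignments$cds1[[tx]])
    expect_equal(translate_mito(extracted),
                 translate_mito(set$alignments$cds1[[tx]]))
  }
})

test_that("CR partitions come back aligned with consistent row lengths", {
  tree <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  parts <- tibble::tibble(label = "cr", length = 300L, class = "CR",
                          strand = "H", rate_multiplier = 2)
  sim <- simulate_alignment(sim_config(tree, parts, seed = 18, indel_rate = 0.3))
  aln <- sim$alignments$cr
  expect_length(unique(nchar(aln)), 1L)
  expect_true(any(grepl("-", aln, fixed = TRUE)))  # the indel process acted
  # degapped rows are what the genome carries
  set <- simulate_mitogenome_set(sim_config(tree, parts, seed = 18, indel_rate = 0.3))
  for (tx in names(aln)) {
    g <- set$genomes$sequence[set$genomes$taxon == tx]
    f <- dplyr::filter(set$features, taxon == tx)
    expect_equal(g, gsub("-", "", set$alignments$cr[[tx]], fixed = TRUE))
    expect_equal(f$stop - f$start + 1L, nchar(g))
  }
})

test_that("indel_process honours forced events, truncation and rate zero", {
  out0 <- indel_process("ACGTACGTACGTACGTACGT", 0.05, rate = 0, length_param = 0.5)
  expect_equal(out0$sequence, "ACGTACGTACGTACGTACGT")
  expect_equal(nrow(out0$log), 0L)

  forced <- tibble::tibble(type = "deletion", position = 5L, length = 3L)
  out1 <- indel_process(strrep("A", 20), 0.05, rate = 1, length_param = 0.5,
                        events = forced)
  expect_equal(nchar(out1$sequence), 17L)
  expect_equal(out1$log, tibble::tibble(type = "deletion", position = 5L,
                                        length = 3L))

  # deletion overrunning the end is truncated and logged with realized length
  forced2 <- tibble::tibble(type = "deletion", position = 18L, length = 10L)
  out2 <- indel_process(strrep("A", 20), 0.05, rate = 1, length_param = 0.5,
                        events = forced2)
  expect_equal(nchar(out2$sequence), 17L)
  expect_equal(out2$log$length, 3L)

  forced3 <- tibble::tibble(type = "insertion", position = 0L, length = 4L)
  out3 <- indel_process(strrep("A", 10), 0.05, rate = 1, length_param = 0.5,
                        events = forced3)
  expect_equal(nchar(out3$sequence), 14L)
})

test_that("indel event counts match the Poisson moment", {
  set.seed(119)
  L <- 400L; t_br <- 0.2; rate <- 0.5
  n_rep <- 1000
  counts <- vapply(seq_len(n_rep), function(i) {
    nrow(indel_process(strrep("A", L), t_br, rate, length_param = 0.5)$log)
  }, numeric(1))
  expected <- rate * L * t_br
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("default mitogenome layout mirrors the canonical feature order", {
  tree <- ape::read.tree(text = "(A:0.01,B:0.01,C:0.01);")
  set <- simulate_mitogenome_set(sim_config(tree, seed = 20))
  fa <- dplyr::filter(set$features, taxon == "A")
  expect_equal(sum(fa$class == "CDS"), 13L)
  expect_equal(sum(fa$class == "tRNA"), 22L)
  expect_equal(sum(fa$class == "rRNA"), 2L)
  expect_equal(sum(fa$class == "CR"), 1L)
  expect_equal(fa$name[1:2], c("tRNA-Phe", "12S"))
  expect_equal(fa$name[nrow(fa)], "CR")
  # extract-and-translate every simulated CDS: no internal stops
  g <- set$genomes$sequence[set$genomes$taxon == "A"]
  cds <- dplyr::filter(extract_feature_seqs(g, fa), class == "CDS")
  for (s in cds$sequence) {
    expect_false(grepl("\\*", translate_mito(s)))
    expect_equal(nchar(translate_mito(s)), nchar(s) / 3 - 1)
  }
})

test_that("config validation rejects malformed inputs", {
  tree <- ape::read.tree(text = "(A:0.1,B:0.1,C:0.1);")
  bad_cds <- tibble::tibble(label = "x", length = 301L, class = "CDS",
                            strand = "H", rate_multiplier = 1)
  expect_error(sim_config(tree, bad_cds), "divisible by 3")
  bad_mult <- tibble::tibble(label = "x", length = 300L, class = "rRNA",
                             strand = "H", rate_multiplier = -1)
  expect_error(sim_config(tree, bad_mult), "multipliers")
  expect_error(sim_config(ape::read.tree(text = "(A,B,C);"), small_parts()),
               "branch lengths")
  expect_error(sim_config("((A:1,B:1);x", small_parts()))
})
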