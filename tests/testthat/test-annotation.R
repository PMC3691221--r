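test_that("local_align finds identical and embedded sequences", {
  hit <- local_align("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage, 1)
  expect_equal(c(hit$target_start, hit$target_end), c(1L, 20L))

  set.seed(42)
  bg <- random_seq(2000)
  motif <- random_seq(60)
  # plant with 3 substitutions at a known window
  planted <- strsplit(motif, "")[[1]]
  pos_mut <- c(10, 30, 50)
  for (p in pos_mut) planted[p] <- setdiff(c("A", "C", "G", "T"), planted[p])[1]
  target <- paste0(substr(bg, 1, 1000), paste(planted, collapse = ""),
                   substr(bg, 1001, 2000))
  hit2 <- local_align(motif, target)
  # identity against the exhaustive known-window oracle: 57 matches / 60
  expect_equal(hit2$identity, 57 / 60, tolerance = 1e-12)
  expect_equal(hit2$target_start, 1001L)
})

test_that("place_feature recovers true coordinates, strands and the origin", {
  set.seed(7)
  g <- random_seq(3000)
  feat <- substr(g, 501, 1500)
  p <- place_feature(feat, g)
  expect_equal(p$start, 501L)
  expect_equal(p$stop, 1500L)
  expect_equal(p$strand, "H")
  expect_equal(p$percent_identity, 1)

  pl <- place_feature(revcomp(feat), g)
  expect_equal(pl$start, 501L)
  expect_equal(pl$stop, 1500L)
  expect_equal(pl$strand, "L")

  wrap_feat <- paste0(substr(g, 2901, 3000), substr(g, 1, 100))
  pw <- place_feature(wrap_feat, g)
  expect_equal(pw$start, 2901L)
  expect_equal(pw$stop, 100L)

  expect_equal(nrow(place_feature(random_seq(300), g)), 0L)  # not found
})

test_that("consensus_annotation applies majority rule and score tie-breaks", {
  mk <- function(starts, stops, scores, strands = "H") {
    tibble::tibble(feature_name = "X", ref_taxon = NA_character_,
                   start = starts, stop = stops, strand = strands,
                   percent_identity = scores, length_coverage = 1,
                   score = scores)
  }
  ident <- consensus_annotation(mk(c(100, 100, 100), c(200, 200, 200), c(.9, .9, .9)))
  expect_equal(ident$start, 100L)
  expect_equal(ident$stop, 200L)
  expect_equal(ident$support, 3L)

  maj <- consensus_annotation(mk(c(100, 100, 103), c(200, 200, 200), c(.8, .8, .99)))
  expect_equal(maj$start, 100L)
  expect_equal(maj$support, 2L)

  tie <- consensus_annotation(mk(c(100, 103), c(200, 200), c(0.99, 0.80)))
  expect_equal(tie$start, 100L)  # tie goes to the higher-scoring placement

  expect_error(consensus_annotation(mk(integer(0), integer(0), numeric(0))[0, ]),
               "not found")
  expect_error(
    consensus_annotation(mk(c(100, 100), c(200, 200), c(.9, .9),
                            strands = c("H", "L"))),
    "strand"
  )
})

test_that("majority rule is invariant to the order of reference placements", {
  set.seed(9)
  base <- tibble::tibble(
    feature_name = "X", ref_taxon = NA_character_,
    start = c(10L, 10L, 12L, 15L, 10L), stop = c(90L, 90L, 92L, 95L, 90L),
    strand = "H", percent_identity = c(.9, .8, .95, .7, .85),
    length_coverage = 1, score = c(.9, .8, .95, .7, .85)
  )
  ref <- consensus_annotation(base)
  for (i in 1:10) {
    perm <- base[sample.int(nrow(base)), ]
    expect_equal(consensus_annotation(perm), ref)
  }
})

test_that("scan_orfs finds known reading frames and nothing in homopolymers", {
  g <- paste0(strrep("C", 100), "ATGTTTTAA", strrep("C", 100))
  orfs <- scan_orfs(g, min_length = 9, both_strands = FALSE, circular = FALSE)
  expect_equal(nrow(orfs), 1L)
  expect_equal(c(orfs$start, orfs$stop, orfs$length), c(101L, 109L, 9L))
  expect_equal(orfs$start_codon, "ATG")

  expect_equal(nrow(scan_orfs(strrep("A", 500), min_length = 60)), 0L)

  # L-strand ORF is reported in H coordinates
  gl <- paste0(strrep("C", 50), revcomp("ATGTTTTTTTAA"), strrep("C", 50))
  ol <- scan_orfs(gl, min_length = 12, circular = FALSE)
  ol <- ol[ol$strand == "L", ]
  expect_equal(c(ol$start, ol$stop), c(51L, 62L))
})

test_that("every simulated CDS is recovered as an ORF", {
  tree <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  parts <- sim_partitions_default()
  parts <- parts[parts$class %in% c("CDS", "rRNA"), ]  # compact genome
  cfg <- sim_config(tree, parts, seed = 301)
  set <- simulate_mitogenome_set(cfg)
  g <- set$genomes$sequence[set$genomes$taxon == "A"]
  fa <- dplyr::filter(set$features, taxon == "A", class == "CDS")
  orfs <- scan_orfs(g, min_length = 150)
  for (i in seq_len(nrow(fa))) {
    # the stop codon pins the 3' end: H-strand ORFs share the feature's stop
    # coordinate, L-strand ORFs its start; the 5' end may extend upstream
    hit <- if (fa$strand[i] == "H") {
      orfs[orfs$strand == "H" & orfs$stop == fa$stop[i] &
             orfs$start <= fa$start[i], ]
    } else {
      orfs[orfs$strand == "L" & orfs$start == fa$start[i] &
             orfs$stop >= fa$stop[i], ]
    }
    expect_gte(nrow(hit), 1L)
  }
})

test_that("self-annotation recovers every feature coordinate exactly", {
  tree <- ape::read.tree(text = "((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  parts <- sim_partitions_default()
  parts <- parts[parts$length >= 60 & parts$class != "CR", ][1:12, ]
  cfg <- sim_config(tree, parts, seed = 77)
  set <- simulate_mitogenome_set(cfg)
  g <- set$genomes$sequence[set$genomes$taxon == "A"]
  fa <- dplyr::filter(set$features, taxon == "A")
  refs <- extract_feature_seqs(g, fa)
  refs <- tibble::tibble(taxon = "A", feature = refs$name, class = refs$class,
                         sequence = refs$sequence)
  ann <- suppressWarnings(annotate_genome(g, refs))
  cmp <- dplyr::inner_join(
    dplyr::select(ann, "name", "start", "stop", "strand"),
    dplyr::select(fa, "name", "start", "stop", "strand"),
    by = "name", suffix = c("_est", "_true")
  )
  expect_equal(nrow(cmp), nrow(fa))
  expect_equal(cmp$start_est, cmp$start_true)
  expect_equal(cmp$stop_est, cmp$stop_true)
  expect_equal(cmp$strand_est, cmp$strand_true)
})

test_that("placements stay within 2 nt per boundary at ~5% divergence", {
  # two taxa separated by 0.05 expected substitutions/site, no indels
  tree <- ape::read.tree(text = "(A:0.025,B:0.025,C:0.025);")
  parts <- sim_partitions_default()
  parts <- parts[parts$class %in% c("CDS", "rRNA"), ]
  n_rep <- 6
  ok <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(tree, parts, seed = 500 + r)
    set <- simulate_mitogenome_set(cfg)
    gA <- set$genomes$sequence[set$genomes$taxon == "A"]
    fA <- dplyr::filter(set$features, taxon == "A")
    refs <- extract_feature_seqs(gA, fA)
    gB <- set$genomes$sequence[set$genomes$taxon == "B"]
    fB <- dplyr::filter(set$features, taxon == "B")
    for (i in seq_len(nrow(refs))) {
      p <- place_feature(refs$sequence[i], gB)
      total <- total + 1L
      if (nrow(p) == 1L &&
          abs(p$start - fB$start[i]) <= 2L && abs(p$stop - fB$stop[i]) <= 2L) {
        ok <- ok + 1L
      }
    }
  }
  expect_gte(ok / total, 0.95)
})
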