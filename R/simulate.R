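BASES <- c("A", "C", "G", "T")

# HKY rate matrix (normalized to one expected substitution per site per unit
# branch length) and its spectral decomposition for computing P(t).
hky_eigen <- function(kappa, freqs) {
  freqs <- freqs[BASES] / sum(freqs[BASES])
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (BASES[i] %in% c("A", "G")) == (BASES[j] %in% c("A", "G"))
    Q[i, j] <- if (ti) kappa * freqs[j] else freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q <- Q / mu
  d <- sqrt(freqs)
  S <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(
    V = diag(1 / d) %*% e$vectors,
    Vinv = t(e$vectors) %*% diag(d),
    lambda = e$values,
    freqs = freqs
  )
}

transition_matrix <- function(eig, t) {
  if (t <= 0) return(diag(4))
  P <- eig$V %*% diag(exp(eig$lambda * t)) %*% eig$Vinv
  P[P < 0] <- 0
  P / rowSums(P)
}

# Sample child states (integers 1..4) from parent states under P.
evolve_states <- function(parent, P) {
  child <- parent
  for (s in 1:4) {
    idx <- which(parent == s)
    if (length(idx)) {
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  child
}

states_to_seq <- function(states) paste(BASES[states], collapse = "")
seq_to_states <- function(x) match(seq_chars(x), BASES)

#' Default simulated-mitogenome partition layout
#'
#' The partition table used by [sim_config()]: the feature order, classes,
#' strands and sizes of the shipped *P. trewavasae* table (CDS sizes rounded
#' down to complete codons so simulated genes stay in frame), with
#' class-level rate multipliers mirroring typical relative rates of
#' mitochondrial partitions: control region fastest, then protein-coding
#' genes and the large rRNA, the small rRNA as the unit reference, tRNAs
#' slowest.
#'
#' @return Tibble with columns `label`, `length`, `class`, `strand`,
#'   `rate_multiplier`.
#' @export
sim_partitions_default <- function() {
  ft <- example_feature_table("PT")
  len <- feature_length(ft$start, ft$stop, max(ft$stop))
  len[ft$class == "CDS"] <- (len[ft$class == "CDS"] %/% 3L) * 3L
  mult <- dplyr::case_when(
    ft$name == "12S" ~ 1.0,
    ft$class == "rRNA" ~ 1.23,
    ft$class == "CDS" ~ 1.25,
    ft$class == "CR" ~ 4.38,
    TRUE ~ 0.75
  )
  tibble(label = ft$name, length = as.integer(len), class = ft$class,
         strand = ft$strand, rate_multiplier = mult)
}

#' Simulation configuration
#'
#' Bundles everything the mitogenome simulator needs: a tree with branch
#' lengths (expected substitutions per site on the reference partition), a
#' partition table with per-partition rate multipliers, the substitution
#' model, the control-region indel process and optional lineage-specific
#' codon-bias shifts.
#'
#' @param tree A `phylo` object or newick string (branch lengths required).
#' @param partitions Tibble `label`, `length`, `class` (CDS/tRNA/rRNA/CR/OL),
#'   `rate_multiplier` (optional `strand`, default H); defaults to
#'   [sim_partitions_default()]. CDS lengths must be divisible by 3.
#' @param model `"HKY"` (default) or `"JC"`.
#' @param kappa Transition/transversion rate ratio (HKY; default 4).
#' @param base_freqs Stationary base frequencies; the default mimics the
#'   H-strand composition of the study genomes (A 0.275, C 0.303, G 0.157,
#'   T 0.265). Forced uniform under JC.
#' @param indel_rate Control-region indel events per site per unit branch
#'   length (default 0.1).
#' @param indel_length_p Geometric length parameter for indel tracts in
#'   (0, 1] (default 0.5, mean tract length 2 nt).
#' @param codon_bias Optional tibble `taxon`, `third_base`, `strength`: after
#'   simulation, each internal codon of that taxon's CDSs has its third base
#'   switched to `third_base` with probability `strength` when the switch is
#'   synonymous.
#' @param seed Integer seed; identical config + seed reproduces outputs
#'   byte-identically.
#' @return List of class `mito_sim_config`.
#' @export
sim_config <- function(tree, partitions = sim_partitions_default(),
                       model = c("HKY", "JC"), kappa = 4,
                       base_freqs = c(A = 0.275, C = 0.303, G = 0.157, T = 0.265),
                       indel_rate = 0.1, indel_length_p = 0.5,
                       codon_bias = NULL, seed = NULL) {
  model <- match.arg(model)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort("tree must be a phylo object or newick string")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (ape::Ntip(tree) < 3L) abort("tree must have at least 3 taxa")
  stopifnot(all(c("label", "length", "class", "rate_multiplier") %in% names(partitions)))
  if (!"strand" %in% names(partitions)) partitions$strand <- "H"
  if (any(partitions$rate_multiplier < 0)) abort("rate multipliers must be >= 0")
  bad <- partitions$class == "CDS" & partitions$length %% 3L != 0L
  if (any(bad)) abort("CDS partition lengths must be divisible by 3")
  if (model == "JC") {
    kappa <- 1
    base_freqs <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  }
  if (indel_length_p <= 0 || indel_length_p > 1) {
    abort("indel_length_p must be in (0, 1]")
  }
  structure(
    list(tree = tree, partitions = partitions, model = model, kappa = kappa,
         base_freqs = base_freqs[BASES] / sum(base_freqs[BASES]),
         indel_rate = indel_rate, indel_length_p = indel_length_p,
         codon_bias = codon_bias, seed = seed),
    class = "mito_sim_config"
  )
}

stop_codon_states <- function(code = mito_genetic_code()) {
  do.call(rbind, lapply(code$stop_codons, seq_to_states))
}

is_stop_codon_int <- function(states3, stop_states) {
  any(apply(stop_states, 1L, function(s) all(s == states3)))
}

# Root CDS: held ATG start, held TAA stop, internal codons drawn from the
# stationary codon distribution restricted to sense codons.
sample_root_cds <- function(length, freqs, code) {
  n_codons <- length %/% 3L
  sense <- code$sense_codons
  w <- vapply(sense, function(cd) prod(freqs[seq_chars(cd)]), numeric(1))
  internal <- sample(sense, n_codons - 2L, replace = TRUE, prob = w)
  seq_to_states(paste0("ATG", paste(internal, collapse = ""), "TAA"))
}

# Evolve one branch of a CDS partition: start/stop codons held, mutations
# creating in-frame stops rejected (codon redrawn, falling back to the parent
# codon so the loop terminates).
evolve_cds_branch <- function(parent, P, stop_states) {
  n <- length(parent)
  child <- evolve_states(parent, P)
  child[1:3] <- parent[1:3]
  child[(n - 2L):n] <- parent[(n - 2L):n]
  n_codons <- n %/% 3L
  for (k in 2L:(n_codons - 1L)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    tries <- 0L
    while (is_stop_codon_int(child[cols], stop_states)) {
      tries <- tries + 1L
      if (tries > 25L) { child[cols] <- parent[cols]; break }
      child[cols] <- evolve_states(parent[cols], P)
    }
  }
  child
}

sample_indel_events <- function(L, branch_length, rate, length_param) {
  n_events <- stats::rpois(1L, rate * L * branch_length)
  if (n_events == 0L) {
    return(tibble(type = character(0), position = integer(0), length = integer(0)))
  }
  tibble(
    type = sample(c("insertion", "deletion"), n_events, replace = TRUE),
    position = integer(n_events),  # drawn at application time (length changes)
    length = stats::rgeom(n_events, length_param) + 1L
  )
}

#' Apply an indel process to a sequence
#'
#' Draws a Poisson number of indel events with mean `rate * length *
#' branch_length`, each equally likely an insertion or a deletion, with
#' geometrically distributed tract lengths (mean `1/length_param`), and
#' applies them sequentially. A deletion overrunning the sequence end is
#' truncated and logged with its realized length. Inserted bases are drawn
#' from `base_freqs`.
#'
#' @param sequence Nucleotide string.
#' @param branch_length Branch length in expected substitutions per site.
#' @param rate Indel events per site per unit branch length.
#' @param length_param Geometric length parameter in (0, 1].
#' @param base_freqs Frequencies for inserted bases.
#' @param events Optional forced event table (`type`, `position`, `length`)
#'   applied verbatim instead of sampling (positions refer to the sequence
#'   state at application time; insertion position = insert after that base,
#'   0 = prepend).
#' @return List with `sequence` (edited) and `log` (tibble `type`,
#'   `position`, `length` of the applied events).
#' @export
#' @examples
#' indel_process("ACGTACGTACGTACGTACGT", 0.05, rate = 0,
#'               length_param = 0.5)$sequence
indel_process <- function(sequence, branch_length, rate, length_param,
                          base_freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          events = NULL) {
  chars <- seq_chars(clean_seq(sequence))
  if (is.null(events)) {
    events <- sample_indel_events(length(chars), branch_length, rate, length_param)
    forced <- FALSE
  } else forced <- TRUE
  log <- list()
  for (i in seq_len(nrow(events))) {
    L <- length(chars)
    type <- events$type[i]
    len <- events$length[i]
    if (type == "deletion") {
      pos <- if (forced) events$position[i] else sample.int(L, 1L)
      len_applied <- min(len, L - pos + 1L)
      chars <- chars[-(pos:(pos + len_applied - 1L))]
      log[[i]] <- tibble(type = "deletion", position = pos, length = len_applied)
    } else {
      pos <- if (forced) events$position[i] else sample.int(L + 1L, 1L) - 1L
      ins <- sample(BASES, len, replace = TRUE, prob = base_freqs[BASES])
      chars <- append(chars, ins, after = pos)
      log[[i]] <- tibble(type = "insertion", position = pos, length = len)
    }
  }
  list(
    sequence = paste(chars, collapse = ""),
    log = if (length(log)) dplyr::bind_rows(log) else
      tibble(type = character(0), position = integer(0), length = integer(0))
  )
}

# --- control-region evolution with a tracked true alignment ----------------
# Every alignment column has a numeric key; sorting keys gives column order.
# Deletions drop keys from a lineage; insertions create fresh keys strictly
# between the flanking keys (jittered so independent insertions in different
# lineages get distinct keys).

insert_keys <- function(keys, pos, k) {
  a <- if (pos == 0L) (if (length(keys)) keys[1L] - 1 else 0) else keys[pos]
  b <- if (pos >= length(keys)) a + 1 else keys[pos + 1L]
  a + (b - a) * (seq_len(k) + stats::runif(1L, -0.3, 0.3)) / (k + 1)
}

evolve_cr_branch <- function(state, t, eig, indel_rate, length_param, freqs) {
  P <- transition_matrix(eig, t)
  state$states <- evolve_states(state$states, P)
  events <- sample_indel_events(length(state$states), t, indel_rate, length_param)
  log <- list()
  for (i in seq_len(nrow(events))) {
    L <- length(state$states)
    if (L == 0L) break
    if (events$type[i] == "deletion") {
      pos <- sample.int(L, 1L)
      len <- min(events$length[i], L - pos + 1L)
      drop <- pos:(pos + len - 1L)
      state$states <- state$states[-drop]
      state$keys <- state$keys[-drop]
      log[[i]] <- tibble(type = "deletion", position = pos, length = len)
    } else {
      pos <- sample.int(L + 1L, 1L) - 1L
      len <- events$length[i]
      newk <- insert_keys(state$keys, pos, len)
      ins <- sample.int(4L, len, replace = TRUE, prob = freqs)
      state$states <- append(state$states, ins, after = pos)
      state$keys <- append(state$keys, newk, after = pos)
      log[[i]] <- tibble(type = "insertion", position = pos, length = len)
    }
  }
  state$log <- if (length(log)) dplyr::bind_rows(log) else
    tibble(type = character(0), position = integer(0), length = integer(0))
  state
}

# Render leaf (keys, states) maps as a gapped multiple alignment.
render_cr_alignment <- function(leaves) {
  all_keys <- sort(unique(unlist(lapply(leaves, `[[`, "keys"))))
  rows <- vapply(leaves, function(lf) {
    col <- rep("-", length(all_keys))
    col[match(lf$keys, all_keys)] <- BASES[lf$states]
    paste(col, collapse = "")
  }, character(1))
  rows
}

#' Simulate gene alignments down a tree
#'
#' Evolves every partition down the supplied tree under the configured
#' substitution model, with per-partition rate = branch length x rate
#' multiplier. The root sequence is drawn from the stationary frequencies.
#' CDS partitions hold their start (ATG) and stop (TAA) codons and reject
#' substitutions that would create an in-frame stop, so simulated genes stay
#' translatable. Control-region (CR) partitions additionally run the indel
#' process and are emitted as a true (generator-known) alignment; all other
#' partitions are emitted ungapped.
#'
#' @param config A [sim_config()].
#' @return List of class `mito_sim` with `alignments` (named list: partition
#'   label -> named character vector keyed by taxon) and `truth` (partition
#'   table with true multipliers, the tree, the seed, per-branch realized
#'   substitution counts, indel logs, and per-taxon codon-bias assignments).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "mito_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- ape::reorder.phylo(config$tree, "cladewise")
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  eig <- hky_eigen(config$kappa, config$base_freqs)
  code <- mito_genetic_code()
  stop_states <- stop_codon_states(code)
  freqs <- config$base_freqs

  alignments <- list()
  sub_counts <- list()
  indel_logs <- list()
  for (p in seq_len(nrow(config$partitions))) {
    part <- config$partitions[p, ]
    mult <- part$rate_multiplier
    if (part$class == "CDS") {
      root_states <- sample_root_cds(part$length, freqs, code)
    } else {
      root_states <- sample.int(4L, part$length, replace = TRUE, prob = freqs)
    }
    if (part$class == "CR") {
      node_state <- vector("list", max(tree$edge))
      node_state[[root]] <- list(keys = as.numeric(seq_len(part$length)),
                                 states = root_states)
      logs <- list()
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        st <- evolve_cr_branch(node_state[[par]], tree$edge.length[e] * mult,
                               eig, config$indel_rate, config$indel_length_p,
                               freqs)
        logs[[e]] <- st$log
        st$log <- NULL
        node_state[[ch]] <- st
      }
      leaves <- setNames(node_state[seq_len(n_tip)], tree$tip.label)
      alignments[[part$label]] <- render_cr_alignment(leaves)
      indel_logs[[part$label]] <- logs
      sub_counts[[part$label]] <- NA_integer_
    } else {
      node_state <- vector("list", max(tree$edge))
      node_state[[root]] <- root_states
      counts <- integer(nrow(tree$edge))
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
        t_e <- tree$edge.length[e] * mult
        P <- transition_matrix(eig, t_e)
        child <- if (part$class == "CDS") {
          evolve_cds_branch(node_state[[par]], P, stop_states)
        } else {
          evolve_states(node_state[[par]], P)
        }
        counts[e] <- sum(child != node_state[[par]])
        node_state[[ch]] <- child
      }
      alignments[[part$label]] <- setNames(
        vapply(seq_len(n_tip), function(i) states_to_seq(node_state[[i]]),
               character(1)),
        tree$tip.label
      )
      sub_counts[[part$label]] <- counts
    }
  }

  bias_truth <- NULL
  if (!is.null(config$codon_bias)) {
    cds_labels <- config$partitions$label[config$partitions$class == "CDS"]
    for (lb in cds_labels) {
      aln <- alignments[[lb]]
      for (i in seq_len(nrow(config$codon_bias))) {
        tx <- config$codon_bias$taxon[i]
        if (!tx %in% names(aln)) next
        aln[[tx]] <- apply_codon_bias(aln[[tx]],
                                      config$codon_bias$third_base[i],
                                      config$codon_bias$strength[i], code)
      }
      alignments[[lb]] <- aln
    }
    bias_truth <- config$codon_bias
  }

  structure(
    list(
      alignments = alignments,
      truth = list(
        partitions = config$partitions,
        tree = ape::write.tree(tree),
        seed = config$seed,
        substitution_counts = sub_counts,
        indel_logs = indel_logs,
        codon_bias = bias_truth
      )
    ),
    class = "mito_sim"
  )
}

# Shift third-codon-position usage toward `third_base` where synonymous;
# start/stop codons held.
apply_codon_bias <- function(cds, third_base, strength, code = mito_genetic_code()) {
  codons <- split_codons(cds)
  n <- length(codons)
  if (n <= 2L) return(cds)
  for (k in 2L:(n - 1L)) {
    if (stats::runif(1L) >= strength) next
    cand <- paste0(substr(codons[k], 1L, 2L), third_base)
    if (cand == codons[k]) next
    if (!cand %in% code$sense_codons) next
    if (code$table[[cand]] == code$table[[codons[k]]]) codons[k] <- cand
  }
  paste(codons, collapse = "")
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Simulate a set of annotated mitogenomes
#'
#' Runs [simulate_alignment()] and assembles, per taxon, a circular genome by
#' concatenating the partitions in their table order (L-strand partitions
#' reverse-complemented into the genome; control-region gaps removed), along
#' with the true per-taxon feature coordinates, so annotation, rate and
#' codon-usage analyses can be tested against known truth.
#'
#' @param config A [sim_config()].
#' @return List of class `mito_sim_set`: `genomes` (tibble `taxon`,
#'   `sequence`, `length`), `features` (tibble with `taxon` plus the feature
#'   table columns; true coordinates), `alignments` and `truth` as in
#'   [simulate_alignment()], plus `truth$codon_tally` (per-taxon sense-codon
#'   counts over all CDS).
#' @export
simulate_mitogenome_set <- function(config) {
  sim <- simulate_alignment(config)
  parts <- config$partitions
  taxa <- names(sim$alignments[[parts$label[1L]]])
  code <- mito_genetic_code()

  genomes <- list(); feats <- list(); tallies <- list()
  for (tx in taxa) {
    pieces <- vapply(seq_len(nrow(parts)), function(p) {
      s <- degap(sim$alignments[[parts$label[p]]][[tx]])
      if (identical(parts$strand[p], "L")) revcomp(s) else s
    }, character(1))
    lens <- nchar(pieces)
    stops <- cumsum(lens)
    starts <- stops - lens + 1L
    genomes[[tx]] <- tibble(taxon = tx, sequence = paste(pieces, collapse = ""),
                            length = sum(lens))
    feats[[tx]] <- tibble(
      taxon = tx, name = parts$label, class = parts$class,
      start = as.integer(starts), stop = as.integer(stops),
      strand = parts$strand,
      start_codon = ifelse(parts$class == "CDS", "ATG", NA_character_),
      stop_class = ifelse(parts$class == "CDS", "TAA", NA_character_),
      anticodon = NA_character_
    )
    cds_idx <- which(parts$class == "CDS")
    if (length(cds_idx)) {
      codons <- unlist(lapply(cds_idx, function(p) {
        split_codons(degap(sim$alignments[[parts$label[p]]][[tx]]))
      }))
      tallies[[tx]] <- setNames(
        as.integer(table(factor(codons[codons %in% code$sense_codons],
                                levels = code$sense_codons))),
        code$sense_codons
      )
    }
  }
  sim$truth$codon_tally <- tallies
  structure(
    list(genomes = dplyr::bind_rows(genomes),
         features = dplyr::bind_rows(feats),
         alignments = sim$alignments, truth = sim$truth),
    class = "mito_sim_set"
  )
}
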