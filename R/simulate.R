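# Synthetic trees, temperature traits, proteomes and toy protein-RNA
# complexes. Every generator is a pure function of (cfg, seed): the
# same configuration and seed always reproduce the same output, so the
# whole pipeline can be tested end to end without any external data.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults aim at
#' a plausible bacterial 30S dataset: 64 species, 20 r-proteins S2-S21
#' with lengths declining from ~235 to ~55 residues, a baseline
#' composition rich in K (11%) and R (10%) as r-proteins are, a
#' thermophile composition shift adding to R/I/Y at the expense of S/T,
#' and interfaces where roughly 30% of residues touch the rRNA.
#'
#' @param n_species Number of tips for the simulated tree.
#' @param birth_rate Yule pure-birth speciation rate (events per unit
#'   branch length).
#' @param trait_switch_rate Rate of mesophile/thermophile switches per
#'   unit branch length (symmetric two-state Markov chain).
#' @param n_proteins Number of r-proteins to simulate (named S2, S3,
#'   ... up to S21).
#' @param protein_lengths Integer vector of ungapped lengths, recycled
#'   to `n_proteins`.
#' @param baseline_freqs Named 20-vector of baseline residue
#'   frequencies; renormalized to sum to 1.
#' @param thermo_effect Named additive shift applied to thermophile
#'   residue frequencies (must keep all frequencies positive; the
#'   shifted vector is renormalized). Default +0.02 on R, I, Y and
#'   -0.03 on S, T.
#' @param contact_fraction Fraction of residues planted as rRNA
#'   contacts in toy complexes.
#' @param positive_contact_bias Odds multiplier favouring K/R residues
#'   when drawing planted contacts (1 = unbiased null).
#' @param gap_rate Per-position probability of replacing a residue with
#'   a gap in [simulate_proteomes()] (default 0: pre-aligned, gap-free).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 64,
                       birth_rate = 1,
                       trait_switch_rate = 0.3,
                       n_proteins = 20,
                       protein_lengths = NULL,
                       baseline_freqs = NULL,
                       thermo_effect = c(R = 0.02, I = 0.02, Y = 0.02,
                                         S = -0.03, T = -0.03),
                       contact_fraction = 0.3,
                       positive_contact_bias = 1,
                       gap_rate = 0) {
  if (n_species < 2) abort("`n_species` must be >= 2.")
  if (birth_rate <= 0 || trait_switch_rate < 0) abort("invalid rates.")
  if (n_proteins < 1 || n_proteins > 20) abort("`n_proteins` must be in 1..20.")
  if (is.null(protein_lengths)) {
    protein_lengths <- round(seq(235, 55, length.out = 20))[seq_len(n_proteins)]
  }
  protein_lengths <- rep_len(as.integer(protein_lengths), n_proteins)
  if (is.null(baseline_freqs)) baseline_freqs <- default_rprotein_freqs()
  baseline_freqs <- check_freqs(baseline_freqs)
  bad <- setdiff(names(thermo_effect), AA_ALPHABET)
  if (length(bad)) abort(paste0("unknown residue(s) in thermo_effect: ",
                                paste(bad, collapse = ", ")))
  shifted <- apply_shift(baseline_freqs, thermo_effect)
  if (any(shifted <= 0)) abort("`thermo_effect` drives a frequency to <= 0.")
  if (contact_fraction <= 0 || contact_fraction > 1) {
    abort("`contact_fraction` must be in (0, 1].")
  }
  if (positive_contact_bias <= 0) abort("`positive_contact_bias` must be > 0.")
  structure(list(
    n_species = as.integer(n_species), birth_rate = birth_rate,
    trait_switch_rate = trait_switch_rate,
    n_proteins = as.integer(n_proteins), protein_lengths = protein_lengths,
    baseline_freqs = baseline_freqs, thermo_effect = thermo_effect,
    contact_fraction = contact_fraction,
    positive_contact_bias = positive_contact_bias, gap_rate = gap_rate
  ), class = "sim_config")
}

# Baseline 30S r-protein-like composition: positively charged residues
# dominate (K ~ 11%, R ~ 10%), acidic and aromatic residues are scarce.
default_rprotein_freqs <- function() {
  f <- c(A = 0.08, C = 0.01, D = 0.04, E = 0.06, F = 0.04, G = 0.08,
         H = 0.02, I = 0.06, K = 0.11, L = 0.07, M = 0.02, N = 0.04,
         P = 0.03, Q = 0.03, R = 0.10, S = 0.05, T = 0.05, V = 0.07,
         W = 0.01, Y = 0.03)
  f / sum(f)
}

check_freqs <- function(f) {
  if (is.null(names(f)) || !setequal(names(f), AA_ALPHABET)) {
    abort("`baseline_freqs` must be named with the 20 amino-acid letters.")
  }
  f <- f[AA_ALPHABET]
  if (any(f <= 0)) abort("all baseline frequencies must be > 0.")
  f / sum(f)
}

apply_shift <- function(freqs, shift) {
  f <- freqs
  f[names(shift)] <- f[names(shift)] + shift
  if (any(f <= 0)) return(f)
  f / sum(f)
}

#' Simulate a Yule pure-birth tree
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the result is a pure function of
#'   (cfg, seed).
#' @return An [ape::phylo] tree with `cfg$n_species` tips labelled
#'   `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(cfg, seed) {
  set.seed(seed)
  tree <- ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(cfg$n_species))
  tree
}

#' Evolve a binary temperature trait along a tree
#'
#' Symmetric two-state Markov chain down the tree: the root is
#' mesophile and along every branch of length t the state switches with
#' probability `(1 - exp(-2 r t)) / 2`, r = `cfg$trait_switch_rate`.
#' Thermophily therefore arises in phylogenetic clusters, as it does in
#' real bacterial trees, rather than being scattered independently.
#'
#' @inheritParams simulate_tree
#' @param tree A tree from [simulate_tree()].
#' @return Tibble: `species_id`, `binary_class` (factor).
#' @export
simulate_trait <- function(tree, cfg, seed) {
  set.seed(seed)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  state <- integer(n_all)
  root <- ntip + 1L
  state[root] <- 0L
  tr <- stats::reorder(tree, "cladewise")  # parents before children
  p_switch <- (1 - exp(-2 * cfg$trait_switch_rate * tr$edge.length)) / 2
  flip <- rbinom(nrow(tr$edge), 1L, p_switch)
  for (i in seq_len(nrow(tr$edge))) {
    state[tr$edge[i, 2]] <- (state[tr$edge[i, 1]] + flip[i]) %% 2L
  }
  tibble(
    species_id = tree$tip.label,
    binary_class = factor(ifelse(state[seq_len(ntip)] == 1L,
                                 "thermophile", "mesophile"),
                          levels = c("mesophile", "thermophile"))
  )
}

#' Simulate trait-conditioned r-protein alignments
#'
#' Draws each species' residues i.i.d. from the baseline frequencies,
#' with `cfg$thermo_effect` added (and the vector renormalized) for
#' thermophiles. Sequences come out pre-aligned - equal length within a
#' protein and gap-free - since alignment is upstream of this analysis;
#' `cfg$gap_rate > 0` optionally punches random gaps to exercise gap
#' handling.
#'
#' @inheritParams simulate_tree
#' @param traits Tibble from [simulate_trait()].
#' @param interface Optional list from [simulate_interface_columns()]:
#'   per-protein column sets conserved across species at which K/R odds
#'   are multiplied by `cfg$positive_contact_bias`, emulating an rRNA
#'   interface that every species shares and keeps positively charged.
#' @return Tibble with `species_id`, `protein_name`, `aligned_seq`,
#'   `length` - one row per species x protein.
#' @export
simulate_proteomes <- function(traits, cfg, seed, interface = NULL) {
  set.seed(seed)
  f_meso <- cfg$baseline_freqs
  f_thermo <- apply_shift(cfg$baseline_freqs, cfg$thermo_effect)
  bias_kr <- function(f) {
    f[c("K", "R")] <- f[c("K", "R")] * cfg$positive_contact_bias
    f / sum(f)
  }
  proteins <- paste0("S", seq(2, length.out = cfg$n_proteins))
  grid <- tidyr::expand_grid(species_id = traits$species_id,
                             protein = seq_len(cfg$n_proteins))
  is_thermo <- traits$binary_class[match(grid$species_id,
                                         traits$species_id)] == "thermophile"
  seqs <- vapply(seq_len(nrow(grid)), function(i) {
    L <- cfg$protein_lengths[grid$protein[i]]
    f <- if (is_thermo[i]) f_thermo else f_meso
    s <- sample(AA_ALPHABET, L, replace = TRUE, prob = f)
    if (!is.null(interface)) {
      cols <- interface[[proteins[grid$protein[i]]]]
      s[cols] <- sample(AA_ALPHABET, length(cols), replace = TRUE,
                        prob = bias_kr(f))
    }
    if (cfg$gap_rate > 0) {
      s[runif(L) < cfg$gap_rate] <- "-"
    }
    paste(s, collapse = "")
  }, character(1L))
  tibble(
    species_id = grid$species_id,
    protein_name = proteins[grid$protein],
    aligned_seq = seqs,
    length = ungapped_length(seqs)
  )
}

#' Draw conserved interface columns for every protein
#'
#' Samples, per protein, the set of alignment columns that act as the
#' conserved rRNA interface: a fraction `cfg$contact_fraction` of each
#' protein's length. Feeding the result to [simulate_proteomes()] (to
#' bias those columns toward K/R in every species) and to
#' [simulate_complex()] (as the planted contact positions of the
#' reference structures) yields a world where contact sites are shared
#' across species, which is the premise of the shared-column
#' projection.
#'
#' @inheritParams simulate_tree
#' @return Named list (by protein) of sorted 1-based column indices.
#' @export
simulate_interface_columns <- function(cfg, seed) {
  set.seed(seed)
  proteins <- paste0("S", seq(2, length.out = cfg$n_proteins))
  out <- lapply(seq_len(cfg$n_proteins), function(i) {
    L <- cfg$protein_lengths[i]
    sort(sample.int(L, max(1L, round(cfg$contact_fraction * L))))
  })
  names(out) <- proteins
  out
}

#' Simulate a toy protein-rRNA complex with planted contacts
#'
#' Builds a one-pseudo-atom-per-residue protein chain (A) and an RNA
#' pseudo-atom chain (B). A planted fraction of residues is drawn
#' without replacement, with K/R odds multiplied by
#' `cfg$positive_contact_bias`, and each planted residue gets an RNA
#' atom 3.0 A away; all other residues sit at least 1.5 A beyond the
#' 3.5 A cutoff from every RNA atom, plus a decoy RNA backbone far from
#' the protein. The geometry is deliberately minimal: the contact
#' detector is geometry-agnostic, so pseudo-atoms exercise it fully
#' while the files stay tiny.
#'
#' @inheritParams simulate_tree
#' @param seq Character scalar: the (ungapped) protein sequence.
#' @param contacts Optional integer positions to plant as contacts
#'   (e.g. one protein's entry from [simulate_interface_columns()]);
#'   when `NULL` (default) they are drawn at random with the K/R odds
#'   bias.
#' @return List with `atoms` (a structure tibble as from
#'   [read_structure()]) and `truth` (tibble `position`, `residue`,
#'   `contact`).
#' @export
simulate_complex <- function(seq, cfg, seed, contacts = NULL) {
  set.seed(seed)
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(res %in% AA_ALPHABET)) abort("`seq` must be ungapped standard residues.")
  L <- length(res)
  if (is.null(contacts)) {
    n_contact <- max(1L, round(cfg$contact_fraction * L))
    if (n_contact > L) abort("infeasible geometry: more contacts than residues.")
    w <- ifelse(res %in% c("K", "R"), cfg$positive_contact_bias, 1)
    planted <- sort(sample.int(L, n_contact, prob = w))
  } else {
    if (any(contacts < 1 | contacts > L)) {
      abort("planted contact positions outside the sequence.")
    }
    planted <- sort(unique(as.integer(contacts)))
    n_contact <- length(planted)
  }

  spacing <- 6
  px <- seq_len(L) * spacing
  prot <- tibble(
    chain = "A", resno = seq_len(L), resid = unname(PROTEIN_RESID[res]),
    elety = "CA", x = px, y = 0, z = 0, occupancy = 1, moltype = "protein"
  )
  rna_res <- sample(c("A", "C", "G", "U"), n_contact + 5L, replace = TRUE)
  rna <- tibble(
    chain = "B",
    resno = seq_len(n_contact + 5L),
    resid = rna_res,
    elety = "P",
    x = c(px[planted], seq_len(5L) * spacing),
    y = c(rep(3.0, n_contact), rep(50, 5L)),
    z = 0, occupancy = 1, moltype = "rna"
  )
  list(
    atoms = bind_rows(prot, rna),
    truth = tibble(position = seq_len(L), residue = res,
                   contact = seq_len(L) %in% planted)
  )
}

#' Write a toy complex to PDB text
#'
#' Emits fixed-width ATOM records that round-trip through
#' [read_structure()].
#'
#' @param complex List from [simulate_complex()].
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(complex, path) {
  at <- complex$atoms
  elem <- ifelse(at$moltype == "protein", "C", "P")
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), at$elety, at$resid, at$chain, at$resno,
    at$x, at$y, at$z, at$occupancy, 0, elem
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining tree, trait and proteome generation
#' with sub-seeds derived from `seed`.
#'
#' @inheritParams simulate_tree
#' @return List with `tree`, `traits`, `seqs`, `cfg`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1) {
  tree <- simulate_tree(cfg, seed)
  traits <- simulate_trait(tree, cfg, seed + 1000L)
  seqs <- simulate_proteomes(traits, cfg, seed + 2000L)
  list(tree = tree, traits = traits, seqs = seqs, cfg = cfg)
}
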