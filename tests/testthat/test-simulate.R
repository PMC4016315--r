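# The synthetic-data generators are pure functions of (cfg, seed) and
# must have the statistical structure the analysis assumes.

test_that("every generator is deterministic given cfg and seed", {
  cfg <- sim_config(n_species = 10, n_proteins = 3)
  expect_identical(ape::write.tree(simulate_tree(cfg, 9)),
                   ape::write.tree(simulate_tree(cfg, 9)))
  tr <- simulate_tree(cfg, 9)
  expect_identical(simulate_trait(tr, cfg, 9), simulate_trait(tr, cfg, 9))
  traits <- simulate_trait(tr, cfg, 9)
  expect_identical(simulate_proteomes(traits, cfg, 9),
                   simulate_proteomes(traits, cfg, 9))
  cx1 <- simulate_complex("KRAST", sim_config(n_species = 2), 9)
  cx2 <- simulate_complex("KRAST", sim_config(n_species = 2), 9)
  expect_identical(cx1, cx2)
})

test_that("tree simulation yields positive branch lengths and the cherry base case", {
  tr <- simulate_tree(sim_config(n_species = 2), seed = 61)
  expect_equal(ape::Ntip(tr), 2)
  big <- simulate_tree(sim_config(n_species = 64), seed = 61)
  expect_equal(ape::Ntip(big), 64)
  expect_true(all(big$edge.length > 0))
  expect_true(ape::is.binary(big))
})

test_that("trait evolution respects the switch rate limits", {
  cfg0 <- sim_config(n_species = 32, trait_switch_rate = 0)
  tr <- simulate_tree(cfg0, seed = 62)
  tr0 <- simulate_trait(tr, cfg0, seed = 62)
  expect_true(all(tr0$binary_class == "mesophile"))

  # very fast switching forgets the root state: ~50/50 across many sims
  cfg_hot <- sim_config(n_species = 32, trait_switch_rate = 50)
  frac <- mean(vapply(1:60, function(s) {
    mean(simulate_trait(tr, cfg_hot, s)$binary_class == "thermophile")
  }, numeric(1)))
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)
})

test_that("proteome composition shifts by the configured effect", {
  tr <- simulate_tree(sim_config(n_species = 2), seed = 63)
  traits <- tibble::tibble(species_id = tr$tip.label,
                           binary_class = factor(c("mesophile", "thermophile"),
                                                 levels = c("mesophile",
                                                            "thermophile")))
  # null: zero effect, expected compositions equal
  cfg0 <- sim_config(n_species = 2, n_proteins = 4, thermo_effect = c(R = 0),
                     protein_lengths = 400)
  diffs <- vapply(1:40, function(s) {
    seqs <- simulate_proteomes(traits, cfg0, s)
    p <- pool_composition(aa_composition(seqs))
    p$proportion[p$residue == "R" & p$species_id == tr$tip.label[2]] -
      p$proportion[p$residue == "R" & p$species_id == tr$tip.label[1]]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.005)

  # planted: +0.03 on R shows up as ~ +0.03 mean difference
  cfg3 <- sim_config(n_species = 2, n_proteins = 4,
                     thermo_effect = c(R = 0.03, S = -0.015, T = -0.015),
                     protein_lengths = 400)
  diffs3 <- vapply(1:60, function(s) {
    seqs <- simulate_proteomes(traits, cfg3, s)
    p <- pool_composition(aa_composition(seqs))
    p$proportion[p$residue == "R" & p$species_id == tr$tip.label[2]] -
      p$proportion[p$residue == "R" & p$species_id == tr$tip.label[1]]
  }, numeric(1))
  expect_lt(abs(mean(diffs3) - 0.03), 0.01)
})

test_that("gap injection adds gaps without touching residue proportions", {
  tr <- simulate_tree(sim_config(n_species = 4), seed = 64)
  traits <- simulate_trait(tr, sim_config(n_species = 4), seed = 64)
  cfg <- sim_config(n_species = 4, n_proteins = 2, gap_rate = 0.15)
  seqs <- simulate_proteomes(traits, cfg, seed = 64)
  expect_true(any(grepl("-", seqs$aligned_seq, fixed = TRUE)))
  expect_true(all(seqs$length < nchar(seqs$aligned_seq)))
  comp <- aa_composition(seqs)
  sums <- comp %>% dplyr::group_by(species_id, protein_name) %>%
    dplyr::summarise(s = sum(proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("unbiased contact planting gives CEF near 1; bias inflates K and R", {
  cfg1 <- sim_config(n_species = 2, contact_fraction = 0.3,
                     positive_contact_bias = 1)
  cfg5 <- sim_config(n_species = 2, contact_fraction = 0.3,
                     positive_contact_bias = 5)
  mean_cef <- function(cfg, n_rep) {
    vals <- vapply(seq_len(n_rep), function(s) {
      seq <- random_seq(150, seed = 7000 + s)
      cx <- simulate_complex(seq, cfg, seed = s)
      det <- contact_residues(cx$atoms, "A", "B")
      tab <- cef_table(make_seqs(list("x", "S4", seq)),
                       tibble::tibble(species_id = "x", protein_name = "S4",
                                      residue = det$residue))
      mean(tab$cef[tab$residue %in% c("K", "R")], na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }
  expect_equal(mean_cef(cfg1, 40), 1, tolerance = 0.1)
  expect_gt(mean_cef(cfg5, 20), 1.5)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(sim_config(birth_rate = 0), "rates")
  expect_error(sim_config(thermo_effect = c(S = -0.2)), "frequency")
  expect_error(sim_config(thermo_effect = c(J = 0.01)), "unknown residue")
  expect_error(sim_config(contact_fraction = 0), "contact_fraction")
  expect_error(sim_config(positive_contact_bias = -2), "positive_contact_bias")
  expect_error(simulate_complex("KR-ST", sim_config(), 1), "ungapped")
})
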