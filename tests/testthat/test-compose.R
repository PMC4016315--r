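# Sequence input, composition, net charge and temperature classes.

test_that("read_msa round-trips generator output and parses headers", {
  cfg <- sim_config(n_species = 50, n_proteins = 1, protein_lengths = 40)
  st <- simulate_study(cfg, seed = 11)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_msa(st$seqs, f)
  back <- read_msa(f)
  expect_equal(back$species_id, st$seqs$species_id)
  expect_equal(back$protein_name, st$seqs$protein_name)
  expect_equal(back$aligned_seq, st$seqs$aligned_seq)
  expect_equal(back$length, st$seqs$length)

  # byte-level round trip: writing what we read reproduces the file
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("read_msa rejects ragged alignments, bad characters and S1", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|S2", "ACDEFGHIKL", ">b|S2", "ACDEFGHIKLM"), f)
  expect_error(read_msa(f), "not aligned")

  writeLines(c(">a|S2", "ACDE7GHIKL"), f)
  expect_error(read_msa(f), "illegal sequence character")

  writeLines(c(">a|S1", "ACDEFGHIKL"), f)
  expect_error(read_msa(f), "S1")
})

test_that("composition handles gaps, trivial cases and matches a counting oracle", {
  comp <- aa_composition(make_seqs(list("x", "S2", "AAAA")))
  expect_equal(comp$proportion[comp$residue == "A"], 1)
  expect_equal(sum(comp$proportion), 1)

  comp <- aa_composition(make_seqs(list("x", "S2", "KK--RR")))
  expect_equal(comp$length[1], 4L)
  expect_equal(comp$proportion[comp$residue == "K"], 0.5)
  expect_equal(comp$proportion[comp$residue == "R"], 0.5)

  expect_error(aa_composition(make_seqs(list("x", "S2", "----"))), "all-gap")

  # brute-force letter-counting oracle on a random 200-mer
  s <- random_seq(200, seed = 42)
  comp <- aa_composition(make_seqs(list("x", "S2", s)))
  letters_s <- strsplit(s, "")[[1]]
  for (res in AA_ALPHABET) {
    expect_equal(comp$count[comp$residue == res], sum(letters_s == res))
  }
  expect_equal(comp$proportion, comp$count / 200)
})

test_that("composition proportions sum to 1 and are gap-insertion invariant", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_seq(sample(10:300, 1))
    comp <- aa_composition(make_seqs(list("x", "S2", s)))
    expect_equal(sum(comp$proportion), 1, tolerance = 1e-9)

    # sprinkle gaps anywhere: proportions unchanged
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch) + 1, 5, replace = TRUE)
    gapped <- ch
    for (p in sort(pos, decreasing = TRUE)) gapped <- append(gapped, "-", p - 1)
    comp_g <- aa_composition(make_seqs(list("x", "S2", paste(gapped, collapse = ""))))
    expect_equal(comp_g$proportion, comp$proportion)
  }
})

test_that("category composition partitions the alphabet and sums member fractions", {
  cats <- default_category_map()
  expect_setequal(unlist(cats), AA_ALPHABET)
  expect_length(unlist(cats), 20)

  s <- random_seq(150, seed = 9)
  comp <- aa_composition(make_seqs(list("x", "S2", s)))
  cc <- category_composition(comp, cats)
  expect_equal(sum(cc$proportion), 1, tolerance = 1e-9)
  for (cat in names(cats)) {
    expect_equal(cc$proportion[cc$category == cat],
                 sum(comp$proportion[comp$residue %in% cats[[cat]]]))
  }
  bad <- cats; bad$polar <- setdiff(bad$polar, "H")
  expect_error(category_composition(comp, bad), "partition")
})

test_that("net charge is (K+R)-(D+E), gap-blind and additive", {
  expect_equal(net_charge(make_seqs(list("x", "S2", "KRDE")))$net_charge, 0L)
  expect_equal(net_charge(make_seqs(list("x", "S2", "KKRR")))$net_charge, 4L)

  set.seed(3)
  for (i in 1:10) {
    a <- random_seq(100)
    b <- random_seq(60)
    nc <- function(s) net_charge(make_seqs(list("x", "S2", s)))$net_charge
    # counting oracle
    la <- strsplit(a, "")[[1]]
    expect_equal(nc(a), sum(la %in% c("K", "R")) - sum(la %in% c("D", "E")))
    # additivity under concatenation
    expect_equal(nc(paste0(a, b)), nc(a) + nc(b))
  }
})

test_that("temperature classification collapses the three cooler categories", {
  expect_equal(as.character(classify_temperature(c(37, 75, 50))),
               c("mesophile", "thermophile", "mesophile"))
  expect_equal(as.character(classify_temperature(
    c("cryophile", "lower_mesophile", "upper_mesophile", "thermophile"))),
    c("mesophile", "mesophile", "mesophile", "thermophile"))
  expect_error(classify_temperature("hyperthermophile"), "unknown")
  expect_error(classify_temperature(NaN), "finite")

  expect_equal(as.character(temperature_category(c(5, 10, 34.9, 35, 50, 50.1))),
               c("cryophile", "lower_mesophile", "lower_mesophile",
                 "upper_mesophile", "upper_mesophile", "thermophile"))
})

test_that("default binding-order table has exactly six primary proteins", {
  bo <- default_binding_order()
  expect_equal(sum(bo$binding_order == "primary"), 6)
  expect_setequal(bo$protein_name, paste0("S", 2:21))
  expect_setequal(bo$protein_name[bo$binding_order == "primary"],
                  c("S4", "S7", "S8", "S15", "S17", "S20"))

  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bo, f)
  expect_equal(read_binding_order(f)$binding_order, bo$binding_order)
})

test_that("trait tables classify via temperature or category column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(species_id = c("a", "b"),
                                  optimal_temp = c(37, 80)), f)
  tr <- read_traits(f)
  expect_equal(as.character(tr$binary_class), c("mesophile", "thermophile"))
  readr::write_tsv(tibble::tibble(species_id = "a", category = "cryophile"), f)
  expect_equal(as.character(read_traits(f)$binary_class), "mesophile")
})
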