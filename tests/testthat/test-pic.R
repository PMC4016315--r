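# Tree handling and phylogenetic independent contrasts.

trait_tbl <- function(sp, cls, x) {
  tibble::tibble(species_id = sp,
                 binary_class = ifelse(cls == 1, "thermophile", "mesophile"),
                 x = x)
}

test_that("newick reading validates branch lengths and parses cherries", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1):0;", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(ape::Ntip(tr), 2)

  writeLines("(A:1,B", f)
  expect_error(read_newick(f), "parse error")

  writeLines("(A,B);", f)
  expect_error(read_newick(f), "branch length")
  expect_warning(tr0 <- read_newick(f, missing_branch_lengths = "zero"),
                 "assigning 0")
  expect_true(all(tr0$edge.length == 0))
})

test_that("generator trees round-trip through newick text", {
  tr <- simulate_tree(sim_config(n_species = 30), seed = 51)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  # identical tip-to-tip distances (topology + branch lengths preserved)
  lab <- tr$tip.label
  expect_equal(ape::cophenetic.phylo(back)[lab, lab],
               ape::cophenetic.phylo(tr)[lab, lab], tolerance = 1e-6)
  # canonical re-serialization is stable
  expect_identical(ape::write.tree(back), ape::write.tree(read_newick(f)))
})

test_that("pruning preserves tip-to-tip path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1.5,D:0.5):1);")
  expect_identical(prune_tree(tr, tr$tip.label), tr)

  cherry <- prune_tree(tr, c("A", "C"))
  expect_equal(sort(cherry$tip.label), c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(cherry)["A", "C"]),
               unname(ape::cophenetic.phylo(tr)["A", "C"]))

  expect_error(prune_tree(tr, c("A", "Z")), "not in tree")
  expect_error(prune_tree(tr, "A"), "at least 2")

  # distance-matrix oracle on random trees and random subsets
  set.seed(52)
  big <- simulate_tree(sim_config(n_species = 50), seed = 52)
  d_full <- ape::cophenetic.phylo(big)
  for (i in 1:5) {
    keep <- sample(big$tip.label, sample(3:20, 1))
    pruned <- prune_tree(big, keep)
    d_sub <- ape::cophenetic.phylo(pruned)
    expect_equal(d_sub[keep, keep], d_full[keep, keep], tolerance = 1e-10)
  }
})

test_that("a divergent cherry gives the two-taxon closed form", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  cs <- pic_contrasts(trait_tbl(c("A", "B"), c(1, 0), c(3, 5)), tr, x)
  expect_equal(attr(cs, "N"), 1L)
  expect_equal(cs$raw, -2)              # thermophile minus mesophile
  expect_equal(cs$variance, 2)
  expect_equal(cs$standardized, -2 / sqrt(2))
  expect_equal(cs$set_label, "sister_taxa")
})

test_that("a uniform binary trait yields zero contrasts, not an error", {
  tr <- simulate_tree(sim_config(n_species = 8), seed = 53)
  cs <- pic_contrasts(trait_tbl(tr$tip.label, rep(0, 8), rnorm(8)), tr, x)
  expect_equal(attr(cs, "N"), 0L)
  tests <- contrast_tests(cs)
  expect_match(tests$note[1], "fewer than 2")
  expect_match(tests$note[2], "no contrasts")
})

test_that("a hand-executed pruning pass on a 4-tip tree is reproduced", {
  # ((A:1,B:1):1,(C:1,D:1):1); thermophile = A only
  # node AB: y diverges (1 vs 0): raw = x_A - x_B, var = 2
  #   ancestral x_AB = (x_A+x_B)/2, adjusted branch = 1 + 0.5 = 1.5
  # node CD: no divergence; x_CD = (x_C+x_D)/2, branch = 1.5
  # root: y_AB = 0.5 vs y_CD = 0 -> diverges:
  #   raw = x_AB - x_CD, var = 1.5 + 1.5 = 3
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cs <- pic_contrasts(trait_tbl(c("A", "B", "C", "D"), c(1, 0, 0, 0),
                                c(4, 2, 1, 3)), tr, x)
  expect_equal(attr(cs, "N"), 2L)
  std <- sort(cs$standardized)
  expect_equal(std, sort(c((4 - 2) / sqrt(2), (3 - 2) / sqrt(3))))
  expect_setequal(cs$set_label, c("sister_taxa", "paraphyletic"))
})

test_that("standardized magnitudes agree with the classic contrasts algorithm", {
  # with a fully divergent trait every node contributes, so |contrasts|
  # must match ape's implementation up to order and sign conventions
  tr <- simulate_tree(sim_config(n_species = 12), seed = 54)
  set.seed(54)
  x <- rnorm(12)
  names(x) <- tr$tip.label
  y <- rep(c(1, 0), 6)  # alternate classes so many nodes diverge
  cs <- pic_contrasts(trait_tbl(tr$tip.label, y, unname(x)), tr, x)
  ref <- ape::pic(x, tr)
  expect_true(all(
    vapply(abs(cs$standardized), function(v)
      any(abs(abs(ref) - v) < 1e-9), logical(1))
  ))
})

test_that("contrast tests delegate to the t and sign machinery", {
  cs <- structure(tibble::tibble(node = 1:4, raw = c(1, 1, 1, -1),
                                 variance = rep(1, 4),
                                 standardized = c(1, 1, 1, -1),
                                 set_label = "sister_taxa"),
                  N = 4L, n_tips = 5L,
                  class = c("pic_contrasts", "tbl_df", "tbl", "data.frame"))
  tests <- contrast_tests(cs)
  expect_equal(tests$p_value[2], sign_test(3, 4)$p_value)
  expect_equal(tests$statistic[1], one_sample_t(c(1, 1, 1, -1), 0)$statistic)

  cs0 <- structure(tibble::tibble(node = 1:3, raw = 0, variance = 1,
                                  standardized = 0, set_label = "sister_taxa"),
                   N = 3L, n_tips = 4L,
                   class = c("pic_contrasts", "tbl_df", "tbl", "data.frame"))
  t0 <- contrast_tests(cs0)
  expect_equal(t0$statistic[1], 0)
  expect_equal(t0$p_value[2], 1)  # 0 of 3 positive ... capped two-tailed
})

test_that("pic on a pre-pruned tree equals pic with internal pruning", {
  big <- simulate_tree(sim_config(n_species = 40), seed = 55)
  set.seed(55)
  keep <- sample(big$tip.label, 15)
  d <- trait_tbl(keep, rbinom(15, 1, 0.5), rnorm(15))
  a <- pic_contrasts(d, big, x)
  b <- pic_contrasts(d, prune_tree(big, keep), x)
  expect_equal(tidy(a)$standardized, tidy(b)$standardized)
})

test_that("polytomies are resolved deterministically with floored branches", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  d <- trait_tbl(c("A", "B", "C", "D"), c(1, 1, 0, 0), c(5, 6, 1, 2))
  cs1 <- pic_contrasts(d, tr, x)
  cs2 <- pic_contrasts(d, tr, x)
  expect_identical(tidy(cs1), tidy(cs2))
  expect_true(all(is.finite(cs1$standardized)))
  expect_true(all(cs1$variance > 0))
})

test_that("tidy, glance and autoplot work on contrast sets", {
  st <- simulate_study(sim_config(n_species = 24, n_proteins = 2), seed = 56)
  pooled <- pool_composition(aa_composition(st$seqs)) %>%
    dplyr::filter(residue == "K") %>%
    dplyr::left_join(st$traits, by = "species_id")
  cs <- pic_contrasts(pooled, st$tree, proportion)
  td <- tidy(cs)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "pic_contrasts"))
  gl <- glance(cs)
  expect_equal(gl$N, attr(cs, "N"))
  expect_s3_class(autoplot(cs), "ggplot")
  expect_output(print(cs), "independent contrasts|Independent contrasts")
})
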