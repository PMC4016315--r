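# Phylogenetic independent contrasts of a continuous variable at nodes
# where a binary trait diverges.
#
# Shared ancestry makes species values non-independent; Felsenstein's
# contrasts restore independence by differencing reconstructed values
# at tree nodes and standardizing by the square root of the summed
# (adjusted) daughter branch lengths. Here the binary temperature trait
# rides through the same pruning pass as a 0/1 continuous character: a
# node contributes a contrast exactly when its two daughter values of
# the binary trait differ, and the contrast of the continuous variable
# is oriented thermophile-minus-mesophile (larger binary value first),
# so a positive mean contrast means the variable is elevated in
# thermophiles.

#' Read a phylogeny from a Newick file
#'
#' Thin wrapper over [ape::read.tree()] that validates branch lengths.
#' Polytomies are preserved at this stage.
#'
#' @param path Newick file.
#' @param missing_branch_lengths `"error"` (default) or `"zero"` (assign
#'   0 with a warning).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, missing_branch_lengths = c("error", "zero")) {
  missing_branch_lengths <- arg_match(missing_branch_lengths)
  tree <- withCallingHandlers(
    tryCatch(ape::read.tree(path),
             error = function(e) abort(paste0("Newick parse error: ",
                                              conditionMessage(e)))),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(tree)) abort("Newick parse error: no tree in file.")
  if (is.null(tree$edge.length)) {
    if (missing_branch_lengths == "error") {
      abort("tree has no branch lengths (use missing_branch_lengths = \"zero\" to assign 0).")
    }
    warn("tree has no branch lengths; assigning 0.")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (missing_branch_lengths == "error") abort("missing branch length(s).")
    warn("missing branch length(s) assigned 0.")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) abort("negative branch length(s).")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels.")
  tree
}

#' Prune a tree to a set of species
#'
#' Drops all other tips; unary internal nodes left behind are collapsed
#' with their branch lengths summed, so every tip-to-tip path length is
#' preserved.
#'
#' @param tree An [ape::phylo] tree.
#' @param keep Character vector of tip labels to retain (>= 2).
#' @return The pruned tree.
#' @export
prune_tree <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2) abort("must keep at least 2 tips.")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Independent contrasts at binary-trait-divergent nodes
#'
#' Runs one Felsenstein pruning pass over the tree for the continuous
#' variable and for the binary trait treated as a 0/1 continuous
#' character (mesophile = 0, thermophile = 1), and collects the
#' standardized contrast of the continuous variable at every node whose
#' two daughter values of the binary trait differ (by more than 1e-9
#' after reconstruction). Polytomies are resolved deterministically to
#' zero-length binary branches first; zero-length branches are floored
#' at `min_branch` to keep contrast variances positive. With a uniform
#' binary trait the result is an empty contrast set, not an error.
#'
#' @param data Data frame with one row per species.
#' @param tree An [ape::phylo] tree whose tips cover `data`'s species;
#'   extra tips are pruned away.
#' @param value Column of `data` holding the continuous variable
#'   (tidy-eval).
#' @param class Column holding the binary trait: a factor/character with
#'   levels mesophile/thermophile, or 0/1 numerics (tidy-eval; default
#'   `binary_class`).
#' @param species Column holding tip labels (default `species_id`).
#' @param min_branch Floor for zero-length branches (default 1e-8).
#' @return A `pic_contrasts` object: a tibble with one row per contrast
#'   (`node`, `raw`, `variance`, `standardized`, `set_label` -
#'   `sister_taxa` when both daughters are tips, else `paraphyletic`)
#'   and attributes `N` (contrast count) and `n_tips`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(A:1,B:1);")
#' d <- tibble::tibble(species_id = c("A", "B"),
#'                     binary_class = c("thermophile", "mesophile"),
#'                     x = c(3, 5))
#' pic_contrasts(d, tr, x)   # one contrast, (3 - 5)/sqrt(2)
pic_contrasts <- function(data, tree, value, class = binary_class,
                          species = species_id, min_branch = 1e-8) {
  sp <- dplyr::pull(data, {{ species }})
  x <- dplyr::pull(data, {{ value }})
  y <- dplyr::pull(data, {{ class }})
  if (anyDuplicated(sp)) abort("one row per species required.")
  if (anyNA(x) || anyNA(y)) abort("missing trait values.")
  if (is.factor(y) || is.character(y)) {
    y <- as.integer(as.character(y) == "thermophile")
  }
  if (!all(y %in% c(0, 1))) abort("`class` must be binary (0/1 or mesophile/thermophile).")

  tree <- prune_tree(tree, sp)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  ord <- match(tree$tip.label, sp)
  xv <- c(x[ord], rep(NA_real_, nnode))
  yv <- c(as.numeric(y[ord]), rep(NA_real_, nnode))

  tree <- stats::reorder(tree, "postorder")
  edge <- tree$edge
  el <- pmax(tree$edge.length, min_branch)
  badj <- numeric(ntip + nnode)
  badj[edge[, 2]] <- el

  parents <- unique(edge[, 1])  # postorder: children before parents
  res <- vector("list", length(parents))
  for (k in seq_along(parents)) {
    nd <- parents[k]
    ch <- edge[edge[, 1] == nd, 2]
    b <- badj[ch]
    ydiff <- yv[ch[1]] - yv[ch[2]]
    if (abs(ydiff) > 1e-9) {
      hi <- if (ydiff > 0) 1L else 2L
      lo <- 3L - hi
      raw <- xv[ch[hi]] - xv[ch[lo]]
      v <- b[1] + b[2]
      res[[k]] <- tibble(
        node = as.integer(nd), raw = raw, variance = v,
        standardized = raw / sqrt(v),
        set_label = if (all(ch <= ntip)) "sister_taxa" else "paraphyletic"
      )
    }
    w <- 1 / b
    xv[nd] <- sum(xv[ch] * w) / sum(w)
    yv[nd] <- sum(yv[ch] * w) / sum(w)
    badj[nd] <- badj[nd] + b[1] * b[2] / (b[1] + b[2])
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(node = integer(), raw = numeric(), variance = numeric(),
                  standardized = numeric(), set_label = character())
  }
  structure(out, N = nrow(out), n_tips = ntip,
            class = c("pic_contrasts", base::class(out)))
}

#' Inference on a set of independent contrasts
#'
#' Two tests of the null of no association between the binary trait and
#' the variable: a one-sample t-test of the contrasts against mean 0
#' (df = N - 1) and the exact binomial sign test on the number of
#' positive contrasts among the non-zero ones (exact zeros are ties and
#' carry no direction; when every contrast is zero the sign test
#' returns p = 1). With N < 2 the t-test row is flagged
#' insufficient; the sign test is still computed for N >= 1.
#'
#' @param contrasts A `pic_contrasts` object.
#' @param use Test the `"standardized"` (default) or `"raw"` contrasts.
#' @return Two-row result tibble (methods `one_sample_t`, `sign_test`).
#' @export
contrast_tests <- function(contrasts, use = c("standardized", "raw")) {
  use <- arg_match(use)
  v <- contrasts[[use]]
  N <- length(v)
  t_row <- if (N >= 2) {
    one_sample_t(v, 0)
  } else {
    test_row("one_sample_t", n = N, note = "fewer than 2 contrasts")
  }
  n_nonzero <- sum(v != 0)
  s_row <- if (N < 1) {
    test_row("sign_test", n = 0L, note = "no contrasts")
  } else if (n_nonzero == 0) {
    test_row("sign_test", 0, p_value = 1, n = N,
             note = "all contrasts tied at zero")
  } else {
    sign_test(sum(v > 0), n_nonzero)
  }
  bind_rows(t_row, s_row)
}

#' @export
tidy.pic_contrasts <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.pic_contrasts <- function(x, ...) {
  tests <- contrast_tests(x)
  tibble(
    N = attr(x, "N"), n_tips = attr(x, "n_tips"),
    mean_contrast = if (nrow(x)) mean(x$standardized) else NA_real_,
    var_contrast = if (nrow(x) > 1) var(x$standardized) else NA_real_,
    t_statistic = tests$statistic[1], t_p = tests$p_value[1],
    n_positive = as.integer(tests$statistic[2]), sign_p = tests$p_value[2]
  )
}

#' @export
autoplot.pic_contrasts <- function(object, bins = 20, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$standardized)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = "standardized contrast (thermophile - mesophile)",
      y = "nodes",
      title = sprintf("%d independent contrasts", attr(object, "N"))
    )
}

#' @export
print.pic_contrasts <- function(x, ...) {
  cat(sprintf("Independent contrasts at binary-trait-divergent nodes: N = %d (%d tips)\n",
              attr(x, "N"), attr(x, "n_tips")))
  NextMethod()
}
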