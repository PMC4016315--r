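# Amino-acid composition, chemical-category composition and net charge.

aa_counts_one <- function(aligned_seq) {
  ch <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  tabulate(match(ch, AA_ALPHABET), nbins = 20L)
}

#' Per-sequence amino-acid composition
#'
#' Computes, for every sequence, the count and proportion of each of the
#' 20 amino acids among its ungapped residues. Gaps never contribute;
#' ambiguity codes (B, Z, X, U) are dropped from numerator and
#' denominator alike (a message reports how many were seen). Proportions
#' over each sequence sum to 1.
#'
#' @param seqs Tibble with columns `species_id`, `protein_name`,
#'   `aligned_seq` (as returned by [read_msa()]).
#' @return A long tibble: `species_id`, `protein_name`, `residue`,
#'   `count`, `length`, `proportion` - 20 rows per input sequence.
#' @export
#' @examples
#' seqs <- tibble::tibble(species_id = "sp1", protein_name = "S4",
#'                        aligned_seq = "KK--RR")
#' aa_composition(seqs)
aa_composition <- function(seqs) {
  validate_sequences(seqs$aligned_seq)
  L <- ungapped_length(seqs$aligned_seq)
  if (any(L == 0)) {
    abort(paste0("all-gap sequence(s) for: ",
                 paste(seqs$species_id[L == 0], collapse = ", ")))
  }
  n_amb <- nchar(seqs$aligned_seq) -
    nchar(gsub(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"), "",
               seqs$aligned_seq))
  if (sum(n_amb) > 0) {
    inform(paste0(sum(n_amb), " ambiguous residue(s) (B/Z/X/U) excluded from counts."))
  }
  counts <- vapply(seqs$aligned_seq, aa_counts_one, integer(20L), USE.NAMES = FALSE)
  tibble(
    species_id   = rep(seqs$species_id, each = 20L),
    protein_name = rep(seqs$protein_name, each = 20L),
    residue      = rep(AA_ALPHABET, times = nrow(seqs)),
    count        = as.integer(counts),
    length       = rep(L, each = 20L)
  ) %>%
    mutate(proportion = .data$count / .data$length)
}

#' Chemical-category composition
#'
#' Collapses a per-residue composition (from [aa_composition()]) into
#' the five chemical categories. Each category fraction is the sum of
#' its member residues' fractions, so the five fractions sum to 1.
#'
#' @param composition Long tibble from [aa_composition()].
#' @param categories Category map; see [default_category_map()].
#' @return Tibble: `species_id`, `protein_name`, `category`, `count`,
#'   `length`, `proportion`.
#' @export
category_composition <- function(composition, categories = default_category_map()) {
  check_category_map(categories)
  map <- tibble(
    residue = unlist(categories, use.names = FALSE),
    category = rep(names(categories), lengths(categories))
  )
  composition %>%
    left_join(map, by = "residue") %>%
    group_by(.data$species_id, .data$protein_name, .data$category,
             .data$length) %>%
    summarise(count = sum(.data$count), proportion = sum(.data$proportion),
              .groups = "drop") %>%
    mutate(category = factor(.data$category, levels = names(categories))) %>%
    arrange(.data$species_id, .data$protein_name, .data$category) %>%
    select("species_id", "protein_name", "category", "count", "length",
           "proportion")
}

#' Net charge of protein sequences
#'
#' Net charge at physiological pH is `(#K + #R) - (#D + #E)`: lysine and
#' arginine carry +1, aspartate and glutamate -1, all other residues are
#' treated as neutral. Gaps and ambiguity codes are ignored.
#'
#' @param seqs Tibble with `species_id`, `protein_name`, `aligned_seq`.
#' @return The input tibble (sequence column dropped) with a
#'   `net_charge` integer column added.
#' @export
#' @examples
#' net_charge(tibble::tibble(species_id = "x", protein_name = "S4",
#'                           aligned_seq = "KRDE"))$net_charge  # 0
net_charge <- function(seqs) {
  validate_sequences(seqs$aligned_seq)
  nc <- vapply(seqs$aligned_seq, function(s) {
    cnt <- aa_counts_one(s)
    names(cnt) <- AA_ALPHABET
    as.integer(cnt["K"] + cnt["R"] - cnt["D"] - cnt["E"])
  }, integer(1L), USE.NAMES = FALSE)
  seqs %>%
    select(-"aligned_seq") %>%
    mutate(net_charge = nc) %>%
    as_tibble()
}

#' Pool composition counts within species
#'
#' Sums residue counts over all of a species' proteins and recomputes
#' proportions from the pooled counts (equivalent to the composition of
#' the concatenated proteome), which is how per-species summaries feed
#' the cross-species tests.
#'
#' @param composition Long tibble from [aa_composition()].
#' @return Tibble: `species_id`, `residue`, `count`, `length`,
#'   `proportion`.
#' @export
pool_composition <- function(composition) {
  composition %>%
    distinct(.data$species_id, .data$protein_name, .data$length) %>%
    group_by(.data$species_id) %>%
    summarise(length = sum(.data$length), .groups = "drop") -> lens
  composition %>%
    group_by(.data$species_id, .data$residue) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    left_join(lens, by = "species_id") %>%
    mutate(proportion = .data$count / .data$length)
}
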