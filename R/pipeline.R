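# End-to-end analyses: each run_* function chains the elementary
# operations into one of the study's comparisons and returns tidy
# tibbles ready for readr::write_tsv().

#' Compare r-protein and non-ribosomal amino-acid compositions
#'
#' For each non-ribosomal protein family, pools each species'
#' r-protein composition and the family's composition, pairs them by
#' species (species missing from a family are dropped for that family)
#' and runs a per-residue paired t-test of the equality of the two
#' distributions. A positive t means the residue is more abundant in
#' the non-ribosomal family.
#'
#' @param rproteins Sequence tibble of r-proteins (all species, all
#'   proteins; see [read_msa()]).
#' @param families Named list of sequence tibbles, one per
#'   non-ribosomal family.
#' @return Tibble: `family`, `residue`, `statistic` (t), `df`,
#'   `p_value`, `n`, `mean_diff` (family minus r-protein).
#' @export
run_composition_comparison <- function(rproteins, families) {
  if (!length(families)) abort("need at least one non-ribosomal family.")
  if (is.null(names(families))) {
    names(families) <- paste0("family", seq_along(families))
  }
  rp <- pool_composition(aa_composition(rproteins))
  purrr::imap_dfr(families, function(fam, fam_name) {
    fp <- pool_composition(aa_composition(fam))
    shared <- intersect(unique(rp$species_id), unique(fp$species_id))
    if (length(shared) < 2) {
      abort(paste0("fewer than 2 overlapping species for family ", fam_name))
    }
    purrr::map_dfr(AA_ALPHABET, function(res) {
      a <- rp %>% filter(.data$residue == res,
                         .data$species_id %in% shared) %>%
        arrange(.data$species_id) %>% pull(.data$proportion)
      b <- fp %>% filter(.data$residue == res,
                         .data$species_id %in% shared) %>%
        arrange(.data$species_id) %>% pull(.data$proportion)
      paired_t(b, a) %>%
        mutate(family = fam_name, residue = res,
               mean_diff = mean(b - a), .before = 1L) %>%
        select(-"method", -"effect_size", -"note")
    })
  })
}

#' Thermophile/mesophile composition differences under PIC
#'
#' Pools each species' composition across its r-proteins, then for
#' every residue (and chemical category, and the species mean net
#' charge) computes independent contrasts of the proportion against
#' the binary temperature trait and both contrast tests. `significant`
#' flags variables where at least one of the two tests rejects at
#' `alpha` - the criterion used throughout the analysis.
#'
#' @param seqs Sequence tibble (all species x proteins).
#' @param tree Phylogeny covering the species.
#' @param traits Tibble with `species_id`, `binary_class`.
#' @param categories Chemical-category map.
#' @param alpha Significance level (default 0.01).
#' @return Tibble: `variable`, `level` (residue/category/net_charge),
#'   `N`, `mean_contrast`, `t_statistic`, `t_p`, `n_positive`,
#'   `sign_p`, `significant`.
#' @export
run_thermo_pic <- function(seqs, tree, traits,
                           categories = default_category_map(),
                           alpha = 0.01) {
  comp <- aa_composition(seqs)
  pooled <- pool_composition(comp)
  percat <- category_composition(comp, categories) %>%
    group_by(.data$species_id, .data$category) %>%
    summarise(count = sum(.data$count), length = sum(.data$length),
              .groups = "drop") %>%
    mutate(proportion = .data$count / .data$length)
  nch <- net_charge(seqs) %>%
    group_by(.data$species_id) %>%
    summarise(value = mean(.data$net_charge), .groups = "drop")

  wide <- bind_rows(
    pooled %>% select("species_id", variable = "residue", value = "proportion") %>%
      mutate(level = "residue"),
    percat %>% mutate(variable = as.character(.data$category)) %>%
      select("species_id", "variable", value = "proportion") %>%
      mutate(level = "category"),
    nch %>% mutate(variable = "net_charge", level = "net_charge")
  ) %>%
    left_join(traits %>% select("species_id", "binary_class"),
              by = "species_id")
  if (anyNA(wide$binary_class)) abort("traits missing for some species.")

  wide %>%
    group_by(.data$level, .data$variable) %>%
    dplyr::group_modify(function(d, key) {
      cs <- pic_contrasts(d, tree, value)
      pic_summary_row(cs, alpha)
    }) %>%
    ungroup()
}

pic_summary_row <- function(cs, alpha) {
  tests <- contrast_tests(cs)
  tibble(
    N = attr(cs, "N"),
    mean_contrast = if (nrow(cs)) mean(cs$standardized) else NA_real_,
    t_statistic = tests$statistic[1], t_p = tests$p_value[1],
    n_positive = as.integer(tests$statistic[2]), sign_p = tests$p_value[2],
    significant = isTRUE(tests$p_value[1] < alpha) |
      isTRUE(tests$p_value[2] < alpha)
  )
}

#' Contact-site composition and CEF across species
#'
#' From two reference species' structure-derived contact sets, finds
#' the shared contact columns of every protein's alignment, projects
#' them onto all species, aggregates counts to species level and tests
#' (i) per residue, whether CEF deviates from 1 across species
#' (one-sample t) and (ii) when a tree and traits are supplied,
#' thermophile/mesophile PIC differences in CEF and in contact
#' proportion Rc/C.
#'
#' @param seqs Sequence tibble (all species x proteins, references
#'   included).
#' @param ref1,ref2 Reference species ids.
#' @param contacts1,contacts2 Named lists (by `protein_name`) of
#'   `contact_set`s for the two references.
#' @param tree,traits Optional phylogeny and binary trait table for the
#'   PIC comparison.
#' @param alpha Significance level (default 0.01).
#' @return List of tibbles: `species_cef` (species-level counts and
#'   CEF), `cef_vs_one` (per-residue one-sample t against 1), and, when
#'   tree and traits are given, `pic_cef` and `pic_contact_proportion`.
#' @export
run_contact_cef <- function(seqs, ref1, ref2, contacts1, contacts2,
                            tree = NULL, traits = NULL, alpha = 0.01) {
  proteins <- intersect(names(contacts1), names(contacts2))
  if (!length(proteins)) abort("no proteins shared by the two contact lists.")
  contacts <- purrr::map_dfr(proteins, function(pn) {
    msa <- seqs %>% filter(.data$protein_name == pn)
    if (!all(c(ref1, ref2) %in% msa$species_id)) {
      warn(paste0("reference species missing from ", pn, "; protein skipped."))
      return(NULL)
    }
    cols <- shared_contact_columns(msa, ref1, ref2,
                                   contacts1[[pn]], contacts2[[pn]])
    project_contacts_all(msa, cols)
  })
  cef <- cef_table(seqs %>% filter(.data$protein_name %in% proteins),
                   contacts %>% select("species_id", "protein_name", "residue"))
  sp_cef <- aggregate_cef(cef, level = "species")

  cef_vs_one <- sp_cef %>%
    filter(.data$defined) %>%
    group_by(.data$residue) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2) return(test_row("one_sample_t", n = nrow(d),
                                       note = "fewer than 2 species"))
      one_sample_t(d$cef, 1)
    }) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)

  out <- list(species_cef = sp_cef, cef_vs_one = cef_vs_one)
  if (!is.null(tree) && !is.null(traits)) {
    joined <- sp_cef %>%
      left_join(traits %>% select("species_id", "binary_class"),
                by = "species_id")
    out$pic_cef <- pic_by_residue(joined, tree, "cef", alpha)
    out$pic_contact_proportion <- pic_by_residue(joined, tree,
                                                 "contact_proportion", alpha)
  }
  out
}

pic_by_residue <- function(joined, tree, col, alpha) {
  joined %>%
    filter(!is.na(.data[[col]])) %>%
    group_by(.data$residue) %>%
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$species_id)) < 3) {
        return(tibble(N = 0L, mean_contrast = NA_real_,
                      t_statistic = NA_real_, t_p = NA_real_,
                      n_positive = NA_integer_, sign_p = NA_real_,
                      significant = FALSE))
      }
      d$value <- d[[col]]
      cs <- pic_contrasts(d, tree, value)
      pic_summary_row(cs, alpha)
    }) %>%
    ungroup()
}

#' Correlations with protein size and binding order
#'
#' Per residue, the Spearman rank correlation between the cross-species
#' mean composition of each protein and its cross-species mean ungapped
#' length; plus, for the positive-residue fraction and net charge, the
#' correlation with binding-order rank (primary = 1 to tertiary = 3)
#' and a pooled-variance two-sample t of primary versus
#' secondary+tertiary proteins.
#'
#' @param seqs Sequence tibble (all species x proteins).
#' @param binding_order Tibble from [default_binding_order()] or
#'   [read_binding_order()].
#' @param categories Chemical-category map.
#' @return List of tibbles: `length_correlations` (per residue),
#'   `order_correlations` (positive fraction, net charge),
#'   `order_t_test` (primary vs rest).
#' @export
run_size_order_correlations <- function(seqs,
                                        binding_order = default_binding_order(),
                                        categories = default_category_map()) {
  if (length(unique(seqs$protein_name)) < 3) abort("need at least 3 proteins.")
  comp <- aa_composition(seqs)
  mean_len <- seqs %>%
    mutate(len = ungapped_length(.data$aligned_seq)) %>%
    group_by(.data$protein_name) %>%
    summarise(mean_length = mean(.data$len), .groups = "drop")
  mean_comp <- comp %>%
    group_by(.data$protein_name, .data$residue) %>%
    summarise(mean_prop = mean(.data$proportion), .groups = "drop") %>%
    left_join(mean_len, by = "protein_name")

  length_correlations <- mean_comp %>%
    group_by(.data$residue) %>%
    dplyr::group_modify(~ spearman_test(.x$mean_prop, .x$mean_length)) %>%
    ungroup() %>%
    select(-"method")

  pos <- categories$positive
  per_protein <- comp %>%
    filter(.data$residue %in% pos) %>%
    group_by(.data$species_id, .data$protein_name) %>%
    summarise(positive_prop = sum(.data$proportion), .groups = "drop") %>%
    left_join(net_charge(seqs), by = c("species_id", "protein_name")) %>%
    group_by(.data$protein_name) %>%
    summarise(positive_prop = mean(.data$positive_prop),
              net_charge = mean(.data$net_charge), .groups = "drop") %>%
    left_join(binding_order, by = "protein_name")
  if (anyNA(per_protein$binding_order)) {
    abort("binding order missing for some proteins.")
  }
  rank_order <- as.integer(per_protein$binding_order)

  order_correlations <- bind_rows(
    spearman_test(per_protein$positive_prop, rank_order) %>%
      mutate(variable = "positive_prop", .before = 1L),
    spearman_test(per_protein$net_charge, rank_order) %>%
      mutate(variable = "net_charge", .before = 1L)
  ) %>% select(-"method")

  is_primary <- per_protein$binding_order == "primary"
  order_t_test <- two_sample_t(per_protein$positive_prop[is_primary],
                               per_protein$positive_prop[!is_primary]) %>%
    mutate(variable = "positive_prop", .before = 1L)

  list(length_correlations = length_correlations,
       order_correlations = order_correlations,
       order_t_test = order_t_test)
}
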