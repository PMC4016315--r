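# The Contact Enrichment Factor:
#
#   CEF = (Rc / C) / (Rt / L)
#
# Rc = contact residues of a given type, C = total contact residues,
# Rt = residues of that type in the protein, L = protein length.
# CEF > 1 marks a residue type over-represented at the rRNA interface
# relative to its overall abundance; CEF = 1 marks indifference.

#' Per-residue contact proportions Rc/C
#'
#' @param contacts Tibble of contact residues with columns `species_id`,
#'   `protein_name`, `residue` (e.g. from [project_contacts_all()]), or
#'   a single `contact_set`.
#' @return Tibble per group and residue with `Rc`, `C` and
#'   `contact_proportion = Rc/C` (NA-flagged when `C = 0`). Proportions
#'   sum to 1 over the 20 residues in every group with `C > 0`.
#' @export
contact_proportions <- function(contacts) {
  grp <- intersect(c("species_id", "protein_name"), names(contacts))
  contacts %>%
    group_by(across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(~ contact_type_counts(.x)) %>%
    ungroup() %>%
    mutate(contact_proportion = ifelse(.data$C > 0, .data$Rc / .data$C, NA_real_))
}

#' Contact Enrichment Factor table
#'
#' Joins per-sequence residue totals (Rt, L) with contact counts
#' (Rc, C) and evaluates `CEF = (Rc/C)/(Rt/L)` for each of the 20
#' residues of each (species, protein) pair. Cells with `Rt = 0` or
#' `C = 0` are undefined: their `cef` is `NA` and `defined` is `FALSE`;
#' they are excluded from (not imputed into) downstream tests.
#'
#' @param seqs Sequence tibble ([read_msa()] rows) supplying Rt and L.
#' @param contacts Contact-residue tibble (`species_id`, `protein_name`,
#'   `residue`), one row per contact residue.
#' @return Tibble: `species_id`, `protein_name`, `residue`, `Rt`, `Rc`,
#'   `L`, `C`, `contact_proportion`, `cef`, `defined`.
#' @export
#' @examples
#' seqs <- tibble::tibble(species_id = "x", protein_name = "S4",
#'                        aligned_seq = "KKAAAAAASS")
#' contacts <- tibble::tibble(species_id = "x", protein_name = "S4",
#'                            residue = c("K", "K", "A", "S"))
#' cef_table(seqs, contacts)  # CEF(K) = (2/4)/(2/10) = 2.5
cef_table <- function(seqs, contacts) {
  comp <- aa_composition(seqs) %>%
    select("species_id", "protein_name", "residue", Rt = "count",
           L = "length")
  cc <- contacts %>%
    group_by(.data$species_id, .data$protein_name, .data$residue) %>%
    summarise(Rc = dplyr::n(), .groups = "drop")
  comp %>%
    left_join(cc, by = c("species_id", "protein_name", "residue")) %>%
    mutate(Rc = ifelse(is.na(.data$Rc), 0L, .data$Rc)) %>%
    group_by(.data$species_id, .data$protein_name) %>%
    mutate(C = as.integer(sum(.data$Rc))) %>%
    ungroup() %>%
    finish_cef()
}

finish_cef <- function(tbl) {
  tbl %>%
    mutate(
      contact_proportion = ifelse(.data$C > 0, .data$Rc / .data$C, NA_real_),
      defined = .data$Rt > 0 & .data$C > 0,
      cef = ifelse(.data$defined,
                   (.data$Rc / .data$C) / (.data$Rt / .data$L), NA_real_)
    )
}

#' Aggregate CEF tables across proteins
#'
#' Species-level (or fully pooled) CEF. The default pools counts -
#' summing Rc, C, Rt and L over the group and re-evaluating the ratio,
#' equivalent to computing CEF on the concatenated pseudo-protein -
#' because CEF is a ratio of proportions and averaging per-protein
#' ratios is not the same quantity. `mode = "average"` provides the
#' ratio-averaging alternative for comparison.
#'
#' @param cef Tibble from [cef_table()].
#' @param level `"species"` (default; one table per species) or
#'   `"pooled"` (one table overall).
#' @param mode `"pool"` (sum counts, default) or `"average"` (mean of
#'   defined per-protein CEFs).
#' @return Tibble with the same statistic columns at the chosen level.
#' @export
aggregate_cef <- function(cef, level = c("species", "pooled"),
                          mode = c("pool", "average")) {
  level <- arg_match(level)
  mode <- arg_match(mode)
  grp <- if (level == "species") c("species_id", "residue") else "residue"
  if (mode == "pool") {
    lens <- cef %>%
      distinct(.data$species_id, .data$protein_name, .data$L, .data$C) %>%
      group_by(across(dplyr::all_of(setdiff(grp, "residue")))) %>%
      summarise(L = sum(.data$L), C = as.integer(sum(.data$C)),
                .groups = "drop")
    out <- cef %>%
      group_by(across(dplyr::all_of(grp))) %>%
      summarise(Rt = sum(.data$Rt), Rc = as.integer(sum(.data$Rc)),
                .groups = "drop")
    out <- if (length(setdiff(grp, "residue"))) {
      left_join(out, lens, by = setdiff(grp, "residue"))
    } else {
      mutate(out, L = lens$L, C = lens$C)
    }
    finish_cef(out)
  } else {
    cef %>%
      filter(.data$defined) %>%
      group_by(across(dplyr::all_of(grp))) %>%
      summarise(cef = mean(.data$cef), n_proteins = dplyr::n(),
                .groups = "drop")
  }
}
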