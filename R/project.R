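# Cross-species projection of structure-derived contact sites through
# the per-protein alignment.

#' Alignment columns contacted in both reference species
#'
#' The structure-derived contact sites of the two reference species
#' (E. coli and T. thermophilus in the canonical analysis) are mapped to
#' alignment columns; a column qualifies only when both references have
#' a residue (not a gap) there and both residues are contact residues.
#' The resulting shared columns are a deliberately conservative
#' definition of the rRNA interface that can be carried to every other
#' species in the alignment.
#'
#' @param msa Tibble from [read_msa()] for one protein.
#' @param ref1,ref2 Species ids of the two reference species in `msa`.
#' @param contacts1,contacts2 Their `contact_set`s from
#'   [contact_residues()]; `position` is the 1-based ungapped residue
#'   index.
#' @return Sorted integer vector of 1-based alignment columns.
#' @export
shared_contact_columns <- function(msa, ref1, ref2, contacts1, contacts2) {
  cols1 <- positions_to_columns(msa, ref1, contacts1$position)
  cols2 <- positions_to_columns(msa, ref2, contacts2$position)
  sort(intersect(cols1, cols2))
}

positions_to_columns <- function(msa, species, positions) {
  row <- msa %>% filter(.data$species_id == species)
  if (nrow(row) == 0) {
    abort(paste0("reference species not in alignment: ", species))
  }
  cmap <- column_position_map(row$aligned_seq[1])
  if (length(positions) && max(positions) > max(cmap, 0, na.rm = TRUE)) {
    abort("contact position beyond the reference sequence length.")
  }
  which(cmap %in% positions)
}

#' Project shared contact columns onto one species
#'
#' Designates as contact sites the species' residues at the shared
#' alignment columns. Columns where the species has a gap (or an
#' ambiguity code) contribute nothing, so the per-species contact count
#' `C` never exceeds the number of shared columns.
#'
#' @param msa Tibble from [read_msa()] for one protein.
#' @param species Species id present in `msa`.
#' @param shared_cols Integer columns from [shared_contact_columns()].
#' @return A `contact_set` tibble: `column`, `position` (1-based
#'   ungapped index), `residue`.
#' @export
project_contacts <- function(msa, species, shared_cols) {
  row <- msa %>% filter(.data$species_id == species)
  if (nrow(row) == 0) abort(paste0("species not in alignment: ", species))
  ch <- strsplit(row$aligned_seq[1], "", fixed = TRUE)[[1]]
  cmap <- column_position_map(row$aligned_seq[1])
  keep <- shared_cols[!is.na(cmap[shared_cols])]
  out <- tibble(
    column = as.integer(keep),
    position = as.integer(cmap[keep]),
    residue = ch[keep]
  )
  new_contact_set(out)
}

#' Project shared contacts onto every species of an alignment
#'
#' @inheritParams project_contacts
#' @return Long tibble: `species_id`, `protein_name`, `column`,
#'   `position`, `residue` - one row per projected contact residue.
#' @export
project_contacts_all <- function(msa, shared_cols) {
  purrr::map_dfr(seq_len(nrow(msa)), function(i) {
    cs <- project_contacts(msa, msa$species_id[i], shared_cols)
    if (nrow(cs) == 0) return(NULL)
    as_tibble(cs) %>%
      mutate(species_id = msa$species_id[i],
             protein_name = msa$protein_name[i], .before = 1L)
  })
}
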