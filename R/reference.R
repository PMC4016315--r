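# Reference 30S crystal structures: chain bookkeeping and the
# interface electrostatics summary computed from them.

#' Chain maps for the two reference 30S crystal structures
#'
#' PDB accessions 2AVY (E. coli) and 1J5E (T. thermophilus) both hold
#' the 16S rRNA in chain A and the r-proteins in the following chains
#' (taken from the PDB annotations): 2AVY chains B-U are S2-S21; 1J5E
#' chains B-T are S2-S20 (T. thermophilus has the additional protein
#' THX rather than S21; it is not part of the S2-S21 analysis set).
#'
#' @return Named list per accession: `rna` (chain id) and `proteins`
#'   (named character vector, protein name -> chain id).
#' @export
reference_chain_maps <- function() {
  list(
    `2AVY` = list(rna = "A",
                  proteins = setNames(LETTERS[2:21], paste0("S", 2:21))),
    `1J5E` = list(rna = "A",
                  proteins = setNames(LETTERS[2:20], paste0("S", 2:20)))
  )
}

#' Fraction of contact residues that are positively charged
#'
#' Runs [contact_residues()] for every protein chain in a chain map
#' against the 16S chain and returns the pooled fraction of contact
#' residues that are lysine or arginine - the interface electrostatics
#' summary of a 30S structure.
#'
#' @param structure Atom tibble from [read_structure()].
#' @param chain_map One entry of [reference_chain_maps()] (fields `rna`
#'   and `proteins`), or a custom list of the same shape.
#' @param cutoff Contact cutoff in angstroms (default 3.5).
#' @return List: `fraction` (positive contacts / total contacts),
#'   `C_total`, and `per_protein` (tibble of per-protein counts).
#' @export
positive_contact_fraction <- function(structure, chain_map, cutoff = 3.5) {
  per <- purrr::imap_dfr(chain_map$proteins, function(ch, pn) {
    if (!any(structure$chain == ch & structure$moltype == "protein")) {
      return(NULL)
    }
    cs <- contact_residues(structure, ch, chain_map$rna, cutoff = cutoff)
    tibble(protein_name = pn, chain = ch,
           C = nrow(cs),
           positive = sum(cs$residue %in% c("K", "R")))
  })
  if (nrow(per) == 0 || sum(per$C) == 0) {
    abort("no contacts found for any protein chain.")
  }
  list(fraction = sum(per$positive) / sum(per$C),
       C_total = sum(per$C), per_protein = per)
}
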