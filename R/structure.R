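# PDB structure input and protein-rRNA contact detection.

PROTEIN_RESID <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE",
                   "LYS", "LEU", "MET", "ASN", "PRO", "GLN", "ARG", "SER",
                   "THR", "VAL", "TRP", "TYR")
names(PROTEIN_RESID) <- AA_ALPHABET
RNA_RESID <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
               "ADE", "CYT", "GUA", "URA")

aa_three_to_one <- function(resid) {
  m <- setNames(AA_ALPHABET, PROTEIN_RESID)
  unname(m[toupper(resid)])
}

#' Read a PDB structure as an atom table
#'
#' Parses ATOM records via [bio3d::read.pdb()] into one tidy tibble of
#' atoms. HETATM records (waters, ions, ligands, modified nucleotides)
#' are excluded, as are hydrogens. When alternate locations are present,
#' only the highest-occupancy conformer of each atom is kept so results
#' do not depend on deposition bookkeeping. Chains are classified as
#' `protein`, `rna` or `other` from their residue names.
#'
#' @param path PDB file.
#' @return A tibble of atoms: `chain`, `resno`, `resid`, `elety`, `x`,
#'   `y`, `z`, `occupancy`, `moltype`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  at <- at %>% filter(.data$type == "ATOM")
  if (nrow(at) == 0) abort("no ATOM records in file.")
  # drop hydrogens (crystal structures of the 30S lack them; exclude for
  # reproducibility when present)
  elem <- if ("elesy" %in% names(at)) at$elesy else NA
  if (all(is.na(elem))) {
    elem <- sub("^[0-9]*", "", trimws(at$elety))
    elem <- substr(elem, 1, 1)
  }
  at <- at[!(toupper(trimws(elem)) %in% c("H", "D")), , drop = FALSE]
  # altloc: keep the highest-occupancy conformer per atom site
  at$o[is.na(at$o)] <- 1
  at <- at %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$elety) %>%
    arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    ungroup()
  at <- at %>%
    mutate(resid = toupper(trimws(.data$resid)),
           moltype = dplyr::case_when(
             .data$resid %in% PROTEIN_RESID ~ "protein",
             .data$resid %in% RNA_RESID ~ "rna",
             TRUE ~ "other"
           )) %>%
    select("chain", "resno", "resid", "elety", "x", "y", "z",
           occupancy = "o", "moltype") %>%
    arrange(.data$chain, .data$resno)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort("non-finite atom coordinates.")
  }
  at
}

#' Detect protein residues in contact with rRNA
#'
#' A residue is a contact residue when at least one of its atoms lies
#' within `cutoff` angstroms (inclusive) of any atom of the given RNA
#' chains - the all-atom 3.5 A rule. The default search uses a cell
#' list (cubic cells of edge `cutoff`, 27-cell neighbourhood); it is
#' contractually identical to the `"brute"` all-pairs scan, which is
#' retained as the independent reference.
#'
#' @param structure Atom tibble from [read_structure()].
#' @param protein_chain Single chain id holding the protein.
#' @param rna_chains Character vector of RNA chain ids.
#' @param cutoff Contact distance in angstroms (default 3.5, inclusive).
#' @param method `"grid"` (cell list, default) or `"brute"` (all pairs).
#' @return A `contact_set`: tibble with one row per contact residue
#'   (`chain`, `resno`, `position` - the 1-based ungapped residue index
#'   within the chain - and `residue`, the one-letter code), with
#'   attributes `C` (contact count), `protein_chain`, `cutoff`.
#' @export
contact_residues <- function(structure, protein_chain, rna_chains,
                             cutoff = 3.5, method = c("grid", "brute")) {
  method <- arg_match(method)
  if (!is.numeric(cutoff) || cutoff <= 0) abort("`cutoff` must be > 0.")
  ip <- structure$chain == protein_chain & structure$moltype == "protein"
  ir <- structure$chain %in% rna_chains & structure$moltype == "rna"
  if (!any(ip)) abort(paste0("no protein atoms in chain ", protein_chain, "."))
  if (!any(ir)) {
    abort(paste0("no RNA atoms in chain(s) ",
                 paste(rna_chains, collapse = ", "), "."))
  }
  prot <- structure[ip, ]
  rna <- structure[ir, ]
  hit <- if (method == "grid") {
    atoms_within_cutoff(prot$x, prot$y, prot$z, rna$x, rna$y, rna$z, cutoff)
  } else {
    brute_within_cutoff(prot, rna, cutoff)
  }
  u <- sort(unique(prot$resno))
  grp <- match(prot$resno, u)
  res_hit <- rowsum(as.integer(hit), grp)[, 1] > 0
  out <- tibble(
    chain = protein_chain,
    resno = u,
    position = seq_along(u),
    residue = aa_three_to_one(prot$resid[match(u, prot$resno)])
  )[res_hit, ]
  new_contact_set(out, protein_chain = protein_chain, cutoff = cutoff)
}

new_contact_set <- function(tbl, protein_chain = NA_character_,
                            cutoff = NA_real_) {
  structure(as_tibble(tbl),
            C = nrow(tbl),
            protein_chain = protein_chain,
            cutoff = cutoff,
            class = c("contact_set", class(as_tibble(tbl))))
}

# All-pairs reference scan, chunked over protein atoms.
brute_within_cutoff <- function(prot, rna, cutoff) {
  c2 <- cutoff^2
  rm <- cbind(rna$x, rna$y, rna$z)
  vapply(seq_len(nrow(prot)), function(i) {
    d2 <- (rm[, 1] - prot$x[i])^2 + (rm[, 2] - prot$y[i])^2 +
      (rm[, 3] - prot$z[i])^2
    any(d2 <= c2)
  }, logical(1L))
}

#' Tally contact residues by amino-acid type
#'
#' @param contacts A `contact_set` (or any tibble with a `residue`
#'   column of one-letter codes).
#' @return Tibble over all 20 residues: `residue`, `Rc` (count of
#'   contact residues of that type) and `C` (total contacts).
#' @export
contact_type_counts <- function(contacts) {
  Rc <- tabulate(match(contacts$residue, AA_ALPHABET), nbins = 20L)
  tibble(residue = AA_ALPHABET, Rc = as.integer(Rc), C = as.integer(sum(Rc)))
}
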