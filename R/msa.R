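# Aligned-FASTA input/output. One file per r-protein; headers follow the
# convention "<species_id>|<protein_name>".

#' Read a per-protein multiple sequence alignment
#'
#' Reads an aligned FASTA file of amino-acid sequences. All records must
#' share one alignment length. Headers are parsed as
#' `"<species_id>|<protein_name>"`; when the pipe is absent the whole
#' header becomes the species id and `protein_name` is taken from the
#' `protein` argument (or left `NA`). Protein S1 is rejected: it is an
#' atypical, loosely associated r-protein and is excluded from the
#' analysis.
#'
#' @param path Aligned FASTA file.
#' @param protein Optional protein name (e.g. `"S4"`) used when headers
#'   carry no protein field.
#' @return A tibble with columns `species_id`, `protein_name`,
#'   `aligned_seq` and `length` (ungapped residue count).
#' @export
read_msa <- function(path, protein = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(paste0("illegal sequence character(s) in ", path))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(set) == 0) abort("empty FASTA file.")
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    abort(paste0("records are not aligned: lengths ",
                 paste(sort(unique(widths)), collapse = ", ")))
  }
  hdr <- names(set)
  sp <- sub("\\|.*$", "", hdr)
  pr <- ifelse(grepl("\\|", hdr), sub("^[^|]*\\|", "", hdr),
               if (is.null(protein)) NA_character_ else protein)
  out <- tibble(
    species_id = sp,
    protein_name = pr,
    aligned_seq = unname(as.character(set))
  )
  validate_sequences(out$aligned_seq)
  if (any(!is.na(out$protein_name) & out$protein_name == "S1")) {
    abort("protein S1 is excluded from the analysis.")
  }
  out$length <- ungapped_length(out$aligned_seq)
  out
}

#' Write sequences to aligned FASTA
#'
#' Inverse of [read_msa()]: headers are `"<species_id>|<protein_name>"`.
#'
#' @param seqs Tibble with `species_id`, `protein_name`, `aligned_seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs$aligned_seq)
  names(set) <- paste0(seqs$species_id, "|", seqs$protein_name)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

validate_sequences <- function(seqs) {
  chars <- unique(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE))
  allowed <- c(AA_ALPHABET, AA_AMBIGUOUS, AA_GAP)
  bad <- setdiff(chars, allowed)
  if (length(bad)) {
    abort(paste0("illegal sequence character(s): ",
                 paste(sort(bad), collapse = " ")))
  }
  invisible(seqs)
}

#' Ungapped length of aligned sequences
#'
#' Counts standard residues only: gaps and ambiguity codes (B, Z, X, U)
#' do not contribute. This is the `L` used by composition proportions
#' and the Contact Enrichment Factor.
#'
#' @param seq Character vector of aligned sequences.
#' @return Integer vector.
#' @export
ungapped_length <- function(seq) {
  nchar(gsub("[BZXU.-]", "", seq))
}

# Map between alignment columns and ungapped residue positions for one
# aligned sequence. Returns an integer vector over columns: the 1-based
# ungapped index at that column, or NA where the sequence has a gap or
# an ambiguity code.
column_position_map <- function(aligned_seq) {
  ch <- strsplit(aligned_seq, "", fixed = TRUE)[[1]]
  is_res <- ch %in% AA_ALPHABET
  idx <- cumsum(is_res)
  idx[!is_res] <- NA_integer_
  idx
}
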