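# Shared fixture builders: everything is generated in code, nothing is
# read from disk except files the tests write themselves.

make_seqs <- function(...) {
  rows <- list(...)
  tibble::tibble(
    species_id = vapply(rows, `[[`, "", 1),
    protein_name = vapply(rows, `[[`, "", 2),
    aligned_seq = vapply(rows, `[[`, "", 3)
  )
}

# random ungapped sequence of length n
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(ribocef::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# bare-bones structure tibble: one atom per row
make_atoms <- function(chain, resno, resid, x, y, z, moltype,
                       elety = "CA") {
  tibble::tibble(chain = chain, resno = resno, resid = resid,
                 elety = elety, x = x, y = y, z = z, occupancy = 1,
                 moltype = moltype)
}

# random protein/RNA point clouds for oracle-equivalence checks
random_cloud_structure <- function(n_prot = 40, n_rna = 60, span = 25) {
  prot <- make_atoms("A", seq_len(n_prot),
                     sample(c("LYS", "ARG", "ALA", "SER", "GLY"), n_prot,
                            replace = TRUE),
                     runif(n_prot, 0, span), runif(n_prot, 0, span),
                     runif(n_prot, 0, span), "protein")
  rna <- make_atoms("B", seq_len(n_rna),
                    sample(c("A", "C", "G", "U"), n_rna, replace = TRUE),
                    runif(n_rna, 0, span), runif(n_rna, 0, span),
                    runif(n_rna, 0, span), "rna", elety = "P")
  dplyr::bind_rows(prot, rna)
}
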