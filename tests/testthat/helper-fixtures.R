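# Shared fixtures built in code; keep tests quiet.
options(devhet.verbose = FALSE)

# Small well-formed expression matrix.
tiny_expression <- function(n_genes = 3, n_stages = 4, species = "spX") {
  vals <- matrix(seq_len(n_genes * n_stages), n_genes, n_stages,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("s", seq_len(n_stages))))
  expression_matrix(vals * 1.0, species)
}

# Phase table constructed directly (bypasses clustering) for heterochrony
# unit tests.
phase_table <- function(species, gene_ids, phases, sub_phases = NULL) {
  out <- data.frame(gene_id = gene_ids, cluster = seq_along(gene_ids),
                    phase = phases,
                    sub_phase = if (is.null(sub_phases)) "none" else sub_phases,
                    stringsAsFactors = FALSE)
  class(out) <- c("GenePhaseTable", "data.frame")
  attr(out, "species_id") <- species
  out
}

# Two-species ortholog map where gene i of A pairs with gene i of B.
paired_map <- function(genes_a, genes_b, sp_a = "A", sp_b = "B") {
  n <- length(genes_a)
  ortholog_map(data.frame(
    group_id = rep(sprintf("og%03d", seq_len(n)), 2),
    species_id = rep(c(sp_a, sp_b), each = n),
    gene_id = c(genes_a, genes_b)
  ))
}

# Independent brute-force oracle for the C-terminal motif classifier:
# scan every 4-mer, record all SQ[DE][FY] occurrences, apply the window
# rule by direct position arithmetic.
oracle_classify <- function(seq, window = 5) {
  len <- nchar(seq)
  if (len < 4) return("none")
  best <- NA_integer_
  for (start in seq_len(len - 3L)) {
    mer <- substr(seq, start, start + 3L)
    if (substr(mer, 1, 1) == "S" && substr(mer, 2, 2) == "Q" &&
        substr(mer, 3, 3) %in% c("D", "E") && substr(mer, 4, 4) %in% c("F", "Y") &&
        start >= len - window + 1L) {
      best <- start
    }
  }
  if (is.na(best)) return("none")
  if (substr(seq, best + 3L, best + 3L) == "Y") "H2AX_Y" else "H2AX_F"
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], len, replace = TRUE),
        collapse = "")
}
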