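# Builders for small in-code fixtures shared across test files.

# An annotated candidate-site table with all quality attributes set
# explicitly; flank flags default to clear so filters under test are the
# ones being varied.
make_sites <- function(scaffold_id, positions, maf = 0.25, gr = 0.9,
                       qual = 30, design = 0.9, flank35 = TRUE,
                       flank40 = TRUE) {
  n <- length(positions)
  positions <- round(as.numeric(positions))
  scaffold_id <- rep_len(scaffold_id, n)
  data.frame(
    snp_id = sprintf("%s_p%.0f", scaffold_id, positions),
    scaffold_id = scaffold_id,
    position = positions,
    ref = rep_len("A", n), alt = rep_len("G", n),
    qual = rep_len(qual, n),
    maf = rep_len(maf, n),
    genotyping_rate = rep_len(gr, n),
    design_score = rep_len(design, n),
    flank_clear_35 = rep_len(flank35, n),
    flank_clear_40 = rep_len(flank40, n),
    stringsAsFactors = FALSE
  )
}

make_scaffolds <- function(lengths, chromosome = NA_character_) {
  data.frame(
    scaffold_id = sprintf("scaffold_%d", seq_along(lengths)),
    length = as.numeric(lengths),
    chromosome = rep_len(chromosome, length(lengths)),
    stringsAsFactors = FALSE
  )
}

# Genotype matrix with named dims from a vector/matrix of codes
make_geno <- function(codes, n_samples, n_snps) {
  m <- matrix(codes, nrow = n_samples, ncol = n_snps)
  rownames(m) <- sprintf("s%02d", seq_len(n_samples))
  colnames(m) <- sprintf("snp%04d", seq_len(n_snps))
  m
}

# Independent closed form for the location score used as an oracle:
# twice the distance to the nearer fragment end.
oracle_location_score <- function(S, E, a) {
  2 * pmin(a - S, E - a)
}
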