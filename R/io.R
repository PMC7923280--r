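# Readers and writers for the plain-text formats the pipeline touches:
# VCF 4.2 (via vcfR on the read side), FASTA-index-like scaffold tables,
# BED intervals, pedigree and design-score tables, panel manifests.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a scaffold index
#'
#' Tab-separated `scaffold_id`, `length`, `chromosome` (`.` when
#' unassigned), no header — the shape of a FASTA index with an extra
#' chromosome column.
#'
#' @param scaffolds Scaffold table.
#' @param path Output path.
#' @export
write_scaffold_index <- function(scaffolds, path) {
  df <- data.frame(
    scaffolds$scaffold_id,
    format(scaffolds$length, scientific = FALSE, trim = TRUE),
    ifelse(is.na(scaffolds$chromosome), ".", scaffolds$chromosome)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a scaffold index
#'
#' @param path Tab-separated file: scaffold id, length in bp, chromosome
#'   or `.`.
#' @return Data.frame `scaffold_id`, `length`, `chromosome` (NA when
#'   unassigned).
#' @export
read_scaffold_index <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("scaffold_id", "length", "chromosome"))
  df$length <- as.numeric(df$length)
  df$chromosome[df$chromosome == "."] <- NA_character_
  df
}

#' Read BED intervals
#'
#' Standard 0-based half-open BED; only the first four columns are used.
#'
#' @param path BED file path.
#' @return Data.frame `scaffold_id`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED needs at least 3 columns", call. = FALSE)
  out <- df[, 1:3]
  names(out) <- c("scaffold_id", "start", "end")
  out$name <- if (ncol(df) >= 4) as.character(df[[4]]) else
    sprintf("region_%d", seq_len(nrow(df)))
  out
}

#' Read a pedigree table
#'
#' @param path Tab-separated `progeny_id`, `sire_id`, `dam_id` with header.
#' @return Data.frame of the three id columns.
#' @export
read_pedigree <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("progeny_id", "sire_id", "dam_id") %in% names(df)))
  df[, c("progeny_id", "sire_id", "dam_id")]
}

#' Read a design-score table
#'
#' @param path Tab-separated `snp_id`, `design_score` with header.
#' @return Data.frame of the two columns.
#' @export
read_design_scores <- function(path) {
  df <- read_tsv(path)
  stopifnot(all(c("snp_id", "design_score") %in% names(df)))
  df
}

geno_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Write a VCF 4.2 callset
#'
#' Plain-text writer for the GT/DP/AD subset the simulator produces.
#' Records are sorted by scaffold (input scaffold order, then appearance
#' order) and 1-based position. Site QUAL is taken from a `qual` column
#' when present, `.` otherwise.
#'
#' @param sites Site table with `snp_id`, `scaffold_id`, `position`,
#'   `ref`, `alt` and optionally `qual`.
#' @param genotypes Samples x SNPs matrix coded 0/1/2/NA; column order
#'   must match `sites`.
#' @param path Output path.
#' @param scaffolds Optional scaffold table used for contig header lines
#'   and record ordering.
#' @param depth,alt_depth Optional samples x SNPs matrices adding DP and
#'   AD fields.
#' @export
write_vcf <- function(sites, genotypes, path, scaffolds = NULL,
                      depth = NULL, alt_depth = NULL) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(sites) || nrow(sites) == 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=alpacapanel", con)
  if (!is.null(scaffolds)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       scaffolds$scaffold_id, as.integer(scaffolds$length)), con)
  }
  writeLines(c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">'
  ), con)
  samples <- rownames(genotypes)
  if (is.null(samples)) samples <- sprintf("sample_%d", seq_len(nrow(genotypes)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(sites) == 0) return(invisible(path))

  scaf_levels <- if (!is.null(scaffolds)) scaffolds$scaffold_id else
    unique(sites$scaffold_id)
  ord <- order(match(sites$scaffold_id, scaf_levels), sites$position)
  has_dp <- !is.null(depth)
  fmt <- if (has_dp) "GT:DP:AD" else "GT"
  qual <- if ("qual" %in% names(sites)) {
    ifelse(is.na(sites$qual), ".", format(sites$qual, trim = TRUE))
  } else rep(".", nrow(sites))

  for (i in ord) {
    gt <- geno_to_gt(genotypes[, i])
    if (has_dp) {
      dp <- depth[, i]
      ad_alt <- if (!is.null(alt_depth)) alt_depth[, i] else rep(0L, length(dp))
      gt <- paste0(gt, ":", dp, ":", dp - ad_alt, ",", ad_alt)
    }
    writeLines(paste(c(sites$scaffold_id[i],
                       format(sites$position[i], scientific = FALSE, trim = TRUE),
                       sites$snp_id[i], sites$ref[i], sites$alt[i],
                       qual[i], "PASS", ".", fmt, gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF callset
#'
#' Parses a VCF through vcfR, keeping biallelic SNP records only;
#' multi-allelic records are excluded and counted. Positions stay
#' 1-based; missing GT becomes a missing code.
#'
#' @param path VCF path (plain or gzipped).
#' @return A list: `sites` (data.frame `snp_id`, `scaffold_id`,
#'   `position`, `ref`, `alt`, `qual`), `genotypes` (samples x SNPs
#'   matrix, 0/1/2/NA), `depth` and `alt_depth` (matrices or NULL), and
#'   `n_multiallelic` (count of excluded records).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(list(sites = data.frame(snp_id = character(0),
                                   scaffold_id = character(0),
                                   position = numeric(0), ref = character(0),
                                   alt = character(0), qual = numeric(0)),
                genotypes = NULL, depth = NULL, alt_depth = NULL,
                n_multiallelic = 0L))
  }
  biallelic <- !grepl(",", fix$ALT) & !is.na(fix$ALT)
  n_multi <- sum(!biallelic)
  keep <- which(biallelic)
  sites <- data.frame(
    snp_id = fix$ID[keep],
    scaffold_id = fix$CHROM[keep],
    position = as.numeric(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])),
    stringsAsFactors = FALSE
  )
  no_id <- is.na(sites$snp_id) | sites$snp_id == "."
  sites$snp_id[no_id] <- paste0(sites$scaffold_id[no_id], "_",
                                format(sites$position[no_id], trim = TRUE,
                                       scientific = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), sites$snp_id))
  gtn <- gsub("\\|", "/", gt)
  code_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (j in seq_len(nrow(gt))) {
    code[, j] <- unname(code_map[gtn[j, ]])
  }
  dp <- tryCatch({
    d <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
    t(d)
  }, error = function(e) NULL)
  ad_alt <- tryCatch({
    a <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
    alt <- suppressWarnings(apply(a, 2, function(x)
      as.numeric(vapply(strsplit(x, ","), function(p)
        if (length(p) >= 2) p[2] else NA_character_, ""))))
    if (is.null(dim(alt))) alt <- matrix(alt, nrow = 1) else alt <- t(alt)
    dimnames(alt) <- dimnames(code)
    alt
  }, error = function(e) NULL)
  if (!is.null(dp)) dimnames(dp) <- dimnames(code)
  list(sites = sites, genotypes = code, depth = dp, alt_depth = ad_alt,
       n_multiallelic = as.integer(n_multi))
}

#' Write a panel manifest
#'
#' Tab-separated, one row per selected SNP with stable column order:
#' snp_id, scaffold, 1-based position, set label, selection round,
#' fragment index, subfragment, location score, MAF, design score.
#'
#' @param panel Panel manifest data.frame from [assemble_panel()].
#' @param path Output path.
#' @export
write_panel_manifest <- function(panel, path) {
  cols <- c("snp_id", "scaffold_id", "position", "set_label", "round",
            "fragment_index", "subfragment", "location_score", "maf",
            "design_score")
  write_tsv(panel[, intersect(cols, names(panel))], path)
}

#' Read a panel manifest
#'
#' @param path Manifest path written by [write_panel_manifest()].
#' @return Data.frame of the manifest columns.
#' @export
read_panel_manifest <- function(path) {
  read_tsv(path)
}
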