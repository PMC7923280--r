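# Per-variant quality attributes and the staged selection filters.
#
# Each candidate SNP carries: site Phred quality, genotyping rate, minor
# allele frequency, a vendor design score in [0,1], and two flank-clear
# flags (no other SNP within 35 or 40 bp). Selection proceeds through
# rounds of decreasing stringency; round 1 is the strictest and later
# rounds relax only genotyping rate, MAF window and flank length.

#' Minor allele frequency of one SNP
#'
#' @param genotypes Vector of per-sample codes in \{0, 1, 2, NA\}.
#' @return `min(p, 1 - p)` where p is the ALT-allele frequency among
#'   non-missing calls.
#' @export
compute_maf <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) == 0) stop("MAF undefined: all genotypes missing", call. = FALSE)
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Genotyping rate of one SNP
#'
#' @param genotypes Vector of per-sample codes in \{0, 1, 2, NA\}.
#' @return Fraction of non-missing calls.
#' @export
compute_genotyping_rate <- function(genotypes) {
  stopifnot(length(genotypes) >= 1)
  mean(!is.na(genotypes))
}

#' Flag SNPs with clear flanking sequence
#'
#' A SNP's probe flanks extend `flank_len` bases each side; the flag is
#' TRUE iff no other SNP on the same scaffold lies within `flank_len` bp
#' (center-to-center distance `<= flank_len` fails). Only adjacent sites
#' can violate the rule, so sorted neighbours are checked.
#'
#' @param sites Site table with `scaffold_id`, `position`, sorted by
#'   position within scaffold.
#' @param flank_len Flank length in bp (35 or 40 for standard probes).
#' @return Logical vector aligned with `sites` rows.
#' @export
annotate_flanking <- function(sites, flank_len) {
  n <- nrow(sites)
  if (n == 0) return(logical(0))
  clear <- rep(TRUE, n)
  for (scaf in unique(sites$scaffold_id)) {
    idx <- which(sites$scaffold_id == scaf)
    pos <- sites$position[idx]
    if (is.unsorted(pos)) {
      stop("sites must be sorted by position within scaffold", call. = FALSE)
    }
    if (length(pos) < 2) next
    d <- diff(pos)
    near <- d <= flank_len
    bad <- rep(FALSE, length(pos))
    bad[which(near)] <- TRUE
    bad[which(near) + 1L] <- TRUE
    clear[idx] <- !bad
  }
  clear
}

#' Drop duplicate variant records
#'
#' Keeps at most one record per (scaffold, position); among duplicates
#' the record with the highest Phred quality survives (first encountered
#' on ties).
#'
#' @param sites Site table with `scaffold_id`, `position` and optionally
#'   `qual`.
#' @return The deduplicated site table, original ordering preserved.
#' @export
dedupe_variants <- function(sites) {
  if (nrow(sites) == 0) return(sites)
  key <- paste(sites$scaffold_id, sites$position)
  qual <- if ("qual" %in% names(sites)) sites$qual else rep(0, nrow(sites))
  qual[is.na(qual)] <- -Inf
  # stable max-by-quality per key: order by quality desc, keep first per key
  ord <- order(-qual, seq_len(nrow(sites)))
  keep_rows <- ord[!duplicated(key[ord])]
  sites[sort(keep_rows), , drop = FALSE]
}

#' One round of selection thresholds
#'
#' @param phred_min Site quality must be strictly greater than this.
#' @param gr_min Minimum genotyping rate (inclusive).
#' @param maf_min,maf_max Inclusive MAF window; `maf_max <= 0.5`.
#' @param design_min Minimum design score (inclusive).
#' @param flank_len Flank length whose clear-flag is required (35 or 40).
#' @return A `round_config` list.
#' @export
round_config <- function(phred_min = 10, gr_min = 0.45, maf_min = 0.05,
                         maf_max = 0.50, design_min = 0.60, flank_len = 40) {
  stopifnot(maf_min <= maf_max, maf_max <= 0.5, flank_len %in% c(35, 40))
  structure(list(phred_min = phred_min, gr_min = gr_min, maf_min = maf_min,
                 maf_max = maf_max, design_min = design_min,
                 flank_len = as.integer(flank_len)),
            class = "round_config")
}

#' The default six-round relaxation schedule
#'
#' Round 1 is the strictest (genotyping rate >= 0.45, MAF 0.05-0.50,
#' 40 bp flanks); later rounds relax genotyping rate to >= 0.15, widen
#' then shift the MAF window down to 0.01-0.039, and alternate 40/35 bp
#' flank lengths. Phred (> 10) and design score (>= 0.60) never relax.
#'
#' @return List of six [round_config()] objects.
#' @export
default_round_schedule <- function() {
  list(
    round_config(10, 0.45, 0.05, 0.50, 0.60, 40),
    round_config(10, 0.45, 0.05, 0.50, 0.60, 35),
    round_config(10, 0.15, 0.04, 0.50, 0.60, 40),
    round_config(10, 0.15, 0.04, 0.50, 0.60, 35),
    round_config(10, 0.15, 0.01, 0.039, 0.60, 40),
    round_config(10, 0.15, 0.01, 0.039, 0.60, 35)
  )
}

#' Annotate per-SNP quality attributes
#'
#' Computes MAF, genotyping rate and both flank-clear flags, and joins
#' design scores, producing the attribute-complete candidate table the
#' round filters consume.
#'
#' @param sites Site table (`snp_id`, `scaffold_id`, `position`, `qual`).
#' @param genotypes Samples x SNPs matrix aligned with `sites` by column.
#' @param scores Optional data.frame `snp_id`, `design_score`.
#' @return `sites` with columns `maf`, `genotyping_rate`, `design_score`,
#'   `flank_clear_35`, `flank_clear_40` added.
#' @export
annotate_sites <- function(sites, genotypes, scores = NULL) {
  stopifnot(ncol(genotypes) == nrow(sites))
  n <- nrow(sites)
  maf <- numeric(n); gr <- numeric(n)
  for (j in seq_len(n)) {
    gj <- genotypes[, j]
    gr[j] <- compute_genotyping_rate(gj)
    maf[j] <- if (all(is.na(gj))) NA_real_ else compute_maf(gj)
  }
  sites$maf <- maf
  sites$genotyping_rate <- gr
  if (!is.null(scores)) {
    sites$design_score <- scores$design_score[match(sites$snp_id, scores$snp_id)]
  } else if (!("design_score" %in% names(sites))) {
    sites$design_score <- NA_real_
  }
  ord <- order(sites$scaffold_id, sites$position)
  sorted <- sites[ord, ]
  clear35 <- annotate_flanking(sorted, 35)
  clear40 <- annotate_flanking(sorted, 40)
  sites$flank_clear_35[ord] <- clear35
  sites$flank_clear_40[ord] <- clear40
  sites
}

#' Apply one round's thresholds
#'
#' Retains sites with Phred quality strictly above `phred_min`,
#' genotyping rate, MAF window and design score satisfied inclusively,
#' and a clear flank at the round's flank length. Missing attributes
#' fail the corresponding criterion.
#'
#' @param sites Annotated site table (see [annotate_sites()]).
#' @param round A [round_config()].
#' @return The retained subset of `sites`.
#' @export
apply_round_filter <- function(sites, round) {
  stopifnot(inherits(round, "round_config"))
  if (nrow(sites) == 0) return(sites)
  flank_col <- paste0("flank_clear_", round$flank_len)
  ok <- !is.na(sites$qual) & sites$qual > round$phred_min &
    !is.na(sites$genotyping_rate) & sites$genotyping_rate >= round$gr_min &
    !is.na(sites$maf) & sites$maf >= round$maf_min & sites$maf <= round$maf_max &
    !is.na(sites$design_score) & sites$design_score >= round$design_min &
    !is.na(sites[[flank_col]]) & sites[[flank_col]]
  sites[ok, , drop = FALSE]
}

#' Per-criterion exclusion counts for one round
#'
#' @param sites Annotated site table.
#' @param round A [round_config()].
#' @return Named integer vector: sites failing each criterion (a site
#'   can fail several) and the retained count.
#' @export
filter_log <- function(sites, round) {
  flank_col <- paste0("flank_clear_", round$flank_len)
  fails <- c(
    phred = sum(is.na(sites$qual) | sites$qual <= round$phred_min),
    genotyping_rate = sum(is.na(sites$genotyping_rate) |
                            sites$genotyping_rate < round$gr_min),
    maf = sum(is.na(sites$maf) | sites$maf < round$maf_min |
                sites$maf > round$maf_max),
    design_score = sum(is.na(sites$design_score) |
                         sites$design_score < round$design_min),
    flank = sum(is.na(sites[[flank_col]]) | !sites[[flank_col]])
  )
  c(input = nrow(sites), fails, retained = nrow(apply_round_filter(sites, round)))
}
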