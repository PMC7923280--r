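# Genome-coverage accounting for a selected panel: a fragment counts as
# covered when it contains at least one panel SNP (candidate entries
# included); covered length is the sum of such fragments' lengths, and
# is reported per chromosome and for the localized / unassigned / total
# scaffold groups.

#' Covered length per scaffold
#'
#' @param panel Panel manifest (needs `scaffold_id`, `position`).
#' @param fragments Fragment table from [partition_fragments()].
#' @return Data.frame `scaffold_id`, `n_snps`, `n_occupied_fragments`,
#'   `covered_length` (bp), one row per scaffold present in `fragments`.
#' @export
covered_length <- function(panel, fragments) {
  fmap <- if (nrow(panel) > 0) map_to_fragments(panel, fragments) else integer(0)
  occupied <- rep(FALSE, nrow(fragments))
  occupied[stats::na.omit(fmap)] <- TRUE
  scafs <- unique(fragments$scaffold_id)
  out <- data.frame(
    scaffold_id = scafs,
    n_snps = vapply(scafs, function(s) sum(panel$scaffold_id == s), 0L),
    n_occupied_fragments = vapply(scafs, function(s)
      sum(occupied & fragments$scaffold_id == s), 0L),
    covered_length = vapply(scafs, function(s)
      sum(fragments$length[occupied & fragments$scaffold_id == s]), 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Percent of a reference length covered
#'
#' @param covered Covered length in bp.
#' @param reference Reference length in bp, > 0.
#' @return `100 * covered / reference`, rounded to 2 decimals.
#' @export
percent_coverage <- function(covered, reference) {
  if (any(reference <= 0)) stop("reference length must be > 0", call. = FALSE)
  round(100 * covered / reference, 2)
}

#' SNP density per chromosome
#'
#' @param panel Panel manifest.
#' @param scaffolds Scaffold table with `chromosome` assignments;
#'   chromosome length is the summed length of its scaffolds.
#' @return Data.frame `chromosome`, `n_snps`, `length_bp`,
#'   `density` (SNPs/Mb), with the across-chromosome `mean` and `sd`
#'   attached as attributes `mean_density` / `sd_density`.
#' @export
snp_density <- function(panel, scaffolds) {
  assigned <- scaffolds[!is.na(scaffolds$chromosome), , drop = FALSE]
  if (nrow(assigned) == 0) {
    out <- data.frame(chromosome = character(0), n_snps = integer(0),
                      length_bp = numeric(0), density = numeric(0))
    attr(out, "mean_density") <- NA_real_
    attr(out, "sd_density") <- NA_real_
    return(out)
  }
  chroms <- unique(assigned$chromosome)
  len <- vapply(chroms, function(ch)
    sum(assigned$length[assigned$chromosome == ch]), 0)
  if (any(len <= 0)) stop("zero-length chromosome", call. = FALSE)
  chrom_of <- assigned$chromosome[match(panel$scaffold_id, assigned$scaffold_id)]
  n <- vapply(chroms, function(ch) sum(chrom_of == ch, na.rm = TRUE), 0L)
  out <- data.frame(chromosome = chroms, n_snps = n, length_bp = len,
                    density = n / (len / 1e6), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_density") <- mean(out$density)
  attr(out, "sd_density") <- stats::sd(out$density)
  out
}

# bin edges (bp) used for inter-SNP interval histograms: 10 kbp steps to
# 100 kbp, then 100 kbp steps to 800 kbp, then open-ended
interval_breaks <- function() {
  c(seq(0, 1e5, 1e4), seq(2e5, 8e5, 1e5), Inf)
}

interval_bin_labels <- function() {
  br <- interval_breaks() / 1000
  lab <- sprintf("[%g,%g)", br[-length(br)], br[-1])
  lab[length(lab)] <- sprintf("[%g,Inf)", br[length(br) - 1])
  lab
}

#' Inter-SNP interval histogram
#'
#' Each panel SNP contributes one interval: its distance to the previous
#' panel SNP on the same scaffold, or to the scaffold start for the
#' first SNP of a scaffold. Counts are binned in 10 kbp steps up to
#' 100 kbp and 100 kbp steps up to 800 kbp; bin counts always sum to
#' the panel size.
#'
#' @param panel Panel manifest.
#' @return Data.frame `bin` (label, kbp), `lower`, `upper` (bp),
#'   `count`; attributes `mean_interval` and `sd_interval` in bp.
#' @export
interval_histogram <- function(panel) {
  br <- interval_breaks()
  intervals <- numeric(0)
  if (nrow(panel) > 0) {
    panel <- panel[order(panel$scaffold_id, panel$position), , drop = FALSE]
    intervals <- unlist(lapply(split(panel$position, panel$scaffold_id),
                               function(p) diff(c(0, sort(p)))))
  }
  idx <- findInterval(intervals, br, rightmost.closed = FALSE)
  count <- tabulate(idx, nbins = length(br) - 1)
  out <- data.frame(bin = interval_bin_labels(),
                    lower = br[-length(br)], upper = br[-1],
                    count = count, stringsAsFactors = FALSE)
  attr(out, "mean_interval") <- if (length(intervals)) mean(intervals) else NA_real_
  attr(out, "sd_interval") <- if (length(intervals) > 1) stats::sd(intervals) else NA_real_
  out
}

#' MAF distribution of a panel
#'
#' @param panel Panel manifest with a `maf` column.
#' @return A list: `histogram` (bins of width 0.05 on \[0, 0.5\]),
#'   `mean`, `sd`, `frac_ge_05`, `frac_ge_10`. All summaries are NA for
#'   an empty panel.
#' @export
maf_distribution <- function(panel) {
  maf <- panel$maf[!is.na(panel$maf)]
  br <- seq(0, 0.5, 0.05)
  if (length(maf) == 0) {
    hist <- data.frame(lower = br[-11], upper = br[-1], count = rep(0L, 10))
    return(list(histogram = hist, mean = NA_real_, sd = NA_real_,
                frac_ge_05 = NA_real_, frac_ge_10 = NA_real_))
  }
  idx <- pmin(findInterval(maf, br, rightmost.closed = TRUE), 10L)
  hist <- data.frame(lower = br[-11], upper = br[-1],
                     count = tabulate(idx, nbins = 10))
  list(histogram = hist,
       mean = mean(maf),
       sd = if (length(maf) > 1) stats::sd(maf) else 0,
       frac_ge_05 = mean(maf >= 0.05),
       frac_ge_10 = mean(maf >= 0.10))
}

#' Genome coverage report
#'
#' The headline accounting table: per-chromosome rows followed by the
#' localized (chromosome-assigned scaffolds), unassigned, and total
#' group rows, each with SNP count, occupied fragments, covered and
#' reference lengths, percent covered, density and mean inter-SNP
#' interval.
#'
#' @param panel Panel manifest.
#' @param fragments Fragment table.
#' @param scaffolds Scaffold table with `chromosome`.
#' @return Data.frame, one row per chromosome and per group
#'   (`localized`, `unassigned`, `total`).
#' @export
coverage_report <- function(panel, fragments, scaffolds) {
  per_scaf <- covered_length(panel, fragments)
  per_scaf$chromosome <- scaffolds$chromosome[
    match(per_scaf$scaffold_id, scaffolds$scaffold_id)]
  per_scaf$ref_length <- scaffolds$length[
    match(per_scaf$scaffold_id, scaffolds$scaffold_id)]

  row_for <- function(label, scafs_in) {
    sub <- per_scaf[per_scaf$scaffold_id %in% scafs_in, , drop = FALSE]
    pan <- panel[panel$scaffold_id %in% scafs_in, , drop = FALSE]
    ih <- interval_histogram(pan)
    data.frame(
      group = label,
      n_snps = sum(sub$n_snps),
      n_occupied_fragments = sum(sub$n_occupied_fragments),
      covered_length = sum(sub$covered_length),
      reference_length = sum(sub$ref_length),
      percent_covered = percent_coverage(sum(sub$covered_length),
                                         sum(sub$ref_length)),
      density = sum(sub$n_snps) / (sum(sub$ref_length) / 1e6),
      mean_interval = attr(ih, "mean_interval"),
      sd_interval = attr(ih, "sd_interval"),
      stringsAsFactors = FALSE
    )
  }

  loc_scafs <- scaffolds$scaffold_id[!is.na(scaffolds$chromosome)]
  una_scafs <- scaffolds$scaffold_id[is.na(scaffolds$chromosome)]
  rows <- list()
  for (ch in unique(scaffolds$chromosome[!is.na(scaffolds$chromosome)])) {
    rows[[length(rows) + 1L]] <-
      row_for(ch, scaffolds$scaffold_id[!is.na(scaffolds$chromosome) &
                                          scaffolds$chromosome == ch])
  }
  if (length(loc_scafs)) rows[[length(rows) + 1L]] <- row_for("localized", loc_scafs)
  if (length(una_scafs)) rows[[length(rows) + 1L]] <- row_for("unassigned", una_scafs)
  rows[[length(rows) + 1L]] <- row_for("total", scaffolds$scaffold_id)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
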