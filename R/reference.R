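#' Published summary tables of the alpaca 76K microarray design
#'
#' Loads the reference summary tables of the published alpaca 76K SNP
#' microarray that the package's defaults are modelled on: the six-round
#' selection schedule with per-round first/second set counts, the panel
#' set sizes (as selected in the study and as finally placed on the
#' array), the fragment-length histogram of inter-SNP spacing, the
#' genome-coverage table (localized / unassigned / total scaffold
#' groups) and the per-gene candidate SNP counts. These are frozen
#' printed values used for arithmetic cross-checks, not outputs of this
#' package.
#'
#' @return A named list of data.frames: `selection_rounds`, `panel_sets`,
#'   `fragment_bins`, `coverage`, `candidate_genes`.
#' @export
alpaca76k_reference <- function() {
  path <- function(f) system.file("extdata", f, package = "alpacapanel",
                                  mustWork = TRUE)
  list(
    selection_rounds = read_tsv(path("alpaca76k_selection_rounds.tsv")),
    panel_sets = read_tsv(path("alpaca76k_panel_sets.tsv")),
    fragment_bins = read_tsv(path("alpaca76k_fragment_bins.tsv")),
    coverage = read_tsv(path("alpaca76k_coverage.tsv")),
    candidate_genes = read_tsv(path("alpaca76k_candidate_genes.tsv"))
  )
}
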