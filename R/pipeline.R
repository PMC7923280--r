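#' Pipeline configuration
#'
#' @param out_dir Output directory for all pipeline artifacts.
#' @param sim A [sim_config()] describing the synthetic inputs.
#' @param interval Fragment length in bp for panel selection.
#' @param round_schedule List of [round_config()]s, strictest first.
#' @param gene_regions Optional BED-style data.frame of candidate-gene
#'   intervals (or a path to a BED file).
#' @param min_depth Minimum read depth for platform-concordance
#'   comparability.
#' @param parent_window,half_sib_window Concordance windows for trio and
#'   half-sib G values.
#' @param seed Optional integer overriding the simulation seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), interval = 40000,
                            round_schedule = default_round_schedule(),
                            gene_regions = NULL, min_depth = 3,
                            parent_window = c(0.35, 0.65),
                            half_sib_window = c(0.15, 0.35),
                            seed = NULL) {
  if (length(round_schedule) == 0) stop("round schedule is empty", call. = FALSE)
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  if (is.character(gene_regions)) gene_regions <- read_bed(gene_regions)
  structure(list(out_dir = out_dir, sim = sim, interval = interval,
                 round_schedule = round_schedule,
                 gene_regions = gene_regions, min_depth = min_depth,
                 parent_window = parent_window,
                 half_sib_window = half_sib_window),
            class = "pipeline_config")
}

stage <- function(name, code) {
  tryCatch(force(code), error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full panel-design pipeline on synthetic data
#'
#' Chains the stages: simulate a genome, population and sequencing
#' calls; write and re-read the plain-text fixtures; annotate and
#' deduplicate variants; select the first, second and candidate panel
#' sets; compute the coverage report; and validate the panel (genomic
#' relationships, trio parentage, inbreeding, heterozygosity,
#' sequencing-vs-truth concordance, pairwise FST). Writes a panel
#' manifest, the coverage tables and a machine-readable JSON summary
#' whose per-stage counts mirror the audit style of a panel-design
#' report. Identical config and seed reproduce an identical summary.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  scaffolds <- stage("simulate", simulate_scaffolds(config$sim))
  pop <- stage("simulate", simulate_population(config$sim, scaffolds))
  calls <- stage("simulate", simulate_gbs_calls(pop$genotypes, config$sim))
  scores <- stage("simulate", simulate_design_scores(pop$sites, config$sim))
  pop$sites$qual <- 30  # simulated calls carry a uniform site quality
  paths <- stage("simulate",
                 write_fixtures(scaffolds, pop$sites, calls, pop$pedigree,
                                scores, config$out_dir))

  vcf <- stage("qc", read_vcf(paths$vcf))
  sites <- stage("qc", {
    s <- dedupe_variants(vcf$sites)
    annotate_sites(s, vcf$genotypes[, s$snp_id, drop = FALSE],
                   read_design_scores(paths$scores))
  })

  fragments <- stage("design", partition_fragments(scaffolds, config$interval))
  first <- stage("design",
                 select_first_set(sites, fragments, config$round_schedule))
  second <- stage("design",
                  select_second_set(sites, first, fragments,
                                    config$round_schedule))
  candidate <- if (!is.null(config$gene_regions)) {
    stage("design", include_candidate_snps(sites, config$gene_regions,
                                           fragments, scaffolds))
  } else empty_panel()
  panel <- stage("design", assemble_panel(first, second, candidate))
  write_panel_manifest(panel, file.path(config$out_dir, "panel.tsv"))

  report <- stage("coverage", coverage_report(panel, fragments, scaffolds))
  write_tsv(report, file.path(config$out_dir, "coverage.tsv"))
  ih <- stage("coverage", interval_histogram(panel))
  write_tsv(ih, file.path(config$out_dir, "intervals.tsv"))
  mafd <- stage("coverage", maf_distribution(panel))

  validation <- stage("validate", {
    panel_geno <- vcf$genotypes[, intersect(panel$snp_id, colnames(vcf$genotypes)),
                                drop = FALSE]
    qc_geno <- filter_polymorphic(panel_geno, min_gr = 0.5)
    g <- compute_grm(qc_geno)
    trios <- classify_trios(g, pop$pedigree, config$parent_window)
    hets <- heterozygosity(qc_geno)
    fvals <- inbreeding_f3(qc_geno)
    truth_panel <- pop$genotypes[, colnames(panel_geno), drop = FALSE]
    conc <- genotype_concordance(
      panel_geno, truth_panel,
      depth_a = calls$depth[, colnames(panel_geno), drop = FALSE],
      min_depth = config$min_depth)
    fst <- if (length(unique(pop$groups)) >= 2)
      fst_pairwise(qc_geno, pop$groups[rownames(qc_geno)]) else NULL
    list(g = g, trios = trios, heterozygosity = hets, inbreeding = fvals,
         concordance = conc, fst = fst)
  })
  write_tsv(validation$trios, file.path(config$out_dir, "trios.tsv"))
  if (!is.null(validation$fst)) {
    write_tsv(validation$fst, file.path(config$out_dir, "fst.tsv"))
  }

  total_row <- report[report$group == "total", ]
  summary <- list(
    seed = config$sim$seed,
    stages = list(
      simulate = list(n_scaffolds = nrow(scaffolds),
                      n_samples = nrow(pop$genotypes),
                      n_sites = nrow(pop$sites)),
      qc = list(n_read = nrow(vcf$sites),
                n_multiallelic = vcf$n_multiallelic,
                n_after_dedupe = nrow(sites)),
      design = list(first_set = nrow(first), second_set = nrow(second),
                    candidate = nrow(candidate), panel = nrow(panel),
                    first_by_round = as.list(table(factor(first$round,
                                                          seq_along(config$round_schedule)))),
                    second_by_round = as.list(table(factor(second$round,
                                                           seq_along(config$round_schedule))))),
      coverage = list(percent_covered_total = total_row$percent_covered,
                      covered_length_total = total_row$covered_length,
                      interval_bins = ih$count,
                      maf_mean = mafd$mean, maf_frac_ge_05 = mafd$frac_ge_05),
      validate = list(
        n_trios = nrow(validation$trios),
        n_trios_concordant = sum(validation$trios$trio_concordant),
        mean_heterozygosity = validation$heterozygosity$mean,
        mean_inbreeding = mean(validation$inbreeding),
        concordance_overall = validation$concordance$overall,
        fst = if (!is.null(validation$fst)) validation$fst$fst else NULL)
    )
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(c(summary, list(panel = panel, report = report,
                            validation = validation)))
}
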