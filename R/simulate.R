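#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the package is modelled on: a
#' multi-scaffold genome in which only a fraction of scaffolds is assigned
#' to chromosomes, a sample drawn from four farm subpopulations, thirty
#' pedigree trios, and reduced-representation sequencing at a mean read
#' depth of about 6x.
#'
#' @param n_scaffolds Number of scaffolds to simulate.
#' @param scaffold_length_range Length-2 numeric, min and max scaffold
#'   length in bp.
#' @param chromosome_assigned_fraction Fraction of scaffolds carrying a
#'   chromosome assignment (the rest stay unplaced).
#' @param n_founders Number of unrelated founder animals.
#' @param n_trios Number of (sire, dam, progeny) trios formed from
#'   founders. Requires `2 * n_trios <= n_founders` unless an explicit
#'   sire assignment reusing sires is passed to [simulate_population()].
#' @param n_sites Total number of biallelic SNP sites across the genome.
#' @param allele_freq_distribution Length-2 shape parameters of the Beta
#'   law from which ancestral ALT-allele frequencies are drawn. The
#'   default `c(1, 3)` gives a discovery-like spectrum whose minor allele
#'   frequencies average about 0.22.
#' @param mean_depth Mean per-sample, per-site sequencing depth (Poisson).
#' @param genotype_error_rate Probability that a non-missing call is
#'   swapped, uniformly, to one of the two other genotype codes.
#' @param dropout_rate Additional independent missingness applied on top
#'   of zero-depth missingness.
#' @param n_subpopulations Number of subpopulations (farms) among which
#'   founders are split evenly.
#' @param divergence FST-like scalar controlling Balding-Nichols
#'   divergence of subpopulation allele frequencies from the ancestral
#'   frequency; 0 means a single panmictic population.
#' @param inbreeding Within-subpopulation inbreeding coefficient f: each
#'   founder genotype is autozygous (two copies of one drawn allele) with
#'   probability f, Hardy-Weinberg otherwise.
#' @param seed Integer seed; identical seed and config reproduce
#'   byte-identical fixtures.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_scaffolds = 20,
                       scaffold_length_range = c(2e5, 2e6),
                       chromosome_assigned_fraction = 0.76,
                       n_founders = 80,
                       n_trios = 30,
                       n_sites = 2000,
                       allele_freq_distribution = c(1, 3),
                       mean_depth = 6,
                       genotype_error_rate = 0.01,
                       dropout_rate = 0,
                       n_subpopulations = 4,
                       divergence = 0.1,
                       inbreeding = 0,
                       seed = 1L) {
  stopifnot(
    n_scaffolds >= 1, n_founders >= 1, n_trios >= 0, n_sites >= 1,
    n_subpopulations >= 1,
    length(scaffold_length_range) == 2,
    length(allele_freq_distribution) == 2,
    all(allele_freq_distribution > 0),
    mean_depth >= 0, divergence >= 0, divergence < 1,
    inbreeding >= 0, inbreeding <= 1
  )
  if (scaffold_length_range[1] < 1 ||
      scaffold_length_range[1] > scaffold_length_range[2]) {
    stop("invalid scaffold_length_range: need 1 <= min <= max", call. = FALSE)
  }
  for (p in c(chromosome_assigned_fraction, genotype_error_rate, dropout_rate)) {
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length_range = as.numeric(scaffold_length_range),
    chromosome_assigned_fraction = chromosome_assigned_fraction,
    n_founders = as.integer(n_founders),
    n_trios = as.integer(n_trios),
    n_sites = as.integer(n_sites),
    allele_freq_distribution = as.numeric(allele_freq_distribution),
    mean_depth = mean_depth,
    genotype_error_rate = genotype_error_rate,
    dropout_rate = dropout_rate,
    n_subpopulations = as.integer(n_subpopulations),
    divergence = divergence,
    inbreeding = inbreeding,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
# `offset` decorrelates the streams of the different simulation stages.
with_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}

#' Simulate a scaffolded genome
#'
#' Draws scaffold lengths uniformly within the configured range and
#' assigns the configured fraction of scaffolds (rounded) to chromosome
#' labels; the remainder stay unplaced, mirroring a draft assembly in
#' which most short scaffolds have no chromosome coordinate.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `scaffold_id`, `length`,
#'   `chromosome` (NA for unplaced scaffolds).
#' @export
simulate_scaffolds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_scaffolds
  rng <- config$scaffold_length_range
  with_seed(config$seed, 101L, {
    len <- floor(stats::runif(n, rng[1], rng[2] + 1))
    len <- pmin(pmax(len, rng[1]), rng[2])
    n_chr <- round(config$chromosome_assigned_fraction * n)
    chrom <- rep(NA_character_, n)
    if (n_chr > 0) {
      chrom[seq_len(n_chr)] <- paste0("chr", ((seq_len(n_chr) - 1L) %% 36L) + 1L)
    }
    data.frame(
      scaffold_id = sprintf("scaffold_%d", seq_len(n)),
      length = as.numeric(len),
      chromosome = chrom,
      stringsAsFactors = FALSE
    )
  })
}

# Balding-Nichols subpopulation frequency: Beta around ancestral p with
# spread set by the FST-like scalar; divergence 0 returns p unchanged.
bn_subpop_freq <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate a pedigreed, subdivided population
#'
#' Places `n_sites` SNPs on the scaffolds (proportionally to length),
#' draws ancestral ALT-allele frequencies from the configured Beta law,
#' diverges them per subpopulation in Balding-Nichols fashion, draws
#' founder genotypes from Hardy-Weinberg proportions (with optional
#' within-subpopulation inbreeding), and creates trio progeny by Mendelian
#' transmission from recorded sires and dams.
#'
#' @param config A [sim_config()].
#' @param scaffolds Output of [simulate_scaffolds()].
#' @param sire_assignment Optional integer vector of length `n_trios`
#'   giving the founder index used as sire of each trio; repeats create
#'   half-sib families. Default: founders `1..n_trios` as sires and
#'   `n_trios+1..2*n_trios` as dams, all distinct.
#' @return A list with `genotypes` (samples x SNPs integer matrix coded
#'   0/1/2), `sites` (data.frame: `snp_id`, `scaffold_id`, `position`,
#'   `ref`, `alt`, `ancestral_freq`), `pedigree` (data.frame:
#'   `progeny_id`, `sire_id`, `dam_id`) and `groups` (named character
#'   vector of subpopulation labels per sample).
#' @export
simulate_population <- function(config, scaffolds, sire_assignment = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(scaffolds) || nrow(scaffolds) == 0) {
    stop("scaffolds must be non-empty", call. = FALSE)
  }
  n_f <- config$n_founders
  n_t <- config$n_trios
  if (is.null(sire_assignment)) {
    if (2L * n_t > n_f) {
      stop("n_trios exceeds available founder pairs (need 2*n_trios <= n_founders)",
           call. = FALSE)
    }
    sire_assignment <- seq_len(n_t)
    dam_assignment <- n_t + seq_len(n_t)
  } else {
    stopifnot(length(sire_assignment) == n_t, all(sire_assignment >= 1),
              all(sire_assignment <= n_f))
    # dams fill from the top so they never collide with assigned sires
    avail <- setdiff(seq_len(n_f), sire_assignment)
    if (length(avail) < n_t) {
      stop("n_trios exceeds available founder pairs for the given sires",
           call. = FALSE)
    }
    dam_assignment <- utils::tail(avail, n_t)
  }

  with_seed(config$seed, 202L, {
    m <- config$n_sites
    # allocate sites to scaffolds proportionally to length, at least the
    # largest remainders get the leftovers
    w <- scaffolds$length / sum(scaffolds$length)
    alloc <- floor(w * m)
    rem <- m - sum(alloc)
    if (rem > 0) {
      extra <- order(w * m - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[extra] <- alloc[extra] + 1L
    }
    pos <- vector("list", nrow(scaffolds))
    for (s in seq_len(nrow(scaffolds))) {
      k <- alloc[s]
      if (k == 0) next
      L <- scaffolds$length[s]
      p <- sort(sample.int(L, min(k, L), replace = FALSE))
      pos[[s]] <- data.frame(
        scaffold_id = scaffolds$scaffold_id[s],
        position = as.numeric(p),
        stringsAsFactors = FALSE
      )
    }
    sites <- do.call(rbind, pos[!vapply(pos, is.null, logical(1))])
    m <- nrow(sites)
    sites$snp_id <- sprintf("snp_%05d", seq_len(m))
    bases <- c("A", "C", "G", "T")
    sites$ref <- sample(bases, m, replace = TRUE)
    sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1L), "")
    af <- config$allele_freq_distribution
    sites$ancestral_freq <- stats::rbeta(m, af[1], af[2])
    sites <- sites[, c("snp_id", "scaffold_id", "position", "ref", "alt",
                       "ancestral_freq")]

    # subpopulation-specific frequencies
    n_sub <- config$n_subpopulations
    subfreq <- matrix(0, nrow = n_sub, ncol = m)
    for (s in seq_len(n_sub)) {
      subfreq[s, ] <- bn_subpop_freq(sites$ancestral_freq, config$divergence)
    }

    founder_sub <- ((seq_len(n_f) - 1L) %% n_sub) + 1L
    f <- config$inbreeding
    geno <- matrix(0L, nrow = n_f + n_t, ncol = m)
    for (i in seq_len(n_f)) {
      p <- subfreq[founder_sub[i], ]
      if (f > 0) {
        ibd <- stats::runif(m) < f
        g_ibd <- 2L * stats::rbinom(m, 1L, p)
        g_hw <- stats::rbinom(m, 2L, p)
        geno[i, ] <- ifelse(ibd, g_ibd, g_hw)
      } else {
        geno[i, ] <- stats::rbinom(m, 2L, p)
      }
    }
    founder_ids <- sprintf("founder_%03d", seq_len(n_f))
    progeny_ids <- if (n_t > 0) sprintf("progeny_%03d", seq_len(n_t)) else character(0)
    # Mendelian transmission: one allele from each parent, P(alt) = g/2
    for (t in seq_len(n_t)) {
      sire_g <- geno[sire_assignment[t], ]
      dam_g <- geno[dam_assignment[t], ]
      geno[n_f + t, ] <- (stats::runif(m) < sire_g / 2) +
        (stats::runif(m) < dam_g / 2)
    }
    rownames(geno) <- c(founder_ids, progeny_ids)
    colnames(geno) <- sites$snp_id

    pedigree <- data.frame(
      progeny_id = progeny_ids,
      sire_id = founder_ids[sire_assignment[seq_len(n_t)]],
      dam_id = founder_ids[dam_assignment[seq_len(n_t)]],
      stringsAsFactors = FALSE
    )
    groups <- c(paste0("pop", founder_sub),
                if (n_t > 0) paste0("pop", founder_sub[sire_assignment]) else character(0))
    names(groups) <- rownames(geno)

    list(genotypes = geno, sites = sites, pedigree = pedigree, groups = groups)
  })
}

#' Simulate sequencing-based genotype calls
#'
#' Emulates genotyping-by-sequencing of known true genotypes: per-sample,
#' per-site read depth is Poisson at the configured mean; ALT read counts
#' are binomial given the true allele dose; a site with zero depth (or an
#' independent dropout) yields a missing call; otherwise the call equals
#' the true genotype, then is swapped to one of the other two codes with
#' probability `genotype_error_rate`. The recorded depths make the
#' standard minimum-read comparability filter (>= 3 reads) meaningful
#' downstream.
#'
#' @param truth Samples x SNPs matrix coded 0/1/2.
#' @param config A [sim_config()].
#' @return A list of three samples x SNPs matrices: `genotypes` (0/1/2,
#'   NA for missing), `depth` (total reads), `alt_depth` (ALT reads).
#' @export
simulate_gbs_calls <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(truth))
  if (!all(truth %in% c(0L, 1L, 2L))) {
    stop("truth matrix must be coded 0/1/2", call. = FALSE)
  }
  with_seed(config$seed, 303L, {
    n <- nrow(truth); m <- ncol(truth)
    depth <- matrix(stats::rpois(n * m, config$mean_depth), n, m)
    alt_depth <- matrix(stats::rbinom(n * m, as.vector(depth),
                                      as.vector(truth) / 2), n, m)
    calls <- truth
    e <- config$genotype_error_rate
    if (e > 0) {
      err <- matrix(stats::runif(n * m) < e, n, m)
      # symmetric swap: uniformly one of the two other codes
      shift <- matrix(sample(c(1L, 2L), n * m, replace = TRUE), n, m)
      calls[err] <- (calls[err] + shift[err]) %% 3L
    }
    calls[depth == 0] <- NA_integer_
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * m) < config$dropout_rate, n, m)
      calls[drop] <- NA_integer_
    }
    dimnames(depth) <- dimnames(alt_depth) <- dimnames(calls) <- dimnames(truth)
    list(genotypes = calls, depth = depth, alt_depth = alt_depth)
  })
}

#' Simulate design scores for SNP probes
#'
#' Draws a vendor-style probe manufacturability score in \[0, 1\] for each
#' site. Scores are Beta-distributed with most mass above 0.6 so that the
#' design-score filter removes a realistic minority of sites.
#'
#' @param sites Site table with `snp_id`.
#' @param config A [sim_config()].
#' @param shape Beta shape parameters, default `c(6, 1.5)`.
#' @return Data.frame `snp_id`, `design_score`.
#' @export
simulate_design_scores <- function(sites, config, shape = c(6, 1.5)) {
  with_seed(config$seed, 404L, {
    data.frame(
      snp_id = sites$snp_id,
      design_score = round(stats::rbeta(nrow(sites), shape[1], shape[2]), 4),
      stringsAsFactors = FALSE
    )
  })
}

#' Write simulation fixtures to disk
#'
#' Emits the file set the rest of the pipeline consumes: a VCF 4.2 with
#' GT/DP/AD fields (1-based positions, sorted within scaffold), a
#' FASTA-index-like scaffold table, a pedigree table and a design-score
#' table. All outputs are plain text and round-trip losslessly through
#' the package's readers.
#'
#' @param scaffolds Scaffold table from [simulate_scaffolds()].
#' @param sites Site table from [simulate_population()].
#' @param calls Call set from [simulate_gbs_calls()] (or a bare genotype
#'   matrix, in which case depth/AD fields are omitted).
#' @param pedigree Pedigree data.frame.
#' @param scores Design-score data.frame.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of file paths.
#' @export
write_fixtures <- function(scaffolds, sites, calls, pedigree, scores, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (is.matrix(calls)) calls <- list(genotypes = calls)
  paths <- list(
    vcf = file.path(out_dir, "calls.vcf"),
    fai = file.path(out_dir, "scaffolds.fai"),
    ped = file.path(out_dir, "pedigree.tsv"),
    scores = file.path(out_dir, "design_scores.tsv")
  )
  write_vcf(sites, calls$genotypes, paths$vcf, scaffolds = scaffolds,
            depth = calls$depth, alt_depth = calls$alt_depth)
  write_scaffold_index(scaffolds, paths$fai)
  write_tsv(pedigree, paths$ped)
  write_tsv(scores, paths$scores)
  invisible(paths)
}
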