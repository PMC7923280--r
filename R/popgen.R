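# Panel validation statistics on a samples x SNPs genotype matrix coded
# 0/1/2 (copies of the ALT allele) with NA for missing calls: genomic
# relationships, trio parentage, inbreeding, heterozygosity, platform
# concordance, LD pruning, FST and principal components.

check_geno_matrix <- function(x) {
  stopifnot(is.matrix(x))
  v <- x[!is.na(x)]
  if (length(v) && !all(v %in% c(0, 1, 2))) {
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  }
  invisible(x)
}

#' Per-SNP allele frequency
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA; the frequency
#'   reported is that of the allele counted by the codes (ALT under the
#'   package's VCF convention).
#' @return Named numeric vector, NA for all-missing SNPs.
#' @export
allele_frequency <- function(matrix) {
  check_geno_matrix(matrix)
  n <- colSums(!is.na(matrix))
  p <- colSums(matrix, na.rm = TRUE) / (2 * n)
  p[n == 0] <- NA_real_
  p
}

#' Remove monomorphic and poorly genotyped SNPs
#'
#' @param matrix Samples x SNPs matrix.
#' @param min_gr Minimum genotyping rate (default 0, i.e. keep all
#'   non-empty).
#' @param min_maf Minimum minor allele frequency (default strictly
#'   polymorphic).
#' @return The column-subset matrix.
#' @export
filter_polymorphic <- function(matrix, min_gr = 0, min_maf = 0) {
  p <- allele_frequency(matrix)
  gr <- colMeans(!is.na(matrix))
  maf <- pmin(p, 1 - p)
  keep <- !is.na(p) & p > 0 & p < 1 & gr >= min_gr & maf >= min_maf
  matrix[, keep, drop = FALSE]
}

#' Genomic relationship matrix
#'
#' VanRaden-type estimator: for individuals j and k,
#' `G_jk = (1/N) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the N SNPs non-missing in both individuals (N is adjusted per
#' pair). Monomorphic SNPs are excluded; allele frequencies are
#' estimated from the matrix itself unless supplied.
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA.
#' @param p Optional per-SNP allele frequencies (same convention as the
#'   codes); default estimated with [allele_frequency()].
#' @return Symmetric samples x samples matrix of class `grm`.
#' @export
compute_grm <- function(matrix, p = NULL) {
  check_geno_matrix(matrix)
  if (is.null(p)) p <- allele_frequency(matrix)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs left for the GRM", call. = FALSE)
  x <- matrix[, poly, drop = FALSE]
  p <- p[poly]
  denom <- sqrt(2 * p * (1 - p))
  w <- sweep(sweep(x, 2, 2 * p, "-"), 2, denom, "/")
  obs <- !is.na(w)
  w[!obs] <- 0
  num <- tcrossprod(w)
  n_pair <- tcrossprod(obs * 1)
  if (any(n_pair == 0)) {
    warning("some sample pairs share no genotyped SNP; their G is NA")
  }
  g <- num / n_pair
  g[n_pair == 0] <- NA_real_
  ids <- rownames(matrix)
  if (!is.null(ids)) dimnames(g) <- list(ids, ids)
  class(g) <- c("grm", class(g))
  g
}

#' Verify pedigree trios against genomic relationships
#'
#' Each recorded parent-offspring pair is concordant when its G value
#' falls inside the parent-offspring window (default \[0.35, 0.65\],
#' centred on the expected 0.5); a trio is concordant when both the sire
#' and the dam pair are. Values above the window (e.g. a duplicated
#' sample posing as its own parent) are flagged, not concordant.
#'
#' @param G A [compute_grm()] matrix with sample ids.
#' @param pedigree Data.frame `progeny_id`, `sire_id`, `dam_id`.
#' @param window Parent-offspring concordance window.
#' @return Data.frame per trio: the two G values, per-pair concordance
#'   and the trio verdict.
#' @export
classify_trios <- function(G, pedigree, window = c(0.35, 0.65)) {
  ids <- rownames(G)
  need <- unique(c(pedigree$progeny_id, pedigree$sire_id, pedigree$dam_id))
  absent <- setdiff(need, ids)
  if (length(absent) > 0) {
    stop("pedigree ids not genotyped: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  g_of <- function(a, b) G[cbind(match(a, ids), match(b, ids))]
  g_sire <- g_of(pedigree$progeny_id, pedigree$sire_id)
  g_dam <- g_of(pedigree$progeny_id, pedigree$dam_id)
  in_win <- function(g) !is.na(g) & g >= window[1] & g <= window[2]
  out <- data.frame(
    progeny_id = pedigree$progeny_id,
    sire_id = pedigree$sire_id, dam_id = pedigree$dam_id,
    g_sire = g_sire, g_dam = g_dam,
    sire_concordant = in_win(g_sire),
    dam_concordant = in_win(g_dam),
    stringsAsFactors = FALSE
  )
  out$trio_concordant <- out$sire_concordant & out$dam_concordant
  out
}

#' Half-sib pairs implied by shared sires
#'
#' @param G A [compute_grm()] matrix.
#' @param pedigree Trio table; progenies sharing a sire are half-sibs.
#' @param window Half-sib concordance window (default \[0.15, 0.35\],
#'   centred on the expected 0.25).
#' @return Data.frame of half-sib pairs with their G value and verdict.
#' @export
classify_half_sibs <- function(G, pedigree, window = c(0.15, 0.35)) {
  ids <- rownames(G)
  pairs <- list()
  for (s in unique(pedigree$sire_id)) {
    prog <- pedigree$progeny_id[pedigree$sire_id == s]
    if (length(prog) < 2) next
    cmb <- utils::combn(prog, 2)
    for (c_i in seq_len(ncol(cmb))) {
      g <- G[match(cmb[1, c_i], ids), match(cmb[2, c_i], ids)]
      pairs[[length(pairs) + 1L]] <- data.frame(
        sire_id = s, progeny_a = cmb[1, c_i], progeny_b = cmb[2, c_i],
        g = g, concordant = !is.na(g) & g >= window[1] & g <= window[2],
        stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(sire_id = character(0), progeny_a = character(0),
                      progeny_b = character(0), g = numeric(0),
                      concordant = logical(0)))
  }
  do.call(rbind, pairs)
}

#' SNP-based inbreeding coefficient
#'
#' The estimator based on the correlation between uniting gametes:
#' per SNP, `(x^2 - (1 + 2 p) x + 2 p^2) / (2 p (1 - p))`, averaged over
#' the sample's non-missing polymorphic SNPs. A heterozygote at p = 0.5
#' contributes -1 (heterozygote excess), a homozygote +1.
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA.
#' @param p Optional per-SNP allele frequencies; default estimated from
#'   the matrix.
#' @return Named numeric vector of per-sample F.
#' @export
inbreeding_f3 <- function(matrix, p = NULL) {
  check_geno_matrix(matrix)
  if (is.null(p)) p <- allele_frequency(matrix)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs for inbreeding", call. = FALSE)
  x <- matrix[, poly, drop = FALSE]
  p <- p[poly]
  h <- 2 * p * (1 - p)
  # per-sample mean of (x^2 - (1+2p) x + 2 p^2) / h over non-missing SNPs
  num <- sweep(x^2 - sweep(x, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  f_terms <- sweep(num, 2, h, "/")
  rowMeans(f_terms, na.rm = TRUE)
}

#' Per-sample heterozygosity
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA.
#' @return A list: `per_sample` (proportion of heterozygous calls among
#'   genotyped loci, NA for fully missing samples), `mean`, `sd`.
#' @export
heterozygosity <- function(matrix) {
  check_geno_matrix(matrix)
  n <- rowSums(!is.na(matrix))
  het <- rowSums(matrix == 1, na.rm = TRUE) / n
  het[n == 0] <- NA_real_
  list(per_sample = het,
       mean = mean(het, na.rm = TRUE),
       sd = stats::sd(het[!is.na(het)]))
}

#' Genotype concordance between two platforms
#'
#' Intersects samples and SNPs of two call sets and scores, per sample,
#' the fraction of comparable calls that agree. A call is comparable
#' when non-missing in both sets and, if a depth matrix accompanies the
#' first set, supported by at least `min_depth` reads there (the
#' standard >= 3-read rule for sequencing-derived genotypes).
#'
#' @param matrix_a,matrix_b Samples x SNPs matrices coded 0/1/2/NA with
#'   sample/SNP dimnames.
#' @param depth_a Optional read-depth matrix aligned with `matrix_a`.
#' @param min_depth Minimum depth in `matrix_a`'s platform (default 3).
#' @return A list: `per_sample` data.frame (sample, comparable calls,
#'   matches, concordance), `overall` (mean of per-sample scores) and
#'   `pooled` (all comparable calls pooled).
#' @export
genotype_concordance <- function(matrix_a, matrix_b, depth_a = NULL,
                                 min_depth = 3) {
  check_geno_matrix(matrix_a); check_geno_matrix(matrix_b)
  samples <- intersect(rownames(matrix_a), rownames(matrix_b))
  snps <- intersect(colnames(matrix_a), colnames(matrix_b))
  if (length(samples) == 0 || length(snps) == 0) {
    stop("no overlapping samples/SNPs between the two call sets",
         call. = FALSE)
  }
  a <- matrix_a[samples, snps, drop = FALSE]
  b <- matrix_b[samples, snps, drop = FALSE]
  comparable <- !is.na(a) & !is.na(b)
  if (!is.null(depth_a)) {
    d <- depth_a[samples, snps, drop = FALSE]
    comparable <- comparable & !is.na(d) & d >= min_depth
  }
  match_m <- comparable & (a == b)
  n_comp <- rowSums(comparable)
  n_match <- rowSums(match_m)
  conc <- ifelse(n_comp > 0, n_match / n_comp, NA_real_)
  per_sample <- data.frame(sample_id = samples, comparable = n_comp,
                           matches = n_match, concordance = conc,
                           stringsAsFactors = FALSE)
  if (all(n_comp == 0)) {
    warning("depth filter leaves no comparable calls")
  }
  list(per_sample = per_sample,
       overall = mean(conc, na.rm = TRUE),
       pooled = if (sum(n_comp) > 0) sum(n_match) / sum(n_comp) else NA_real_)
}

#' LD-based SNP pruning
#'
#' Sliding-window genotype-correlation pruning in the style of standard
#' whole-genome toolkits: within each window of `window_snps` SNPs
#' (advanced by `step_snps`), any pair of retained SNPs with squared
#' Pearson correlation above `r2_max` loses its later member (by input
#' order). Deterministic given the input ordering, which should be by
#' scaffold and position.
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA, columns ordered
#'   by genome position.
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Step between window starts (default 5).
#' @param r2_max Maximum allowed squared correlation (default 0.5).
#' @return Character vector of retained SNP ids (column names), or
#'   retained column indices when the matrix is unnamed.
#' @export
ld_prune <- function(matrix, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  check_geno_matrix(matrix)
  m <- ncol(matrix)
  keep <- rep(TRUE, m)
  if (m >= 2 && r2_max < 1) {
    starts <- seq(1L, max(1L, m - 1L), by = step_snps)
    for (s in starts) {
      idx <- seq(s, min(s + window_snps - 1L, m))
      idx <- idx[keep[idx]]
      if (length(idx) < 2) next
      r <- suppressWarnings(stats::cor(matrix[, idx, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- r^2
      for (i in seq_along(idx)) {
        if (!keep[idx[i]]) next
        for (j in seq_along(idx)) {
          if (j <= i || !keep[idx[j]]) next
          if (!is.na(r2[i, j]) && r2[i, j] > r2_max) keep[idx[j]] <- FALSE
        }
      }
    }
  }
  ids <- colnames(matrix)
  if (is.null(ids)) which(keep) else ids[keep]
}

# Weir-Cockerham variance components (a, b, c) for one SNP across r
# groups; n = genotyped counts, p = allele freqs, h = het freqs
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Pairwise FST between groups
#'
#' Weir-Cockerham estimator, ratio-of-sums over SNPs
#' (`sum(a) / sum(a + b + c)`), for every pair of group labels.
#' Negative estimates are reported as computed, not clipped to zero.
#'
#' @param matrix Samples x SNPs matrix coded 0/1/2/NA.
#' @param groups Character vector of group labels, one per sample (or a
#'   named vector matched against rownames).
#' @return Data.frame `group_a`, `group_b`, `fst`, `n_snps` (SNPs with
#'   defined components).
#' @export
fst_pairwise <- function(matrix, groups) {
  check_geno_matrix(matrix)
  if (!is.null(names(groups)) && !is.null(rownames(matrix))) {
    groups <- groups[rownames(matrix)]
  }
  stopifnot(length(groups) == nrow(matrix))
  labs <- sort(unique(groups))
  if (length(labs) < 2) stop("need at least two groups", call. = FALSE)
  small <- labs[table(factor(groups, labs)) < 2]
  if (length(small) > 0) {
    stop("groups with fewer than 2 samples: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  pairs <- utils::combn(labs, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    ga <- matrix[groups == pairs[1, k], , drop = FALSE]
    gb <- matrix[groups == pairs[2, k], , drop = FALSE]
    na_ <- colSums(!is.na(ga)); nb_ <- colSums(!is.na(gb))
    ok <- na_ >= 1 & nb_ >= 1 & (na_ + nb_) >= 3
    num <- den <- 0; used <- 0L
    for (i in which(ok)) {
      n <- c(na_[i], nb_[i])
      p <- c(sum(ga[, i], na.rm = TRUE) / (2 * n[1]),
             sum(gb[, i], na.rm = TRUE) / (2 * n[2]))
      h <- c(sum(ga[, i] == 1, na.rm = TRUE) / n[1],
             sum(gb[, i] == 1, na.rm = TRUE) / n[2])
      comp <- wc_components(n, p, h)
      if (any(!is.finite(comp))) next
      num <- num + comp["a"]
      den <- den + sum(comp)
      used <- used + 1L
    }
    out[[k]] <- data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
                           fst = if (den != 0) unname(num / den) else NA_real_,
                           n_snps = used, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Principal components of a relationship matrix
#'
#' Top-k eigenvectors of G scaled by the square roots of their
#' eigenvalues. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so repeated runs are identical.
#'
#' @param G A [compute_grm()] matrix.
#' @param k Number of components (<= sample count).
#' @return Samples x k matrix of coordinates; eigenvalues attached as
#'   attribute `eigenvalues`.
#' @export
pca_structure <- function(G, k = 2) {
  n <- nrow(G)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  eig <- eigen(unclass(G), symmetric = TRUE)
  vals <- pmax(eig$values[seq_len(k)], 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(vals), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (length(i_max) && coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  attr(coords, "eigenvalues") <- eig$values[seq_len(k)]
  coords
}
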