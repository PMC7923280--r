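# Panel selection: tile each scaffold into 40 kbp fragments, pick the
# best-centred passing SNP per fragment across relaxation rounds (first
# set), add a second SNP per fragment two 8 kbp subfragments clockwise
# from the first (second set), and include candidate-gene SNPs.
#
# Coordinates: fragments are 0-based half-open; VCF site positions are
# 1-based and converted internally (a = position - 1).

#' Tile scaffolds into equidistant fragments
#'
#' Produces ceiling(length / interval) fragments per scaffold starting
#' at 0, interval, 2*interval, ...; the final fragment is clipped to the
#' scaffold length, so terminal fragments may be shorter.
#'
#' @param scaffolds Scaffold table (`scaffold_id`, `length`).
#' @param interval Fragment length in bp (default 40000).
#' @return Data.frame `scaffold_id`, `index` (0-based), `start`, `end`
#'   (0-based half-open), `length`.
#' @export
partition_fragments <- function(scaffolds, interval = 40000) {
  if (interval <= 0) stop("interval must be positive", call. = FALSE)
  stopifnot(all(scaffolds$length >= 1))
  parts <- lapply(seq_len(nrow(scaffolds)), function(s) {
    L <- scaffolds$length[s]
    k <- ceiling(L / interval)
    start <- (seq_len(k) - 1) * interval
    end <- pmin(start + interval, L)
    data.frame(scaffold_id = scaffolds$scaffold_id[s],
               index = seq_len(k) - 1L, start = start, end = end,
               length = end - start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  attr(out, "interval") <- interval
  out
}

#' Location score of a SNP within a fragment
#'
#' The score is the fragment length minus twice the distance of the SNP
#' from the fragment midpoint: maximal (= E - S) for a SNP exactly at
#' the midpoint, approaching 0 at either end. Selecting the maximal
#' score therefore prefers centrally placed SNPs and keeps consecutive
#' selected SNPs near the fragment spacing apart.
#'
#' @param S,E Fragment start and end (0-based half-open), `S < E`.
#' @param a SNP position on the same 0-based scale, `S <= a < E`.
#' @return Score in bp (vectorized over `a`, and over S/E of equal
#'   length).
#' @export
location_score <- function(S, E, a) {
  if (any(a < S | a >= E)) {
    stop("SNP position outside fragment [S, E)", call. = FALSE)
  }
  (E - S) - 2 * abs(a - (E + S) / 2)
}

#' Subfragment index of a position
#'
#' Fragments are divided into five equal subfragments (8 kbp for a full
#' 40 kbp fragment; shorter terminal fragments compress proportionally,
#' width = length / 5). Subfragment 1 covers the first fifth, 5 the
#' last.
#'
#' @param a 0-based position within the fragment.
#' @param fragment One-row fragment record (`start`, `end`).
#' @return Integer in 1..5 (vectorized over `a`).
#' @export
subfragment_index <- function(a, fragment) {
  if (any(a < fragment$start | a >= fragment$end)) {
    stop("position outside fragment", call. = FALSE)
  }
  width <- (fragment$end - fragment$start) / 5
  pmin(1L + as.integer(floor((a - fragment$start) / width)), 5L)
}

# 0-based half-open bounds of subfragment t of a fragment
subfragment_bounds <- function(fragment, t) {
  width <- (fragment$end - fragment$start) / 5
  c(fragment$start + (t - 1) * width,
    if (t == 5) fragment$end else fragment$start + t * width)
}

# map each site to its fragment row index, NA when off the tiling
map_to_fragments <- function(sites, fragments) {
  out <- rep(NA_integer_, nrow(sites))
  for (scaf in unique(sites$scaffold_id)) {
    si <- which(sites$scaffold_id == scaf)
    fi <- which(fragments$scaffold_id == scaf)
    if (length(fi) == 0) next
    pos0 <- sites$position[si] - 1
    hit <- findInterval(pos0, fragments$start[fi])
    ok <- hit >= 1 & pos0 < fragments$end[fi][pmax(hit, 1)]
    out[si[ok]] <- fi[hit[ok]]
  }
  out
}

# deterministic pick among candidate rows: max score, ties broken by
# higher MAF then lower position
pick_best <- function(score, maf, position) {
  ord <- order(-score, -maf, position)
  ord[1]
}

panel_entry_cols <- c("snp_id", "scaffold_id", "position", "set_label",
                      "round", "fragment_index", "subfragment",
                      "location_score", "maf", "design_score")

empty_panel <- function() {
  data.frame(snp_id = character(0), scaffold_id = character(0),
              position = numeric(0), set_label = character(0),
              round = integer(0), fragment_index = integer(0),
              subfragment = integer(0), location_score = numeric(0),
              maf = numeric(0), design_score = numeric(0),
              stringsAsFactors = FALSE)
}

#' Select the first panel set (one SNP per fragment)
#'
#' Rounds are visited in schedule order (strictest first). In each round
#' every still-empty fragment considers the sites passing that round's
#' filter and takes the one with maximal [location_score()] relative to
#' the fragment midpoint; ties break to higher MAF, then lower position.
#' A fragment filled in an earlier round is never revisited, and each
#' entry records the round that filled it.
#'
#' @param sites Annotated site table (see [annotate_sites()]).
#' @param fragments Fragment table from [partition_fragments()].
#' @param round_schedule List of [round_config()] objects, strictest
#'   first; default [default_round_schedule()].
#' @return Panel entry data.frame (one row per filled fragment).
#' @export
select_first_set <- function(sites, fragments,
                             round_schedule = default_round_schedule()) {
  if (length(round_schedule) == 0) {
    stop("round schedule must be non-empty", call. = FALSE)
  }
  sites$.frag <- map_to_fragments(sites, fragments)
  filled <- rep(FALSE, nrow(fragments))
  entries <- list()
  for (r in seq_along(round_schedule)) {
    pass <- apply_round_filter(sites, round_schedule[[r]])
    pass <- pass[!is.na(pass$.frag) & !filled[pass$.frag], , drop = FALSE]
    if (nrow(pass) == 0) next
    for (f in unique(pass$.frag)) {
      rows <- pass[pass$.frag == f, , drop = FALSE]
      frag <- fragments[f, ]
      a <- rows$position - 1
      score <- location_score(frag$start, frag$end, a)
      i <- pick_best(score, rows$maf, rows$position)
      entries[[length(entries) + 1L]] <- data.frame(
        snp_id = rows$snp_id[i], scaffold_id = rows$scaffold_id[i],
        position = rows$position[i], set_label = "first",
        round = r, fragment_index = frag$index,
        subfragment = subfragment_index(a[i], frag),
        location_score = score[i], maf = rows$maf[i],
        design_score = rows$design_score[i], stringsAsFactors = FALSE)
      filled[f] <- TRUE
    }
  }
  if (length(entries) == 0) return(empty_panel())
  out <- do.call(rbind, entries)
  out[order(match(out$scaffold_id, unique(fragments$scaffold_id)),
            out$fragment_index), , drop = FALSE]
}

#' Select the second panel set (densification pass)
#'
#' For each fragment holding a first-set SNP in subfragment i, the
#' second SNP is sought in the target subfragment two steps clockwise,
#' t = ((i - 1 + 2) mod 5) + 1 (so 1 -> 3, 2 -> 4, 3 -> 5, 4 -> 1,
#' 5 -> 2). The relaxation rounds apply within the target subfragment;
#' the winner maximizes the location score computed against the
#' subfragment's own midpoint. Fragments whose target subfragment holds
#' no passing SNP after all rounds get no second entry.
#'
#' @param sites Annotated site table.
#' @param first_set Output of [select_first_set()].
#' @param fragments Fragment table.
#' @param round_schedule As in [select_first_set()].
#' @return Panel entry data.frame labelled `"second"`.
#' @export
select_second_set <- function(sites, first_set, fragments,
                              round_schedule = default_round_schedule()) {
  if (nrow(first_set) == 0) return(empty_panel())
  sites$.frag <- map_to_fragments(sites, fragments)
  frag_key <- paste(fragments$scaffold_id, fragments$index)
  entries <- list()
  for (k in seq_len(nrow(first_set))) {
    f <- match(paste(first_set$scaffold_id[k], first_set$fragment_index[k]),
               frag_key)
    frag <- fragments[f, ]
    t <- ((first_set$subfragment[k] - 1L + 2L) %% 5L) + 1L
    b <- subfragment_bounds(frag, t)
    cand <- sites[!is.na(sites$.frag) & sites$.frag == f &
                    sites$position - 1 >= b[1] & sites$position - 1 < b[2] &
                    sites$snp_id != first_set$snp_id[k], , drop = FALSE]
    if (nrow(cand) == 0) next
    for (r in seq_along(round_schedule)) {
      pass <- apply_round_filter(cand, round_schedule[[r]])
      if (nrow(pass) == 0) next
      a <- pass$position - 1
      score <- location_score(b[1], b[2], a)
      i <- pick_best(score, pass$maf, pass$position)
      entries[[length(entries) + 1L]] <- data.frame(
        snp_id = pass$snp_id[i], scaffold_id = pass$scaffold_id[i],
        position = pass$position[i], set_label = "second",
        round = r, fragment_index = frag$index, subfragment = t,
        location_score = score[i], maf = pass$maf[i],
        design_score = pass$design_score[i], stringsAsFactors = FALSE)
      break
    }
  }
  if (length(entries) == 0) return(empty_panel())
  do.call(rbind, entries)
}

#' Include candidate-gene SNPs
#'
#' Adds every site overlapping a candidate-gene interval (fibre-quality
#' and colour genes such as the KRT/KRTAP clusters, ASIP, MC1R, TYRP1,
#' KIT) that has design score >= `design_min` and a clear flank. These
#' entries are exempt from the one-SNP-per-fragment rule.
#'
#' @param sites Annotated site table.
#' @param gene_regions BED-style data.frame `scaffold_id`, `start`,
#'   `end` (0-based half-open), optional `name`.
#' @param fragments Optional fragment table used to record each
#'   candidate's fragment index (for coverage accounting).
#' @param scaffolds Optional scaffold table; intervals naming a scaffold
#'   absent from it raise a reference-mismatch error.
#' @param design_min Minimum design score (default 0.6).
#' @param flank_len Flank length whose clear-flag is required (default 40).
#' @return Panel entry data.frame labelled `"candidate"`.
#' @export
include_candidate_snps <- function(sites, gene_regions, fragments = NULL,
                                   scaffolds = NULL, design_min = 0.6,
                                   flank_len = 40) {
  if (!is.null(scaffolds)) {
    missing_scaf <- setdiff(gene_regions$scaffold_id, scaffolds$scaffold_id)
    if (length(missing_scaf) > 0) {
      stop("gene regions reference unknown scaffolds: ",
           paste(missing_scaf, collapse = ", "), call. = FALSE)
    }
  }
  flank_col <- paste0("flank_clear_", flank_len)
  hit <- rep(FALSE, nrow(sites))
  pos0 <- sites$position - 1
  for (g in seq_len(nrow(gene_regions))) {
    hit <- hit | (sites$scaffold_id == gene_regions$scaffold_id[g] &
                    pos0 >= gene_regions$start[g] &
                    pos0 < gene_regions$end[g])
  }
  keep <- hit & !is.na(sites$design_score) &
    sites$design_score >= design_min &
    !is.na(sites[[flank_col]]) & sites[[flank_col]]
  cand <- sites[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_panel())
  frag_idx <- rep(NA_integer_, nrow(cand))
  if (!is.null(fragments)) {
    fmap <- map_to_fragments(cand, fragments)
    frag_idx <- ifelse(is.na(fmap), NA_integer_, fragments$index[fmap])
  }
  data.frame(
    snp_id = cand$snp_id, scaffold_id = cand$scaffold_id,
    position = cand$position, set_label = "candidate",
    round = NA_integer_, fragment_index = frag_idx,
    subfragment = NA_integer_, location_score = NA_real_,
    maf = cand$maf, design_score = cand$design_score,
    stringsAsFactors = FALSE)
}

#' Assemble the panel manifest
#'
#' Concatenates the first, second and candidate sets, removing duplicate
#' SNPs by (scaffold, position); when a SNP appears in several sets the
#' candidate label wins, then first, then second.
#'
#' @param first,second,candidate Panel entry data.frames (any may be
#'   empty).
#' @return The combined manifest, ordered by scaffold and position.
#' @export
assemble_panel <- function(first, second = empty_panel(),
                           candidate = empty_panel()) {
  all <- rbind(candidate[, panel_entry_cols],
               first[, panel_entry_cols],
               second[, panel_entry_cols])
  if (nrow(all) == 0) return(empty_panel())
  key <- paste(all$scaffold_id, all$position)
  all <- all[!duplicated(key), , drop = FALSE]
  all[order(all$scaffold_id, all$position), , drop = FALSE]
}
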