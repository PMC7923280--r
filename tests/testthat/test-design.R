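test_that("fragment tiling covers each scaffold without gaps or overlap", {
  fr <- partition_fragments(make_scaffolds(100000))
  expect_equal(fr$start, c(0, 40000, 80000))
  expect_equal(fr$end, c(40000, 80000, 100000))
  expect_equal(nrow(partition_fragments(make_scaffolds(40000))), 1)
  tiny <- partition_fragments(make_scaffolds(1))
  expect_equal(tiny$length, 1)
  expect_error(partition_fragments(make_scaffolds(100), interval = 0),
               "interval")
  # property: tiling reconstructs the scaffold
  set.seed(3)
  for (L in sample(1:500000, 20)) {
    fr <- partition_fragments(make_scaffolds(L))
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)], L)
    if (nrow(fr) > 1) expect_equal(fr$start[-1], fr$end[-nrow(fr)])
    expect_true(all(fr$length <= 40000))
  }
})

test_that("location score peaks at the fragment midpoint", {
  expect_equal(location_score(0, 40000, 20000), 40000)
  expect_equal(location_score(0, 40000, 0), 0)
  expect_equal(location_score(0, 40000, 10000), 20000)
  expect_error(location_score(0, 40000, 40000), "outside")
  expect_error(location_score(0, 40000, -1), "outside")
  # oracle: twice the distance to the nearer end, maximal at midpoint
  set.seed(4)
  for (i in 1:200) {
    S <- sample(0:1e6, 1); E <- S + sample(1:80000, 1)
    a <- S + sample(0:(E - S - 1), 1)
    expect_equal(location_score(S, E, a), oracle_location_score(S, E, a))
  }
})

test_that("subfragments are fifths of the fragment, compressed when short", {
  full <- data.frame(start = 0, end = 40000)
  expect_equal(subfragment_index(0, full), 1L)
  expect_equal(subfragment_index(32000, full), 5L)
  expect_equal(subfragment_index(15999, full), 2L)
  expect_equal(subfragment_index(39999, full), 5L)
  expect_error(subfragment_index(40000, full), "outside")
  short <- data.frame(start = 80000, end = 90000)  # width 2000 per fifth
  expect_equal(subfragment_index(80000, short), 1L)
  expect_equal(subfragment_index(84500, short), 3L)
  expect_equal(subfragment_index(89999, short), 5L)
})

test_that("first-set selection takes the best-centred passing SNP per round", {
  sc <- make_scaffolds(40000)
  fr <- partition_fragments(sc)
  sites <- make_sites("scaffold_1", c(5001, 18001))  # offsets 5000, 18000
  sel <- select_first_set(sites, fr)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$position, 18001)
  expect_equal(sel$location_score, 36000)
  expect_equal(sel$round, 1)

  # a fragment whose only SNP is rare fills at round 5, not round 1
  rare <- make_sites("scaffold_1", 20001, maf = 0.02, gr = 0.2)
  sel_rare <- select_first_set(rare, fr)
  expect_equal(sel_rare$round, 5)

  # nothing passes in any round -> fragment stays empty
  bad <- make_sites("scaffold_1", 20001, design = 0.1)
  expect_equal(nrow(select_first_set(bad, fr)), 0)
  expect_error(select_first_set(sites, fr, list()), "non-empty")

  # ties in score break to higher MAF, then lower position
  tie <- make_sites("scaffold_1", c(15001, 25001))
  tie$maf <- c(0.10, 0.30)
  expect_equal(select_first_set(tie, fr)$position, 25001)
  tie$maf <- c(0.30, 0.30)
  expect_equal(select_first_set(tie, fr)$position, 15001)
})

test_that("earlier rounds keep their fragments when later rounds run", {
  sc <- make_scaffolds(80000)
  fr <- partition_fragments(sc)
  sites <- rbind(
    make_sites("scaffold_1", c(20001, 21001)),            # fragment 0, round 1
    make_sites("scaffold_1", 60001, maf = 0.02, gr = 0.2) # fragment 1, round 5
  )
  sel <- select_first_set(sites, fr)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$round[sel$fragment_index == 0], 1)
  expect_equal(sel$round[sel$fragment_index == 1], 5)
  # every entry passes its recorded round's filter
  sched <- default_round_schedule()
  for (k in seq_len(nrow(sel))) {
    row <- sites[sites$snp_id == sel$snp_id[k], ]
    expect_equal(nrow(apply_round_filter(row, sched[[sel$round[k]]])), 1)
  }
})

test_that("second set lands two subfragments clockwise from the first", {
  sc <- make_scaffolds(40000)
  fr <- partition_fragments(sc)
  # first SNP in subfragment 1; candidates in subfragments 2..5
  sites <- make_sites("scaffold_1", c(4001, 12001, 20001, 28001, 36001))
  first <- make_sites("scaffold_1", 4001)
  first_sel <- select_first_set(first, fr)
  expect_equal(first_sel$subfragment, 1L)
  second <- select_second_set(sites, first_sel, fr)
  expect_equal(second$subfragment, 3L)          # 1 -> 3
  expect_true(second$position - 1 >= 16000 && second$position - 1 < 24000)

  # wrap rule: subfragment 4 -> 1, 5 -> 2
  first4 <- select_first_set(make_sites("scaffold_1", 28001), fr)
  expect_equal(first4$subfragment, 4L)
  second4 <- select_second_set(sites, first4, fr)
  expect_equal(second4$subfragment, 1L)
  expect_equal(second4$position, 4001)

  first5 <- select_first_set(make_sites("scaffold_1", 36001), fr)
  second5 <- select_second_set(sites, first5, fr)
  expect_equal(second5$subfragment, 2L)

  # the first-set SNP itself is never reused even if it sits in target
  lone <- make_sites("scaffold_1", 20001)
  fs <- select_first_set(lone, fr)        # subfragment 3
  expect_equal(nrow(select_second_set(lone, fs, fr)), 0)
})

test_that("second-set scores are computed against the subfragment midpoint", {
  sc <- make_scaffolds(40000)
  fr <- partition_fragments(sc)
  first_sel <- select_first_set(make_sites("scaffold_1", 4001), fr)
  # target subfragment 3 spans [16000, 24000); midpoint 20000
  cands <- make_sites("scaffold_1", c(17001, 20001, 23001))
  second <- select_second_set(cands, first_sel, fr)
  expect_equal(second$position, 20001)
  expect_equal(second$location_score, 8000)
})

test_that("candidate-gene inclusion respects half-open intervals and filters", {
  sc <- make_scaffolds(50000)
  fr <- partition_fragments(sc)
  bed <- data.frame(scaffold_id = "scaffold_1", start = 10000, end = 12000,
                    name = "KRT_cluster")
  inside <- make_sites("scaffold_1", c(10001, 11001, 12000))
  # 0-based offsets 10000, 11000, 11999: all inside [10000, 12000)
  got <- include_candidate_snps(inside, bed, fr, sc)
  expect_equal(nrow(got), 3)
  expect_true(all(got$set_label == "candidate"))

  at_end <- make_sites("scaffold_1", 12001)  # offset 12000: excluded
  expect_equal(nrow(include_candidate_snps(at_end, bed, fr, sc)), 0)

  mixed <- make_sites("scaffold_1", 10001 + 0:9 * 100)
  mixed$design_score <- c(rep(0.7, 7), rep(0.3, 3))
  mixed$flank_clear_40 <- TRUE
  expect_equal(nrow(include_candidate_snps(mixed, bed, fr, sc)), 7)

  bad_bed <- data.frame(scaffold_id = "scaffold_9", start = 0, end = 10)
  expect_error(include_candidate_snps(inside, bad_bed, fr, sc), "unknown")
})

test_that("panel assembly deduplicates across sets with candidate priority", {
  sc <- make_scaffolds(200000)
  fr <- partition_fragments(sc)
  first <- select_first_set(make_sites("scaffold_1", c(20001, 60001, 100001)), fr)
  second <- select_second_set(
    make_sites("scaffold_1", c(20001, 60001, 100001, 52001, 92001)), first, fr)
  bed <- data.frame(scaffold_id = "scaffold_1", start = 19000, end = 21000)
  cand <- include_candidate_snps(make_sites("scaffold_1", c(20001, 140001)),
                                 bed, fr, sc)
  expect_equal(nrow(cand), 1)  # 140001 outside the interval
  panel <- assemble_panel(first, second, cand)
  expect_equal(nrow(panel), nrow(first) + nrow(second))  # overlap removed
  expect_equal(panel$set_label[panel$position == 20001], "candidate")
  expect_false(any(duplicated(paste(panel$scaffold_id, panel$position))))
  # additivity with disjoint sets
  panel2 <- assemble_panel(first, second)
  expect_equal(nrow(panel2), nrow(first) + nrow(second))
})

test_that("per fragment there is at most one first and one second entry", {
  set.seed(42)
  sc <- make_scaffolds(sample(50000:300000, 5))
  fr <- partition_fragments(sc)
  sites <- do.call(rbind, lapply(seq_len(nrow(sc)), function(s) {
    n <- 60
    st <- make_sites(sc$scaffold_id[s], sort(sample.int(sc$length[s], n)))
    st$maf <- round(runif(n, 0.005, 0.5), 3)
    st$genotyping_rate <- round(runif(n, 0.1, 1), 2)
    st$flank_clear_35 <- st$flank_clear_40 <- runif(n) < 0.9
    st
  }))
  first <- select_first_set(sites, fr)
  second <- select_second_set(sites, first, fr)
  expect_false(any(duplicated(paste(first$scaffold_id, first$fragment_index))))
  expect_false(any(duplicated(paste(second$scaffold_id, second$fragment_index))))
  both <- merge(first, second, by = c("scaffold_id", "fragment_index"))
  # first and second always differ by exactly two subfragments (mod 5)
  expect_true(all((both$subfragment.y - both$subfragment.x) %% 5 == 2))
})
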