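test_that("the synthetic single-copy locus meets its design constraints", {
  s <- build_single_locus(seed = 1)
  seq <- s$locus$sequence
  # probe fragment is exactly 5.2 kb
  d <- virtual_digest(seq, probe = s$truth$probe)
  expect_equal(d$length[d$contains_probe], 5200L)
  expect_equal(s$truth$expected_single_fragment_bp, 5200L)
  # no GAATTC anywhere between the two flanking sites
  inner <- substr(seq, s$locus$left_ecoRI + 7L, s$locus$right_ecoRI)
  expect_false(grepl("GAATTC", inner, fixed = TRUE))
  # CUP1 is a 61-codon ORF on the minus strand
  f <- s$locus$features
  cup1 <- f[f$name == "CUP1", ]
  expect_equal(cup1$end - cup1$start, 186L)
  orf <- revcomp(substr(seq, cup1$start + 1L, cup1$end))
  expect_equal(substr(orf, 1, 3), "ATG")
  expect_true(substr(orf, 184, 186) %in% c("TAA", "TAG", "TGA"))
  codons <- substring(orf, seq(4, 180, 3), seq(6, 182, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  # every future junction has at most 3 bp of natural microhomology
  for (j in s$truth$junctions) expect_lte(j$microhomology, 3L)
})

test_that("the generator is deterministic per seed", {
  a <- build_single_locus(seed = 9)
  b <- build_single_locus(seed = 9)
  expect_identical(a$locus$sequence, b$locus$sequence)
  expect_identical(a$truth$primers, b$truth$primers)
  expect_false(identical(build_single_locus(seed = 10)$locus$sequence,
                         a$locus$sequence))
  x <- generate_array_strain(3, 7, seed = 4)
  y <- generate_array_strain(3, 7, seed = 4)
  expect_identical(x$locus$sequence, y$locus$sequence)
  expect_identical(x$truth$n_mutations, y$truth$n_mutations)
})

test_that("infeasible locus configurations are rejected", {
  cfg <- default_locus_config()
  cfg$cup1 <- c(100L, 286L)          # outside RUF5
  expect_error(build_single_locus(seed = 1, config = cfg), "infeasible")
  cfg2 <- default_locus_config()
  cfg2$rsc30 <- c(2000L, 4620L)      # overlaps RUF5
  expect_error(build_single_locus(seed = 1, config = cfg2), "infeasible")
})

test_that("array strains carry their truth-logged structure", {
  # unit length recovery at zero divergence
  arr <- generate_array_strain(1, 2, divergence = zero_divergence,
                               seed = 7)
  pc <- infer_unit_length(array_span(arr), 1000, 2500)
  expect_equal(pc$period, arr$truth$unit_len_bp)
  expect_equal(pc$match_fraction, 1)
  # event log: one NHEJ duplication then n - 2 crossover expansions
  arr5 <- generate_array_strain(2, 5, divergence = zero_divergence,
                                seed = 2)
  kinds <- vapply(arr5$truth$events, `[[`, "", "kind")
  expect_equal(kinds, c("NHEJ_dup", rep("unequal_CO", 3)))
  # expected fragment arithmetic
  expect_equal(arr5$truth$expected_fragment_bp, 5200L + 4L * 1800L)
  # n = 1 yields the single locus and no outward PCR product
  one <- generate_array_strain(4, 1, seed = 3)
  pr <- one$truth$single_truth$primers
  expect_equal(nrow(insilico_pcr(one$locus$sequence, pr$cup1_fwd,
                                 pr$cup1_rev)), 0L)
  expect_error(generate_array_strain(7, 2, seed = 1))
})

test_that("junction cases are recovered exactly at zero mismatch rate", {
  cases <- generate_junction_cases(seed = 5, n_cases = 100,
                                   mh_range = c(3L, 3L),
                                   ins_range = c(0L, 0L))
  expect_true(all(cases$truth$microhomology == 3L))
  hits <- 0L
  for (i in seq_len(100)) {
    jc <- map_junction(cases$junctions[i], cases$distal_refs[i],
                       cases$proximal_refs[i])
    if (jc$microhomology_len == 3L && jc$inserted_seq == "") hits <- hits + 1L
  }
  expect_equal(hits, 100L)

  # blunt case
  blunt <- generate_junction_cases(seed = 6, n_cases = 10,
                                   mh_range = c(0L, 0L),
                                   ins_range = c(0L, 0L))
  for (i in 1:10) {
    jc <- map_junction(blunt$junctions[i], blunt$distal_refs[i],
                       blunt$proximal_refs[i])
    expect_equal(jc$microhomology_len, 0L)
    expect_equal(jc$inserted_seq, "")
  }

  # an isolated SNP in the distal match is tolerated and recorded
  snp <- generate_junction_cases(seed = 8, n_cases = 30,
                                 mismatch_rate = 1)
  idx <- which(snp$truth$has_snp)
  expect_gt(length(idx), 0L)
  for (i in idx) {
    jc <- map_junction(snp$junctions[i], snp$distal_refs[i],
                       snp$proximal_refs[i])
    expect_equal(jc$prefix_len, snp$truth$prefix_len[i])
    expect_gte(length(jc$mismatch_positions), 1L)
  }
})

test_that("homopolymer-expansion inserts are generated and recovered", {
  cases <- generate_junction_cases(seed = 12, n_cases = 80,
                                   mh_range = c(0L, 0L),
                                   ins_range = c(7L, 7L),
                                   homopolymer_fraction = 1)
  hp <- cases$truth$is_homopolymer
  expect_gt(sum(hp), 0L)
  for (i in which(hp)[1:10]) {
    jc <- map_junction(cases$junctions[i], cases$distal_refs[i],
                       cases$proximal_refs[i])
    expect_equal(nchar(jc$inserted_seq), 7L)
    expect_equal(jc$inserted_seq, cases$truth$ins_seq[i])
    # all inserted bases equal the adjacent repeated base
    expect_equal(length(unique(strsplit(jc$inserted_seq, "")[[1]])), 1L)
  }
})

test_that("depth tracks behave as Poisson coverage scaled by copy number", {
  arr1 <- generate_array_strain(2, 1, seed = 6)
  trk1 <- generate_depth_track(arr1$truth, mean_coverage = 30, seed = 6)
  est1 <- copy_number_from_depth(trk1$depth, trk1$unit_interval,
                                 trk1$baseline_intervals)
  expect_equal(est1$copies, 1, tolerance = 0.05)
  arr18 <- generate_array_strain(3, 18, divergence = zero_divergence,
                                 seed = 6)
  trk18 <- generate_depth_track(arr18$truth, mean_coverage = 30, seed = 7)
  est18 <- copy_number_from_depth(trk18$depth, trk18$unit_interval,
                                  trk18$baseline_intervals)
  expect_equal(est18$copies_rounded, 18L)
  expect_warning(generate_depth_track(arr1$truth, mean_coverage = 0.5),
                 "unreliable")
})

test_that("synthetic strains round-trip through FASTA/GFF3/JSON on disk", {
  arr <- generate_array_strain(5, 3, divergence = zero_divergence,
                               seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_strain(arr, dir, name = "t5n3")
  expect_true(all(file.exists(paths)))
  fa <- read_fasta(paths["fasta"])
  expect_identical(unname(fa["t5n3"]), arr$locus$sequence)
  feats <- read_gff3(paths["gff3"])
  expect_equal(nrow(feats), nrow(arr$locus$features))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$n, 3L)
  expect_equal(truth$type_id, 5L)
})

test_that("the full pipeline recovers truth across types and copy numbers", {
  # digest -> copy number; period -> type; junction -> classification,
  # at the default divergence (0.7%/0.4%/0.5%)
  grid <- expand.grid(type = 1:5, n = c(2L, 3L, 7L, 14L, 18L))
  grid <- grid[order(grid$type), ]
  seeds <- seq_len(nrow(grid)) + 100L
  for (i in seq_len(nrow(grid))) {
    ty <- grid$type[i]; n <- grid$n[i]
    arr <- generate_array_strain(ty, n, seed = seeds[i])
    tr <- arr$truth
    # copy number from the virtual digest (probe matching tolerant of
    # the repeat-internal divergence, as hybridization is)
    d <- virtual_digest(arr$locus$sequence, probe = tr$single_truth$probe,
                        probe_mismatch = 8L)
    frag_kb <- d$length[d$contains_probe] / 1000
    expect_equal(
      copy_number_from_fragment(frag_kb, 5.2, tr$unit_len_bp / 1000),
      n, info = sprintf("type %d n %d", ty, n))
    # repeat type from the inferred period
    pc <- infer_unit_length(array_span(arr), 1000, 2200)
    cls <- classify_repeat_type(pc$period)
    expect_equal(cls$type_id, ty, info = sprintf("type %d n %d", ty, n))
    # junction classification from the first junction
    seq0 <- build_single_locus(seed = seeds[i])$locus$sequence
    w <- 80L
    junction <- substr(arr$locus$sequence,
                       tr$distal_break - w + 1L,
                       tr$distal_break + nchar(tr$insert) + w)
    distal_ref <- substr(seq0, tr$distal_break - w + 1L,
                         tr$distal_break + 300L)
    proximal_ref <- substr(seq0, tr$proximal_break - 300L,
                           tr$proximal_break + w)
    jc <- map_junction(junction, distal_ref, proximal_ref)
    expect_equal(jc$classification, "nonhomologous",
                 info = sprintf("type %d n %d", ty, n))
  }
  # single-copy strains complete the grid: flanking assay, no repeat
  # (zero divergence: exact-match primer binding is not a hybridization
  # model, so diverged primer sites are out of the assay's scope)
  for (ty in 1:5) {
    one <- generate_array_strain(ty, 1L, divergence = zero_divergence,
                                 seed = 200L + ty)
    pr <- one$truth$single_truth$primers
    fl <- insilico_pcr(one$locus$sequence, pr$flank_fwd, pr$flank_rev)
    expect_equal(nrow(fl), 1L)
  }
})
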