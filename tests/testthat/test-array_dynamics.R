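test_that("NHEJ duplication conserves sequence across reciprocal products", {
  loc <- toy_locus(100)
  ev <- nhej_duplicate(loc, 30, 50)
  expect_equal(nchar(ev$duplication$sequence), 120L)
  expect_equal(nchar(ev$deletion$sequence), 80L)
  expect_equal(nchar(ev$duplication$sequence) + nchar(ev$deletion$sequence),
               2L * nchar(loc$sequence))
  # with an insertion, the duplication grows by the inserted bases only
  ev2 <- nhej_duplicate(loc, 30, 50, insertion = "TT")
  expect_equal(nchar(ev2$duplication$sequence), 122L)
  # the duplicated segment is present twice
  seg <- substr(loc$sequence, 31, 50)
  hits <- gregexpr(seg, ev$duplication$sequence, fixed = TRUE)[[1]]
  expect_gte(sum(hits > 0), 2L)
  # breaks outside the locus are rejected
  expect_error(nhej_duplicate(loc, 2, 50), "forbidden")
  expect_error(nhej_duplicate(loc, 50, 30))
  # declared microhomology must actually be present at both ends
  expect_error(nhej_duplicate(loc, 30, 50, microhomology_used = 8L),
               "microhomology")
})

test_that("junction mapping recovers the breakpoints of a type-spec duplication", {
  single <- build_single_locus(seed = 7)
  for (sp in single$truth$specs) {
    ev <- nhej_duplicate(single$locus, sp$proximal_break, sp$distal_break,
                         insertion = sp$junction_insert)
    seq0 <- single$locus$sequence
    w <- 80L
    jstart <- ev$junction_at - w          # 0-based
    jend <- ev$junction_at + nchar(sp$junction_insert) + w
    junction <- substr(ev$duplication$sequence, jstart + 1L, jend)
    distal_ref <- substr(seq0, sp$distal_break - w + 1L,
                         min(sp$distal_break + 300L, nchar(seq0)))
    proximal_ref <- substr(seq0, max(1L, sp$proximal_break - 300L),
                           sp$proximal_break + w)
    jc <- map_junction(junction, distal_ref, proximal_ref)
    truth <- single$truth$junctions[[sp$type_id]]
    expect_equal(jc$inserted_seq, truth$insert)
    expect_equal(jc$microhomology_len, truth$microhomology)
    expect_equal(jc$classification, "nonhomologous")
    # matched extensions place the breaks exactly, up to microhomology
    expect_equal(jc$prefix_len + jc$suffix_len - jc$microhomology_len +
                   nchar(jc$inserted_seq), nchar(junction))
  }
})

test_that("unequal crossover transfers units and markers reciprocally", {
  a <- array_state(14, marker_units = 7)
  b <- array_state(14, marker_units = 7)
  ev <- unequal_crossover(a, b, k = 13, cross_after = 1)
  expect_equal(ev$gain$n, 27L)
  expect_equal(ev$loss$n, 1L)
  # the single-unit product carries no marker; the long product both
  expect_length(ev$loss$marker_units, 0L)
  expect_equal(ev$gain$marker_units, c(7L, 20L))
  # offsets that would empty an array are rejected
  expect_error(unequal_crossover(a, b, k = 14))
  expect_error(unequal_crossover(a, b, k = 0))
})

test_that("crossover products match the token-level oracle exhaustively", {
  for (na in 2:4) for (nb in 2:4) {
    for (ma in 1:na) for (mb in 1:nb) {
      a <- array_state(na, ma); b <- array_state(nb, mb)
      for (k in 1:(nb - 1)) {
        i_max <- min(na, nb - k)
        if (i_max < 1) next
        for (i in 1:i_max) {
          ev <- unequal_crossover(a, b, k, cross_after = i)
          orc <- oracle_crossover(marks_vec(na, ma), marks_vec(nb, mb),
                                  k, i)
          expect_equal(ev$gain$n, length(orc$gain))
          expect_equal(ev$loss$n, length(orc$loss))
          expect_equal(ev$gain$marker_units, which(orc$gain))
          expect_equal(ev$loss$marker_units, which(orc$loss))
        }
      }
    }
  }
})

test_that("crossovers conserve total units and markers over random events", {
  set.seed(99)
  for (rep in 1:500) {
    na <- sample(2:20, 1); nb <- sample(2:20, 1)
    a <- array_state(na, sample.int(na, sample(0:2, 1)))
    b <- array_state(nb, sample.int(nb, sample(0:2, 1)))
    k <- sample.int(nb - 1, 1)
    ev <- unequal_crossover(a, b, k)
    expect_equal(ev$gain$n + ev$loss$n, na + nb)
    expect_equal(length(ev$gain$marker_units) + length(ev$loss$marker_units),
                 length(a$marker_units) + length(b$marker_units))
  }
})

test_that("contractions remove units and excised markers correctly", {
  a <- array_state(14, marker_units = 5)
  ev <- contract_array(a, "popout", k_lost = 13, start = 1)
  expect_equal(ev$state$n, 1L)
  expect_length(ev$state$marker_units, 0L)
  expect_equal(ev$circle_units, 13L)
  ev2 <- contract_array(array_state(2, 1), "SSA", k_lost = 1, start = 2)
  expect_equal(ev2$state$n, 1L)
  expect_equal(ev2$state$marker_units, 1L)
  expect_null(ev2$circle_units)
  # marker at unit 5, excision spanning units 3-9
  ev3 <- contract_array(a, "SSA", k_lost = 7, start = 3)
  expect_length(ev3$state$marker_units, 0L)
  # marker outside the excised span survives, reindexed
  ev4 <- contract_array(a, "popout", k_lost = 3, start = 1)
  expect_equal(ev4$state$marker_units, 2L)
  expect_error(contract_array(a, "popout", k_lost = 14))
})

test_that("marker-loss simulation matches the enumerated closed form", {
  # degenerate distribution forcing k = n - 1: every loss ends single-copy
  sim1 <- simulate_marker_loss(14, 7, per_division_loss_rate = 0.5,
                               kind_weights = c(popout = 1),
                               k_sampler = function(m, n0)
                                 rep(n0 - 1L, m),
                               n_events = 2000, seed = 1)
  expect_equal(sim1$fraction_single_copy, 1.0)
  # zero events
  sim0 <- simulate_marker_loss(14, 7, per_division_loss_rate = 1e-9,
                               n_divisions = 10, seed = 1)
  expect_equal(sim0$n_events, 0L)
  expect_true(is.na(sim0$fraction_single_copy))

  # pop-out model, uniform k and span: exact conditional probability of
  # the single-copy endpoint among marker-loss events, by enumeration
  n0 <- 14L; m <- 7L
  p_loss <- p_single <- 0
  for (k in 1:(n0 - 1L)) {
    for (s in 1:(n0 - k + 1L)) {
      w <- (1 / (n0 - 1L)) * (1 / (n0 - k + 1L))
      if (s <= m && m <= s + k - 1L) {
        p_loss <- p_loss + w
        if (k == n0 - 1L) p_single <- p_single + w
      }
    }
  }
  expected <- p_single / p_loss
  sim <- simulate_marker_loss(n0, m, per_division_loss_rate = 0.5,
                              kind_weights = c(popout = 1),
                              n_events = 1e5, seed = 42)
  se <- sqrt(expected * (1 - expected) / sim$loss_events)
  expect_lt(abs(sim$fraction_single_copy - expected), 4 * se)
})

test_that("marker-loss simulation is reproducible given a seed", {
  s1 <- simulate_marker_loss(14, 7, 0.2, n_divisions = 1e5, seed = 7)
  s2 <- simulate_marker_loss(14, 7, 0.2, n_divisions = 1e5, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_marker_loss(14, 7, 0.2, n_divisions = 1e5, seed = 8)
  expect_false(identical(s1$loss_events, s3$loss_events) &&
                 identical(s1$n_events, s3$n_events))
})
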