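# Independent brute-force junction oracle.
#
# For one side it enumerates every reference start position and, per
# start, the candidate match lengths (the window itself and each position
# just before a mismatch), accepting the longest whose mismatch pattern
# satisfies the policy predicate below.  The predicate is written
# directly from the policy definition, independently of the extension
# algorithm in the package.

oracle_policy_ok <- function(eq, flank = 5L) {
  mm <- which(!eq)
  if (!length(mm)) return(TRUE)
  all(mm > flank) &&
    all(mm <= length(eq) - flank) &&
    (length(mm) < 2L || all(diff(mm) > flank))
}

oracle_side_max <- function(query, ref, flank = 5L,
                            allow_mismatches = TRUE) {
  qv <- utf8ToInt(query)
  rv <- utf8ToInt(ref)
  best <- 0L
  for (s in seq_along(rv)) {
    w <- min(length(qv), length(rv) - s + 1L)
    if (w < 1L) next
    eq <- qv[seq_len(w)] == rv[s:(s + w - 1L)]
    if (!allow_mismatches) {
      mm <- which(!eq)
      p <- if (length(mm)) mm[1] - 1L else w
      best <- max(best, p)
      next
    }
    mm <- which(!eq)
    for (p in sort(unique(c(w, mm - 1L)), decreasing = TRUE)) {
      if (p <= best) break
      if (oracle_policy_ok(eq[seq_len(p)], flank)) {
        best <- p
        break
      }
    }
  }
  best
}

oracle_map_junction <- function(junction, distal_ref, proximal_ref,
                                flank = 5L, allow_mismatches = TRUE) {
  Lj <- nchar(junction)
  rev_str <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  P <- min(Lj, oracle_side_max(junction, distal_ref, flank,
                               allow_mismatches))
  S <- min(Lj, oracle_side_max(rev_str(junction), rev_str(proximal_ref),
                               flank, allow_mismatches))
  if (P + S >= Lj) {
    list(microhomology = P + S - Lj, inserted_seq = "")
  } else {
    list(microhomology = 0L,
         inserted_seq = substr(junction, P + 1L, Lj - S))
  }
}

# Token-level oracle for unequal crossover: represents each array as a
# logical vector (TRUE = unit carries the marker) and performs the
# exchange by concatenation.
oracle_crossover <- function(a_marks, b_marks, k, i) {
  na <- length(a_marks); nb <- length(b_marks)
  gain <- c(b_marks[seq_len(i + k)],
            if (i < na) a_marks[(i + 1L):na])
  loss <- c(a_marks[seq_len(i)],
            if (i + k < nb) b_marks[(i + k + 1L):nb])
  list(gain = gain, loss = loss)
}

marks_vec <- function(n, marker_units) {
  v <- rep(FALSE, n)
  v[marker_units] <- TRUE
  v
}

# repeat span of a synthetic array strain (0-based half-open
# [proximal_break, distal_break + (n-1)*unit) as a 1-based substring)
array_span <- function(strain) {
  tr <- strain$truth
  substr(strain$locus$sequence, tr$proximal_break + 1L,
         tr$distal_break + (tr$n - 1L) * tr$unit_len_bp)
}

zero_divergence <- c(proximal = 0, distal = 0, repeats = 0)

# guard string whose i-th base differs from the i-th base of `against`
guard_bases <- function(against) {
  ch <- strsplit(against, "")[[1]]
  paste(vapply(ch, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1)), collapse = "")
}

# a minimal valid locus_map for event tests: GAATTC sites at 0 and
# len-6, one feature in the middle
toy_locus <- function(len = 100L, seed = 42L) {
  set.seed(seed)
  s <- random_dna(len)
  substr(s, 1, 6) <- "GAATTC"
  substr(s, len - 5L, len) <- "GAATTC"
  # scrub accidental internal sites
  repeat {
    h <- gregexpr("GAATTC", s, fixed = TRUE)[[1]]
    h <- setdiff(as.integer(h) - 1L, c(0L, len - 6L))
    if (!length(h)) break
    substr(s, h[1] + 3L, h[1] + 3L) <- "C"
  }
  locus_map(s, gene_features("GENE", 10L, 20L, "+"), 0L, len - 6L)
}
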