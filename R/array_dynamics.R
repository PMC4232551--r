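#' Tandem-array state for population simulation
#'
#' A unit-count abstraction of a CUP1 array: the number of repeat units
#' and the (1-based) indices of units carrying an integrated URA3 marker.
#' Reciprocal recombination products can carry 0, 1, or 2 markers, so
#' `marker_units` is a vector.
#'
#' @param n repeat count, at least 1.
#' @param marker_units integer vector of marked unit indices (possibly
#'   empty).
#' @return an object of class `array_state`.
#' @export
array_state <- function(n, marker_units = integer(0)) {
  n <- as.integer(n); marker_units <- as.integer(marker_units)
  stopifnot(n >= 1L)
  if (length(marker_units) &&
      (any(marker_units < 1L) || any(marker_units > n)))
    stop("marker_units must lie in [1, n]")
  structure(list(n = n, marker_units = sort(marker_units)),
            class = "array_state")
}

#' @export
print.array_state <- function(x, ...) {
  cat("<array_state> ", x$n, " units",
      if (length(x$marker_units))
        paste0("; marker at unit ",
               paste(x$marker_units, collapse = ",")) else "",
      "\n", sep = "")
  invisible(x)
}

## lift a feature table across the two segments of an NHEJ product
.lift_features <- function(features, keep_end = NULL, keep_start = NULL,
                           shift = 0L) {
  out <- features[0, ]
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    if (!is.null(keep_end)) {          # segment [0, keep_end)
      s <- f$start; e <- min(f$end, keep_end)
      if (s < keep_end && e > s) {
        f2 <- f; f2$start <- s; f2$end <- e
        out <- rbind(out, f2)
      }
    }
    if (!is.null(keep_start)) {        # segment [keep_start, L) shifted
      s <- max(f$start, keep_start); e <- f$end
      if (e > keep_start && e > s) {
        f2 <- f; f2$start <- s + shift; f2$end <- e + shift
        out <- rbind(out, f2)
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Generate a duplication (and reciprocal deletion) by unequal NHEJ
#'
#' Models the genesis of a tandem duplication from a single-copy locus:
#' one replication fork breaks centromere-proximal to the locus
#' (`proximal_break`) and the other centromere-distal (`distal_break`);
#' nonhomologous end-joining of the distal end of one sister to the
#' proximal end of the other duplicates the intervening segment, while
#' joining of the remaining two ends deletes it from the sister
#' chromatid.
#'
#' @param locus a [locus_map()] of the single-copy locus.
#' @param proximal_break,distal_break 0-based break positions,
#'   `proximal_break < distal_break`, both strictly between the flanking
#'   *Eco*RI cut positions.
#' @param insertion DNA string added at the new junction (possibly "").
#' @param microhomology_used bases of identity at the two break ends used
#'   by the joining; when positive the sequence immediately left of both
#'   breaks must be identical over that many bases.
#' @return an object of class `nhej_event`: `duplication` and `deletion`
#'   locus maps, plus `junction_at`, the 0-based position in the
#'   duplication product where the second copy (or insertion) begins.
#'   Lengths obey `len(dup) = L + (distal - proximal) + nchar(insertion)`
#'   and `len(del) = L - (distal - proximal)`.
#' @export
nhej_duplicate <- function(locus, proximal_break, distal_break,
                           insertion = "", microhomology_used = 0L) {
  stopifnot(inherits(locus, "locus_map"))
  seq <- locus$sequence
  L <- nchar(seq)
  proximal_break <- as.integer(proximal_break)
  distal_break <- as.integer(distal_break)
  insertion <- toupper(insertion)
  if (proximal_break >= distal_break)
    stop("proximal_break must be < distal_break")
  lo <- locus$left_ecoRI + 6L; hi <- locus$right_ecoRI
  if (proximal_break <= lo || distal_break >= hi)
    stop("breaks fall in a forbidden zone outside the locus (beyond the ",
         "flanking EcoRI sites)")
  m <- as.integer(microhomology_used)
  if (m > 0L) {
    a <- .sub0(seq, distal_break - m, distal_break)
    b <- .sub0(seq, proximal_break - m, proximal_break)
    if (a != b)
      stop("microhomology_used = ", m,
           " but break ends are not identical over that span")
  }
  span <- distal_break - proximal_break
  ins_len <- nchar(insertion)

  dup_seq <- paste0(.sub0(seq, 0L, distal_break), insertion,
                    .sub0(seq, proximal_break, L))
  dup_feats <- rbind(
    .lift_features(locus$features, keep_end = distal_break),
    .lift_features(locus$features, keep_start = proximal_break,
                   shift = span + ins_len)
  )
  dup <- locus_map(dup_seq, dup_feats, locus$left_ecoRI,
                   locus$right_ecoRI + span + ins_len)

  del_seq <- paste0(.sub0(seq, 0L, proximal_break),
                    .sub0(seq, distal_break, L))
  del_feats <- rbind(
    .lift_features(locus$features, keep_end = proximal_break),
    .lift_features(locus$features, keep_start = distal_break,
                   shift = -span)
  )
  del <- locus_map(del_seq, del_feats, locus$left_ecoRI,
                   locus$right_ecoRI - span)

  structure(list(duplication = dup, deletion = del,
                 proximal_break = proximal_break,
                 distal_break = distal_break,
                 insertion = insertion,
                 microhomology_used = m,
                 junction_at = distal_break),
            class = "nhej_event")
}

#' Unequal crossover between two sister arrays
#'
#' Homologous recombination between misaligned arrays: with the second
#' array slid `k` units, a crossover at the boundary after unit
#' `cross_after` of `a` yields reciprocal products of `a$n + k` and
#' `b$n - k` units.  Total unit count and total marker count are
#' conserved; markers are reassigned by unit index, so a product can
#' carry 0, 1, or 2 markers.
#'
#' @param a,b [array_state()] objects (sister chromatids).
#' @param k misalignment offset in units, `1 <= k <= b$n - 1` (both
#'   products must retain at least one unit).
#' @param cross_after boundary in `a` after which the exchange occurs,
#'   in `1..min(a$n, b$n - k)`; drawn uniformly from that range when
#'   `NULL` (uses the current RNG stream).
#' @return list of class `crossover_event` with `gain` (`a$n + k` units),
#'   `loss` (`b$n - k` units), `k`, and `cross_after`.
#' @export
unequal_crossover <- function(a, b, k, cross_after = NULL) {
  stopifnot(inherits(a, "array_state"), inherits(b, "array_state"))
  k <- as.integer(k)
  if (k < 1L || k > b$n - 1L)
    stop("offset k must satisfy 1 <= k <= b$n - 1 (products must each ",
         "retain at least one unit)")
  i_max <- min(a$n, b$n - k)
  if (i_max < 1L) stop("no feasible crossover boundary for this offset")
  i <- if (is.null(cross_after)) sample.int(i_max, 1L)
       else as.integer(cross_after)
  if (i < 1L || i > i_max)
    stop("cross_after must lie in 1..", i_max)
  ## gain = b[1..i+k] ++ a[i+1..a$n] ; loss = a[1..i] ++ b[i+k+1..b$n]
  gain_marks <- c(b$marker_units[b$marker_units <= i + k],
                  a$marker_units[a$marker_units > i] + k)
  loss_marks <- c(a$marker_units[a$marker_units <= i],
                  b$marker_units[b$marker_units > i + k] - k)
  structure(list(gain = array_state(a$n + k, gain_marks),
                 loss = array_state(b$n - k, loss_marks),
                 k = k, cross_after = i),
            class = "crossover_event")
}

#' Contract an array by pop-out or single-strand annealing
#'
#' Removes `k_lost` contiguous units.  An intrachromatid pop-out
#' additionally excises those units as a circular molecule; single-strand
#' annealing destroys them.  The marker is lost iff a marked unit lies in
#' the excised span.
#'
#' @param a an [array_state()].
#' @param kind `"popout"` or `"SSA"`.
#' @param k_lost units removed, `1 <= k_lost <= a$n - 1`.
#' @param start first excised unit (1-based); drawn uniformly from the
#'   feasible range when `NULL`.
#' @return list of class `contraction_event` with `state` (the contracted
#'   array), `excised_span` (`c(first, last)` unit indices), and, for
#'   pop-outs, `circle_units`.
#' @export
contract_array <- function(a, kind = c("popout", "SSA"), k_lost,
                           start = NULL) {
  stopifnot(inherits(a, "array_state"))
  kind <- match.arg(kind)
  k_lost <- as.integer(k_lost)
  if (k_lost < 1L || k_lost >= a$n)
    stop("k_lost must satisfy 1 <= k_lost <= n - 1")
  s_max <- a$n - k_lost + 1L
  s <- if (is.null(start)) sample.int(s_max, 1L) else as.integer(start)
  if (s < 1L || s > s_max) stop("start must lie in 1..", s_max)
  e <- s + k_lost - 1L
  keep <- a$marker_units[a$marker_units < s | a$marker_units > e]
  keep[keep > e] <- keep[keep > e] - k_lost
  structure(list(state = array_state(a$n - k_lost, keep),
                 kind = kind, excised_span = c(s, e),
                 circle_units = if (kind == "popout") k_lost else NULL),
            class = "contraction_event")
}

#' Simulate loss of an array-internal URA3 marker over many divisions
#'
#' Emulates a 5-FOA marker-loss screen: events arise at
#' `per_division_loss_rate` per division over `n_divisions` divisions;
#' each event acts independently on a fresh copy of the starting array
#' (event kinds: unequal crossover between identical marked sisters, with
#' one daughter product inherited at random; pop-out; single-strand
#' annealing).  The tally records how many events actually lost the
#' marker and, among those, how many reduced the array to a single copy
#' -- the experimental endpoint of a single-copy revertant screen.
#'
#' @param n0 starting repeat count.
#' @param marker_unit index of the marked unit.
#' @param per_division_loss_rate event rate per division, in (0, 1).
#' @param n_divisions divisions simulated (ignored when `n_events`
#'   given).
#' @param kind_weights named weights over
#'   `c("unequal_CO", "popout", "SSA")`; must sum to a positive value.
#' @param k_sampler optional `function(m, n0)` returning `m` event sizes
#'   in `1..n0-1`; uniform when `NULL`.
#' @param n_events directly sets the number of events (bypasses the
#'   binomial draw over divisions); useful for fixed-size experiments.
#' @param seed optional seed applied with [set.seed()].
#' @return list of class `marker_loss_sim`: `n_events`, `loss_events`,
#'   `single_copy_events` (marker-loss events ending at one repeat),
#'   `fraction_single_copy` (among marker-loss events), and a per-kind
#'   breakdown.
#' @export
simulate_marker_loss <- function(n0, marker_unit, per_division_loss_rate,
                                 n_divisions = NULL,
                                 kind_weights = c(unequal_CO = 1/3,
                                                  popout = 1/3, SSA = 1/3),
                                 k_sampler = NULL, n_events = NULL,
                                 seed = NULL) {
  n0 <- as.integer(n0); m <- as.integer(marker_unit)
  stopifnot(n0 >= 2L, m >= 1L, m <= n0)
  if (is.null(n_events)) {
    stopifnot(per_division_loss_rate > 0, per_division_loss_rate < 1,
              !is.null(n_divisions))
    if (!is.null(seed)) set.seed(seed)
    n_events <- rbinom(1L, as.integer(n_divisions),
                       per_division_loss_rate)
  } else if (!is.null(seed)) set.seed(seed)
  kw <- kind_weights[c("unequal_CO", "popout", "SSA")]
  kw[is.na(kw)] <- 0
  if (any(kw < 0) || sum(kw) <= 0)
    stop("kind_weights must be nonnegative and sum to a positive value")
  empty <- list(n_events = n_events, loss_events = 0L,
                single_copy_events = 0L, fraction_single_copy = NA_real_,
                by_kind = stats::setNames(integer(3), names(kw)))
  if (n_events == 0L) return(structure(empty, class = "marker_loss_sim"))

  kinds <- sample(names(kw), n_events, replace = TRUE, prob = kw)
  k <- if (is.null(k_sampler)) sample.int(n0 - 1L, n_events, replace = TRUE)
       else as.integer(k_sampler(n_events, n0))
  if (any(k < 1L) || any(k > n0 - 1L))
    stop("event sizes must lie in 1..n0-1")

  lost <- logical(n_events); single <- logical(n_events)
  co <- kinds == "unequal_CO"
  if (any(co)) {
    kc <- k[co]
    i <- 1L + floor(runif(sum(co)) * (n0 - kc))       # boundary, 1..n0-k
    short <- runif(sum(co)) < 0.5                     # which daughter
    ## loss product a[1..i] ++ b[i+k+1..n0] is markerless iff i < m <= i+k
    lost[co] <- short & (i < m) & (m <= i + kc)
    single[co] <- lost[co] & (n0 - kc == 1L)
  }
  con <- !co
  if (any(con)) {
    kc <- k[con]
    s <- 1L + floor(runif(sum(con)) * (n0 - kc + 1L))  # span start
    lost[con] <- (s <= m) & (m <= s + kc - 1L)
    single[con] <- lost[con] & (kc == n0 - 1L)
  }
  by_kind <- vapply(names(kw), function(x) sum(lost & kinds == x),
                    integer(1))
  structure(list(
    n_events = n_events,
    loss_events = sum(lost),
    single_copy_events = sum(single),
    fraction_single_copy = if (any(lost)) sum(single) / sum(lost)
                           else NA_real_,
    by_kind = by_kind), class = "marker_loss_sim")
}

#' @export
print.marker_loss_sim <- function(x, ...) {
  cat("<marker_loss_sim> ", x$n_events, " events, ", x$loss_events,
      " lost the marker; ", x$single_copy_events,
      " reduced the array to a single copy (fraction ",
      signif(x$fraction_single_copy, 3), ")\n", sep = "")
  invisible(x)
}
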