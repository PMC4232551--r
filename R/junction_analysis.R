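## Maximal valid match length given the per-position equality vector of a
## candidate alignment.  Under the mismatch policy a single-base mismatch is
## tolerated only when flanked by >= `flank` exact matches on both sides
## (within the matched segment); two mismatches closer than `flank + 1`
## terminate the extension.
.max_valid_prefix <- function(eq, flank = 5L, allow_mismatches = TRUE) {
  n <- length(eq)
  mm <- which(!eq)
  if (!length(mm)) return(n)
  if (!allow_mismatches) return(mm[1] - 1L)
  prev <- -(flank + 1L)
  for (i in mm) {
    if (i <= flank) return(i - 1L)        # no room for a left flank
    if (i - prev <= flank) return(prev - 1L)  # two mismatches too close
    prev <- i
  }
  last <- mm[length(mm)]
  if (n < last + flank) last - 1L else n
}

## Longest prefix of `query` matching a substring of `ref` under the
## mismatch policy.  Ties between equally long matches are broken towards
## the match whose end lies closest to the end of `ref` (deterministic).
## Returns the match length, the 0-based ref start, and mismatch offsets
## (1-based within the matched prefix).
.best_prefix_match <- function(query, ref, flank = 5L,
                               allow_mismatches = TRUE) {
  qv <- .s2i(query); rv <- .s2i(ref)
  L <- length(qv); R <- length(rv)
  best <- list(len = 0L, ref_start = NA_integer_, mismatches = integer(0),
               ref_end = -1L)
  for (s in seq_len(R)) {
    w <- min(L, R - s + 1L)
    if (w <= best$len && s + best$len - 1L <= best$ref_end) next
    if (w < 1L) break
    eq <- qv[seq_len(w)] == rv[s:(s + w - 1L)]
    p <- .max_valid_prefix(eq, flank, allow_mismatches)
    if (p > best$len ||
        (p == best$len && p > 0L && (s + p - 1L) > best$ref_end)) {
      best <- list(len = p, ref_start = s - 1L,
                   mismatches = which(!eq[seq_len(p)]),
                   ref_end = s + p - 1L)
    }
  }
  best
}

.rev_str <- function(x) .i2s(rev(.s2i(x)))

## longest run of TRUE in a logical vector
.max_run <- function(x) {
  if (!length(x)) return(0L)
  r <- rle(x)
  m <- r$lengths[r$values]
  if (length(m)) max(m) else 0L
}

#' Map a repeat junction against its two flanking references
#'
#' Locates the breakpoint structure of a tandem-repeat junction: the
#' maximal extension of the junction start matching the centromere-distal
#' flanking reference, the maximal extension of the junction end matching
#' the centromere-proximal flanking reference, the overlap of the two
#' matched spans (microhomology, bases attributable to both references),
#' and any unmatched middle segment (inserted bases attributable to
#' neither).
#'
#' Matched extensions tolerate isolated single-base mismatches when flanked
#' by at least `mismatch_flank` exact matches on both sides; two mismatches
#' closer than that terminate the extension.  Among equally long prefix
#' matches the one ending closest to the distal reference's end is taken;
#' symmetrically, the suffix match starting closest to the proximal
#' reference's start (deterministic tie-breaking).
#'
#' @param junction junction DNA string.
#' @param distal_ref centromere-distal flanking reference.
#' @param proximal_ref centromere-proximal flanking reference.
#' @param seed_len minimum run of exact matches required to anchor a side;
#'   if neither side reaches it the junction is reported unmappable.
#' @param allow_mismatches logical; `FALSE` makes extensions strictly exact.
#' @param mismatch_flank exact-match flank required around a tolerated
#'   mismatch.
#' @param homology_threshold_bp passed to [classify_junction()].
#' @return an object of class `junction_call` with fields `prefix_len`,
#'   `suffix_len`, `microhomology_len`, `inserted_seq`,
#'   `mismatch_positions` (1-based offsets within the junction),
#'   `distal_ref_end` / `proximal_ref_start` (1-based reference coordinates
#'   of the matched spans), `mappable`, and `classification`.  The
#'   accounting identity
#'   `prefix_len + suffix_len - microhomology_len + nchar(inserted_seq) ==
#'   nchar(junction)` holds for every mappable call, and a nonempty
#'   insertion implies zero microhomology.
#' @export
map_junction <- function(junction, distal_ref, proximal_ref,
                         seed_len = 12L, allow_mismatches = TRUE,
                         mismatch_flank = 5L, homology_threshold_bp = 3L) {
  junction <- unname(toupper(junction))
  distal_ref <- unname(toupper(distal_ref))
  proximal_ref <- unname(toupper(proximal_ref))
  stopifnot(nchar(junction) > 0L, nchar(distal_ref) > 0L,
            nchar(proximal_ref) > 0L)
  Lj <- nchar(junction)

  pre <- .best_prefix_match(junction, distal_ref,
                            flank = mismatch_flank,
                            allow_mismatches = allow_mismatches)
  ## suffix of junction vs substring of proximal_ref: reverse both; the
  ## prefix tie-break (end nearest ref end) maps to start nearest ref start
  suf <- .best_prefix_match(.rev_str(junction), .rev_str(proximal_ref),
                            flank = mismatch_flank,
                            allow_mismatches = allow_mismatches)

  anchored <- function(m) {
    if (m$len == 0L) return(FALSE)
    eq <- rep(TRUE, m$len); eq[m$mismatches] <- FALSE
    .max_run(eq) >= seed_len
  }
  if (!anchored(pre) && !anchored(suf)) {
    call <- structure(list(prefix_len = NA_integer_,
                           suffix_len = NA_integer_,
                           microhomology_len = NA_integer_,
                           inserted_seq = NA_character_,
                           mismatch_positions = integer(0),
                           distal_ref_end = NA_integer_,
                           proximal_ref_start = NA_integer_,
                           junction_len = Lj, mappable = FALSE,
                           classification = "unmappable"),
                      class = "junction_call")
    return(call)
  }

  pl <- pre$len; sl <- suf$len
  ## cap so the two matched spans cannot each exceed the junction
  pl <- min(pl, Lj); sl <- min(sl, Lj)
  if (pl + sl >= Lj) {
    mh <- pl + sl - Lj
    ins <- ""
  } else {
    mh <- 0L
    ins <- .sub0(junction, pl, Lj - sl)
  }
  mism <- sort(unique(c(pre$mismatches,
                        Lj - suf$mismatches + 1L)))
  call <- structure(list(
    prefix_len = pl, suffix_len = sl, microhomology_len = as.integer(mh),
    inserted_seq = ins, mismatch_positions = as.integer(mism),
    distal_ref_end = if (pl > 0L) pre$ref_start + pl else NA_integer_,
    proximal_ref_start =
      if (sl > 0L) nchar(proximal_ref) - (suf$ref_start + sl) + 1L
      else NA_integer_,
    junction_len = Lj, mappable = TRUE,
    classification = NA_character_), class = "junction_call")
  call$classification <- classify_junction(call, homology_threshold_bp)
  call
}

#' @export
print.junction_call <- function(x, ...) {
  if (!x$mappable) {
    cat("<junction_call> unmappable (", x$junction_len, " bp)\n", sep = "")
    return(invisible(x))
  }
  cat("<junction_call> ", x$junction_len, " bp; prefix ", x$prefix_len,
      ", suffix ", x$suffix_len, ", microhomology ", x$microhomology_len,
      " bp, insertion '", x$inserted_seq, "' (",
      length(x$mismatch_positions), " mismatches); ",
      x$classification, "\n", sep = "")
  invisible(x)
}

#' Classify the joining mechanism of a junction
#'
#' Junctions with at most `homology_threshold_bp` bases of shared homology
#' at the breakpoint are classified `"nonhomologous"` (NHEJ-compatible);
#' longer shared homology indicates a homology-mediated join.
#'
#' @param call a `junction_call` from [map_junction()].
#' @param homology_threshold_bp microhomology tolerated for a
#'   nonhomologous call (default 3 bp).
#' @return `"nonhomologous"`, `"homology-mediated"`, or `"unmappable"`.
#' @export
classify_junction <- function(call, homology_threshold_bp = 3L) {
  stopifnot(inherits(call, "junction_call"))
  if (!isTRUE(call$mappable)) return("unmappable")
  if (call$microhomology_len <= homology_threshold_bp) "nonhomologous"
  else "homology-mediated"
}

#' Infer the repeat-unit length of a tandem array
#'
#' Finds the period `p` in `[min_p, max_p]` maximizing the fraction of
#' positions `i` with `seq[i] == seq[i + p]`; the smallest period wins
#' ties.  A period is only called when the best fraction reaches
#' `match_threshold`; otherwise a no-tandem-structure result is returned.
#'
#' @param array_seq DNA string; must be at least `2 * min_p` long.
#' @param min_p,max_p period search range in bp.
#' @param match_threshold minimum self-match fraction (default 0.95,
#'   comfortably above the ~1% per-position divergence expected between
#'   repeat copies diverging at 0.5% each).
#' @return an object of class `period_call`: `period` (or `NA`),
#'   `match_fraction`, `tandem` (logical), and `phase`, the 0-based offset
#'   of the start of the longest perfectly periodic run.
#' @export
infer_unit_length <- function(array_seq, min_p, max_p,
                              match_threshold = 0.95) {
  array_seq <- toupper(array_seq)
  L <- nchar(array_seq)
  min_p <- as.integer(min_p); max_p <- as.integer(max_p)
  stopifnot(min_p >= 1L, max_p >= min_p)
  if (L < 2L * min_p)
    stop("array_seq must be at least 2 * min_p long")
  v <- .s2i(array_seq)
  ## candidate periods must leave at least min_p bases of self-overlap so
  ## the match fraction is estimated on a meaningful number of positions
  max_p_eff <- min(max_p, L - min_p)
  best_p <- NA_integer_; best_frac <- -1
  for (p in min_p:max_p_eff) {
    frac <- mean(v[seq_len(L - p)] == v[(p + 1L):L])
    if (frac > best_frac + 1e-12) {   # strict: smallest p wins ties
      best_frac <- frac; best_p <- p
    }
  }
  if (is.na(best_p) || best_frac < match_threshold) {
    return(structure(list(period = NA_integer_,
                          match_fraction = max(best_frac, 0),
                          tandem = FALSE, phase = NA_integer_),
                     class = "period_call"))
  }
  eq <- v[seq_len(L - best_p)] == v[(best_p + 1L):L]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  phase <- if (length(runs)) {
    k <- runs[which.max(r$lengths[runs])]
    as.integer(ends[k] - r$lengths[k])     # 0-based start of longest run
  } else NA_integer_
  structure(list(period = best_p, match_fraction = best_frac,
                 tandem = TRUE, phase = phase),
            class = "period_call")
}

#' @export
print.period_call <- function(x, ...) {
  if (x$tandem)
    cat("<period_call> period ", x$period, " bp (match fraction ",
        round(x$match_fraction, 4), ", phase ", x$phase, ")\n", sep = "")
  else
    cat("<period_call> no tandem structure (best match fraction ",
        round(x$match_fraction, 4), ")\n", sep = "")
  invisible(x)
}

#' Assign a repeat unit length to one of the five CUP1 repeat types
#'
#' Matches an inferred unit length to the nearest repeat-type exact length
#' within `tolerance_bp`.  If two nominal lengths both fall within
#' tolerance (possible for the 1998 bp Type 1 vs the 1900 bp Type 4) the
#' call is ambiguous.
#'
#' @param unit_len_bp positive unit length in bp.
#' @param specs list of [repeat_type_spec()] objects (defaults to the
#'   packaged five types).
#' @param tolerance_bp maximum distance to a nominal length (default 60).
#' @return list with `type_id` (integer or `NA`) and `status` one of
#'   `"assigned"`, `"unknown"`, `"ambiguous"`.
#' @export
classify_repeat_type <- function(unit_len_bp,
                                 specs = default_repeat_specs(),
                                 tolerance_bp = 60L) {
  stopifnot(unit_len_bp > 0)
  lens <- vapply(specs, function(s) s$exact_len_bp, integer(1))
  ids <- vapply(specs, function(s) s$type_id, integer(1))
  d <- abs(unit_len_bp - lens)
  hit <- which(d <= tolerance_bp)
  if (length(hit) == 0L)
    list(type_id = NA_integer_, status = "unknown")
  else if (length(hit) > 1L)
    list(type_id = NA_integer_, status = "ambiguous")
  else
    list(type_id = ids[hit], status = "assigned")
}
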