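#' Virtual restriction digest
#'
#' Cuts a sequence at every occurrence of a recognition site.  The cut
#' position within the site is fixed by convention after `cut_offset`
#' bases (default 1, i.e. `G^AATTC` for *Eco*RI); this is irrelevant to
#' fragment lengths at kb resolution but makes fragment boundaries
#' deterministic.
#'
#' @param seq DNA string.
#' @param site recognition sequence (default `GAATTC`).
#' @param cut_offset bases into the site at which the cut falls.
#' @param probe optional probe sequence; fragments containing an
#'   occurrence of the probe (either strand, up to `probe_mismatch`
#'   substitutions) are flagged.
#' @param probe_mismatch substitutions tolerated when locating the probe
#'   (default 0, exact match; hybridization-like tolerance can be
#'   emulated with a small positive value).
#' @return `data.frame` with 0-based half-open `start`, `end`, `length`,
#'   and `contains_probe`.  Fragments partition the input: lengths sum to
#'   `nchar(seq)`.
#' @export
virtual_digest <- function(seq, site = "GAATTC", cut_offset = 1L,
                           probe = NULL, probe_mismatch = 0L) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) > 0L, nchar(site) > 0L,
            cut_offset >= 0L, cut_offset <= nchar(site))
  L <- nchar(seq)
  hits <- gregexpr(site, seq, fixed = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else as.integer(hits) - 1L + cut_offset
  bounds <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
  frags <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  frags$length <- frags$end - frags$start
  frags$contains_probe <- FALSE
  if (!is.null(probe)) {
    probe <- toupper(probe)
    subj <- Biostrings::DNAString(seq)
    for (p in unique(c(probe, revcomp(probe)))) {
      ph <- Biostrings::matchPattern(p, subj,
                                     max.mismatch = probe_mismatch)
      for (s in Biostrings::start(ph) - 1L) {
        e <- s + nchar(p)
        frags$contains_probe <- frags$contains_probe |
          (frags$start <= s & frags$end >= e)
      }
    }
  }
  frags
}

#' Copy number from an EcoRI fragment size
#'
#' The *Eco*RI fragment hybridizing to a CUP1 probe grows by one repeat
#' unit per extra copy, so `n = round((L_frag - L_single)/unit) + 1`,
#' rounding to the nearest unit count with ties rounded down
#' (`ceiling(q - 1/2)`).  The tie rule matters: a 18.7 kb fragment of
#' 1.8 kb repeats sits exactly on a half-unit boundary
#' ((18.7 - 5.2)/1.8 = 7.5), and only the tie-down convention is
#' consistent with the copy number tabulated for that strain.
#' `L_single` is the fragment length of a single-copy locus, 5.2 kb by
#' default; the Type 3 rows of the bundled table are only jointly
#' consistent with a smaller effective constant (about 4.4 kb), so the
#' constant is exposed per call.
#'
#' @param L_frag_kb observed fragment size(s), kb.
#' @param L_single_kb single-copy fragment constant, kb (default 5.2).
#' @param unit_kb repeat unit size(s), kb.
#' @param tolerance_kb sizing tolerance; fragments smaller than
#'   `L_single_kb - tolerance_kb` are rejected (default 0.5 kb, gel-sizing
#'   precision).
#' @return integer copy number(s), always at least 1.
#' @export
copy_number_from_fragment <- function(L_frag_kb, L_single_kb = 5.2, unit_kb,
                                      tolerance_kb = 0.5) {
  stopifnot(all(unit_kb > 0))
  if (any(L_frag_kb < L_single_kb - tolerance_kb))
    stop("fragment smaller than the single-copy fragment beyond tolerance")
  q <- (L_frag_kb - L_single_kb) / unit_kb
  n <- as.integer(ceiling(q - 0.5)) + 1L    # nearest, ties down
  pmax(n, 1L)
}

#' Predict the EcoRI fragment size of an n-copy array
#'
#' Inverse of [copy_number_from_fragment()]:
#' `L_frag = L_single + (n - 1) * unit`.
#'
#' @param L_single_kb single-copy fragment constant, kb.
#' @param unit_kb repeat unit size, kb.
#' @param n copy number(s), at least 1.
#' @return predicted fragment size(s), kb.
#' @export
predict_fragment <- function(L_single_kb, unit_kb, n) {
  stopifnot(all(n >= 1))
  L_single_kb + (n - 1) * unit_kb
}

#' Copy number from relative sequencing depth
#'
#' Estimates repeat copies as the mean depth over the repeat span divided
#' by the median depth over single-copy baseline intervals.
#'
#' @param depth per-base depth vector.
#' @param unit_interval 0-based half-open `c(start, end)` of the repeat
#'   span on the collapsed (single-copy) reference.
#' @param baseline_intervals list of 0-based half-open intervals over
#'   single-copy sequence.
#' @return list with `copies` (real-valued) and `copies_rounded`.
#' @export
copy_number_from_depth <- function(depth, unit_interval,
                                   baseline_intervals) {
  stopifnot(is.numeric(depth), length(unit_interval) == 2L)
  if (!is.list(baseline_intervals)) baseline_intervals <-
      list(baseline_intervals)
  idx <- function(iv) {
    stopifnot(iv[1] >= 0, iv[2] <= length(depth), iv[1] < iv[2])
    (iv[1] + 1L):iv[2]
  }
  base <- unlist(lapply(baseline_intervals, idx))
  m <- median(depth[base])
  if (!is.finite(m) || m <= 0)
    stop("baseline median depth must be positive")
  copies <- mean(depth[idx(unit_interval)]) / m
  list(copies = copies, copies_rounded = as.integer(round(copies)))
}

.primer_sites <- function(template, primer) {
  ## plus-strand sites: primer occurs forward; 5' end = match start
  ## minus-strand sites: reverse complement occurs; 5' end = match end
  l <- nchar(primer)
  fw <- gregexpr(primer, template, fixed = TRUE)[[1]]
  rc <- gregexpr(revcomp(primer), template, fixed = TRUE)[[1]]
  list(
    plus = if (fw[1] == -1L) integer(0) else as.integer(fw),        # 1-based start
    minus = if (rc[1] == -1L) integer(0) else as.integer(rc) + l - 1L  # 1-based 5' end
  )
}

#' In-silico PCR
#'
#' Reports every convergently oriented pair of exact primer binding sites
#' whose product is at most `max_len` bases.  Binding is exact-match: the
#' assays modeled are presence/absence, not thermodynamic.
#'
#' @param template template DNA string.
#' @param fwd,rev primer sequences, at least 15 bases, written 5' to 3'.
#' @param max_len maximum product length reported (default 3000, a
#'   practical extension limit that keeps across-junction assays to
#'   adjacent repeat copies).
#' @return `data.frame` with 1-based `fwd_5p` and `rev_5p` (template
#'   coordinates of the two primers' 5' ends), `length`, and `pair`
#'   (which primer bound the plus strand).  Zero rows when no product
#'   forms (not an error).
#' @export
insilico_pcr <- function(template, fwd, rev, max_len = 3000L) {
  template <- toupper(template); fwd <- toupper(fwd); rev <- toupper(rev)
  stopifnot(nchar(fwd) >= 15L, nchar(rev) >= 15L)
  out <- data.frame(fwd_5p = integer(0), rev_5p = integer(0),
                    length = integer(0), pair = character(0),
                    stringsAsFactors = FALSE)
  add <- function(plus_sites, minus_sites, min_len, label) {
    for (f in plus_sites) for (r in minus_sites) {
      len <- r - f + 1L
      if (len >= min_len && len <= max_len)
        out[nrow(out) + 1L, ] <<- list(f, r, len, label)
    }
  }
  sf <- .primer_sites(template, fwd)
  sr <- .primer_sites(template, rev)
  add(sf$plus, sr$minus, max(nchar(fwd), nchar(rev)), "fwd+/rev-")
  add(sr$plus, sf$minus, max(nchar(fwd), nchar(rev)), "rev+/fwd-")
  out[order(out$length, out$fwd_5p), , drop = FALSE]
}
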