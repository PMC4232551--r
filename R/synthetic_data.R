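#' Default geometry of the synthetic single-copy CUP1 locus
#'
#' All coordinates are internal 0-based half-open positions on the
#' synthetic locus.  The layout emulates the single-copy locus of a
#' copper-sensitive strain: *CIC1*, a ~150 bp intergenic spacer, the
#' noncoding *RUF5* gene carrying a 186 bp (61-codon) *CUP1* ORF on the
#' opposite strand, an ARS overlapping the *RUF5* 3' end, a ~70 bp
#' spacer, and *RSC30*; the flanking `GAATTC` sites are placed so the
#' single-copy *Eco*RI probe fragment is exactly 5200 bp, and the
#' flanking-gene primer pair yields a 2700 bp product.  Gene lengths are
#' configuration, chosen so that all five repeat types' breakpoints are
#' realizable.
#'
#' @return a named list of layout parameters.
#' @export
default_locus_config <- function() {
  list(
    locus_len = 5500L,
    left_ecoRI = 150L,            # GAATTC site start; cut after the G
    right_ecoRI = 5350L,          # cut positions 151 and 5351: 5200 bp apart
    cic1 = c(250L, 1350L), cic1_strand = "+",
    intergenic1 = c(1350L, 1500L),
    ruf5 = c(1500L, 2550L), ruf5_strand = "+",
    cup1 = c(1800L, 1986L), cup1_strand = "-",
    ars = c(2470L, 2600L),
    intergenic2 = c(2550L, 2620L),
    rsc30 = c(2620L, 4620L), rsc30_strand = "-",
    primer_len = 20L,
    ## outward CUP1 primer pair: 5' ends placed so the across-junction
    ## product is exactly unit - 40 bp
    cup1_fwd_5p = 1891L,          # plus strand, points distal
    cup1_rev_5p = 1850L,          # minus strand, points proximal
    ## flanking-gene pair: product 3849 - 1150 + 1 = 2700 bp
    flank_fwd_5p = 1150L,
    flank_rev_5p = 3849L,
    ## divergence defaults (substitution rates)
    divergence = c(proximal = 0.007, distal = 0.004, repeats = 0.005),
    flank_window = 600L           # flanking window the divergence applies to
  )
}

.validate_locus_config <- function(cfg) {
  ord <- c(cfg$left_ecoRI + 6L, cfg$cic1, cfg$intergenic1[2], cfg$ruf5[2],
           cfg$rsc30, cfg$right_ecoRI)
  if (is.unsorted(ord, strictly = FALSE))
    stop("infeasible locus config: features overlap or are out of order")
  if (cfg$intergenic1[1] != cfg$cic1[2] || cfg$ruf5[1] != cfg$intergenic1[2])
    stop("infeasible locus config: CIC1-RUF5 spacer must abut its genes")
  if (cfg$cup1[1] < cfg$ruf5[1] || cfg$cup1[2] > cfg$ruf5[2])
    stop("infeasible locus config: CUP1 must lie within RUF5")
  if (cfg$ars[1] >= cfg$ruf5[2] || cfg$ars[2] <= cfg$ruf5[2])
    stop("infeasible locus config: ARS must overlap the RUF5 3' end")
  if (cfg$right_ecoRI + 6L > cfg$locus_len)
    stop("infeasible locus config: right EcoRI site beyond sequence end")
  invisible(cfg)
}

#' Default specifications of the five CUP1 repeat types
#'
#' Breakpoint positions refer to the synthetic single-copy locus of
#' [default_locus_config()].  Centromere-proximal breaks fall in the
#' *CIC1*-*RUF5* intergenic region (Types 1, 2, 3, 5) or within *CIC1*
#' (Type 4); centromere-distal breaks fall within *RSC30* (Types 1, 2,
#' 4, 5) or in the *RUF5*-*RSC30* intergenic region (Type 3).  Only the
#' Type 1 junction carries an inserted base.  Exact unit lengths are
#' 1998 bp for Type 1 and configured 1800/1200/1900/1600 bp for Types
#' 2-5.
#'
#' @param config locus layout, see [default_locus_config()].
#' @return list of five [repeat_type_spec()] objects, indexed by type.
#' @export
default_repeat_specs <- function(config = default_locus_config()) {
  list(
    repeat_type_spec(1L, 2.0, 1998L, 1400L, 3397L, "A"),
    repeat_type_spec(2L, 1.8, 1800L, 1380L, 3180L, ""),
    repeat_type_spec(3L, 1.2, 1200L, 1415L, 2615L, ""),
    repeat_type_spec(4L, 1.9, 1900L, 1300L, 3200L, ""),
    repeat_type_spec(5L, 1.6, 1600L, 1420L, 3020L, "")
  )
}

## set base at 0-based position `pos` to the first base that differs from
## every base in `avoid` and does not create a GAATTC in the local window
.set_base_safe <- function(seq, pos, avoid) {
  for (b in c("A", "C", "G", "T")) {
    if (b %in% avoid) next
    cand <- seq
    substr(cand, pos + 1L, pos + 1L) <- b
    win_s <- max(0L, pos - 5L); win_e <- min(nchar(cand), pos + 6L)
    if (!grepl("GAATTC", .sub0(cand, win_s, win_e), fixed = TRUE))
      return(cand)
  }
  stop("cannot set base at ", pos, " without creating a GAATTC site")
}

## remove every GAATTC occurrence except those starting at `keep`
.scrub_gaattc <- function(seq, keep = integer(0)) {
  repeat {
    hits <- gregexpr("GAATTC", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    hits0 <- as.integer(hits) - 1L
    hits0 <- setdiff(hits0, keep)
    if (!length(hits0)) return(seq)
    ## break the site by flipping its middle base
    pos <- hits0[1] + 2L
    cur <- .sub0(seq, pos, pos + 1L)
    seq <- .set_base_safe(seq, pos, avoid = cur)
  }
}

## forward / backward identity run lengths at a junction pair of breaks
.kf <- function(v, dist, prox, max_k = 25L) {
  k <- 0L
  while (k < max_k && dist + k < length(v) && v[dist + 1L + k] == v[prox + 1L + k])
    k <- k + 1L
  k
}
.kb <- function(v, dist, prox, max_k = 25L) {
  k <- 0L
  while (k < max_k && prox - k >= 1L && v[dist - k] == v[prox - k])
    k <- k + 1L
  k
}

#' Build the synthetic single-copy CUP1 locus
#'
#' Generates a random locus with the layout of [default_locus_config()]:
#' annotated *CIC1*, *RUF5* (containing an oppositely oriented 61-codon
#' *CUP1* ORF), ARS, and *RSC30*, with flanking `GAATTC` sites placed so
#' the single-copy probe fragment is exactly 5200 bp and no `GAATTC`
#' occurs anywhere between them.  Junction neighbourhoods of all five
#' repeat-type breakpoints are conditioned so that the natural
#' microhomology at each future junction is at most 3 bp and the Type 1
#' inserted base matches neither flanking sequence, as observed for the
#' real junctions.  Deterministic per (seed, config).
#'
#' @param seed RNG seed (applied with [set.seed()]).
#' @param config locus layout; see [default_locus_config()].
#' @return list with `locus` (a [locus_map()]) and `truth` (a
#'   `synthetic_truth` object: layout, repeat specs, probe and primer
#'   sequences, per-type junction microhomology/insert truth, expected
#'   single-copy fragment length).
#' @export
build_single_locus <- function(seed = 1L, config = default_locus_config()) {
  cfg <- .validate_locus_config(config)
  set.seed(seed)
  seq <- random_dna(cfg$locus_len)

  ## CUP1 ORF on the minus strand: a 61-residue coding sequence
  ## (ATG + 60 sense codons) + TGA stop = 186 bp
  stops <- c("TAA", "TAG", "TGA")
  codons <- character(60L)
  for (i in seq_along(codons)) {
    repeat {
      cd <- random_dna(3L)
      if (!(cd %in% stops)) break
    }
    codons[i] <- cd
  }
  orf <- paste0("ATG", paste(codons, collapse = ""), "TGA")
  stopifnot(nchar(orf) == cfg$cup1[2] - cfg$cup1[1])
  substr(seq, cfg$cup1[1] + 1L, cfg$cup1[2]) <- revcomp(orf)

  ## plant the two EcoRI sites, then remove all others
  substr(seq, cfg$left_ecoRI + 1L, cfg$left_ecoRI + 6L) <- "GAATTC"
  substr(seq, cfg$right_ecoRI + 1L, cfg$right_ecoRI + 6L) <- "GAATTC"
  seq <- .scrub_gaattc(seq, keep = c(cfg$left_ecoRI, cfg$right_ecoRI))

  ## condition junction neighbourhoods: cap the natural microhomology of
  ## each future junction (forward run <= 2, backward run <= 1) and make
  ## the Type 1 insert base foreign to both flanks
  specs <- default_repeat_specs(cfg)
  for (pass in 1:10) {
    v <- .s2i(seq)
    changed <- FALSE
    for (sp in specs) {
      d <- sp$distal_break; p <- sp$proximal_break
      if (.kf(v, d, p) > 2L) {
        seq <- .set_base_safe(seq, d + 2L,
                              avoid = .sub0(seq, p + 2L, p + 3L))
        changed <- TRUE
      }
      if (.kb(v, d, p) > 1L) {
        seq <- .set_base_safe(seq, d - 2L,
                              avoid = .sub0(seq, p - 2L, p - 1L))
        changed <- TRUE
      }
      if (nchar(sp$junction_insert)) {
        ins1 <- substr(sp$junction_insert, 1L, 1L)
        insL <- substr(sp$junction_insert, nchar(sp$junction_insert),
                       nchar(sp$junction_insert))
        if (.sub0(seq, d, d + 1L) == ins1) {
          seq <- .set_base_safe(seq, d, avoid = ins1)
          changed <- TRUE
        }
        if (.sub0(seq, p - 1L, p) == insL) {
          seq <- .set_base_safe(seq, p - 1L, avoid = insL)
          changed <- TRUE
        }
      }
      if (changed) v <- .s2i(seq)
    }
    if (!changed) break
  }
  v <- .s2i(seq)
  for (sp in specs) {
    mh <- if (nchar(sp$junction_insert)) 0L
          else .kf(v, sp$distal_break, sp$proximal_break) +
               .kb(v, sp$distal_break, sp$proximal_break)
    if (mh > 3L)
      stop("junction conditioning failed for type ", sp$type_id)
  }

  feats <- gene_features(
    name = c("CIC1", "RUF5", "CUP1", "ARS", "RSC30"),
    start = c(cfg$cic1[1], cfg$ruf5[1], cfg$cup1[1], cfg$ars[1],
              cfg$rsc30[1]),
    end = c(cfg$cic1[2], cfg$ruf5[2], cfg$cup1[2], cfg$ars[2],
            cfg$rsc30[2]),
    strand = c(cfg$cic1_strand, cfg$ruf5_strand, cfg$cup1_strand, "+",
               cfg$rsc30_strand)
  )
  locus <- locus_map(seq, feats, cfg$left_ecoRI, cfg$right_ecoRI)

  pl <- cfg$primer_len
  primers <- list(
    cup1_fwd = .sub0(seq, cfg$cup1_fwd_5p, cfg$cup1_fwd_5p + pl),
    cup1_rev = revcomp(.sub0(seq, cfg$cup1_rev_5p - pl + 1L,
                             cfg$cup1_rev_5p + 1L)),
    flank_fwd = .sub0(seq, cfg$flank_fwd_5p, cfg$flank_fwd_5p + pl),
    flank_rev = revcomp(.sub0(seq, cfg$flank_rev_5p - pl + 1L,
                              cfg$flank_rev_5p + 1L))
  )
  for (p in primers) {
    n_hits <- function(x) {
      h <- gregexpr(x, seq, fixed = TRUE)[[1]]
      sum(h > 0L)
    }
    if (n_hits(p) + n_hits(revcomp(p)) != 1L)
      stop("primer sequence is not unique on the synthetic locus; ",
           "choose another seed")
  }

  junctions <- lapply(specs, function(sp) {
    kf <- .kf(v, sp$distal_break, sp$proximal_break)
    kb <- .kb(v, sp$distal_break, sp$proximal_break)
    list(type_id = sp$type_id,
         proximal_break = sp$proximal_break,
         distal_break = sp$distal_break,
         insert = sp$junction_insert,
         forward_homology = kf, backward_homology = kb,
         microhomology = if (nchar(sp$junction_insert)) 0L else kf + kb)
  })

  truth <- structure(list(
    seed = seed, config = cfg, specs = specs,
    features = feats,
    probe = .sub0(seq, cfg$cup1[1], cfg$cup1[2]),
    primers = primers,
    junctions = junctions,
    expected_single_fragment_bp =
      (cfg$right_ecoRI + 1L) - (cfg$left_ecoRI + 1L)
  ), class = "synthetic_truth")

  list(locus = locus, truth = truth)
}

## substitution mutagenesis over a 0-based half-open interval
.mutate_region <- function(seq, start, end, rate) {
  len <- end - start
  if (len <= 0L || rate <= 0) return(list(seq = seq, n = 0L))
  k <- rbinom(1L, len, rate)
  if (k == 0L) return(list(seq = seq, n = 0L))
  pos <- start + sample.int(len, k) - 1L
  for (p in pos) {
    cur <- .sub0(seq, p, p + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    substr(seq, p + 1L, p + 1L) <- alt
  }
  list(seq = seq, n = k)
}

#' Generate a synthetic strain carrying an n-copy CUP1 array
#'
#' Realizes the two-step model of array genesis: a de novo duplication of
#' the single-copy locus by unequal nonhomologous end-joining at the
#' repeat type's breakpoints, followed by expansion to `n` copies through
#' successive unequal crossovers between sister chromatids.  Optional
#' substitution divergence is then applied -- by default 0.7% over the
#' 600 bp centromere-proximal flank, 0.4% over the distal flank, and
#' 0.5% within each repeat copy independently (no indels; junction insert
#' bases are preserved).  `GAATTC` sites created by mutation between the
#' flanking *Eco*RI sites are scrubbed so the digest stays two-cut.  All
#' truth is logged; deterministic per (seed, arguments).
#'
#' @param type_id repeat type 1-5.
#' @param n final copy number, at least 1.
#' @param divergence named substitution rates `c(proximal=, distal=,
#'   repeats=)`, each in `[0, 0.05]`; use `c(0, 0, 0)` to disable.
#' @param seed RNG seed.
#' @param config locus layout.
#' @return list with `locus` (the array [locus_map()]) and `truth`
#'   (`synthetic_strain_truth`: type, n, unit length, event log, expected
#'   *Eco*RI probe-fragment length, junction truth, mutation counts, and
#'   the underlying single-locus truth).
#' @export
generate_array_strain <- function(type_id, n,
                                  divergence = NULL,
                                  seed = 1L,
                                  config = default_locus_config()) {
  stopifnot(type_id %in% 1:5, n >= 1L)
  n <- as.integer(n)
  divergence <- divergence %||% config$divergence
  if (any(divergence < 0) || any(divergence > 0.05))
    stop("divergence rates must lie in [0, 0.05]")
  single <- build_single_locus(seed = seed, config = config)
  cfg <- single$truth$config
  sp <- single$truth$specs[[type_id]]
  seq0 <- single$locus$sequence
  L0 <- nchar(seq0)
  prox <- sp$proximal_break; dist <- sp$distal_break
  ins <- sp$junction_insert; u <- sp$exact_len_bp

  events <- list()
  if (n >= 2L) {
    ev <- nhej_duplicate(single$locus, prox, dist, insertion = ins)
    events[[1]] <- list(kind = "NHEJ_dup", proximal_break = prox,
                        distal_break = dist, insertion = ins)
    state <- array_state(2L)
    j <- 2L
    while (j < n) {
      co <- unequal_crossover(state, array_state(state$n), k = 1L,
                              cross_after = 1L)
      events[[length(events) + 1L]] <-
        list(kind = "unequal_CO", k = 1L, from = state$n,
             to = co$gain$n)
      state <- co$gain
      j <- j + 1L
    }
    arr_seq <- paste0(.sub0(seq0, 0L, dist),
                      strrep(paste0(ins, .sub0(seq0, prox, dist)), n - 1L),
                      .sub0(seq0, dist, L0))
    if (n == 2L) stopifnot(identical(arr_seq, ev$duplication$sequence))
  } else {
    arr_seq <- seq0
  }
  shift_last <- (n - 1L) * u
  stopifnot(nchar(arr_seq) == L0 + shift_last)

  ## lift annotations across the n-copy structure
  lift <- list()
  add <- function(name, start, end, strand)
    lift[[length(lift) + 1L]] <<- list(name, start, end, strand)
  for (i in seq_len(nrow(single$locus$features))) {
    f <- single$locus$features[i, ]
    if (f$end <= prox) {
      add(f$name, f$start, f$end, f$strand)
    } else if (f$start >= dist) {
      add(f$name, f$start + shift_last, f$end + shift_last, f$strand)
    } else if (f$start >= prox && f$end <= dist) {
      for (c in seq_len(n))
        add(f$name, f$start + (c - 1L) * u, f$end + (c - 1L) * u, f$strand)
    } else if (f$start < prox && f$end <= dist) {
      add(f$name, f$start, f$end, f$strand)   # intact in the first frame
      if (n >= 2L) for (c in 2:n)
        add(paste0(f$name, "_frag"), prox + (c - 1L) * u,
            f$end + (c - 1L) * u, f$strand)
    } else if (f$start >= prox && f$end > dist) {
      add(f$name, f$start + shift_last, f$end + shift_last, f$strand)
      nm <- if (f$name == "RSC30") "YHR054C" else paste0(f$name, "_frag")
      if (n >= 2L) for (c in seq_len(n - 1L))
        add(nm, f$start + (c - 1L) * u, dist + (c - 1L) * u, f$strand)
    } else {
      stop("feature ", f$name, " spans both breakpoints; unsupported")
    }
  }
  feats <- do.call(rbind, lapply(lift, function(x)
    gene_features(x[[1]], x[[2]], x[[3]], x[[4]])))

  ## divergence (substitutions only)
  n_mut <- c(proximal = 0L, distal = 0L, repeats = 0L)
  fw <- cfg$flank_window
  r <- .mutate_region(arr_seq, max(cfg$left_ecoRI + 6L, prox - fw), prox,
                      divergence[["proximal"]])
  arr_seq <- r$seq; n_mut["proximal"] <- r$n
  r <- .mutate_region(arr_seq, dist + shift_last,
                      min(dist + shift_last + fw,
                          cfg$right_ecoRI + shift_last),
                      divergence[["distal"]])
  arr_seq <- r$seq; n_mut["distal"] <- r$n
  ins_len <- nchar(ins)
  for (c in seq_len(n)) {
    s <- prox + (c - 1L) * u            # copy start (after any insert)
    r <- .mutate_region(arr_seq, s, s + (dist - prox),
                        divergence[["repeats"]])
    arr_seq <- r$seq; n_mut["repeats"] <- n_mut["repeats"] + r$n
  }
  arr_seq <- .scrub_gaattc(arr_seq,
                           keep = c(cfg$left_ecoRI,
                                    cfg$right_ecoRI + shift_last))

  locus <- locus_map(arr_seq, feats, cfg$left_ecoRI,
                     cfg$right_ecoRI + shift_last)
  truth <- structure(list(
    seed = seed, type_id = as.integer(type_id), n = n,
    unit_len_bp = u,
    proximal_break = prox, distal_break = dist, insert = ins,
    junction = single$truth$junctions[[type_id]],
    events = events,
    divergence = divergence, n_mutations = n_mut,
    expected_fragment_bp =
      single$truth$expected_single_fragment_bp + (n - 1L) * u,
    expected_fragment_kb =
      (single$truth$expected_single_fragment_bp + (n - 1L) * u) / 1000,
    single_truth = single$truth
  ), class = "synthetic_strain_truth")

  list(locus = locus, truth = truth)
}

#' Write a synthetic strain to FASTA + GFF3 + truth JSON
#'
#' @param strain result of [generate_array_strain()].
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
write_synthetic_strain <- function(strain, dir, name = "strain") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fasta"))
  gff <- file.path(dir, paste0(name, ".gff3"))
  js <- file.path(dir, paste0(name, ".truth.json"))
  write_fasta(stats::setNames(strain$locus$sequence, name), fa)
  write_gff3(strain$locus$features, gff, seqname = name)
  tr <- strain$truth
  tr$single_truth <- NULL
  tr$events <- NULL
  jsonlite::write_json(unclass(tr), js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, truth = js))
}

## pick `n` bases, each differing from the corresponding base of `ref`
.differing_bases <- function(ref_bases) {
  vapply(ref_bases, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1),
    USE.NAMES = FALSE)
}

#' Generate labeled junction test cases
#'
#' Constructs junctions with known breakpoint structure against fresh
#' random flanking references: blunt joins, microhomology of known
#' length, insertions of known length (including homopolymer expansions
#' of the adjacent base, emulating junction tract-length changes), and
#' optionally one isolated SNP in the distal matched segment.  The six
#' reference bases beyond each planted match are forced to differ from
#' the corresponding junction bases, so the truth labels are exact.
#'
#' @param seed RNG seed.
#' @param n_cases number of cases.
#' @param mh_range inclusive microhomology range (default 0-10).
#' @param ins_range inclusive insertion-length range (default 0-10).
#' @param mismatch_rate fraction of cases carrying one isolated SNP in
#'   the distal match (default 0).
#' @param homopolymer_fraction fraction of insertion cases whose insert
#'   repeats the adjacent junction base (default 0.25).
#' @return list with character vectors `junctions`, `distal_refs`,
#'   `proximal_refs` (named `case_1` ...) and a `truth` data.frame with
#'   `microhomology`, `ins_len`, `ins_seq`, `prefix_len`, `suffix_len`,
#'   `has_snp`, `is_homopolymer`.
#' @export
generate_junction_cases <- function(seed = 1L, n_cases = 100L,
                                    mh_range = c(0L, 10L),
                                    ins_range = c(0L, 10L),
                                    mismatch_rate = 0,
                                    homopolymer_fraction = 0.25) {
  stopifnot(mh_range[1] >= 0L, mh_range[2] >= mh_range[1],
            ins_range[1] >= 0L, ins_range[2] >= ins_range[1],
            mismatch_rate >= 0, mismatch_rate <= 1)
  set.seed(seed)
  juncs <- dists <- proxs <- character(n_cases)
  truth <- data.frame(microhomology = integer(n_cases),
                      ins_len = integer(n_cases),
                      ins_seq = character(n_cases),
                      prefix_len = integer(n_cases),
                      suffix_len = integer(n_cases),
                      has_snp = logical(n_cases),
                      is_homopolymer = logical(n_cases),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_cases)) {
    Lj <- .sample1(80:150)
    is_ins <- runif(1) < 0.5 && ins_range[2] > 0L
    m <- if (is_ins) 0L else .sample1(mh_range[1]:mh_range[2])
    il <- if (is_ins) .sample1(max(1L, ins_range[1]):ins_range[2]) else 0L
    p <- .sample1(30:(Lj - 30L - m - il))      # end of the core prefix
    J <- random_dna(Lj)
    homo <- FALSE
    if (il > 0L) {
      homo <- runif(1) < homopolymer_fraction
      insert <- if (homo) strrep(substr(J, p, p), il)
                else random_dna(il)
      substr(J, p + 1L, p + il) <- insert
    }
    P <- p + m                                   # planted prefix length
    S <- Lj - p - il                             # planted suffix length
    jv <- strsplit(J, "")[[1]]
    ## distal reference: pad + J[1..P] + 6 differing guards + pad
    g1 <- .differing_bases(jv[pmin(P + 1:6, Lj)])
    D <- paste0(random_dna(40L), substr(J, 1L, P),
                paste(g1, collapse = ""), random_dna(34L))
    ## proximal reference: pad + 6 differing guards + J[(p+il+1)..Lj] + pad
    gidx <- pmax(p + il - 5:0, 1L)
    g2 <- .differing_bases(jv[gidx])
    Pref <- paste0(random_dna(34L), paste(g2, collapse = ""),
                   substr(J, p + il + 1L, Lj), random_dna(40L))
    has_snp <- runif(1) < mismatch_rate && P >= 13L
    if (has_snp) {
      off <- .sample1(7:(P - 6L))              # interior, isolated
      pos <- 40L + off
      cur <- substr(D, pos, pos)
      substr(D, pos, pos) <-
        sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    juncs[i] <- J; dists[i] <- D; proxs[i] <- Pref
    truth$microhomology[i] <- m
    truth$ins_len[i] <- il
    truth$ins_seq[i] <- if (il > 0L) substr(J, p + 1L, p + il) else ""
    truth$prefix_len[i] <- P
    truth$suffix_len[i] <- S
    truth$has_snp[i] <- has_snp
    truth$is_homopolymer[i] <- homo
  }
  nm <- paste0("case_", seq_len(n_cases))
  names(juncs) <- names(dists) <- names(proxs) <- nm
  truth$case <- nm
  list(junctions = juncs, distal_refs = dists, proximal_refs = proxs,
       truth = truth)
}

#' Generate a read-depth track for a synthetic strain
#'
#' Simulates per-base sequencing depth over the collapsed single-copy
#' reference: independent Poisson depth at `mean_coverage`, multiplied by
#' the strain's copy number over the repeat span.  This is the input
#' geometry of a depth-based copy-number estimate, where array reads all
#' pile onto the one repeat unit present in the reference.
#'
#' @param truth a `synthetic_strain_truth` from [generate_array_strain()].
#' @param mean_coverage mean single-copy depth; a warning is issued below
#'   5x, where rounding the depth ratio to a copy number is unreliable.
#' @param seed optional RNG seed.
#' @return list with `depth` (integer vector over the single-copy locus),
#'   `unit_interval` (0-based half-open repeat span), and
#'   `baseline_intervals` (single-copy spans), ready for
#'   [copy_number_from_depth()].
#' @export
generate_depth_track <- function(truth, mean_coverage, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_strain_truth"), mean_coverage > 0)
  if (mean_coverage < 5)
    warning("mean coverage below 5x: rounded depth-based copy numbers ",
            "are unreliable")
  if (!is.null(seed)) set.seed(seed)
  L0 <- truth$single_truth$config$locus_len
  d <- rpois(L0, mean_coverage)
  span <- (truth$proximal_break + 1L):truth$distal_break
  d[span] <- d[span] * truth$n
  list(depth = d,
       unit_interval = c(truth$proximal_break, truth$distal_break),
       baseline_intervals = list(c(0L, truth$proximal_break),
                                 c(truth$distal_break, L0)))
}
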