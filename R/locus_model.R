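#' Construct a table of gene features
#'
#' Features are stored with internal 0-based half-open coordinates; see
#' [to_external_coords()] for the reporting convention.
#'
#' @param name character vector of feature labels (e.g. `CIC1`, `RUF5`,
#'   `CUP1`, `ARS`, `RSC30`, `YHR054C`, `URA3`).
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector of `"+"`/`"-"`.
#' @return a `data.frame` with columns `name`, `start`, `end`, `strand`.
#' @export
gene_features <- function(name, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(name) == length(start), length(start) == length(end),
            length(end) == length(strand))
  if (any(start < 0L) || any(start >= end))
    stop("gene feature intervals must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  data.frame(name = as.character(name), start = start, end = end,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Construct an annotated CUP1 locus
#'
#' A `locus_map` bundles a DNA sequence with its gene features and the
#' positions of the two *Eco*RI sites flanking the locus (the sites cut by
#' the Southern-blot digest).
#'
#' @param sequence DNA string over `A,C,G,T` (uppercased on input).
#' @param features data.frame from [gene_features()].
#' @param left_ecoRI,right_ecoRI 0-based start positions of the flanking
#'   `GAATTC` sites.  Both sites must lie outside the span of all gene
#'   features.
#' @return an object of class `locus_map`.
#' @export
locus_map <- function(sequence, features, left_ecoRI, right_ecoRI) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("locus sequence contains characters outside {A,C,G,T,N}")
  L <- nchar(sequence)
  left_ecoRI <- as.integer(left_ecoRI); right_ecoRI <- as.integer(right_ecoRI)
  if (nrow(features)) {
    if (any(features$end > L))
      stop("features exceed sequence length")
    if (left_ecoRI >= min(features$start) || right_ecoRI < max(features$end))
      stop("EcoRI sites must flank all gene features")
  }
  for (site in c(left_ecoRI, right_ecoRI)) {
    if (.sub0(sequence, site, site + 6L) != "GAATTC")
      stop("no GAATTC at declared EcoRI position ", site)
  }
  structure(list(sequence = sequence, features = features,
                 left_ecoRI = left_ecoRI, right_ecoRI = right_ecoRI),
            class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat("<locus_map> ", nchar(x$sequence), " bp, ",
      nrow(x$features), " features; EcoRI sites at ",
      x$left_ecoRI + 1L, " and ", x$right_ecoRI + 1L,
      " (1-based)\n", sep = "")
  ext <- to_external_coords(x$features$start, x$features$end)
  print(data.frame(name = x$features$name, first = ext$first,
                   last = ext$last, strand = x$features$strand))
  invisible(x)
}

#' Repeat-type specification
#'
#' Describes one of the five CUP1 repeat classes by its breakpoints on the
#' single-copy locus: the centromere-proximal break, the centromere-distal
#' break, and any bases inserted at the junction when the two broken ends
#' were joined.  The realized unit length is
#' `distal_break - proximal_break + nchar(junction_insert)`.
#'
#' @param type_id integer 1-5.
#' @param nominal_kb printed approximate unit size (2.0, 1.8, 1.2, 1.9, 1.6).
#' @param exact_len_bp exact unit length in bp (1998 for Type 1).
#' @param proximal_break,distal_break 0-based positions on the single-copy
#'   locus; `proximal_break < distal_break`.
#' @param junction_insert DNA string inserted at the junction (possibly "").
#' @return an object of class `repeat_type_spec`.
#' @export
repeat_type_spec <- function(type_id, nominal_kb, exact_len_bp,
                             proximal_break, distal_break,
                             junction_insert = "") {
  stopifnot(type_id %in% 1:5, proximal_break < distal_break)
  if (distal_break - proximal_break + nchar(junction_insert) != exact_len_bp)
    stop("breakpoints and insert inconsistent with exact_len_bp for type ",
         type_id)
  structure(list(type_id = as.integer(type_id), nominal_kb = nominal_kb,
                 exact_len_bp = as.integer(exact_len_bp),
                 proximal_break = as.integer(proximal_break),
                 distal_break = as.integer(distal_break),
                 junction_insert = toupper(junction_insert)),
            class = "repeat_type_spec")
}

#' Convert internal to external coordinates
#'
#' Internal coordinates are 0-based half-open; external (reported)
#' coordinates are 1-based inclusive, the SGD convention.
#'
#' @param start,end internal 0-based half-open interval(s).
#' @return list with `first` and `last`, 1-based inclusive.
#' @examples
#' to_external_coords(212555, 212556)  # the CUP1 coding SNP position
#' @export
to_external_coords <- function(start, end) {
  if (any(start < 0) || any(start >= end))
    stop("internal coordinates must satisfy 0 <= start < end")
  list(first = as.integer(start) + 1L, last = as.integer(end))
}

#' Convert external to internal coordinates
#'
#' Inverse of [to_external_coords()].
#'
#' @param first,last 1-based inclusive interval(s).
#' @return list with `start` and `end`, 0-based half-open.
#' @export
to_internal_coords <- function(first, last) {
  if (any(first < 1) || any(first > last))
    stop("external coordinates must satisfy 1 <= first <= last")
  list(start = as.integer(first) - 1L, end = as.integer(last))
}

.strain_table_header <- c("strain", "repeat_type", "unit_kb", "ecoRI_frag_kb",
                    "southern_copies", "deepseq_copies", "cu_inhib_mM",
                    "ploidy")

#' Path to the bundled 14-strain CUP1 array table
#'
#' The packaged CSV transcribes, for 14 yeast strains, the repeat type and
#' unit size, the *Eco*RI fragment length carrying the array, the Southern
#' and deep-sequencing copy-number estimates, and the minimal inhibitory
#' copper concentration.
#'
#' @return path to the CSV file.
#' @export
strain_table_path <- function() {
  system.file("extdata", "cup1_strains.csv", package = "cuparray",
              mustWork = TRUE)
}

#' Load a strain table
#'
#' Reads a CSV with header
#' `strain,repeat_type,unit_kb,ecoRI_frag_kb,southern_copies,deepseq_copies,cu_inhib_mM,ploidy`.
#' Censored copper values written `"<x"` are parsed as the bound `x` with
#' `cu_censored = TRUE` (an explicit flag, never a sentinel number); missing
#' deep-sequencing estimates are `NA` with `deepseq_missing = TRUE`.
#'
#' @param path CSV path (defaults to the bundled strain table).
#' @return a `data.frame` of class `strain_table`, one row per strain, in
#'   file order, with `repeat_type` as integer (`NA` for single-copy
#'   strains) plus logical flags `cu_censored` and `deepseq_missing`.
#' @export
load_strain_table <- function(path = strain_table_path()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), .strain_table_header))
    stop("strain table header must be exactly: ",
         paste(.strain_table_header, collapse = ","))
  n <- nrow(raw)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    missing_ok <- is.na(raw[[col]]) | raw[[col]] %in% c("", "NA", "ND", "NR")
    bad <- which(is.na(x) & !missing_ok)
    if (length(bad))
      stop("malformed numeric field '", col, "' in row ", bad[1],
           " (strain ", raw$strain[bad[1]], ")")
    x
  }
  rt_chr <- raw$repeat_type
  bad_rt <- which(!(rt_chr %in% c("1", "2", "3", "4", "5", "none")))
  if (length(bad_rt))
    stop("unknown repeat type label '", rt_chr[bad_rt[1]], "' in row ",
         bad_rt[1])
  repeat_type <- rep(NA_integer_, n)
  typed <- rt_chr != "none"
  repeat_type[typed] <- as.integer(rt_chr[typed])
  cu_raw <- raw$cu_inhib_mM
  cu_censored <- grepl("^<", cu_raw)
  cu <- suppressWarnings(as.numeric(sub("^<", "", cu_raw)))
  bad_cu <- which(is.na(cu) & !(is.na(cu_raw) | cu_raw %in% c("", "NA")))
  if (length(bad_cu))
    stop("malformed cu_inhib_mM in row ", bad_cu[1])
  out <- data.frame(
    strain = raw$strain,
    repeat_type = repeat_type,
    unit_kb = num("unit_kb"),
    ecoRI_frag_kb = num("ecoRI_frag_kb"),
    southern_copies = as.integer(num("southern_copies")),
    deepseq_copies = as.integer(num("deepseq_copies")),
    cu_inhib_mM = cu,
    cu_censored = cu_censored,
    ploidy = raw$ploidy,
    stringsAsFactors = FALSE
  )
  if (!all(out$ploidy %in% c("haploid", "diploid") | n == 0L))
    stop("ploidy must be 'haploid' or 'diploid'")
  bad_single <- which(is.na(out$repeat_type) & out$southern_copies != 1L)
  if (length(bad_single))
    stop("strain without a repeat type must have southern_copies == 1 (row ",
         bad_single[1], ")")
  out$deepseq_missing <- is.na(out$deepseq_copies)
  class(out) <- c("strain_table", "data.frame")
  out
}

#' Write a strain table
#'
#' Inverse of [load_strain_table()]; censored copper bounds are re-emitted
#' as `"<x"` so that a write/reload round trip is lossless.
#'
#' @param table a `strain_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(table, path) {
  out <- data.frame(
    strain = table$strain,
    repeat_type = ifelse(is.na(table$repeat_type), "none",
                         as.character(table$repeat_type)),
    unit_kb = table$unit_kb,
    ecoRI_frag_kb = table$ecoRI_frag_kb,
    southern_copies = table$southern_copies,
    deepseq_copies = table$deepseq_copies,
    cu_inhib_mM = ifelse(table$cu_censored,
                         paste0("<", table$cu_inhib_mM),
                         as.character(table$cu_inhib_mM)),
    ploidy = table$ploidy,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in FASTA record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad] %||% which(bad), collapse = ", "))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene features from GFF3
#'
#' Coordinates in the file are 1-based inclusive and converted to the
#' internal 0-based half-open convention on read.
#'
#' @param path GFF3 path.
#' @return a features `data.frame` as from [gene_features()], plus the
#'   sequence name in attribute `seqname`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- gr$Name
  if (is.null(nm)) nm <- as.character(gr$type)
  feats <- gene_features(
    name = nm,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+")
  )
  attr(feats, "seqname") <-
    as.character(GenomicRanges::seqnames(gr))[1] %||% NA_character_
  feats
}

#' Write gene features to GFF3
#'
#' Internal 0-based half-open intervals are written 1-based inclusive.
#'
#' @param features features `data.frame` from [gene_features()].
#' @param path output path.
#' @param seqname sequence identifier to write.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, seqname = "locus") {
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand
  )
  gr$type <- "region"
  gr$Name <- features$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
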