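#' One-shot reproduction of the desk-scale array analyses
#'
#' Runs, from a strain table, every analysis the package can recompute at
#' the desk: per-strain copy numbers from *Eco*RI fragment sizes
#' (compared against the table's Southern values), the three
#' copy-number/copper regressions, and the composite single-copy
#' reversion rate from a marker-loss screen.
#'
#' @param table_path strain-table CSV (defaults to the bundled table).
#' @param single_copy_kb single-copy fragment constant in kb, either one
#'   number for all types or a vector indexed by repeat type (default a
#'   uniform 5.2).
#' @param strains optional character vector restricting the analysis to a
#'   subset of strains; an empty selection is an error, never a partial
#'   report.
#' @param marker_loss list with the marker-loss screen inputs:
#'   `k_events` single-copy derivatives, `n_screened` derivatives
#'   screened, `base_rate` per-division marker-loss rate.
#' @return an object of class `array_report`: `copy_numbers`
#'   (data.frame with computed vs tabulated copies), `correlations`
#'   (see [strain_correlations()]), and `reversion` (see
#'   [composite_rate()]).
#' @export
run_array_analyses <- function(table_path = strain_table_path(),
                               single_copy_kb = 5.2,
                               strains = NULL,
                               marker_loss = list(k_events = 6L,
                                                  n_screened = 135L,
                                                  base_rate = 1.7e-5)) {
  tab <- load_strain_table(table_path)
  if (!is.null(strains)) {
    tab <- tab[tab$strain %in% strains, , drop = FALSE]
    class(tab) <- c("strain_table", "data.frame")
  }
  if (nrow(tab) == 0L)
    stop("empty strain subset; no analyses run")

  multi <- !is.na(tab$repeat_type)
  L1 <- if (length(single_copy_kb) == 1L)
    rep(single_copy_kb, sum(multi))
  else single_copy_kb[tab$repeat_type[multi]]
  computed <- copy_number_from_fragment(tab$ecoRI_frag_kb[multi],
                                        L1, tab$unit_kb[multi])
  copy_numbers <- data.frame(
    strain = tab$strain[multi],
    repeat_type = tab$repeat_type[multi],
    ecoRI_frag_kb = tab$ecoRI_frag_kb[multi],
    computed_copies = computed,
    southern_copies = tab$southern_copies[multi],
    matches_southern = computed == tab$southern_copies[multi],
    stringsAsFactors = FALSE
  )

  correlations <- if (nrow(tab) >= 3L) strain_correlations(tab) else NULL
  reversion <- composite_rate(marker_loss$k_events,
                              marker_loss$n_screened,
                              marker_loss$base_rate)

  structure(list(copy_numbers = copy_numbers,
                 correlations = correlations,
                 reversion = reversion,
                 table_path = table_path,
                 single_copy_kb = single_copy_kb),
            class = "array_report")
}

#' @export
print.array_report <- function(x, ...) {
  cat("== CUP1 tandem-array analyses ==\n\n")
  cat("Copy number from EcoRI fragment size (single-copy constant ",
      paste(x$single_copy_kb, collapse = "/"), " kb):\n", sep = "")
  print(x$copy_numbers, row.names = FALSE)
  cat("\n", sum(x$copy_numbers$matches_southern), " of ",
      nrow(x$copy_numbers),
      " computed copy numbers match the Southern estimate\n", sep = "")
  if (!is.null(x$correlations)) {
    cc <- x$correlations
    cat("\nCorrelations:\n")
    cat(sprintf("  deep-seq vs Southern copies : R^2 = %.2f (p = %.2g, n = %d)\n",
                cc$southern_vs_deepseq$r_squared,
                cc$southern_vs_deepseq$p_two_sided,
                cc$southern_vs_deepseq$n_points))
    cat(sprintf("  [Cu2+] vs copies (diploids) : R^2 = %.2f (p = %.2g, n = %d)\n",
                cc$cu_vs_copies_diploid$r_squared,
                cc$cu_vs_copies_diploid$p_two_sided,
                cc$cu_vs_copies_diploid$n_points))
    cat(sprintf("  [Cu2+] vs copies (all)      : R^2 = %.2f (p = %.2g, n = %d)\n",
                cc$cu_vs_copies_all$r_squared,
                cc$cu_vs_copies_all$p_two_sided,
                cc$cu_vs_copies_all$n_points))
    cens <- attr(cc, "censored_at_bound")
    if (length(cens))
      cat("  (censored copper bound used at face value for: ",
          paste(cens, collapse = ", "), ")\n", sep = "")
  }
  cat(sprintf("\nSingle-copy reversion rate: %.2g x %.2g = %.2g /division\n",
              x$reversion$proportion,
              x$reversion$rate / x$reversion$proportion,
              x$reversion$rate))
  invisible(x)
}
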