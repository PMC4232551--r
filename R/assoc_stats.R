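#' Ordinary least-squares fit with correlation summary
#'
#' Fits `y ~ x` by OLS and reports the slope, intercept, Pearson r, R
#' squared, and the two-sided p-value of the zero-slope test on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3, all finite.
#'   Censored values must be resolved upstream (see
#'   [strain_correlations()]).
#' @return an object of class `linfit_result` with fields `slope`,
#'   `intercept`, `r`, `r_squared`, `p_two_sided`, `n_points`.
#' @export
linfit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  if (var(x) == 0) stop("x has zero variance; no regression possible")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = cor(x, y),
                 r_squared = sm$r.squared,
                 p_two_sided = unname(sm$coefficients[2, 4]),
                 n_points = length(x)),
            class = "linfit_result")
}

#' @export
print.linfit_result <- function(x, ...) {
  cat("<linfit_result> n = ", x$n_points, ": y = ",
      signif(x$slope, 4), " x + ", signif(x$intercept, 4),
      "; R^2 = ", round(x$r_squared, 3),
      ", p = ", signif(x$p_two_sided, 2), "\n", sep = "")
  invisible(x)
}

#' Copy-number and copper-resistance correlations on a strain table
#'
#' Runs the three planned regressions on a [load_strain_table()] table:
#'
#' 1. deep-sequencing copy number on Southern copy number, strains with
#'    both estimates;
#' 2. inhibitory copper concentration on Southern copy number, diploid
#'    strains;
#' 3. the same including haploids, with censored copper bounds (recorded
#'    as `"<x"`) substituted at their bound -- an explicit assumption,
#'    flagged in the result.
#'
#' @param table a `strain_table`.
#' @return list of `linfit_result` objects named `southern_vs_deepseq`,
#'   `cu_vs_copies_diploid`, `cu_vs_copies_all`, with attribute
#'   `censored_at_bound` giving the strains whose censored copper value
#'   entered regression 3 at its bound.
#' @export
strain_correlations <- function(table) {
  stopifnot(inherits(table, "strain_table"))
  both <- !is.na(table$southern_copies) & !is.na(table$deepseq_copies)
  r1 <- linfit(table$southern_copies[both], table$deepseq_copies[both])
  dip <- table$ploidy == "diploid" & !is.na(table$cu_inhib_mM) &
    !table$cu_censored
  r2 <- linfit(table$southern_copies[dip], table$cu_inhib_mM[dip])
  all_cu <- !is.na(table$cu_inhib_mM)
  r3 <- linfit(table$southern_copies[all_cu], table$cu_inhib_mM[all_cu])
  out <- list(southern_vs_deepseq = r1,
              cu_vs_copies_diploid = r2,
              cu_vs_copies_all = r3)
  attr(out, "censored_at_bound") <-
    table$strain[all_cu & table$cu_censored]
  out
}
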