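#' Simulate Luria-Delbruck cultures
#'
#' Grows each culture from `N0` to `N_final` cells by discrete divisions.
#' In each generation every cell divides (the final generation is
#' partial, so total divisions equal `N_final - N0` exactly); each
#' wild-type division yields a mutant daughter with probability `mu`, and
#' existing mutant lineages double alongside.  Plating efficiency and
#' phenotypic lag are assumed perfect.
#'
#' @param mu per-division mutation rate (0 <= mu << 1).
#' @param N0 inoculum size (default 1000 cells).
#' @param N_final final cells per culture (default 2e7).
#' @param n_cultures number of independent cultures.
#' @param seed optional seed applied with [set.seed()].
#' @return integer vector of per-culture mutant counts, with the number
#'   of de novo mutation events per culture in attribute
#'   `mutation_events` (their expectation is `mu * (N_final - N0)`).
#' @export
simulate_ld_cultures <- function(mu, N0 = 1e3, N_final = 2e7, n_cultures,
                                 seed = NULL) {
  stopifnot(mu >= 0, mu < 1, N0 >= 1, N0 < N_final, n_cultures >= 1)
  if (!is.null(seed)) set.seed(seed)
  one <- function() {
    N <- N0; m <- 0; events <- 0L
    while (N < N_final) {
      d <- min(N, N_final - N)          # cells dividing this generation
      dm <- if (m > 0) rbinom(1L, m, d / N) else 0L   # dividing mutants
      dw <- d - dm
      new_m <- if (dw > 0) rbinom(1L, dw, mu) else 0L
      m <- m + dm + new_m
      events <- events + new_m
      N <- N + d
    }
    c(m, events)
  }
  res <- vapply(seq_len(n_cultures), function(i) as.integer(one()),
                integer(2))
  structure(res[1, ], mutation_events = res[2, ])
}

#' Method-of-the-median fluctuation rate estimate
#'
#' Lea-Coulson median estimator: with `r` the median mutant count per
#' culture, the expected number of mutations per culture `m` solves
#' `r/m - ln(m) = 1.24`; the per-division rate is `m / N_final`.  The
#' equation is solved by root bisection on `log m` over
#' `m in [1e-6, 1e9]` to a relative tolerance of 1e-9.
#'
#' @param mutant_counts integer vector of per-culture mutant counts
#'   (a warning is issued below 10 cultures).
#' @param N_final final cells per culture.
#' @return an object of class `fluctuation_result`: `median_mutants`,
#'   `m_hat`, `mu_hat = m_hat / N_final`, `n_cultures`, `N_final`, and
#'   `below_detection`.  When the median count is zero the rate is below
#'   detection and `m_hat`/`mu_hat` are `NA`.
#' @export
lc_median_estimate <- function(mutant_counts, N_final) {
  stopifnot(all(mutant_counts >= 0), N_final > 0)
  if (length(mutant_counts) < 10L)
    warning("fewer than 10 cultures; the median estimator is unreliable")
  r <- median(mutant_counts)
  if (r == 0) {
    return(structure(list(median_mutants = r, m_hat = NA_real_,
                          mu_hat = NA_real_,
                          n_cultures = length(mutant_counts),
                          N_final = N_final, below_detection = TRUE),
                     class = "fluctuation_result"))
  }
  f <- function(logm) r / exp(logm) - logm - 1.24
  lo <- log(1e-6); hi <- log(1e9)
  if (f(hi) > 0) stop("median mutant count too large for the solver range")
  root <- uniroot(f, c(lo, hi), tol = 1e-10)
  m_hat <- exp(root$root)
  structure(list(median_mutants = r, m_hat = m_hat,
                 mu_hat = m_hat / N_final,
                 n_cultures = length(mutant_counts),
                 N_final = N_final, below_detection = FALSE),
            class = "fluctuation_result")
}

#' @export
print.fluctuation_result <- function(x, ...) {
  if (x$below_detection) {
    cat("<fluctuation_result> median mutant count 0: rate below detection",
        "(", x$n_cultures, "cultures )\n")
  } else {
    cat("<fluctuation_result> median ", x$median_mutants, " mutants/culture",
        "; m = ", signif(x$m_hat, 4), " mutations/culture; rate = ",
        signif(x$mu_hat, 3), "/division (", x$n_cultures, " cultures, ",
        format(x$N_final, scientific = TRUE), " cells/culture)\n", sep = "")
  }
  invisible(x)
}

#' Composite rate from a screened fraction of events
#'
#' Scales a base per-division rate by the fraction of screened derivatives
#' showing the endpoint of interest: `rate = (k/n) * base_rate`.  A
#' Clopper-Pearson binomial interval on `k/n` is propagated to the rate.
#'
#' @param k_events endpoint-positive derivatives among those screened.
#' @param n_screened derivatives screened (> 0).
#' @param base_rate per-division rate of the selectable event.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `rate`, `proportion`, and `conf_int` (rate scale).
#' @export
composite_rate <- function(k_events, n_screened, base_rate,
                           conf_level = 0.95) {
  stopifnot(n_screened > 0, k_events >= 0, k_events <= n_screened,
            base_rate >= 0)
  ci <- binom.test(k_events, n_screened,
                   conf.level = conf_level)$conf.int
  list(rate = (k_events / n_screened) * base_rate,
       proportion = k_events / n_screened,
       conf_int = as.numeric(ci) * base_rate)
}
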