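#' SNP index of a pool
#'
#' Fraction of reads carrying the non-reference allele,
#' `depth_alt / (depth_ref + depth_alt)`. Because both pools are aligned to
#' a public reference genome (not a parental assembly), fixed differences
#' between the parental line and the reference sit near 1 in *both* pools
#' and cancel in the delta; only mutagen-induced SNPs segregate. At a
#' recessive causal SNP the mutant-phenotype pool is expected at 1 and the
#' wild-phenotype pool at 1/3; unlinked loci sit at 1/2 in both pools.
#'
#' @param depth_ref,depth_alt Non-negative read counts (vectorized).
#' @return Fraction in `[0, 1]`; `NA` where total depth is zero.
#' @export
#' @examples
#' snp_index(0, 30)   # causal SNP, mutant pool: 1
#' snp_index(18, 9)   # 1/3
snp_index <- function(depth_ref, depth_alt) {
  stopifnot(all(depth_ref >= 0, na.rm = TRUE),
            all(depth_alt >= 0, na.rm = TRUE))
  tot <- depth_ref + depth_alt
  ifelse(tot > 0, depth_alt / tot, NA_real_)
}

#' Delta SNP index
#'
#' SNP index of the mutant-phenotype pool (A) minus that of the
#' wild-phenotype pool (B). Expected 2/3 at a recessive causal SNP and 0 at
#' unlinked loci; fixed parental-versus-reference differences cancel.
#'
#' @param index_a,index_b SNP indices in `[0, 1]` (vectorized). `NA`
#'   (undefined) propagates.
#' @return Difference in `[-1, 1]`, or `NA` where either index is undefined.
#' @export
delta_index <- function(index_a, index_b) {
  stopifnot(all(index_a >= 0 & index_a <= 1, na.rm = TRUE),
            all(index_b >= 0 & index_b <= 1, na.rm = TRUE))
  index_a - index_b
}

#' Pooled Fst between the two pools
#'
#' Nei's G_ST computed from the two pool allele frequencies: the proportion
#' of total genetic diversity due to the allele-frequency difference
#' between pools, `(H_T - H_S) / H_T`, where `H_T = 2 p_bar (1 - p_bar)`
#' with `p_bar = (p_a + p_b) / 2`, and `H_S` is the mean of the per-pool
#' heterozygosities `2 p_i (1 - p_i)`. Defined as 0 where `H_T = 0`.
#'
#' @param p_a,p_b Allele frequencies in `[0, 1]` (vectorized), e.g. the two
#'   SNP indices.
#' @return Fst in `[0, 1]`.
#' @export
#' @examples
#' pooled_fst(1, 1/3)  # 0.5
#' pooled_fst(1, 0)    # fixed difference: 1
pooled_fst <- function(p_a, p_b) {
  stopifnot(all(p_a >= 0 & p_a <= 1, na.rm = TRUE),
            all(p_b >= 0 & p_b <= 1, na.rm = TRUE))
  p_bar <- (p_a + p_b) / 2
  h_t <- 2 * p_bar * (1 - p_bar)
  h_s <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, 0)
  pmin(pmax(fst, 0), 1)
}

#' Retention bounds for the delta SNP-index screen
#'
#' At a recessive causal SNP the delta SNP index is expected at 2/3;
#' sampling noise spreads observed values around it, and the default
#' retention band 0.6-0.8 (inclusive at both ends) captures that
#' neighbourhood while discarding unlinked loci near 0.
#'
#' @param delta_low,delta_high Lower and upper retention bounds with
#'   `0 <= delta_low < delta_high <= 1`.
#' @return A `screen_config` list.
#' @export
screen_config <- function(delta_low = 0.6, delta_high = 0.8) {
  stopifnot(is.numeric(delta_low), is.numeric(delta_high),
            length(delta_low) == 1, length(delta_high) == 1,
            delta_low >= 0, delta_low < delta_high, delta_high <= 1)
  structure(list(delta_low = delta_low, delta_high = delta_high),
            class = "screen_config")
}

#' Screen a variant table on the delta SNP index
#'
#' Retains rows with `delta_low <= delta <= delta_high` (inclusive bounds);
#' rows with undefined delta are dropped. Order is preserved.
#'
#' @param table A data frame with a `delta` column.
#' @param config A [screen_config()].
#' @return The retained subset of `table`.
#' @export
screen_delta <- function(table, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"), "delta" %in% names(table))
  keep <- !is.na(table$delta) &
    table$delta >= config$delta_low & table$delta <= config$delta_high
  table[keep, , drop = FALSE]
}

#' Chi-square test of a Mendelian segregation ratio
#'
#' Goodness-of-fit of observed dominant:recessive phenotype counts against
#' an expected ratio (default 3:1 for a single recessive gene), with one
#' degree of freedom.
#'
#' @param n_dominant,n_recessive Observed counts (both classes must be
#'   observed, total > 0).
#' @param ratio Expected dominant:recessive ratio as a length-2 numeric,
#'   default `c(3, 1)`.
#' @param alpha Significance level for the consistency call, default 0.05.
#' @return A `segregation_test` list with elements `observed_dominant`,
#'   `observed_recessive`, `ratio`, `chi_square`, `df` (1), `p_value`,
#'   `alpha` and `consistent` (`TRUE` when the statistic is below the
#'   alpha critical value).
#' @export
#' @examples
#' segregation_test(820, 267)  # chi-square ~ 0.111, consistent with 3:1
segregation_test <- function(n_dominant, n_recessive, ratio = c(3, 1),
                             alpha = 0.05) {
  stopifnot(length(ratio) == 2, all(ratio > 0),
            n_dominant >= 0, n_recessive >= 0,
            alpha > 0, alpha < 1)
  if (n_dominant + n_recessive <= 0) {
    stop("segregation_test: zero total count", call. = FALSE)
  }
  ht <- stats::chisq.test(c(n_dominant, n_recessive),
                          p = ratio / sum(ratio))
  structure(
    list(observed_dominant = n_dominant,
         observed_recessive = n_recessive,
         ratio = ratio,
         chi_square = unname(ht$statistic),
         df = 1L,
         p_value = unname(ht$p.value),
         alpha = alpha,
         consistent = unname(ht$statistic) <
           stats::qchisq(1 - alpha, df = 1)),
    class = "segregation_test"
  )
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(
    "Segregation test: %d:%d observed vs %g:%g expected\n",
    x$observed_dominant, x$observed_recessive, x$ratio[1], x$ratio[2]))
  cat(sprintf("  chi-square = %.4f (df = 1), p = %.4f -> %s at alpha = %g\n",
              x$chi_square, x$p_value,
              if (x$consistent) "consistent" else "inconsistent", x$alpha))
  invisible(x)
}
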