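#' Genotype counts for a biallelic deletion
#'
#' Convenience constructor and validator for the three-class genotype count
#' summary (`+/+`, `D/+`, `D/D`) used by the carrier-frequency and
#' homozygote-deficit operations.
#'
#' @param n_wildtype,n_carrier,n_homozygous non-negative counts.
#' @return list of class `ls_genotype_counts` with the three counts and `N`.
#' @export
genotype_counts <- function(n_wildtype, n_carrier, n_homozygous = 0) {
  counts <- c(n_wildtype = n_wildtype, n_carrier = n_carrier,
              n_homozygous = n_homozygous)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  structure(list(n_wildtype = as.integer(n_wildtype),
                 n_carrier = as.integer(n_carrier),
                 n_homozygous = as.integer(n_homozygous),
                 N = as.integer(sum(counts))),
            class = "ls_genotype_counts")
}

#' Carrier frequency with Wilson confidence interval
#'
#' Estimates the population carrier (heterozygote) frequency from genotype
#' counts as `n_carrier / N`, with a 95% Wilson score interval (accurate for
#' small proportions, unlike the Wald interval).
#'
#' @param counts an [genotype_counts()] object, or a list/vector with
#'   `n_carrier` and `N` resolvable.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `lower`, `upper`, `n_carrier`, `N`.
#' @examples
#' carrier_frequency(genotype_counts(2813, 225, 0)) # ~7.4%
#' @export
carrier_frequency <- function(counts, conf = 0.95) {
  if (!inherits(counts, "ls_genotype_counts")) {
    counts <- genotype_counts(counts[[1]], counts[[2]],
                              if (length(counts) >= 3) counts[[3]] else 0)
  }
  if (counts$N == 0) stop("N must be positive")
  x <- counts$n_carrier
  n <- counts$N
  est <- x / n
  ci <- if (x == 0) {
    c(0, stats::prop.test(0, n, correct = FALSE, conf.level = conf)$conf.int[2])
  } else if (x == n) {
    c(stats::prop.test(n, n, correct = FALSE, conf.level = conf)$conf.int[1], 1)
  } else {
    as.numeric(stats::prop.test(x, n, correct = FALSE,
                                conf.level = conf)$conf.int)
  }
  list(estimate = est, lower = ci[1], upper = ci[2],
       n_carrier = x, N = n, conf = conf)
}

#' Deletion allele frequency from carrier frequency under Hardy-Weinberg
#'
#' Back-calculates the allele frequency `q` from the heterozygote (carrier)
#' frequency `c` by solving `2q(1-q) = c` for its smaller root. Only
#' `c <= 0.5` admits a real root on `[0, 0.5]`.
#'
#' @param c carrier frequency in `[0, 0.5]`.
#' @return allele frequency `q`.
#' @examples
#' allele_freq_from_carrier(0.074) # ~0.0385
#' @export
allele_freq_from_carrier <- function(c) {
  if (any(c < 0) || any(c > 0.5)) {
    stop("carrier frequency must lie in [0, 0.5] for a real root q <= 0.5")
  }
  (1 - sqrt(1 - 2 * c)) / 2
}

#' Expected incidence of the homozygous condition from carrier frequency
#'
#' Uses the carrier-pairing approximation `incidence = c^2 / 4` (probability
#' both parents are carriers times the 1/4 Mendelian transmission), the form
#' under which the field quotes "1 in N births". The exact Hardy-Weinberg
#' alternative `q^2` (about 8% larger at c = 0.074) is returned alongside.
#'
#' @param c carrier frequency in `[0, 1]`.
#' @return list with `incidence` (`c^2/4`), `reciprocal` (`1/incidence`
#'   rounded to the nearest 10), `reciprocal_raw`, and `incidence_hwe`
#'   (`q^2`, `NA` when `c > 0.5`).
#' @examples
#' expected_incidence(0.074)$reciprocal # 730
#' @export
expected_incidence <- function(c) {
  stopifnot(c >= 0, c <= 1)
  inc <- c^2 / 4
  rec <- if (inc > 0) 1 / inc else Inf
  q2 <- if (c <= 0.5) allele_freq_from_carrier(c)^2 else NA_real_
  list(incidence = inc,
       reciprocal = if (is.finite(rec)) round(rec / 10) * 10 else Inf,
       reciprocal_raw = rec,
       incidence_hwe = q2)
}

#' Probability of observing zero homozygotes in a sample
#'
#' Exact binomial zero-class probability `(1 - q^2)^N` of seeing no
#' homozygous individuals among `N` random individuals when the deletion
#' allele frequency is `q` under Hardy-Weinberg proportions. A small value is
#' evidence of a homozygote deficit, e.g. from in-utero death of homozygotes.
#'
#' @param q allele frequency in `[0, 1]`.
#' @param N sample size, `>= 1`.
#' @return the probability.
#' @examples
#' prob_zero_homozygotes(allele_freq_from_carrier(0.074), 3038) # ~0.011
#' @export
prob_zero_homozygotes <- function(q, N) {
  stopifnot(q >= 0, q <= 1, N >= 1)
  (1 - q^2)^N
}

#' Survival-adjusted expected incidence at birth
#'
#' Scales the conception incidence `c^2/4` by the fraction of homozygous
#' conceptuses surviving to term, answering "given in-utero mortality, one
#' affected birth per how many calvings would still be expected?".
#'
#' @param c carrier frequency.
#' @param survival fraction of homozygous conceptuses surviving to birth,
#'   in `[0, 1]`.
#' @return list with `incidence`, `reciprocal_raw`, and `reciprocal` rounded
#'   to the nearest 100 above 1,000 (nearest 10 otherwise); `survival = 0`
#'   returns `Inf` reciprocal (no affected births expected).
#' @examples
#' survival_adjusted_incidence(0.074, 0.5)$reciprocal # 1500
#' @export
survival_adjusted_incidence <- function(c, survival) {
  stopifnot(c >= 0, c <= 1, survival >= 0, survival <= 1)
  inc <- (c^2 / 4) * survival
  if (inc == 0) {
    return(list(incidence = 0, reciprocal_raw = Inf, reciprocal = Inf))
  }
  rec <- 1 / inc
  rounded <- if (rec > 1000) round(rec / 100) * 100 else round(rec / 10) * 10
  list(incidence = inc, reciprocal_raw = rec, reciprocal = rounded)
}
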