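#' Probability that a dam carries the deletion given her sire's genotype
#'
#' Dams in insemination records are classified by the genotype of their own
#' (genotyped) sire. A carrier-sired dam inherits the deletion from the
#' grand-sire with probability 1/2, and from the ungenotyped grand-dam with
#' probability `c/2` (the grand-dam is a carrier with probability `c` and
#' transmits with probability 1/2); ignoring the negligible double-inheritance
#' overlap the combined probability is `0.5 + c/2`. A non-carrier-sired dam
#' can only have inherited from the grand-dam: probability `c/2`.
#'
#' @param dam_sire_is_carrier logical (vectorised).
#' @param c population carrier frequency.
#' @return probability the dam is a carrier.
#' @examples
#' dam_carrier_probability(TRUE, 0.074)  # 0.537
#' dam_carrier_probability(FALSE, 0.074) # 0.037
#' @export
dam_carrier_probability <- function(dam_sire_is_carrier, c) {
  stopifnot(c >= 0, c <= 1)
  ifelse(dam_sire_is_carrier, 0.5 + c / 2, c / 2)
}

#' Expected fraction of homozygous mutant conceptuses per mating class
#'
#' For a genotyped carrier sire, a conceptus is homozygous mutant when the
#' dam is also a carrier and both parents transmit: `P(dam carrier) * 1/4`.
#' A genotyped non-carrier sire cannot transmit, so the fraction is 0.
#'
#' @param sire_is_carrier logical (vectorised).
#' @param dam_sire_is_carrier logical (vectorised).
#' @param c population carrier frequency.
#' @return expected homozygous-conceptus fraction.
#' @examples
#' expected_homozygote_fraction(TRUE, TRUE, 0.074) # 0.537 * 0.25 = 0.134
#' @export
expected_homozygote_fraction <- function(sire_is_carrier, dam_sire_is_carrier, c) {
  ifelse(sire_is_carrier,
         dam_carrier_probability(dam_sire_is_carrier, c) / 4,
         0)
}

mating_class_label <- function(sire_class, dam_sire_class) {
  paste0(ifelse(dam_sire_class == "C", "Cdam", "NCdam"), "x",
         ifelse(sire_class == "C", "Csire", "NCsire"))
}

#' Mating-class failure summaries and contrasts against the reference class
#'
#' Summarises pregnancy-failure (return-to-oestrus) rates at 56, 90 and 270
#' days post-insemination per mating class, and contrasts every class against
#' the non-carrier x non-carrier reference: additive excess failure
#' `rate_class(t) - rate_ref(t)` with a 2x2 chi-square test (no continuity
#' correction; Fisher's exact test is substituted automatically when any
#' expected cell count is below 5).
#'
#' @param records mating records as produced by [simulate_matings()] (columns
#'   `sire_class`, `dam_sire_class`, `fail56`, `fail90`, `fail270`).
#' @return list with
#'   \describe{
#'     \item{summary}{`data.frame`, one row per class: n, failure counts and
#'       rates per stage.}
#'     \item{contrasts}{`data.frame`, one row per non-reference class and
#'       stage: excess failure, test statistic, p-value, test used.}
#'   }
#' @export
class_contrasts <- function(records) {
  stopifnot(all(c("sire_class", "dam_sire_class",
                  "fail56", "fail90", "fail270") %in% names(records)))
  records$class <- mating_class_label(records$sire_class,
                                      records$dam_sire_class)
  ref_label <- "NCdamxNCsire"
  if (!any(records$class == ref_label)) {
    stop("reference class NCdamxNCsire has no records")
  }
  stages <- c(56, 90, 270)
  cols <- paste0("fail", stages)
  agg <- do.call(rbind, lapply(split(records, records$class), function(d) {
    fails <- vapply(cols, function(cl) sum(d[[cl]]), numeric(1))
    data.frame(class = d$class[1], n = nrow(d),
               t(setNames(fails, paste0("fail", stages))),
               t(setNames(fails / nrow(d), paste0("rate", stages))),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  ord <- c("NCdamxNCsire", "CdamxNCsire", "NCdamxCsire", "CdamxCsire")
  agg <- agg[order(match(agg$class, ord)), , drop = FALSE]
  rownames(agg) <- NULL

  ref <- agg[agg$class == ref_label, ]
  other <- agg[agg$class != ref_label, , drop = FALSE]
  contrasts <- do.call(rbind, lapply(seq_len(nrow(other)), function(i) {
    do.call(rbind, lapply(seq_along(stages), function(s) {
      x1 <- other[[paste0("fail", stages[s])]][i]
      n1 <- other$n[i]
      x0 <- ref[[paste0("fail", stages[s])]]
      n0 <- ref$n
      tab <- matrix(c(x1, n1 - x1, x0, n0 - x0), nrow = 2, byrow = TRUE)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- stats::fisher.test(tab)
        stat <- NA_real_; p <- ft$p.value; test <- "fisher"
      } else {
        ct <- stats::chisq.test(tab, correct = FALSE)
        stat <- unname(ct$statistic); p <- ct$p.value; test <- "chisq"
      }
      data.frame(class = other$class[i], day = stages[s],
                 rate = x1 / n1, ref_rate = x0 / n0,
                 excess = x1 / n1 - x0 / n0,
                 statistic = stat, p_value = p, test = test,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(contrasts) <- NULL
  list(summary = agg, contrasts = contrasts)
}

#' Estimate cumulative in-utero mortality of homozygous conceptuses
#'
#' Method-of-moments estimator: the excess failure of the informative class
#' over the non-carrier x non-carrier reference at day `t` equals
#' `P_hom * m(t)` under the additive recessive-lethal model, so
#' `m_hat(t) = excess(t) / P_hom`, clipped to `[0, 1]`. Two 95% confidence
#' intervals are attached per stage: a delta-method interval from the
#' binomial variance of the risk difference, and (optionally) a
#' nonparametric bootstrap over matings.
#'
#' @param records mating records (see [class_contrasts()]).
#' @param carrier_freq population carrier frequency `c` used to compute the
#'   expected homozygote fraction `P_hom` of the informative class.
#' @param class informative class label (default `"CdamxCsire"`).
#' @param n_boot bootstrap replicates (default 200; 0 disables).
#' @param conf confidence level.
#' @param isotonic force the reported `m_hat` to be non-decreasing over
#'   stages via a cumulative maximum (default `FALSE`).
#' @param seed optional seed for the bootstrap.
#' @return list of class `ls_lethality` with `estimate` (data.frame per
#'   stage: excess, m_hat, delta and bootstrap CIs, p-value of the contrast),
#'   `P_hom`, `class`, `n`.
#' @examples
#' recs <- simulate_matings(20000, carrier_freq = 0.074, seed = 5)
#' estimate_mortality(recs, 0.074, n_boot = 0)
#' @export
estimate_mortality <- function(records, carrier_freq, class = "CdamxCsire",
                               n_boot = 200, conf = 0.95, isotonic = FALSE,
                               seed = NULL) {
  cc <- class_contrasts(records)
  P_hom <- switch(class,
                  CdamxCsire = expected_homozygote_fraction(TRUE, TRUE, carrier_freq),
                  NCdamxCsire = expected_homozygote_fraction(TRUE, FALSE, carrier_freq),
                  stop("class must have a carrier sire to be informative"))
  if (P_hom <= 0) stop("expected homozygote fraction is zero: class uninformative")
  con <- cc$contrasts[cc$contrasts$class == class, , drop = FALSE]
  if (!nrow(con)) stop("class ", class, " has no records")
  sum_cls <- cc$summary[cc$summary$class == class, ]
  sum_ref <- cc$summary[cc$summary$class == "NCdamxNCsire", ]
  z <- stats::qnorm(1 - (1 - conf) / 2)

  est <- do.call(rbind, lapply(seq_len(nrow(con)), function(i) {
    day <- con$day[i]
    p1 <- con$rate[i]; n1 <- sum_cls$n
    p0 <- con$ref_rate[i]; n0 <- sum_ref$n
    se_diff <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
    m_hat <- con$excess[i] / P_hom
    data.frame(day = day, excess = con$excess[i],
               m_hat = min(1, max(0, m_hat)),
               delta_lower = min(1, max(0, m_hat - z * se_diff / P_hom)),
               delta_upper = min(1, max(0, m_hat + z * se_diff / P_hom)),
               p_value = con$p_value[i],
               stringsAsFactors = FALSE)
  }))

  if (n_boot > 0) {
    cls_rows <- records[mating_class_label(records$sire_class,
                                           records$dam_sire_class) == class, ]
    ref_rows <- records[mating_class_label(records$sire_class,
                                           records$dam_sire_class) == "NCdamxNCsire", ]
    stages <- paste0("fail", est$day)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i1 <- sample.int(nrow(cls_rows), replace = TRUE)
        i0 <- sample.int(nrow(ref_rows), replace = TRUE)
        vapply(stages, function(cl) {
          (mean(cls_rows[[cl]][i1]) - mean(ref_rows[[cl]][i0])) / P_hom
        }, numeric(1))
      }, numeric(length(stages)))
    })
    boot <- matrix(boot, nrow = length(stages))
    qs <- apply(boot, 1, stats::quantile,
                probs = c((1 - conf) / 2, 1 - (1 - conf) / 2))
    est$boot_lower <- pmin(1, pmax(0, qs[1, ]))
    est$boot_upper <- pmin(1, pmax(0, qs[2, ]))
  }
  if (isotonic) est$m_hat <- cummax(est$m_hat)

  structure(list(estimate = est, P_hom = P_hom, class = class,
                 n = c(class_n = sum_cls$n, ref_n = sum_ref$n),
                 conf = conf),
            class = "ls_lethality")
}

#' @export
print.ls_lethality <- function(x, ...) {
  cat("Cumulative homozygote in-utero mortality (class ", x$class,
      ", P_hom = ", signif(x$P_hom, 4), ")\n", sep = "")
  df <- x$estimate
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  day %3d: m_hat = %.3f (excess %.4f; %d%% delta CI %.3f-%.3f)\n",
                df$day[i], df$m_hat[i], df$excess[i],
                round(100 * x$conf), df$delta_lower[i], df$delta_upper[i]))
  }
  invisible(x)
}

#' Parameter-recovery experiment for the mortality estimator
#'
#' Simulate-then-estimate loop: generates `n_reps` independent sets of mating
#' records from known mortality parameters and re-estimates them, reporting
#' bias, root-mean-square error, and empirical coverage of the delta-method
#' confidence intervals per gestation stage.
#'
#' @param n_per_class matings per class per replicate.
#' @param carrier_freq population carrier frequency.
#' @param baseline,mortality cumulative baseline failure and homozygote
#'   mortality vectors at 56/90/270 d (see [simulate_matings()]).
#' @param n_reps number of replicates (>= 10).
#' @param conf confidence level for coverage assessment.
#' @param seed integer seed; each replicate derives its own substream.
#' @return `data.frame`, one row per stage: truth, mean estimate, bias, RMSE,
#'   CI coverage.
#' @export
recover_parameters <- function(n_per_class, carrier_freq,
                               baseline = c(0.35, 0.40, 0.45),
                               mortality = c(0.30, 0.40, 0.52),
                               n_reps = 50, conf = 0.95, seed = NULL) {
  if (n_reps < 10) stop("n_reps must be >= 10")
  res <- lapply(seq_len(n_reps), function(r) {
    s <- if (is.null(seed)) NULL else child_seed(seed, paste0("recover", r))
    recs <- simulate_matings(n_per_class, carrier_freq, baseline, mortality,
                             seed = s)
    est <- estimate_mortality(recs, carrier_freq, n_boot = 0, conf = conf)
    est$estimate
  })
  stages <- res[[1]]$day
  do.call(rbind, lapply(seq_along(stages), function(s) {
    m_hats <- vapply(res, function(e) e$m_hat[s], numeric(1))
    lo <- vapply(res, function(e) e$delta_lower[s], numeric(1))
    hi <- vapply(res, function(e) e$delta_upper[s], numeric(1))
    truth <- mortality[s]
    data.frame(day = stages[s], truth = truth,
               mean_estimate = mean(m_hats),
               bias = mean(m_hats) - truth,
               rmse = sqrt(mean((m_hats - truth)^2)),
               coverage = mean(lo <= truth & truth <= hi),
               n_reps = n_reps,
               stringsAsFactors = FALSE)
  }))
}
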