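#' Simulate artificial-insemination records with recessive in-utero lethality
#'
#' Generates one record per insemination for the four mating classes used in
#' the fertility contrast: sire genotyped non-carrier or carrier crossed with
#' a dam whose own sire (the maternal grand-sire) is genotyped non-carrier or
#' carrier. Dam carrier status is latent: a carrier-sired dam carries the
#' deletion with probability `0.5 + c/2` (one half from the grand-sire plus
#' `c/2` from the ungenotyped grand-dam), a non-carrier-sired dam with
#' probability `c/2`.
#'
#' A conceptus is homozygous mutant (D/D) only when both the sire and the dam
#' are carriers and both transmit (probability 1/4). Pregnancy failure
#' (return to oestrus) by day `t` in (56, 90, 270) is generated under an
#' additive cumulative-risk model: every mating carries the baseline failure
#' probability `baseline[t]`, and a D/D conceptus adds the stage-specific
#' cumulative mortality `m[t]` as a disjoint failure cause, so class failure
#' probabilities are exactly `baseline(t) + P(D/D) * m(t)` and baseline risk
#' cancels in between-class contrasts. Both cumulative vectors must be
#' non-decreasing with `baseline + mortality <= 1`, which makes every
#' record's failure indicators monotone across stages.
#'
#' @param n_per_class number of matings in each of the four classes (scalar
#'   or length-4 vector ordered NCxNC, CdamxNCsire, NCdamxCsire, CxC; the
#'   first label is the dam-side class, i.e. the dam's sire).
#' @param carrier_freq population carrier frequency `c`.
#' @param baseline cumulative baseline failure probabilities at 56/90/270 d
#'   (default `c(0.35, 0.40, 0.45)`).
#' @param mortality cumulative D/D mortality m(56), m(90), m(270)
#'   (default `c(0.30, 0.40, 0.52)`).
#' @param seed integer seed.
#' @return `data.frame` of class `ls_matings` with columns `mating_id`,
#'   `sire_class` (`"C"`/`"NC"`), `dam_sire_class`, `fail56`, `fail90`,
#'   `fail270` (0/1), `truth_dam_carrier` (0/1), and the latent
#'   `truth_conceptus` genotype (`"+/+"`, `"D/+"`, `"D/D"`).
#' @examples
#' recs <- simulate_matings(1000, carrier_freq = 0.074, seed = 11)
#' table(recs$sire_class, recs$dam_sire_class)
#' @export
simulate_matings <- function(n_per_class, carrier_freq,
                             baseline = c(0.35, 0.40, 0.45),
                             mortality = c(0.30, 0.40, 0.52),
                             seed = NULL) {
  stopifnot(carrier_freq >= 0, carrier_freq <= 1,
            length(baseline) == 3, length(mortality) == 3)
  if (any(diff(baseline) < 0) || any(diff(mortality) < 0)) {
    stop("baseline and mortality vectors must be non-decreasing over stages")
  }
  if (any(baseline < 0 | baseline > 1) || any(mortality < 0 | mortality > 1)) {
    stop("baseline and mortality must lie in [0, 1]")
  }
  if (any(baseline + mortality > 1)) {
    stop("baseline(t) + mortality(t) must not exceed 1 (additive risks)")
  }
  n_per_class <- rep_len(as.integer(n_per_class), 4L)
  classes <- data.frame(sire = c("NC", "NC", "C", "C"),
                        dam_sire = c("NC", "C", "NC", "C"),
                        stringsAsFactors = FALSE)
  with_seed(seed, {
    n <- sum(n_per_class)
    sire_class <- rep(classes$sire, n_per_class)
    dam_sire_class <- rep(classes$dam_sire, n_per_class)
    c_ <- carrier_freq
    p_dam <- ifelse(dam_sire_class == "C", 0.5 + c_ / 2, c_ / 2)
    dam_carrier <- runif(n) < p_dam
    sire_carrier <- sire_class == "C"
    # independent Mendelian transmissions from each carrier parent (D/+)
    sire_transmits <- sire_carrier & runif(n) < 0.5
    dam_transmits <- dam_carrier & runif(n) < 0.5
    n_del <- as.integer(sire_transmits) + as.integer(dam_transmits)
    conceptus <- c("+/+", "D/+", "D/D")[n_del + 1L]
    dd <- n_del == 2L

    # one uniform per mating; baseline and lethality occupy disjoint slices of
    # [0, 1], so risks add exactly and failure is monotone over stages
    u <- runif(n)
    fail <- vapply(1:3, function(s) {
      as.integer(u < baseline[s] + dd * mortality[s])
    }, integer(n))

    out <- data.frame(mating_id = sprintf("m%07d", seq_len(n)),
                      sire_class = sire_class,
                      dam_sire_class = dam_sire_class,
                      fail56 = fail[, 1], fail90 = fail[, 2],
                      fail270 = fail[, 3],
                      truth_dam_carrier = as.integer(dam_carrier),
                      truth_conceptus = conceptus,
                      stringsAsFactors = FALSE)
    class(out) <- c("ls_matings", "data.frame")
    out
  })
}
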