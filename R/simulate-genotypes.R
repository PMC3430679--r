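#' Simulate case/control SNP genotypes with a planted autozygous haplotype
#'
#' Generates diploid genotypes for `n_cases` affected individuals that are all
#' homozygous for one planted identical-by-descent (IBD) carrier haplotype
#' across a contiguous chromosomal interval, plus `n_controls` unrelated
#' controls drawn as two independent haplotypes from the population (phase is
#' retained, so the controls double as the phased reference pool the mapping
#' step needs).
#'
#' Within the planted interval a control haplotype is a copy of the carrier
#' haplotype with probability `q`, the smaller root of `2q(1-q) = c` where `c`
#' is the carrier (heterozygote) frequency: under Hardy-Weinberg this makes
#' the expected fraction of heterozygous (D/+) controls exactly `c`, and the
#' fraction carrying at least one copy `c + q^2` (indistinguishable from `c`
#' at realistic sample sizes). Outside the interval, and for non-carrier
#' haplotypes inside it, alleles are drawn independently per marker from
#' per-marker control allele frequencies. Homozygous-carrier controls are not
#' suppressed; they arise at their natural `q^2` rate so homozygote-deficit
#' tests see the unconstrained model.
#'
#' @param map marker map from [marker_map()].
#' @param n_cases,n_controls sample sizes.
#' @param carrier_freq population carrier (heterozygote) frequency `c` in
#'   `[0, 0.5]`.
#' @param interval planted IBD interval: list or vector with `chrom`, `start`,
#'   `end` (1-based bp, inclusive); must contain at least 10 markers.
#' @param control_af optional vector of control alternate-allele frequencies,
#'   one per marker; defaults to draws from Uniform(0.05, 0.95).
#' @param seed integer seed.
#' @return an object of class `ls_genotypes`: a list with
#'   \describe{
#'     \item{geno}{integer matrix, individuals x markers, alt-allele dosage
#'       0/1/2 (`NA` = missing; the simulator emits none).}
#'     \item{map}{the marker map.}
#'     \item{case_ids, control_ids}{row names of cases and controls.}
#'     \item{control_haplotypes}{0/1 matrix, `2 * n_controls` x markers; rows
#'       `2i-1`, `2i` are the phased haplotypes of control `i`.}
#'     \item{planted_haplotype}{0/1 allele vector of the carrier haplotype
#'       over the planted-interval markers.}
#'     \item{interval, interval_markers}{the planted interval and the map row
#'       indices it covers.}
#'     \item{truth_bed}{one-row 0-based half-open BED `data.frame` of the
#'       planted interval.}
#'   }
#' @examples
#' map <- marker_map("21", 60, 6e6, seed = 2)
#' sim <- simulate_genotypes(map, n_cases = 6, n_controls = 50,
#'                           carrier_freq = 0.074,
#'                           interval = list(chrom = "21", start = 2e6, end = 4e6),
#'                           seed = 7)
#' dim(sim$geno)
#' @export
simulate_genotypes <- function(map, n_cases, n_controls, carrier_freq,
                               interval, control_af = NULL, seed = NULL) {
  validate_marker_map(map)
  stopifnot(n_cases >= 1, n_controls >= 0,
            carrier_freq >= 0, carrier_freq <= 0.5)
  interval <- as.list(interval)
  idx <- markers_in_interval(map, interval$chrom,
                             as.numeric(interval$start), as.numeric(interval$end))
  if (length(idx) < 10L) {
    stop("planted interval covered by ", length(idx),
         " markers; >= 10 required")
  }
  m <- nrow(map)
  with_seed(seed, {
    af <- control_af %||% runif(m, 0.05, 0.95)
    stopifnot(length(af) == m, all(af >= 0 & af <= 1))
    # carrier haplotype: one fixed random allele vector, drawn once
    carrier_hap <- rbinom(m, 1L, af)
    q <- allele_freq_from_carrier(carrier_freq)

    draw_background <- function(n_hap) {
      matrix(rbinom(n_hap * m, 1L, rep(af, each = n_hap)), nrow = n_hap)
    }

    # cases: planted haplotype doubled across the interval, background elsewhere
    case_h1 <- draw_background(n_cases)
    case_h2 <- draw_background(n_cases)
    case_h1[, idx] <- rep(carrier_hap[idx], each = n_cases)
    case_h2[, idx] <- rep(carrier_hap[idx], each = n_cases)

    # controls: two independent haplotypes; carrier copies with prob q
    ctrl <- draw_background(2L * max(n_controls, 1L))
    if (n_controls > 0) {
      ctrl <- ctrl[seq_len(2L * n_controls), , drop = FALSE]
      is_carrier_hap <- runif(2L * n_controls) < q
      if (any(is_carrier_hap)) {
        ctrl[is_carrier_hap, idx] <- rep(carrier_hap[idx],
                                         each = sum(is_carrier_hap))
      }
    } else {
      ctrl <- ctrl[0, , drop = FALSE]
    }

    geno <- rbind(case_h1 + case_h2,
                  if (n_controls > 0) {
                    ctrl[seq(1, 2 * n_controls, by = 2), , drop = FALSE] +
                      ctrl[seq(2, 2 * n_controls, by = 2), , drop = FALSE]
                  })
    case_ids <- sprintf("case_%02d", seq_len(n_cases))
    control_ids <- if (n_controls > 0) {
      sprintf("ctrl_%04d", seq_len(n_controls))
    } else character()
    rownames(geno) <- c(case_ids, control_ids)
    colnames(geno) <- map$id
    if (n_controls > 0) {
      rownames(ctrl) <- paste0(rep(control_ids, each = 2), c("_h1", "_h2"))
    }
    truth_bed <- data.frame(chrom = as.character(interval$chrom),
                            start = as.numeric(interval$start) - 1,
                            end = as.numeric(interval$end),
                            name = "planted_ibd_interval",
                            stringsAsFactors = FALSE)
    structure(list(geno = geno, map = map,
                   case_ids = case_ids, control_ids = control_ids,
                   control_haplotypes = ctrl,
                   planted_haplotype = carrier_hap[idx],
                   interval = interval, interval_markers = idx,
                   truth_bed = truth_bed),
              class = "ls_genotypes")
  })
}

#' @export
print.ls_genotypes <- function(x, ...) {
  cat("Simulated genotypes:", length(x$case_ids), "cases,",
      length(x$control_ids), "controls,", nrow(x$map), "markers\n")
  cat("Planted IBD interval:", x$interval$chrom, ":",
      format(x$interval$start, big.mark = ","), "-",
      format(x$interval$end, big.mark = ","),
      sprintf("(%d markers)\n", length(x$interval_markers)))
  invisible(x)
}
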