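#' Detect runs of homozygosity in one individual
#'
#' Scans an individual's genotypes chromosome by chromosome for maximal runs
#' containing at least `min_markers` markers and at most `max_het`
#' heterozygous calls. Missing genotypes always break a run (conservative:
#' autozygosity is only declared where it is observed). With `max_het > 0`
#' the maximal windows may overlap; every window that cannot be extended on
#' either side without violating the constraints is reported.
#'
#' @param genotypes an `ls_genotypes` object, or a list with elements `geno`
#'   (individuals x markers dosage matrix) and `map`.
#' @param individual row name or index of the individual to scan.
#' @param min_markers minimum markers per run (default 20).
#' @param max_het maximum heterozygous calls tolerated inside a run
#'   (default 0).
#' @return `data.frame` with one row per run: `chrom`, `start_idx`/`end_idx`
#'   (0-based half-open indices into the chromosome's markers), `start_bp`,
#'   `end_bp` (1-based positions of the flanking markers), `n_markers`,
#'   `n_het`. Empty for an all-missing individual.
#' @examples
#' map <- marker_map("1", 30, 3e6, seed = 1)
#' sim <- simulate_genotypes(map, 2, 10, 0.1,
#'                           list(chrom = "1", start = 1, end = 3e6), seed = 1)
#' detect_roh(sim, "case_01", min_markers = 10)
#' @export
detect_roh <- function(genotypes, individual, min_markers = 20, max_het = 0) {
  geno <- genotypes$geno
  map <- genotypes$map
  if (is.character(individual) && !individual %in% rownames(geno)) {
    stop("individual ", individual, " not present")
  }
  g <- geno[individual, ]
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    gc <- g[sel]
    pos <- map$pos[sel]
    n <- length(gc)
    usable <- !is.na(gc)
    het <- !is.na(gc) & gc == 1L
    # maximal windows with <= max_het hets, no missing, >= min_markers
    i <- 1L
    runs <- list()
    while (i <= n) {
      if (!usable[i]) { i <- i + 1L; next }
      # extend j as far as feasible starting at i
      j <- i
      nh <- 0L
      while (j <= n && usable[j] && nh + het[j] <= max_het) {
        nh <- nh + het[j]
        j <- j + 1L
      }
      # window [i, j) is start-maximal; it is end-maximal by construction
      if (j - i >= min_markers) {
        runs[[length(runs) + 1L]] <- c(i, j, sum(het[i:(j - 1L)]))
      }
      # next start: first position after i where dropping leading markers
      # could allow a longer extension (i.e. just past the first het), else j
      nxt <- if (max_het > 0L && any(het[i:(j - 1L)])) {
        i + which(het[i:(j - 1L)])[1L]
      } else j
      i <- max(nxt, i + 1L)
    }
    if (length(runs)) {
      rm_ <- do.call(rbind, runs)
      # drop windows contained in a longer reported window
      keep <- rep(TRUE, nrow(rm_))
      if (nrow(rm_) > 1) {
        for (k in seq_len(nrow(rm_))) {
          contained <- any(rm_[-k, 1] <= rm_[k, 1] & rm_[-k, 2] >= rm_[k, 2])
          if (contained) keep[k] <- FALSE
        }
      }
      rm_ <- rm_[keep, , drop = FALSE]
      out[[ch]] <- data.frame(chrom = ch,
                              start_idx = rm_[, 1] - 1L, end_idx = rm_[, 2] - 1L,
                              start_bp = pos[rm_[, 1]], end_bp = pos[rm_[, 2] - 1L],
                              n_markers = rm_[, 2] - rm_[, 1],
                              n_het = rm_[, 3],
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_markers = integer(),
                      n_het = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Maximal shared homozygous segment through a marker
#'
#' Finds the maximal marker interval containing `marker_index` on which every
#' case is homozygous and all case genotypes are identical — the signature of
#' a haplotype shared identical-by-descent on both chromosomes by all
#' affected individuals. Returns `NULL` when any case is heterozygous or
#' missing at the query marker.
#'
#' @param genotypes an `ls_genotypes` object (or list with `geno`, `map`).
#' @param case_ids row names/indices of the affected individuals (>= 2).
#' @param marker_index global marker index (1-based row of the map).
#' @return `NULL`, or a list of class `ls_shared_segment` with `chrom`,
#'   `start_idx`/`end_idx` (0-based half-open global marker indices),
#'   `start_bp`/`end_bp`, `n_markers`, `n_cases`, and `haplotype` (the shared
#'   allele-dosage vector divided by 2, i.e. the 0/1 haplotype).
#' @export
shared_segment_at <- function(genotypes, case_ids, marker_index) {
  geno <- genotypes$geno
  map <- genotypes$map
  if (length(case_ids) < 2) stop("need >= 2 cases")
  if (marker_index < 1 || marker_index > nrow(map)) {
    stop("marker_index out of range")
  }
  G <- geno[case_ids, , drop = FALSE]
  ch <- map$chrom[marker_index]
  sel <- which(map$chrom == ch)
  Gc <- G[, sel, drop = FALSE]
  k <- match(marker_index, sel)
  share <- shareable_markers(Gc)
  if (!share[k]) return(NULL)
  a <- k; while (a > 1L && share[a - 1L]) a <- a - 1L
  b <- k; while (b < length(sel) && share[b + 1L]) b <- b + 1L
  new_shared_segment(map, sel, a, b, Gc[1, a:b] %/% 2L, length(case_ids))
}

# markers where all cases are homozygous, non-missing, and identical:
# equivalently, every case is 0 or every case is 2
shareable_markers <- function(Gc) {
  n <- nrow(Gc)
  G0 <- Gc
  G0[is.na(G0)] <- -1L
  colSums(G0 == 0L) == n | colSums(G0 == 2L) == n
}

new_shared_segment <- function(map, sel, a, b, haplotype, n_cases) {
  structure(list(chrom = map$chrom[sel[a]],
                 start_idx = sel[a] - 1L, end_idx = sel[b],
                 start_bp = map$pos[sel[a]], end_bp = map$pos[sel[b]],
                 n_markers = b - a + 1L, n_cases = n_cases,
                 haplotype = as.integer(haplotype)),
            class = "ls_shared_segment")
}

#' Chance-sharing point probability of a shared segment
#'
#' Estimates the population frequency `f` of the cases' shared haplotype
#' from a phased control pool with an add-one pseudocount,
#' `f = (matches + pseudocount) / (2 N_controls + 2 pseudocount)`, and
#' returns the probability `p(s) = f^(2n)` that `2n` chromosomes drawn at
#' random would all carry that haplotype — the point probability that the
#' `n` cases share the segment homozygous by chance alone.
#'
#' @param segment an `ls_shared_segment` from [shared_segment_at()].
#' @param control_haplotypes 0/1 matrix of phased control haplotypes over all
#'   markers (rows = haplotypes), e.g. `sim$control_haplotypes`.
#' @param pseudocount added to the match count (default 1).
#' @return list with `p` (the point probability), `f`, `matches`,
#'   `n_control_haplotypes`.
#' @export
sharing_statistic <- function(segment, control_haplotypes, pseudocount = 1) {
  if (is.null(dim(control_haplotypes)) || nrow(control_haplotypes) == 0) {
    stop("need at least one control haplotype")
  }
  cols <- (segment$start_idx + 1L):segment$end_idx
  H <- control_haplotypes[, cols, drop = FALSE]
  matches <- sum(colSums(t(H) != segment$haplotype) == 0)
  f <- (matches + pseudocount) / (nrow(H) + 2 * pseudocount)
  list(p = f^(2 * segment$n_cases), f = f, matches = matches,
       n_control_haplotypes = nrow(H))
}

# per-marker point probabilities for a set of case genotypes, exploiting the
# fact that all markers inside one maximal shared segment share its p(s)
scan_point_probs <- function(G, map, control_haplotypes, pseudocount,
                             n_cases) {
  m <- nrow(map)
  p <- rep(1, m)
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    Gc <- G[, sel, drop = FALSE]
    share <- shareable_markers(Gc)
    k <- 1L
    while (k <= length(sel)) {
      if (!share[k]) { k <- k + 1L; next }
      b <- k
      while (b < length(sel) && share[b + 1L]) b <- b + 1L
      seg <- new_shared_segment(map, sel, k, b, Gc[1, k:b] %/% 2L, n_cases)
      ps <- sharing_statistic(seg, control_haplotypes, pseudocount)$p
      p[sel[k:b]] <- ps
      k <- b + 1L
    }
  }
  p
}

#' Genome-wide autozygosity scan with Monte-Carlo significance
#'
#' Computes the chance-sharing point probability `p(s)` at every marker for
#' the observed cases, then calibrates the genome-wide minimum against a
#' Monte-Carlo null: in each replicate, `2n` chromosomes are drawn with
#' replacement from the phased control pool to form `n` pseudo-cases, the
#' identical scan is run, and the replicate's genome-wide minimum `p(s)` is
#' recorded. The genome-wide probability of the observed segment is the
#' add-one estimator `P_gw = (1 + #(null minima <= observed p)) / (n_reps + 1)`,
#' bounded below by `1/(n_reps + 1)`.
#'
#' Note the null resamples single chromosomes, ignoring relatedness among the
#' real cases; with closely related cases the scan is anti-conservative.
#'
#' @param genotypes an `ls_genotypes` object.
#' @param case_ids the affected individuals (>= 2).
#' @param control_haplotypes phased control haplotype matrix; defaults to the
#'   pool stored in `genotypes`.
#' @param n_reps Monte-Carlo replicates (>= 100, default 1000).
#' @param pseudocount haplotype-frequency pseudocount (default 1).
#' @param seed integer seed for the null draws.
#' @return list of class `ls_scan` with
#'   \describe{
#'     \item{per_marker}{`data.frame` `marker`, `chrom`, `pos`, `p_point`,
#'       `neg_log10`.}
#'     \item{best_segment}{the `ls_shared_segment` attaining the minimum
#'       `p(s)`, with `p_point` and `P_gw` attached (`NULL` if the cases
#'       share no segment anywhere).}
#'     \item{null_min}{the vector of null genome-wide minima.}
#'   }
#' @export
genomewide_scan <- function(genotypes, case_ids,
                            control_haplotypes = genotypes$control_haplotypes,
                            n_reps = 1000, pseudocount = 1, seed = NULL) {
  if (n_reps < 100) stop("n_reps must be >= 100")
  if (is.null(dim(control_haplotypes)) || nrow(control_haplotypes) < 2) {
    stop("phased control haplotypes required")
  }
  map <- genotypes$map
  n_cases <- length(case_ids)
  G <- genotypes$geno[case_ids, , drop = FALSE]
  p_obs <- scan_point_probs(G, map, control_haplotypes, pseudocount, n_cases)
  obs_min <- min(p_obs)

  best <- NULL
  if (obs_min < 1) {
    best_marker <- which.min(p_obs)
    best <- shared_segment_at(genotypes, case_ids, best_marker)
  }

  null_min <- with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      rows <- sample.int(nrow(control_haplotypes), 2 * n_cases, replace = TRUE)
      H <- control_haplotypes[rows, , drop = FALSE]
      Gn <- H[seq(1, 2 * n_cases, by = 2), , drop = FALSE] +
        H[seq(2, 2 * n_cases, by = 2), , drop = FALSE]
      min(scan_point_probs(Gn, map, control_haplotypes, pseudocount, n_cases))
    }, numeric(1))
  })
  P_gw <- (1 + sum(null_min <= obs_min)) / (n_reps + 1)
  if (!is.null(best)) {
    best$p_point <- obs_min
    best$P_gw <- P_gw
  }
  structure(list(per_marker = data.frame(marker = map$id, chrom = map$chrom,
                                         pos = map$pos, p_point = p_obs,
                                         neg_log10 = -log10(p_obs),
                                         stringsAsFactors = FALSE),
                 best_segment = best, P_gw = P_gw, null_min = null_min,
                 n_reps = n_reps),
            class = "ls_scan")
}

#' @export
print.ls_scan <- function(x, ...) {
  cat("Autozygosity scan over", nrow(x$per_marker), "markers;",
      x$n_reps, "null replicates\n")
  if (is.null(x$best_segment)) {
    cat("No segment shared homozygous by all cases.\n")
  } else {
    s <- x$best_segment
    cat(sprintf("Best segment: %s:%s-%s (%d markers), p = %.3g, P_gw = %.4g\n",
                s$chrom, format(s$start_bp, big.mark = ","),
                format(s$end_bp, big.mark = ","), s$n_markers,
                s$p_point, s$P_gw))
  }
  invisible(x)
}
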