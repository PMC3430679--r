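#' Fit the concordant insert-size model of a mate-pair library
#'
#' Robust location/spread of the reference-mapped distance between read
#' pairs, computed from the central quantiles so that a minority of
#' deletion-spanning (inflated-distance) pairs does not bias the model, plus
#' the discordance threshold `mean + k * sd` above which a pair is treated as
#' structural-variant evidence.
#'
#' @param pairs mate-pair `data.frame` with a `mapped_distance` column (and
#'   optionally `orientation`).
#' @param trim_quantile fraction trimmed from each tail before computing
#'   mean/sd (default 0.05).
#' @param k discordance threshold in trimmed standard deviations above the
#'   trimmed mean (default 4).
#' @return list of class `ls_insert_model` with `mean`, `sd`, `threshold`,
#'   `k`, `trim_quantile`, `n_pairs`.
#' @examples
#' mp <- simulate_matepairs(5e4, coverage = 5, seed = 1)
#' fit_insert_model(mp$pairs)
#' @export
fit_insert_model <- function(pairs, trim_quantile = 0.05, k = 4) {
  d <- pairs$mapped_distance
  if (length(d) < 100) stop("need >= 100 pairs to fit the insert model")
  stopifnot(trim_quantile >= 0, trim_quantile < 0.5, k > 0)
  qs <- stats::quantile(d, c(trim_quantile, 1 - trim_quantile), names = FALSE)
  core <- d[d >= qs[1] & d <= qs[2]]
  mu <- mean(core)
  s <- stats::sd(core)
  if (is.na(s) || s == 0) s <- 0
  structure(list(mean = mu, sd = s, threshold = mu + k * max(s, 1),
                 k = k, trim_quantile = trim_quantile, n_pairs = length(d)),
            class = "ls_insert_model")
}

#' Cluster discordant mate pairs into deletion candidates
#'
#' Pairs whose mapped distance exceeds the insert model's discordance
#' threshold (and are in the expected forward-reverse orientation) each
#' bracket a putative deleted segment between the end of their left read and
#' the start of their right read. Pairs whose brackets overlap (allowing
#' `max_gap` bp of slack) are grouped by single linkage; each cluster reports
#' the tight bracket (intersection of member brackets), a support count, and
#' an estimated deletion size `mean(member distance) - insert mean`.
#'
#' @param pairs mate-pair `data.frame` (`chrom`, `pos1`, `pos2`,
#'   `orientation`, `mapped_distance`; positions 0-based leftmost read
#'   coordinates).
#' @param model an `ls_insert_model`.
#' @param read_length read length used to convert `pos1` to the left read's
#'   end (default 76).
#' @param max_gap clustering slack in bp (default 1000).
#' @return `data.frame`, one row per candidate: `chrom`, `start`, `end`
#'   (0-based half-open tight bracket), `n_discordant_pairs`,
#'   `estimated_size`, `mean_distance`. Zero rows when nothing is discordant.
#' @export
cluster_discordant <- function(pairs, model, read_length = 76, max_gap = 1000) {
  stopifnot(inherits(model, "ls_insert_model"))
  disc <- pairs[pairs$mapped_distance > model$threshold, , drop = FALSE]
  if ("orientation" %in% names(disc)) {
    disc <- disc[disc$orientation == "FR", , drop = FALSE]
  }
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_discordant_pairs = integer(), estimated_size = numeric(),
                      mean_distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(disc)) return(empty)
  out <- list()
  for (ch in unique(disc$chrom)) {
    d <- disc[disc$chrom == ch, , drop = FALSE]
    # bracket of pair i: [pos1 + read_length, pos2)
    d$bs <- d$pos1 + read_length
    d$be <- d$pos2
    d <- d[order(d$bs), , drop = FALSE]
    # single-linkage: new cluster when this bracket starts beyond the running
    # max end of the current cluster plus max_gap
    grp <- integer(nrow(d))
    g <- 1L
    run_end <- d$be[1]
    grp[1] <- g
    for (i in seq_len(nrow(d))[-1]) {
      if (d$bs[i] > run_end + max_gap) {
        g <- g + 1L
        run_end <- d$be[i]
      } else {
        run_end <- max(run_end, d$be[i])
      }
      grp[i] <- g
    }
    for (g_ in unique(grp)) {
      m <- d[grp == g_, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = max(m$bs), end = min(m$be),
        n_discordant_pairs = nrow(m),
        estimated_size = mean(m$mapped_distance) - model$mean,
        mean_distance = mean(m$mapped_distance),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  # a sane cluster's tight bracket is non-empty; degenerate ones are kept but
  # flagged by start >= end
  rownames(res) <- NULL
  res
}

#' Detect coverage-dropout intervals
#'
#' Finds maximal intervals of zero depth (homozygous-deletion mode) or of
#' roughly half the flanking depth (heterozygous mode) that are at least
#' `window` bp long and flanked on both sides by `window` bp of depth
#' averaging at least `min_flank_depth`. In sparse-coverage libraries the
#' `window` floor is what separates a genuine dropout from the Poisson gaps
#' expected between reads.
#'
#' @param depth `data.frame` with `pos` (0-based, contiguous) and `depth`.
#' @param window minimum dropout length and flank width in bp (default 500).
#' @param min_flank_depth minimum mean depth over each flank (default 1).
#' @param mode `"zero"` (default) or `"half"`; in half mode the dropout band
#'   is mean flank depth times `0.5 +/- half_band`.
#' @param half_band half-depth tolerance as a fraction of flank depth
#'   (default 0.2).
#' @return `data.frame` with `start`, `end` (0-based half-open), `length`,
#'   `mean_flank_depth`, `mode`. Errors when the whole track is zero (no
#'   flanking coverage to calibrate against).
#' @export
detect_dropout <- function(depth, window = 500, min_flank_depth = 1,
                           mode = c("zero", "half"), half_band = 0.2) {
  mode <- match.arg(mode)
  d <- depth$depth
  n <- length(d)
  if (all(d == 0)) stop("no flanking coverage: depth track is all zero")
  if (mode == "zero") {
    low <- d == 0
  } else {
    # smooth per-base depth first: raw counts are Poisson-noisy, and a long
    # half-depth run only shows up in the local mean
    w <- max(51L, (window %/% 5) %/% 2 * 2 + 1L)
    sm <- as.numeric(stats::filter(d, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- d[is.na(sm)]
    target <- mean(d[d > 0])
    low <- sm >= target * (0.5 - half_band) & sm <= target * (0.5 + half_band)
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= window)
  out <- list()
  for (i in cand) {
    s <- starts[i]; e <- ends[i] # 1-based inclusive indices
    lf <- d[max(1, s - window):(s - 1)]
    rf <- d[(e + 1):min(n, e + window)]
    if (s == 1 || e == n) next # dropout must be flanked on both sides
    if (length(lf) >= window && length(rf) >= window &&
        mean(lf) >= min_flank_depth && mean(rf) >= min_flank_depth) {
      out[[length(out) + 1L]] <- data.frame(
        start = depth$pos[s], end = depth$pos[e] + 1,
        length = e - s + 1L,
        mean_flank_depth = mean(c(lf, rf)),
        mode = mode, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(), end = numeric(), length = integer(),
                      mean_flank_depth = numeric(), mode = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge discordant-pair and dropout evidence into deletion calls
#'
#' A discordant-pair cluster and a dropout interval describing the same event
#' (reciprocal overlap >= `min_reciprocal`) merge into a tier-1 call whose
#' boundaries come from the dropout interval (read-resolution evidence);
#' unmatched clusters and dropouts become lower-tier single-evidence calls.
#'
#' @param clusters output of [cluster_discordant()].
#' @param dropouts output of [detect_dropout()]; a `chrom` column is added if
#'   absent (single-chromosome tracks).
#' @param chrom chromosome label applied to dropouts lacking one.
#' @param min_reciprocal minimum reciprocal overlap to merge (default 0.5).
#' @return `data.frame` of calls: `chrom`, `start`, `end`, `size`,
#'   `n_discordant_pairs`, `evidence` (`"pair+dropout"`, `"pair-only"`,
#'   `"dropout-only"`), `tier` (1 or 2), `estimated_size`, `refined`
#'   (FALSE), `microhomology` (NA until refined), sorted tier-first.
#' @export
merge_evidence <- function(clusters, dropouts, chrom = "21",
                           min_reciprocal = 0.5) {
  if (nrow(dropouts) && !"chrom" %in% names(dropouts)) dropouts$chrom <- chrom
  calls <- list()
  used_drop <- rep(FALSE, nrow(dropouts))
  if (nrow(clusters)) {
    for (i in seq_len(nrow(clusters))) {
      cl <- clusters[i, ]
      merged <- FALSE
      if (nrow(dropouts)) {
        for (j in seq_len(nrow(dropouts))) {
          dr <- dropouts[j, ]
          if (dr$chrom != cl$chrom) next
          ov <- min(cl$end, dr$end) - max(cl$start, dr$start)
          if (ov <= 0) next
          rec <- min(ov / (cl$end - cl$start), ov / (dr$end - dr$start))
          # guard: a degenerate (empty) cluster bracket cannot merge
          if (cl$end <= cl$start) next
          if (rec >= min_reciprocal) {
            calls[[length(calls) + 1L]] <- data.frame(
              chrom = cl$chrom, start = dr$start, end = dr$end,
              size = dr$end - dr$start,
              n_discordant_pairs = cl$n_discordant_pairs,
              evidence = "pair+dropout", tier = 1L,
              estimated_size = cl$estimated_size,
              refined = FALSE, microhomology = NA_integer_,
              stringsAsFactors = FALSE)
            used_drop[j] <- TRUE
            merged <- TRUE
            break
          }
        }
      }
      if (!merged) {
        start <- cl$start
        end <- max(cl$end, cl$start + cl$estimated_size)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = cl$chrom, start = start, end = end, size = end - start,
          n_discordant_pairs = cl$n_discordant_pairs,
          evidence = "pair-only", tier = 2L,
          estimated_size = cl$estimated_size,
          refined = FALSE, microhomology = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (nrow(dropouts)) {
    for (j in which(!used_drop)) {
      dr <- dropouts[j, ]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = dr$chrom, start = dr$start, end = dr$end,
        size = dr$end - dr$start,
        n_discordant_pairs = 0L,
        evidence = "dropout-only", tier = 2L,
        estimated_size = dr$end - dr$start,
        refined = FALSE, microhomology = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      size = numeric(), n_discordant_pairs = integer(),
                      evidence = character(), tier = integer(),
                      estimated_size = numeric(), refined = logical(),
                      microhomology = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, calls)
  res <- res[order(res$tier, -res$n_discordant_pairs), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# longest exact prefix of `read` matching `reference` anywhere; returns the
# best (0-based ref start, matched length), seeded on the first `seed_len`
# bases. NULL when the seed does not occur.
longest_prefix_match <- function(read, reference, seed_len = 20) {
  seed <- substr(read, 1, seed_len)
  if (nchar(seed) < seed_len) return(NULL)
  hits <- gregexpr(seed, reference, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NULL)
  best <- NULL
  rl <- nchar(read)
  for (h in as.integer(hits)) {
    len <- seed_len
    while (len < rl &&
           substr(reference, h + len, h + len) == substr(read, len + 1, len + 1) &&
           h + len <= nchar(reference)) {
      len <- len + 1
    }
    if (is.null(best) || len > best[2]) best <- c(h - 1L, len)
  }
  best
}

# longest exact suffix of `read` matching `reference`; returns (0-based ref
# start of the suffix alignment, matched length)
longest_suffix_match <- function(read, reference, seed_len = 20) {
  rl <- nchar(read)
  seed <- substr(read, rl - seed_len + 1, rl)
  if (nchar(seed) < seed_len) return(NULL)
  hits <- gregexpr(seed, reference, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NULL)
  best <- NULL
  for (h in as.integer(hits)) {
    # h is 1-based ref position of the seed start; extend leftwards
    len <- seed_len
    while (len < rl && h - (len - seed_len) > 1 &&
           substr(reference, h - (len - seed_len) - 1, h - (len - seed_len) - 1) ==
           substr(read, rl - len, rl - len)) {
      len <- len + 1
    }
    start0 <- (h - 1L) - (len - seed_len) # 0-based start of matched suffix
    if (is.null(best) || len > best[2]) best <- c(start0, len)
  }
  best
}

#' Refine deletion breakpoints from junction-bridging reads
#'
#' Split-aligns reads that cross the deletion junction against the reference
#' by exact-match seed-and-extend: the longest reference-matching prefix of
#' the read anchors the left breakpoint and the longest matching suffix the
#' right one. When the two alignments overlap inside the read, the overlap
#' length is the breakpoint microhomology (the junction position is then
#' ambiguous by that many bases; the left-most placement is reported, and the
#' deletion *size* is unaffected). The refined call takes the consensus
#' (majority) breakpoints over all usable reads.
#'
#' @param call one deletion call (single row of [merge_evidence()] output, or
#'   any list with `chrom`, `start`, `end`).
#' @param junction_reads character vector of read sequences crossing the
#'   junction (e.g. `sim$junction_reads`).
#' @param reference reference sequence string.
#' @param seed_len exact-match seed length (default 20).
#' @return the call as a one-row `data.frame` with `start`, `end`, `size`
#'   replaced by the refined values, `refined = TRUE` and `microhomology`
#'   set; returned unrefined (with a message) when no read split-aligns on
#'   both sides.
#' @export
refine_breakpoints <- function(call, junction_reads, reference, seed_len = 20) {
  call <- as.data.frame(as.list(call), stringsAsFactors = FALSE)
  votes <- list()
  for (read in junction_reads) {
    pre <- longest_prefix_match(read, reference, seed_len)
    suf <- longest_suffix_match(read, reference, seed_len)
    if (is.null(pre) || is.null(suf)) next
    rl <- nchar(read)
    L1 <- pre[2]; p <- pre[1]
    L2 <- suf[2]; q <- suf[1]
    if (L1 + L2 < rl) next # read does not fully split-align: unusable
    if (q <= p) next       # not a deletion-consistent split
    mh <- L1 + L2 - rl
    # left-most placement: use the minimal prefix consistent with the suffix
    junction_offset <- rl - L2
    del_start <- p + junction_offset
    del_end <- q
    if (del_end <= del_start) next
    votes[[length(votes) + 1L]] <- c(del_start, del_end, mh)
  }
  if (!length(votes)) {
    message("no junction read aligned on both sides; call returned unrefined")
    return(call)
  }
  V <- do.call(rbind, votes)
  key <- paste(V[, 1], V[, 2])
  top <- names(sort(table(key), decreasing = TRUE))[1]
  sel <- which(key == top)[1]
  call$start <- V[sel, 1]
  call$end <- V[sel, 2]
  call$size <- call$end - call$start
  call$refined <- TRUE
  call$microhomology <- as.integer(V[sel, 3])
  call$n_junction_reads <- length(votes)
  call
}
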