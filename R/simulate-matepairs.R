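#' Simulate a long-insert mate-pair library over a deletion
#'
#' Emulates a mate-pair sequencing experiment (circularised 4-4.5 kb
#' fragments, short reads from both fragment ends) over a reference window in
#' which one haplotype may carry a multi-kb deletion. Fragments are sampled
#' uniformly from the *allele* sequence (reference with the deleted segment
#' excised for a D haplotype), then the reads are projected back onto
#' reference coordinates. Consequences baked into the generator:
#'
#' * a fragment whose insert spans the junction on a D haplotype maps with
#'   reference distance `insert + deletion length` (the discordant-pair
#'   signature);
#' * a read that itself crosses the junction carries the concatenated
#'   breakpoint sequence and is emitted in `junction_reads` (it has no single
#'   reference interval);
#' * no read from a D haplotype overlaps the deleted interval, so a
#'   homozygous-deletion (D/D) individual shows a complete coverage dropout
#'   there, while +/+ coverage is uniform and D/+ is halved.
#'
#' The number of pairs is deterministic:
#' `round(coverage * ref_length / (2 * read_length))`.
#'
#' @param ref_length reference window length (bp).
#' @param deletion 0-based half-open deletion interval `c(start, end)` within
#'   the reference, or `NULL` for no deletion.
#' @param genotype deletion genotype of the individual: `"+/+"`, `"D/+"` or
#'   `"D/D"`.
#' @param insert insert-size model: `list(dist = "uniform", low =, high =)`
#'   (default 4000-4500) or `list(dist = "normal", mean =, sd =)`.
#' @param read_length read length in bp (default 76, i.e. 2x76 bp pairs).
#' @param coverage target sequence coverage (x); must be > 0.
#' @param reference optional reference sequence string of length
#'   `ref_length`; generated randomly when omitted.
#' @param chrom chromosome label used in the output tables.
#' @param seed integer seed.
#' @return an object of class `ls_matepairs`: list with
#'   \describe{
#'     \item{pairs}{`data.frame` `pair_id, chrom, pos1, pos2, orientation,
#'       mapped_distance, spans_deletion` — `pos1`/`pos2` are 0-based leftmost
#'       reference coordinates of the two reads (junction-crossing reads are
#'       anchored at their left segment), `mapped_distance` is the outer
#'       distance `pos2 + read_length - pos1`.}
#'     \item{depth}{`data.frame` `pos` (0-based), `depth` per reference base.}
#'     \item{junction_reads}{character vector of read sequences crossing the
#'       breakpoint.}
#'     \item{reference}{the reference sequence string.}
#'     \item{config}{the simulation settings, including the planted deletion.}
#'   }
#' @examples
#' mp <- simulate_matepairs(6e4, deletion = c(30000, 33329), genotype = "D/D",
#'                          coverage = 10, seed = 3)
#' mean(mp$pairs$mapped_distance[mp$pairs$spans_deletion])
#' @export
simulate_matepairs <- function(ref_length, deletion = NULL,
                               genotype = c("+/+", "D/+", "D/D"),
                               insert = list(dist = "uniform", low = 4000, high = 4500),
                               read_length = 76, coverage = 1.7,
                               reference = NULL, chrom = "21", seed = NULL) {
  genotype <- match.arg(genotype)
  ref_length <- as.integer(ref_length)
  if (coverage <= 0) stop("coverage must be > 0")
  mean_insert <- switch(insert$dist,
                        uniform = (insert$low + insert$high) / 2,
                        normal = insert$mean,
                        stop("insert$dist must be 'uniform' or 'normal'"))
  max_insert <- switch(insert$dist, uniform = insert$high,
                       normal = insert$mean + 6 * insert$sd)
  if (mean_insert <= 2 * read_length) stop("insert must exceed 2 * read_length")
  del_len <- 0L
  if (!is.null(deletion)) {
    deletion <- as.integer(deletion)
    if (deletion[1] < 0 || deletion[2] > ref_length || deletion[2] <= deletion[1]) {
      stop("deletion interval must be a non-empty 0-based half-open interval ",
           "inside the reference")
    }
    del_len <- deletion[2] - deletion[1]
  }
  with_seed(seed, {
    if (is.null(reference)) reference <- random_dna(ref_length)
    stopifnot(nchar(reference) == ref_length)

    n_pairs <- round(coverage * ref_length / (2 * read_length))
    if (n_pairs < 1) stop("coverage too low: no pairs to simulate")

    # haplotype of origin per fragment: TRUE = deleted allele
    from_del <- switch(genotype,
                       "+/+" = rep(FALSE, n_pairs),
                       "D/D" = rep(!is.null(deletion), n_pairs),
                       "D/+" = if (is.null(deletion)) rep(FALSE, n_pairs) else
                         runif(n_pairs) < 0.5)

    ins <- switch(insert$dist,
                  uniform = floor(runif(n_pairs, insert$low, insert$high + 1)),
                  normal = pmax(2 * read_length + 1,
                                round(rnorm(n_pairs, insert$mean, insert$sd))))
    allele_len <- ifelse(from_del, ref_length - del_len, ref_length)
    # fragment start on the allele sequence (0-based)
    start <- floor(runif(n_pairs) * pmax(1, allele_len - ins + 1))
    ok <- start + ins <= allele_len
    start <- start[ok]; ins <- ins[ok]; from_del <- from_del[ok]
    np <- length(start)

    # allele -> reference coordinate projection for the deleted allele
    proj <- function(p, is_del) ifelse(is_del & p >= deletion[1], p + del_len, p)
    r1_start <- start
    r2_start <- start + ins - read_length
    if (del_len > 0) {
      r1_ref <- proj(r1_start, from_del)
      r2_ref <- proj(r2_start, from_del)
      r1_cross <- from_del & r1_start < deletion[1] & r1_start + read_length > deletion[1]
      r2_cross <- from_del & r2_start < deletion[1] & r2_start + read_length > deletion[1]
      # a junction-crossing read is anchored at its left segment
      r1_ref[r1_cross] <- r1_start[r1_cross]
      r2_ref[r2_cross] <- r2_start[r2_cross]
      # discordant signature: both reads map cleanly on opposite sides, so
      # the pair's reference distance is insert + deletion length exactly;
      # reads that themselves cross the junction become junction_reads and
      # their pair keeps an ordinary left-anchored distance
      spans <- from_del & r1_start + read_length <= deletion[1] &
        r2_start >= deletion[1]
    } else {
      r1_ref <- r1_start; r2_ref <- r2_start
      r1_cross <- r2_cross <- spans <- rep(FALSE, np)
    }
    mapped_distance <- r2_ref + read_length - r1_ref

    pairs <- data.frame(pair_id = sprintf("mp%06d", seq_len(np)),
                        chrom = chrom,
                        pos1 = r1_ref, pos2 = r2_ref,
                        orientation = "FR",
                        mapped_distance = mapped_distance,
                        spans_deletion = spans,
                        stringsAsFactors = FALSE)

    # per-base depth on the reference; junction-crossing reads contribute to
    # both flanks of the breakpoint
    cover <- numeric(ref_length + 1L)
    add_iv <- function(s, e) { # 0-based half-open, vectors
      s <- pmax(s, 0L); e <- pmin(e, ref_length)
      keep <- e > s
      s <- s[keep]; e <- e[keep]
      if (!length(s)) return(invisible())
      cover <<- cover + tabulate(s + 1L, ref_length + 1L) -
        tabulate(e + 1L, ref_length + 1L)
    }
    add_crossing <- function(rs) {
      # rs: allele-space starts of junction-crossing reads; the read splits
      # into [rs, del_start) and [del_end, del_end + remaining) on the ref
      left_len <- deletion[1] - rs
      add_iv(rs, rs + left_len)
      add_iv(rep(deletion[2], length(rs)),
             deletion[2] + (read_length - left_len))
    }
    if (del_len > 0) {
      plain1 <- !r1_cross; plain2 <- !r2_cross
      add_iv(r1_ref[plain1], r1_ref[plain1] + read_length)
      add_iv(r2_ref[plain2], r2_ref[plain2] + read_length)
      if (any(r1_cross)) add_crossing(r1_start[r1_cross])
      if (any(r2_cross)) add_crossing(r2_start[r2_cross])
    } else {
      add_iv(c(r1_ref, r2_ref), c(r1_ref, r2_ref) + read_length)
    }
    depth <- cumsum(cover[seq_len(ref_length)])

    # junction-crossing read sequences: concatenated breakpoint sequence
    junction_reads <- character()
    if (del_len > 0) {
      cross_starts <- c(r1_start[r1_cross], r2_start[r2_cross])
      if (length(cross_starts)) {
        junction_reads <- vapply(cross_starts, function(s) {
          left <- substr(reference, s + 1L, deletion[1])
          right <- substr(reference, deletion[2] + 1L,
                          deletion[2] + read_length - nchar(left))
          paste0(left, right)
        }, "")
      }
    }

    structure(list(pairs = pairs,
                   depth = data.frame(pos = seq_len(ref_length) - 1L,
                                      depth = depth),
                   junction_reads = junction_reads,
                   reference = reference,
                   config = list(ref_length = ref_length, deletion = deletion,
                                 genotype = genotype, insert = insert,
                                 read_length = read_length,
                                 coverage = coverage, chrom = chrom,
                                 n_pairs = n_pairs)),
              class = "ls_matepairs")
  })
}

#' @export
print.ls_matepairs <- function(x, ...) {
  cat("Simulated mate pairs:", nrow(x$pairs), "pairs,",
      x$config$genotype, "individual,",
      length(x$junction_reads), "junction-crossing reads\n")
  invisible(x)
}
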