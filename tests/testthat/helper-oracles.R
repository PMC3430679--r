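# Independent oracles and small builders used across the suite. Everything
# here is deliberately brute-force / hand-rolled so it shares no code with
# the implementation it checks.

# brute force: maximal interval around marker k where all case rows are
# homozygous and identical; NULL if none. G: cases x markers of one chromosome.
oracle_shared_segment <- function(G, k) {
  ok <- function(j) {
    col <- G[, j]
    !any(is.na(col)) && all(col %in% c(0L, 2L)) && length(unique(col)) == 1L
  }
  if (!ok(k)) return(NULL)
  best <- NULL
  for (a in seq_len(k)) {
    for (b in k:ncol(G)) {
      if (all(vapply(a:b, ok, logical(1)))) {
        if (is.null(best) || (b - a) > (best[2] - best[1])) best <- c(a, b)
      }
    }
  }
  best
}

# brute force ROH: all maximal sub-intervals with <= max_het hets, no NA,
# >= min_markers markers; returns matrix of (start, end) 1-based inclusive
oracle_roh <- function(g, min_markers, max_het) {
  n <- length(g)
  feasible <- function(a, b) {
    seg <- g[a:b]
    !any(is.na(seg)) && sum(seg == 1L) <= max_het
  }
  out <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (b - a + 1 < min_markers) next
      if (!feasible(a, b)) next
      left_ext <- a > 1 && feasible(a - 1, b)
      right_ext <- b < n && feasible(a, b + 1)
      if (!left_ext && !right_ext) out[[length(out) + 1]] <- c(a, b)
    }
  }
  if (!length(out)) return(matrix(numeric(), ncol = 2))
  unique(do.call(rbind, out))
}

# hand-rolled Wilson score interval
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# hand-rolled 2x2 chi-square without continuity correction
oracle_chisq2x2 <- function(a, b, c_, d) {
  N <- a + b + c_ + d
  N * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# hand-rolled codon-table translation (independent of Biostrings)
oracle_translate <- function(nt) {
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  tab <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    tab[k] <- paste0(b1, b2, b3)
  }
  names(aas) <- tab
  n <- nchar(nt) %/% 3
  paste(vapply(seq_len(n), function(i) {
    aas[[substr(nt, 3 * i - 2, 3 * i)]]
  }, ""), collapse = "")
}

# synthetic gene: builds a genomic sequence from explicit exon sequences
# separated by random introns; CDS given in transcript coordinates.
# Returns list(model, genome, exon_seqs).
make_gene <- function(exon_seqs, cds_start, cds_end, intron_len = 50,
                      pad = 30, chrom = "geneA") {
  introns <- replicate(length(exon_seqs) - 1,
                       paste(sample(c("A", "C", "G", "T"), intron_len,
                                    replace = TRUE), collapse = ""))
  genome <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                  collapse = "")
  exons <- matrix(0, length(exon_seqs), 2)
  for (i in seq_along(exon_seqs)) {
    exons[i, 1] <- nchar(genome)
    genome <- paste0(genome, exon_seqs[i])
    exons[i, 2] <- nchar(genome)
    if (i < length(exon_seqs)) genome <- paste0(genome, introns[i])
  }
  genome <- paste0(genome,
                   paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                         collapse = ""))
  list(model = gene_model(chrom, "+", exons, cds_start, cds_end),
       genome = genome, exon_seqs = exon_seqs)
}

# random CDS of n_codons (ATG ... TAA, no internal stop)
random_cds <- function(n_codons) {
  safe <- c("GCT", "TGC", "GAT", "GAA", "TTT", "GGG", "CAC", "ATT",
            "AAA", "CTT", "ATG", "AAT", "CCC", "CAA", "CGT", "TCT",
            "ACT", "GTT", "TGG", "TAC")
  paste0("ATG", paste(sample(safe, n_codons - 2, replace = TRUE),
                      collapse = ""), "TAA")
}
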