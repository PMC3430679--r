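#' Build a SNP marker map
#'
#' A marker map is the positional scaffold for genotype simulation and
#' autozygosity scanning: one row per biallelic SNP with chromosome, physical
#' position, identifier and reference/alternate alleles, emulating a
#' medium-density (50K-style) array.
#'
#' @param chrom chromosome label(s), recycled against `n_markers`.
#' @param n_markers number of markers per chromosome (integer vector parallel
#'   to `chrom`).
#' @param length_bp chromosome length(s) in bp; positions are drawn uniformly
#'   and sorted, or spaced evenly when `spacing = "even"`.
#' @param spacing `"random"` (default) or `"even"`.
#' @param seed optional integer seed for the random positions and alleles.
#' @return a `data.frame` with columns `chrom`, `pos` (1-based bp, strictly
#'   increasing within chromosome), `id`, `ref`, `alt`.
#' @examples
#' map <- marker_map("21", n_markers = 50, length_bp = 5e6, seed = 1)
#' head(map)
#' @export
marker_map <- function(chrom, n_markers, length_bp, spacing = c("random", "even"),
                       seed = NULL) {
  spacing <- match.arg(spacing)
  stopifnot(length(n_markers) %in% c(1L, length(chrom)),
            length(length_bp) %in% c(1L, length(chrom)))
  n_markers <- rep_len(as.integer(n_markers), length(chrom))
  length_bp <- rep_len(as.numeric(length_bp), length(chrom))
  if (any(n_markers < 2L)) stop("each chromosome needs >= 2 markers")
  with_seed(seed, {
    pieces <- lapply(seq_along(chrom), function(i) {
      n <- n_markers[i]
      pos <- if (spacing == "even") {
        round(seq(1, length_bp[i], length.out = n))
      } else {
        sort(sample.int(length_bp[i], n))
      }
      alleles <- c("A", "C", "G", "T")
      ref <- sample(alleles, n, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
      data.frame(chrom = as.character(chrom[i]), pos = as.numeric(pos),
                 id = sprintf("%s_%d", chrom[i], pos),
                 ref = ref, alt = unname(alt),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    map <- do.call(rbind, pieces)
    validate_marker_map(map)
    map
  })
}

validate_marker_map <- function(map) {
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(map))) {
    stop("marker map must have columns ", paste(need, collapse = ", "))
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (length(p) < 2L) stop("chromosome ", ch, " has < 2 markers")
    if (any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing on chromosome ", ch)
    }
  }
  invisible(map)
}

# indices of map rows falling inside a 1-based closed bp interval
markers_in_interval <- function(map, chrom, start_bp, end_bp) {
  which(map$chrom == as.character(chrom) & map$pos >= start_bp & map$pos <= end_bp)
}
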