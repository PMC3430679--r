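#' Construct a gene model
#'
#' A minimal exon/CDS gene model tied to a genomic sequence window. Exons are
#' 0-based half-open genomic intervals, non-overlapping and sorted in
#' transcript orientation (ascending for `+`, descending for `-`); the CDS is
#' given in transcript coordinates (1-based, inclusive) and its length must
#' be a multiple of 3 (start codon through stop codon).
#'
#' @param chrom chromosome label.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix (start, end) of 0-based half-open genomic
#'   exon intervals, one row per exon, in transcript order.
#' @param cds_start,cds_end CDS boundaries in transcript coordinates
#'   (1-based, inclusive of the stop codon).
#' @return list of class `ls_gene_model`.
#' @export
gene_model <- function(chrom, strand = "+", exons, cds_start, cds_end) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  if (any(exons[, 2] <= exons[, 1])) stop("empty exon interval")
  gstart <- exons[, 1][order(exons[, 1])]
  gend <- exons[, 2][order(exons[, 1])]
  if (any(utils::head(gend, -1) > utils::tail(gstart, -1))) {
    stop("exons overlap")
  }
  ord <- order(exons[, 1])
  if (strand == "+" && !identical(ord, seq_len(nrow(exons)))) {
    stop("exons must be sorted 5'->3' in transcript orientation")
  }
  if (strand == "-" && !identical(ord, rev(seq_len(nrow(exons))))) {
    stop("exons must be sorted 5'->3' in transcript orientation")
  }
  tlen <- sum(exons[, 2] - exons[, 1])
  stopifnot(cds_start >= 1, cds_end <= tlen, cds_end > cds_start)
  if ((cds_end - cds_start + 1) %% 3 != 0) {
    stop("CDS length must be divisible by 3")
  }
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "ls_gene_model")
}

exon_lengths <- function(model) model$exons[, 2] - model$exons[, 1]

transcript_length <- function(model) sum(exon_lengths(model))

# transcript sequence from a genomic sequence string covering the window
transcript_seq <- function(model, genome) {
  pieces <- apply(model$exons, 1, function(e) {
    substr(genome, e[1] + 1, e[2])
  })
  tx <- paste(pieces, collapse = "")
  if (model$strand == "-") tx <- revcomp(tx)
  tx
}

# 1-based transcript coordinate of a genomic position (0-based) lying in an
# exon; NA if intronic
genomic_to_transcript <- function(model, gpos) {
  offset <- 0
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    if (gpos >= e[1] && gpos < e[2]) {
      within <- if (model$strand == "+") gpos - e[1] else e[2] - 1 - gpos
      return(offset + within + 1)
    }
    offset <- offset + (e[2] - e[1])
  }
  NA_real_
}

#' Apply a genomic deletion to a gene model
#'
#' Removes exons fully contained in the deletion, juxtaposing their
#' neighbours in the mutant transcript. Deletions that split an exon
#' (partial-exon overlap) are rejected: the whole-exon case is the one this
#' operation models, and guessing a truncated exon's splicing behaviour would
#' be speculation. Genomic coordinates of the remaining exons are left
#' untouched (the transcript, the concatenation of exon sequences, is what
#' changes). The CDS is trimmed by the deleted coding length so downstream
#' translation sees the correct mutant CDS window.
#'
#' @param model an [gene_model()].
#' @param deletion 0-based half-open genomic interval `c(start, end)`.
#' @return the mutant `ls_gene_model`, with attributes
#'   `deleted_exons` (indices into the wild-type exon list) and
#'   `deleted_coding_length` (bp of CDS removed).
#' @export
apply_deletion <- function(model, deletion) {
  stopifnot(inherits(model, "ls_gene_model"))
  deletion <- as.numeric(deletion)
  if (deletion[2] < deletion[1]) stop("deletion end before start")
  if (deletion[2] == deletion[1]) { # zero-length: identity
    mut <- model
    attr(mut, "deleted_exons") <- integer()
    attr(mut, "deleted_coding_length") <- 0
    return(mut)
  }
  ex <- model$exons
  full <- ex[, 1] >= deletion[1] & ex[, 2] <= deletion[2]
  partial <- !full & ex[, 1] < deletion[2] & ex[, 2] > deletion[1]
  if (any(partial)) {
    stop("unsupported case: deletion splits exon(s) ",
         paste(which(partial), collapse = ", "))
  }
  if (!any(full)) { # entirely intronic/intergenic: transcript unchanged
    mut <- model
    attr(mut, "deleted_exons") <- integer()
    attr(mut, "deleted_coding_length") <- 0
    return(mut)
  }
  # deleted coding length: overlap of deleted exons with the CDS in
  # transcript coordinates
  lens <- exon_lengths(model)
  tx_end <- cumsum(lens)
  tx_start <- tx_end - lens + 1
  del_cds <- sum(vapply(which(full), function(i) {
    max(0, min(tx_end[i], model$cds_end) - max(tx_start[i], model$cds_start) + 1)
  }, numeric(1)))
  del_before_cds <- sum(vapply(which(full), function(i) {
    max(0, min(tx_end[i], model$cds_start - 1) - tx_start[i] + 1)
  }, numeric(1)))

  mut_exons <- ex[!full, , drop = FALSE]
  if (nrow(mut_exons) == 0) stop("deletion removes the whole transcript")
  mut <- structure(list(chrom = model$chrom, strand = model$strand,
                        exons = mut_exons,
                        cds_start = model$cds_start - del_before_cds,
                        cds_end = model$cds_end - del_before_cds - del_cds),
                   class = "ls_gene_model")
  attr(mut, "deleted_exons") <- which(full)
  attr(mut, "deleted_coding_length") <- del_cds
  mut
}

translate_dna <- function(nt) {
  if (nchar(nt) < 3) return("")
  nt <- substr(nt, 1, 3 * (nchar(nt) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

#' Protein-level effect of an exon deletion
#'
#' Translates the wild-type and mutant coding sequences and reports the
#' consequence: in-frame exon loss (deleted coding length divisible by 3) or
#' frameshift, the first divergent codon, the length of the illegitimate
#' novel peptide read in the shifted frame up to its stop codon, the number
#' of wild-type C-terminal residues lost, the mutant-transcript position and
#' exon of the premature termination codon, and whether nonsense-mediated
#' decay is predicted ([predict_nmd()]).
#'
#' @param model wild-type [gene_model()].
#' @param mutant mutant model from [apply_deletion()].
#' @param genome genomic sequence string underlying both models.
#' @return list of class `ls_transcript_effect`: `deleted_exons`,
#'   `deleted_coding_length`, `in_frame`, `frameshift_position` (first
#'   divergent codon, NA if in frame or no divergence),
#'   `novel_peptide_length`, `truncated_residues`, `wt_protein_length`,
#'   `ptc_tx_pos` (1-based mutant-transcript coordinate of the stop codon's
#'   first base, NA when the mutant reads through), `ptc_exon` (index in the
#'   mutant model), `nmd_predicted`, plus the two protein sequences.
#' @export
protein_effect <- function(model, mutant, genome) {
  wt_tx <- transcript_seq(model, genome)
  mut_tx <- transcript_seq(mutant, genome)
  wt_cds <- substr(wt_tx, model$cds_start, model$cds_end)
  wt_prot <- translate_dna(wt_cds)
  if (substr(wt_cds, 1, 3) != "ATG") stop("model invalid: CDS lacks ATG start")
  wt_aa <- sub("\\*$", "", wt_prot)
  if (grepl("\\*", wt_aa)) stop("model invalid: internal stop in wild-type CDS")

  del_cds <- attr(mutant, "deleted_coding_length") %||% 0
  in_frame <- del_cds %% 3 == 0

  # mutant CDS: from the (unchanged) start codon to the first stop or the
  # transcript end
  mut_from_start <- substr(mut_tx, mutant$cds_start, nchar(mut_tx))
  mut_prot_full <- translate_dna(mut_from_start)
  stop_at <- regexpr("*", mut_prot_full, fixed = TRUE)
  mut_aa <- if (stop_at > 0) substr(mut_prot_full, 1, stop_at - 1) else mut_prot_full

  # first divergent residue
  nmin <- min(nchar(wt_aa), nchar(mut_aa))
  div <- NA_real_
  if (nmin > 0) {
    wt_v <- strsplit(substr(wt_aa, 1, nmin), "")[[1]]
    mu_v <- strsplit(substr(mut_aa, 1, nmin), "")[[1]]
    neq <- which(wt_v != mu_v)
    if (length(neq)) div <- neq[1]
  }
  if (is.na(div) && nchar(mut_aa) != nchar(wt_aa)) div <- nmin + 1

  novel_len <- if (is.na(div)) 0 else max(0, nchar(mut_aa) - (div - 1))
  truncated <- if (is.na(div)) 0 else nchar(wt_aa) - (div - 1)

  ptc_tx_pos <- if (stop_at > 0) {
    mutant$cds_start + 3 * (stop_at - 1)
  } else NA_real_
  ptc_exon <- NA_integer_
  nmd <- FALSE
  if (!is.na(ptc_tx_pos)) {
    lens <- exon_lengths(mutant)
    tx_end <- cumsum(lens)
    ptc_exon <- which(ptc_tx_pos <= tx_end)[1]
    nmd <- predict_nmd(mutant, ptc_tx_pos)
  }

  structure(list(deleted_exons = attr(mutant, "deleted_exons"),
                 deleted_coding_length = del_cds,
                 in_frame = in_frame,
                 frameshift_position = if (in_frame) NA_real_ else div,
                 novel_peptide_length = if (in_frame) 0 else novel_len,
                 truncated_residues = truncated,
                 wt_protein_length = nchar(wt_aa),
                 mut_protein_length = nchar(mut_aa),
                 ptc_tx_pos = ptc_tx_pos, ptc_exon = ptc_exon,
                 nmd_predicted = nmd,
                 wt_protein = wt_aa, mut_protein = mut_aa),
            class = "ls_transcript_effect")
}

#' @export
print.ls_transcript_effect <- function(x, ...) {
  cat("Transcript effect: exons", paste(x$deleted_exons, collapse = ","),
      "deleted (", x$deleted_coding_length, "coding bp )\n")
  if (x$in_frame) {
    cat("  in-frame exon loss\n")
  } else {
    cat(sprintf("  frameshift at aa %d: %d C-terminal residues replaced by a %d-residue novel peptide\n",
                x$frameshift_position, x$truncated_residues,
                x$novel_peptide_length))
  }
  cat("  NMD predicted:", x$nmd_predicted, "\n")
  invisible(x)
}

#' Nonsense-mediated decay prediction (50-nt rule)
#'
#' A premature termination codon triggers NMD when it lies at least
#' `boundary_nt` nucleotides (default 50, boundary inclusive; 55 is the
#' common alternative) upstream of the final exon-exon junction of the
#' mutant transcript. A PTC in the last exon, or any PTC in a single-exon
#' transcript, escapes.
#'
#' @param mutant mutant `ls_gene_model`.
#' @param ptc_tx_pos 1-based transcript position of the first base of the
#'   termination codon.
#' @param boundary_nt rule boundary (default 50).
#' @return logical flag.
#' @export
predict_nmd <- function(mutant, ptc_tx_pos, boundary_nt = 50) {
  lens <- exon_lengths(mutant)
  if (length(lens) < 2) return(FALSE)
  tlen <- sum(lens)
  if (ptc_tx_pos < 1 || ptc_tx_pos > tlen) stop("PTC outside mutant transcript")
  last_junction <- tlen - lens[length(lens)] # nt upstream of final junction
  (last_junction - ptc_tx_pos) >= boundary_nt
}

match_once <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(NA_integer_)
  if (length(hits) > 1) stop("ambiguity error: primer matches multiply")
  as.integer(hits[1])
}

#' Predict PCR amplicons on wild-type and mutant templates
#'
#' Exact-match PCR logic: the forward primer must occur once on the template
#' plus strand and the reverse primer once on the minus strand (i.e. its
#' reverse complement once on the template). The product size is the
#' distance between the two primers' 5' ends, inclusive. No product is
#' reported when either site is absent or the span exceeds `max_amplicon`
#' (polymerase reach on genomic DNA); a primer matching more than once
#' raises an ambiguity error.
#'
#' @param forward,reverse primer sequences (5'->3'; the reverse primer is
#'   given as its own 5'->3' sequence, as synthesised).
#' @param templates named character vector/list of template sequences (e.g.
#'   `c(wt = ..., mut = ...)`).
#' @param max_amplicon maximum product size (default 5000).
#' @return `data.frame` with one row per template: `template`, `product_size`
#'   (NA = no product), `fwd_pos`, `rev_pos` (1-based 5'-end positions).
#' @export
predict_amplicons <- function(forward, reverse, templates, max_amplicon = 5000) {
  rc <- revcomp(reverse)
  out <- lapply(names(templates) %||% seq_along(templates), function(nm) {
    tpl <- templates[[nm]]
    f <- match_once(forward, tpl)
    r <- match_once(rc, tpl)
    size <- NA_real_
    rev5 <- NA_integer_
    if (!is.na(f) && !is.na(r)) {
      rev5 <- r + nchar(reverse) - 1L # 5' end of the reverse primer
      if (rev5 >= f) {
        size <- rev5 - f + 1
        if (size > max_amplicon) size <- NA_real_
      }
    }
    data.frame(template = as.character(nm), product_size = size,
               fwd_pos = f, rev_pos = rev5, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Triage candidate causative variants
#'
#' Removes variants exactly matching a set of known polymorphisms (same
#' chromosome, position, ref and alt — previously reported variation is
#' unlikely to cause a breed-specific recessive lethal), annotates the
#' remainder as coding or non-coding against gene-model CDS exons, and by
#' default retains only the coding ones.
#'
#' @param variants `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param known_variants `data.frame` with the same columns (may be empty).
#' @param gene_models list of [gene_model()] objects.
#' @param coding_only drop non-coding novel variants (default `TRUE`).
#' @return the retained variants with added columns `known` (all `FALSE` in
#'   the retained set) and `coding`.
#' @export
filter_candidate_variants <- function(variants, known_variants, gene_models,
                                      coding_only = TRUE) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  known <- if (nrow(known_variants)) key(variants) %in% key(known_variants)
           else rep(FALSE, nrow(variants))
  out <- variants[!known, , drop = FALSE]
  if (!nrow(out)) {
    out$coding <- logical(0)
    return(out)
  }
  coding <- vapply(seq_len(nrow(out)), function(i) {
    g0 <- out$pos[i] - 1 # 0-based
    any(vapply(gene_models, function(m) {
      if (m$chrom != out$chrom[i]) return(FALSE)
      tpos <- genomic_to_transcript(m, g0)
      !is.na(tpos) && tpos >= m$cds_start && tpos <= m$cds_end
    }, logical(1)))
  }, logical(1))
  out$coding <- coding
  if (coding_only) out <- out[out$coding, , drop = FALSE]
  rownames(out) <- NULL
  out
}
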