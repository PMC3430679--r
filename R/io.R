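#' Write simulated genotypes to VCF
#'
#' Minimal VCFv4.2 writer for the simulated genotype matrix: one biallelic
#' SNP record per marker with GT-only sample columns. Case genotypes are
#' written unphased (`0/1` style) from dosages; control genotypes are written
#' phased (`0|1`) from the stored truth haplotypes, so the phase the mapping
#' step requires survives a round trip.
#'
#' @param sim an `ls_genotypes` object.
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(sim, path) {
  map <- sim$map
  n_cases <- length(sim$case_ids)
  n_ctrl <- length(sim$control_ids)
  gt_case <- matrix("0/0", n_cases, nrow(map))
  if (n_cases) {
    d <- sim$geno[sim$case_ids, , drop = FALSE]
    gt_case <- matrix(c("0/0", "0/1", "1/1")[d + 1L], n_cases, nrow(map))
  }
  gt_ctrl <- NULL
  if (n_ctrl) {
    h1 <- sim$control_haplotypes[seq(1, 2 * n_ctrl, 2), , drop = FALSE]
    h2 <- sim$control_haplotypes[seq(2, 2 * n_ctrl, 2), , drop = FALSE]
    gt_ctrl <- matrix(paste0(h1, "|", h2), n_ctrl, nrow(map))
  }
  gt <- rbind(gt_case, gt_ctrl)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lethalscan",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sim$case_ids, sim$control_ids),
                 collapse = "\t"))
  body <- vapply(seq_len(nrow(map)), function(i) {
    paste(c(map$chrom[i], map$pos[i], map$id[i], map$ref[i], map$alt[i],
            ".", "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype VCF into the matrix form the mapping step uses
#'
#' Reads a (possibly lethalscan-written) GT-only VCF with `vcfR` and returns
#' the dosage matrix, marker map, and — for samples with phased genotypes —
#' the haplotype matrix.
#'
#' @param path VCF file.
#' @param case_ids,control_ids sample ids assigning roles; defaults infer
#'   cases as samples whose id starts with `"case"`.
#' @return an `ls_genotypes`-classed list (without planted-truth fields).
#' @export
read_genotypes_vcf <- function(path, case_ids = NULL, control_ids = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  map <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    id = fix$ID, ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  case_ids <- case_ids %||% samples[startsWith(samples, "case")]
  control_ids <- control_ids %||% setdiff(samples, case_ids)
  alleles <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(p) sum(as.integer(p)), numeric(1))
  }
  geno <- t(apply(gt, 2, alleles))
  rownames(geno) <- samples
  colnames(geno) <- map$id
  haps <- NULL
  if (length(control_ids)) {
    phased <- gt[, control_ids, drop = FALSE]
    h1 <- apply(phased, 2, function(x) as.integer(sub("\\|.*", "", x)))
    h2 <- apply(phased, 2, function(x) as.integer(sub(".*\\|", "", x)))
    haps <- matrix(0L, 2 * length(control_ids), nrow(map))
    haps[seq(1, nrow(haps), 2), ] <- t(h1)
    haps[seq(2, nrow(haps), 2), ] <- t(h2)
    rownames(haps) <- paste0(rep(control_ids, each = 2), c("_h1", "_h2"))
  }
  structure(list(geno = geno, map = map, case_ids = case_ids,
                 control_ids = control_ids, control_haplotypes = haps),
            class = "ls_genotypes")
}

#' Write genotypes as PED/MAP
#'
#' PLINK-dialect text pair: `.map` with chromosome, marker id, 0 cM, bp
#' position; `.ped` with family/individual ids, zeroed parents/sex, affection
#' status (2 = case, 1 = control) and two allele columns per marker.
#'
#' @param sim an `ls_genotypes` object.
#' @param prefix output path prefix (writes `prefix.ped`, `prefix.map`).
#' @return the two paths, invisibly.
#' @export
write_ped_map <- function(sim, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map <- sim$map
  utils::write.table(data.frame(map$chrom, map$id, 0, map$pos),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ids <- c(sim$case_ids, sim$control_ids)
  status <- c(rep(2, length(sim$case_ids)), rep(1, length(sim$control_ids)))
  lines <- vapply(seq_along(ids), function(i) {
    d <- sim$geno[ids[i], ]
    a1 <- ifelse(d >= 1, map$alt, map$ref)
    a2 <- ifelse(d == 2, map$alt, map$ref)
    paste(c("FAM", ids[i], 0, 0, 0, status[i], rbind(a1, a2)), collapse = " ")
  }, "")
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write a BED file (0-based half-open)
#' @param bed `data.frame` with `chrom`, `start`, `end` and optional further
#'   columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(bed, path) {
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write symbolic-deletion calls as VCF
#'
#' One `<DEL>` record per call, 1-based POS with `END`/`SVLEN` INFO keys and
#' the evidence tier and discordant-pair support as INFO.
#'
#' @param calls call `data.frame` from [merge_evidence()] /
#'   [refine_breakpoints()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lethalscan",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=TIER,Number=1,Type=Integer,Description=\"Evidence tier\">",
           "##INFO=<ID=PAIRS,Number=1,Type=Integer,Description=\"Discordant pairs\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO"), collapse = "\t"))
  body <- if (nrow(calls)) {
    vapply(seq_len(nrow(calls)), function(i) {
      paste(c(calls$chrom[i], calls$start[i] + 1, sprintf("del%02d", i),
              "N", "<DEL>", ".", "PASS",
              sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d;TIER=%d;PAIRS=%d",
                      as.integer(calls$end[i]), as.integer(calls$size[i]),
                      as.integer(calls$tier[i]),
                      as.integer(calls$n_discordant_pairs[i]))),
            collapse = "\t")
    }, "")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname lethalscan_tsv
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plain TSV read/write used for mate-pair, depth and mating tables
#'
#' @param df data.frame to write.
#' @param path file path.
#' @name lethalscan_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
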