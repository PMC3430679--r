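test_that("gene models validate exon ordering and CDS frame", {
  exons <- rbind(c(0, 100), c(150, 250), c(300, 400))
  m <- gene_model("g", "+", exons, cds_start = 10, cds_end = 249)
  expect_s3_class(m, "ls_gene_model")
  expect_error(gene_model("g", "+", rbind(c(0, 100), c(50, 150)), 1, 90),
               "overlap")
  expect_error(gene_model("g", "+", exons, 10, 248), "divisible")
  expect_error(gene_model("g", "-", exons, 10, 249), "orientation")
})

test_that("whole-exon deletions juxtapose neighbours; partial deletions are rejected", {
  exons <- cbind(seq(0, 900, by = 100), seq(60, 960, by = 100))
  m <- gene_model("g", "+", exons, cds_start = 1, cds_end = 600)
  # exons 5-6 (rows) removed -> 8 exons, neighbours adjacent in transcript
  mut <- apply_deletion(m, c(395, 575))
  expect_equal(nrow(mut$exons), 8)
  expect_equal(attr(mut, "deleted_exons"), c(5L, 6L))
  expect_error(apply_deletion(m, c(395, 420)), "splits")
  # intronic deletion leaves the transcript sequence identical
  set.seed(71)
  genome <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                  collapse = "")
  mut_i <- apply_deletion(m, c(62, 98))
  expect_equal(lethalscan:::transcript_seq(mut_i, genome),
               lethalscan:::transcript_seq(m, genome))
  # zero-length deletion is the identity
  mut_0 <- apply_deletion(m, c(500, 500))
  expect_equal(mut_0$exons, m$exons)
  expect_equal(attr(mut_0, "deleted_coding_length"), 0)
  # 37-exon model, exons 25-27 deleted -> 34 exons with 24/28 juxtaposed
  big <- cbind(seq(0, by = 200, length.out = 37),
               seq(120, by = 200, length.out = 37))
  gm37 <- gene_model("g", "+", big, cds_start = 1, cds_end = 37 * 120)
  del <- c(big[25, 1] - 10, big[27, 2] + 10)
  mut37 <- apply_deletion(gm37, del)
  expect_equal(nrow(mut37$exons), 34)
  expect_equal(attr(mut37, "deleted_exons"), 25:27)
  expect_equal(mut37$exons[24, 2], big[24, 2])
  expect_equal(mut37$exons[25, 1], big[28, 1])
})

test_that("frameshift flag equals deleted-coding-length mod 3 against a translation oracle", {
  set.seed(81)
  for (rep in 1:25) {
    n_ex <- sample(4:8, 1)
    # exon lengths: random, total CDS plus UTRs
    ex_lens <- sample(seq(30, 150, by = 3), n_ex, replace = TRUE) +
      sample(0:2, n_ex, replace = TRUE)
    utr5 <- sample(5:20, 1)
    tlen <- sum(ex_lens)
    cds_len <- 3 * ((tlen - utr5 - sample(3:15, 1)) %/% 3)
    if (cds_len < 60) next
    cds <- random_cds(cds_len / 3)
    tx <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                       collapse = ""),
                 cds,
                 paste(sample(c("A", "C", "G", "T"),
                              tlen - utr5 - cds_len, replace = TRUE),
                       collapse = ""))
    exon_seqs <- character(n_ex)
    off <- 0
    for (i in seq_len(n_ex)) {
      exon_seqs[i] <- substr(tx, off + 1, off + ex_lens[i])
      off <- off + ex_lens[i]
    }
    g <- make_gene(exon_seqs, cds_start = utr5 + 1, cds_end = utr5 + cds_len)
    # delete an internal exon block
    i0 <- sample(2:(n_ex - 1), 1)
    i1 <- min(n_ex - 1, i0 + sample(0:1, 1))
    del <- c(g$model$exons[i0, 1] - 2, g$model$exons[i1, 2] + 2)
    mut <- apply_deletion(g$model, del)
    eff <- protein_effect(g$model, mut, g$genome)
    # oracle: deleted coding length by direct interval arithmetic
    tx_end <- cumsum(ex_lens)
    tx_start <- tx_end - ex_lens + 1
    del_cds_oracle <- sum(pmax(0, pmin(tx_end[i0:i1], utr5 + cds_len) -
                                  pmax(tx_start[i0:i1], utr5 + 1) + 1))
    expect_equal(eff$deleted_coding_length, del_cds_oracle)
    expect_equal(eff$in_frame, del_cds_oracle %% 3 == 0)
    # oracle translation of the wild-type CDS agrees
    expect_equal(paste0(eff$wt_protein, "*"), oracle_translate(cds))
  }
})

test_that("frameshift arithmetic reproduces divergence/truncation/novel-peptide identities", {
  # engineer divergence at codon 877 of a 1,328-aa protein: truncated = 451
  set.seed(82)
  wt_codons <- 1329 # 1,328 aa + stop
  cds <- random_cds(wt_codons)
  utr5 <- 12
  # exon 1: UTR + codons 1..876 + 1 extra nt of codon 877
  e1_len <- utr5 + 876 * 3 + 1
  # deleted exon: length == 2 mod 3 so the frame shifts by one
  e2_len <- 101
  tx_rest <- nchar(cds) + utr5 + 9 - e1_len - e2_len
  tx <- paste0(paste(rep("T", utr5), collapse = ""), cds, "ACGTACGTA")
  exon_seqs <- c(substr(tx, 1, e1_len),
                 substr(tx, e1_len + 1, e1_len + e2_len),
                 substr(tx, e1_len + e2_len + 1, nchar(tx)))
  g <- make_gene(exon_seqs, cds_start = utr5 + 1,
                 cds_end = utr5 + nchar(cds))
  mut <- apply_deletion(g$model, g$model$exons[2, ] + c(-3, 3))
  eff <- protein_effect(g$model, mut, g$genome)
  expect_false(eff$in_frame)
  expect_equal(eff$wt_protein_length, 1328)
  expect_equal(eff$frameshift_position, 877)
  expect_equal(eff$truncated_residues, 1328 - 876)
  expect_gte(eff$novel_peptide_length, 0)
  # novel peptide read in the shifted frame matches a direct translation
  mut_tx <- lethalscan:::transcript_seq(mut, g$genome)
  mut_cds_on <- substr(mut_tx, mut$cds_start, nchar(mut_tx))
  oracle_prot <- oracle_translate(mut_cds_on)
  oracle_trunc <- sub("\\*.*", "", oracle_prot)
  expect_equal(eff$mut_protein, oracle_trunc)
})

test_that("NMD prediction implements the 50-nt junction rule with inclusive boundary", {
  exons <- rbind(c(0, 300), c(400, 700), c(800, 1100))
  m <- gene_model("g", "+", exons, cds_start = 1, cds_end = 900)
  # final junction at transcript position 600
  expect_false(predict_nmd(m, 700)) # PTC in last exon
  expect_true(predict_nmd(m, 400))  # 200 nt upstream
  expect_true(predict_nmd(m, 550))  # exactly 50 nt upstream: inclusive
  expect_false(predict_nmd(m, 551))
  single <- gene_model("g", "+", rbind(c(0, 300)), 1, 300)
  expect_false(predict_nmd(single, 100))
  expect_error(predict_nmd(m, 5000), "outside")
})

test_that("amplicon prediction reproduces the deletion-typing PCR logic", {
  set.seed(91)
  seg <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  fwd <- "ACCGTTAGACCGTTAGGACT"
  rev <- "TGCAACGGTTGCAACGGTAC" # as synthesised (5'->3' on minus strand)
  inner_f <- "GGATCCGGATCCTTAAGGCC"
  inner_r <- "CCTTGGAACCTTGGAAGTCC"
  # wild type: fwd [..] inner_f [..] inner_r_rc [..] rev_rc; deletion removes
  # everything between the outer primers except 369 bp, leaving a 409 bp
  # junction product; the wild-type outer span exceeds the 5 kb polymerase
  # reach
  left_pad <- seg(500)
  a <- seg(80)
  deleted <- paste0(seg(1000), inner_f, seg(300),
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(inner_r))), seg(3561))
  b <- seg(289)
  right_pad <- seg(500)
  wt <- paste0(left_pad, fwd, a, deleted, b,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(rev))), right_pad)
  mut <- sub(deleted, "", wt, fixed = TRUE)
  # genomic junction amplicon: no product on wild type (span > 5 kb),
  # 409 bp on the deleted allele
  res <- predict_amplicons(fwd, rev, c(wt = wt, mut = mut))
  expect_true(is.na(res$product_size[res$template == "wt"]))
  expect_equal(res$product_size[res$template == "mut"], 409)
  # internal primers: product on wild type only
  res_in <- predict_amplicons(inner_f, inner_r, c(wt = wt, mut = mut))
  expect_false(is.na(res_in$product_size[res_in$template == "wt"]))
  expect_true(is.na(res_in$product_size[res_in$template == "mut"]))
  # multiply-matching primer is an ambiguity error
  expect_error(predict_amplicons("ACGT", rev, c(wt = wt)), "ambiguity")
})

test_that("cDNA amplicon sizes shrink by exactly the summed deleted exon lengths", {
  set.seed(92)
  for (rep in 1:10) {
    n_ex <- sample(5:9, 1)
    ex_lens <- sample(60:200, n_ex, replace = TRUE)
    exon_seqs <- vapply(ex_lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
    tlen <- sum(ex_lens)
    cds_len <- 3 * ((tlen - 20) %/% 3)
    g <- make_gene(exon_seqs, cds_start = 1, cds_end = cds_len)
    i0 <- sample(2:(n_ex - 2), 1)
    i1 <- i0 + 1
    del <- c(g$model$exons[i0, 1] - 1, g$model$exons[i1, 2] + 1)
    mut <- apply_deletion(g$model, del)
    wt_tx <- lethalscan:::transcript_seq(g$model, g$genome)
    mut_tx <- lethalscan:::transcript_seq(mut, g$genome)
    # primers in the first and last exons
    fwd <- substr(exon_seqs[1], 5, 24)
    last_seq <- exon_seqs[n_ex]
    rev_site <- substr(last_seq, nchar(last_seq) - 29, nchar(last_seq) - 10)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev_site)))
    res <- predict_amplicons(fwd, rev, c(wt = wt_tx, mut = mut_tx),
                             max_amplicon = 1e5)
    wt_size <- res$product_size[res$template == "wt"]
    mut_size <- res$product_size[res$template == "mut"]
    if (is.na(wt_size) || is.na(mut_size)) next # rare duplicate primer site
    expect_equal(wt_size - mut_size, sum(ex_lens[i0:i1]))
  }
})

test_that("candidate-variant triage removes known and non-coding variants", {
  exons <- rbind(c(100, 220), c(300, 420))
  m <- gene_model("chr1", "+", exons, cds_start = 11, cds_end = 220)
  vars <- data.frame(chrom = "chr1", pos = c(150, 250, 350, 150),
                     ref = c("A", "C", "G", "A"),
                     alt = c("T", "G", "A", "C"),
                     stringsAsFactors = FALSE)
  known <- vars[1, ]
  out <- filter_candidate_variants(vars, known, list(m))
  # variant 1 known; 250 intronic; 350 is transcript pos 171 -> within CDS;
  # 150/A>C is novel coding (pos 150 -> transcript 51)
  expect_equal(sort(out$pos), c(150, 350))
  expect_true(all(out$coding))
  out_all <- filter_candidate_variants(vars, known, list(m),
                                       coding_only = FALSE)
  expect_equal(nrow(out_all), 3)
  expect_equal(sum(out_all$coding), 2)
})
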