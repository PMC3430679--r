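test_that("insert model is exact on constant data and robust to contamination", {
  const <- data.frame(mapped_distance = rep(4250, 200))
  m <- fit_insert_model(const)
  expect_equal(m$mean, 4250)
  expect_equal(m$sd, 0)
  expect_error(fit_insert_model(data.frame(mapped_distance = rep(4250, 50))),
               "100")
  set.seed(7)
  u <- data.frame(mapped_distance = runif(5000, 4000, 4500))
  expect_lt(abs(fit_insert_model(u)$mean - 4250), 50)
  # 1% contaminating 8 kb pairs: trimmed fit unaffected
  cont <- data.frame(mapped_distance = c(runif(4950, 4000, 4500),
                                         rep(8000, 50)))
  expect_lt(abs(fit_insert_model(cont, trim_quantile = 0.05)$mean - 4250), 50)
})

test_that("discordant clustering recovers planted deletion size and count", {
  mp <- simulate_matepairs(120000, deletion = c(60000, 63329),
                           genotype = "D/D", coverage = 20, seed = 51)
  model <- fit_insert_model(mp$pairs)
  cl <- cluster_discordant(mp$pairs, model)
  expect_equal(nrow(cl), 1)
  expect_lt(abs(cl$estimated_size - 3329), 300)
  expect_gt(cl$n_discordant_pairs, 50)
  # the tight bracket encloses the deletion to within read length (a read
  # crossing the junction anchors up to one read length past the breakpoint)
  expect_lte(cl$start, 60000 + 76)
  expect_gte(cl$end, 63329 - 76)
  # no deletion -> no discordance
  wt <- simulate_matepairs(60000, genotype = "+/+", coverage = 10, seed = 52)
  mw <- fit_insert_model(wt$pairs)
  expect_equal(nrow(cluster_discordant(wt$pairs, mw)), 0)
})

test_that("two well-separated deletions yield exactly two clusters", {
  # assemble pairs by hand around two planted events 50 kb apart
  set.seed(8)
  conc <- data.frame(chrom = "21", pos1 = round(runif(500, 0, 9e4)),
                     orientation = "FR",
                     mapped_distance = round(runif(500, 4000, 4500)))
  conc$pos2 <- conc$pos1 + conc$mapped_distance - 76
  d1 <- data.frame(chrom = "21", pos1 = round(runif(20, 18000, 19500)),
                   orientation = "FR",
                   mapped_distance = round(runif(20, 7300, 7900)))
  d1$pos2 <- d1$pos1 + d1$mapped_distance - 76
  d2 <- data.frame(chrom = "21", pos1 = round(runif(20, 68000, 69500)),
                   orientation = "FR",
                   mapped_distance = round(runif(20, 7300, 7900)))
  d2$pos2 <- d2$pos1 + d2$mapped_distance - 76
  pairs <- rbind(conc, d1, d2)
  model <- fit_insert_model(pairs)
  cl <- cluster_discordant(pairs, model)
  expect_equal(nrow(cl), 2)
})

test_that("coverage dropout detection separates real gaps from Poisson gaps", {
  mp <- simulate_matepairs(90000, deletion = c(40000, 43329),
                           genotype = "D/D", coverage = 30, seed = 53)
  dr <- detect_dropout(mp$depth, window = 500, min_flank_depth = 1)
  expect_equal(nrow(dr), 1)
  expect_lt(abs(dr$start - 40000), 500)
  expect_lt(abs(dr$end - 43329), 500)
  # uniform track: nothing
  wt <- simulate_matepairs(90000, genotype = "+/+", coverage = 30, seed = 54)
  expect_equal(nrow(detect_dropout(wt$depth, 500, 1)), 0)
  # all-zero track is an error (no flanking coverage)
  zero <- data.frame(pos = 0:999, depth = 0)
  expect_error(detect_dropout(zero), "flanking")
  # sparse 1.7x library still reveals a 3.3 kb deletion at window >= 500
  sparse <- simulate_matepairs(200000, deletion = c(90000, 93329),
                               genotype = "D/D", coverage = 1.7, seed = 55)
  drs <- detect_dropout(sparse$depth, window = 500, min_flank_depth = 0.5)
  hit <- drs[drs$start > 85000 & drs$end < 98000, ]
  expect_equal(nrow(hit), 1)
  # heterozygous mode flags the half-depth band
  het <- simulate_matepairs(90000, deletion = c(40000, 43329),
                            genotype = "D/+", coverage = 40, seed = 56)
  drh <- detect_dropout(het$depth, window = 500, min_flank_depth = 10,
                        mode = "half")
  expect_gte(nrow(drh), 1)
  expect_true(any(drh$start > 39000 & drh$end < 44500))
})

test_that("evidence merging ranks pair+dropout calls first and keeps singletons apart", {
  clusters <- data.frame(chrom = "21", start = 10000, end = 13300,
                         n_discordant_pairs = 30L, estimated_size = 3300,
                         mean_distance = 7550, stringsAsFactors = FALSE)
  dropouts <- data.frame(start = 10050, end = 13350, length = 3300L,
                         mean_flank_depth = 25, mode = "zero",
                         stringsAsFactors = FALSE)
  calls <- merge_evidence(clusters, dropouts, chrom = "21")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$evidence, "pair+dropout")
  expect_equal(calls$tier, 1L)
  expect_equal(calls$start, 10050)
  # cluster alone -> pair-only
  alone <- merge_evidence(clusters, dropouts[0, ], chrom = "21")
  expect_equal(alone$evidence, "pair-only")
  expect_equal(alone$tier, 2L)
  # disjoint evidence on different chromosomes stays separate
  far <- dropouts
  far$chrom <- "22"
  two <- merge_evidence(clusters, far)
  expect_equal(nrow(two), 2)
  expect_true(all(two$tier == 2L))
})

test_that("no false tier-1 call arises on wild-type simulations", {
  false_calls <- 0
  for (s in 1:25) {
    wt <- simulate_matepairs(60000, deletion = c(30000, 33329),
                             genotype = "+/+", coverage = 12, seed = 600 + s)
    model <- fit_insert_model(wt$pairs)
    cl <- cluster_discordant(wt$pairs, model)
    dr <- detect_dropout(wt$depth, 500, 1)
    calls <- merge_evidence(cl, dr)
    if (any(calls$tier == 1)) false_calls <- false_calls + 1
  }
  expect_equal(false_calls, 0)
})

test_that("breakpoint refinement is exact for planted sizes and reports microhomology", {
  for (size in c(500, 3329, 10000)) {
    for (s in 1:5) {
      del <- c(25000, 25000 + size)
      mp <- simulate_matepairs(80000, deletion = del, genotype = "D/D",
                               coverage = 20, seed = 700 + 10 * size + s)
      expect_gt(length(mp$junction_reads), 0)
      call <- list(chrom = "21", start = del[1] + 40, end = del[2] - 40,
                   size = size - 80, tier = 1L, n_discordant_pairs = 10L,
                   evidence = "pair+dropout", refined = FALSE,
                   microhomology = NA_integer_, estimated_size = size)
      ref <- refine_breakpoints(call, mp$junction_reads, mp$reference)
      expect_true(ref$refined)
      expect_equal(ref$size, size)
    }
  }
})

test_that("engineered breakpoint homology is measured and random homology is short", {
  set.seed(31)
  # engineer 5 bp of identical sequence immediately after both breakpoints
  left <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  hom <- "ACGTA"
  reference <- paste0(left, hom, mid, hom, right)
  del <- c(nchar(left), nchar(left) + 5 + 2000) # deletes hom+mid, leaves hom
  mp <- simulate_matepairs(nchar(reference), deletion = del,
                           genotype = "D/D", coverage = 40,
                           reference = reference, seed = 57)
  expect_gt(length(mp$junction_reads), 0)
  call <- list(chrom = "21", start = del[1], end = del[2], size = 2005,
               tier = 1L, n_discordant_pairs = 5L, evidence = "pair+dropout",
               refined = FALSE, microhomology = NA_integer_,
               estimated_size = 2005)
  ref <- refine_breakpoints(call, mp$junction_reads, mp$reference)
  expect_true(ref$refined)
  expect_equal(ref$size, del[2] - del[1])
  expect_gte(ref$microhomology, 5)
  # random breakpoints: homology typically <= 3
  mh <- vapply(1:8, function(s) {
    mpr <- simulate_matepairs(50000, deletion = c(20000, 23329),
                              genotype = "D/D", coverage = 15,
                              seed = 800 + s)
    call <- list(chrom = "21", start = 20000, end = 23329, size = 3329,
                 tier = 1L, n_discordant_pairs = 5L,
                 evidence = "pair+dropout", refined = FALSE,
                 microhomology = NA_integer_, estimated_size = 3329)
    refine_breakpoints(call, mpr$junction_reads, mpr$reference)$microhomology
  }, integer(1))
  expect_true(median(mh) <= 3)
})

test_that("refinement without usable junction reads returns the call unchanged", {
  call <- data.frame(chrom = "21", start = 100, end = 600, size = 500,
                     refined = FALSE, microhomology = NA_integer_)
  expect_message(
    out <- refine_breakpoints(call, character(), paste(rep("ACGT", 500),
                                                       collapse = "")),
    "unrefined")
  expect_false(out$refined)
  expect_equal(out$start, 100)
})

test_that("pre-refinement size estimates are unbiased over replicate libraries", {
  sizes <- vapply(1:60, function(s) {
    mp <- simulate_matepairs(90000, deletion = c(40000, 43329),
                             genotype = "D/D", coverage = 8, seed = 900 + s)
    model <- fit_insert_model(mp$pairs)
    cl <- cluster_discordant(mp$pairs, model)
    cl$estimated_size[which.max(cl$n_discordant_pairs)]
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 3329) / 3329, 0.02)
})
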