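#' Default pipeline configuration
#'
#' Returns the full default `RunConfig` list: one root seed, an output
#' directory, per-stage parameter blocks and enable flags. Any YAML/ list
#' supplied to [run_pipeline()] is merged over these defaults, so a config
#' need only name what it changes.
#'
#' The defaults run a deliberately compact but complete study: a single
#' 60 Mb chromosome with 1,200 markers carrying a 2.46 Mb planted autozygous
#' interval in 6 cases against 100 phased controls; a 150 kb resequencing
#' window with the 3,329 bp deletion at 30x mate-pair coverage; a synthetic
#' 37-exon gene model over the deletion; a 3,038-animal genotyping sample;
#' and 100,000 matings per class.
#'
#' @return nested list of pipeline parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "lethalscan_run",
    carrier_freq = 0.074,
    stages = list(simulate = TRUE, map = TRUE, callsv = TRUE,
                  consequence = TRUE, popgen = TRUE, fertility = TRUE),
    genotypes = list(chrom = "21", n_markers = 1200L, chrom_length = 6e7,
                     n_cases = 6L, n_controls = 100L,
                     interval_start = 20132767, interval_end = 22592767),
    matepairs = list(ref_length = 150000L, del_start = 80000L,
                     del_len = 3329L, coverage = 30,
                     insert_low = 4000, insert_high = 4500,
                     read_length = 76L),
    map = list(n_reps = 1000L, min_markers = 20L, pseudocount = 1),
    callsv = list(trim_quantile = 0.05, k = 4, window = 500,
                  min_flank_depth = 1, max_gap = 1000),
    consequence = list(n_exons = 37L, deleted_exons = 25:27),
    popgen = list(sample_size = 3038L),
    fertility = list(n_per_class = 100000L,
                     baseline = c(0.35, 0.40, 0.45),
                     mortality = c(0.30, 0.40, 0.52),
                     n_boot = 200L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# synthetic many-exon gene over the mate-pair reference window, with the
# planted deletion removing a whole block of internal exons
build_gene_over_deletion <- function(cfg, reference) {
  n_ex <- cfg$consequence$n_exons
  del <- c(cfg$matepairs$del_start,
           cfg$matepairs$del_start + cfg$matepairs$del_len)
  del_idx <- cfg$consequence$deleted_exons
  # deleted exons sit inside the deletion; others tile the flanks
  n_before <- min(del_idx) - 1L
  n_after <- n_ex - max(del_idx)
  exon_len <- 120L # multiple of 3 keeps frame bookkeeping simple...
  # ...so nudge the deleted block to a non-multiple-of-3 coding length:
  del_lens <- rep(exon_len, length(del_idx))
  del_lens[1] <- exon_len + 1L # frameshift by construction
  gap <- 40L
  starts_before <- del[1] - (n_before:1) * (exon_len + gap)
  starts_del <- del[1] + 10L + cumsum(c(0L, utils::head(del_lens, -1) + gap))
  starts_after <- del[2] + 10L + (0:(n_after - 1L)) * (exon_len + gap)
  exons <- rbind(cbind(starts_before, starts_before + exon_len),
                 cbind(starts_del, starts_del + del_lens),
                 cbind(starts_after, starts_after + exon_len))
  if (min(exons) < 0 || max(exons) > nchar(reference)) {
    stop("reference window too small for the synthetic gene model")
  }
  tlen <- sum(exons[, 2] - exons[, 1])
  cds_len <- 3L * ((tlen - 60L) %/% 3L)
  model <- gene_model(cfg$matepairs$chrom %||% "21", "+", exons,
                      cds_start = 31, cds_end = 30 + cds_len)
  # genome copy engineered so the wild-type CDS translates cleanly: ATG at
  # the CDS start, no internal stops, a stop codon at the end
  genome <- engineer_orf(reference, model)
  list(model = model, genome = genome)
}

# rewrite the exonic portion of `reference` so the model's CDS is a clean ORF
engineer_orf <- function(reference, model) {
  tlen <- transcript_length(model)
  codons_no_stop <- c("GCT", "TGC", "GAT", "GAA", "TTC", "GGA", "CAT", "ATC",
                      "AAA", "CTG", "ATG", "AAC", "CCA", "CAG", "AGA", "AGC",
                      "ACA", "GTG", "TGG", "TAT")
  n_codons <- (model$cds_end - model$cds_start + 1) %/% 3
  body <- sample(codons_no_stop, n_codons - 2, replace = TRUE)
  cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
  utr5 <- random_dna(model$cds_start - 1)
  utr3 <- random_dna(tlen - model$cds_end)
  tx <- paste0(utr5, cds, utr3)
  stopifnot(nchar(tx) == tlen)
  # splice the transcript back into the genomic exons (plus strand)
  genome <- reference
  off <- 0
  for (i in seq_len(nrow(model$exons))) {
    e <- model$exons[i, ]
    len <- e[2] - e[1]
    piece <- substr(tx, off + 1, off + len)
    substr(genome, e[1] + 1, e[2]) <- piece
    off <- off + len
  }
  genome
}

#' Run the full analysis pipeline from one seeded configuration
#'
#' Executes the enabled stages in order — simulate genotypes, autozygosity
#' map, simulate mate pairs and call the deletion, predict the transcript
#' consequence, population-genetic summaries, simulate matings and estimate
#' lethality — writing each stage's tabular outputs under `out_dir` and
#' recording a JSON run manifest with the package version, the root seed,
#' each stage's derived seed, and md5 hashes of every output file. Re-running
#' the same config yields byte-identical outputs.
#'
#' Every random draw descends from the root seed through a named per-stage
#' substream, so disabling or re-running one stage never perturbs another.
#'
#' @param config a named list overriding [default_config()], or a path to a
#'   YAML file of such overrides, or `NULL` for pure defaults.
#' @return the run manifest (list of class `ls_manifest`), invisibly
#'   written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- default_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("config must set a seed")
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_results <- list()
  outputs <- character()
  results <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(invisible())
    message(sprintf("[lethalscan] stage %-11s seed %d", name,
                    child_seed(cfg$seed, name)))
    t1 <- Sys.time()
    files <- tryCatch(fun(child_seed(cfg$seed, name)), error = function(e) {
      marker <- file.path(out, paste0(name, ".partial"))
      writeLines(conditionMessage(e), marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_results[[name]] <<- list(
      seed = child_seed(cfg$seed, name),
      elapsed_s = round(as.numeric(difftime(Sys.time(), t1, units = "secs")), 3),
      outputs = files)
    outputs <<- c(outputs, files)
    invisible()
  }

  run_stage("simulate", function(seed) {
    map <- marker_map(cfg$genotypes$chrom, cfg$genotypes$n_markers,
                      cfg$genotypes$chrom_length, seed = seed)
    sim <- simulate_genotypes(map, cfg$genotypes$n_cases,
                              cfg$genotypes$n_controls, cfg$carrier_freq,
                              list(chrom = cfg$genotypes$chrom,
                                   start = cfg$genotypes$interval_start,
                                   end = cfg$genotypes$interval_end),
                              seed = seed)
    results$genotypes <- sim
    f1 <- file.path(out, "genotypes.vcf")
    write_genotypes_vcf(sim, f1)
    f2 <- file.path(out, "truth_interval.bed")
    write_bed(sim$truth_bed, f2)
    c(f1, f2)
  })

  run_stage("map", function(seed) {
    sim <- results$genotypes
    if (is.null(sim)) stop("map stage needs the simulate stage's genotypes")
    scan <- genomewide_scan(sim, sim$case_ids, n_reps = cfg$map$n_reps,
                            pseudocount = cfg$map$pseudocount, seed = seed)
    results$scan <- scan
    f1 <- file.path(out, "scan_per_marker.tsv")
    write_tsv(scan$per_marker, f1)
    f2 <- file.path(out, "candidate_interval.bed")
    seg <- scan$best_segment
    if (!is.null(seg)) {
      write_bed(data.frame(chrom = seg$chrom, start = seg$start_bp - 1,
                           end = seg$end_bp,
                           name = sprintf("P_gw=%.4g", seg$P_gw)), f2)
    } else {
      write_bed(data.frame(chrom = character(), start = numeric(),
                           end = numeric()), f2)
    }
    c(f1, f2)
  })

  run_stage("callsv", function(seed) {
    mpc <- cfg$matepairs
    del <- c(mpc$del_start, mpc$del_start + mpc$del_len)
    sim <- simulate_matepairs(mpc$ref_length, deletion = del,
                              genotype = "D/D",
                              insert = list(dist = "uniform",
                                            low = mpc$insert_low,
                                            high = mpc$insert_high),
                              read_length = mpc$read_length,
                              coverage = mpc$coverage,
                              chrom = cfg$genotypes$chrom, seed = seed)
    results$matepairs <- sim
    model <- fit_insert_model(sim$pairs, cfg$callsv$trim_quantile,
                              cfg$callsv$k)
    clusters <- cluster_discordant(sim$pairs, model,
                                   read_length = mpc$read_length,
                                   max_gap = cfg$callsv$max_gap)
    dropouts <- detect_dropout(sim$depth, cfg$callsv$window,
                               cfg$callsv$min_flank_depth)
    calls <- merge_evidence(clusters, dropouts, chrom = cfg$genotypes$chrom)
    if (nrow(calls)) {
      refined <- refine_breakpoints(calls[1, ], sim$junction_reads,
                                    sim$reference)
      calls <- rbind(refined[names(calls)],
                     calls[-1, , drop = FALSE])
      if (!is.null(refined$n_junction_reads)) {
        calls$refined[1] <- TRUE
      }
    }
    results$calls <- calls
    f1 <- file.path(out, "pairs.tsv"); write_tsv(sim$pairs, f1)
    f2 <- file.path(out, "depth.tsv"); write_tsv(sim$depth, f2)
    f3 <- file.path(out, "deletions.vcf"); write_deletion_vcf(calls, f3)
    f4 <- file.path(out, "deletion_evidence.tsv"); write_tsv(calls, f4)
    c(f1, f2, f3, f4)
  })

  run_stage("consequence", function(seed) {
    sim <- results$matepairs
    if (is.null(sim)) stop("consequence stage needs the callsv stage's reference")
    call <- results$calls[1, ]
    with_seed(seed, {
      gm <- build_gene_over_deletion(cfg, sim$reference)
      mutant <- apply_deletion(gm$model, c(call$start, call$end))
      eff <- protein_effect(gm$model, mutant, gm$genome)
      results$effect <- eff
      f1 <- file.path(out, "effect.tsv")
      write_tsv(data.frame(
        deleted_exons = paste(eff$deleted_exons, collapse = ","),
        deleted_coding_bp = eff$deleted_coding_length,
        in_frame = eff$in_frame,
        frameshift_aa = eff$frameshift_position,
        novel_peptide_aa = eff$novel_peptide_length,
        truncated_aa = eff$truncated_residues,
        nmd = eff$nmd_predicted), f1)
      f1
    })
  })

  run_stage("popgen", function(seed) {
    q <- allele_freq_from_carrier(cfg$carrier_freq)
    N <- cfg$popgen$sample_size
    counts <- with_seed(seed, {
      g <- rbinom(N, 2, q)
      genotype_counts(sum(g == 0), sum(g == 1), sum(g == 2))
    })
    cf <- carrier_frequency(counts)
    tab <- data.frame(
      metric = c("carrier_freq_est", "carrier_ci_lower", "carrier_ci_upper",
                 "allele_freq_q", "expected_incidence_reciprocal",
                 "prob_zero_homozygotes",
                 "survival50_incidence_reciprocal"),
      value = c(cf$estimate, cf$lower, cf$upper, q,
                expected_incidence(cfg$carrier_freq)$reciprocal,
                prob_zero_homozygotes(q, N),
                survival_adjusted_incidence(cfg$carrier_freq, 0.5)$reciprocal))
    results$popgen <- tab
    f1 <- file.path(out, "popgen.tsv")
    write_tsv(tab, f1)
    f1
  })

  run_stage("fertility", function(seed) {
    fc <- cfg$fertility
    recs <- simulate_matings(fc$n_per_class, cfg$carrier_freq,
                             fc$baseline, fc$mortality, seed = seed)
    cc <- class_contrasts(recs)
    est <- estimate_mortality(recs, cfg$carrier_freq, n_boot = fc$n_boot,
                              seed = child_seed(seed, "boot"))
    results$lethality <- est
    f1 <- file.path(out, "matings.tsv"); write_tsv(recs, f1)
    f2 <- file.path(out, "class_summary.tsv"); write_tsv(cc$summary, f2)
    f3 <- file.path(out, "lethality.json")
    jsonlite::write_json(list(P_hom = est$P_hom, class = est$class,
                              estimate = est$estimate),
                         f3, auto_unbox = TRUE, digits = 10)
    c(f1, f2, f3)
  })

  manifest <- list(
    package = "lethalscan",
    version = as.character(utils::packageVersion("lethalscan")),
    seed = cfg$seed,
    config = cfg,
    stages = stage_results,
    hashes = as.list(tools::md5sum(outputs)),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10,
                       force = TRUE)
  class(manifest) <- "ls_manifest"
  invisible(manifest)
}

#' Assemble a human-readable report from a pipeline run directory
#'
#' Reads the manifest and stage outputs under `run_dir` and renders a plain
#' text report with one section per analysis: candidate interval, deletion
#' call, transcript effect, population-genetic table, and lethality
#' estimates. Missing stage outputs produce an "absent" section rather than
#' an error.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param path optional output file; when `NULL` the report is returned only.
#' @return character vector of report lines, invisibly when written.
#' @export
make_report <- function(run_dir, path = NULL) {
  mf <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest in ", run_dir)
  manifest <- jsonlite::read_json(mf)
  lines <- c("lethalscan run report",
             paste0("seed: ", manifest$seed),
             paste0("version: ", manifest$version), "")
  section <- function(title, file, render) {
    f <- file.path(run_dir, file)
    if (file.exists(f)) c(paste0("## ", title), render(f), "")
    else c(paste0("## ", title), "(absent)", "")
  }
  lines <- c(lines,
    section("Candidate interval", "candidate_interval.bed", function(f) {
      b <- utils::read.table(f, sep = "\t", stringsAsFactors = FALSE)
      if (!nrow(b)) return("no shared segment")
      sprintf("%s:%s-%s (%s)", b[1, 1], format(b[1, 2] + 1, big.mark = ","),
              format(b[1, 3], big.mark = ","), b[1, 4])
    }),
    section("Deletion call", "deletion_evidence.tsv", function(f) {
      d <- read_tsv(f)
      if (!nrow(d)) return("no call")
      sprintf("%s:%d-%d (%d bp, %s, %d discordant pairs, refined=%s, microhomology=%s)",
              d$chrom[1], as.integer(d$start[1]), as.integer(d$end[1]),
              as.integer(d$size[1]), d$evidence[1],
              as.integer(d$n_discordant_pairs[1]), d$refined[1],
              d$microhomology[1])
    }),
    section("Transcript effect", "effect.tsv", function(f) {
      e <- read_tsv(f)
      sprintf("exons %s deleted (%d coding bp); %s; NMD=%s",
              e$deleted_exons[1], e$deleted_coding_bp[1],
              if (e$in_frame[1]) "in-frame" else
                sprintf("frameshift at aa %d, %d residues replaced by %d-aa novel peptide",
                        e$frameshift_aa[1], e$truncated_aa[1],
                        e$novel_peptide_aa[1]),
              e$nmd[1])
    }),
    section("Population genetics", "popgen.tsv", function(f) {
      p <- read_tsv(f)
      sprintf("%s = %.6g", p$metric, p$value)
    }),
    section("Lethality", "lethality.json", function(f) {
      l <- jsonlite::read_json(f, simplifyVector = TRUE)
      c(sprintf("informative class %s, P_hom = %.4f", l$class, l$P_hom),
        sprintf("day %3d: m_hat = %.3f (excess %.4f)",
                l$estimate$day, l$estimate$m_hat, l$estimate$excess))
    }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
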