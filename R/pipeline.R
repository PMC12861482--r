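# End-to-end orchestration: simulate (optional) -> read inputs -> tetrads ->
# promoters + pairwise alignments -> conservation classes -> convergence ->
# expression statistics -> TFBS conservation -> variants -> TSV outputs +
# manifest. Deterministic under a fixed config and seed.

PIPELINE_PAIRS <- list(c("Ar", "An"), c("Co", "Cn"), c("Ar", "Co"), c("An", "Cn"))

# exact A/B swap of a promoter alignment (columns unchanged)
swap_alignment <- function(aln) {
  out <- aln
  out$pos_a <- aln$pos_b; out$pos_b <- aln$pos_a
  out$len_a <- aln$len_b; out$len_b <- aln$len_a
  out$coverage_a <- aln$coverage_b; out$coverage_b <- aln$coverage_a
  out
}

align_tetrad_pair <- function(tetrads, promoters, g1, g2) {
  out <- vector("list", nrow(tetrads))
  names(out) <- tetrads$tetrad_id
  for (i in seq_len(nrow(tetrads))) {
    p1 <- promoters[[g1]][[tetrads[[g1]][i]]]
    p2 <- promoters[[g2]][[tetrads[[g2]][i]]]
    out[[i]] <- align_promoters(p1$seq, p2$seq)
  }
  out
}

read_benchmark_inputs <- function(paths) {
  genomes <- GENOME_LABELS
  assemblies <- lapply(setNames(genomes, genomes), function(g) {
    read_genome_fasta(paths$genomes[[g]], label = g)
  })
  genes <- lapply(setNames(genomes, genomes), function(g) {
    read_gene_models(paths$genes[[g]], assemblies[[g]])
  })
  gene_seqs <- lapply(setNames(genomes, genomes), function(g) {
    ss <- Biostrings::readDNAStringSet(paths$gene_seqs[[g]])
    setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  })
  peaks <- lapply(setNames(genomes, genomes), function(g) {
    do.call(rbind, lapply(MARKS, function(mk) {
      read_peaks_bed(paths$peaks[[g]][[mk]], mk)
    }))
  })
  expr <- lapply(setNames(genomes, genomes), function(g) {
    read_expression_tsv(paths$expression[[g]])
  })
  pwms <- read_pwm_library(paths$motifs)
  list(assemblies = assemblies, genes = genes, gene_seqs = gene_seqs,
       peaks = peaks, expression = expr, pwms = pwms)
}

#' Standard input-file layout of a benchmark directory
#'
#' Maps a directory produced by [simulate_benchmark()] to the `inputs` list
#' understood by [run_pipeline()].
#'
#' @param dir Benchmark directory.
#' @return Named list of file paths (genomes, genes, gene_seqs, peaks,
#'   expression, motifs).
#' @export
benchmark_paths <- function(dir) {
  g <- setNames(GENOME_LABELS, GENOME_LABELS)
  list(genomes = lapply(g, function(x) file.path(dir, paste0("genome_", x, ".fa"))),
       genes = lapply(g, function(x) file.path(dir, paste0("genes_", x, ".gff3"))),
       gene_seqs = lapply(g, function(x) file.path(dir, paste0("geneseq_", x, ".fa"))),
       peaks = lapply(g, function(x) {
         setNames(lapply(MARKS, function(mk) file.path(dir, sprintf("peaks_%s_%s.bed", x, mk))), MARKS)
       }),
       expression = lapply(g, function(x) file.path(dir, paste0("expr_", x, ".tsv"))),
       motifs = file.path(dir, "motifs.jaspar"))
}

#' Run the full comparative pipeline
#'
#' @param config Named list (or path to a YAML file) with elements:
#'   * `simulate`: arguments for [sim_config()]; when present the benchmark
#'     is generated under `<outdir>/sim` and used as input.
#'   * `inputs`: alternatively, a list of input paths as produced by
#'     `benchmark_paths()` (genomes, genes, gene_seqs, peaks, expression,
#'     motifs).
#'   * `outdir`: output directory.
#'   * `thresholds`: optional overrides (min_lift, min_identity,
#'     min_epi_overlap, motif_score, fc_threshold, cs_cutoff, min_cscore,
#'     min_anchors, max_gap).
#'   * `tetrads`: optional path to a precomputed tetrad TSV (skips the
#'     orthology stage).
#' @param quiet Suppress progress messages.
#' @return List of class `homeoconverge_run` with all stage results; TSV
#'   outputs and a run manifest are written under `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$outdir %||% stopf("config$outdir is required")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  th <- modifyList(list(min_lift = 0.5, min_identity = 0.7, min_epi_overlap = 0.5,
                        motif_score = 10, fc_threshold = 1, cs_cutoff = 0.6,
                        min_cscore = 0.99, min_anchors = 4L, max_gap = 10L),
                   config$thresholds %||% list())
  say <- function(...) if (!quiet) msg(...)

  if (!is.null(config$simulate)) {
    cfg <- if (inherits(config$simulate, "sim_config")) config$simulate
           else do.call(sim_config, config$simulate)
    say("simulating benchmark: %d tetrads, seed %d", cfg$n_tetrads, cfg$seed)
    simdir <- file.path(outdir, "sim")
    simulate_benchmark(cfg, simdir)
    paths <- benchmark_paths(simdir)
  } else {
    paths <- config$inputs %||% stopf("config needs either simulate or inputs")
  }
  for (g in GENOME_LABELS) {
    for (mk in MARKS) {
      if (!file.exists(paths$peaks[[g]][[mk]])) {
        stopf("missing peak file for mark %s (genome %s)", mk, g)
      }
    }
  }
  say("reading inputs")
  inp <- read_benchmark_inputs(paths)

  if (!is.null(config$tetrads)) {
    tetrads <- read.table(config$tetrads, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  } else {
    say("identifying tetrads")
    gene_orders <- lapply(inp$genes, function(gm) {
      gm <- gm[order(gm$chrom, gm$start), ]
      split(gm$gene_id, gm$chrom)
    })
    tetrads <- find_tetrads(inp$gene_seqs, gene_orders,
                            min_anchors = th$min_anchors, max_gap = th$max_gap,
                            min_cscore = th$min_cscore)
  }
  if (nrow(tetrads) == 0) stopf("no tetrads identified")
  say("%d tetrads", nrow(tetrads))

  say("extracting promoters")
  promoters <- lapply(setNames(GENOME_LABELS, GENOME_LABELS), function(g) {
    gm <- inp$genes[[g]]
    gm <- gm[gm$gene_id %in% tetrads[[g]], , drop = FALSE]
    suppressWarnings(extract_promoters(gm, inp$assemblies[[g]]))
  })
  peaks_local <- lapply(setNames(GENOME_LABELS, GENOME_LABELS), function(g) {
    lapply(promoters[[g]], function(pr) peaks_to_promoter(inp$peaks[[g]], pr))
  })

  say("aligning promoter pairs")
  alignments <- list()
  for (pd in PIPELINE_PAIRS) {
    key <- paste0(pd[1], "-", pd[2])
    alignments[[key]] <- align_tetrad_pair(tetrads, promoters, pd[1], pd[2])
  }

  say("calling peak conservation")
  calls <- do.call(rbind, lapply(PIPELINE_PAIRS, function(pd) {
    key <- paste0(pd[1], "-", pd[2])
    pair_calls(tetrads, pd, promoters, peaks_local, alignments[[key]],
               marks = MARKS, thresholds = th)
  }))
  class_summary <- do.call(rbind, lapply(c("Ar-An", "Co-Cn", "Ar-Co", "An-Cn"), function(pr) {
    do.call(rbind, lapply(CLASS_MARKS, function(mk) {
      sub <- calls[calls$pair == pr & calls$mark == mk & calls$klass %in% c("I", "II", "III"), ]
      if (nrow(sub) == 0) return(NULL)
      cp <- class_proportions(calls, pair = pr, mark = mk)
      cbind(pair = pr, mark = mk, cp, stringsAsFactors = FALSE)
    }))
  }))

  say("calling convergence")
  ancn <- calls[calls$pair == "An-Cn", ]
  arco <- calls[calls$pair == "Ar-Co", ]
  convergence <- do.call(rbind, lapply(CLASS_MARKS, function(mk) {
    rbind(call_epigenomic_convergence(ancn, arco, mk),
          call_sequence_convergence(ancn, arco, mk))
  }))
  conv_summary <- convergence_summary(convergence)
  expr_conv <- call_expression_convergence(inp$expression, tetrads,
                                           fc_threshold = th$fc_threshold)

  say("expression statistics")
  tpm_of <- function(g) {
    v <- inp$expression[[g]][tetrads[[g]]]; v[is.na(v)] <- 0; unname(v)
  }
  ar <- tpm_of("Ar"); co <- tpm_of("Co"); an <- tpm_of("An"); cn <- tpm_of("Cn")
  divergence <- data.frame(
    tetrad_id = tetrads$tetrad_id,
    log2fc_ArAn = log2_fold_change(ar, an), log2fc_CoCn = log2_fold_change(co, cn),
    log2fc_ArCo = log2_fold_change(ar, co), log2fc_AnCn = log2_fold_change(an, cn))
  bins <- rbind(data.frame(pair = "Ar-Co", bin = TPM_DIFF_BINS,
                           count = as.integer(tpm_diff_bins(ar, co))),
                data.frame(pair = "An-Cn", bin = TPM_DIFF_BINS,
                           count = as.integer(tpm_diff_bins(an, cn))))
  # divergent-pair contingency (|log2FC| > fc_threshold): diploids vs subgenomes
  n_t <- nrow(tetrads)
  div_tab <- matrix(c(sum(divergence$log2fc_ArCo > th$fc_threshold),
                      n_t - sum(divergence$log2fc_ArCo > th$fc_threshold),
                      sum(divergence$log2fc_AnCn > th$fc_threshold),
                      n_t - sum(divergence$log2fc_AnCn > th$fc_threshold)),
                    2, 2, byrow = TRUE)
  div_chi2 <- tryCatch(chi_square_2x2(div_tab), error = function(e) NULL)
  marked <- do.call(rbind, lapply(MARKS, function(mk) {
    has_peak <- function(g) {
      vapply(tetrads[[g]], function(gid) {
        any(peaks_local[[g]][[gid]]$mark == mk)
      }, logical(1))
    }
    n_ar <- sum(has_peak("Ar")); n_an <- sum(has_peak("An"))
    n_co <- sum(has_peak("Co")); n_cn <- sum(has_peak("Cn"))
    data.frame(mark = mk, Ar = n_ar, An = n_an, Co = n_co, Cn = n_cn,
               shift_ArAn = marked_gene_shift(n_ar, n_an, n_t),
               shift_CoCn = marked_gene_shift(n_co, n_cn, n_t),
               stringsAsFactors = FALSE)
  }))
  signal_cor <- do.call(rbind, lapply(MARKS, function(mk) {
    do.call(rbind, lapply(GENOME_LABELS, function(g) {
      sig <- vapply(tetrads[[g]], function(gid) {
        pk <- peaks_local[[g]][[gid]]
        s <- pk$score[pk$mark == mk]
        if (length(s)) max(s) else 0
      }, numeric(1))
      tpm <- inp$expression[[g]][tetrads[[g]]]; tpm[is.na(tpm)] <- 0
      r <- tryCatch(signal_expression_correlation(sig, unname(tpm)),
                    error = function(e) NA_real_)
      data.frame(mark = mk, genome = g, pearson_r = r, stringsAsFactors = FALSE)
    }))
  }))

  say("TFBS scanning")
  hits <- lapply(setNames(GENOME_LABELS, GENOME_LABELS), function(g) {
    per_gene <- lapply(promoters[[g]], function(pr) {
      scan_promoter_library(pr$seq, inp$pwms, threshold = th$motif_score)
    })
    tab <- do.call(rbind, per_gene)
    tab$gene_id <- rep(names(per_gene), vapply(per_gene, nrow, integer(1)))
    list(per_gene = per_gene, table = tab)
  })
  cs_of <- function(tet_g, dip_g) {
    vapply(seq_len(n_t), function(i) {
      tfbs_conservation_score(hits[[tet_g]]$per_gene[[tetrads[[tet_g]][i]]],
                              hits[[dip_g]]$per_gene[[tetrads[[dip_g]][i]]])$cs
    }, numeric(1))
  }
  cs_an <- cs_of("An", "Ar"); cs_cn <- cs_of("Cn", "Co")
  cs_table <- data.frame(tetrad_id = tetrads$tetrad_id, cs_An = cs_an, cs_Cn = cs_cn)
  high_cs <- c(An = tryCatch(high_conservation_fraction(cs_an, th$cs_cutoff),
                             error = function(e) NA_real_),
               Cn = tryCatch(high_conservation_fraction(cs_cn, th$cs_cutoff),
                             error = function(e) NA_real_))
  targets <- tf_target_counts(lapply(hits, `[[`, "table"), tetrads)

  say("variant calling")
  motif_lengths <- vapply(inp$pwms, function(p) ncol(p$prob), integer(1))
  variant_stage <- function(dip_g, tet_g) {
    key <- paste0(dip_g, "-", tet_g)
    rows <- list(); per_gene_len <- numeric(n_t)
    fr_acc <- matrix(0, 2, 3, dimnames = list(c("hit", "n"), c("SNV", "InDel", "SV")))
    for (i in seq_len(n_t)) {
      aln <- swap_alignment(alignments[[key]][[tetrads$tetrad_id[i]]])
      tet_gene <- tetrads[[tet_g]][i]; dip_gene <- tetrads[[dip_g]][i]
      attr(aln, "seq_a_chars") <- strsplit(promoters[[tet_g]][[tet_gene]]$seq, "")[[1]]
      attr(aln, "seq_b_chars") <- strsplit(promoters[[dip_g]][[dip_gene]]$seq, "")[[1]]
      v <- call_variants(aln)
      per_gene_len[i] <- sum(v$length)
      th_hits <- hits[[tet_g]]$per_gene[[tet_gene]]
      td_hits <- hits[[dip_g]]$per_gene[[dip_gene]]
      conserved <- th_hits$motif_id %in% unique(td_hits$motif_id)
      ov <- overlap_with_tfbs(v, th_hits, conserved, motif_lengths)
      v <- ov$variants
      if (nrow(v)) {
        v$tetrad_id <- tetrads$tetrad_id[i]; v$pair <- key
        rows[[length(rows) + 1L]] <- v[, c("tetrad_id", "pair", "vtype", "position",
                                           "length", "overlaps_nonconserved_tfbs")]
      }
      for (t in colnames(fr_acc)) {
        sel <- v$vtype == t
        fr_acc["n", t] <- fr_acc["n", t] + sum(sel)
        fr_acc["hit", t] <- fr_acc["hit", t] + sum(v$overlaps_nonconserved_tfbs[sel])
      }
    }
    list(variants = if (length(rows)) do.call(rbind, rows) else NULL,
         per_gene_length = per_gene_len,
         overlap_fraction = fr_acc["hit", ] / pmax(fr_acc["n", ], 1),
         counts = fr_acc["n", ])
  }
  var_an <- variant_stage("Ar", "An")
  var_cn <- variant_stage("Co", "Cn")
  var_summary <- rbind(
    data.frame(pair = "Ar-An", vtype = names(var_an$counts),
               count = as.integer(var_an$counts),
               overlap_nonconserved_tfbs = var_an$overlap_fraction),
    data.frame(pair = "Co-Cn", vtype = names(var_cn$counts),
               count = as.integer(var_cn$counts),
               overlap_nonconserved_tfbs = var_cn$overlap_fraction))
  len_vs_cs <- tryCatch(
    variation_length_vs_cs(c(var_an$per_gene_length, var_cn$per_gene_length),
                           c(cs_an, cs_cn)),
    error = function(e) list(rho = NA_real_, p_value = NA_real_))

  # expression divergence of convergent vs Class III tetrads (An-Cn);
  # groups made mutually exclusive so other-mark divergence does not blur the
  # contrast
  conv_any <- unique(convergence$tetrad_id[convergence$layer == "epigenomic" &
                                           convergence$category == "convergent"])
  cls3_any <- unique(ancn$tetrad_id[ancn$klass == "III"])
  epi_conv_ids <- setdiff(conv_any, cls3_any)
  cls3_ids <- setdiff(cls3_any, conv_any)
  conv_vs_class3 <- if (length(epi_conv_ids) >= 3 && length(cls3_ids) >= 3) {
    wt <- wilcox.test(divergence$log2fc_AnCn[match(epi_conv_ids, tetrads$tetrad_id)],
                      divergence$log2fc_AnCn[match(cls3_ids, tetrads$tetrad_id)],
                      alternative = "less")
    list(p_value = wt$p.value,
         median_convergent = stats::median(divergence$log2fc_AnCn[match(epi_conv_ids, tetrads$tetrad_id)]),
         median_class3 = stats::median(divergence$log2fc_AnCn[match(cls3_ids, tetrads$tetrad_id)]))
  } else list(p_value = NA_real_, median_convergent = NA_real_, median_class3 = NA_real_)

  say("writing outputs")
  tables <- list(
    tetrads = tetrads,
    pair_calls = calls,
    class_summary = class_summary,
    convergence_calls = convergence,
    convergence_summary = conv_summary,
    expression_convergence = expr_conv,
    expression_divergence = divergence,
    tpm_diff_bins = bins,
    marked_genes = marked,
    signal_expression = signal_cor,
    tfbs_conservation = cs_table,
    tf_target_comparison = targets$comparison,
    variant_summary = var_summary)
  files <- write_results(tables, outdir)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  structure(list(tetrads = tetrads, calls = calls, class_summary = class_summary,
                 convergence = convergence, convergence_summary = conv_summary,
                 expression_convergence = expr_conv, divergence = divergence,
                 tpm_diff_bins = bins, divergent_pair_chi2 = div_chi2,
                 marked_genes = marked, signal_expression = signal_cor,
                 cs_table = cs_table, high_cs = high_cs,
                 tf_targets = targets, variant_summary = var_summary,
                 variants = list(`Ar-An` = var_an, `Co-Cn` = var_cn),
                 variation_length_vs_cs = len_vs_cs,
                 conv_vs_class3 = conv_vs_class3,
                 thresholds = th, manifest = manifest, outdir = outdir),
            class = "homeoconverge_run")
}

#' @export
print.homeoconverge_run <- function(x, ...) {
  cat("homeoconverge pipeline run\n")
  cat(sprintf("  tetrads: %d\n", nrow(x$tetrads)))
  cat(sprintf("  pair calls: %d (marks: %s)\n", nrow(x$calls),
              paste(unique(x$calls$mark), collapse = ", ")))
  cat(sprintf("  high TFBS conservation (CS > %.2g): An %.1f%%, Cn %.1f%%\n",
              x$thresholds$cs_cutoff, 100 * x$high_cs[["An"]], 100 * x$high_cs[["Cn"]]))
  cat(sprintf("  outputs: %s\n", x$outdir))
  invisible(x)
}
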