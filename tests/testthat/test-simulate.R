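test_that("simulation config validates its inputs", {
  expect_error(sim_config(n_tetrads = 0), "n_tetrads")
  expect_error(sim_config(class_mix = c(I = 0.5, II = 0.5, III = 0.5)), "sum to 1")
  expect_error(sim_config(snv_rate = 1.5), "rates")
  expect_error(sim_config(sv_len_range = c(30, 40)), "50 bp")
})

test_that("fixed seed gives byte-identical benchmark output", {
  d1 <- file.path(withr::local_tempdir(), "s1")
  d2 <- file.path(withr::local_tempdir(), "s2")
  cfg <- sim_config(n_tetrads = 10, seed = 1)
  simulate_benchmark(cfg, d1)
  simulate_benchmark(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the sequences
  simulate_benchmark(sim_config(n_tetrads = 10, seed = 2), d2)
  expect_false(identical(readLines(file.path(d1, "genome_Ar.fa")),
                         readLines(file.path(d2, "genome_Ar.fa"))))
})

test_that("promoters span 1.5 kb upstream and 0.5 kb downstream of the TSS", {
  cfg <- sim_config_zero_noise(n_tetrads = 6, seed = 3)
  bench <- simulate_benchmark(cfg, file.path(withr::local_tempdir(), "zn"))
  for (g in c("Ar", "An")) {
    proms <- extract_promoters(bench$genes[[g]], bench$assemblies[[g]])
    expect_true(all(vapply(proms, function(p) nchar(p$seq), numeric(1)) == 2000))
    for (p in proms) {
      gm <- bench$genes[[g]][bench$genes[[g]]$gene_id == p$gene_id, ]
      expect_true(gm$tss >= p$start && gm$tss < p$end)
    }
  }
})

test_that("zero divergence makes all four promoters identical", {
  cfg <- sim_config_zero_noise(n_tetrads = 5, seed = 4)
  bench <- simulate_benchmark(cfg, file.path(withr::local_tempdir(), "zn2"))
  proms <- lapply(c(Ar = "Ar", Co = "Co", An = "An", Cn = "Cn"), function(g) {
    extract_promoters(bench$genes[[g]], bench$assemblies[[g]])
  })
  for (i in seq_len(5)) {
    seqs <- vapply(names(proms), function(g) {
      proms[[g]][[bench$tetrads[[g]][i]]]$seq
    }, character(1))
    expect_equal(length(unique(seqs)), 1L)
  }
})

test_that("emitted peaks sit on the truth windows in every genome", {
  cfg <- sim_config(n_tetrads = 20, seed = 6)
  bench <- simulate_benchmark(cfg, file.path(withr::local_tempdir(), "pk"))
  for (g in c("Ar", "Cn")) {
    proms <- suppressWarnings(extract_promoters(bench$genes[[g]], bench$assemblies[[g]]))
    pk <- bench$peaks[[g]]
    # every emitted peak lies within its gene's promoter window
    for (r in seq_len(nrow(pk))) {
      covered <- any(vapply(proms, function(p) {
        p$chrom == pk$chrom[r] && pk$start[r] >= p$start && pk$end[r] <= p$end
      }, logical(1)))
      expect_true(covered)
    }
  }
})

test_that("expression noise grows with pair class and marks act multiplicatively", {
  # mark_effect = 1 isolates the class-dependent noise: Class III pairs must
  # diverge more than all-Class-I pairs purely through sigma_III > sigma_I
  cfg <- sim_config(n_tetrads = 1000, seed = 8, mark_effect = 1,
                    conv_epi_prob = 0, conv_seq_prob = 0)
  anc <- simulate_ancestor(cfg)
  drv <- derive_four_genomes(anc, cfg)
  expr <- simulate_expression(drv, cfg)
  cl <- apply(drv$truth$pair_class[, , "Ar-An"], 1, function(x) {
    c("I", "II", "III")[max(match(x, c("I", "II", "III")))]
  })
  fc <- log2_fold_change(expr$Ar[drv$tetrads$Ar], expr$An[drv$tetrads$An])
  expect_gt(median(fc[cl == "III"]), median(fc[cl == "I"]))
  wt3 <- wilcox.test(fc[cl == "III"], fc[cl == "I"], alternative = "greater")
  expect_lt(wt3$p.value, 0.001)

  # with the default mark effect, an activating peak in one member shifts
  # the pair's expression ratio by about log2(mark_effect)
  cfg_m <- sim_config(n_tetrads = 500, seed = 18,
                      expression_sigma = c(I = 0.1, II = 0.1, III = 0.1),
                      conv_epi_prob = 0, conv_seq_prob = 0)
  anc_m <- simulate_ancestor(cfg_m)
  drv_m <- derive_four_genomes(anc_m, cfg_m)
  expr_m <- simulate_expression(drv_m, cfg_m)
  pp <- drv_m$truth$peak_present
  k4_only_diff <- pp[, "H3K4me3", "Ar"] != pp[, "H3K4me3", "An"] &
    apply(pp[, c("H3K4me1", "H3K27me3", "H3K9me2", "ACR"), "Ar"] ==
          pp[, c("H3K4me1", "H3K27me3", "H3K9me2", "ACR"), "An"], 1, all)
  fc_m <- log2_fold_change(expr_m$Ar[drv_m$tetrads$Ar], expr_m$An[drv_m$tetrads$An])
  expect_equal(median(fc_m[k4_only_diff]), log2(cfg_m$mark_effect), tolerance = 0.15)

  # null dataset: no mark effect, equal sigmas -> divergence independent of class
  cfg0 <- sim_config(n_tetrads = 600, seed = 9, mark_effect = 1,
                     expression_sigma = c(I = 0.5, II = 0.5, III = 0.5),
                     conv_epi_prob = 0, conv_seq_prob = 0)
  anc0 <- simulate_ancestor(cfg0)
  drv0 <- derive_four_genomes(anc0, cfg0)
  expr0 <- simulate_expression(drv0, cfg0)
  cl0 <- apply(drv0$truth$pair_class[, , "Ar-An"], 1, function(x) {
    c("I", "II", "III")[max(match(x, c("I", "II", "III")))]
  })
  fc0 <- log2_fold_change(expr0$Ar[drv0$tetrads$Ar], expr0$An[drv0$tetrads$An])
  wt <- wilcox.test(fc0[cl0 == "III"], fc0[cl0 == "I"])
  expect_gt(wt$p.value, 0.001)  # no detectable class effect under the null
})

test_that("truth labels re-derive from the emitted files (generator self-audit)", {
  run <- benchmark_run_small()
  truth <- read_truth(run, "pairs")
  key <- function(d) paste(d$tetrad_id, d$pair, d$mark)
  m <- match(key(run$calls), key(truth))
  expect_false(anyNA(m))
  sel <- truth$klass[m] %in% c("I", "II", "III")
  expect_gte(mean(run$calls$klass[sel] == truth$klass[m][sel]), 0.95)
})
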