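test_that("mismatches become SNVs, gap runs split at the 50 bp boundary", {
  set.seed(71)
  a <- random_seq(300)
  b <- a
  substr(b, 120, 120) <- setdiff(c("A", "C", "G", "T"), substr(a, 120, 120))[1]
  v <- call_variants_pair(a, b)
  expect_equal(nrow(v), 1L)
  expect_equal(v$vtype, "SNV")
  expect_equal(v$length, 1L)
  expect_equal(v$position, 119L)

  # 50 bp deletion in B -> InDel; 51 bp -> SV (boundary law)
  del50 <- paste0(substr(a, 1, 100), substr(a, 151, 300))
  v50 <- call_variants_pair(a, del50)
  expect_equal(v50$vtype[v50$length == 50], "InDel")
  del51 <- paste0(substr(a, 1, 100), substr(a, 152, 300))
  v51 <- call_variants_pair(a, del51)
  expect_equal(v51$vtype[v51$length == 51], "SV")
  expect_false(any(v50$length == 50 & v50$vtype == "SV"))
  expect_false(any(v51$length == 51 & v51$vtype == "InDel"))
})

test_that("adjacent mismatch columns stay separate SNVs", {
  a <- paste0(strrep("A", 20), "CCC", strrep("A", 20))
  b <- paste0(strrep("A", 20), "GGG", strrep("A", 20))
  v <- call_variants_pair(a, b)
  expect_equal(sum(v$vtype == "SNV"), 3L)
  expect_true(all(v$length == 1))
})

test_that("variant round trip reconstructs the partner sequence exactly", {
  set.seed(72)
  for (i in 1:60) {
    a <- random_seq(sample(300:800, 1))
    b <- mutate_seq(a, sub_rate = 0.03, n_indels = sample(0:3, 1), indel_max = 70)
    v <- call_variants_pair(a, b)
    expect_identical(apply_variants(a, v), b)
  }
})

test_that("variant counts are stable under member swap up to polarity", {
  set.seed(73)
  a <- random_seq(500)
  b <- mutate_seq(a, 0.02, 2, 60)
  v_ab <- call_variants_pair(a, b)
  v_ba <- call_variants_pair(b, a)
  expect_equal(sum(v_ab$vtype == "SNV"), sum(v_ba$vtype == "SNV"))
  expect_equal(sort(v_ab$length[v_ab$vtype != "SNV"]),
               sort(v_ba$length[v_ba$vtype != "SNV"]))
})

test_that("nonconserved-TFBS overlap is half-open and by-type", {
  hits <- data.frame(motif_id = c("m1", "m2"), offset = c(100L, 300L),
                     strand = "+", log_odds = 12, stringsAsFactors = FALSE)
  lens <- c(m1 = 10L, m2 = 10L)
  conserved <- c(FALSE, TRUE)  # m1 nonconserved
  vars <- data.frame(vtype = c("SNV", "SV", "SNV"),
                     position = c(105L, 95L, 300L),
                     length = c(1L, 80L, 1L),
                     seq_a = "A", seq_b = "C", stringsAsFactors = FALSE)
  out <- overlap_with_tfbs(vars, hits, conserved, lens)
  expect_true(out$variants$overlaps_nonconserved_tfbs[1])   # inside m1 window
  expect_true(out$variants$overlaps_nonconserved_tfbs[2])   # SV straddles m1
  expect_false(out$variants$overlaps_nonconserved_tfbs[3])  # m2 is conserved
  # adjacency does not count: variant ending exactly at window start
  adj <- data.frame(vtype = "SV", position = 20L, length = 80L,
                    seq_a = "A", seq_b = "-", stringsAsFactors = FALSE)
  expect_false(overlap_with_tfbs(adj, hits, conserved, lens)$variants$overlaps_nonconserved_tfbs)
  expect_error(overlap_with_tfbs(vars, hits, TRUE, lens), "mismatch")
})

test_that("longer variants overlap nonconserved sites more often (geometry)", {
  # uniform variant placement against fixed nonconserved windows: the overlap
  # probability grows with footprint length; compare observed fractions with
  # the analytic expectation (window + footprint - 1 positions out of n)
  set.seed(74)
  n <- 2000L
  win <- c(1000L, 1010L)  # one nonconserved 10 bp hit
  hits <- data.frame(motif_id = "m1", offset = win[1], strand = "+",
                     log_odds = 12, stringsAsFactors = FALSE)
  frac <- vapply(c(1L, 60L), function(len) {
    pos <- sample.int(n - len, 3000L, replace = TRUE) - 1L
    vars <- data.frame(vtype = ifelse(len > 50, "SV", "SNV"), position = pos,
                       length = len, seq_a = "A", seq_b = "C",
                       stringsAsFactors = FALSE)
    out <- overlap_with_tfbs(vars, hits, FALSE, c(m1 = 10L))
    mean(out$variants$overlaps_nonconserved_tfbs)
  }, numeric(1))
  expect_gt(frac[2], frac[1])
  expect_equal(frac[1], 10 / (n - 1), tolerance = 0.5)
  expect_equal(frac[2], (10 + 60 - 1) / (n - 60), tolerance = 0.3)
})

test_that("variant burden anticorrelates with TFBS conservation", {
  # constructed: CS strictly decreasing in variant length
  expect_equal(variation_length_vs_cs(1:10, seq(1, 0.1, length.out = 10))$rho, -1)
  expect_error(variation_length_vs_cs(1:10, rep(0.5, 10)), "zero variance")
  run <- benchmark_run_2000()
  expect_lt(run$variation_length_vs_cs$rho, 0)
  expect_lt(run$variation_length_vs_cs$p_value, 0.01)
})

test_that("zero-divergence simulation yields zero variants", {
  run <- benchmark_run_zero()
  expect_equal(sum(run$variant_summary$count), 0L)
})
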