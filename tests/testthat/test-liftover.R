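test_that("promoter extraction is strand-aware and clipped at ends", {
  fa <- Biostrings::DNAStringSet(setNames(paste(rep("ACGT", 2500), collapse = ""), "c1"))
  f <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(fa, f)
  asm <- read_genome_fasta(f)

  plus <- list(gene_id = "p", chrom = "c1", strand = "+", tss = 5000L)
  pr <- extract_promoter(as.data.frame(plus), asm)
  expect_equal(c(pr$start, pr$end), c(3500L, 5500L))
  expect_equal(nchar(pr$seq), 2000L)
  expect_equal(pr$seq, substr(asm[["c1"]], 3501, 5500))

  minus <- list(gene_id = "m", chrom = "c1", strand = "-", tss = 5000L)
  pm <- extract_promoter(as.data.frame(minus), asm)
  expect_equal(c(pm$start, pm$end), c(4500L, 6500L))
  sub <- substr(asm[["c1"]], 4501, 6500)
  expect_equal(pm$seq, as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub))))

  near <- list(gene_id = "n", chrom = "c1", strand = "+", tss = 100L)
  expect_warning(pn <- extract_promoter(as.data.frame(near), asm), "clipped")
  expect_equal(c(pn$start, pn$end), c(0L, 600L))
  expect_true(pn$clipped)
})

test_that("global alignment handles identity, substitutions, and scoring", {
  s <- random_seq(100)
  aln <- align_promoters(s, s)
  expect_equal(aln$identity, 1)
  expect_equal(aln$coverage_a, 1)
  expect_equal(aln$score, 200)

  s2 <- s
  substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"), substr(s, 50, 50))[1]
  aln2 <- align_promoters(s, s2)
  expect_equal(sum(!aln2$match), 1L)
  expect_equal(which(!aln2$match), 50L)

  expect_error(align_promoters("ACGT", ""), "empty")
  expect_error(align_promoters("ACXT", "ACGT"), "non-ACGTN")
})

test_that("N bases align as mismatch, never match", {
  aln <- align_promoters("ANNGT", "ANNGT")
  expect_equal(sum(aln$match), 3L)  # A, G, T only
})

test_that("alignment score equals independent full-matrix oracle (<= 300 bp)", {
  set.seed(401)
  for (i in 1:25) {
    n <- sample(50:300, 1)
    a <- random_seq(n)
    b <- if (i %% 2 == 0) mutate_seq(a, 0.05, 2, 40) else random_seq(sample(50:300, 1))
    expect_equal(align_promoters(a, b)$score, oracle_align_score(a, b))
  }
})

test_that("alignment recovers implanted edits in long promoters", {
  set.seed(402)
  a <- random_seq(2000)
  # one substitution at 500 (0-based 499) and a 20 bp deletion at 1200
  b <- a
  substr(b, 500, 500) <- setdiff(c("A", "C", "G", "T"), substr(a, 500, 500))[1]
  b <- paste0(substr(b, 1, 1200), substr(b, 1221, 2000))
  aln <- align_promoters(a, b)
  expect_equal(aln$score, oracle_align_score(a, b))
  mism <- which(!aln$match & !is.na(aln$pos_a) & !is.na(aln$pos_b))
  expect_equal(aln$pos_a[mism], 499L)
  gap_cols <- which(is.na(aln$pos_b))
  expect_length(gap_cols, 20L)
  expect_true(all(diff(gap_cols) == 1))
})

test_that("interval lift-over: identity, deletions, and straddled insertions", {
  s <- random_seq(50)
  aln <- align_promoters(s, s)
  # exhaustive round trip over all subintervals of a 50 bp promoter
  for (st in 0:49) {
    for (en in (st + 1):50) {
      lf <- lift_interval(c(st, en), aln)
      expect_equal(lf$target, c(st, en))
      expect_equal(lf$lifted_fraction, 1)
      back <- lift_interval(lf$target, aln, direction = "b2a")
      expect_equal(back$target, c(st, en))
    }
  }

  # interval entirely inside a 60 bp deletion in B
  a <- random_seq(300)
  b <- paste0(substr(a, 1, 100), substr(a, 161, 300))
  aln <- align_promoters(a, b)
  lf <- lift_interval(c(110, 140), aln)
  expect_null(lf$target)
  expect_equal(lf$lifted_fraction, 0)

  # interval straddling a 10 bp insertion in B: target widens by 10
  ins <- paste0(substr(a, 1, 150), random_seq(10), substr(a, 151, 300))
  aln <- align_promoters(a, ins)
  lf <- lift_interval(c(140, 160), aln)
  expect_equal(lf$lifted_fraction, 1)
  expect_equal(diff(lf$target), 30)

  expect_error(lift_interval(c(-5, 10), aln), "outside")
})

test_that("lifted fraction decreases as gap edits accumulate inside the interval", {
  set.seed(403)
  a <- random_seq(400)
  fractions <- numeric(4)
  b <- a
  for (k in 1:4) {
    # delete successive 15 bp blocks inside [100, 200)
    cut <- 100 + (k - 1) * 20
    b <- paste0(substr(b, 1, cut), substr(b, cut + 16, nchar(b)))
    aln <- align_promoters(a, b)
    fractions[k] <- lift_interval(c(100, 200), aln)$lifted_fraction
  }
  expect_true(all(diff(fractions) <= 0))
})
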