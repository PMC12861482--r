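pwms <- read_pwm_library(packaged_pwm_library())

test_that("PWM library parses into normalised probability matrices", {
  expect_gte(length(pwms), 10L)
  for (p in pwms) {
    expect_equal(unname(colSums(p$prob)), rep(1, ncol(p$prob)), tolerance = 1e-9)
    expect_gte(ncol(p$prob), 4L)
  }
  # round trip through the writer
  f <- withr::local_tempfile(fileext = ".jaspar")
  write_pwm_library(pwms[1:2], f)
  back <- read_pwm_library(f)
  expect_equal(back[[1]]$prob, pwms[[1]]$prob, tolerance = 1e-3)
})

test_that("consensus scores match direct computation; uniform PWM never hits", {
  p <- pwms[[1]]
  cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)], collapse = "")
  seq <- paste0(strrep("A", 30), cons, strrep("A", 30))
  hits <- scan_promoter(seq, p, threshold = 10)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$offset, 30L)
  expect_equal(fwd$log_odds, sum(apply(p$logodds, 2, max)), tolerance = 1e-9)

  unif <- list(motif_id = "U",
                           prob = matrix(0.25, 4, 10,
                                         dimnames = list(c("A", "C", "G", "T"), NULL)),
                           logodds = matrix(0, 4, 10))
  expect_equal(nrow(scan_promoter(random_seq(500), unif, threshold = 0)), 0L)
})

test_that("reverse-complement of the consensus scores equally on the minus strand", {
  p <- pwms[[2]]
  cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)], collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  seq <- paste0(strrep("C", 25), rc, strrep("C", 25))
  hits <- scan_promoter(seq, p, threshold = 10)
  minus <- hits[hits$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$offset, 25L)
  expect_equal(minus$log_odds, sum(apply(p$logodds, 2, max)), tolerance = 1e-9)
})

test_that("scanner equals brute-force all-window scoring on promoters <= 500 bp", {
  brute_scan <- function(seq, pwm, threshold) {
    bases <- c("A", "C", "G", "T")
    code <- strsplit(seq, "", fixed = TRUE)[[1]]
    ri <- match(code, bases)          # NA for N
    L <- ncol(pwm$logodds)
    out <- list()
    for (off in 0:(length(code) - L)) {
      win <- ri[(off + 1):(off + L)]
      if (anyNA(win)) next
      fwd <- sum(pwm$logodds[cbind(win, seq_len(L))])
      rev_ <- sum(pwm$logodds[cbind(rev(5 - win), seq_len(L))])
      if (fwd > threshold) out[[length(out) + 1]] <- c(off, 1, fwd)
      if (rev_ > threshold) out[[length(out) + 1]] <- c(off, -1, rev_)
    }
    do.call(rbind, out)
  }
  set.seed(61)
  for (rep in 1:5) {
    seq <- random_seq(sample(200:500, 1))
    # implant two noisy consensus copies so hits exist
    for (p in pwms[sample(length(pwms), 2)]) {
      cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)], collapse = "")
      off <- sample(nchar(seq) - nchar(cons), 1)
      substr(seq, off, off + nchar(cons) - 1) <- cons
    }
    for (p in pwms) {
      got <- scan_promoter(seq, p, threshold = 8)
      want <- brute_scan(seq, p, threshold = 8)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(nrow(got), nrow(want))
        o <- order(got$offset, got$strand)
        w <- want[order(want[, 1], ifelse(want[, 2] > 0, "+", "-")), , drop = FALSE]
        expect_equal(got$offset[o], as.integer(w[, 1]))
        expect_equal(got$log_odds[o], w[, 3], tolerance = 1e-9)
      }
    }
  }
})

test_that("windows containing N are skipped", {
  p <- pwms[[1]]
  cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)], collapse = "")
  broken <- cons
  substr(broken, 3, 3) <- "N"
  expect_equal(nrow(scan_promoter(paste0("AAAA", broken, "AAAA"), p, 0)), 0L)
})

test_that("conservation score counts shared-motif hits on the tetraploid side", {
  h <- function(ids) data.frame(motif_id = ids, offset = seq_along(ids) * 20L,
                                strand = rep("+", length(ids)),
                                log_odds = rep(12, length(ids)),
                                stringsAsFactors = FALSE)
  expect_equal(tfbs_conservation_score(h(c("a", "b")), h(c("a", "b")))$cs, 1)
  cs <- tfbs_conservation_score(h(c("a", "b", "c", "d")), h("a"))
  expect_equal(cs$cs, 0.25)
  expect_equal(cs$n_conserved, 1L)
  none <- tfbs_conservation_score(h(character(0)), h("a"))
  expect_true(is.na(none$cs))
  # monotone non-increasing under additional tetraploid-only gains
  base_ids <- c("a", "b")
  cs_seq <- vapply(0:3, function(k) {
    gains <- if (k == 0) character(0) else paste0("x", 1:k)
    tfbs_conservation_score(h(c(base_ids, gains)), h(base_ids))$cs
  }, numeric(1))
  expect_true(all(diff(cs_seq) < 0))
})

test_that("identical promoters give CS = 1 end to end", {
  set.seed(62)
  seq <- random_seq(800)
  p <- pwms[[3]]
  cons <- paste(rownames(p$prob)[apply(p$prob, 2, which.max)], collapse = "")
  substr(seq, 100, 99 + nchar(cons)) <- cons
  hits <- scan_promoter_library(seq, pwms, 10)
  expect_gte(nrow(hits), 1L)
  expect_equal(tfbs_conservation_score(hits, hits)$cs, 1)
})

test_that("TF target counts and comparisons recover identity and scaling", {
  n <- 40
  tets <- data.frame(tetrad_id = sprintf("t%02d", 1:n),
                     Ar = sprintf("a%02d", 1:n), Co = sprintf("c%02d", 1:n),
                     An = sprintf("n%02d", 1:n), Cn = sprintf("m%02d", 1:n),
                     stringsAsFactors = FALSE)
  mk_hits <- function(genes, motif) {
    data.frame(motif_id = rep(motif, length(genes)), gene_id = genes,
               offset = 0L, strand = "+", log_odds = 12, stringsAsFactors = FALSE)
  }
  # per-motif gene counts 4, 8, 12 in every genome -> identity comparison
  per_genome <- function(ids) rbind(mk_hits(ids[1:4], "m1"),
                                    mk_hits(ids[1:8], "m2"),
                                    mk_hits(ids[1:12], "m3"))
  hits <- list(Ar = per_genome(tets$Ar), Co = per_genome(tets$Co),
               An = per_genome(tets$An), Cn = per_genome(tets$Cn))
  out <- tf_target_counts(hits, tets)
  expect_equal(unname(out$counts[, "Ar"]), c(4L, 8L, 12L))
  expect_true(all(out$comparison$r == 1))
  expect_true(all(abs(out$comparison$slope - 1) < 1e-12))
  expect_error(tf_target_counts(lapply(hits, function(h) h[h$motif_id == "m1", ]), tets),
               "2 motifs")

  # counts_Co = 2 x counts_Ar exactly: slope (y = Co on x = Ar) is 2
  doubled <- rbind(mk_hits(tets$Co[1:8], "m1"), mk_hits(tets$Co[1:16], "m2"),
                   mk_hits(tets$Co[1:24], "m3"))
  hits2 <- list(Ar = hits$Ar, Co = doubled, An = hits$An, Cn = hits$Cn)
  out2 <- tf_target_counts(hits2, tets, comparisons = list(c("Ar", "Co")))
  expect_equal(out2$comparison$slope, 2)
  # a duplicated hit in the same gene does not create a new target
  dup <- rbind(hits$Ar, mk_hits(tets$Ar[1], "m1"))
  out3 <- tf_target_counts(list(Ar = dup, Co = hits$Co, An = hits$An, Cn = hits$Cn),
                           tets, comparisons = list(c("Ar", "Co")))
  expect_equal(unname(out3$counts[, "Ar"]), c(4L, 8L, 12L))
})

test_that("implanted An-only motif gains raise the An-on-Ar slope above 1", {
  out <- file.path(tempdir(), "hc_gain")
  run <- run_pipeline(list(
    simulate = list(n_tetrads = 200, seed = 19, an_extra_motif_prob = 1,
                    tet_motif_gain_prob = 0, sv_prob = 0),
    outdir = out), quiet = TRUE)
  cmp <- run$tf_targets$comparison
  aran <- cmp[cmp$x == "Ar" & cmp$y == "An", ]
  expect_gt(aran$slope, 1)
  expect_gt(aran$r, 0.9)
})

test_that("high-conservation fraction uses a strict cutoff", {
  expect_equal(high_conservation_fraction(c(0.2, 0.61, 1.0)), 2 / 3)
  expect_equal(high_conservation_fraction(rep(0.6, 5)), 0)
  expect_equal(high_conservation_fraction(c(NA, 0.7)), 1)
  expect_error(high_conservation_fraction(NA_real_), "no non-null")
})

test_that("the An subgenome shows lower TFBS conservation than Cn", {
  run <- benchmark_run_2000()
  expect_lt(run$high_cs[["An"]], run$high_cs[["Cn"]])
  expect_lt(mean(run$cs_table$cs_An, na.rm = TRUE),
            mean(run$cs_table$cs_Cn, na.rm = TRUE))
})
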