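test_that("reciprocal best hits: identity, ties, and noisy recovery", {
  a <- setNames(c("ACGTACGTACGTACGTACGT"), "gA")
  b <- setNames(c("ACGTACGTACGTACGTACGT"), "gB")
  bh <- best_hits(a, b, top_candidates = 3)
  expect_equal(nrow(bh), 1L)
  expect_equal(bh$cscore, 1)
  expect_false(bh$ambiguous)

  # two equally scoring partners: lexicographic tie-break, flagged ambiguous
  twin <- setNames(rep("ACGTACGTACGTACGTACGT", 2), c("gB2", "gB1"))
  bh2 <- best_hits(a, twin)
  expect_equal(bh2$gene_b, "gB1")
  expect_true(bh2$ambiguous)

  expect_error(best_hits(character(0), b), "empty")

  # 20 simulated genes at ~5% divergence: all true pairs recovered
  set.seed(31)
  ga <- setNames(replicate(20, random_seq(300)), sprintf("a%02d", 1:20))
  gb <- setNames(vapply(ga, mutate_seq, "", sub_rate = 0.05, n_indels = 1,
                        indel_max = 8), sprintf("b%02d", 1:20))
  bh3 <- best_hits(ga, gb)
  expect_equal(nrow(bh3), 20L)
  expect_equal(sub("a", "", bh3$gene_a), sub("b", "", bh3$gene_b))
})

test_that("collinearity filtering keeps chains and drops isolated pairs", {
  genes_a <- sprintf("a%02d", 1:10)
  genes_b <- sprintf("b%02d", 1:10)
  pairs <- data.frame(gene_a = genes_a, gene_b = genes_b,
                      score = 100, cscore = 1, ambiguous = FALSE,
                      stringsAsFactors = FALSE)
  kept <- collinear_chains(pairs, genes_a, genes_b)
  expect_equal(nrow(kept), 10L)

  # one isolated off-diagonal pair among 10 collinear is dropped
  pairs2 <- rbind(pairs, data.frame(gene_a = "a11", gene_b = "b30",
                                    score = 100, cscore = 1, ambiguous = FALSE))
  oa <- c(genes_a, "a11")
  ob <- c(genes_b, sprintf("b%02d", 11:30))
  kept2 <- collinear_chains(pairs2, oa, ob, max_gap = 5)
  expect_equal(sort(kept2$gene_a), sort(genes_a))

  # inverted block of 5 is kept (monotone decreasing allowed); verified
  # against brute-force enumeration of monotone chains on the toy instance
  inv <- data.frame(gene_a = sprintf("a%d", 1:5), gene_b = sprintf("b%d", 5:1),
                    score = 100, cscore = 1, ambiguous = FALSE,
                    stringsAsFactors = FALSE)
  brute_best_chain <- function(ra, rb, max_gap = 10) {
    n <- length(ra)
    best <- 0
    for (dirn in c(1, -1)) {
      for (mask in seq_len(2^n - 1)) {
        idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
        idx <- idx[order(ra[idx])]
        da <- diff(ra[idx]); db <- diff(dirn * rb[idx])
        if (length(idx) == 1 ||
            (all(da > 0 & da <= max_gap) && all(db > 0 & db <= max_gap))) {
          best <- max(best, length(idx))
        }
      }
    }
    best
  }
  expect_equal(brute_best_chain(1:5, 5:1), 5)
  kept3 <- collinear_chains(inv, sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  expect_equal(nrow(kept3), 5L)

  # cscore below threshold filtered even when collinear
  low <- pairs
  low$cscore[3] <- 0.9
  expect_equal(nrow(collinear_chains(low, genes_a, genes_b)), 9L)
})

test_that("tetrad assembly enforces strict 1:1:1:1", {
  p <- function(a, b) data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
  tet <- assemble_tetrads(p("ar1", "co1"), p("ar1", "an1"), p("co1", "cn1"))
  expect_equal(nrow(tet), 1L)
  expect_equal(unlist(tet[1, c("Ar", "Co", "An", "Cn")], use.names = FALSE),
               c("ar1", "co1", "an1", "cn1"))

  # an Ar gene mapping into two candidate quartets invalidates both
  tet2 <- assemble_tetrads(p(c("ar1", "ar2"), c("co1", "co1")),
                           p(c("ar1", "ar2"), c("an1", "an2")),
                           p("co1", "cn1"))
  expect_equal(nrow(tet2), 0L)

  # closed-quartet requirement rejects inconsistent An-Cn edges
  tet3 <- assemble_tetrads(p("ar1", "co1"), p("ar1", "an1"), p("co1", "cn1"),
                           p("an1", "cnX"), require_closed_quartet = TRUE)
  expect_equal(nrow(tet3), 0L)
})

test_that("tetrad recovery is complete on mutation-free simulation", {
  run <- benchmark_run_zero()
  truth <- read_truth(run, "tetrads")
  expect_equal(nrow(run$tetrads), nrow(truth))
  m <- match(run$tetrads$Ar, truth$Ar)
  expect_true(all(!is.na(m)))
  expect_equal(run$tetrads$Cn, truth$Cn[m])
})

test_that("tetrad recovery is high and false-quartet-free at default noise", {
  run <- benchmark_run_small()
  truth <- read_truth(run, "tetrads")
  m <- match(run$tetrads$Ar, truth$Ar)
  expect_true(all(!is.na(m)))  # no false quartets
  consistent <- run$tetrads$Co == truth$Co[m] & run$tetrads$An == truth$An[m] &
    run$tetrads$Cn == truth$Cn[m]
  expect_true(all(consistent))
  expect_gte(nrow(run$tetrads) / nrow(truth), 0.95)
})

test_that("raising the cscore threshold never increases the tetrad count", {
  set.seed(77)
  ga <- setNames(replicate(12, random_seq(200)), sprintf("a%02d", 1:12))
  gb <- setNames(vapply(ga, mutate_seq, "", sub_rate = 0.08, n_indels = 1,
                        indel_max = 6), sprintf("b%02d", 1:12))
  bh <- best_hits(ga, gb)
  n_at <- vapply(c(0.5, 0.9, 0.99, 1.0), function(cs) {
    nrow(collinear_chains(bh, names(ga), names(gb), min_cscore = cs))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})
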