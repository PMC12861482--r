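# Shared fixtures: benchmarks are generated once per test run and cached in
# the session; all fixtures are built in code, nothing is stored on disk.

.bench_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.bench_cache[[key]])) assign(key, maker(), envir = .bench_cache)
  get(key, envir = .bench_cache)
}

# full-scale truth-recovery run: 2000 tetrads, seed 42
benchmark_run_2000 <- function() {
  cached("run2000", function() {
    out <- file.path(tempdir(), "hc_bench2000")
    run_pipeline(list(simulate = list(n_tetrads = 2000, seed = 42), outdir = out),
                 quiet = TRUE)
  })
}

# small default-noise run for module-level checks: 200 tetrads
benchmark_run_small <- function() {
  cached("run200", function() {
    out <- file.path(tempdir(), "hc_bench200")
    run_pipeline(list(simulate = list(n_tetrads = 200, seed = 7), outdir = out),
                 quiet = TRUE)
  })
}

# zero-divergence run: identical genomes
benchmark_run_zero <- function() {
  cached("runzero", function() {
    out <- file.path(tempdir(), "hc_benchzero")
    run_pipeline(list(simulate = sim_config_zero_noise(n_tetrads = 40, seed = 5),
                      outdir = out), quiet = TRUE)
  })
}

read_truth <- function(run, what = c("pairs", "convergence", "tetrads", "motifs")) {
  what <- match.arg(what)
  read.delim(file.path(run$outdir, "sim", paste0("truth_", what, ".tsv")),
             stringsAsFactors = FALSE)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# introduce substitutions and indels into a sequence (for aligner fixtures)
mutate_seq <- function(s, sub_rate = 0.03, n_indels = 2, indel_max = 60) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- runif(length(ch)) < sub_rate
  ch[i] <- sample(c("A", "C", "G", "T"), sum(i), replace = TRUE)
  for (k in seq_len(n_indels)) {
    p <- sample(length(ch), 1)
    L <- sample(seq_len(indel_max), 1)
    if (runif(1) < 0.5) {
      ch <- append(ch, sample(c("A", "C", "G", "T"), L, replace = TRUE), after = p)
    } else {
      ch <- ch[-(p:min(p + L - 1, length(ch)))]
    }
  }
  paste(ch, collapse = "")
}

# independent alignment score oracle (Biostrings, same scoring scheme)
oracle_align_score <- function(a, b) {
  m <- matrix(-3, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  diag(m) <- 2
  m["N", "N"] <- -3
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = m, gapOpening = 5, gapExtension = 2))
}
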