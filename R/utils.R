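#' @useDynLib homeoconverge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats chisq.test cor cor.test coef lm rbinom rlnorm rnorm runif
#'   setNames wilcox.test
#' @importFrom utils read.table write.table modifyList
NULL

GENOME_LABELS <- c("Ar", "Co", "An", "Cn")
MARKS <- c("H3K4me3", "H3K4me1", "H3K27me3", "H3K9me2", "ACR")
ACTIVATING_MARKS <- c("H3K4me3", "ACR")
REPRESSIVE_MARKS <- c("H3K27me3", "H3K9me2")
# class analyses cover all marks except the heterochromatic H3K9me2
CLASS_MARKS <- c("H3K4me3", "H3K4me1", "H3K27me3", "ACR")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' @keywords internal
msg <- function(...) message("[homeoconverge] ", sprintf(...))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
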