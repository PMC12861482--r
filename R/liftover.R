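# Promoter extraction, pairwise promoter alignment, and interval lift-over.
# The genome-wide chain/net machinery of reference-based pipelines is replaced
# by one global affine-gap alignment per homoeologous promoter pair: the
# tetrads already provide synteny anchoring, so local chaining adds nothing at
# promoter scale and a single deterministic aligner keeps every lift testable
# against an oracle.

PROMOTER_UP <- 1500L
PROMOTER_DOWN <- 500L

#' Extract a promoter region around the TSS
#'
#' The promoter spans 1.5 kb upstream of the TSS and 0.5 kb downstream,
#' measured in transcription direction. On the minus strand "upstream" means
#' higher coordinates and the returned sequence is reverse-complemented so
#' that all promoters read 5'-to-3' in transcription direction. Windows are
#' clipped at chromosome ends (with a warning).
#'
#' @param gene One row of a gene-model data.frame (gene_id, chrom, strand, tss).
#' @param assembly `genome_assembly` containing the gene's chromosome.
#' @param upstream,downstream Window sizes in bp.
#' @return List with gene_id, chrom, start, end (0-based half-open genome
#'   interval), strand, clipped flag, and seq (transcription-direction DNA).
#' @export
extract_promoter <- function(gene, assembly, upstream = PROMOTER_UP, downstream = PROMOTER_DOWN) {
  L <- attr(assembly, "lengths")[[gene$chrom]]
  if (is.null(L)) stopf("gene %s on unknown chromosome %s", gene$gene_id, gene$chrom)
  tss <- gene$tss
  if (gene$strand == "+") {
    s <- tss - upstream; e <- tss + downstream
  } else {
    s <- tss - downstream; e <- tss + upstream
  }
  clipped <- s < 0 || e > L
  if (clipped) {
    warning(sprintf("promoter of %s clipped at chromosome end", gene$gene_id), call. = FALSE)
    s <- max(s, 0L); e <- min(e, L)
  }
  seq <- substr(assembly[[gene$chrom]], s + 1L, e)
  if (gene$strand == "-") seq <- revcomp(seq)
  list(gene_id = gene$gene_id, chrom = gene$chrom, start = as.integer(s),
       end = as.integer(e), strand = gene$strand, clipped = clipped, seq = seq)
}

#' Extract promoters for all genes of a genome
#' @param genes Gene-model data.frame.
#' @param assembly `genome_assembly`.
#' @inheritParams extract_promoter
#' @return Named list of promoter records (see [extract_promoter()]).
#' @export
extract_promoters <- function(genes, assembly, upstream = PROMOTER_UP, downstream = PROMOTER_DOWN) {
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    out[[i]] <- extract_promoter(genes[i, ], assembly, upstream, downstream)
  }
  names(out) <- genes$gene_id
  out
}

#' Globally align two promoter sequences
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gaps (match +2,
#' mismatch -3, gap open -5, gap extend -2; a gap of length L costs
#' 5 + 2L). N bases align as mismatch, never match. Traceback ties are
#' resolved deterministically: diagonal, then gap-in-A, then gap-in-B.
#'
#' @param seq_a,seq_b DNA strings (ACGTN).
#' @return Object of class `promoter_alignment`: list with `score`, `pos_a`,
#'   `pos_b` (0-based positions per alignment column, NA at gaps), `match`
#'   (logical per column), `identity` (matches / aligned columns),
#'   `coverage_a`, `coverage_b` (aligned fraction of each sequence).
#' @export
align_promoters <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stopf("empty sequence")
  aln <- .gotoh_align(seq_a, seq_b)
  aligned <- !is.na(aln$pos_a) & !is.na(aln$pos_b)
  aln$identity <- if (any(aligned)) sum(aln$match[aligned]) / sum(aligned) else 0
  aln$coverage_a <- sum(aligned) / nchar(seq_a)
  aln$coverage_b <- sum(aligned) / nchar(seq_b)
  aln$len_a <- nchar(seq_a)
  aln$len_b <- nchar(seq_b)
  class(aln) <- "promoter_alignment"
  aln
}

#' @export
print.promoter_alignment <- function(x, ...) {
  cat(sprintf("promoter alignment: %d x %d bp, score %.0f, identity %.3f, coverage %.3f/%.3f\n",
              x$len_a, x$len_b, x$score, x$identity, x$coverage_a, x$coverage_b))
  invisible(x)
}

#' Lift an interval across a promoter alignment
#'
#' Projects a 0-based half-open interval from one member of an aligned
#' promoter pair onto the other. The target is the [min, max) hull of aligned
#' partner positions of the interval's bases; the lift fails (NULL target)
#' when fewer than `min_lift` of the source bases have an aligned partner.
#'
#' @param iv Integer vector `c(start, end)`, 0-based half-open, in the source
#'   promoter's coordinates.
#' @param aln A `promoter_alignment`.
#' @param direction `"a2b"` or `"b2a"`.
#' @param min_lift Minimum aligned fraction of source bases for a successful
#'   lift (default 0.5).
#' @return List with `source`, `target` (or NULL), `lifted_fraction`, and
#'   `identity_in_region` (match fraction among the interval's aligned bases).
#' @export
lift_interval <- function(iv, aln, direction = "a2b", min_lift = 0.5) {
  direction <- direction[1]
  if (identical(direction, "a2b")) {
    src <- aln$pos_a; dst <- aln$pos_b; n_src <- aln$len_a
  } else if (identical(direction, "b2a")) {
    src <- aln$pos_b; dst <- aln$pos_a; n_src <- aln$len_b
  } else stopf("direction must be 'a2b' or 'b2a'")
  s <- iv[1]; e <- iv[2]
  if (s < 0 || e > n_src || s >= e) stopf("interval [%d,%d) outside promoter of length %d", s, e, n_src)
  in_iv <- !is.na(src) & src >= s & src < e
  aligned <- in_iv & !is.na(dst)
  lifted_fraction <- sum(aligned) / (e - s)
  identity_in_region <- if (any(aligned)) sum(aln$match[aligned]) / sum(aligned) else 0
  target <- NULL
  if (lifted_fraction >= min_lift) {
    tp <- dst[aligned]
    target <- c(min(tp), max(tp) + 1L)
  }
  list(source = c(s, e), target = target,
       lifted_fraction = lifted_fraction,
       identity_in_region = identity_in_region)
}

# Convert genome-coordinate peaks to promoter-local coordinates
# (transcription direction). Peaks are intersected with the promoter window;
# peaks not overlapping it are dropped.
peaks_to_promoter <- function(peaks, prom) {
  hit <- peaks$chrom == prom$chrom & peaks$end > prom$start & peaks$start < prom$end
  pk <- peaks[hit, , drop = FALSE]
  if (nrow(pk) == 0) {
    return(data.frame(mark = character(), start = integer(), end = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  s <- pmax(pk$start, prom$start); e <- pmin(pk$end, prom$end)
  if (prom$strand == "+") {
    ls <- s - prom$start; le <- e - prom$start
  } else {
    ls <- prom$end - e; le <- prom$end - s
  }
  data.frame(mark = pk$mark, start = as.integer(ls), end = as.integer(le),
             score = pk$score, stringsAsFactors = FALSE)
}
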