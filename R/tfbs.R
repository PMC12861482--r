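# PWM motif scanning and TFBS conservation scoring.
# Log-odds convention: natural log of p(base) / 0.25 with a small pseudocount
# added before normalisation; hits retained with score strictly above the
# threshold (default 10). Both strands are scanned; windows containing N are
# skipped.

#' Read a JASPAR-style PWM library
#'
#' Expects records of the form `>motif_id name` followed by four rows
#' `A [ counts... ]`, `C [...]`, `G [...]`, `T [...]`. Counts are normalised
#' to per-position probabilities with a pseudocount.
#'
#' @param path Library file path.
#' @param pseudocount Added to every count before column normalisation.
#' @return Named list of `pwm` objects (list with motif_id, prob 4xL matrix,
#'   logodds 4xL matrix).
#' @export
read_pwm_library <- function(path, pseudocount = 1e-3) {
  if (!file.exists(path)) stopf("PWM library not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stopf("no motif records in %s", path)
  pwms <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    hdr <- sub("^>\\s*", "", lines[i])
    motif_id <- strsplit(hdr, "\\s+")[[1]][1]
    rows <- lines[(i + 1):(i + 4)]
    parse_row <- function(r) {
      body <- sub("^\\s*[ACGT]", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    }
    bases <- substr(trimws(rows), 1, 1)
    if (!identical(bases, c("A", "C", "G", "T"))) {
      stopf("motif %s: expected A/C/G/T rows in order", motif_id)
    }
    counts <- do.call(rbind, lapply(rows, parse_row))
    if (ncol(counts) < 4) stopf("motif %s shorter than 4 positions", motif_id)
    rownames(counts) <- c("A", "C", "G", "T")
    pwms[[motif_id]] <- make_pwm(motif_id, counts, pseudocount)
  }
  pwms
}

make_pwm <- function(motif_id, counts, pseudocount = 1e-3) {
  prob <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  list(motif_id = motif_id, prob = prob, logodds = log(prob / 0.25))
}

#' Write a PWM library in JASPAR-style format
#' @param pwms Named list of 4xL count (or probability) matrices, or `pwm`
#'   objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm_library <- function(pwms, path) {
  out <- character(0)
  for (nm in names(pwms)) {
    m <- pwms[[nm]]
    if (is.list(m)) m <- m$prob * 100
    out <- c(out, paste0(">", nm),
             sprintf("%s [ %s ]", c("A", "C", "G", "T"),
                     apply(m, 1, function(r) paste(format(r, trim = TRUE), collapse = " "))))
  }
  writeLines(out, path)
  invisible(path)
}

#' Scan a promoter sequence with one PWM
#'
#' @param seq DNA string (ACGTN).
#' @param pwm A `pwm` object from [read_pwm_library()].
#' @param threshold Retain hits with log-odds strictly above this (default 10).
#' @return data.frame: motif_id, offset (0-based), strand (+/-), log_odds.
#'   Overlapping hits are all kept.
#' @export
scan_promoter <- function(seq, pwm, threshold = 10) {
  hits <- .pwm_scan(seq, pwm$logodds, threshold)
  data.frame(motif_id = rep(pwm$motif_id, nrow(hits)),
             offset = hits$offset,
             strand = ifelse(hits$strand > 0, "+", "-"),
             log_odds = hits$log_odds,
             stringsAsFactors = FALSE)
}

#' Scan a promoter with a whole PWM library
#' @inheritParams scan_promoter
#' @param pwms Named list of `pwm` objects.
#' @return data.frame of hits across all motifs.
#' @export
scan_promoter_library <- function(seq, pwms, threshold = 10) {
  raw <- lapply(pwms, function(p) .pwm_scan(seq, p$logodds, threshold))
  nh <- vapply(raw, function(h) length(h$offset), integer(1))
  data.frame(motif_id = rep(names(pwms), nh),
             offset = unlist(lapply(raw, `[[`, "offset"), use.names = FALSE),
             strand = ifelse(unlist(lapply(raw, `[[`, "strand"), use.names = FALSE) > 0, "+", "-"),
             log_odds = unlist(lapply(raw, `[[`, "log_odds"), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' TFBS conservation score for a homoeologous promoter pair
#'
#' A tetraploid TFBS is conserved when a hit of the same motif is identified
#' in the diploid homolog (motif-identity level; position_matched additionally
#' requires the tetraploid hit to lift onto an overlapping same-motif diploid
#' hit through the pair's promoter alignment). CS = conserved / total
#' tetraploid hits, on the [0, 1] scale; NULL-like (NA) when the tetraploid
#' promoter has no hits.
#'
#' @param hits_tetraploid,hits_diploid Hit tables from
#'   [scan_promoter_library()].
#' @param position_matched Require positional overlap after lift-over.
#' @param aln `promoter_alignment` (tetraploid as sequence A); only used when
#'   `position_matched` is TRUE.
#' @param motif_lengths Named integer vector of motif lengths; only used when
#'   `position_matched` is TRUE.
#' @return List with cs, n_total, n_conserved.
#' @export
tfbs_conservation_score <- function(hits_tetraploid, hits_diploid,
                                    position_matched = FALSE, aln = NULL,
                                    motif_lengths = NULL) {
  n_total <- nrow(hits_tetraploid)
  if (n_total == 0) return(list(cs = NA_real_, n_total = 0L, n_conserved = 0L))
  if (!position_matched) {
    conserved <- hits_tetraploid$motif_id %in% unique(hits_diploid$motif_id)
  } else {
    if (is.null(aln) || is.null(motif_lengths)) stopf("position_matched needs aln and motif_lengths")
    conserved <- vapply(seq_len(n_total), function(i) {
      mid <- hits_tetraploid$motif_id[i]
      L <- motif_lengths[[mid]]
      lf <- lift_interval(c(hits_tetraploid$offset[i], hits_tetraploid$offset[i] + L),
                          aln, direction = "a2b")
      if (is.null(lf$target)) return(FALSE)
      dh <- hits_diploid[hits_diploid$motif_id == mid, , drop = FALSE]
      if (nrow(dh) == 0) return(FALSE)
      any(pmin(dh$offset + L, lf$target[2]) > pmax(dh$offset, lf$target[1]))
    }, logical(1))
  }
  list(cs = sum(conserved) / n_total, n_total = as.integer(n_total),
       n_conserved = as.integer(sum(conserved)))
}

#' Per-motif TF target counts across the four (sub)genomes
#'
#' A tetrad gene is a target of a motif in a genome when its promoter carries
#' at least one hit of that motif. Pairwise comparisons report Pearson r and
#' the ordinary least-squares slope of y on x with x the first-named genome.
#'
#' @param hits_by_genome Named list (genome -> hit table with gene_id column).
#' @param tetrads Tetrad data.frame.
#' @param comparisons List of genome-label pairs (x, y).
#' @return List with `counts` (motif x genome matrix) and `comparison`
#'   data.frame (x, y, r, slope).
#' @export
tf_target_counts <- function(hits_by_genome, tetrads,
                             comparisons = list(c("Ar", "Co"), c("An", "Cn"),
                                                c("Ar", "An"), c("Co", "Cn"))) {
  motifs <- sort(unique(unlist(lapply(hits_by_genome, function(h) h$motif_id))))
  if (length(motifs) < 2) stopf("need at least 2 motifs")
  genomes <- names(hits_by_genome)
  counts <- matrix(0L, nrow = length(motifs), ncol = length(genomes),
                   dimnames = list(motifs, genomes))
  for (g in genomes) {
    h <- hits_by_genome[[g]]
    h <- h[h$gene_id %in% tetrads[[g]], , drop = FALSE]
    tb <- table(h$motif_id[!duplicated(paste(h$motif_id, h$gene_id))])
    counts[names(tb), g] <- as.integer(tb)
  }
  cmp <- do.call(rbind, lapply(comparisons, function(p) {
    x <- counts[, p[1]]; y <- counts[, p[2]]
    fit <- lm(y ~ x)
    data.frame(x = p[1], y = p[2], r = cor(x, y), slope = unname(coef(fit)[2]),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, comparison = cmp)
}

#' Fraction of promoters with high TFBS conservation
#'
#' @param cs Vector of conservation scores on [0, 1] (NAs dropped).
#' @param cutoff Strict cutoff (default 0.6).
#' @return Fraction of scores strictly above `cutoff`.
#' @export
high_conservation_fraction <- function(cs, cutoff = 0.6) {
  cs <- cs[!is.na(cs)]
  if (length(cs) == 0) stopf("no non-null conservation scores")
  mean(cs > cutoff)
}
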