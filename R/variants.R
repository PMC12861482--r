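# Alignment-derived promoter variants: every mismatch column is one SNV (no
# MNV merging); every maximal contiguous gap run in either sequence is one
# InDel (run length 1-50 bp) or SV (> 50 bp). Coordinates are reported on
# sequence A of the alignment, which in pipeline use is the tetraploid member
# of a diploid-tetraploid pair.

#' Call variants from a promoter alignment
#'
#' @param aln `promoter_alignment` (A = tetraploid member, B = diploid).
#' @return data.frame: vtype (SNV/InDel/SV), position (0-based offset on A;
#'   for gaps in A, the A position before which the inserted B bases sit),
#'   length (gap-run length; 1 for SNV), seq_a, seq_b (alleles, "-" for
#'   absent), enabling exact reconstruction of B from A.
#' @export
call_variants <- function(aln) {
  pos_a <- aln$pos_a; pos_b <- aln$pos_b; matched <- aln$match
  n <- length(pos_a)
  seq_a_chars <- attr(aln, "seq_a_chars"); seq_b_chars <- attr(aln, "seq_b_chars")
  # column states: 0 aligned, 1 gap in B (A-only), 2 gap in A (B-only)
  state <- ifelse(!is.na(pos_a) & !is.na(pos_b), 0L, ifelse(is.na(pos_b), 1L, 2L))
  # SNVs: every mismatched aligned column
  snv_cols <- which(state == 0L & !matched)
  # gap runs: maximal stretches of a constant nonzero state
  runs <- rle(state)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  gap_idx <- which(runs$values != 0L)

  n_var <- length(snv_cols) + length(gap_idx)
  vtype <- character(n_var); position <- integer(n_var); length_ <- integer(n_var)
  seq_a <- rep(NA_character_, n_var); seq_b <- rep(NA_character_, n_var)
  k <- length(snv_cols)
  if (k > 0) {
    vtype[1:k] <- "SNV"
    position[1:k] <- pos_a[snv_cols]
    length_[1:k] <- 1L
    if (!is.null(seq_a_chars)) seq_a[1:k] <- seq_a_chars[pos_a[snv_cols] + 1L]
    if (!is.null(seq_b_chars)) seq_b[1:k] <- seq_b_chars[pos_b[snv_cols] + 1L]
  }
  for (g in gap_idx) {
    k <- k + 1L
    i <- run_start[g]; j <- run_end[g]
    len <- j - i + 1L
    vtype[k] <- if (len > 50L) "SV" else "InDel"
    length_[k] <- len
    if (runs$values[g] == 1L) {      # bases present in A only
      position[k] <- pos_a[i]
      if (!is.null(seq_a_chars)) seq_a[k] <- paste(seq_a_chars[pos_a[i:j] + 1L], collapse = "")
      seq_b[k] <- "-"
    } else {                          # bases present in B only
      position[k] <- if (j < n && !is.na(pos_a[j + 1L])) pos_a[j + 1L] else aln$len_a
      seq_a[k] <- "-"
      if (!is.null(seq_b_chars)) seq_b[k] <- paste(seq_b_chars[pos_b[i:j] + 1L], collapse = "")
    }
  }
  ord <- order(position, seq_len(n_var))
  data.frame(vtype = vtype[ord], position = position[ord], length = length_[ord],
             seq_a = seq_a[ord], seq_b = seq_b[ord], stringsAsFactors = FALSE)
}

#' Align two promoters and call variants with allele sequences
#' @param seq_a,seq_b DNA strings (A = tetraploid member).
#' @return data.frame as [call_variants()], with alleles filled in.
#' @export
call_variants_pair <- function(seq_a, seq_b) {
  aln <- align_promoters(seq_a, seq_b)
  attr(aln, "seq_a_chars") <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  attr(aln, "seq_b_chars") <- strsplit(seq_b, "", fixed = TRUE)[[1]]
  call_variants(aln)
}

#' Reconstruct sequence B by applying called variants to sequence A
#'
#' Round-trip check for [call_variants_pair()]: editing A by the variant list
#' must reproduce B exactly.
#'
#' @param seq_a Sequence A.
#' @param variants data.frame from [call_variants_pair()].
#' @return Reconstructed sequence B.
#' @export
apply_variants <- function(seq_a, variants) {
  a <- strsplit(seq_a, "", fixed = TRUE)[[1]]
  # replacement per A position, and insertions anchored before A positions
  repl <- as.list(a)
  ins <- rep("", length(a) + 1L)
  if (nrow(variants) > 0) {
    for (r in seq_len(nrow(variants))) {
      v <- variants[r, ]
      if (v$vtype == "SNV") {
        repl[[v$position + 1L]] <- v$seq_b
      } else if (v$seq_b == "-") {                 # bases present in A only
        for (p in v$position:(v$position + v$length - 1L)) repl[[p + 1L]] <- ""
      } else {                                     # bases present in B only
        ins[v$position + 1L] <- paste0(ins[v$position + 1L], v$seq_b)
      }
    }
  }
  paste0(paste0(ins[seq_along(a)], unlist(repl), collapse = ""), ins[length(a) + 1L])
}

#' Annotate variants with nonconserved-TFBS overlap
#'
#' A variant overlaps a nonconserved TFBS when its footprint
#' [position, position + length) intersects a nonconserved hit window by at
#' least 1 bp (half-open intervals; insertions relative to A have a zero-width
#' footprint at their anchor and are widened to 1 bp for the intersection).
#'
#' @param variants data.frame from [call_variants_pair()] (coordinates on the
#'   tetraploid promoter).
#' @param hits Hit table on the same promoter ([scan_promoter_library()]).
#' @param conserved_flags Logical per hit row; FALSE = nonconserved.
#' @param motif_lengths Named integer vector of motif lengths.
#' @return List with `variants` (input plus overlaps_nonconserved_tfbs) and
#'   `fractions` (per-vtype overlap fraction).
#' @export
overlap_with_tfbs <- function(variants, hits, conserved_flags, motif_lengths) {
  if (nrow(hits) != length(conserved_flags)) stopf("hits/flags length mismatch")
  nc <- hits[!conserved_flags, , drop = FALSE]
  nc_start <- nc$offset
  nc_end <- nc$offset + as.integer(motif_lengths[nc$motif_id])
  v_start <- variants$position
  v_end <- variants$position + ifelse(variants$seq_b != "-" & variants$seq_a == "-",
                                      1L, variants$length)
  ov <- vapply(seq_len(nrow(variants)), function(i) {
    any(pmin(nc_end, v_end[i]) > pmax(nc_start, v_start[i]))
  }, logical(1))
  variants$overlaps_nonconserved_tfbs <- if (nrow(variants)) ov else logical(0)
  fr <- vapply(c("SNV", "InDel", "SV"), function(t) {
    sel <- variants$vtype == t
    if (!any(sel)) return(NA_real_)
    mean(variants$overlaps_nonconserved_tfbs[sel])
  }, numeric(1))
  list(variants = variants, fractions = fr)
}

#' Correlation between promoter variant burden and TFBS conservation
#'
#' Spearman correlation of total variant length per promoter against the
#' promoter's TFBS conservation score.
#'
#' @param variant_length Per-gene total variant length.
#' @param cs Per-gene conservation score (same order, NAs dropped pairwise).
#' @return List with rho and p_value.
#' @export
variation_length_vs_cs <- function(variant_length, cs) {
  keep <- !is.na(variant_length) & !is.na(cs)
  x <- variant_length[keep]; y <- cs[keep]
  if (length(x) < 3) stopf("need n >= 3")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) stopf("zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
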