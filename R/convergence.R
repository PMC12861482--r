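# Intersubgenomic convergence: features conserved between the allotetraploid
# subgenomes (An-Cn) categorised by their state in the diploid progenitors
# (Ar-Co): Same (also conserved in the diploids), Convergent (divergent in
# the diploids), Others (no peak detected in the diploids).

#' Categorise epigenomic convergence per tetrad for one mark
#'
#' Defined for tetrads whose An-Cn call is epigenome-conserved: `same` if
#' Ar-Co is also epigenome-conserved, `convergent` if Ar-Co has peak(s) but
#' is not epigenome-conserved, `others` if Ar-Co has no peak.
#'
#' @param calls_ancn,calls_arco Call data.frames from [pair_calls()] for the
#'   An-Cn and Ar-Co pairs.
#' @param mark Mark to evaluate.
#' @param others_includes_unclassified Count Ar-Co `unclassified` calls as
#'   `others` rather than `convergent` (default FALSE: only `no_peak`).
#' @return data.frame: tetrad_id, mark, layer, category.
#' @export
call_epigenomic_convergence <- function(calls_ancn, calls_arco, mark,
                                        others_includes_unclassified = FALSE) {
  a <- calls_ancn[calls_ancn$mark == mark, , drop = FALSE]
  d <- calls_arco[calls_arco$mark == mark, , drop = FALSE]
  conserved <- a[!is.na(a$epi_conserved) & a$epi_conserved, , drop = FALSE]
  i <- match(conserved$tetrad_id, d$tetrad_id)
  if (anyNA(i)) stopf("tetrad(s) missing from Ar-Co calls: %s",
                      paste(conserved$tetrad_id[is.na(i)], collapse = ", "))
  dd <- d[i, , drop = FALSE]
  category <- ifelse(dd$klass == "no_peak", "others",
              ifelse(!is.na(dd$epi_conserved) & dd$epi_conserved, "same", "convergent"))
  if (others_includes_unclassified) {
    category[dd$klass == "unclassified"] <- "others"
  }
  data.frame(tetrad_id = conserved$tetrad_id, mark = mark, layer = "epigenomic",
             category = category, stringsAsFactors = FALSE)
}

#' Categorise sequence convergence per tetrad for one mark
#'
#' Defined for tetrads whose An-Cn call is sequence-conserved (Class I or
#' II); categories follow the diploid Ar-Co sequence status analogously to
#' [call_epigenomic_convergence()].
#'
#' @inheritParams call_epigenomic_convergence
#' @return data.frame: tetrad_id, mark, layer, category.
#' @export
call_sequence_convergence <- function(calls_ancn, calls_arco, mark,
                                      others_includes_unclassified = FALSE) {
  a <- calls_ancn[calls_ancn$mark == mark, , drop = FALSE]
  d <- calls_arco[calls_arco$mark == mark, , drop = FALSE]
  conserved <- a[!is.na(a$seq_conserved) & a$seq_conserved, , drop = FALSE]
  i <- match(conserved$tetrad_id, d$tetrad_id)
  if (anyNA(i)) stopf("tetrad(s) missing from Ar-Co calls: %s",
                      paste(conserved$tetrad_id[is.na(i)], collapse = ", "))
  dd <- d[i, , drop = FALSE]
  category <- ifelse(dd$klass == "no_peak", "others",
              ifelse(!is.na(dd$seq_conserved) & dd$seq_conserved, "same", "convergent"))
  if (others_includes_unclassified) {
    category[dd$klass == "unclassified"] <- "others"
  }
  data.frame(tetrad_id = conserved$tetrad_id, mark = mark, layer = "sequence",
             category = category, stringsAsFactors = FALSE)
}

#' Call expression convergence per tetrad
#'
#' A tetrad is expression-convergent when its subgenome divergence falls
#' below the fold-change threshold while the diploid divergence does not:
#' |log2FC(An, Cn)| < `fc_threshold` and |log2FC(Ar, Co)| >= `fc_threshold`,
#' with log2FC = log2((max TPM + eps) / (min TPM + eps)).
#'
#' @param expr Named list (Ar, Co, An, Cn) of named TPM vectors.
#' @param tetrads Tetrad data.frame.
#' @param fc_threshold Fold-change threshold on the log2 scale (default 1).
#' @param eps Pseudocount (default 1).
#' @return data.frame: tetrad_id, log2fc_diploid, log2fc_tetraploid,
#'   convergent.
#' @export
call_expression_convergence <- function(expr, tetrads, fc_threshold = 1, eps = 1) {
  tpm <- function(genome, ids) {
    v <- expr[[genome]][ids]
    v[is.na(v)] <- 0   # explicitly absent genes count as unexpressed
    if (any(v < 0)) stopf("negative TPM for genome %s", genome)
    unname(v)
  }
  ar <- tpm("Ar", tetrads$Ar); co <- tpm("Co", tetrads$Co)
  an <- tpm("An", tetrads$An); cn <- tpm("Cn", tetrads$Cn)
  fc_dip <- log2_fold_change(ar, co, eps = eps)
  fc_tet <- log2_fold_change(an, cn, eps = eps)
  data.frame(tetrad_id = tetrads$tetrad_id,
             log2fc_diploid = fc_dip, log2fc_tetraploid = fc_tet,
             convergent = fc_tet < fc_threshold & fc_dip >= fc_threshold,
             stringsAsFactors = FALSE)
}

#' Summarise convergence categories per mark
#' @param conv data.frame from the convergence callers (possibly rbind-ed).
#' @return data.frame with mark, layer, category counts and percentages.
#' @export
convergence_summary <- function(conv) {
  out <- list()
  for (grp in split(conv, list(conv$mark, conv$layer), drop = TRUE)) {
    counts <- table(factor(grp$category, levels = c("same", "convergent", "others")))
    out[[length(out) + 1L]] <- data.frame(
      mark = grp$mark[1], layer = grp$layer[1],
      category = names(counts), count = as.integer(counts),
      percent = 100 * as.numeric(counts) / sum(counts),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
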