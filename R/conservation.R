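# Dual sequence/epigenome conservation calls for promoter peaks, and the
# Class I/II/III partition of homoeologous gene pairs:
#   Class I   sequence conserved and epigenome conserved
#   Class II  sequence conserved, epigenome divergent
#   Class III both divergent
# Pairs whose epigenome is conserved on a divergent sequence do not fit the
# three-class scheme and are reported as "unclassified"; pairs without any
# promoter peak of the mark are "no_peak". Both are excluded from class
# denominators.

default_thresholds <- function() {
  list(min_lift = 0.5,        # aligned fraction of peak bases for a lift
       min_identity = 0.7,    # aligned identity inside the peak footprint
       min_epi_overlap = 0.5, # partner-peak coverage of the lifted region
       seq_rule = "all",      # all peaks must be sequence-conserved
       epi_rule = "any")      # any conserved peak satisfies the epigenome layer
}

# does interval iv (0-based half-open) get covered >= frac by any same-mark
# peak interval in `peaks` (local coords)?
covered_by_peak <- function(iv, peaks, frac) {
  if (nrow(peaks) == 0) return(FALSE)
  ov <- pmin(peaks$end, iv[2]) - pmax(peaks$start, iv[1])
  any(ov / (iv[2] - iv[1]) >= frac)
}

#' Call sequence and epigenome conservation for one pair and mark
#'
#' Sequence conservation: every promoter peak of the mark (in whichever
#' member has peaks; both if both do) lifts onto the partner promoter with at
#' least `min_lift` of its bases aligned and aligned identity of at least
#' `min_identity` within the peak footprint. Epigenome conservation: some
#' lifted peak region is covered by at least `min_epi_overlap` of a same-mark
#' peak in the partner promoter (either direction suffices).
#'
#' @param peaks_1,peaks_2 Promoter-local peak tables (mark, start, end) for
#'   the two pair members.
#' @param aln `promoter_alignment` of member 1 vs member 2.
#' @param mark Mark to evaluate.
#' @param thresholds List as from `default_thresholds()`.
#' @return List with seq_conserved, epi_conserved, klass.
#' @export
call_peak_conservation <- function(peaks_1, peaks_2, aln, mark,
                                   thresholds = default_thresholds()) {
  if (is.null(aln)) stopf("missing promoter alignment")
  th <- modifyList(default_thresholds(), thresholds)
  p1 <- peaks_1[peaks_1$mark == mark, , drop = FALSE]
  p2 <- peaks_2[peaks_2$mark == mark, , drop = FALSE]
  if (nrow(p1) == 0 && nrow(p2) == 0) {
    return(list(seq_conserved = NA, epi_conserved = NA, klass = "no_peak"))
  }
  lift_one <- function(pk, dirn) {
    lapply(seq_len(nrow(pk)), function(i) {
      lift_interval(c(pk$start[i], pk$end[i]), aln, direction = dirn,
                    min_lift = th$min_lift)
    })
  }
  lifts1 <- lift_one(p1, "a2b")
  lifts2 <- lift_one(p2, "b2a")
  seq_ok <- vapply(c(lifts1, lifts2), function(lf) {
    lf$lifted_fraction >= th$min_lift && lf$identity_in_region >= th$min_identity
  }, logical(1))
  seq_conserved <- if (identical(th$seq_rule, "all")) all(seq_ok) else any(seq_ok)

  epi_ok <- c(
    vapply(lifts1, function(lf) {
      !is.null(lf$target) && covered_by_peak(lf$target, p2, th$min_epi_overlap)
    }, logical(1)),
    vapply(lifts2, function(lf) {
      !is.null(lf$target) && covered_by_peak(lf$target, p1, th$min_epi_overlap)
    }, logical(1)))
  epi_conserved <- if (identical(th$epi_rule, "any")) any(epi_ok) else all(epi_ok) && length(epi_ok) > 0

  klass <- if (seq_conserved && epi_conserved) "I"
    else if (seq_conserved && !epi_conserved) "II"
    else if (!seq_conserved && !epi_conserved) "III"
    else "unclassified"
  list(seq_conserved = seq_conserved, epi_conserved = epi_conserved, klass = klass)
}

#' Conservation calls for all tetrads of one genome pair
#'
#' @param tetrads Tetrad data.frame (tetrad_id plus genome columns).
#' @param pair Character vector of two genome labels, e.g. `c("Ar","An")`.
#' @param promoters Named list (genome label -> named promoter list).
#' @param peaks_local Named list (genome label -> named list of
#'   promoter-local peak tables per gene).
#' @param alignments Named list of `promoter_alignment`s keyed by tetrad_id
#'   for this pair.
#' @param marks Marks to evaluate.
#' @param thresholds See [call_peak_conservation()].
#' @return data.frame: tetrad_id, pair, mark, seq_conserved, epi_conserved,
#'   klass.
#' @export
pair_calls <- function(tetrads, pair, promoters, peaks_local, alignments,
                       marks = CLASS_MARKS, thresholds = default_thresholds()) {
  g1 <- pair[1]; g2 <- pair[2]
  n <- nrow(tetrads) * length(marks)
  tid_v <- character(n); mark_v <- character(n)
  seq_v <- logical(n); epi_v <- logical(n); klass_v <- character(n)
  k <- 0L
  for (i in seq_len(nrow(tetrads))) {
    tid <- tetrads$tetrad_id[i]
    gene1 <- tetrads[[g1]][i]; gene2 <- tetrads[[g2]][i]
    aln <- alignments[[tid]]
    if (is.null(aln)) stopf("missing alignment for tetrad %s pair %s-%s", tid, g1, g2)
    pk1 <- peaks_local[[g1]][[gene1]]
    pk2 <- peaks_local[[g2]][[gene2]]
    for (mk in marks) {
      cc <- call_peak_conservation(pk1, pk2, aln, mk, thresholds)
      k <- k + 1L
      tid_v[k] <- tid; mark_v[k] <- mk
      seq_v[k] <- cc$seq_conserved; epi_v[k] <- cc$epi_conserved
      klass_v[k] <- cc$klass
    }
  }
  data.frame(tetrad_id = tid_v, pair = paste0(g1, "-", g2), mark = mark_v,
             seq_conserved = seq_v, epi_conserved = epi_v, klass = klass_v,
             stringsAsFactors = FALSE)
}

#' Class proportions over Class I/II/III
#'
#' Denominators exclude `no_peak` and `unclassified` calls.
#'
#' @param calls data.frame from [pair_calls()].
#' @param pair Optional pair label filter (e.g. `"Ar-An"`).
#' @param mark Optional mark filter.
#' @return data.frame with klass, count, proportion.
#' @export
class_proportions <- function(calls, pair = NULL, mark = NULL) {
  if (!is.null(pair)) calls <- calls[calls$pair == pair, , drop = FALSE]
  if (!is.null(mark)) calls <- calls[calls$mark == mark, , drop = FALSE]
  calls <- calls[calls$klass %in% c("I", "II", "III"), , drop = FALSE]
  if (nrow(calls) == 0) stopf("empty class denominator")
  counts <- table(factor(calls$klass, levels = c("I", "II", "III")))
  data.frame(klass = names(counts), count = as.integer(counts),
             proportion = as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE)
}
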