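# Homoeologous tetrad identification: reciprocal best hits on gene sequences,
# filtered for collinearity with a cscore-style criterion, then assembled into
# strict 1:1:1:1 quartets across the four (sub)genomes.

# shared k-mer counts between every gene of A and its candidate partners in B;
# keeps all-vs-all alignment off the critical path.
kmer_candidates <- function(seqs_a, seqs_b, k = 13L, top = 5L) {
  kmerize <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  kb <- lapply(seqs_b, kmerize)
  dict <- unique(unlist(kb, use.names = FALSE))
  by_kmer <- split(rep(seq_along(kb), lengths(kb)),
                   match(unlist(kb, use.names = FALSE), dict))
  ka <- lapply(seqs_a, kmerize)
  # one global hash lookup instead of one per gene
  hits <- match(unlist(ka, use.names = FALSE), dict)
  gene_of <- rep(seq_along(ka), lengths(ka))
  keep <- !is.na(hits)
  shared <- by_kmer[as.character(hits[keep])]
  pair_a <- rep(gene_of[keep], lengths(shared))
  pair_b <- unlist(shared, use.names = FALSE)
  out <- rep(list(integer(0)), length(seqs_a))
  if (length(pair_a)) {
    tab <- split(pair_b, pair_a)
    for (nm in names(tab)) {
      cnt <- table(tab[[nm]])
      ord <- order(-as.integer(cnt))
      out[[as.integer(nm)]] <- as.integer(names(cnt))[ord[seq_len(min(top, length(ord)))]]
    }
  }
  out
}

#' Reciprocal best hits between two gene sets
#'
#' Scores candidate gene pairs by banded global alignment (match +1, mismatch
#' -1, gap -2 per base) and retains pairs that are mutually best. Candidate
#' partners are prescreened by shared k-mer counts so the search scales to
#' thousands of genes. The cscore of a retained pair is its score divided by
#' the larger of the two genes' best scores (MCScan convention). Score ties
#' are broken by lexicographic partner id and flagged ambiguous.
#'
#' @param seqs_a,seqs_b Named character vectors of gene sequences.
#' @param top_candidates Number of k-mer prescreen candidates per gene.
#' @return data.frame with gene_a, gene_b, score, cscore, ambiguous.
#' @export
best_hits <- function(seqs_a, seqs_b, top_candidates = 5L) {
  if (length(seqs_a) == 0 || length(seqs_b) == 0) stopf("empty gene set")
  cand_ab <- kmer_candidates(seqs_a, seqs_b, top = top_candidates)
  best_of <- function(seqs_x, seqs_y, cands) {
    idx <- integer(length(seqs_x)); sc <- rep(-Inf, length(seqs_x))
    amb <- logical(length(seqs_x))
    for (i in seq_along(seqs_x)) {
      cs <- cands[[i]]
      if (length(cs) == 0) next
      scores <- vapply(cs, function(j) .banded_score(seqs_x[[i]], seqs_y[[j]]), numeric(1))
      mx <- max(scores)
      ties <- cs[scores == mx]
      if (length(ties) > 1) {
        ties <- ties[order(names(seqs_y)[ties])]
        amb[i] <- TRUE
      }
      idx[i] <- ties[1]; sc[i] <- mx
    }
    list(idx = idx, score = sc, ambiguous = amb)
  }
  fwd <- best_of(seqs_a, seqs_b, cand_ab)
  # candidates for B genes: invert the A->B candidate lists
  cand_ba <- vector("list", length(seqs_b))
  for (i in seq_along(cand_ab)) for (j in cand_ab[[i]]) cand_ba[[j]] <- c(cand_ba[[j]], i)
  cand_ba <- lapply(cand_ba, unique)
  rev <- best_of(seqs_b, seqs_a, cand_ba)
  keep <- which(fwd$idx > 0)
  keep <- keep[rev$idx[fwd$idx[keep]] == keep]
  if (length(keep) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(), score = numeric(),
                      cscore = numeric(), ambiguous = logical(), stringsAsFactors = FALSE))
  }
  j <- fwd$idx[keep]
  data.frame(gene_a = names(seqs_a)[keep], gene_b = names(seqs_b)[j],
             score = fwd$score[keep],
             cscore = fwd$score[keep] / pmax(fwd$score[keep], rev$score[j]),
             ambiguous = fwd$ambiguous[keep] | rev$ambiguous[j],
             stringsAsFactors = FALSE)
}

#' Retain collinear (syntenic) anchor pairs
#'
#' A pair is kept iff it belongs to a chain of at least `min_anchors` pairs
#' whose gene ranks are monotone (increasing or decreasing) in both genomes,
#' with inter-anchor rank gaps of at most `max_gap` on both sides; chains are
#' found by longest-chain dynamic programming per chromosome pair. Surviving
#' pairs are then filtered for cscore >= `min_cscore`.
#'
#' @param pairs data.frame from [best_hits()].
#' @param order_a,order_b Named lists: chromosome -> character vector of gene
#'   ids in genomic order (or a single character vector for one chromosome).
#' @param min_anchors Minimum chain size (default 4).
#' @param max_gap Maximum inter-anchor gap in gene ranks (default 10).
#' @param min_cscore cscore threshold (default 0.99).
#' @return Subset of `pairs` on syntenic chains.
#' @export
collinear_chains <- function(pairs, order_a, order_b, min_anchors = 4L,
                             max_gap = 10L, min_cscore = 0.99) {
  if (!is.list(order_a)) order_a <- list(chr = order_a)
  if (!is.list(order_b)) order_b <- list(chr = order_b)
  rank_of <- function(orders) {
    df <- data.frame(gene = unlist(orders, use.names = FALSE),
                     chrom = rep(names(orders), lengths(orders)),
                     rank = unlist(lapply(orders, seq_along), use.names = FALSE),
                     stringsAsFactors = FALSE)
    df
  }
  ra <- rank_of(order_a); rb <- rank_of(order_b)
  ia <- match(pairs$gene_a, ra$gene); ib <- match(pairs$gene_b, rb$gene)
  if (anyNA(ia) || anyNA(ib)) stopf("pair gene missing from gene ordering")
  pr <- cbind(pairs,
              chrom_a = ra$chrom[ia], rank_a = ra$rank[ia],
              chrom_b = rb$chrom[ib], rank_b = rb$rank[ib])
  keep <- logical(nrow(pr))
  for (grp in split(seq_len(nrow(pr)), paste(pr$chrom_a, pr$chrom_b))) {
    sub <- pr[grp, , drop = FALSE]
    for (dirn in c(1, -1)) {
      rb_dir <- dirn * sub$rank_b
      o <- order(sub$rank_a, rb_dir)
      ra_s <- sub$rank_a[o]; rb_s <- rb_dir[o]
      n <- length(o)
      # chain length through each anchor = forward + backward best - 1;
      # predecessors restricted to the max_gap rank window (anchors sorted
      # by rank_a, so eligible j lie in a contiguous tail)
      fwd <- rep(1L, n); bwd <- rep(1L, n)
      lo_of <- findInterval(ra_s - max_gap - 0.5, ra_s) + 1L
      for (i in seq_len(n)) {
        js <- seq.int(lo_of[i], i - 1L)
        js <- js[js >= 1L & js < i]
        if (!length(js)) next
        da <- ra_s[i] - ra_s[js]; db <- rb_s[i] - rb_s[js]
        ok_j <- da > 0 & db > 0 & db <= max_gap
        if (any(ok_j)) fwd[i] <- max(fwd[i], fwd[js[ok_j]] + 1L)
      }
      hi_of <- findInterval(ra_s + max_gap, ra_s)
      for (i in rev(seq_len(n))) {
        js <- seq.int(i + 1L, hi_of[i])
        js <- js[js > i & js <= n]
        if (!length(js)) next
        da <- ra_s[js] - ra_s[i]; db <- rb_s[js] - rb_s[i]
        ok_j <- da > 0 & db > 0 & db <= max_gap
        if (any(ok_j)) bwd[i] <- max(bwd[i], bwd[js[ok_j]] + 1L)
      }
      ok <- (fwd + bwd - 1L) >= min_anchors
      keep[grp[o[ok]]] <- TRUE
    }
  }
  out <- pr[keep & pr$cscore >= min_cscore, names(pairs), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble 1:1:1:1 homoeologous tetrads from pairwise syntenic maps
#'
#' Joins the Ar-Co, Ar-An and Co-Cn syntenic pair maps into candidate
#' quartets. When `require_closed_quartet` is TRUE the An-Cn map must also
#' contain the closing edge. Any gene participating in more than one
#' candidate quartet invalidates all of its quartets (strict 1:1:1:1).
#'
#' @param ar_co,ar_an,co_cn,an_cn Pair data.frames (gene_a, gene_b) with
#'   gene_a from the first-named genome.
#' @param require_closed_quartet Require a consistent An-Cn edge.
#' @return data.frame with tetrad_id, Ar, Co, An, Cn.
#' @export
assemble_tetrads <- function(ar_co, ar_an, co_cn, an_cn = NULL,
                             require_closed_quartet = FALSE) {
  map <- function(p) setNames(p$gene_b, p$gene_a)
  m_co <- map(ar_co); m_an <- map(ar_an); m_cn <- map(co_cn)
  ar_genes <- intersect(names(m_co), names(m_an))
  co <- m_co[ar_genes]; an <- m_an[ar_genes]
  cn <- m_cn[co]
  ok <- !is.na(cn)
  if (require_closed_quartet) {
    if (is.null(an_cn)) stopf("an_cn pairs required when require_closed_quartet = TRUE")
    m_ancn <- map(an_cn)
    ok <- ok & !is.na(m_ancn[an]) & m_ancn[an] == cn
  }
  cand <- data.frame(Ar = ar_genes[ok], Co = unname(co[ok]),
                     An = unname(an[ok]), Cn = unname(cn[ok]),
                     stringsAsFactors = FALSE)
  # strict 1:1:1:1: drop every quartet touching a multiply-used gene
  bad <- rep(FALSE, nrow(cand))
  for (col in c("Ar", "Co", "An", "Cn")) {
    bad <- bad | cand[[col]] %in% cand[[col]][duplicated(cand[[col]])]
  }
  cand <- cand[!bad, , drop = FALSE]
  cand <- cand[order(cand$Ar), , drop = FALSE]
  rownames(cand) <- NULL
  if (nrow(cand) > 0) {
    cand <- cbind(tetrad_id = sprintf("tetrad_%05d", seq_len(nrow(cand))), cand,
                  stringsAsFactors = FALSE)
  } else {
    cand <- data.frame(tetrad_id = character(), Ar = character(), Co = character(),
                       An = character(), Cn = character(), stringsAsFactors = FALSE)
  }
  cand
}

#' Identify homoeologous tetrads from four gene-sequence sets
#'
#' Convenience wrapper: reciprocal best hits and collinearity filtering for
#' the Ar-Co, Ar-An, Co-Cn (and optionally An-Cn) genome pairs, then quartet
#' assembly.
#'
#' @param gene_seqs Named list of named character vectors (Ar, Co, An, Cn).
#' @param gene_orders Named list of per-genome gene orderings (chromosome ->
#'   ordered gene ids).
#' @param min_anchors,max_gap,min_cscore See [collinear_chains()].
#' @param require_closed_quartet See [assemble_tetrads()].
#' @return data.frame of tetrads.
#' @export
find_tetrads <- function(gene_seqs, gene_orders, min_anchors = 4L, max_gap = 10L,
                         min_cscore = 0.99, require_closed_quartet = FALSE) {
  syn <- function(a, b) {
    bh <- best_hits(gene_seqs[[a]], gene_seqs[[b]])
    collinear_chains(bh, gene_orders[[a]], gene_orders[[b]],
                     min_anchors = min_anchors, max_gap = max_gap,
                     min_cscore = min_cscore)
  }
  ar_co <- syn("Ar", "Co"); ar_an <- syn("Ar", "An"); co_cn <- syn("Co", "Cn")
  an_cn <- if (require_closed_quartet) syn("An", "Cn") else NULL
  assemble_tetrads(ar_co, ar_an, co_cn, an_cn,
                   require_closed_quartet = require_closed_quartet)
}
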