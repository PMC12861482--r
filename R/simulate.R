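# Synthetic four-(sub)genome benchmark with known truth at every layer.
#
# Each gene occupies a "slot" built in transcription direction from pieces:
#   s0 | W1 | s1 | W2 | s2 | W3 | s3 | W4 | s4 | W5 | s5a | body | sp
# where W1..W5 are fixed 160-bp mark windows (H3K4me3, H3K4me1, H3K27me3,
# H3K9me2, ACR) upstream of the TSS, s* are background segments, body is the
# 600-bp gene body starting at the TSS (its first 500 bp are the promoter's
# downstream part), and sp is an intergenic spacer. Keeping windows as
# separate pieces lets the generator (i) confine class-defining sequence
# edits to a mark's own peak footprint, (ii) compute exact genome coordinates
# for every window after indels elsewhere in the slot, and (iii) derive truth
# labels from piece identity rather than re-alignment.
#
# Per tetrad and mark the generator samples either a convergence scenario
# (epigenomic: peak presence equalised in An/Cn while Ar/Co stay divergent;
# sequence: the Ar window replacement is inherited by An and copied to Cn) or
# independent Class I/II/III labels for the two derivation pairs Ar-An and
# Co-Cn:
#   I   window inherited verbatim, peak in both members
#   II  window inherited verbatim, peak in exactly one member
#   III child window replaced by random sequence, peak in exactly one member
# Window replacements are length-neutral so that a replaced window still
# lifts (as mismatch columns) but fails the identity threshold -- exactly the
# failure mode the classifier must detect. All four pair labels (including
# Ar-Co and An-Cn) then follow from window-content identity and peak
# presence, which is how the truth table is filled in.

WINDOW_LEN <- 160L
WINDOW_MARKS <- c("H3K4me3", "H3K4me1", "H3K27me3", "H3K9me2", "ACR")
BODY_LEN <- 600L
SPACER_LEN <- 150L
PIECE_NAMES <- c("s0", "w1", "s1", "w2", "s2", "w3", "s3", "w4", "s4", "w5",
                 "s5a", "body", "sp")
ANC_PIECE_LENS <- c(s0 = 40L, w1 = WINDOW_LEN, s1 = 120L, w2 = WINDOW_LEN,
                    s2 = 120L, w3 = WINDOW_LEN, s3 = 120L, w4 = WINDOW_LEN,
                    s4 = 120L, w5 = WINDOW_LEN, s5a = 180L,
                    body = BODY_LEN, sp = SPACER_LEN)

#' Default simulation configuration
#'
#' The defaults define the benchmark's study conditions: moderate promoter
#' divergence (1% substitutions and 0.1% indels per branch, 15% of promoters
#' receiving a 60-120 bp structural variant downstream of the TSS), a
#' Class I/II/III mix of 50/30/20% per mark and derivation pair, 8%
#' epigenomic- and 8% sequence-convergence implants, an An branch mutating at
#' twice the base rate (the subgenome asymmetry), a 4-fold expression effect
#' per activating/repressive peak, and pair expression noise growing with
#' class (sigma 0.2/0.6/1.2 on the log2 scale).
#'
#' @param n_tetrads Number of homoeologous tetrads to simulate.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param class_mix Probabilities over Class I/II/III per derivation pair.
#' @param snv_rate,indel_rate Per-base substitution/indel probabilities per
#'   branch (background segments; windows are edited only by class labels).
#' @param sv_prob Per-promoter probability of one structural variant
#'   (downstream of the TSS) per derivation branch.
#' @param sv_len_range Structural-variant length range in bp (> 50).
#' @param diploid_window_div Probability that a diploid's mark window diverged
#'   from the ancestor (drives Ar-Co baseline divergence).
#' @param conv_epi_prob,conv_seq_prob Per-tetrad-per-mark probabilities of an
#'   implanted epigenomic / sequence convergence scenario.
#' @param expression_sigma Log2 expression noise per class (named I/II/III).
#' @param diploid_expr_sigma Log2 expression noise of each diploid.
#' @param mark_effect Multiplicative expression effect of an activating peak
#'   (repressive peaks divide by it).
#' @param motif_implant_prob Per-site implant probability (8 candidate sites
#'   per ancestral promoter).
#' @param tet_motif_gain_prob Per-promoter probability of one novel motif
#'   gain on each tetraploid branch (multiplied by `an_rate_mult` for An);
#'   gains create tetraploid-only TFBSs, the events that lower the
#'   conservation score.
#' @param sv_motif_prob Probability that an SV insertion carries a novel
#'   motif instance (couples variant length to TFBS turnover).
#' @param disrupt_motif_prob Probability that a Class III window replacement
#'   embeds a novel motif instance.
#' @param an_rate_mult Multiplier on all mutation rates of the An branch.
#' @param an_extra_motif_prob Probability of one extra An-only motif implant
#'   per promoter (0 by default; used for gain-of-site experiments).
#' @param n_chroms Chromosomes per genome.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_tetrads = 200L, seed = 1L,
                       class_mix = c(I = 0.5, II = 0.3, III = 0.2),
                       snv_rate = 0.01, indel_rate = 0.001,
                       sv_prob = 0.15, sv_len_range = c(60L, 120L),
                       diploid_window_div = 0.15,
                       conv_epi_prob = 0.08, conv_seq_prob = 0.08,
                       expression_sigma = c(I = 0.2, II = 0.6, III = 1.2),
                       diploid_expr_sigma = 0.8,
                       mark_effect = 4,
                       motif_implant_prob = 0.5,
                       tet_motif_gain_prob = 0.25,
                       sv_motif_prob = 0.5,
                       disrupt_motif_prob = 0.3,
                       an_rate_mult = 2,
                       an_extra_motif_prob = 0,
                       n_chroms = 3L) {
  if (n_tetrads < 1) stopf("n_tetrads must be >= 1")
  if (abs(sum(class_mix) - 1) > 1e-9) stopf("class_mix must sum to 1")
  rates <- c(snv_rate, indel_rate, sv_prob, diploid_window_div,
             conv_epi_prob, conv_seq_prob, motif_implant_prob, an_extra_motif_prob)
  if (any(rates < 0 | rates > 1)) stopf("rates must lie in [0, 1]")
  if (sv_len_range[1] <= 50) stopf("sv_len_range must exceed the 50 bp InDel bound")
  structure(list(n_tetrads = as.integer(n_tetrads), seed = as.integer(seed),
                 class_mix = class_mix, snv_rate = snv_rate,
                 indel_rate = indel_rate, sv_prob = sv_prob,
                 sv_len_range = as.integer(sv_len_range),
                 diploid_window_div = diploid_window_div,
                 conv_epi_prob = conv_epi_prob, conv_seq_prob = conv_seq_prob,
                 expression_sigma = expression_sigma,
                 diploid_expr_sigma = diploid_expr_sigma,
                 mark_effect = mark_effect,
                 motif_implant_prob = motif_implant_prob,
                 tet_motif_gain_prob = tet_motif_gain_prob,
                 sv_motif_prob = sv_motif_prob,
                 disrupt_motif_prob = disrupt_motif_prob,
                 an_rate_mult = an_rate_mult,
                 an_extra_motif_prob = an_extra_motif_prob,
                 n_chroms = as.integer(n_chroms)),
            class = "sim_config")
}

# one global PRNG; sub-streams per stage keyed by stage name
STAGE_OFFSETS <- c(ancestor = 101L, genomes = 202L, expression = 303L)
stage_seed <- function(cfg, stage) {
  (cfg$seed %% 1000000L) * 1000L + STAGE_OFFSETS[[stage]]
}

#' Path of the packaged synthetic PWM library
#' @return File path inside the installed package.
#' @export
packaged_pwm_library <- function() {
  system.file("extdata", "motifs_synthetic.jaspar", package = "homeoconverge",
              mustWork = TRUE)
}

sample_motif_instance <- function(pwm, noise = 0.1) {
  consensus <- rownames(pwm$prob)[apply(pwm$prob, 2, which.max)]
  flip <- runif(length(consensus)) < noise
  consensus[flip] <- vapply(consensus[flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(consensus, collapse = "")
}

#' Simulate the ancestral gene set
#'
#' Generates `n_tetrads` ancestral gene slots (promoter + body + spacer) of
#' i.i.d. uniform DNA with motif instances implanted at up to 8 random
#' promoter sites (consensus sampled with 10% per-position noise), assigned
#' in collinear order to chromosomes.
#'
#' @param cfg A `sim_config`.
#' @param pwms PWM library (defaults to the packaged synthetic library).
#' @return List with `pieces` (per tetrad: named character vector of slot
#'   pieces), `motifs` (data.frame tetrad, motif_id, offset), `chrom`,
#'   `strand` assignments.
#' @export
simulate_ancestor <- function(cfg, pwms = read_pwm_library(packaged_pwm_library())) {
  set.seed(stage_seed(cfg, "ancestor"))
  n <- cfg$n_tetrads
  pieces <- vector("list", n)
  motif_rows <- list()
  for (i in seq_len(n)) {
    prom <- random_dna(2000L)
    n_sites <- 8L
    implant <- which(runif(n_sites) < cfg$motif_implant_prob)
    for (s in implant) {
      # harmonic weights: per-motif target counts spread over a wide range,
      # as real TF motif target counts do
      pwm <- pwms[[sample(length(pwms), 1, prob = 1 / seq_along(pwms))]]
      L <- ncol(pwm$prob)
      off <- sample.int(1990L - L, 1)  # anywhere in the promoter
      inst <- sample_motif_instance(pwm)
      substr(prom, off + 1L, off + L) <- inst
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(tetrad = i, motif_id = pwm$motif_id, offset = off,
                   stringsAsFactors = FALSE)
    }
    slot <- paste0(prom, random_dna(BODY_LEN - 500L), random_dna(SPACER_LEN))
    # split into pieces at ancestral boundaries
    ends <- cumsum(ANC_PIECE_LENS)
    starts <- c(0L, ends[-length(ends)])
    pc <- substring(slot, starts + 1L, ends)
    names(pc) <- PIECE_NAMES
    pieces[[i]] <- pc
  }
  chrom <- sort(rep_len(seq_len(cfg$n_chroms), n))
  strand <- rep_len(c("+", "-"), n)
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(tetrad = integer(), motif_id = character(), offset = integer())
  list(pieces = pieces, motifs = motifs, chrom = chrom, strand = strand,
       pwms = pwms)
}

# background edits on one segment string: substitutions + short indels
mutate_segment <- function(s, snv_rate, indel_rate) {
  n <- nchar(s)
  if (n == 0 || (snv_rate == 0 && indel_rate == 0)) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  sub_idx <- which(runif(n) < snv_rate)
  for (i in sub_idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  n_ind <- rbinom(1, n, indel_rate)
  for (k in seq_len(n_ind)) {
    pos <- sample.int(length(ch), 1)
    len <- sample.int(8L, 1)
    if (runif(1) < 0.5) {
      ch <- append(ch, strsplit(random_dna(len), "")[[1]], after = pos)
    } else {
      drop <- pos:min(pos + len - 1L, length(ch))
      if (length(drop) < length(ch)) ch <- ch[-drop]
    }
  }
  paste(ch, collapse = "")
}

# a random sequence of length n, optionally embedding a novel motif instance
novel_sequence <- function(n, pwms, motif_prob) {
  s <- random_dna(n)
  if (!is.null(pwms) && runif(1) < motif_prob) {
    pwm <- pwms[[sample(length(pwms), 1)]]
    L <- ncol(pwm$prob)
    if (n > L + 2L) {
      off <- sample.int(n - L, 1)
      substr(s, off + 1L, off + L) <- sample_motif_instance(pwm, noise = 0)
    }
  }
  s
}

# one structural variant downstream of the TSS (inside the body's first 500 bp)
apply_sv <- function(body, cfg, pwms = NULL) {
  len <- sample(cfg$sv_len_range[1]:cfg$sv_len_range[2], 1)
  pos <- sample(20:380, 1)
  if (runif(1) < 0.5) {
    ins <- novel_sequence(len, pwms, cfg$sv_motif_prob)
    paste0(substr(body, 1, pos), ins, substr(body, pos + 1L, nchar(body)))
  } else {
    if (pos + len + 20L > nchar(body)) pos <- nchar(body) - len - 20L
    paste0(substr(body, 1, pos), substr(body, pos + len + 1L, nchar(body)))
  }
}

derive_child_pieces <- function(parent, cfg, mult = 1, pwms = NULL, tet = FALSE) {
  out <- parent
  for (nm in c("s0", "s1", "s2", "s3", "s4", "s5a", "sp")) {
    out[[nm]] <- mutate_segment(parent[[nm]], cfg$snv_rate * mult, cfg$indel_rate * mult)
  }
  out[["body"]] <- mutate_segment(parent[["body"]], cfg$snv_rate * mult, 0)
  if (runif(1) < min(1, cfg$sv_prob * mult)) out[["body"]] <- apply_sv(out[["body"]], cfg, pwms)
  if (tet && !is.null(pwms) && runif(1) < min(1, cfg$tet_motif_gain_prob * mult)) {
    # novel motif gain on the tetraploid branch, in a random upstream segment
    seg_nm <- sample(c("s0", "s1", "s2", "s3", "s4"), 1)
    seg <- out[[seg_nm]]
    pwm <- pwms[[sample(length(pwms), 1)]]
    L <- ncol(pwm$prob)
    if (nchar(seg) > L + 2L) {
      off <- sample.int(nchar(seg) - L, 1)
      substr(seg, off + 1L, off + L) <- sample_motif_instance(pwm, noise = 0)
      out[[seg_nm]] <- seg
    }
  }
  out  # windows inherited verbatim; class labels overwrite them separately
}

# truth pair label from window content and peak presence (length-neutral
# window replacements always lift, so epigenome conservation reduces to joint
# peak presence and sequence conservation to content identity)
truth_pair_label <- function(win1, win2, peak1, peak2) {
  if (!peak1 && !peak2) {
    return(list(seq = NA, epi = NA, klass = "no_peak"))
  }
  seq_c <- identical(win1, win2)
  epi_c <- peak1 && peak2
  klass <- if (seq_c && epi_c) "I" else if (seq_c) "II"
    else if (!epi_c) "III" else "unclassified"
  list(seq = seq_c, epi = epi_c, klass = klass)
}

#' Derive the four (sub)genomes from the ancestor
#'
#' Ar and Co diverge independently from the ancestor; An and Cn derive from
#' Ar and Co respectively, the An branch mutating at `an_rate_mult` times the
#' base rates. Class labels (sampled per tetrad, mark and derivation pair
#' from `class_mix`) and convergence implants decide window replacement and
#' peak presence as described above.
#'
#' @param ancestor Result of [simulate_ancestor()].
#' @param cfg A `sim_config`.
#' @return List with `assemblies`, `genes`, `gene_seqs`, `peaks` (per-genome
#'   lists), `tetrads` (truth tetrad table) and `truth` (list with `pairs`,
#'   `convergence`, `pair_class` used for expression coupling, `motifs`).
#' @export
derive_four_genomes <- function(ancestor, cfg) {
  set.seed(stage_seed(cfg, "genomes"))
  n <- cfg$n_tetrads
  genomes <- GENOME_LABELS
  marks <- WINDOW_MARKS
  win_names <- paste0("w", 1:5)

  pwms <- ancestor$pwms
  pieces <- list()  # genome -> list of per-tetrad piece vectors
  # diploids first (background edits; windows from ancestor, possibly diverged)
  for (g in c("Ar", "Co")) {
    pieces[[g]] <- lapply(ancestor$pieces, derive_child_pieces, cfg = cfg, pwms = pwms)
  }
  # diploid window divergence relative to the ancestor
  for (i in seq_len(n)) {
    for (w in win_names) {
      for (g in c("Ar", "Co")) {
        if (runif(1) < cfg$diploid_window_div) {
          pieces[[g]][[i]][[w]] <- random_dna(WINDOW_LEN)
        }
      }
    }
  }
  # tetraploid subgenomes: background edits on top of their progenitors
  pieces[["An"]] <- lapply(pieces[["Ar"]], derive_child_pieces, cfg = cfg,
                           mult = cfg$an_rate_mult, pwms = pwms, tet = TRUE)
  pieces[["Cn"]] <- lapply(pieces[["Co"]], derive_child_pieces, cfg = cfg,
                           pwms = pwms, tet = TRUE)

  # peak presence and window edits per tetrad x mark
  peak_present <- array(FALSE, dim = c(n, length(marks), 4),
                        dimnames = list(NULL, marks, genomes))
  scenario <- matrix("independent", n, length(marks), dimnames = list(NULL, marks))
  pair_class <- array(NA_character_, dim = c(n, length(marks), 2),
                      dimnames = list(NULL, marks, c("Ar-An", "Co-Cn")))
  sample_class <- function() sample(names(cfg$class_mix), 1, prob = cfg$class_mix)
  for (i in seq_len(n)) {
    for (mi in seq_along(marks)) {
      w <- win_names[mi]
      u <- runif(1)
      if (u < cfg$conv_epi_prob) {
        scenario[i, mi] <- "conv_epi"
        # windows untouched; diploid peaks divergent, subgenome peaks equalised
        dip_with_peak <- sample(c("Ar", "Co"), 1)
        peak_present[i, mi, dip_with_peak] <- TRUE
        peak_present[i, mi, c("An", "Cn")] <- TRUE
        pieces[["An"]][[i]][[w]] <- pieces[["Ar"]][[i]][[w]]
        pieces[["Cn"]][[i]][[w]] <- pieces[["Co"]][[i]][[w]]
        # make the window ancestral on all four so the sequence layer is clean
        for (g in genomes) pieces[[g]][[i]][[w]] <- ancestor$pieces[[i]][[w]]
        pair_class[i, mi, ] <- ifelse(c("Ar", "Co") == dip_with_peak, "I", "II")
      } else if (u < cfg$conv_epi_prob + cfg$conv_seq_prob) {
        scenario[i, mi] <- "conv_seq"
        # Ar carries a window replacement; An inherits it and Cn receives a
        # copy of the same edit, while Co stays ancestral
        repl <- novel_sequence(WINDOW_LEN, pwms, cfg$disrupt_motif_prob)
        pieces[["Ar"]][[i]][[w]] <- repl
        pieces[["An"]][[i]][[w]] <- repl
        pieces[["Cn"]][[i]][[w]] <- repl
        pieces[["Co"]][[i]][[w]] <- ancestor$pieces[[i]][[w]]
        peak_present[i, mi, c("Ar", "An", "Cn")] <- TRUE
        pair_class[i, mi, ] <- c("I", "III")
      } else {
        for (pi in 1:2) {
          parent <- c("Ar", "Co")[pi]; child <- c("An", "Cn")[pi]
          cl <- sample_class()
          pair_class[i, mi, pi] <- cl
          pieces[[child]][[i]][[w]] <- pieces[[parent]][[i]][[w]]
          if (cl == "I") {
            peak_present[i, mi, c(parent, child)] <- TRUE
          } else if (cl == "II") {
            peak_present[i, mi, sample(c(parent, child), 1)] <- TRUE
          } else {
            pieces[[child]][[i]][[w]] <- novel_sequence(WINDOW_LEN, pwms,
                                                        cfg$disrupt_motif_prob)
            peak_present[i, mi, sample(c(parent, child), 1)] <- TRUE
          }
        }
      }
    }
  }

  # optional An-only motif gains, sampled proportionally to how often each
  # motif occurs in the ancestral implants so gains scale with target counts
  gain_rows <- list()
  if (cfg$an_extra_motif_prob > 0) {
    w <- table(factor(ancestor$motifs$motif_id, levels = names(ancestor$pwms)))
    w <- as.numeric(w)
    if (sum(w) == 0) w <- rep(1, length(ancestor$pwms))
    for (i in seq_len(n)) {
      if (runif(1) < cfg$an_extra_motif_prob) {
        pwm <- ancestor$pwms[[sample(length(ancestor$pwms), 1, prob = w)]]
        L <- ncol(pwm$prob)
        seg <- pieces[["An"]][[i]][["s5a"]]
        if (nchar(seg) > L + 2L) {
          off <- sample.int(nchar(seg) - L, 1)
          substr(seg, off + 1L, off + L) <- sample_motif_instance(pwm, noise = 0)
          pieces[["An"]][[i]][["s5a"]] <- seg
          gain_rows[[length(gain_rows) + 1L]] <-
            data.frame(tetrad = i, motif_id = pwm$motif_id, stringsAsFactors = FALSE)
        }
      }
    }
  }

  # assemble chromosomes, gene models, peaks (slots pasted per chromosome in
  # one pass; slot starts from cumulative lengths)
  pad <- 300L
  assemblies <- list(); genes <- list(); gene_seqs <- list(); peaks <- list()
  gene_ids <- sprintf("G%05d", seq_len(n))
  for (g in genomes) {
    slot_seq <- character(n); slot_len <- integer(n); slot_start <- integer(n)
    offs_list <- vector("list", n)
    for (i in seq_len(n)) {
      pc <- pieces[[g]][[i]]
      lens <- nchar(pc)
      slot <- paste(pc, collapse = "")
      slot_len[i] <- nchar(slot)
      slot_seq[i] <- if (ancestor$strand[i] == "+") slot else revcomp(slot)
      offs <- cumsum(c(0L, lens))[seq_along(lens)]
      names(offs) <- names(lens)
      offs_list[[i]] <- list(offs = offs, lens = lens)
    }
    chrom_of <- paste0(g, "_chr", ancestor$chrom)
    chrom_seq <- setNames(character(cfg$n_chroms), paste0(g, "_chr", seq_len(cfg$n_chroms)))
    for (ch in names(chrom_seq)) {
      idx <- which(chrom_of == ch)
      starts <- pad + cumsum(c(0L, (slot_len + pad)[idx]))[seq_along(idx)]
      slot_start[idx] <- starts
      chrom_seq[[ch]] <- paste0(strrep("N", pad),
                                paste0(slot_seq[idx], collapse = strrep("N", pad)),
                                collapse = "")
    }
    gs <- character(n)
    gm_start <- integer(n); gm_end <- integer(n); gm_tss <- integer(n)
    pk_chrom <- character(0); pk_start <- integer(0); pk_end <- integer(0)
    pk_mark <- character(0); pk_score <- numeric(0)
    for (i in seq_len(n)) {
      lens <- offs_list[[i]]$lens; offs <- offs_list[[i]]$offs
      L <- slot_len[i]
      strand <- ancestor$strand[i]
      up_len <- offs[["body"]]
      if (strand == "+") {
        gm_start[i] <- slot_start[i] + up_len
        gm_end[i] <- gm_start[i] + lens[["body"]]
        gm_tss[i] <- gm_start[i]
      } else {
        gm_end[i] <- slot_start[i] + L - up_len
        gm_start[i] <- gm_end[i] - lens[["body"]]
        gm_tss[i] <- gm_end[i] - 1L
      }
      gs[i] <- pieces[[g]][[i]][["body"]]
      for (mi in seq_along(marks)) {
        if (!peak_present[i, mi, g]) next
        w <- win_names[mi]
        a <- offs[[w]]; b <- a + lens[[w]]
        iv <- if (strand == "+") c(slot_start[i] + a, slot_start[i] + b)
              else c(slot_start[i] + L - b, slot_start[i] + L - a)
        pk_chrom <- c(pk_chrom, chrom_of[i]); pk_start <- c(pk_start, iv[1])
        pk_end <- c(pk_end, iv[2]); pk_mark <- c(pk_mark, marks[mi])
        pk_score <- c(pk_score, round(runif(1, 5, 15), 2))
      }
    }
    names(gs) <- paste0(g, gene_ids)
    assemblies[[g]] <- structure(chrom_seq, label = g,
                                 lengths = setNames(nchar(chrom_seq), names(chrom_seq)),
                                 class = "genome_assembly")
    genes[[g]] <- data.frame(gene_id = paste0(g, gene_ids), chrom = chrom_of,
                             strand = ancestor$strand, start = gm_start,
                             end = gm_end, tss = gm_tss, stringsAsFactors = FALSE)
    gene_seqs[[g]] <- gs
    peaks[[g]] <- data.frame(chrom = pk_chrom, start = pk_start, end = pk_end,
                             mark = pk_mark, score = pk_score,
                             stringsAsFactors = FALSE)
  }

  tetrads <- data.frame(tetrad_id = sprintf("tetrad_%05d", seq_len(n)),
                        Ar = paste0("Ar", gene_ids), Co = paste0("Co", gene_ids),
                        An = paste0("An", gene_ids), Cn = paste0("Cn", gene_ids),
                        stringsAsFactors = FALSE)

  # truth labels for all four evaluated pairs
  pair_defs <- list(c("Ar", "An"), c("Co", "Cn"), c("Ar", "Co"), c("An", "Cn"))
  n_rows <- n * length(marks) * length(pair_defs)
  t_tid <- character(n_rows); t_pair <- character(n_rows); t_mark <- character(n_rows)
  t_seq <- logical(n_rows); t_epi <- logical(n_rows); t_klass <- character(n_rows)
  r <- 0L
  for (i in seq_len(n)) {
    for (mi in seq_along(marks)) {
      w <- win_names[mi]
      for (pd in pair_defs) {
        lb <- truth_pair_label(pieces[[pd[1]]][[i]][[w]], pieces[[pd[2]]][[i]][[w]],
                               peak_present[i, mi, pd[1]], peak_present[i, mi, pd[2]])
        r <- r + 1L
        t_tid[r] <- tetrads$tetrad_id[i]
        t_pair[r] <- paste0(pd[1], "-", pd[2])
        t_mark[r] <- marks[mi]
        t_seq[r] <- lb$seq; t_epi[r] <- lb$epi; t_klass[r] <- lb$klass
      }
    }
  }
  truth_pairs <- data.frame(tetrad_id = t_tid, pair = t_pair, mark = t_mark,
                            seq_conserved = t_seq, epi_conserved = t_epi,
                            klass = t_klass, stringsAsFactors = FALSE)

  # convergence truth from the pair truth labels
  conv_rows <- list()
  for (mk in marks) {
    tp <- truth_pairs[truth_pairs$mark == mk, ]
    ancn <- tp[tp$pair == "An-Cn", ]; arco <- tp[tp$pair == "Ar-Co", ]
    arco <- arco[match(ancn$tetrad_id, arco$tetrad_id), ]
    for (layer in c("epigenomic", "sequence")) {
      cons <- if (layer == "epigenomic") !is.na(ancn$epi_conserved) & ancn$epi_conserved
              else !is.na(ancn$seq_conserved) & ancn$seq_conserved
      dstat <- if (layer == "epigenomic") arco$epi_conserved else arco$seq_conserved
      cat <- ifelse(arco$klass == "no_peak", "others",
             ifelse(!is.na(dstat) & dstat, "same", "convergent"))
      sel <- which(cons)
      if (length(sel)) {
        conv_rows[[length(conv_rows) + 1L]] <- data.frame(
          tetrad_id = ancn$tetrad_id[sel], mark = mk, layer = layer,
          category = cat[sel],
          implanted = scenario[match(ancn$tetrad_id[sel], tetrads$tetrad_id), mk] ==
            if (layer == "epigenomic") "conv_epi" else "conv_seq",
          stringsAsFactors = FALSE)
      }
    }
  }
  truth_conv <- do.call(rbind, conv_rows)

  list(assemblies = assemblies, genes = genes, gene_seqs = gene_seqs,
       peaks = peaks, tetrads = tetrads,
       truth = list(pairs = truth_pairs, convergence = truth_conv,
                    pair_class = pair_class, peak_present = peak_present,
                    scenario = scenario, motifs = ancestor$motifs,
                    an_gains = if (length(gain_rows)) do.call(rbind, gain_rows) else NULL))
}

#' Simulate gene expression coupled to peak truth
#'
#' Base expression per tetrad is lognormal; each activating peak (H3K4me3,
#' ACR) multiplies the expectation by `mark_effect` and each repressive peak
#' (H3K27me3, H3K9me2) divides by it. Diploid values add independent log2
#' noise of sd `diploid_expr_sigma`; each subgenome adds noise around its
#' progenitor with sd `expression_sigma[class]`, class being the worst
#' (highest) class of its derivation pair across marks.
#'
#' @param derived Result of [derive_four_genomes()].
#' @param cfg A `sim_config`.
#' @return Named list (Ar, Co, An, Cn) of named TPM vectors.
#' @export
simulate_expression <- function(derived, cfg) {
  set.seed(stage_seed(cfg, "expression"))
  n <- nrow(derived$tetrads)
  base <- rlnorm(n, meanlog = log(10), sdlog = 1)
  pp <- derived$truth$peak_present
  mark_mult <- function(g) {
    m <- rep(1, n)
    for (mk in WINDOW_MARKS) {
      eff <- ifelse(pp[, mk, g], cfg$mark_effect, 1)
      if (mk %in% REPRESSIVE_MARKS) m <- m / eff else m <- m * eff
    }
    m
  }
  worst_class <- function(pair) {
    cl <- derived$truth$pair_class[, , pair, drop = FALSE]
    apply(cl, 1, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) "I" else c("I", "II", "III")[max(match(x, c("I", "II", "III")))]
    })
  }
  sig_an <- cfg$expression_sigma[worst_class("Ar-An")]
  sig_cn <- cfg$expression_sigma[worst_class("Co-Cn")]
  ar <- base * mark_mult("Ar") * 2^rnorm(n, 0, cfg$diploid_expr_sigma)
  co <- base * mark_mult("Co") * 2^rnorm(n, 0, cfg$diploid_expr_sigma)
  an <- ar / mark_mult("Ar") * mark_mult("An") * 2^rnorm(n, 0, sig_an)
  cn <- co / mark_mult("Co") * mark_mult("Cn") * 2^rnorm(n, 0, sig_cn)
  list(Ar = setNames(round(ar, 3), derived$tetrads$Ar),
       Co = setNames(round(co, 3), derived$tetrads$Co),
       An = setNames(round(an, 3), derived$tetrads$An),
       Cn = setNames(round(cn, 3), derived$tetrads$Cn))
}

#' Generate a complete benchmark and write it to disk
#'
#' Emits, per genome: `genome_<g>.fa`, `genes_<g>.gff3`, `geneseq_<g>.fa`
#' (gene-body sequences for orthology), `peaks_<g>_<mark>.bed`,
#' `expr_<g>.tsv`; plus the PWM library copy `motifs.jaspar`, truth tables
#' (`truth_tetrads.tsv`, `truth_pairs.tsv`, `truth_convergence.tsv`,
#' `truth_motifs.tsv`) and the resolved `sim_config.yaml`.
#'
#' @param cfg A `sim_config`.
#' @param outdir Output directory.
#' @return The in-memory benchmark (list as [derive_four_genomes()] plus
#'   `expression` and `dir`), invisibly.
#' @export
simulate_benchmark <- function(cfg, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  anc <- simulate_ancestor(cfg)
  drv <- derive_four_genomes(anc, cfg)
  expr <- simulate_expression(drv, cfg)
  for (g in GENOME_LABELS) {
    write_genome_fasta(drv$assemblies[[g]], file.path(outdir, paste0("genome_", g, ".fa")))
    write_gene_models(drv$genes[[g]], file.path(outdir, paste0("genes_", g, ".gff3")))
    ss <- Biostrings::DNAStringSet(drv$gene_seqs[[g]])
    Biostrings::writeXStringSet(ss, file.path(outdir, paste0("geneseq_", g, ".fa")), width = 80L)
    for (mk in WINDOW_MARKS) {
      pk <- drv$peaks[[g]]
      write_peaks_bed(pk[pk$mark == mk, , drop = FALSE],
                      file.path(outdir, sprintf("peaks_%s_%s.bed", g, mk)))
    }
    write_expression_tsv(expr[[g]], file.path(outdir, paste0("expr_", g, ".tsv")))
  }
  file.copy(packaged_pwm_library(), file.path(outdir, "motifs.jaspar"), overwrite = TRUE)
  write.table(drv$tetrads, file.path(outdir, "truth_tetrads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(drv$truth$pairs, file.path(outdir, "truth_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(drv$truth$convergence, file.path(outdir, "truth_convergence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(drv$truth$motifs, file.path(outdir, "truth_motifs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(outdir, "sim_config.yaml"))
  drv$expression <- expr
  drv$dir <- outdir
  invisible(drv)
}

#' Zero-noise configuration (identical genomes, all Class I)
#' @param n_tetrads Number of tetrads.
#' @param seed Seed.
#' @return A `sim_config` with all divergence switched off.
#' @export
sim_config_zero_noise <- function(n_tetrads = 50L, seed = 1L) {
  sim_config(n_tetrads = n_tetrads, seed = seed,
             class_mix = c(I = 1, II = 0, III = 0),
             snv_rate = 0, indel_rate = 0, sv_prob = 0,
             diploid_window_div = 0, conv_epi_prob = 0, conv_seq_prob = 0,
             expression_sigma = c(I = 0, II = 0, III = 0),
             diploid_expr_sigma = 0, an_rate_mult = 1,
             tet_motif_gain_prob = 0, sv_motif_prob = 0, disrupt_motif_prob = 0)
}
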