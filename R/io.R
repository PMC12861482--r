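# Format IO. Internal coordinates are 0-based half-open everywhere; conversion
# to/from 1-based inclusive happens only at the GFF3 boundary.

#' Read a genome FASTA into an assembly
#'
#' Loads all records of a FASTA file, normalises sequence case to upper case
#' and validates the alphabet (A/C/G/T/N only).
#'
#' @param path Path to a FASTA file.
#' @param label Optional genome label (e.g. `"Ar"`); stored as an attribute.
#' @return An object of class `genome_assembly`: a named character vector of
#'   chromosome sequences with attributes `label` and `lengths`.
#' @export
read_genome_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e)))
  if (length(ss) == 0) stopf("empty FASTA: %s", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stopf("duplicate sequence names in %s: %s", path,
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("non-ACGTN characters in record(s): %s", paste(nm[bad], collapse = ", "))
  structure(seqs, label = label, lengths = setNames(nchar(seqs), nm),
            class = "genome_assembly")
}

#' Write a genome assembly to FASTA
#' @param assembly A `genome_assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(assembly, path) {
  ss <- Biostrings::DNAStringSet(unclass(assembly)[seq_along(assembly)])
  names(ss) <- names(assembly)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Reads `gene` features, converts 1-based inclusive coordinates to internal
#' 0-based half-open, and derives the TSS (start of the span on `+`, end-1 on
#' `-`).
#'
#' @param path GFF3 file path.
#' @param assembly `genome_assembly` used for bounds checking.
#' @return data.frame with columns gene_id, chrom, strand, start, end, tss
#'   (0-based half-open span).
#' @export
read_gene_models <- function(path, assembly) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("malformed GFF3 '%s': %s", path, conditionMessage(e)))
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stopf("no gene features in %s", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-"))) stopf("unknown strand for gene(s) in %s", path)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stopf("gene feature without ID attribute in %s", path)
  if (anyDuplicated(ids)) stopf("duplicate gene ids in %s", path)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L      # to 0-based
  end0 <- GenomicRanges::end(gr)               # half-open
  lens <- attr(assembly, "lengths")
  unknown <- !chrom %in% names(lens)
  if (any(unknown)) stopf("gene(s) on unknown chromosome: %s", paste(ids[unknown], collapse = ", "))
  oob <- start0 < 0 | end0 > lens[chrom]
  if (any(oob)) stopf("gene(s) outside chromosome bounds: %s", paste(ids[oob], collapse = ", "))
  tss <- ifelse(strand == "+", start0, end0 - 1L)
  data.frame(gene_id = as.character(ids), chrom = chrom, strand = strand,
             start = as.integer(start0), end = as.integer(end0),
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

#' Write gene models to GFF3 (inverse of [read_gene_models()])
#' @param genes Gene model data.frame (0-based half-open).
#' @param path Output path.
#' @param source Source column value.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path, source = "homeoconverge") {
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, source, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read peaks from a BED3+ file
#'
#' BED coordinates are 0-based half-open and preserved bit-exact. Column 5,
#' when present, is taken as the peak score (real-valued); otherwise 0.
#'
#' @param path BED file path.
#' @param mark Mark type, one of H3K4me3, H3K4me1, H3K27me3, H3K9me2, ACR.
#' @return data.frame with columns chrom, start, end, mark, score.
#' @export
read_peaks_bed <- function(path, mark) {
  mark <- match.arg(mark, MARKS)
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mark = character(), score = numeric(), stringsAsFactors = FALSE))
  }
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  if (ncol(tb) < 3) stopf("BED file %s has fewer than 3 columns", path)
  start <- as.integer(tb[[2]]); end <- as.integer(tb[[3]])
  if (any(is.na(start)) || any(is.na(end))) stopf("non-integer coordinates in %s", path)
  if (any(start >= end)) stopf("start >= end in %s (line %d)", path, which(start >= end)[1])
  if (any(start < 0)) stopf("negative start in %s", path)
  score <- if (ncol(tb) >= 5) suppressWarnings(as.numeric(tb[[5]])) else rep(0, nrow(tb))
  score[is.na(score)] <- 0
  data.frame(chrom = as.character(tb[[1]]), start = start, end = end,
             mark = mark, score = score, stringsAsFactors = FALSE)
}

#' Write peaks to BED6
#' @param peaks Peak data.frame (chrom, start, end, mark, score).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  tb <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   paste0(peaks$mark, "_", seq_len(max(nrow(peaks), 0))),
                   peaks$score, ".")
  write.table(tb[seq_len(nrow(peaks)), , drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-level expression table (TSV: gene_id, tpm)
#' @param path TSV path with header columns `gene_id` and `tpm`.
#' @return Named numeric vector of TPM values.
#' @export
read_expression_tsv <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tpm") %in% names(tb))) stopf("expression table %s needs gene_id, tpm columns", path)
  if (any(tb$tpm < 0)) stopf("negative TPM in %s", path)
  setNames(tb$tpm, tb$gene_id)
}

#' Write an expression table
#' @param tpm Named numeric vector (gene_id -> TPM).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(tpm, path) {
  write.table(data.frame(gene_id = names(tpm), tpm = unname(tpm)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables as TSV with deterministic row order
#'
#' Each table is sorted by `tetrad_id` then `mark` when those columns exist,
#' so reruns on identical inputs produce byte-identical files.
#'
#' @param tables Named list of data.frames.
#' @param outdir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(tables, outdir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory %s", outdir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    keys <- intersect(c("tetrad_id", "mark"), names(tb))
    if (length(keys) > 0 && nrow(tb) > 0) {
      tb <- tb[do.call(order, tb[keys]), , drop = FALSE]
    }
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tb, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Read a run configuration YAML
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}
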