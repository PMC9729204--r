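# File input/output for the standard formats.  Internally everything is
# 0-based half-open; BED is native, VCF positions are converted from 1-based.

#' Load and normalize design inputs
#'
#' Reads any subset of the four input file types: template sequences (FASTA),
#' template regions (BED), target spots (BED or VCF) and pre-designed primer
#' lists (TSV with columns id, seq), plus an optional specificity reference
#' and common-variant VCF.  Coordinates are normalized to 0-based half-open;
#' VCF positions are 1-based on input and converted.
#'
#' @param templates FASTA path of template sequences.
#' @param regions BED path of template regions.
#' @param targets BED or VCF path of target spots.
#' @param primers TSV path of pre-designed primers (`id`, `seq`).
#' @param reference FASTA path of the specificity reference (defaults to the
#'   templates).
#' @param snps VCF path of common variants for degenerate masking.
#' @return list with elements `templates` (named character), `regions`,
#'   `targets`, `primers` (data.tables or `NULL`), `reference`, `snps`.
#' @export
load_inputs <- function(templates = NULL, regions = NULL, targets = NULL,
                        primers = NULL, reference = NULL, snps = NULL) {
  out <- list(templates = NULL, regions = NULL, targets = NULL,
              primers = NULL, reference = NULL, snps = NULL)
  if (!is.null(templates)) out$templates <- .as_named_seqs(templates)
  if (!is.null(reference)) out$reference <- .as_named_seqs(reference)
  if (is.null(out$reference)) out$reference <- out$templates
  if (!is.null(regions)) out$regions <- read_bed(regions)
  if (!is.null(targets)) {
    out$targets <- if (grepl("\\.vcf(\\.gz)?$", targets)) {
      vt <- .read_variant_table(targets)
      data.table::data.table(ref_id = vt$chrom, pos = vt$pos - 1L,
                             ref = vt$ref, alt = vt$alt, strand = "+")
    } else {
      b <- read_bed(targets)
      data.table::data.table(ref_id = b$ref_id, pos = b$start,
                             ref = NA_character_, alt = NA_character_,
                             strand = b$strand)
    }
  }
  if (!is.null(primers)) out$primers <- read_primer_list(primers)
  if (!is.null(snps)) out$snps <- .read_variant_table(snps)
  out
}

#' Read a BED file (0-based half-open)
#'
#' @param path BED file path.
#' @return data.table with `ref_id`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  st <- as.character(BiocGenerics::strand(gr))
  data.table::data.table(
    ref_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    strand = data.table::fifelse(st %in% c("+", "-"), st, "+"))
}

#' Write a BED file from 0-based half-open intervals
#'
#' @param dt data.frame with `ref_id`, `start`, `end` (optional `name`,
#'   `strand`).
#' @param path output path.
#' @export
write_bed <- function(dt, path) {
  dt <- data.table::as.data.table(dt)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", dt$ref_id, dt$start, dt$end,
                   if (!is.null(dt$name)) dt$name else ".",
                   if (!is.null(dt$strand)) dt$strand else "+")
  writeLines(lines, path)
  invisible(path)
}

#' Read a pre-designed primer list
#'
#' Tab-separated, two or more columns (`id`, `seq`, extra columns kept); a
#' header line is auto-detected.  Sequences must be plain DNA; an offending
#' line is reported by number.
#'
#' @param path TSV path.
#' @return data.table with `id`, `seq`.
#' @export
read_primer_list <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) stop("empty primer list: ", path)
  skip <- grepl("^#", raw[1]) ||
    grepl("\t(seq|sequence)(\t|$)", tolower(raw[1]))
  body <- if (skip) raw[-1] else raw
  line_no <- which(if (skip) c(FALSE, rep(TRUE, length(raw) - 1)) else
                     rep(TRUE, length(raw)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad_cols <- which(lengths(parts) < 2L)
  if (length(bad_cols))
    stop("primer list line ", line_no[bad_cols[1]], ": need id<TAB>seq")
  id <- vapply(parts, `[[`, "", 1L)
  seq <- toupper(vapply(parts, `[[`, "", 2L))
  bad <- which(!grepl("^[ACGT]+$", seq))
  if (length(bad))
    stop("primer list line ", line_no[bad[1]],
         ": non-ACGT character in sequence '", seq[bad[1]], "'")
  data.table::data.table(id = id, seq = seq)
}

#' Write a minimal VCF (v4.2, CHROM/POS/REF/ALT)
#'
#' @param dt data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param path output path.
#' @param contigs optional named lengths for contig header lines.
#' @export
write_vcf <- function(dt, path, contigs = NULL) {
  dt <- data.table::as.data.table(dt)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", dt$chrom, dt$pos, dt$ref, dt$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write ranked pairs / dimer tables as TSV
#'
#' @param x data.frame (e.g. `pairs` or `dimers` from [design()]).
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  x <- data.table::as.data.table(x)
  listcols <- names(x)[vapply(x, is.list, TRUE)]
  for (cn in listcols)
    data.table::set(x, j = cn,
                    value = vapply(x[[cn]], paste, "", collapse = ","))
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
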