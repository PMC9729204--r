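# Candidate generation by walking along templates, single-primer feature
# extraction and scoring.  All coordinates are 0-based half-open; candidate
# sequences are stored 5'->3' on their own strand.

.IUPAC_MAP <- Biostrings::IUPAC_CODE_MAP
.IUPAC_REV <- stats::setNames(
  names(.IUPAC_MAP),
  vapply(.IUPAC_MAP, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
)

.iupac_union <- function(codes) {
  bases <- unique(unlist(strsplit(unname(.IUPAC_MAP[codes]), "")))
  .IUPAC_REV[[paste(sort(bases), collapse = "")]]
}

.as_named_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("[ACGTNacgtn]{20}", x) && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named (or given as FASTA/DNAStringSet)")
    return(toupper(x))
  }
  stop("cannot interpret reference/template input")
}

#' Mask common variants into a degenerate reference
#'
#' Replaces each substitution position of the reference with the IUPAC
#' ambiguity code covering the reference plus all alternate alleles
#' (multi-allelic records at one position are merged into one code).  Indel
#' records cannot be expressed as single-base codes; they are annotated in a
#' side-channel interval table covering `max(len(REF), len(ALT)) - 1` bases
#' after the anchor base.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param variants VCF path (CHROM/POS/REF/ALT consumed) or a data.frame with
#'   columns `chrom`, `pos` (1-based), `ref`, `alt`; `NULL` for no variants.
#' @param out optional path to write the masked FASTA.
#' @return list with `masked` (named character vector of degenerate sequences)
#'   and `indels` (data.table `ref_id`, `start`, `end`, `length`, 0-based
#'   half-open affected intervals).
#' @export
mask_reference <- function(reference, variants = NULL, out = NULL) {
  seqs <- .as_named_seqs(reference)
  vt <- .read_variant_table(variants)
  indels <- data.table::data.table(ref_id = character(), start = integer(),
                                   end = integer(), length = integer())
  if (NROW(vt)) {
    bad <- setdiff(unique(vt$chrom), names(seqs))
    if (length(bad))
      stop("variant contig(s) not present in reference: ", paste(bad, collapse = ", "))
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
    for (r in seq_len(nrow(vt))) {
      chrom <- vt$chrom[r]; pos0 <- vt$pos[r] - 1L
      ref <- toupper(vt$ref[r]); alts <- toupper(strsplit(vt$alt[r], ",")[[1]])
      if (pos0 < 0L || pos0 + nchar(ref) > length(chars[[chrom]]))
        stop("variant position out of range: ", chrom, ":", vt$pos[r])
      if (nchar(ref) == 1L && all(nchar(alts) == 1L)) {
        have <- chars[[chrom]][pos0 + 1L]
        if (have %in% c("A", "C", "G", "T") && have != ref)
          stop("VCF REF allele disagrees with reference at ", chrom, ":", vt$pos[r])
        chars[[chrom]][pos0 + 1L] <- .iupac_union(c(have, alts))
      } else {
        len <- max(nchar(ref), max(nchar(alts))) - 1L
        indels <- rbind(indels, data.table::data.table(
          ref_id = chrom, start = pos0 + 1L, end = pos0 + 1L + len, length = len))
      }
    }
    seqs <- vapply(chars, paste, "", collapse = "")
  }
  if (!is.null(out)) {
    ss <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(ss, out)
  }
  list(masked = seqs, indels = indels)
}

.read_variant_table <- function(variants) {
  if (is.null(variants))
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  ref = character(), alt = character()))
  if (is.character(variants) && length(variants) == 1L) {
    v <- vcfR::read.vcfR(variants, verbose = FALSE)
    fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    return(data.table::data.table(chrom = fx$CHROM, pos = as.integer(fx$POS),
                                  ref = fx$REF, alt = fx$ALT))
  }
  dt <- data.table::as.data.table(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(dt)))
  dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt))]
}

#' A template region
#'
#' @param ref_id sequence name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return list of class `template_region`.
#' @export
template_region <- function(ref_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("need 0 <= start < end")
  structure(list(ref_id = ref_id, start = start, end = end, strand = strand),
            class = "template_region")
}

#' Generate candidate primers by walking a region
#'
#' Enumerates one candidate per (start position, length) on the configured
#' grid, on the requested strand(s), deterministically ordered by strand,
#' position, then length.  Candidate sequences are taken from the plain
#' reference; degenerate sequences from the masked reference when supplied.
#' Minus-strand candidates are reverse-complemented so `seq` always reads
#' 5'->3' and `three_prime` holds the reference coordinate of the 3'-terminal
#' base.
#'
#' @param region a [template_region()] (or list with `ref_id`, `start`, `end`).
#' @param reference named character vector / `DNAStringSet` / FASTA path.
#' @param masked optional degenerate reference (same shape) from
#'   [mask_reference()].
#' @param min_len,max_len primer length bounds (defaults 18-30).
#' @param pos_step,len_step walking steps (defaults 1 and 2).
#' @param strands subset of `c("+", "-")`.
#' @return data.table with columns `id`, `ref_id`, `strand`, `start`, `end`,
#'   `length`, `three_prime`, `seq`, `degen_seq`.  A region shorter than
#'   `min_len` yields an empty table.
#' @export
walk_candidates <- function(region, reference, masked = NULL,
                            min_len = 18L, max_len = 30L,
                            pos_step = 1L, len_step = 2L,
                            strands = c("+", "-")) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (pos_step < 1L || len_step < 1L) stop("steps must be >= 1")
  seqs <- .as_named_seqs(reference)
  if (!region$ref_id %in% names(seqs)) stop("unknown template: ", region$ref_id)
  tpl <- seqs[[region$ref_id]]
  mtpl <- if (is.null(masked)) tpl else .as_named_seqs(masked)[[region$ref_id]]
  rlen <- region$end - region$start
  grids <- list()
  for (len in seq(as.integer(min_len), as.integer(max_len), by = as.integer(len_step))) {
    if (rlen < len) next
    starts <- seq(region$start, region$end - len, by = as.integer(pos_step))
    grids[[length(grids) + 1L]] <- data.table::data.table(start = starts, length = len)
  }
  if (!length(grids) || !length(intersect(c("+", "-"), strands)))
    return(.empty_candidates())
  g <- data.table::rbindlist(grids)
  data.table::setorder(g, start, length)
  out <- data.table::rbindlist(lapply(intersect(c("+", "-"), strands), function(st) {
    d <- data.table::copy(g)
    d[, `:=`(ref_id = region$ref_id, strand = st, end = start + length)]
    d[, seq := substr(rep(tpl, .N), start + 1L, end)]
    d[, degen_seq := substr(rep(mtpl, .N), start + 1L, end)]
    if (st == "-") {
      d[, seq := .revcomp_chr(seq)]
      d[, degen_seq := .revcomp_chr(degen_seq)]
      d[, three_prime := start]
    } else {
      d[, three_prime := end - 1L]
    }
    d
  }))
  out[, id := paste0(ref_id, ":", strand, ":", start, ":", length)]
  data.table::setcolorder(out, c("id", "ref_id", "strand", "start", "end",
                                 "length", "three_prime", "seq", "degen_seq"))
  out[]
}

.empty_candidates <- function() {
  data.table::data.table(id = character(), ref_id = character(),
                         strand = character(), start = integer(),
                         end = integer(), length = integer(),
                         three_prime = integer(), seq = character(),
                         degen_seq = character())
}

.revcomp_chr <- function(x) {
  y <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(y, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Evaluate the seven single-primer features
#'
#' Computes Tm, GC fraction, self-structure Tm, 3'-terminal A run length,
#' 3'-end stack free energy, covered SNPs (parsed from the degenerate
#' sequence; indel intervals can be injected via `extra_snps`) and homopolymer
#' runs of at least `poly_min` bases.  SNP/poly positions are 0-based
#' distances from the 3' end (terminal base = 0).
#'
#' @param seq plain candidate sequence 5'->3'.
#' @param degen_seq IUPAC degenerate version of `seq` (defaults to `seq`).
#' @param cond [thermo_conditions()].
#' @param extra_snps optional data.frame of additional SNP-like sites
#'   (`dist3`, `length`), e.g. indel side-channel overlaps.
#' @param poly_min minimum homopolymer run length reported (default 4).
#' @return list of class `feature_set` with elements `tm`, `gc`, `self_tm`,
#'   `end_a`, `end_dg`, `snps`, `polys`.
#' @export
extract_features <- function(seq, degen_seq = seq, cond = thermo_conditions(),
                             extra_snps = NULL, poly_min = 4L) {
  n <- nchar(seq)
  ch <- strsplit(toupper(seq), "")[[1]]
  if (nchar(degen_seq) != n) stop("degen_seq must have the same length as seq")
  dch <- strsplit(toupper(degen_seq), "")[[1]]

  gc <- sum(ch %in% c("G", "C")) / n
  end_a <- 0L
  i <- n
  while (i >= 1L && ch[i] == "A") { end_a <- end_a + 1L; i <- i - 1L }

  snp_pos <- which(!dch %in% c("A", "C", "G", "T"))
  snps <- data.frame(dist3 = n - snp_pos, length = rep(1L, length(snp_pos)))
  if (!is.null(extra_snps) && NROW(extra_snps))
    snps <- rbind(snps, as.data.frame(extra_snps)[, c("dist3", "length")])

  r <- rle(ch)
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= poly_min
  polys <- data.frame(dist3 = n - ends[keep], length = r$lengths[keep])

  structure(list(
    tm = oligo_tm(seq, cond),
    gc = gc,
    self_tm = self_structure_tm(seq, cond),
    end_a = end_a,
    end_dg = end_stability_dg(seq),
    snps = snps,
    polys = polys
  ), class = "feature_set")
}

#' Score a single primer
#'
#' Scores each of the seven features with its piecewise logistic model (SNPs
#' and polys with the composite penalty) and returns the weighted total on the
#' 0-100 scale together with the per-feature breakdown.  An all-optimal primer
#' scores exactly 100.
#'
#' @param features a `feature_set` from [extract_features()].
#' @param models registry from [feature_models()] (carries the user's optimal
#'   Tm in its `tm` entry).
#' @param weights primer weight table (see [default_weights()]).
#' @return list with `score`, `breakdown` (named per-feature scores on the
#'   0-1 scale) and `features`.
#' @export
score_primer <- function(features, models = feature_models(),
                         weights = default_weights()$primer) {
  br <- c(
    tm     = piecewise_score(features$tm, models$tm),
    gc     = piecewise_score(features$gc, models$gc),
    self   = piecewise_score(features$self_tm, models$self),
    end_a  = piecewise_score(features$end_a, models$end_a),
    end_dg = piecewise_score(features$end_dg, models$end_dg),
    snp    = site_penalty_score(features$snps, "snp", models),
    poly   = site_penalty_score(features$polys, "poly", models)
  )
  list(score = weighted_total(br, weights), breakdown = br, features = features)
}

# vectorised candidate scoring used by the design orchestration: adds feature
# and score columns to a candidate table (one extract_features/score_primer
# call per row; self-structure search dominates the cost)
.evaluate_candidate_table <- function(cands, cond, models, weights,
                                      indels = NULL, poly_min = 4L) {
  if (!nrow(cands)) {
    cands[, c("tm", "gc", "self_tm", "end_a", "end_dg", "n_snp", "n_poly",
              "score") := numeric(0)]
    return(cands)
  }
  res <- lapply(seq_len(nrow(cands)), function(r) {
    extra <- NULL
    if (!is.null(indels) && nrow(indels)) {
      ov <- indels[ref_id == cands$ref_id[r] & start < cands$end[r] &
                     end > cands$start[r]]
      if (nrow(ov)) {
        os <- pmax(ov$start, cands$start[r]); oe <- pmin(ov$end, cands$end[r])
        d3 <- if (cands$strand[r] == "+") cands$end[r] - oe else os - cands$start[r]
        extra <- data.frame(dist3 = d3, length = oe - os)
      }
    }
    f <- extract_features(cands$seq[r], cands$degen_seq[r], cond,
                          extra_snps = extra, poly_min = poly_min)
    s <- score_primer(f, models, weights)
    c(tm = f$tm, gc = f$gc, self_tm = f$self_tm, end_a = as.numeric(f$end_a),
      end_dg = f$end_dg, n_snp = nrow(f$snps), n_poly = nrow(f$polys),
      s_snp = unname(s$breakdown["snp"]), s_poly = unname(s$breakdown["poly"]),
      score = s$score)
  })
  m <- do.call(rbind, res)
  for (cn in colnames(m)) data.table::set(cands, j = cn, value = m[, cn])
  cands[]
}
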