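# Seeded synthetic fixture generator: random references with duplicated
# segments at controlled divergence (predictable off-target products),
# embedded SNPs, homopolymer runs, target spots, and planted primer binding
# sites with a controlled number of mismatches.  Everything is reproducible
# from the seed and accompanied by machine-readable truth tables.

.random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_positions <- function(seq, pos1) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos1) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- sample(alt, 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic reference fixture
#'
#' Builds a random reference with optional planted structure and writes
#' plain-text FASTA/BED/VCF files plus truth tables for oracle tests:
#'
#' * `duplications`: a source segment copied elsewhere with a given
#'   per-base divergence, creating predictable off-target binding sites;
#' * `snps`: random substitution variants (for degenerate masking);
#' * `homopolymers`: inserted runs of one base;
#' * `targets`: random target spots with ref/alt alleles;
#' * `planted`: copies of a GC-rich probe carrying 0..k substitutions each,
#'   clustered at the probe's 5' end so the 3'-proximal bases (and at least
#'   one exact seed word) are preserved.
#'
#' @param genome_len reference length in bases.
#' @param chrom reference sequence name.
#' @param gc GC fraction of the random background.
#' @param duplications list with `length`, `copies`, `divergence` (fraction),
#'   or `NULL`.
#' @param snps number of random substitution SNPs.
#' @param homopolymers number of inserted homopolymer runs (length 6-10).
#' @param targets number of random target spots.
#' @param planted list with `site_len` (probe length), `n_mismatch` (integer
#'   vector, one planted copy per entry), `gc` (probe GC fraction), or `NULL`.
#' @param seed integer seed fixing all randomness.
#' @param dir output directory for files (`NULL` = no files written).
#' @return list with `reference` (named character), `files` (paths), `snps`,
#'   `targets`, `regions`, and `truth` (per-feature truth tables).
#' @export
generate_fixture <- function(genome_len = 10000L, chrom = "chr1", gc = 0.5,
                             duplications = NULL, snps = 0L,
                             homopolymers = 0L, targets = 0L,
                             planted = NULL, seed = 1L, dir = NULL) {
  set.seed(seed)
  genome_len <- as.integer(genome_len)
  g <- .random_dna(genome_len, gc)
  truth <- list()

  if (!is.null(duplications)) {
    dl <- as.integer(duplications$length)
    if (dl > genome_len %/% (duplications$copies + 1L))
      stop("duplicated segment too long for the genome")
    # lay segment copies on an even grid so they never overlap
    slots <- floor(seq(0L, genome_len - dl, length.out = duplications$copies + 1L))
    src <- substr(g, slots[1] + 1L, slots[1] + dl)
    copies <- data.table::data.table(start = slots[1], divergence = 0,
                                     n_sub = 0L)
    for (i in seq_len(duplications$copies)) {
      n_sub <- round(duplications$divergence * dl)
      mut <- if (n_sub > 0) .mutate_positions(src, sample(dl, n_sub)) else src
      at <- slots[i + 1L]
      substr(g, at + 1L, at + dl) <- mut
      copies <- rbind(copies, data.table::data.table(
        start = at, divergence = duplications$divergence, n_sub = n_sub))
    }
    truth$duplications <- cbind(copies, length = dl)
  }

  if (homopolymers > 0L) {
    hp_starts <- sort(sample(genome_len - 12L, homopolymers))
    hp_len <- sample(6:10, homopolymers, replace = TRUE)
    hp_base <- sample(c("A", "C", "G", "T"), homopolymers, replace = TRUE)
    for (i in seq_len(homopolymers))
      substr(g, hp_starts[i] + 1L, hp_starts[i] + hp_len[i]) <-
        strrep(hp_base[i], hp_len[i])
    truth$homopolymers <- data.table::data.table(
      start = hp_starts, length = hp_len, base = hp_base)
  }

  planted_truth <- NULL
  if (!is.null(planted)) {
    sl <- as.integer(planted$site_len %||% 20L)
    pgc <- planted$gc %||% 0.8
    nm <- as.integer(planted$n_mismatch %||% 0:7)
    # substitutions go at the 5' end, so the probe's 3'-proximal stretch --
    # the part that stays matched in every planted copy -- is built with a
    # fixed high GC count to keep even the most mismatched duplex above the
    # bound-Tm floor (a low-GC tail would make the site unamplifiable, which
    # is a property of the site, not of the search)
    head_len <- min(max(nm), sl - 8L)
    tail_len <- sl - head_len
    n_gc <- round(pgc * tail_len)
    tail <- paste(sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
                           sample(c("A", "T"), tail_len - n_gc, replace = TRUE))),
                  collapse = "")
    probe <- paste0(if (head_len > 0) .random_dna(head_len, gc) else "", tail)
    slots <- floor(seq(genome_len * 0.05, genome_len * 0.95 - sl,
                       length.out = length(nm)))
    rows <- list()
    for (i in seq_along(nm)) {
      # substitutions clustered at the probe 5' end keep >= 1 exact word
      site <- if (nm[i] > 0) .mutate_positions(probe, seq_len(nm[i])) else probe
      at <- as.integer(slots[i])
      substr(g, at + 1L, at + sl) <- site
      rows[[i]] <- data.table::data.table(
        start = at, end = at + sl, strand = "+", n_mismatch = nm[i],
        mismatch_frac = nm[i] / sl)
    }
    planted_truth <- data.table::rbindlist(rows)
    truth$planted <- planted_truth
    truth$probe <- probe
  }

  snp_tab <- data.table::data.table(chrom = character(), pos = integer(),
                                    ref = character(), alt = character())
  if (snps > 0L) {
    sp <- sort(sample(genome_len, snps))
    ref <- substring(g, sp, sp)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    snp_tab <- data.table::data.table(chrom = chrom, pos = sp, ref = ref,
                                      alt = unname(alt))
  }

  tgt_tab <- data.table::data.table(ref_id = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    strand = character())
  if (targets > 0L) {
    margin <- max(300L, genome_len %/% 10L)
    tp <- sort(sample(seq(margin, genome_len - margin), targets))
    ref <- substring(g, tp + 1L, tp + 1L)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    tgt_tab <- data.table::data.table(ref_id = chrom, pos = tp, ref = ref,
                                      alt = unname(alt), strand = "+")
  }

  reference <- stats::setNames(g, chrom)
  regions <- data.table::data.table(ref_id = chrom, start = 0L,
                                    end = genome_len, name = "region1",
                                    strand = "+")
  files <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files$fasta <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), files$fasta)
    files$regions <- write_bed(regions, file.path(dir, "regions.bed"))
    if (nrow(snp_tab))
      files$snps <- write_vcf(snp_tab, file.path(dir, "common_snps.vcf"),
                              contigs = stats::setNames(genome_len, chrom))
    if (nrow(tgt_tab))
      files$targets <- write_bed(
        data.table::data.table(ref_id = tgt_tab$ref_id, start = tgt_tab$pos,
                               end = tgt_tab$pos + 1L, name = "target",
                               strand = tgt_tab$strand),
        file.path(dir, "targets.bed"))
    if (!is.null(planted_truth)) {
      files$truth <- file.path(dir, "planted_truth.tsv")
      write_tsv(planted_truth, files$truth)
    }
  }
  list(reference = reference, files = files, snps = snp_tab,
       targets = tgt_tab, regions = regions, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
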