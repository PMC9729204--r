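# In-silico PCR specificity: 7-mer seed-and-extend binding-site discovery,
# per-site bound efficiency, product enumeration per orientation, and the
# off-target efficiency sum (oEff).
#
# The external-aligner role (BLAST in the original pipeline) is played by an
# exact-word index over both strands plus ungapped full-length extension;
# any site sharing at least one exact word with the primer and passing the
# efficiency cutoff is guaranteed to be found.  An external aligner emitting
# (ref, strand, start) triples can be plugged in via the `hits` argument of
# find_binding_sites().

#' Build an exact k-mer seed index over a reference
#'
#' Indexes every word of size `word` on both strands of every reference
#' sequence.  Minus-strand occurrences are stored by the 0-based plus-strand
#' start of the window whose reverse complement equals the word.
#'
#' @param reference FASTA path, `DNAStringSet`, or named character vector.
#' @param word word (seed) size, default 7.
#' @return object of class `seed_index` (keyed data.table of word positions
#'   plus the reference sequences).
#' @export
build_seed_index <- function(reference, word = 7L) {
  word <- as.integer(word)
  if (word < 4L) stop("word size must be >= 4")
  seqs <- .as_named_seqs(reference)
  if (!length(seqs) || any(nchar(seqs) == 0)) stop("reference must be non-empty")
  idx <- data.table::rbindlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < word) return(NULL)
    n <- L - word + 1L
    pos <- seq_len(n)
    fw <- substring(s, pos, pos + word - 1L)
    rc <- .revcomp_chr(s)
    rv <- substring(rc, pos, pos + word - 1L)
    data.table::data.table(
      word = c(fw, rv),
      ref_id = nm,
      strand = rep(c("+", "-"), each = n),
      # 0-based plus-strand start of the window
      pos = c(pos - 1L, L - (pos - 1L) - word)
    )
  }))
  data.table::setkey(idx, word)
  structure(list(word = word, index = idx, seqs = seqs,
                 lens = nchar(seqs)), class = "seed_index")
}

#' Bound efficiency of a primer-site alignment
#'
#' The predicted fraction of template molecules a bound primer converts to
#' product: the product of the bound-Tm factor and one factor per mismatch,
#' each from its piecewise logistic model,
#' \deqn{E = f(btm) \prod_j f(m_j).}
#' Mismatch distances are 1-based from the 3' end; a 3'-terminal mismatch
#' (`m = 1`) keeps a small positive factor (~1.4e-4) because a trace of
#' product is still made.
#'
#' @param bound_tm duplex Tm of the alignment, degrees C.
#' @param mismatch_dist3 integer vector of mismatch distances (1-based from
#'   the 3' end); empty for a perfect match.
#' @param models registry from [feature_models()] (uses `btm` and `mismatch`).
#' @return efficiency (dimensionless; 1 when everything is optimal).
#' @export
bound_efficiency <- function(bound_tm, mismatch_dist3 = integer(),
                             models = feature_models()) {
  e <- piecewise_score(bound_tm, models$btm)
  if (length(mismatch_dist3))
    e <- e * prod(piecewise_score(mismatch_dist3, models$mismatch))
  e
}

.empty_sites <- function() {
  data.table::data.table(ref_id = character(), strand = character(),
                         start = integer(), end = integer(),
                         bound_tm = numeric(), n_mismatch = integer(),
                         mismatch_dist3 = list(), efficiency = numeric())
}

#' Find all plausible binding sites of a primer
#'
#' Seeds every word of the primer against the index, extends each hit
#' ungapped to the full primer length, computes the bound Tm and mismatch
#' positions, and keeps sites whose bound efficiency reaches the cutoff.
#' Detection contract: any full-length site sharing at least one exact word
#' with the primer and passing the cutoff is reported (a site with up to 35%
#' mismatches is detectable whenever one exact word survives).  Sites running
#' off the reference end are skipped.
#'
#' @param primer primer sequence 5'->3' (or a candidate table row).
#' @param index a `seed_index` from [build_seed_index()].
#' @param cond [thermo_conditions()].
#' @param efficiency_cutoff minimum retained efficiency (default 1e-4).
#' @param models registry from [feature_models()].
#' @param hits optional external hit table (`ref_id`, `strand`, `start`)
#'   replacing the internal seeding (pluggable aligner hook).
#' @return data.table of binding sites: `ref_id`, `strand`, `start`, `end`
#'   (0-based half-open on the plus strand), `bound_tm`, `n_mismatch`,
#'   `mismatch_dist3` (list column, 1-based from the 3' end), `efficiency`.
#' @export
find_binding_sites <- function(primer, index, cond = thermo_conditions(),
                               efficiency_cutoff = 1e-4,
                               models = feature_models(), hits = NULL) {
  if (is.list(primer) && !is.null(primer$seq)) primer <- primer$seq[1]
  n <- nchar(primer)
  w <- index$word
  if (n < w) stop("primer shorter than the seed word")
  if (is.null(hits)) {
    offs <- 0:(n - w)
    words <- substring(primer, offs + 1L, offs + w)
    hk <- index$index[data.table::data.table(word = words, off = offs),
                      on = "word", nomatch = NULL, allow.cartesian = TRUE]
    if (!nrow(hk)) return(.empty_sites())
    hk[, start := data.table::fifelse(strand == "+", pos - off,
                                      pos + off + w - n)]
    hits <- unique(hk[, .(ref_id, strand, start)])
  } else {
    hits <- data.table::as.data.table(hits)[, .(ref_id, strand, start)]
    hits <- unique(hits)
  }
  hits <- hits[start >= 0L & start + n <= index$lens[ref_id]]
  if (!nrow(hits)) return(.empty_sites())
  data.table::setorder(hits, ref_id, strand, start)
  res <- lapply(seq_len(nrow(hits)), function(r) {
    s <- substr(index$seqs[[hits$ref_id[r]]], hits$start[r] + 1L, hits$start[r] + n)
    if (hits$strand[r] == "-") s <- .revcomp_chr(s)
    d <- duplex_bound_tm(primer, s, cond)
    list(tm = d$tm, mm = d$mismatch_dist3,
         eff = bound_efficiency(d$tm, d$mismatch_dist3, models))
  })
  hits[, `:=`(end = start + n,
              bound_tm = vapply(res, `[[`, 0, "tm"),
              n_mismatch = vapply(res, function(x) length(x$mm), 0L),
              mismatch_dist3 = lapply(res, `[[`, "mm"),
              efficiency = vapply(res, `[[`, 0, "eff"))]
  out <- hits[efficiency >= efficiency_cutoff]
  data.table::setcolorder(out, c("ref_id", "strand", "start", "end", "bound_tm",
                                 "n_mismatch", "mismatch_dist3", "efficiency"))
  out[]
}

# geometry of one legal site pair per orientation; bdis definitions:
#   face-to-face : converging sites on opposite strands; bdis = product size,
#                  the inclusive span between the two 5' ends
#   back-to-back : diverging sites on opposite strands; bdis = gap between the
#                  two 5' ends (the unamplified spacer on the circle)
#   unidirectional: both sites on one strand; bdis = primer2 5' start minus
#                  primer1 3' end along the strand direction (negative =
#                  nested overlap)
.pair_geometry <- function(s1, s2, orientation) {
  g <- data.table::CJ(i = seq_len(nrow(s1)), j = seq_len(nrow(s2)))
  g[, `:=`(ref1 = s1$ref_id[i], st1 = s1$strand[i],
           a1 = s1$start[i], e1 = s1$end[i],
           ref2 = s2$ref_id[j], st2 = s2$strand[j],
           a2 = s2$start[j], e2 = s2$end[j])]
  g <- g[ref1 == ref2]
  if (orientation == "face-to-face") {
    g <- g[st1 != st2]
    g[, bdis := data.table::fifelse(st1 == "+", e2 - a1, e1 - a2)]
    g[, `:=`(span_start = pmin(a1, a2), span_end = pmax(e1, e2))]
  } else if (orientation == "back-to-back") {
    g <- g[st1 != st2]
    # the plus-strand site points away rightward, the minus-strand leftward;
    # gap = plus 5' start - minus 5' end
    g[, bdis := data.table::fifelse(st1 == "+", a1 - e2, a2 - e1)]
    g[, `:=`(span_start = pmin(a1, a2), span_end = pmax(e1, e2))]
  } else if (orientation == "unidirectional") {
    g <- g[st1 == st2]
    g[, bdis := data.table::fifelse(st1 == "+", a2 - e1, a1 - e2)]
    g[, `:=`(span_start = pmin(a1, a2), span_end = pmax(e1, e2))]
  } else stop("unknown orientation: ", orientation)
  g
}

#' Enumerate candidate products of two binding-site lists
#'
#' Every geometry-legal pair of sites (same reference, strands and order
#' matching the orientation, `MinL <= bdis <= MaxL` of the distance model)
#' becomes a product with efficiency
#' \deqn{E_{prod} = E_1 E_2 f(bdis);}
#' products below the cutoff are dropped.  The product whose two sites match
#' the designed locus (`target`) is flagged.
#'
#' @param sites1,sites2 binding-site tables from [find_binding_sites()] for
#'   Primer1 and Primer2.
#' @param orientation `"face-to-face"`, `"back-to-back"` or
#'   `"unidirectional"`.
#' @param dis_params distance [model_params()] (task-specific; face-to-face
#'   default has `MinL = 30`).
#' @param efficiency_cutoff minimum retained product efficiency.
#' @param target optional list with `site1` and `site2`, each
#'   `c(ref_id, strand, start)`, identifying the designed product.
#' @return data.table of products: site coordinates for both primers, `bdis`,
#'   `efficiency`, `is_target`.
#' @export
enumerate_products <- function(sites1, sites2, orientation = "face-to-face",
                               dis_params = feature_models()$dis,
                               efficiency_cutoff = 1e-4, target = NULL) {
  empty <- data.table::data.table(ref_id = character(), strand1 = character(),
                                  start1 = integer(), end1 = integer(),
                                  strand2 = character(), start2 = integer(),
                                  end2 = integer(), bdis = integer(),
                                  eff1 = numeric(), eff2 = numeric(),
                                  efficiency = numeric(), is_target = logical())
  if (!NROW(sites1) || !NROW(sites2)) return(empty)
  dp <- .as_model_params(dis_params)
  g <- .pair_geometry(sites1, sites2, orientation)
  g <- g[bdis >= dp[["min_l"]] & bdis <= dp[["max_l"]]]
  if (!nrow(g)) return(empty)
  g[, `:=`(eff1 = sites1$efficiency[i], eff2 = sites2$efficiency[j])]
  g[, efficiency := eff1 * eff2 * piecewise_score(bdis, dp)]
  g[, is_target := FALSE]
  if (!is.null(target)) {
    g[, is_target :=
        ref1 == target$site1[1] & st1 == target$site1[2] &
        a1 == as.integer(target$site1[3]) &
        st2 == target$site2[2] & a2 == as.integer(target$site2[3])]
  }
  g <- g[efficiency >= efficiency_cutoff]
  out <- g[, .(ref_id = ref1, strand1 = st1, start1 = a1, end1 = e1,
               strand2 = st2, start2 = a2, end2 = e2,
               bdis = as.integer(bdis), eff1, eff2, efficiency, is_target)]
  data.table::setorder(out, ref_id, start1, start2)
  out[]
}

#' Off-target efficiency sum (oEff)
#'
#' Sum of the predicted efficiencies of all non-target products; the value of
#' the pair's specificity feature (scored downstream with the `oeff` model,
#' where 0 is perfect and anything above 0.02 scores negatively).
#'
#' @param products product table from [enumerate_products()].
#' @return non-negative number.
#' @export
off_target_sum <- function(products) {
  if (!NROW(products)) return(0)
  sum(products$efficiency[!products$is_target])
}
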