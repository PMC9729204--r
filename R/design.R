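# Design orchestration: pair enumeration per orientation, relation scoring,
# final pair scores, top-N selection (never a hard "design failure"),
# full-coverage tiling, genotyping/ARMS allele handling, evaluation of
# pre-designed primers, and multiplex cross-dimer screening.

#' Score the five pair relation features
#'
#' Scores Tm difference, length difference, distance of Primer1 to the target
#' (Pos), primer distance / product size (Dis) and the off-target efficiency
#' sum (oEff) with their piecewise logistic models and returns the weighted
#' total on the 0-100 scale.  For tasks without a target spot (generic,
#' fully-covered tiling) Pos is undefined; its weight is redistributed
#' proportionally over the other four features.
#'
#' @param rel list or one-row data.frame with `tmdiff`, `lendiff`, `pos`
#'   (ignored when `has_target = FALSE`), `dis`, `oeff`.
#' @param models registry from [feature_models()].
#' @param weights relation weight table (see [default_weights()]).
#' @param has_target whether a target spot exists for this task.
#' @return list with `score` and per-feature `breakdown`.
#' @export
relation_score <- function(rel, models = feature_models(),
                           weights = default_weights()$relation,
                           has_target = TRUE) {
  w <- .relation_weights(weights, has_target)
  br <- c(
    tmdiff  = piecewise_score(rel$tmdiff, models$tmdiff),
    lendiff = piecewise_score(rel$lendiff, models$lendiff),
    pos     = if (has_target) piecewise_score(rel$pos, models$pos) else NA_real_,
    dis     = piecewise_score(rel$dis, models$dis),
    oeff    = piecewise_score(rel$oeff, models$oeff)
  )
  list(score = sum(w * br[names(w)]), breakdown = br)
}

.relation_weights <- function(weights, has_target) {
  .validate_weights(weights)
  if (has_target) return(weights)
  w <- weights[setdiff(names(weights), "pos")]
  w * 100 / sum(w)
}

#' Final score of a primer pair
#'
#' Weighted composition of the Primer1 score, Primer2 score and relation
#' score (each on the 0-100 scale) into the final 0-100 pair score.
#'
#' @param score1,score2,rel_score component scores (0-100 scale).
#' @param weights pair weight table (`primer1`, `primer2`, `relation`).
#' @return final pair score.
#' @export
pair_total <- function(score1, score2, rel_score,
                       weights = default_weights()$pair) {
  .validate_weights(weights)
  (weights[["primer1"]] * score1 + weights[["primer2"]] * score2 +
     weights[["relation"]] * rel_score) / 100
}

# template-coordinate pair geometry for candidate tables (each table must be
# single-strand); returns data.table(i1, i2, bdis)
.candidate_pairs <- function(cands1, cands2, orientation, dis_params) {
  stopifnot(length(unique(cands1$strand)) <= 1L,
            length(unique(cands2$strand)) <= 1L)
  if (!nrow(cands1) || !nrow(cands2))
    return(data.table::data.table(i1 = integer(), i2 = integer(), bdis = integer()))
  dp <- .as_model_params(dis_params)
  minl <- dp[["min_l"]]; maxl <- dp[["max_l"]]
  st1 <- cands1$strand[1]; st2 <- cands2$strand[1]
  c1 <- data.table::data.table(i1 = seq_len(nrow(cands1)),
                               start1 = cands1$start, end1 = cands1$end)
  c2 <- data.table::data.table(i2 = seq_len(nrow(cands2)),
                               start2 = cands2$start, end2 = cands2$end)
  if (orientation == "face-to-face") {
    if (!(st1 == "+" && st2 == "-")) stop("face-to-face expects Primer1 on +, Primer2 on -")
    c1[, `:=`(lo = start1 + minl, hi = start1 + maxl)]
    pr <- c2[c1, on = .(end2 >= lo, end2 <= hi), nomatch = NULL,
             allow.cartesian = TRUE, .(i1 = i.i1, i2 = x.i2, bdis = x.end2 - i.start1)]
  } else if (orientation == "back-to-back") {
    if (!(st1 == "+" && st2 == "-")) stop("back-to-back expects Primer1 on +, Primer2 on -")
    c1[, `:=`(lo = start1 - maxl, hi = start1 - minl)]
    pr <- c2[c1, on = .(end2 >= lo, end2 <= hi), nomatch = NULL,
             allow.cartesian = TRUE, .(i1 = i.i1, i2 = x.i2, bdis = i.start1 - x.end2)]
  } else if (orientation == "unidirectional") {
    if (st1 != st2) stop("unidirectional expects both primers on one strand")
    if (st1 == "+") {
      c1[, `:=`(lo = end1 + minl, hi = end1 + maxl)]
      pr <- c2[c1, on = .(start2 >= lo, start2 <= hi), nomatch = NULL,
               allow.cartesian = TRUE, .(i1 = i.i1, i2 = x.i2, bdis = x.start2 - i.end1)]
    } else {
      c1[, `:=`(lo = start1 - maxl, hi = start1 - minl)]
      pr <- c2[c1, on = .(end2 >= lo, end2 <= hi), nomatch = NULL,
               allow.cartesian = TRUE, .(i1 = i.i1, i2 = x.i2, bdis = i.start1 - x.end2)]
    }
  } else stop("unknown orientation: ", orientation)
  pr[, bdis := as.integer(bdis)]
  pr
}

# binding-site cache keyed by primer sequence
.site_cache <- function() new.env(parent = emptyenv())
.cached_sites <- function(cache, seq, index, cond, cutoff, models) {
  if (is.null(cache)) return(find_binding_sites(seq, index, cond, cutoff, models))
  if (is.null(cache[[seq]]))
    cache[[seq]] <- find_binding_sites(seq, index, cond, cutoff, models)
  cache[[seq]]
}

#' Enumerate and score all legal primer pairs
#'
#' Evaluates every orientation/distance-legal pair of two candidate sets:
#' single-primer scores, the five relation features, the off-target
#' efficiency sum from in-silico product enumeration, and the final weighted
#' pair score.  Pairs are ranked descending with deterministic tie-breaking
#' (smaller oEff, then distance closer to the optimal midpoint, then ids).
#' The best pairs found are ALWAYS returned, however poor the scores; an
#' empty result with a structured warning occurs only when no geometrically
#' legal pair exists.
#'
#' Because the oEff feature can only lower a score (its best score is 1), the
#' off-target search is evaluated lazily, best-first, until the top
#' `n_return` true scores provably dominate every unevaluated pair's upper
#' bound; the result is identical to exhaustive evaluation.
#'
#' @param cands1,cands2 candidate tables from [walk_candidates()] (scored on
#'   the fly if needed; each single-strand).
#' @param config a [run_config()] / [apply_preset()] object.
#' @param index a `seed_index` over the specificity reference.
#' @param target optional 0-based reference coordinate of the target spot.
#' @param models score-model registry (defaults derived from `config`).
#' @param site_cache optional environment reused across calls.
#' @param indels indel side-channel table from [mask_reference()].
#' @return data.table of ranked pairs (one row per pair, columns for both
#'   primers, relation features, per-component scores, product count, rank).
#' @export
enumerate_and_score_pairs <- function(cands1, cands2, config, index,
                                      target = NULL, models = NULL,
                                      site_cache = NULL, indels = NULL) {
  if (is.null(models)) models <- .config_models(config)
  w <- config$weights
  cond <- config$thermo
  for (cc in list(cands1, cands2)) {
    if (nrow(cc) && !"score" %in% names(cc))
      .evaluate_candidate_table(cc, cond, models, w$primer, indels,
                                config$poly_min)
  }
  pr <- .candidate_pairs(cands1, cands2, config$orientation, models$dis)
  if (!nrow(pr)) {
    warning("no geometrically legal primer pair for this target/region",
            call. = FALSE)
    return(.empty_pairs())
  }
  has_target <- !is.null(target)
  rw <- .relation_weights(w$relation, has_target)
  pr[, `:=`(tm1 = cands1$tm[i1], tm2 = cands2$tm[i2],
            len1 = cands1$length[i1], len2 = cands2$length[i2],
            score1 = cands1$score[i1], score2 = cands2$score[i2])]
  pr[, `:=`(tmdiff = abs(tm1 - tm2), lendiff = abs(len1 - len2))]
  if (has_target) {
    tp1 <- cands1$three_prime[pr$i1]
    pr[, pos := data.table::fifelse(cands1$strand[i1] == "+",
                                    as.integer(target) - tp1,
                                    tp1 - as.integer(target))]
  } else pr[, pos := NA_integer_]
  pr[, rel_base :=
       rw[["tmdiff"]] * piecewise_score(tmdiff, models$tmdiff) +
       rw[["lendiff"]] * piecewise_score(lendiff, models$lendiff) +
       rw[["dis"]] * piecewise_score(bdis, models$dis) +
       (if (has_target) rw[["pos"]] * piecewise_score(pos, models$pos) else 0)]
  pw <- w$pair
  pr[, final_ub := (pw[["primer1"]] * score1 + pw[["primer2"]] * score2 +
                      pw[["relation"]] * (rel_base + rw[["oeff"]])) / 100]
  mid <- (models$dis[["min_o"]] + models$dis[["max_o"]]) / 2
  data.table::setorder(pr, -final_ub)
  pr[, `:=`(oeff = NA_real_, n_products = NA_integer_, final = NA_real_)]

  if (is.null(site_cache)) site_cache <- .site_cache()
  n_ret <- config$n_return
  k <- 0L
  while (k < nrow(pr)) {
    top <- min(k + 64L, nrow(pr))
    for (r in (k + 1L):top) {
      i1 <- pr$i1[r]; i2 <- pr$i2[r]
      s1 <- .cached_sites(site_cache, cands1$seq[i1], index, cond,
                          config$efficiency_cutoff, models)
      s2 <- .cached_sites(site_cache, cands2$seq[i2], index, cond,
                          config$efficiency_cutoff, models)
      tgt <- list(site1 = c(cands1$ref_id[i1], cands1$strand[i1], cands1$start[i1]),
                  site2 = c(cands2$ref_id[i2], cands2$strand[i2], cands2$start[i2]))
      prods <- enumerate_products(s1, s2, config$orientation, models$dis,
                                  config$efficiency_cutoff, target = tgt)
      oe <- off_target_sum(prods)
      rel <- pr$rel_base[r] + rw[["oeff"]] * piecewise_score(oe, models$oeff)
      data.table::set(pr, r, "oeff", oe)
      data.table::set(pr, r, "n_products", nrow(prods))
      data.table::set(pr, r, "final",
                      pair_total(pr$score1[r], pr$score2[r], rel, pw))
    }
    k <- top
    done <- pr[!is.na(final)]
    if (nrow(done) >= min(n_ret, nrow(pr))) {
      nth <- sort(done$final, decreasing = TRUE)[min(n_ret, nrow(done))]
      if (k >= nrow(pr) || nth >= pr$final_ub[k + 1L] - 1e-12) break
    }
  }
  res <- pr[!is.na(final)]
  res[, `:=`(id1 = cands1$id[i1], seq1 = cands1$seq[i1],
             strand1 = cands1$strand[i1], start1 = cands1$start[i1],
             end1 = cands1$end[i1], three_prime1 = cands1$three_prime[i1],
             id2 = cands2$id[i2], seq2 = cands2$seq[i2],
             strand2 = cands2$strand[i2], start2 = cands2$start[i2],
             end2 = cands2$end[i2], three_prime2 = cands2$three_prime[i2],
             relation_score = (final * 100 - pw[["primer1"]] * score1 -
                                 pw[["primer2"]] * score2) / pw[["relation"]],
             dis_dev = abs(bdis - mid))]
  data.table::setorder(res, -final, oeff, dis_dev, id1, id2)
  res <- utils::head(res, n_ret)
  res[, rank := seq_len(.N)]
  res[, c("i1", "i2", "rel_base", "final_ub", "dis_dev") := NULL]
  data.table::setnames(res, c("bdis", "final"), c("dis", "final_score"))
  data.table::setcolorder(res, c("rank", "id1", "seq1", "strand1", "start1",
                                 "end1", "three_prime1", "id2", "seq2",
                                 "strand2", "start2", "end2", "three_prime2",
                                 "tm1", "tm2", "len1", "len2", "tmdiff",
                                 "lendiff", "pos", "dis", "oeff", "n_products",
                                 "score1", "score2", "relation_score",
                                 "final_score"))
  res[]
}

.empty_pairs <- function() {
  data.table::data.table(rank = integer(), id1 = character(), seq1 = character(),
                         strand1 = character(), start1 = integer(), end1 = integer(),
                         three_prime1 = integer(), id2 = character(), seq2 = character(),
                         strand2 = character(), start2 = integer(), end2 = integer(),
                         three_prime2 = integer(), tm1 = numeric(), tm2 = numeric(),
                         len1 = integer(), len2 = integer(), tmdiff = numeric(),
                         lendiff = numeric(), pos = integer(), dis = integer(),
                         oeff = numeric(), n_products = integer(), score1 = numeric(),
                         score2 = numeric(), relation_score = numeric(),
                         final_score = numeric())
}

.config_models <- function(config) {
  ov <- config$model_overrides
  ov$dis <- config$dis_params
  ov$pos <- config$pos_params
  feature_models(config$opt_tm, ov)
}

# walking helper clipped to the reference
.walk_window <- function(ref_id, lo, hi, reference, masked, config, strand) {
  lens <- nchar(.as_named_seqs(reference))
  lo <- max(0L, as.integer(floor(lo)))
  hi <- min(as.integer(lens[[ref_id]]), as.integer(ceiling(hi)))
  if (hi - lo < config$min_len) return(.empty_candidates())
  walk_candidates(template_region(ref_id, lo, hi), reference, masked,
                  config$min_len, config$max_len, config$pos_step,
                  config$len_step, strands = strand)
}

#' Run a primer design task
#'
#' Dispatches a design task over its inputs: candidate generation on the
#' task-appropriate flanks, pair enumeration and scoring, top-N selection per
#' region/target, and a cross-dimer check over the selected primers when more
#' than one target is designed.
#'
#' Tasks: `generic` (face-to-face pairs per region), `genotyping`
#' (face-to-face around a target spot, Primer1 placed by the Pos model),
#' `arms` (allele-specific: Primer1's 3'-terminal base sits on the target,
#' one primer per allele), `inverse` (back-to-back around a target on a
#' circular template), `anchored` (unidirectional nested primers pointing at
#' the target), `full_covered` (the template is partitioned into windows and
#' the top pairs per window tile it evenly).
#'
#' @param config a [run_config()] / [apply_preset()] object.
#' @param reference FASTA path / `DNAStringSet` / named character vector used
#'   both as template source and specificity database.
#' @param regions data.frame (`ref_id`, `start`, `end`, 0-based half-open)
#'   for region tasks; defaults to whole sequences.
#' @param targets data.frame (`ref_id`, `pos` 0-based, optional `ref`, `alt`,
#'   `strand`) for spot tasks.
#' @param snps optional common-variant VCF path or table for degenerate-base
#'   masking.
#' @return list of class `design_result` with `pairs` (ranked pairs, one
#'   block per target/region), `dimers` (cross-dimer hits among selected
#'   primers), `warnings`, and the effective `config`.
#' @export
design <- function(config, reference, regions = NULL, targets = NULL,
                   snps = NULL) {
  seqs <- .as_named_seqs(reference)
  msk <- mask_reference(seqs, snps)
  masked <- msk$masked
  index <- build_seed_index(seqs, config$word)
  models <- .config_models(config)
  cache <- .site_cache()
  warns <- character()
  task <- config$task
  out <- list()

  add <- function(label, pairs) {
    if (!nrow(pairs)) return()
    pairs[, target_id := label]
    data.table::setcolorder(pairs, "target_id")
    out[[length(out) + 1L]] <<- pairs
  }
  run_pairs <- function(c1, c2, target, label) {
    p <- withCallingHandlers(
      enumerate_and_score_pairs(c1, c2, config, index, target = target,
                                models = models, site_cache = cache,
                                indels = msk$indels),
      warning = function(wc) {
        warns <<- c(warns, paste0(label, ": ", conditionMessage(wc)))
        invokeRestart("muffleWarning")
      })
    add(label, p)
  }

  if (task %in% c("generic", "full_covered")) {
    if (is.null(regions))
      regions <- data.frame(ref_id = names(seqs), start = 0L,
                            end = nchar(seqs))
    for (r in seq_len(nrow(regions))) {
      reg <- template_region(regions$ref_id[r], regions$start[r], regions$end[r])
      wins <- if (task == "full_covered") .tiling_windows(reg, config)
              else list(c(reg$start, reg$end))
      for (wi in seq_along(wins)) {
        wlo <- wins[[wi]][1]; whi <- wins[[wi]][2]
        if (whi - wlo < config$min_len + config$dis_params[["min"]] / 4) {
          warns <- c(warns, sprintf("%s:%d-%d window too small, skipped",
                                    reg$ref_id, wlo, whi))
          next
        }
        label <- sprintf("%s:%d-%d", reg$ref_id, wlo, whi)
        c1 <- .walk_window(reg$ref_id, wlo, whi, seqs, masked, config, "+")
        c2 <- .walk_window(reg$ref_id, wlo, whi, seqs, masked, config, "-")
        run_pairs(c1, c2, NULL, label)
      }
    }
  } else if (task %in% c("genotyping", "arms", "inverse", "anchored")) {
    if (is.null(targets)) stop("task '", task, "' requires target spots")
    pp <- config$pos_params; dp <- config$dis_params
    for (r in seq_len(nrow(targets))) {
      tg <- as.integer(targets$pos[r]); rid <- targets$ref_id[r]
      if (!rid %in% names(seqs)) stop("target contig not in reference: ", rid)
      if (tg < 0L || tg >= nchar(seqs[[rid]]))
        stop("target outside reference: ", rid, ":", tg)
      label <- sprintf("%s:%d", rid, tg)
      if (task == "genotyping" || task == "arms") {
        if (task == "arms") {
          c1 <- .arms_candidates(rid, tg, targets[r, , drop = FALSE],
                                 seqs, masked, config)
        } else {
          c1 <- .walk_window(rid, tg - pp[["max"]] - config$max_len, tg + 1,
                             seqs, masked, config, "+")
          c1 <- c1[tg - three_prime >= pp[["min"]] & tg - three_prime <= pp[["max"]]]
        }
        if (nrow(c1)) {
          lo2 <- min(c1$start, tg) + dp[["min_l"]] - 1
          hi2 <- max(c1$start, tg) + dp[["max_l"]] + 1
          c2 <- .walk_window(rid, lo2, hi2, seqs, masked, config, "-")
          c2 <- c2[start > tg]   # product must cover the target
        } else c2 <- .empty_candidates()
      } else if (task == "inverse") {
        c1 <- .walk_window(rid, tg - pp[["max"]] - config$max_len, tg + 1,
                           seqs, masked, config, "+")
        c1 <- c1[tg - three_prime >= pp[["min"]] & tg - three_prime <= pp[["max"]]]
        if (nrow(c1)) {
          lo2 <- min(c1$start, tg) - dp[["max_l"]] - config$max_len
          hi2 <- max(c1$start, tg) - dp[["min_l"]] + config$max_len
          c2 <- .walk_window(rid, lo2, hi2, seqs, masked, config, "-")
        } else c2 <- .empty_candidates()
      } else {  # anchored
        st <- if (!is.null(targets$strand)) targets$strand[r] else "+"
        if (is.na(st) || !st %in% c("+", "-")) st <- "+"
        if (st == "+") {
          c1 <- .walk_window(rid, tg - pp[["max"]] - config$max_len, tg + 1,
                             seqs, masked, config, "+")
          c1 <- c1[tg - three_prime >= pp[["min"]] & tg - three_prime <= pp[["max"]]]
        } else {
          c1 <- .walk_window(rid, tg, tg + pp[["max"]] + config$max_len + 1,
                             seqs, masked, config, "-")
          c1 <- c1[three_prime - tg >= pp[["min"]] & three_prime - tg <= pp[["max"]]]
        }
        if (nrow(c1)) {
          rng <- range(c(c1$start, c1$end, tg))
          c2 <- .walk_window(rid, rng[1] + dp[["min_l"]] - config$max_len,
                             rng[2] + dp[["max_l"]] + config$max_len,
                             seqs, masked, config, st)
        } else c2 <- .empty_candidates()
      }
      run_pairs(c1, c2, tg, label)
    }
  } else stop("unknown task: ", task)

  pairs <- if (length(out)) data.table::rbindlist(out) else {
    e <- .empty_pairs(); e[, target_id := character()]
    data.table::setcolorder(e, "target_id"); e
  }
  dimers <- check_cross_dimers(pairs, config$dimer_tm, config$thermo)
  structure(list(pairs = pairs, dimers = dimers, warnings = warns,
                 config = config), class = "design_result")
}

.tiling_windows <- function(reg, config) {
  len <- reg$end - reg$start
  n <- config$tiling_count
  if (is.null(n) && !is.null(config$tiling_spacing))
    n <- ceiling(len / config$tiling_spacing)
  if (is.null(n)) n <- max(1L, ceiling(len / 500))
  bounds <- reg$start + round(seq(0, len, length.out = n + 1L))
  lapply(seq_len(n), function(i) c(bounds[i], bounds[i + 1L]))
}

# ARMS Primer1 candidates: 3'-terminal base pinned on the target, one variant
# per allele, lengths on the configured grid
.arms_candidates <- function(rid, tg, target_row, seqs, masked, config) {
  tpl <- seqs[[rid]]
  mtpl <- .as_named_seqs(masked)[[rid]]
  alleles <- toupper(c(
    if (!is.null(target_row$ref)) target_row$ref else substr(tpl, tg + 1L, tg + 1L),
    if (!is.null(target_row$alt) && !is.na(target_row$alt))
      strsplit(target_row$alt, ",")[[1]] else character()
  ))
  alleles <- unique(alleles[nchar(alleles) == 1L & alleles %in% c("A", "C", "G", "T")])
  rows <- list()
  for (len in seq(config$min_len, config$max_len, by = config$len_step)) {
    start <- tg - len + 1L
    if (start < 0L) next
    base_seq <- substr(tpl, start + 1L, tg + 1L)
    dseq <- substr(mtpl, start + 1L, tg + 1L)
    for (al in alleles) {
      s <- base_seq
      substr(s, len, len) <- al
      rows[[length(rows) + 1L]] <- data.table::data.table(
        id = sprintf("%s:+:%d:%d:%s", rid, start, len, al),
        ref_id = rid, strand = "+", start = start, end = tg + 1L,
        length = len, three_prime = tg, seq = s, degen_seq = dseq)
    }
  }
  if (!length(rows)) return(walk_candidates(template_region(rid, 0, 1), seqs,
                                            masked, 2L, 1L, strands = character()))
  data.table::rbindlist(rows)
}

#' Cross-dimer check across a multiplex panel
#'
#' All-vs-all duplex screen (including each primer against itself) over the
#' primers of the selected top pairs of every target.  Hits at or above the
#' reporting threshold are returned with a flag marking 3'-anchored duplexes;
#' reporting only, no automatic re-selection.
#'
#' @param pairs ranked pair table from [design()]/[enumerate_and_score_pairs()],
#'   or a data.frame with `id`/`seq` columns of primers.
#' @param threshold_tm reporting threshold in degrees C (default 45).
#' @param cond [thermo_conditions()].
#' @return data.table of hits (`primer_a`, `primer_b`, `duplex_tm`,
#'   `end_anchored`); attribute `n_comparisons` carries the number of duplex
#'   evaluations performed.
#' @export
check_cross_dimers <- function(pairs, threshold_tm = 45,
                               cond = thermo_conditions()) {
  if (NROW(pairs) && all(c("seq1", "seq2") %in% names(pairs))) {
    prim <- unique(data.table::data.table(
      id = c(pairs$id1, pairs$id2), seq = c(pairs$seq1, pairs$seq2)))
  } else if (NROW(pairs)) {
    prim <- unique(data.table::as.data.table(pairs)[, .(id, seq)])
  } else prim <- data.table::data.table(id = character(), seq = character())
  empty <- data.table::data.table(primer_a = character(), primer_b = character(),
                                  duplex_tm = numeric(), end_anchored = logical())
  k <- nrow(prim)
  if (!k) return(structure(empty, n_comparisons = 0L))
  data.table::setorder(prim, id)
  combos <- data.table::CJ(i = seq_len(k), j = seq_len(k))[i <= j]
  hits <- lapply(seq_len(nrow(combos)), function(r) {
    d <- cross_dimer_tm(prim$seq[combos$i[r]], prim$seq[combos$j[r]], cond)
    if (d$tm >= threshold_tm)
      data.table::data.table(primer_a = prim$id[combos$i[r]],
                             primer_b = prim$id[combos$j[r]],
                             duplex_tm = d$tm, end_anchored = d$end_anchored)
  })
  hits <- data.table::rbindlist(hits)
  if (!nrow(hits)) hits <- empty
  structure(hits[], n_comparisons = nrow(combos))
}

#' Evaluate pre-designed primers
#'
#' Scores a list of existing primers exactly as design-time candidates are
#' scored: the seven features with their models and weights, plus (when a
#' reference is supplied) the number of binding sites found by the
#' specificity search.
#'
#' @param primers data.frame with columns `id` and `seq` (as read by
#'   [load_inputs()]).
#' @param config a [run_config()] object.
#' @param reference optional specificity reference.
#' @param snps optional common-variant VCF/table; when given together with
#'   `reference`, each primer's best perfect site is used to recover covered
#'   SNPs from the masked reference.
#' @return data.table with features, per-feature scores and the total score
#'   per primer.
#' @export
evaluate_primers <- function(primers, config = run_config(), reference = NULL,
                             snps = NULL) {
  primers <- data.table::as.data.table(primers)
  stopifnot(all(c("id", "seq") %in% names(primers)))
  models <- .config_models(config)
  index <- NULL; masked <- NULL
  if (!is.null(reference)) {
    seqs <- .as_named_seqs(reference)
    index <- build_seed_index(seqs, config$word)
    masked <- mask_reference(seqs, snps)$masked
  }
  rows <- lapply(seq_len(nrow(primers)), function(r) {
    sq <- toupper(primers$seq[r])
    dseq <- sq
    n_sites <- NA_integer_
    if (!is.null(index)) {
      st <- find_binding_sites(sq, index, config$thermo,
                               config$efficiency_cutoff, models)
      n_sites <- nrow(st)
      pf <- st[n_mismatch == 0L]
      if (!is.null(snps) && nrow(pf)) {
        b <- pf[which.max(efficiency)]
        ds <- substr(masked[[b$ref_id]], b$start + 1L, b$end)
        if (b$strand == "-") ds <- .revcomp_chr(ds)
        dseq <- ds
      }
    }
    f <- extract_features(sq, dseq, config$thermo, poly_min = config$poly_min)
    s <- score_primer(f, models, config$weights$primer)
    data.table::data.table(
      id = primers$id[r], seq = sq, length = nchar(sq),
      tm = f$tm, gc = f$gc, self_tm = f$self_tm, end_a = f$end_a,
      end_dg = f$end_dg, n_snp = nrow(f$snps), n_poly = nrow(f$polys),
      s_tm = s$breakdown[["tm"]], s_gc = s$breakdown[["gc"]],
      s_self = s$breakdown[["self"]], s_end_a = s$breakdown[["end_a"]],
      s_end_dg = s$breakdown[["end_dg"]], s_snp = s$breakdown[["snp"]],
      s_poly = s$breakdown[["poly"]], n_sites = n_sites, score = s$score)
  })
  data.table::rbindlist(rows)
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", length(unique(x$pairs$target_id)), " target(s), ",
      nrow(x$pairs), " ranked pair(s), ", nrow(x$dimers),
      " cross-dimer hit(s)\n", sep = "")
  if (length(x$warnings)) cat("warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}
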