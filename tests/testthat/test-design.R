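test_that("relation scoring hits the full score and the documented endpoints", {
  m <- feature_models()
  w <- default_weights()$relation
  full <- relation_score(list(tmdiff = 0.5, lendiff = 1, pos = 15, dis = 140,
                              oeff = 0), m, w)
  expect_equal(full$score, 100)
  # distance at the permitted minimum contributes nothing
  dis_min <- relation_score(list(tmdiff = 0.5, lendiff = 1, pos = 15,
                                 dis = 100, oeff = 0), m, w)
  expect_equal(dis_min$score, 100 - w[["dis"]], tolerance = 1e-9)
  # heavy off-target load drags the relation strongly negative
  bad <- relation_score(list(tmdiff = 0.5, lendiff = 1, pos = 15, dis = 140,
                             oeff = 0.1), m, w)
  expect_equal(bad$score, 100 - w[["oeff"]] * (1 + 19.94441), tolerance = 1e-3)
  # without a target spot the Pos weight is redistributed proportionally
  no_tgt <- relation_score(list(tmdiff = 0.5, lendiff = 1, dis = 140,
                                oeff = 0), m, w, has_target = FALSE)
  expect_equal(no_tgt$score, 100)
  expect_true(is.na(no_tgt$breakdown[["pos"]]))
})

test_that("an all-optimal pair composes to exactly 100", {
  w <- default_weights()
  expect_equal(pair_total(100, 100, 100, w$pair), 100)
  expect_equal(pair_total(100, 100, 0, w$pair), 100 - w$pair[["relation"]])
})

test_that("pair enumeration is optimal, deterministic and returns n_return pairs", {
  set.seed(71)
  ref <- c(t1 = random_dna(150, gc = 0.55))
  cfg <- apply_preset("generic", min_len = 20, max_len = 20, len_step = 1)
  idx <- build_seed_index(ref)
  models <- pcrscore:::.config_models(cfg)
  c1 <- walk_candidates(template_region("t1", 0, 150), ref, min_len = 20,
                        max_len = 20, strands = "+")
  c2 <- walk_candidates(template_region("t1", 0, 150), ref, min_len = 20,
                        max_len = 20, strands = "-")
  res <- enumerate_and_score_pairs(c1, c2, cfg, idx)
  expect_equal(nrow(res), 3L)
  expect_equal(res$rank, 1:3)
  # brute force: evaluate every legal pair exhaustively through the scoring
  # primitives and compare the maximum
  dp <- cfg$dis_params
  best <- -Inf
  cache <- new.env()
  for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
    bdis <- c2$end[j] - c1$start[i]
    if (bdis < dp[["min_l"]] || bdis > dp[["max_l"]]) next
    for (sq in c(c1$seq[i], c2$seq[j]))
      if (is.null(cache[[sq]])) cache[[sq]] <- find_binding_sites(sq, idx, cfg$thermo,
                                                                  cfg$efficiency_cutoff, models)
    prods <- enumerate_products(cache[[c1$seq[i]]], cache[[c2$seq[j]]],
                                "face-to-face", models$dis, cfg$efficiency_cutoff,
                                target = list(site1 = c("t1", "+", c1$start[i]),
                                              site2 = c("t1", "-", c2$start[j])))
    rel <- relation_score(list(tmdiff = abs(c1$tm[i] - c2$tm[j]),
                               lendiff = abs(c1$length[i] - c2$length[j]),
                               dis = bdis, oeff = off_target_sum(prods)),
                          models, cfg$weights$relation, has_target = FALSE)
    best <- max(best, pair_total(c1$score[i], c2$score[j], rel$score,
                                 cfg$weights$pair))
  }
  expect_equal(res$final_score[1], best, tolerance = 1e-9)
  # byte-identical reruns
  res2 <- enumerate_and_score_pairs(c1, c2, cfg, idx)
  expect_identical(res, res2)
})

test_that("worsening one primer feature never raises the pair score", {
  m <- feature_models(60)
  w <- default_weights()
  f_opt <- list(tm = 60.5, gc = 0.575, self_tm = -60, end_a = 1, end_dg = -8,
                snps = NULL, polys = NULL)
  s_opt <- score_primer(f_opt, m, w$primer)$score
  rel <- relation_score(list(tmdiff = 0.5, lendiff = 0, pos = 15, dis = 140,
                             oeff = 0), m, w$relation)$score
  base <- pair_total(s_opt, s_opt, rel, w$pair)
  for (tweak in list(list(gc = 0.48), list(tm = 64), list(end_a = 3),
                     list(self_tm = 47), list(end_dg = -12.5),
                     list(snps = data.frame(dist3 = 2, length = 1)))) {
    f <- utils::modifyList(f_opt, tweak)
    s <- score_primer(f, m, w$primer)$score
    expect_lte(pair_total(s, s_opt, rel, w$pair), base)
  }
})

test_that("generic design returns three ranked pairs per region and no failures on poor templates", {
  fx <- generate_fixture(genome_len = 2600, seed = 73)
  cfg <- apply_preset("generic", min_len = 20, max_len = 24)
  res <- design(cfg, fx$reference,
                regions = data.frame(ref_id = "chr1", start = 800L, end = 1050L))
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(res$pairs$rank, 1:3)
  expect_true(all(res$pairs$final_score <= 100))
  expect_true(all(diff(res$pairs$final_score) <= 1e-12))
  # hostile template: pairs still come back, never a design failure
  set.seed(79)
  cfg2 <- apply_preset("generic", min_len = 20, max_len = 20, len_step = 1)
  for (i in 1:5) {
    tpl <- c(t1 = hostile_template(160))
    r <- suppressWarnings(design(cfg2, tpl))
    expect_gte(nrow(r$pairs), 1L)
  }
})

test_that("ARMS design pins one allele-specific primer 3' base per allele on the target", {
  set.seed(83)
  g <- random_dna(900, gc = 0.5)
  substr(g, 451, 451) <- "A"
  tgt <- data.frame(ref_id = "chr1", pos = 450L, ref = "A", alt = "G",
                    strand = "+")
  cfg <- apply_preset("arms", min_len = 20, max_len = 22)
  res <- design(cfg, c(chr1 = g), targets = tgt)
  expect_gte(nrow(res$pairs), 1L)
  expect_true(all(res$pairs$three_prime1 == 450L))
  expect_true(all(res$pairs$pos == 0L))
  last_base <- substr(res$pairs$seq1, nchar(res$pairs$seq1), nchar(res$pairs$seq1))
  expect_true(all(last_base %in% c("A", "G")))
  # both alleles are represented among the generated Primer1 candidates
  c1 <- pcrscore:::.arms_candidates("chr1", 450L, tgt, c(chr1 = g),
                                    c(chr1 = g), cfg)
  expect_setequal(unique(substr(c1$seq, c1$length, c1$length)), c("A", "G"))
})

test_that("genotyping, inverse and anchored geometries respect Pos and Dis ranges", {
  set.seed(89)
  g <- c(chr1 = random_dna(2200, gc = 0.5))
  tgt <- data.frame(ref_id = "chr1", pos = 1100L, ref = NA, alt = NA,
                    strand = "+")
  for (preset in c("inverse", "anchored")) {
    cfg <- apply_preset(preset, min_len = 20, max_len = 22)
    res <- suppressWarnings(design(cfg, g, targets = tgt))
    expect_gte(nrow(res$pairs), 1L)
    pp <- cfg$pos_params; dp <- cfg$dis_params
    expect_true(all(res$pairs$pos >= pp[["min"]] & res$pairs$pos <= pp[["max"]]))
    expect_true(all(res$pairs$dis >= dp[["min_l"]] & res$pairs$dis <= dp[["max_l"]]))
    if (preset == "anchored") {
      expect_true(all(res$pairs$strand1 == res$pairs$strand2))
      expect_true(all(res$pairs$dis < 0))   # nested overlap
    } else {
      expect_true(all(res$pairs$strand1 != res$pairs$strand2))
    }
  }
  cfgG <- apply_preset("sanger_genotyping", min_len = 20, max_len = 22,
                       dis_params = "180,220,150,260")
  resG <- suppressWarnings(design(cfgG, g, targets = tgt,
                                  snps = data.frame(chrom = "chr1", pos = 1101,
                                                    ref = substr(g[["chr1"]], 1101, 1101),
                                                    alt = "N")))
  expect_gte(nrow(resG$pairs), 1L)
  # the product must cover the target spot
  expect_true(all(resG$pairs$start1 <= 1100 & resG$pairs$end2 > 1100))
})

test_that("full coverage tiling partitions the template into the requested windows", {
  fx <- generate_fixture(genome_len = 1500, seed = 97)
  cfg <- apply_preset("full_covered", min_len = 20, max_len = 20,
                      len_step = 1, tiling_count = 5L)
  res <- design(cfg, fx$reference)
  expect_equal(length(unique(res$pairs$target_id)), 5L)
  expect_true(all(table(res$pairs$target_id) >= 1L))
})

test_that("evaluating a designed primer reproduces its design-time score", {
  set.seed(101)
  ref <- c(t1 = random_dna(400, gc = 0.5))
  cfg <- apply_preset("generic", min_len = 20, max_len = 20)
  res <- design(cfg, ref, regions = data.frame(ref_id = "t1", start = 100L,
                                               end = 340L))
  ev <- evaluate_primers(data.frame(id = "p1", seq = res$pairs$seq1[1]), cfg,
                         reference = ref)
  cands <- walk_candidates(template_region("t1", 100, 340), ref,
                           min_len = 20, max_len = 20)
  crow <- cands[seq == res$pairs$seq1[1]][1]
  f <- extract_features(crow$seq, crow$degen_seq)
  s <- score_primer(f, pcrscore:::.config_models(cfg), cfg$weights$primer)
  expect_equal(ev$score, s$score, tolerance = 1e-9)
  expect_equal(ev$score, res$pairs$score1[1], tolerance = 1e-9)
  expect_gte(ev$n_sites, 1L)
})

test_that("cross-dimer screening reports reverse complements and counts all comparisons", {
  prim <- data.frame(
    id = c("a", "b", "c"),
    seq = c("ATCGGCTAAGCGTGCAGTCA",
            oracle_revcomp("ATCGGCTAAGCGTGCAGTCA"),
            "TTATATTATATTGATTATAT"))
  hits <- check_cross_dimers(prim, threshold_tm = 45)
  expect_equal(attr(hits, "n_comparisons"), choose(3, 2) + 3)
  ab <- hits[(primer_a == "a" & primer_b == "b")]
  expect_equal(nrow(ab), 1L)
  expect_true(ab$end_anchored)
  expect_false(any(hits$primer_a == "c" | hits$primer_b == "c"))
})

test_that("design over multiple targets screens the selected panel for dimers", {
  set.seed(103)
  g <- c(chr1 = random_dna(1600, gc = 0.5))
  cfg <- apply_preset("generic", min_len = 20, max_len = 20, len_step = 1)
  res <- design(cfg, g, regions = data.frame(ref_id = "chr1",
                                             start = c(100L, 900L),
                                             end = c(350L, 1150L)))
  expect_equal(length(unique(res$pairs$target_id)), 2L)
  k <- length(unique(c(res$pairs$id1, res$pairs$id2)))
  expect_equal(attr(res$dimers, "n_comparisons"), choose(k, 2) + k)
})
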