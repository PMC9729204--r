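test_that("seed index is exhaustive and strand-symmetric", {
  set.seed(41)
  ref <- c(g1 = random_dna(1000))
  idx <- build_seed_index(ref, word = 7)
  # every forward 7-mer occurrence is retrievable (naive scan oracle)
  g <- ref[["g1"]]
  for (p in sample(994, 25)) {
    w <- substr(g, p, p + 6)
    naive <- which(vapply(1:994, function(q) substr(g, q, q + 6) == w, TRUE)) - 1L
    hits <- idx$index[word == w & strand == "+", sort(pos)]
    expect_equal(hits, naive)
  }
  # index of the reverse-complemented genome = same words with strands
  # swapped and positions mirrored
  rc <- c(g1 = oracle_revcomp(g))
  idx2 <- build_seed_index(rc, word = 7)
  a <- idx$index[order(word, strand, pos)]
  b <- idx2$index[, .(word, strand = ifelse(strand == "+", "-", "+"),
                      pos = 1000L - pos - 7L)][order(word, strand, pos)]
  expect_equal(a[, .(word, strand, pos)], b)
  expect_error(build_seed_index(ref, word = 3), "word size")
})

test_that("a duplicated segment doubles its word hits", {
  set.seed(43)
  fx <- generate_fixture(genome_len = 3000, seed = 43,
                         duplications = list(length = 500, copies = 1,
                                             divergence = 0))
  idx <- build_seed_index(fx$reference)
  seg_start <- fx$truth$duplications$start[1]
  g <- fx$reference[[1]]
  for (o in seq(0, 490, by = 70)) {
    w <- substr(g, seg_start + o + 1, seg_start + o + 7)
    expect_gte(nrow(idx$index[word == w & strand == "+"]), 2L)
  }
})

test_that("bound efficiency follows the bound-Tm and mismatch models", {
  m <- feature_models()
  expect_equal(bound_efficiency(65, integer(), m), 1)
  expect_equal(bound_efficiency(62, 30L, m), 1)      # f(m >= 25) = 1
  expect_equal(bound_efficiency(45, integer(), m), 0, tolerance = 1e-12)
  # 3'-terminal mismatch: exact substitution gives 1.4058e-4, just above
  # the default 1e-4 cutoff
  expect_equal(bound_efficiency(65, 1L, m), 1.4058e-4, tolerance = 1e-3)
  expect_equal(bound_efficiency(65, 1L, m),
               oracle_logistic(1, c(25, 100, 0.95, 100, 0.95, 100)),
               tolerance = 1e-12)
})

test_that("a primer finds its own locus as a perfect full-efficiency site", {
  set.seed(47)
  ref <- c(g1 = random_dna(2000, gc = 0.6))
  idx <- build_seed_index(ref)
  # deterministic scan for a 22-mer window with bound Tm in the optimal range
  starts <- seq(100L, 1900L, by = 7L)
  tms <- vapply(starts, function(s) oligo_tm(substr(ref[["g1"]], s + 1L, s + 22L)), 0)
  s0 <- starts[which(tms >= 60)[1]]
  primer <- substr(ref[["g1"]], s0 + 1L, s0 + 22L)
  sites <- find_binding_sites(primer, idx)
  own <- sites[strand == "+" & start == s0]
  expect_equal(nrow(own), 1L)
  expect_equal(own$efficiency, 1)
  expect_equal(own$n_mismatch, 0L)
})

test_that("sites with 35% mismatches and one preserved word are detected", {
  fx <- generate_fixture(genome_len = 3000, seed = 19,
                         planted = list(site_len = 20, n_mismatch = c(0, 4, 7)))
  idx <- build_seed_index(fx$reference)
  sites <- find_binding_sites(fx$truth$probe, idx)
  found <- sites[fx$truth$planted, on = c("start", "strand"), nomatch = NULL]
  expect_equal(nrow(found), 3L)
  expect_equal(max(found$n_mismatch) / 20, 0.35)
})

test_that("indexed site discovery matches the brute-force slide oracle", {
  set.seed(53)
  for (i in 1:3) {
    fx <- generate_fixture(genome_len = 1500, seed = 530 + i,
                           duplications = list(length = 300, copies = 2,
                                               divergence = 0.08))
    idx <- build_seed_index(fx$reference)
    st <- fx$truth$duplications$start[1]
    primer <- substr(fx$reference[[1]], st + 41, st + 62)
    got <- find_binding_sites(primer, idx)
    want <- oracle_sites(primer, fx$reference)
    expect_equal(got[, .(ref_id, strand, start, end, n_mismatch)],
                 want[, .(ref_id, strand, start, end, n_mismatch)])
    expect_equal(got$efficiency, want$efficiency, tolerance = 1e-9)
    expect_identical(got$mismatch_dist3, want$mismatch_dist3)
  }
})

test_that("face-to-face products multiply site efficiencies with the distance factor", {
  s1 <- data.table::data.table(ref_id = "g", strand = "+", start = 100L,
                               end = 120L, efficiency = 1)
  s2 <- data.table::data.table(ref_id = "g", strand = "-", start = 220L,
                               end = 240L, efficiency = 1)
  dis <- feature_models()$dis
  pr <- enumerate_products(s1, s2, "face-to-face", dis)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$bdis, 140L)          # span between the two 5' ends
  expect_equal(pr$efficiency, 1)
  # a weak second site survives exactly when E1*E2*f(bdis) >= cutoff
  s2b <- rbind(s2, data.table::data.table(ref_id = "g", strand = "-",
                                          start = 230L, end = 250L,
                                          efficiency = 1.4058e-4))
  pr2 <- enumerate_products(s1, s2b, "face-to-face", dis)
  expect_equal(nrow(pr2), 2L)
  expect_equal(sort(pr2$efficiency), sort(c(1, 1.4058e-4)), tolerance = 1e-6)
  # below the distance floor (MinL 30 by default geometry bounds) no product
  s2c <- data.table::data.table(ref_id = "g", strand = "-", start = 105L,
                                end = 125L, efficiency = 1)
  dis30 <- model_params(120, 160, 100, 180, 30, 2000)
  expect_equal(nrow(enumerate_products(s1, s2c, "face-to-face", dis30)), 0L)
})

test_that("k sites per primer give k^2 raw pair combinations before distance filtering", {
  k <- 3L
  s1 <- data.table::data.table(ref_id = "g", strand = "+",
                               start = c(0L, 1000L, 2000L),
                               end = c(20L, 1020L, 2020L), efficiency = 1)
  s2 <- data.table::data.table(ref_id = "g", strand = "-",
                               start = c(140L, 1140L, 2140L),
                               end = c(160L, 1160L, 2160L), efficiency = 1)
  raw <- pcrscore:::.pair_geometry(s1, s2, "face-to-face")
  expect_equal(nrow(raw), k^2)
  # with unbounded permitted/limit ceilings every converging combo survives
  wide <- model_params(120, 160, 100, 1e6, 30, 1e7)
  pr <- enumerate_products(s1, s2, "face-to-face", wide, efficiency_cutoff = 0)
  expect_equal(nrow(pr), k * (k + 1) / 2)   # converging pairs only
})

test_that("product enumeration matches the brute-force oracle on a duplicated fixture", {
  fx <- generate_fixture(genome_len = 2500, seed = 61,
                         duplications = list(length = 400, copies = 1,
                                             divergence = 0.05))
  idx <- build_seed_index(fx$reference)
  st <- fx$truth$duplications$start[1]
  g <- fx$reference[[1]]
  p1 <- substr(g, st + 21, st + 42)
  p2 <- oracle_revcomp(substr(g, st + 161, st + 182))
  s1 <- find_binding_sites(p1, idx); s2 <- find_binding_sites(p2, idx)
  dis <- feature_models()$dis
  got <- enumerate_products(s1, s2, "face-to-face", dis)
  want <- oracle_products_f2f(s1, s2, unclass(dis))
  expect_equal(got[, .(ref_id, start1, start2, bdis)],
               want[, .(ref_id, start1, start2, bdis)])
  expect_equal(got$efficiency, want$efficiency, tolerance = 1e-9)
})

test_that("oEff sums non-target efficiencies and scores through the oeff model", {
  pr <- data.table::data.table(efficiency = c(1, 0.003, 0.004),
                               is_target = c(TRUE, FALSE, FALSE))
  expect_equal(off_target_sum(pr), 0.007)
  expect_equal(off_target_sum(pr[is_target == TRUE]), 0)
  m <- feature_models()$oeff
  expect_equal(piecewise_score(0, m), 1)
  expect_equal(piecewise_score(0.02, m), 0, tolerance = 1e-12)
  expect_equal(piecewise_score(0.1, m), -19.94441, tolerance = 1e-5)
})
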