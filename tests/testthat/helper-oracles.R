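# Independent oracles used across the suite.  These re-derive the quantities
# from first principles (direct formula substitution, naive scans, exhaustive
# enumeration) without going through the package's indexed/vectorized paths.

# direct piecewise-logistic evaluation straight from the curve definitions
oracle_logistic <- function(x, p) {
  p <- as.numeric(p)   # (MinO, MaxO, Min, Max, MinL, MaxL)
  one <- function(xx) {
    if (xx <= p[1]) {
      if (p[1] == p[5]) return(1)
      k <- 10 / (p[1] - p[5]); x0 <- (p[1] + p[5]) / 2
      y0 <- exp(k * (p[3] - x0))
      (1 + y0) / (1 + exp(-k * (xx - x0))) - y0
    } else if (xx <= p[2]) 1 else {
      if (p[2] == p[6]) return(1)
      k <- 10 / (p[2] - p[6]); x0 <- (p[2] + p[6]) / 2
      y0 <- exp(k * (p[4] - x0))
      (1 + y0) / (1 + exp(-k * (xx - x0))) - y0
    }
  }
  vapply(x, one, 0)
}

# random strictly-ordered valid parameter set (all branches non-degenerate)
random_valid_params <- function(lo = -50, hi = 150) {
  v <- sort(stats::runif(6, lo, hi))
  model_params(v[3], v[4], v[2], v[5], v[1], v[6])
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# brute-force binding-site discovery: slide the primer over every position
# and strand, demand one shared exact word (the documented detection
# contract), measure the duplex, and score efficiency by direct formula
oracle_sites <- function(primer, refs, word = 7L, cutoff = 1e-4,
                         cond = thermo_conditions()) {
  n <- nchar(primer)
  btm_p <- c(60, 100, 45, 100, 45, 100)
  mm_p <- c(25, 100, 0.95, 100, 0.95, 100)
  pw <- substring(primer, 1:(n - word + 1L), word:n)
  rows <- list()
  for (rid in names(refs)) {
    g <- refs[[rid]]
    L <- nchar(g)
    if (L < n) next
    starts <- 0:(L - n)
    for (st in c("+", "-")) {
      shares <- rep(FALSE, length(starts))
      for (o in seq_along(pw)) {
        win <- if (st == "+") {
          substring(g, starts + o, starts + o + word - 1L)
        } else {
          # primer offset o-1 sits at plus coords [S + n - o + 1 - word + 1, ...]
          vapply(substring(g, starts + n - o - word + 2L, starts + n - o + 1L),
                 oracle_revcomp, "", USE.NAMES = FALSE)
        }
        shares <- shares | (win == pw[o])
      }
      for (S in starts[shares]) {
        site <- substr(g, S + 1L, S + n)
        if (st == "-") site <- oracle_revcomp(site)
        d <- duplex_bound_tm(primer, site, cond)
        eff <- oracle_logistic(d$tm, btm_p)
        if (length(d$mismatch_dist3))
          eff <- eff * prod(oracle_logistic(d$mismatch_dist3, mm_p))
        if (eff >= cutoff)
          rows[[length(rows) + 1L]] <- data.table::data.table(
            ref_id = rid, strand = st, start = S, end = S + n,
            bound_tm = d$tm, n_mismatch = length(d$mismatch_dist3),
            mismatch_dist3 = list(d$mismatch_dist3), efficiency = eff)
      }
    }
  }
  if (!length(rows)) return(pcrscore:::.empty_sites())
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, ref_id, strand, start)
  out
}

# brute-force product enumeration from two site tables (face-to-face),
# applying the geometry definitions and Eq.-style efficiency directly
oracle_products_f2f <- function(s1, s2, dis_p, cutoff = 1e-4) {
  rows <- list()
  for (i in seq_len(nrow(s1))) for (j in seq_len(nrow(s2))) {
    if (s1$ref_id[i] != s2$ref_id[j]) next
    if (s1$strand[i] == s2$strand[j]) next
    bdis <- if (s1$strand[i] == "+") s2$end[j] - s1$start[i]
            else s1$end[i] - s2$start[j]
    if (bdis < dis_p[5] || bdis > dis_p[6]) next
    eff <- s1$efficiency[i] * s2$efficiency[j] * oracle_logistic(bdis, dis_p)
    if (eff >= cutoff)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        ref_id = s1$ref_id[i], strand1 = s1$strand[i], start1 = s1$start[i],
        strand2 = s2$strand[j], start2 = s2$start[j],
        bdis = as.integer(bdis), efficiency = eff)
  }
  if (!length(rows))
    return(data.table::data.table(ref_id = character(), strand1 = character(),
                                  start1 = integer(), strand2 = character(),
                                  start2 = integer(), bdis = integer(),
                                  efficiency = numeric()))
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, ref_id, start1, start2)
  out
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# hostile template: GC extremes, a homopolymer and an internal repeat
hostile_template <- function(n = 160) {
  gc <- sample(c(0.05, 0.2, 0.8, 0.95), 1)
  s <- random_dna(n, gc)
  hp <- sample(c("A", "G"), 1)
  at <- sample(n - 40, 1)
  substr(s, at, at + 11) <- strrep(hp, 12)
  rep_at <- sample(n - 70, 1)
  substr(s, rep_at + 35, rep_at + 59) <- substr(s, rep_at, rep_at + 24)
  s
}
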