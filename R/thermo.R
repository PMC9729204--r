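# Nearest-neighbor DNA thermodynamics: oligo Tm, mismatched duplex Tm,
# self-structure (dimer/hairpin) Tm, and 3'-end stack free energy.
#
# Parameters: SantaLucia (1998) unified nearest-neighbor set, two-state model
#   Tm = 1000*dH / (dS_salt + R*ln(C/4)) - 273.15
# with the entropy salt correction dS + 0.368*(N-1)*ln[Mon+] and divalent
# cations folded into the effective monovalent concentration as
# 120*sqrt([divalent] - [dNTP]) (the Primer3 oligotm convention).
# Any nearest-neighbor stack containing a mismatched pair receives fixed
# destabilization values (.MM_DH/.MM_DS) instead of a full mismatch table:
# the contracts honored here are perfect-match equality and monotone
# destabilization, not equivalence with any particular external engine.

.BASES <- c("A", "C", "G", "T")

# dH kcal/mol, dS cal/(mol K); index = 4*(b1-1) + b2 over A,C,G,T codes 1..4
.NN_TABLE <- local({
  nn <- list(
    AA = c(-7.9, -22.2), AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
    CA = c(-8.5, -22.7), GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
    GA = c(-8.2, -22.2), CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
    GG = c(-8.0, -19.9)
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  dh <- ds <- numeric(16)
  for (b1 in 1:4) for (b2 in 1:4) {
    s <- paste0(.BASES[b1], .BASES[b2])
    if (is.null(nn[[s]])) s <- paste0(comp[.BASES[b2]], comp[.BASES[b1]])
    dh[4 * (b1 - 1) + b2] <- nn[[s]][1]
    ds[4 * (b1 - 1) + b2] <- nn[[s]][2]
  }
  list(dh = dh, ds = ds)
})
# duplex initiation per terminal base pair: A/T vs G/C
.INIT_DH <- c(2.3, 0.1, 0.1, 2.3)
.INIT_DS <- c(4.1, -2.8, -2.8, 4.1)
# fixed values for any stack containing a mismatched pair
.MM_DH <- -2.0
.MM_DS <- -6.0
.R_GAS <- 1.9872      # cal/(mol K)
.T37 <- 310.15        # K
# unimolecular hairpin loop initiation, dG37 ~ +3.5 kcal/mol as entropy
.HAIRPIN_LOOP_DS <- -3.5 * 1000 / .T37
.TM_FLOOR <- -273.15  # reported when no stable duplex exists

#' Thermodynamic reaction conditions
#'
#' Concentrations used in melting-temperature calculations.  Defaults follow
#' common PCR practice (50 nM oligo, 50 mM monovalent salt, 1.5 mM Mg, 0.6 mM
#' dNTP).
#'
#' @param oligo_conc oligo concentration, molar.
#' @param monovalent monovalent cation concentration, molar.
#' @param divalent divalent cation concentration, molar.
#' @param dntp dNTP concentration, molar (binds divalent cations).
#' @return object of class `thermo_conditions`.
#' @export
thermo_conditions <- function(oligo_conc = 50e-9, monovalent = 50e-3,
                              divalent = 1.5e-3, dntp = 0.6e-3) {
  v <- c(oligo_conc = oligo_conc, monovalent = monovalent,
         divalent = divalent, dntp = dntp)
  if (any(!is.finite(v)) || any(v < 0)) stop("concentrations must be finite and >= 0")
  structure(as.list(v), class = "thermo_conditions")
}

# IUPAC-degenerate bases are resolved to the Tm-minimizing (A/T-preferring)
# allele; the degenerate code itself is consumed by the SNP feature instead.
.IUPAC_WORST <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "A", Y = "T", S = "C", W = "A", K = "T", M = "A",
                  B = "T", D = "A", H = "A", V = "A", N = "A")

.seq2int <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  v <- match(ch, .BASES)
  if (anyNA(v)) {
    ch2 <- unname(.IUPAC_WORST[ch])
    if (anyNA(ch2))
      stop("non-DNA character(s) in sequence: ",
           paste(unique(ch[is.na(ch2)]), collapse = ", "))
    v <- match(ch2, .BASES)
  }
  v
}

.revcomp_int <- function(v) rev(5L - v)

.salt_mono <- function(cond) {
  cond$monovalent + 120 * sqrt(max(cond$divalent - cond$dntp, 0) * 1000) / 1000
}

# bimolecular Tm from accumulated dH (kcal) and dS (e.u.); n = duplex length
.tm_bimol <- function(dh, ds, n, cond) {
  mon <- .salt_mono(cond)
  if (mon <= 0 || cond$oligo_conc <= 0) stop("need positive salt and oligo concentrations")
  ds <- ds + 0.368 * (n - 1) * log(mon)
  den <- ds + .R_GAS * log(cond$oligo_conc / 4)
  if (dh >= 0 || den >= 0) return(.TM_FLOOR)
  1000 * dh / den - 273.15
}

# dH/dS over a gap-free duplex given primer codes p and a per-position match
# flag; mismatch-containing stacks take the fixed penalty values
.duplex_hs <- function(p, match) {
  n <- length(p)
  i <- seq_len(n - 1L)
  ok <- match[i] & match[i + 1L]
  idx <- 4L * (p[i] - 1L) + p[i + 1L]
  dh <- sum(.NN_TABLE$dh[idx[ok]]) + .MM_DH * sum(!ok)
  ds <- sum(.NN_TABLE$ds[idx[ok]]) + .MM_DS * sum(!ok)
  dh <- dh + .INIT_DH[p[1L]] + .INIT_DH[p[n]]
  ds <- ds + .INIT_DS[p[1L]] + .INIT_DS[p[n]]
  c(dh, ds)
}

#' Oligo melting temperature
#'
#' Two-state nearest-neighbor Tm of a primer against its perfect complement.
#'
#' @param seq DNA string (>= 8 bases; IUPAC codes resolved conservatively to
#'   the least stable allele).
#' @param cond [thermo_conditions()].
#' @return temperature in degrees C.
#' @examples
#' oligo_tm("AGCGTCCTAGCATGCAATTC")
#' @export
oligo_tm <- function(seq, cond = thermo_conditions()) {
  p <- .seq2int(seq)
  if (length(p) < 8L) stop("sequence too short for a meaningful Tm (need >= 8 bases)")
  hs <- .duplex_hs(p, rep(TRUE, length(p)))
  .tm_bimol(hs[1], hs[2], length(p), cond)
}

#' Duplex Tm of a primer bound to a (possibly mismatched) site
#'
#' Computes the melting temperature of the gap-free full-length hybrid between
#' a primer and a reference binding site, plus the mismatch positions as
#' 1-based distances from the primer 3' end (terminal base = 1).  A perfect
#' complement reproduces [oligo_tm()] exactly.
#'
#' @param primer primer sequence 5'->3'.
#' @param site_seq the site sequence in primer orientation, i.e. the reference
#'   strand the primer would have to equal for a perfect match; must have the
#'   same length as `primer`.
#' @param cond [thermo_conditions()].
#' @return list with `tm` (degrees C) and `mismatch_dist3` (integer vector).
#' @export
duplex_bound_tm <- function(primer, site_seq, cond = thermo_conditions()) {
  p <- .seq2int(primer)
  s <- .seq2int(site_seq)
  if (length(p) != length(s)) stop("primer and site must have equal lengths (ungapped alignment)")
  m <- p == s
  hs <- .duplex_hs(p, m)
  list(tm = .tm_bimol(hs[1], hs[2], length(p), cond),
       mismatch_dist3 = as.integer(length(p) - which(!m) + 1L))
}

# best antiparallel duplex between integer-coded a and b over all ungapped
# offsets; overlap trimmed to its outermost complementary pair, interior
# mismatches kept as penalized stacks.  Returns Tm and the trimmed pairing
# ranges on each strand (for 3'-anchor detection).
.best_dimer <- function(a, b, cond) {
  na <- length(a); nb <- length(b)
  br <- rev(b)                       # b read 3'->5' so a[i] pairs br[i + o]
  best <- list(tm = .TM_FLOOR, a_range = NULL, b_range = NULL)
  for (o in (1L - na):(nb - 1L)) {
    i1 <- max(1L, 1L - o); i2 <- min(na, nb - o)
    if (i2 - i1 < 1L) next
    i <- i1:i2
    m <- br[i + o] == (5L - a[i])
    w <- which(m)
    if (length(w) < 2L) next
    j1 <- i1 + w[1L] - 1L; j2 <- i1 + w[length(w)] - 1L
    if (j2 - j1 < 1L) next
    seg <- j1:j2
    hs <- .duplex_hs(a[seg], m[seg - i1 + 1L])
    tm <- .tm_bimol(hs[1], hs[2], length(seg), cond)
    if (tm > best$tm) {
      bpos <- nb + 1L - (seg + o)    # 1-based positions on b, 5'->3'
      best <- list(tm = tm, a_range = c(j1, j2), b_range = range(bpos))
    }
  }
  best
}

# best hairpin Tm: enumerate innermost stem pairs (i, j) with loop >= 3,
# extend outward while complementary; unimolecular, loop entropy penalty
.best_hairpin <- function(p, cond) {
  n <- length(p)
  if (n < 8L) return(.TM_FLOOR)
  best <- .TM_FLOOR
  mon <- .salt_mono(cond)
  for (i in 1:(n - 4L)) {
    for (j in (i + 4L):n) {
      if (p[j] != 5L - p[i]) next
      t <- 0L
      while (i - t - 1L >= 1L && j + t + 1L <= n &&
             p[j + t + 1L] == 5L - p[i - t - 1L]) t <- t + 1L
      if (t + 1L < 3L) next                      # stem of >= 3 pairs
      arm <- (i - t):i                            # 5' arm, 5'->3'
      k <- seq_len(length(arm) - 1L)
      idx <- 4L * (p[arm[k]] - 1L) + p[arm[k + 1L]]
      dh <- sum(.NN_TABLE$dh[idx])
      ds <- sum(.NN_TABLE$ds[idx]) + .HAIRPIN_LOOP_DS +
        0.368 * (length(arm) - 1L) * log(mon)
      if (dh < 0 && ds < 0) best <- max(best, 1000 * dh / ds - 273.15)
    }
  }
  best
}

#' Self-structure melting temperature
#'
#' The self-complementarity feature value: the maximum of the best self-dimer
#' Tm (the oligo annealed antiparallel against a second copy of itself, over
#' all ungapped offsets) and the best hairpin stem Tm.  Sequences without any
#' complementary stretch report -273.15, which scores as fully unstructured.
#'
#' @param seq DNA string.
#' @param cond [thermo_conditions()].
#' @return temperature in degrees C.
#' @export
self_structure_tm <- function(seq, cond = thermo_conditions()) {
  p <- .seq2int(seq)
  max(.best_dimer(p, p, cond)$tm, .best_hairpin(p, cond))
}

#' Cross-dimer between two primers
#'
#' Best antiparallel duplex Tm between two oligos over all ungapped offsets,
#' with a flag marking whether the 3'-terminal base of either primer lies
#' inside the paired region (3'-anchored dimers are extensible by polymerase
#' and the more dangerous kind).
#'
#' @param seq_a,seq_b primer sequences 5'->3'.
#' @param cond [thermo_conditions()].
#' @return list with `tm` and logical `end_anchored`.
#' @export
cross_dimer_tm <- function(seq_a, seq_b, cond = thermo_conditions()) {
  a <- .seq2int(seq_a); b <- .seq2int(seq_b)
  d <- .best_dimer(a, b, cond)
  anchored <- FALSE
  if (!is.null(d$a_range))
    anchored <- (d$a_range[2] == length(a)) || (d$b_range[2] == length(b))
  list(tm = d$tm, end_anchored = anchored)
}

#' 3'-end stability (stack free energy of the terminal five bases)
#'
#' Sum of the four nearest-neighbor stack dG37 terms over the 3'-terminal five
#' bases (`dG = dH - 310.15 dS / 1000`).  More negative means a more stable,
#' more extensible (and more mispriming-prone) 3' end.
#'
#' @param seq DNA string of length >= 5.
#' @return free energy in kcal/mol.
#' @export
end_stability_dg <- function(seq) {
  p <- .seq2int(seq)
  n <- length(p)
  if (n < 5L) stop("need at least 5 bases for 3'-end stability")
  i <- (n - 4L):(n - 1L)
  idx <- 4L * (p[i] - 1L) + p[i + 1L]
  sum(.NN_TABLE$dh[idx] - .T37 * .NN_TABLE$ds[idx] / 1000)
}
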