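#' Piecewise logistic model parameters
#'
#' A feature score model is defined by six numbers `(MinO, MaxO, Min, Max,
#' MinL, MaxL)`: the optimal range `(MinO, MaxO]` where the score is the full
#' score 1, the permitted range endpoints `Min`/`Max` where the score crosses
#' 0, and the limiting endpoints `MinL`/`MaxL` towards which the score
#' saturates at its (usually negative) minimum.  Outside the optimal range the
#' score follows a logistic (sigmoid) curve on each side.
#'
#' Setting `MinO == MinL` (or `MaxO == MaxL`) disables the corresponding
#' branch: the score is 1 everywhere on that side.  This is how one-sided
#' features (e.g. self-complementarity, which only penalizes high values) are
#' expressed.
#'
#' @param min_o,max_o optimal range bounds (score 1), or a single numeric
#'   vector of all six values in order.
#' @param min,max permitted range bounds (score 0).
#' @param min_l,max_l limiting bounds (score saturates).
#' @return an object of class `model_params` (named numeric of length 6).
#' @examples
#' gc <- model_params(0.55, 0.6, 0.45, 0.65, 0.3, 0.7)
#' piecewise_score(c(0.45, 0.575, 0.7), gc)
#' @export
model_params <- function(min_o, max_o = NULL, min = NULL, max = NULL,
                         min_l = NULL, max_l = NULL) {
  if (is.null(max_o) && length(min_o) == 6L) {
    v <- as.numeric(min_o)
  } else {
    v <- as.numeric(c(min_o, max_o, min, max, min_l, max_l))
  }
  names(v) <- c("min_o", "max_o", "min", "max", "min_l", "max_l")
  if (length(v) != 6L || any(!is.finite(v)))
    stop("model_params requires six finite values (MinO, MaxO, Min, Max, MinL, MaxL)")
  with(as.list(v), {
    if (!(min_l <= min && min <= min_o && min_o <= max_o &&
          max_o <= max && max <= max_l))
      stop("model_params must satisfy MinL <= Min <= MinO <= MaxO <= Max <= MaxL; got (",
           paste(signif(v, 6), collapse = ", "), ")")
  })
  structure(v, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> optimal (", x[["min_o"]], ", ", x[["max_o"]],
      "] zero at ", x[["min"]], "/", x[["max"]],
      " limits [", x[["min_l"]], ", ", x[["max_l"]], "]\n", sep = "")
  invisible(x)
}

.as_model_params <- function(p) {
  if (inherits(p, "model_params")) p else model_params(p)
}

#' Logistic branch constants of a score model
#'
#' Computes, for each side of the optimal range, the logistic constants
#' `k = 10/(MinO - MinL)`, `x0 = (MinO + MinL)/2`, `y0 = exp(k*(Min - x0))`
#' and `L = 1 + y0` (mirrored on the right with `MaxO`, `Max`, `MaxL`).
#' A degenerate branch (`MinO == MinL` or `MaxO == MaxL`) is disabled and
#' returned as `NULL`.
#'
#' @param params a [model_params] object.
#' @return list with elements `left` and `right`; each is either `NULL`
#'   (disabled branch) or a list with `k`, `x0`, `y0`, `l`.
#' @export
logistic_constants <- function(params) {
  p <- .as_model_params(params)
  left <- right <- NULL
  if (p[["min_o"]] > p[["min_l"]]) {
    k <- 10 / (p[["min_o"]] - p[["min_l"]])
    x0 <- (p[["min_o"]] + p[["min_l"]]) / 2
    y0 <- exp(k * (p[["min"]] - x0))
    left <- list(k = k, x0 = x0, y0 = y0, l = 1 + y0)
  }
  if (p[["max_o"]] < p[["max_l"]]) {
    k <- 10 / (p[["max_o"]] - p[["max_l"]])   # negative
    x0 <- (p[["max_o"]] + p[["max_l"]]) / 2
    y0 <- exp(k * (p[["max"]] - x0))
    right <- list(k = k, x0 = x0, y0 = y0, l = 1 + y0)
  }
  list(left = left, right = right)
}

#' Piecewise logistic feature score
#'
#' Scores a feature value: the left logistic branch for `x <= MinO`, exactly 1
#' on the optimal range `(MinO, MaxO]`, and the right logistic branch for
#' `x > MaxO`.  By construction the score is 1 in the optimal range, crosses 0
#' at `Min`/`Max`, and saturates at `-y0` beyond `MinL`/`MaxL` (no clamping: the
#' logistic is already monotone and bounded there).  A disabled branch scores 1
#' on its whole side.  A point optimum (`MinO == MaxO`, as in the 3'-adenine
#' model whose only optimal value is 1) includes its single point: the full
#' score must be attainable there, so `x == MinO` scores 1 in that case while
#' for an extended optimal range `x == MinO` takes the left-logistic value
#' (~0.975) as the curve definition states.
#'
#' @param x numeric vector of feature values.
#' @param params a [model_params] object.
#' @return numeric vector of scores (\eqn{\le} 1, possibly negative).
#' @export
piecewise_score <- function(x, params) {
  p <- .as_model_params(params)
  cc <- logistic_constants(p)
  out <- rep(1, length(x))
  lo <- x <= p[["min_o"]]
  hi <- x > p[["max_o"]]
  if (p[["min_o"]] == p[["max_o"]]) lo <- lo & x != p[["min_o"]]
  if (!is.null(cc$left) && any(lo)) {
    b <- cc$left
    out[lo] <- b$l / (1 + exp(-b$k * (x[lo] - b$x0))) - b$y0
  }
  if (!is.null(cc$right) && any(hi)) {
    b <- cc$right
    out[hi] <- b$l / (1 + exp(-b$k * (x[hi] - b$x0))) - b$y0
  }
  out
}

# composite-penalty constants: a scales the term, b is the position-independent
# base penalty of one site
.penalty_constants <- list(
  snp  = list(a = 4, b = 0.2),
  poly = list(a = 2, b = 2)
)

#' Composite SNP / homopolymer penalty score
#'
#' A primer may cover several common SNPs or homopolymer runs ("polys"), each
#' described by its distance to the primer's 3' end and its length.  The
#' composite score is
#' \deqn{F = 1 - \sum_j a \, [f(p_j) + b] \, f(l_j)}
#' where `f(p)` is the shared position model (a site at the 3' terminus is
#' penalized most) and `f(l)` the kind-specific length model; `a = 4, b = 0.2`
#' for SNPs and `a = 2, b = 2` for polys.  An empty site list scores exactly 1;
#' the result is not clamped and can be well below 0.
#'
#' @param sites data.frame (or list) with columns/elements `dist3` (0-based
#'   distance of the site's 3'-most base from the primer 3' end) and `length`.
#' @param kind `"snp"` or `"poly"`.
#' @param models model registry from [feature_models()] (uses `site_pos` and
#'   `snp_len`/`poly_len`).
#' @return a single score (\eqn{\le} 1).
#' @export
site_penalty_score <- function(sites, kind = c("snp", "poly"),
                               models = feature_models()) {
  kind <- match.arg(kind)
  if (is.null(sites) || NROW(sites) == 0L) return(1)
  sites <- as.data.frame(sites)
  if (any(sites$dist3 < 0)) stop("site dist3 must be >= 0")
  if (any(sites$length < 1)) stop("site length must be >= 1")
  k <- .penalty_constants[[kind]]
  fp <- piecewise_score(sites$dist3, models$site_pos)
  fl <- piecewise_score(sites$length,
                        if (kind == "snp") models$snp_len else models$poly_len)
  1 - sum(k$a * (fp + k$b) * fl)
}

#' Weighted total of feature scores
#'
#' Combines per-feature scores (full score 1 each) with a weight table summing
#' to 100, so an all-optimal input totals exactly 100.  Used for the seven
#' single-primer features, the five pair relation features and (with
#' `scale = 100`) the final Primer1/Primer2/relation composition, where the
#' three inputs are themselves 0-100 scores.
#'
#' @param scores named numeric vector of feature scores.
#' @param weights named numeric weight table (must cover every score name and
#'   sum to 100).
#' @param scale divisor applied to the weighted sum (1 for feature scores on
#'   the 0-1 scale, 100 when combining 0-100 component scores).
#' @return the weighted total.
#' @export
weighted_total <- function(scores, weights, scale = 1) {
  .validate_weights(weights)
  if (!all(names(weights) %in% names(scores)))
    stop("missing feature score(s): ",
         paste(setdiff(names(weights), names(scores)), collapse = ", "))
  sum(weights * unlist(scores)[names(weights)]) / scale
}

.validate_weights <- function(weights) {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be a named vector")
  if (any(weights < 0)) stop("weights must be >= 0")
  if (abs(sum(weights) - 100) > 1e-9)
    stop("weights must sum to 100 (got ", sum(weights), ")")
  invisible(TRUE)
}

#' Default score-model registry
#'
#' All built-in piecewise logistic parameter sets, keyed by feature name.  The
#' Tm model is instantiated from the user's optimal Tm `T` as
#' `(T, T+1, T-2, T+5, T-5, T+10)`.  Any entry can be overridden.
#'
#' Registry entries: primer features `tm`, `gc`, `self`, `end_a`, `end_dg`;
#' SNP/poly penalty models `site_pos`, `snp_len`, `poly_len`; efficiency
#' models `btm` (bound Tm of an alignment) and `mismatch` (distance of a
#' mismatch to the 3' end); relation features `tmdiff`, `lendiff`, `pos`,
#' `dis`, `oeff`.
#'
#' @param opt_tm optimal primer Tm in degrees C (default 60).
#' @param overrides named list of [model_params] (or six-number vectors)
#'   replacing individual registry entries.
#' @return named list of `model_params`.
#' @export
feature_models <- function(opt_tm = 60, overrides = list()) {
  tt <- opt_tm
  reg <- list(
    tm       = model_params(tt, tt + 1, tt - 2, tt + 5, tt - 5, tt + 10),
    gc       = model_params(0.55, 0.6, 0.45, 0.65, 0.3, 0.7),
    self     = model_params(-50, 45, -50, 50, -50, 55),
    end_a    = model_params(1, 1, 0, 4, -1, 7),
    end_dg   = model_params(-9, -7, -12, -6, -14, -5),
    site_pos = model_params(0, 0, 0, 10, 0, 10),
    snp_len  = model_params(15, 100, -15, 100, -15, 100),
    poly_len = model_params(15, 100, 0, 100, 0, 100),
    btm      = model_params(60, 100, 45, 100, 45, 100),
    mismatch = model_params(25, 100, 0.95, 100, 0.95, 100),
    tmdiff   = model_params(0, 1, 0, 4, 0, 8),
    lendiff  = model_params(0, 2, 0, 6, 0, 10),
    pos      = model_params(10, 20, 5, 45, 5, 45),
    dis      = model_params(120, 160, 100, 180, 80, 200),
    oeff     = model_params(0, 0, 0, 0.02, 0, 0.1)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(reg)) stop("unknown model name: ", nm)
    reg[[nm]] <- .as_model_params(overrides[[nm]])
  }
  reg
}

#' Default weight tables
#'
#' The paper-style scoring uses three weight tables, each summing to 100: the
#' seven single-primer features, the five pair relation features, and the
#' three-way pair composition (Primer1, Primer2, relation).  The individual
#' defaults are a package choice (only the sum is fixed): Tm and GC dominate
#' the primer score, the off-target efficiency sum dominates the relation.
#'
#' @return named list with elements `primer`, `relation`, `pair`.
#' @export
default_weights <- function() {
  list(
    primer   = c(tm = 30, gc = 15, self = 15, end_dg = 15, snp = 15,
                 poly = 7, end_a = 3),
    relation = c(oeff = 50, dis = 25, pos = 15, tmdiff = 6, lendiff = 4),
    pair     = c(primer1 = 25, primer2 = 25, relation = 50)
  )
}
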