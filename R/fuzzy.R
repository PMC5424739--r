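# Mamdani-style fuzzy fusion of the three intention features. Inputs are
# normalized to [0,1] (features 1 and 2 inverted so that high = selection-like),
# converted to Low/High membership degrees through piecewise-linear ramps,
# combined over the 8-rule table with MIN or MAX inference, aggregated per
# output label, and defuzzified to a score in [0,1].

#' Linear membership-function parameters for one feature
#'
#' The Low function is 1 on `[0, aL]`, descends linearly to 0 at `bL`, and is
#' 0 afterwards; the High function is 0 on `[0, aH]`, ascends linearly to 1 at
#' `bH`, and is 1 afterwards. The ramp slopes/intercepts `(p, q)` follow from
#' continuity (`pL*aL + qL = 1`, `pL*bL + qL = 0`; `pH*aH + qH = 0`,
#' `pH*bH + qH = 1`).
#'
#' @param aL,bL Low ramp knees, `0 <= aL < bL <= 1`.
#' @param aH,bH High ramp knees, `0 <= aH < bH <= 1`.
#' @return a `membership_params` list with the eight Eq.-style constants.
#' @export
membership_params <- function(aL, bL, aH, bH) {
  stopifnot(aL >= 0, aL < bL, bL <= 1, aH >= 0, aH < bH, bH <= 1)
  structure(list(aL = aL, bL = bL, pL = -1 / (bL - aL), qL = bL / (bL - aL),
                 aH = aH, bH = bH, pH = 1 / (bH - aH), qH = -aH / (bH - aH)),
            class = "membership_params")
}

#' Illustrative membership parameters for the three features
#'
#' Complementary Low/High ramps per feature: feature 1 over `[0.2, 0.6]`,
#' feature 2 over `[0.1, 0.4]`, feature 3 over `[0.11, 0.61]`. These are the
#' package's worked-example defaults (e.g. feature 1 at 0.30 gives degrees
#' 0.75 Low / 0.25 High); calibrated systems should fit their own parameters
#' with [fit_membership_gap()] or [fit_membership_entropy()].
#'
#' @return named list of three `membership_params` (`f1`, `f2`, `f3`).
#' @export
example_membership_params <- function() {
  list(f1 = membership_params(0.2, 0.6, 0.2, 0.6),
       f2 = membership_params(0.1, 0.4, 0.1, 0.4),
       f3 = membership_params(0.11, 0.61, 0.11, 0.61))
}

#' Evaluate the Low/High membership degrees of one feature value
#'
#' @param x feature value in `[0, 1]` (vectorized).
#' @param params a `membership_params`.
#' @return for scalar `x`, named `c(L, H)`; for vector `x`, a 2-column matrix.
#' @export
eval_membership <- function(x, params) {
  muL <- ifelse(x <= params$aL, 1,
                ifelse(x >= params$bL, 0, params$pL * x + params$qL))
  muH <- ifelse(x <= params$aH, 0,
                ifelse(x >= params$bH, 1, params$pH * x + params$qH))
  if (length(x) == 1L) c(L = muL, H = muH) else cbind(L = muL, H = muH)
}

#' Fit membership ramps by the maximum-entropy criterion
#'
#' Histograms both labelled feature distributions on `[0, 1]` (bin width
#' `bin`, normalized to sum 1), grid-searches the ramp knees `(a, b)` at step
#' `step`, and picks the parameters maximizing
#' `H = -p_L log p_L - p_H log p_H`, where `p_L` is the non-gazing
#' distribution integrated against the Low function and `p_H` the gazing
#' distribution against the High function. The two entropy terms depend on
#' disjoint parameters, so each ramp is optimized independently (equivalent to
#' the joint grid search). Deterministic given the grid; ties go to the first
#' grid point in `(a, b)` lexicographic order.
#'
#' @param gazing feature values of the gazing-for-selection class.
#' @param non_gazing feature values of the non-gazing class.
#' @param step grid step for the knees.
#' @param bin histogram bin width.
#' @return a `membership_params` with an `entropy` attribute (the achieved
#'   maximum).
#' @export
fit_membership_entropy <- function(gazing, non_gazing, step = 0.01, bin = 0.01) {
  stopifnot(length(gazing) > 0, length(non_gazing) > 0)
  edges <- seq(0, 1, by = bin)
  centers <- edges[-1] - bin / 2
  histo <- function(v) {
    ct <- tabulate(pmin(pmax(ceiling(clamp(v, 0, 1) / bin), 1L), length(centers)),
                   nbins = length(centers))
    ct / sum(ct)
  }
  mH <- histo(gazing); mL <- histo(non_gazing)

  grid <- seq(0, 1, by = step)
  best_ramp <- function(m, high) {
    best <- list(val = -Inf)
    for (a in grid) {
      bs <- grid[grid > a]
      for (b in bs) {
        mu <- if (high) {
          ifelse(centers <= a, 0, ifelse(centers >= b, 1, (centers - a) / (b - a)))
        } else {
          ifelse(centers <= a, 1, ifelse(centers >= b, 0, (b - centers) / (b - a)))
        }
        p <- sum(m * mu)
        val <- if (p > 0) -p * log(p) else -Inf
        if (val > best$val) best <- list(val = val, a = a, b = b, p = p)
      }
    }
    if (!is.finite(best$val)) abort("non-overlapping ramps: class mass never covered")
    best
  }
  L <- best_ramp(mL, high = FALSE)
  H <- best_ramp(mH, high = TRUE)
  out <- membership_params(L$a, L$b, H$a, H$b)
  attr(out, "entropy") <- L$val + H$val
  attr(out, "p_L") <- L$p
  attr(out, "p_H") <- H$p
  out
}

#' Fit membership ramps across a feature's natural break
#'
#' Unsupervised calibration (and the fallback of [fit_membership_gap()], the
#' pipeline default): the Low and High linguistic classes of a feature are
#' identified with the two modes of its pooled (normalized) value
#' distribution. The split point is Otsu's
#' inter-class-variance threshold; the complementary ramps span the gap
#' between the clusters (from the maximum of the low cluster to the minimum
#' of the high one), so clearly bimodal features get crisp degrees while
#' overlapping clusters collapse the ramp onto the split point at a minimum
#' width and degrade gracefully.
#'
#' @param values normalized feature values (both classes pooled).
#' @param min_width minimum ramp width.
#' @return a `membership_params` (same knees for the L and H ramps).
#' @export
fit_membership_cluster <- function(values, min_width = 0.05) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 2)
  t <- otsu_threshold(values)
  lo <- values[values <= t]; hi <- values[values > t]
  if (length(lo) == 0L || length(hi) == 0L) {
    a <- t - min_width / 2; b <- t + min_width / 2
  } else {
    a <- max(lo); b <- min(hi)
  }
  if (b - a < min_width) {
    m <- (a + b) / 2
    a <- m - min_width / 2; b <- m + min_width / 2
  }
  a <- clamp(a, 0, 1 - min_width)
  b <- clamp(b, a + min_width, 1)
  membership_params(a, b, a, b)
}

# Otsu threshold of a 1-D sample on [0, 1] (maximum between-class variance
# over histogram bin edges).
otsu_threshold <- function(v, nbins = 100) {
  h <- tabulate(pmin(pmax(ceiling(clamp(v, 0, 1) * nbins), 1L), nbins), nbins = nbins)
  p <- h / sum(h)
  centers <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[nbins]
  valid <- w0 > 0 & w0 < 1
  bc <- rep(-Inf, nbins)
  bc[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(bc)
  k / nbins
}

#' Fit membership ramps from the training class gap
#'
#' Supervised calibration used as the pipeline default. If the labelled
#' classes are separable on this feature (every non-gazing value below every
#' gazing value, with at least `min_width` of clearance), the complementary
#' ramps span exactly that gap, giving crisp degrees with the widest possible
#' margin. When the classes overlap on this feature (as they legitimately do
#' for the dwell feature, where an unintentional fixation is as still as an
#' intentional one), the ramp falls back to the feature's own distributional
#' split via [fit_membership_cluster()].
#'
#' @param gazing,non_gazing normalized (inverted where applicable) feature
#'   values of the two training classes.
#' @param gap_min smallest class gap treated as real separation; narrower
#'   gaps are treated as overlap.
#' @param min_width minimum ramp width used by the cluster fallback.
#' @return a `membership_params` (same knees for the L and H ramps).
#' @export
fit_membership_gap <- function(gazing, non_gazing, gap_min = 0.01,
                               min_width = 0.05) {
  a <- max(non_gazing); b <- min(gazing)
  if (b - a < gap_min) return(fit_membership_cluster(c(gazing, non_gazing), min_width))
  a <- clamp(a, 0, 1 - gap_min)
  b <- clamp(b, a + gap_min, 1)
  membership_params(a, b, a, b)
}

#' The eight-entry fuzzy rule table
#'
#' Antecedents are the Low/High labels of features 1-3; the consequent is the
#' output label: LLL->L, LLH->L, LHL->M, LHH->H, HLL->L, HLH->M, HHL->H,
#' HHH->H.
#'
#' @return tibble with columns `f1`, `f2`, `f3`, `out`.
#' @export
rule_table <- function() {
  tibble(
    f1 = c("L", "L", "L", "L", "H", "H", "H", "H"),
    f2 = c("L", "L", "H", "H", "L", "L", "H", "H"),
    f3 = c("L", "H", "L", "H", "L", "H", "L", "H"),
    out = c("L", "L", "M", "H", "L", "M", "H", "H"))
}

#' Inference values for all eight label combinations
#'
#' For each rule, looks up the membership degree of each feature's label and
#' combines the three degrees by the MIN (or MAX) rule into the inference
#' value (IV); the rule's consequent is the IV's output label.
#'
#' @param fv numeric `c(f1, f2, f3)` in `[0, 1]` (already inverted where
#'   applicable, see [normalize_features()]).
#' @param params list of three `membership_params` (`f1`, `f2`, `f3`).
#' @param rules rule table, default [rule_table()].
#' @param mode `"MIN"` or `"MAX"`.
#' @return tibble with `f1`, `f2`, `f3` (labels), `iv`, `out` per rule.
#' @export
infer_ivs <- function(fv, params, rules = rule_table(), mode = c("MIN", "MAX")) {
  mode <- match.arg(mode)
  deg <- list(f1 = eval_membership(fv[[1]], params$f1),
              f2 = eval_membership(fv[[2]], params$f2),
              f3 = eval_membership(fv[[3]], params$f3))
  comb <- if (mode == "MIN") pmin else pmax
  rules$iv <- as.numeric(comb(deg$f1[rules$f1], deg$f2[rules$f2], deg$f3[rules$f3]))
  rules[, c("f1", "f2", "f3", "iv", "out")]
}

# Output membership functions on [0,1]: L descends 1 -> 0 over [0, 0.5],
# M is the triangle 0 -> 1 -> 0 with apex at 0.5, H ascends 0 -> 1 over
# [0.5, 1]. Returns cbind(L, M, H) for vector x.
output_mf <- function(x) {
  cbind(L = clamp(1 - 2 * x, 0, 1),
        M = clamp(1 - 2 * abs(x - 0.5), 0, 1),
        H = clamp(2 * x - 1, 0, 1))
}

# Per-label aggregate heights (standard Mamdani max-aggregation).
aggregate_heights <- function(ivs) {
  h <- c(L = 0, M = 0, H = 0)
  for (lab in c("L", "M", "H")) {
    v <- ivs$iv[ivs$out == lab]
    if (length(v)) h[lab] <- max(v)
  }
  h
}

# Height of the clipped union at x (vectorized): each output MF clipped at
# its aggregate height, overlaps counted once (pointwise maximum).
union_height <- function(x, heights) {
  mf <- output_mf(x)
  pmax(pmin(mf[, "L"], heights["L"]),
       pmin(mf[, "M"], heights["M"]),
       pmin(mf[, "H"], heights["H"]))
}

#' Defuzzify aggregated inference values to a score
#'
#' Clips each output membership function at its label's aggregate height (the
#' maximum IV sharing that label) and reduces the union region, overlaps
#' counted once, to a single abscissa: first/last of maxima (FOM/LOM), their
#' midpoint (MOM), center of gravity (COG, centroid of the union region), or
#' bisector of area (BOA, the abscissa splitting the union's area in half).
#' COG and BOA are computed in closed form on the piecewise-linear union. If
#' every IV is zero the score is 0 (with a warning).
#'
#' @param ivs tibble from [infer_ivs()] (or any tibble with `iv`, `out`).
#' @param method one of `"FOM"`, `"MOM"`, `"LOM"`, `"COG"`, `"BOA"`.
#' @return score in `[0, 1]`.
#' @export
defuzzify <- function(ivs, method = c("COG", "BOA", "FOM", "MOM", "LOM")) {
  method <- match.arg(method)
  h <- aggregate_heights(ivs)
  if (all(h == 0)) {
    warn("all inference values are zero; score 0 by convention")
    return(0)
  }
  seg <- union_segments(h)
  if (method %in% c("FOM", "LOM", "MOM")) {
    vals <- union_height(seg$x, h)
    top <- max(vals)
    at_top <- seg$x[vals >= top - 1e-12]
    w1 <- min(at_top); w3 <- max(at_top)
    return(switch(method, FOM = w1, LOM = w3, MOM = (w1 + w3) / 2))
  }
  x <- seg$x; y <- union_height(x, h)
  nseg <- length(x) - 1
  dx <- diff(x)
  area_i <- dx * (y[-length(y)] + y[-1]) / 2
  area <- sum(area_i)
  if (area <= 0) return(0)
  if (method == "COG") {
    # per segment h(t) = alpha + beta t; moment = integral t h(t) dt
    beta <- ifelse(dx > 0, diff(y) / dx, 0)
    alpha <- y[-length(y)] - beta * x[-length(x)]
    u <- x[-length(x)]; v <- x[-1]
    mom <- alpha * (v^2 - u^2) / 2 + beta * (v^3 - u^3) / 3
    return(sum(mom) / area)
  }
  # BOA: walk cumulative area to area/2, solve the quadratic in-segment
  target <- area / 2
  cum <- c(0, cumsum(area_i))
  i <- which(cum[-1] >= target - 1e-15)[1]
  u <- x[i]; v <- x[i + 1]
  rem <- target - cum[i]
  beta <- if (v > u) (y[i + 1] - y[i]) / (v - u) else 0
  alpha <- y[i] - beta * u
  # solve alpha*(t-u) + beta*(t^2-u^2)/2 = rem for t in [u, v]
  if (abs(beta) < 1e-14) {
    t <- if (alpha > 0) u + rem / alpha else v
  } else {
    A <- beta / 2; B <- alpha; C <- -(rem + alpha * u + beta * u^2 / 2)
    disc <- max(B^2 - 4 * A * C, 0)
    roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
    inb <- roots[roots >= u - 1e-12 & roots <= v + 1e-12]
    t <- if (length(inb)) inb[1] else v
  }
  clamp(t, u, v)
}

# Breakpoints of the clipped-union height function: the output-MF knees, the
# clip abscissae, and the pairwise crossings of the clipped curves inside each
# interval (between consecutive candidate points each clipped MF is linear, so
# crossings are found exactly).
union_segments <- function(heights) {
  cand <- c(0, 0.5, 1,
            (1 - heights["L"]) / 2,                 # L meets its clip level
            heights["M"] / 2, 1 - heights["M"] / 2, # M meets its clip level
            (1 + heights["H"]) / 2)                 # H meets its clip level
  cand <- sort(unique(clamp(cand, 0, 1)))
  clipped <- function(x) {
    mf <- output_mf(x)
    cbind(pmin(mf[, "L"], heights["L"]),
          pmin(mf[, "M"], heights["M"]),
          pmin(mf[, "H"], heights["H"]))
  }
  xs <- cand
  for (i in seq_len(length(cand) - 1)) {
    u <- cand[i]; v <- cand[i + 1]
    if (v - u < 1e-12) next
    yu <- clipped(u); yv <- clipped(v)
    sl <- (yv - yu) / (v - u)
    ic <- yu - sl * u
    for (p in 1:2) for (q in (p + 1):3) {
      if (abs(sl[p] - sl[q]) > 1e-12) {
        t <- (ic[q] - ic[p]) / (sl[p] - sl[q])
        if (t > u + 1e-12 && t < v - 1e-12) xs <- c(xs, t)
      }
    }
  }
  list(x = sort(unique(xs)))
}

#' Threshold a fuzzy score into a selection decision
#'
#' @param score fuzzy output score in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]`; selection requires
#'   `score > threshold` (strict).
#' @return `"selected"` or `"not_selected"`.
#' @export
decide <- function(score, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(score > threshold, "selected", "not_selected")
}

#' Normalize raw features to the fuzzy input scale
#'
#' Min-max scales each raw feature by its training range, clips to `[0, 1]`,
#' and inverts features 1 and 2 (`f <- 1 - f`) so that for all three features
#' larger means more selection-like.
#'
#' @param raw_f1,raw_f2,raw_f3 raw feature values (vectorized).
#' @param ranges list with elements `f1`, `f2`, `f3`, each `c(min, max)` from
#'   training data.
#' @return for scalars, named `c(f1, f2, f3)`; for vectors, a 3-column matrix.
#' @export
normalize_features <- function(raw_f1, raw_f2, raw_f3, ranges) {
  sc <- function(v, r) {
    if (r[2] <= r[1]) abort("degenerate feature range: max must exceed min")
    clamp((v - r[1]) / (r[2] - r[1]), 0, 1)
  }
  f1 <- 1 - sc(raw_f1, ranges$f1)
  f2 <- 1 - sc(raw_f2, ranges$f2)
  f3 <- sc(raw_f3, ranges$f3)
  if (length(raw_f1) == 1L) c(f1 = f1, f2 = f2, f3 = f3) else cbind(f1 = f1, f2 = f2, f3 = f3)
}

#' Construct a fuzzy target-selection system
#'
#' Bundles the per-feature membership parameters, the rule table, the
#' inference mode, the defuzzification method, the decision threshold and the
#' training feature ranges into one object usable with [score_features()].
#'
#' @param params list of three `membership_params`; default
#'   [example_membership_params()].
#' @param mode `"MIN"` or `"MAX"` inference.
#' @param method defuzzification method (see [defuzzify()]).
#' @param threshold decision threshold.
#' @param feature_ranges training ranges for [normalize_features()], or `NULL`
#'   if features are already normalized.
#' @param rules rule table.
#' @return a `fuzzy_system`.
#' @export
fuzzy_system <- function(params = example_membership_params(),
                         mode = "MIN", method = "COG", threshold = 0.5,
                         feature_ranges = NULL, rules = rule_table()) {
  structure(list(params = params, rules = rules, mode = mode, method = method,
                 threshold = threshold, feature_ranges = feature_ranges),
            class = "fuzzy_system")
}

#' Score a table of feature vectors with a fuzzy system
#'
#' @param fs a [fuzzy_system()].
#' @param features tibble with raw features `f1_raw`, `f2_raw`, `f3_raw` (when
#'   the system carries training ranges) or normalized `f1`, `f2`, `f3`.
#' @return the input tibble with `f1`, `f2`, `f3` (normalized), `score`, and
#'   `decision` columns appended.
#' @export
score_features <- function(fs, features) {
  if (!is.null(fs$feature_ranges)) {
    fv <- normalize_features(features$f1_raw, features$f2_raw, features$f3_raw,
                             fs$feature_ranges)
    if (is.null(dim(fv))) fv <- matrix(fv, 1, dimnames = list(NULL, names(fv)))
  } else {
    fv <- cbind(f1 = features$f1, f2 = features$f2, f3 = features$f3)
  }
  scores <- vapply(seq_len(nrow(fv)), function(i) {
    if (anyNA(fv[i, ])) return(NA_real_)
    ivs <- infer_ivs(fv[i, ], fs$params, fs$rules, fs$mode)
    suppressWarnings(defuzzify(ivs, fs$method))
  }, numeric(1))
  features$f1 <- fv[, "f1"]; features$f2 <- fv[, "f2"]; features$f3 <- fv[, "f3"]
  features$score <- scores
  features$decision <- decide(scores, fs$threshold)
  features
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat("Fuzzy target-selection system\n")
  cat("  inference:", x$mode, " defuzzification:", x$method,
      " threshold:", x$threshold, "\n")
  for (f in names(x$params)) {
    p <- x$params[[f]]
    cat(sprintf("  %s: L ramp [%.3f, %.3f], H ramp [%.3f, %.3f]\n",
                f, p$aL, p$bL, p$aH, p$bH))
  }
  invisible(x)
}

#' Tidy the membership parameters of a fuzzy system
#' @param x a `fuzzy_system`.
#' @param ... unused.
#' @return tibble with one row per feature and the eight ramp constants.
#' @export
tidy.fuzzy_system <- function(x, ...) {
  bind_rows(purrr::imap(x$params, function(p, nm) {
    tibble(feature = nm, aL = p$aL, bL = p$bL, pL = p$pL, qL = p$qL,
           aH = p$aH, bH = p$bH, pH = p$pH, qH = p$qH)
  }))
}

#' One-row summary of a fuzzy system
#' @param x a `fuzzy_system`.
#' @param ... unused.
#' @export
glance.fuzzy_system <- function(x, ...) {
  tibble(mode = x$mode, method = x$method, threshold = x$threshold,
         n_rules = nrow(x$rules), n_features = length(x$params))
}
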