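# Fuzzy fusion: membership evaluation and fitting, rule inference,
# defuzzification, and decisions.

test_that("membership ramps evaluate piecewise with continuity constraints", {
  p <- membership_params(0.2, 0.6, 0.2, 0.6)
  expect_equal(unname(eval_membership(0.1, p)), c(1, 0))
  expect_equal(unname(eval_membership(0.9, p)), c(0, 1))
  expect_equal(unname(eval_membership(0.4, p)), c(0.5, 0.5))   # midpoint of the ramp
  # continuity: pL*aL + qL = 1, pL*bL + qL = 0, pH*aH + qH = 0, pH*bH + qH = 1
  expect_equal(p$pL * p$aL + p$qL, 1)
  expect_equal(p$pL * p$bL + p$qL, 0)
  expect_equal(p$pH * p$aH + p$qH, 0)
  expect_equal(p$pH * p$bH + p$qH, 1)
  expect_lt(p$pL, 0); expect_gt(p$pH, 0)
})

test_that("worked-example degrees reproduce the printed values", {
  p <- fig_params()
  expect_equal(unname(eval_membership(0.30, p$f1)), c(0.75, 0.25))
  expect_equal(unname(eval_membership(0.50, p$f2)), c(0.00, 1.00))
  expect_equal(unname(eval_membership(0.45, p$f3)), c(0.32, 0.68))
})

test_that("the rule table holds the eight published antecedent-consequent pairs", {
  rt <- rule_table()
  expect_equal(nrow(rt), 8)
  want <- c(LLL = "L", LLH = "L", LHL = "M", LHH = "H",
            HLL = "L", HLH = "M", HHL = "H", HHH = "H")
  got <- setNames(rt$out, paste0(rt$f1, rt$f2, rt$f3))
  expect_equal(got[names(want)], want)
})

test_that("MIN and MAX inference reproduce the published IV table", {
  fv <- c(0.30, 0.50, 0.45)
  p <- fig_params()
  mn <- infer_ivs(fv, p, mode = "MIN")
  mx <- infer_ivs(fv, p, mode = "MAX")
  # all eight MIN-rule inference values with labels
  expect_equal(mn$iv, c(0.00, 0.00, 0.32, 0.68, 0.00, 0.00, 0.25, 0.25))
  expect_equal(mn$out, c("L", "L", "M", "H", "L", "M", "H", "H"))
  # all eight MAX-rule inference values with labels
  expect_equal(mx$iv, c(0.75, 0.75, 1.00, 1.00, 0.32, 0.68, 1.00, 1.00))
  expect_equal(mx$out, c("L", "L", "M", "H", "L", "M", "H", "H"))
  # the worked (H, L, H) combination: 0.00(M) under MIN, 0.68(M) under MAX
  hlh <- mn$f1 == "H" & mn$f2 == "L" & mn$f3 == "H"
  expect_equal(mn$iv[hlh], 0.00)
  expect_equal(mx$iv[hlh], 0.68)
  expect_equal(mn$out[hlh], "M")
  expect_equal(mx$out[hlh], "M")
  # MIN <= MAX per combination, always
  set.seed(3)
  for (i in 1:50) {
    fvr <- runif(3)
    expect_true(all(infer_ivs(fvr, p, mode = "MIN")$iv <=
                    infer_ivs(fvr, p, mode = "MAX")$iv))
  }
})

test_that("defuzzifiers agree with geometry and the integration oracle", {
  p <- fig_params()
  mn <- infer_ivs(c(0.30, 0.50, 0.45), p, mode = "MIN")
  # aggregate heights L=0, M=0.32, H=0.68; frozen oracle values from
  # trapezoidal integration at step 1e-5
  expect_equal(defuzzify(mn, "COG"), 0.6162817, tolerance = 1e-4)
  expect_equal(defuzzify(mn, "BOA"), 0.6794436, tolerance = 1e-4)
  expect_equal(defuzzify(mn, "FOM"), 0.84)   # H plateau starts at (1+0.68)/2
  expect_equal(defuzzify(mn, "LOM"), 1)
  expect_equal(defuzzify(mn, "MOM"), 0.92)

  # L-only activation: FOM sits at the plateau start, 0
  l_only <- tibble::tibble(iv = c(0.6, 0, 0), out = c("L", "M", "H"))
  expect_equal(defuzzify(l_only, "FOM"), 0)
  expect_equal(defuzzify(l_only, "LOM"), (1 - 0.6) / 2)
  expect_equal(defuzzify(l_only, "MOM"),
               (defuzzify(l_only, "FOM") + defuzzify(l_only, "LOM")) / 2)

  expect_warning(sc <- defuzzify(tibble::tibble(iv = c(0, 0, 0),
                                                out = c("L", "M", "H"))),
                 "zero")
  expect_equal(sc, 0)
})

test_that("COG and BOA match numeric integration on 1000 random IV sets", {
  set.seed(101)
  max_dev <- 0
  for (i in 1:1000) {
    ivs <- tibble::tibble(iv = runif(8),
                          out = sample(c("L", "M", "H"), 8, replace = TRUE))
    orc <- defuzz_oracle(iv_heights(ivs))
    max_dev <- max(max_dev,
                   abs(defuzzify(ivs, "COG") - orc$cog),
                   abs(defuzzify(ivs, "BOA") - orc$boa))
  }
  expect_lt(max_dev, 1e-4)
})

test_that("defuzzifier ordering and support invariants hold", {
  set.seed(55)
  for (i in 1:200) {
    ivs <- tibble::tibble(iv = runif(8) * rbinom(8, 1, 0.8),
                          out = sample(c("L", "M", "H"), 8, replace = TRUE))
    if (all(ivs$iv == 0)) next
    fom <- defuzzify(ivs, "FOM"); mom <- defuzzify(ivs, "MOM")
    lom <- defuzzify(ivs, "LOM")
    expect_lte(fom, mom + 1e-12); expect_lte(mom, lom + 1e-12)
    for (m in c("COG", "BOA")) {
      v <- defuzzify(ivs, m)
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
})

test_that("COG scores are bounded by and attained at the label corners", {
  # raising one feature toward High is not globally monotone under this rule
  # base (H-L-L fires the Low consequent, so a rising f1 can raise the Low
  # aggregate); the sound ordering property is that the all-Low and all-High
  # corners bound every achievable score and are attained
  p <- fig_params()
  lo_corner <- suppressWarnings(defuzzify(infer_ivs(c(0, 0, 0), p, mode = "MIN"), "COG"))
  hi_corner <- suppressWarnings(defuzzify(infer_ivs(c(1, 1, 1), p, mode = "MIN"), "COG"))
  expect_equal(lo_corner, 1 / 6, tolerance = 1e-9)   # centroid of the L triangle
  expect_equal(hi_corner, 5 / 6, tolerance = 1e-9)   # centroid of the H triangle
  set.seed(202)
  for (i in 1:2000) {
    s <- suppressWarnings(defuzzify(infer_ivs(runif(3), p, mode = "MIN"), "COG"))
    expect_gte(s, lo_corner - 1e-9)
    expect_lte(s, hi_corner + 1e-9)
  }
  # on the High plateaus of all three features the score is pinned at the top
  expect_equal(suppressWarnings(
    defuzzify(infer_ivs(c(0.8, 0.9, 0.95), p, mode = "MIN"), "COG")), hi_corner)
})

test_that("entropy fitting targets the 1/e coverage and refines monotonically", {
  gaz <- rep(0.9, 200)
  non <- rep(0.1, 200)
  fit <- fit_membership_entropy(gaz, non, step = 0.05)
  expect_lt(abs(attr(fit, "p_L") - exp(-1)), 0.15)
  expect_lt(abs(attr(fit, "p_H") - exp(-1)), 0.15)
  # oracle: the achieved entropy equals the exhaustive grid evaluation
  best <- -Inf
  grid <- seq(0, 1, by = 0.05)
  centers <- seq(0.005, 0.995, by = 0.01)
  mL <- as.numeric(abs(centers - 0.095) < 0.005)
  mH <- as.numeric(abs(centers - 0.895) < 0.005)
  term <- function(p) if (p > 0) -p * log(p) else -Inf
  bl <- -Inf; bh <- -Inf
  for (a in grid) for (b in grid[grid > a]) {
    muL <- ifelse(centers <= a, 1, ifelse(centers >= b, 0, (b - centers) / (b - a)))
    muH <- ifelse(centers <= a, 0, ifelse(centers >= b, 1, (centers - a) / (b - a)))
    bl <- max(bl, term(sum(mL * muL)))
    bh <- max(bh, term(sum(mH * muH)))
  }
  expect_equal(attr(fit, "entropy"), bl + bh, tolerance = 1e-10)

  # refining the grid never decreases the achieved maximum
  finer <- fit_membership_entropy(gaz, non, step = 0.01)
  expect_gte(attr(finer, "entropy"), attr(fit, "entropy") - 1e-12)

  # identical class distributions: the entropy surface is symmetric under
  # swapping the L and H ramp parameter pairs (direct evaluation)
  m <- mL + mH; m <- m / sum(m)
  entro <- function(la, lb, ha, hb) {
    muL <- ifelse(centers <= la, 1, ifelse(centers >= lb, 0, (lb - centers) / (lb - la)))
    muH <- ifelse(centers <= ha, 0, ifelse(centers >= hb, 1, (centers - ha) / (hb - ha)))
    term(sum(m * muL)) + term(sum(m * muH))
  }
  mirror <- function(a, b) c(1 - b, 1 - a)   # reflected ramp covers the same mass
  for (pars in list(c(0.1, 0.4, 0.5, 0.9), c(0.2, 0.3, 0.3, 0.8))) {
    swapped <- c(mirror(pars[3], pars[4]), mirror(pars[1], pars[2]))
    direct <- entro(pars[1], pars[2], pars[3], pars[4])
    flipped <- entro(swapped[1], swapped[2], swapped[3], swapped[4])
    # symmetric distributions make the two assignments agree
    msym <- rev(m)
    entro_sym <- function(la, lb, ha, hb, dist) {
      muL <- ifelse(centers <= la, 1, ifelse(centers >= lb, 0, (lb - centers) / (lb - la)))
      muH <- ifelse(centers <= ha, 0, ifelse(centers >= hb, 1, (centers - ha) / (hb - ha)))
      term(sum(dist * muL)) + term(sum(dist * muH))
    }
    expect_equal(entro_sym(pars[1], pars[2], pars[3], pars[4], m),
                 entro_sym(swapped[1], swapped[2], swapped[3], swapped[4], msym),
                 tolerance = 1e-12)
  }
})

test_that("gap and cluster calibrations bracket separable classes", {
  set.seed(12)
  gaz <- runif(50, 0.8, 1)
  non <- runif(50, 0, 0.5)
  g <- fit_membership_gap(gaz, non)
  expect_gte(g$aL, max(non) - 1e-9)
  expect_lte(g$bL, min(gaz) + 1e-9)
  expect_true(all(eval_membership(non, g)[, "H"] == 0))
  expect_true(all(eval_membership(gaz, g)[, "H"] == 1))

  cl <- fit_membership_cluster(c(gaz, non))
  expect_gt(cl$aL, max(non) - 0.05)
  expect_lt(cl$bL, min(gaz) + 0.05)

  # overlapping classes fall back to a narrow mid ramp without error
  ov <- fit_membership_gap(runif(50, 0.3, 0.7), runif(50, 0.2, 0.6))
  expect_lt(ov$bL - ov$aL, 0.2)
})

test_that("feature normalization scales, clips, and inverts", {
  ranges <- list(f1 = c(0, 2), f2 = c(10, 110), f3 = c(0, 4))
  fv <- normalize_features(0, 110, 4, ranges)
  expect_equal(unname(fv), c(1, 0, 1))
  expect_equal(unname(normalize_features(5, -10, 2, ranges)), c(0, 1, 0.5))
  expect_error(normalize_features(1, 1, 1, list(f1 = c(1, 1), f2 = c(0, 1),
                                                f3 = c(0, 1))),
               "degenerate feature range")
})

test_that("decisions use a strict threshold", {
  expect_equal(decide(0.68, 0.30), "selected")
  expect_equal(decide(0.30, 0.30), "not_selected")
  expect_equal(decide(1, 1), "not_selected")
})

test_that("fuzzy_system scores feature tables and has tidy methods", {
  fs <- fuzzy_system(feature_ranges = list(f1 = c(0, 1), f2 = c(0, 100),
                                           f3 = c(0, 5)))
  feats <- tibble::tibble(f1_raw = c(0.05, 0.9), f2_raw = c(5, 90),
                          f3_raw = c(4.5, 0.2))
  out <- score_features(fs, feats)
  expect_gt(out$score[1], out$score[2])
  expect_equal(out$decision, c("selected", "not_selected"))
  td <- tidy(fs)
  expect_equal(nrow(td), 3)
  expect_named(glance(fs), c("mode", "method", "threshold", "n_rules", "n_features"))
})
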