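test_that("channel categories follow the stable/inducible/inconclusive rules", {
  ## both non-significant -> stable
  expect_equal(classify_channel(0.5, 2, 0.9, -1)$category, "stable")
  ## one contrast a full DMS -> inducible via that contrast
  r <- classify_channel(0.001, 20, 0.3, 5)
  expect_equal(r$category, "inducible")
  expect_equal(r$induced_by, "within")
  ## significant but sub-threshold everywhere -> inconclusive
  expect_equal(classify_channel(0.001, 10, 0.001, -12)$category, "inconclusive")
  ## precedence: one inducing contrast beats the other's sub-threshold signal
  r2 <- classify_channel(0.001, 10, 0.001, 20)
  expect_equal(r2$category, "inducible")
  expect_equal(r2$induced_by, "trans")
  ## missing q -> unclassifiable
  expect_true(is.na(classify_channel(NA, 10, 0.5, 5)$category))
})

test_that("direction matching compares signs, transgenerational wins conflicts", {
  d <- classify_direction(20, 18, NA, "within")
  expect_equal(d$direction, "expected")
  d <- classify_direction(20, -16, NA, "within")
  expect_equal(d$direction, "opposite")
  ## both induce and disagree: trans label, conflict flagged
  d <- classify_direction(20, 16, -18, "within+trans")
  expect_equal(d$direction, "opposite")
  expect_true(d$conflict)
  ## zero wild difference cannot be matched
  d <- classify_direction(0, 16, 16, "within+trans")
  expect_equal(d$direction, "not-applicable")
})

test_that("delta.meth.diff identities hold under both orientations", {
  expect_equal(delta_meth_diff(30, 30), 100)
  expect_equal(delta_meth_diff(30, 0), 70)
  expect_equal(delta_meth_diff(20, 35), 115)   # overshoot allowed
  ## exactness at equality for any sign
  withr::with_seed(3, {
    w <- runif(100, -50, 50)
    expect_equal(delta_meth_diff(w, w), rep(100, 100))
    ## negative wild differences are sign-flipped, not penalized
    expect_equal(delta_meth_diff(-30, -30), 100)
    expect_equal(delta_meth_diff(-30, 0), 70)
  })
})

test_that("acclimation ANOVA matches a hand-computed balanced decomposition", {
  ## balanced 2x2 with 5 replicates per cell
  withr::with_seed(5, {
    cells <- expand.grid(direction = c("hypo", "hyper"),
                         acclim = c("within", "trans"))
    mu <- c(80, 90, 95, 93)  # direction x acclimation means
    y <- unlist(lapply(seq_len(4), function(i) mu[i] + rnorm(5, 0, 4)))
    dirf <- rep(cells$direction, each = 5)
    accf <- rep(cells$acclim, each = 5)
    r <- acclimation_anova(y, dirf, accf)

    ## textbook sums of squares for the balanced case
    n <- 5
    ybar <- mean(y)
    m_dir <- tapply(y, dirf, mean)
    m_acc <- tapply(y, accf, mean)
    m_cell <- tapply(y, paste(dirf, accf), mean)
    ss_acc <- 2 * n * sum((m_acc - ybar)^2)
    ss_dir <- 2 * n * sum((m_dir - ybar)^2)
    ss_cell <- n * sum((m_cell - ybar)^2)
    ss_int <- ss_cell - ss_acc - ss_dir
    ss_res <- sum((y - ave(y, paste(dirf, accf)))^2)
    f_acc <- (ss_acc / 1) / (ss_res / 16)
    f_int <- (ss_int / 1) / (ss_res / 16)
    expect_equal(r$F_main, f_acc, tolerance = 1e-6)
    expect_equal(r$F_interaction, f_int, tolerance = 1e-6)
    expect_equal(r$df_resid, 16)
  })
})

test_that("acclimation ANOVA detects a pure main effect and exact null interactions", {
  ## identical value sets per cell: interaction sum of squares is exactly 0
  base <- c(88, 90, 92)
  y <- rep(base, 4)
  dirf <- rep(rep(c("hypo", "hyper"), each = 3), 2)
  accf <- rep(c("within", "trans"), each = 6)
  r0 <- acclimation_anova(y, dirf, accf)
  expect_equal(r0$F_interaction, 0)
  ## shifting the trans cells uniformly creates a main effect only
  y2 <- y + ifelse(accf == "trans", 10, 0)
  r1 <- acclimation_anova(y2, dirf, accf)
  expect_gt(r1$F_main, 10)
  expect_equal(r1$F_interaction, 0)
  ## empty cell: interaction not estimable, flagged
  keep <- !(dirf == "hypo" & accf == "trans")
  r2 <- acclimation_anova(y2[keep], dirf[keep], accf[keep])
  expect_equal(r2$flag, "empty_cell")
  expect_true(is.na(r2$F_interaction))
})

test_that("enrichment randomization is seeded, calibrated at equality, and powerful", {
  withr::with_seed(9, {
    universe <- sample(c("inducible", "stable", "inconclusive"), 2000,
                       replace = TRUE, prob = c(0.1, 0.6, 0.3))
  })
  r1 <- enrichment_randomization(universe, c(inducible = 30, stable = 180,
                                             inconclusive = 90),
                                 reps = 300, seed = 4)
  r2 <- enrichment_randomization(universe, c(inducible = 30, stable = 180,
                                             inconclusive = 90),
                                 reps = 300, seed = 4)
  expect_identical(r1, r2)                       # bit-reproducible
  ## observed equal to expected -> chi2 exactly 0, p 1
  r3 <- enrichment_randomization(universe, r1$expected, reps = 300, seed = 4,
                                 n_popdms = 300)
  expect_equal(r3$chi2, 0)
  expect_equal(r3$p, 1)
  ## strong inducible excess -> tiny p
  r4 <- enrichment_randomization(universe, c(inducible = 200, stable = 70,
                                             inconclusive = 30),
                                 reps = 300, seed = 4)
  expect_lt(r4$p, 1e-3)
  expect_error(enrichment_randomization(universe, c(1, 1, 1), n_popdms = 1e6),
               "exceeds")
})

test_that("the hepatosomatic index is liver over total weight times 100", {
  expect_equal(hepatosomatic_index(0.05, 1.0), 5)
  expect_equal(hepatosomatic_index(2, 2), 100)
  expect_error(hepatosomatic_index(0, 1), "positive")
  expect_error(hepatosomatic_index(0.1, -1), "positive")
})

test_that("channel tables partition sites and record orientation", {
  mk_tab <- function(pos, q, diff) {
    structure(data.frame(chrom = "chr1", pos = pos, level_a = 50,
                         level_b = 50 + diff, meth_diff = diff,
                         lrt_stat = 1, df = 1L, p = q, q = q, flag = "",
                         dms = q < 0.0125 & abs(diff) >= 15,
                         stringsAsFactors = FALSE),
              class = c("diffmeth_table", "data.frame"))
  }
  pos <- c(10L, 20L, 30L)
  wild <- mk_tab(pos, c(0.001, 0.001, 0.001), c(30, -25, 20))
  within <- mk_tab(pos, c(0.001, 0.5, 0.001), c(18, 1, 5))
  trans <- mk_tab(pos, c(0.001, 0.6, 0.002), c(30, 0, 8))
  ch <- classify_channels(wild, within, trans)
  expect_equal(nrow(ch), 3L)
  expect_equal(ch$category, c("inducible", "stable", "inconclusive"))
  expect_equal(ch$direction[1], "expected")
  expect_equal(ch$meth_direction[1], "hyper")
  expect_true(all(table(ch$category) >= 0) &&
                sum(table(ch$category)) == nrow(ch))
  ## negative wild difference flagged as oriented
  expect_true(ch$oriented[2])
  expect_equal(ch$delta_meth_diff_trans[1], 100)
})
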