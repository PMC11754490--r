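test_that("Dice handles identity, disjoint, partial and empty masks", {
  sp <- c(1, 1, 1)
  a <- binary_mask(array(c(rep(TRUE, 4), rep(FALSE, 12)), c(4, 4, 1)), sp)
  expect_equal(dice(a, a), 1)
  b_bits <- array(FALSE, c(4, 4, 1)); b_bits[13:16] <- TRUE
  b <- binary_mask(b_bits, sp)
  expect_equal(dice(a, b), 0)
  # |A| = 4, |B| = 4, overlap 2 -> 0.5
  c_bits <- array(FALSE, c(4, 4, 1)); c_bits[3:6] <- TRUE
  expect_equal(dice(a, binary_mask(c_bits, sp)), 0.5)
  e <- binary_mask(array(FALSE, c(4, 4, 1)), sp)
  expect_equal(dice(e, e), 1)
  expect_error(dice(a, binary_mask(array(FALSE, c(4, 4, 2)), sp)),
               "shapes differ")
})

test_that("confusion matrices tally pairs with exact marginals", {
  cm <- confusion(rep("II", 10), rep("II", 10))
  expect_equal(sum(cm), 10)
  expect_equal(cm["II", "II"], 10, ignore_attr = TRUE)

  cm2 <- confusion(c("0", "0", "IV"), c("0", "I", "III"))
  expect_equal(cm2["0", "0"], 1, ignore_attr = TRUE)
  expect_equal(cm2["0", "I"], 1, ignore_attr = TRUE)
  expect_equal(cm2["IV", "III"], 1, ignore_attr = TRUE)
  expect_equal(sum(cm2), 3)

  set.seed(5)
  grades <- c("0", "I", "II", "III", "IV")
  ref <- sample(grades, 100, replace = TRUE)
  prd <- sample(grades, 100, replace = TRUE)
  cm3 <- confusion(ref, prd)
  expect_equal(as.vector(rowSums(cm3)),
               as.vector(table(factor(ref, levels = grades))))
  expect_error(confusion(c("0", "V"), c("0", "I")), "positions: 2")
  expect_error(confusion(c("0"), c("0", "I")), "lengths")
})

test_that("kappa matches hand values and brute-force tallies", {
  perfect <- diag(c(5, 8, 2, 4, 1))
  expect_equal(cohen_kappa(perfect)$kappa, 1)

  even <- matrix(c(10, 10, 10, 10), 2, 2)
  expect_equal(cohen_kappa(even)$kappa, 0)

  k <- cohen_kappa(matrix(c(45, 15, 5, 35), 2, 2))
  expect_equal(k$kappa, 0.6, tolerance = 1e-12)
  expect_lt(k$ci_low, 0.6)
  expect_gt(k$ci_high, 0.6)

  degenerate <- matrix(0, 3, 3); degenerate[1, 1] <- 10
  res <- cohen_kappa(degenerate)
  expect_true(is.na(res$kappa))
  expect_match(res$note, "undefined")
})

test_that("kappa agrees with an independent implementation", {
  set.seed(17)
  for (i in 1:25) {
    cm <- random_cm5()
    if (sum(cm) < 2) next
    ours <- cohen_kappa(cm)$kappa
    expect_equal(ours, bf_kappa(cm), tolerance = 1e-12)
    expect_equal(ours, e1071::classAgreement(cm)$kappa, tolerance = 1e-10)
    expect_lte(ours, 1)
  }
})

test_that("asymptotic and bootstrap intervals roughly agree", {
  cm <- matrix(c(40, 6, 3, 2, 5, 30, 4, 1, 2, 6, 25, 3, 1, 2, 4, 20),
               4, 4)
  asym <- cohen_kappa(cm)
  boot <- cohen_kappa(cm, method = "bootstrap", n_boot = 2000L, seed = 9L)
  expect_equal(asym$kappa, boot$kappa)
  expect_lt(abs(asym$ci_low - boot$ci_low), 0.06)
  expect_lt(abs(asym$ci_high - boot$ci_high), 0.06)
})

test_that("per-category diagnostics match one-vs-rest tallies", {
  perfect <- diag(c(5, 8, 2, 4, 1))
  dimnames(perfect) <- list(c("0", "I", "II", "III", "IV"),
                            c("0", "I", "II", "III", "IV"))
  pm <- per_category_metrics(perfect)
  expect_true(all(pm$sensitivity == 1 & pm$specificity == 1 &
                  pm$ppv == 1 & pm$npv == 1 & pm$f1 == 1))

  # hand-built 3-grade matrix
  cm <- matrix(c(8, 1, 0, 2, 6, 2, 0, 3, 8), 3, 3)
  pm2 <- per_category_metrics(cm)
  expect_equal(pm2$sensitivity[1], 0.8)
  expect_equal(pm2$ppv[1], 8 / 9)
  expect_equal(pm2$f1[1], 2 * 0.8 * (8 / 9) / (0.8 + 8 / 9),
               tolerance = 1e-12)

  # grade absent everywhere: sensitivity unavailable, specificity 1
  sparse <- matrix(0, 5, 5); sparse[1, 1] <- 4; sparse[3, 3] <- 6
  pm3 <- per_category_metrics(sparse)
  expect_true(is.na(pm3$sensitivity[2]))
  expect_equal(pm3$specificity[2], 1)
  expect_false(any(pm3$sensitivity == 0, na.rm = TRUE))

  set.seed(29)
  for (i in 1:25) {
    cm <- random_cm5()
    if (sum(cm) < 1) next
    pm <- per_category_metrics(cm)
    for (g in 1:5) {
      want <- bf_one_vs_rest(cm, g)
      expect_equal(pm$sensitivity[g], unname(want["sens"]),
                   tolerance = 1e-12)
      expect_equal(pm$specificity[g], unname(want["spec"]),
                   tolerance = 1e-12)
      expect_equal(pm$ppv[g], unname(want["ppv"]), tolerance = 1e-12)
      expect_equal(pm$npv[g], unname(want["npv"]), tolerance = 1e-12)
      expect_equal(pm$f1[g], unname(want["f1"]), tolerance = 1e-12)
    }
  }
})

test_that("agreement fractions partition the cohort", {
  perfect <- diag(c(5, 8, 2, 4, 1))
  ag <- agreement_summary(perfect)
  expect_equal(ag$exact, 1)
  expect_equal(ag$within_one + ag$beyond_one, 0)

  shifted <- matrix(0, 5, 5)
  for (g in 1:4) shifted[g, g + 1] <- 3
  ag2 <- agreement_summary(shifted)
  expect_equal(ag2$within_one, 1)
  expect_equal(ag2$over_estimated, 1)

  emb <- matrix(0, 5, 5)
  emb[1:2, 1:2] <- matrix(c(3, 1, 1, 3), 2, 2)
  ag3 <- agreement_summary(emb)
  expect_equal(ag3$exact, 0.75)
  expect_equal(ag3$within_one, 0.25)

  set.seed(31)
  for (i in 1:20) {
    cm <- random_cm5()
    if (sum(cm) < 1) next
    ag <- agreement_summary(cm)
    expect_equal(ag$exact + ag$within_one + ag$beyond_one, 1,
                 tolerance = 1e-12)
    want <- bf_agreement(cm)
    expect_equal(ag$over_estimated, unname(want["over"]),
                 tolerance = 1e-12)
    expect_equal(ag$under_estimated, unname(want["under"]),
                 tolerance = 1e-12)
  }
})

test_that("presence/absence diagnostics binarize at any-calcium", {
  expect_equal(presence_metrics(c(0, 5, 10), c(0, 5, 10)),
               list(sensitivity = 1, specificity = 1))
  allzero <- presence_metrics(c(0, 0), c(0, 0))
  expect_true(is.na(allzero$sensitivity))
  expect_equal(allzero$specificity, 1)
  pm <- presence_metrics(c(0, 0, 5, 10), c(0, 3, 5, 0))
  expect_equal(pm$sensitivity, 0.5)
  expect_equal(pm$specificity, 0.5)
  expect_error(presence_metrics(c(0, 1), c(0)), "lengths")
})
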