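test_that("pooled t test matches the textbook formula and its conventions", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  tt <- tTestTwoSample(a, b)
  sp2 <- (2 * var(a) + 5 * var(b)) / 7
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 6))
  expect_equal(tt$statistic, tHand, tolerance = 1e-12)
  expect_equal(tt$df, 7L)
  expect_equal(tt$p, 2 * pt(-abs(tHand), 7), tolerance = 1e-12)

  ident <- tTestTwoSample(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p, 1)

  shift <- tTestTwoSample(a + 100, b + 100)
  expect_equal(shift$statistic, tt$statistic, tolerance = 1e-12)

  expect_error(tTestTwoSample(1, b), class = "pianoSign_stats_error")
})

test_that("chi-square uses Pearson without continuity correction", {
  even <- chiSquare2x2(matrix(10, 2, 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p, 1)

  tab <- rbind(c(119, 83), c(32, 33))
  cs <- chiSquare2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cs$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(cs$p, pchisq(cs$statistic, 1, lower.tail = FALSE), tolerance = 1e-12)

  ## transposition symmetry
  expect_equal(chiSquare2x2(t(tab))$statistic, cs$statistic, tolerance = 1e-12)
  expect_error(chiSquare2x2(rbind(c(5, 0), c(7, 0))), class = "pianoSign_stats_error")
})

test_that("one-way ANOVA matches sums of squares and the t-squared identity", {
  gEq <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  avEq <- oneWayAnova(gEq)
  expect_equal(avEq$statistic, 0, tolerance = 1e-12)
  expect_equal(avEq$p, 1, tolerance = 1e-12)

  a <- c(1.2, 2.8, 2.1, 3.3); b <- c(2.0, 4.1, 3.3)
  av2 <- oneWayAnova(list(a, b))
  tt <- tTestTwoSample(a, b)
  expect_equal(av2$statistic, tt$statistic^2, tolerance = 1e-12)
  expect_equal(av2$p, tt$p, tolerance = 1e-12)

  g3 <- list(c(1, 2), c(4, 6), c(9, 11))
  av3 <- oneWayAnova(g3)
  x <- unlist(g3); gm <- mean(x)
  ssb <- sum(vapply(g3, function(v) length(v) * (mean(v) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  expect_equal(av3$statistic, (ssb / 2) / (ssw / 3), tolerance = 1e-12)
})

test_that("Bonferroni ordering strings follow corrected significance", {
  set.seed(4)
  groups <- list(A = rnorm(20, 10, 0.3), B = rnorm(20, 5, 0.3), C = rnorm(20, 0, 0.3))
  bp <- bonferroniPairwise(groups)
  expect_equal(bp$ordering, "A > B > C")
  expect_true(all(bp$pairs$pAdj <= 1))
  expect_true(all(bp$pairs$pAdj >= bp$pairs$p))

  same <- rnorm(20)
  bp2 <- bonferroniPairwise(list(A = same, B = same, C = same - 8))
  expect_equal(bp2$ordering, "A = B > C")
})

test_that("ICC(2,1) is 1 for identical raters and penalizes constant bias", {
  set.seed(5)
  x <- rnorm(30, 10, 3)
  expect_equal(iccAbsoluteSingle(cbind(x, x)), 1, tolerance = 1e-12)
  biased <- iccAbsoluteSingle(cbind(x, x + 2))
  expect_lt(biased, 1)
  expect_gt(biased, 0.5)

  ## against the classical mean-squares formula on a small table
  X <- rbind(c(9, 2, 5, 8), c(6, 1, 3, 2), c(8, 4, 6, 8),
             c(7, 1, 2, 6), c(10, 5, 6, 9), c(6, 2, 4, 7))
  n <- nrow(X); k <- ncol(X)
  a <- anova(aov(y ~ subj + rater,
                 data = data.frame(y = as.vector(X),
                                   subj = factor(rep(1:n, k)),
                                   rater = factor(rep(1:k, each = n)))))
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  expect_equal(iccAbsoluteSingle(X),
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
               tolerance = 1e-12)

  expect_error(iccAbsoluteSingle(matrix(3, 4, 2)), class = "pianoSign_stats_error")
})

test_that("cohort summaries recover planted sex effects and count correctly", {
  rec <- rbind(fakeRecords(60, 60, meanF = 0.68, meanM = 0.58, reference = "sTEA"),
               fakeRecords(60, 60, meanF = 0.64, meanM = 0.56, seed = 2, reference = "WSL"),
               fakeRecords(60, 60, meanF = 0.70, meanM = 0.70, seed = 3, reference = "FEA"))
  s <- summarizeCohort(rec)
  expect_equal(nrow(s$bySex), 3L)
  expect_equal(s$bySex$nFemale, rep(60L, 3L))
  expect_lt(s$bySex$p[s$bySex$reference == "sTEA"], 0.05)
  expect_gt(s$bySex$meanFemale[1], s$bySex$meanMale[1])
  expect_gt(s$bySex$p[s$bySex$reference == "FEA"], 0.05)
  expect_equal(nrow(s$byReference), 3L)
  expect_true(all(c("F", "ordering") %in% names(s$byReference)))
  expect_equal(sum(s$shapeCounts[, c("double", "single")]), 120L)
  expect_true(all(c("ML", "MpLp", "MpLp_ML_pct", "LD", "LD_ML_pct") %in% s$widths$parameter))
  ## ML planted higher in male-like records
  expect_lt(s$widths$p[s$widths$parameter == "ML"], 0.05)

  expect_error(summarizeCohort(rec[, setdiff(names(rec), "MedL_LatL")]),
               class = "pianoSign_stats_error")

  ## single-shape cohorts yield NA for the shape test instead of failing
  recOne <- fakeRecords(10, 10, 0.65, 0.6)
  recOne$shape <- "double_peak"
  expect_true(is.na(summarizeCohort(recOne)$shapeCounts$p[1]))
})
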