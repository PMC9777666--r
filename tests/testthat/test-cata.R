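test_that("the emoji lexicon has the study's valence structure", {
  lex <- emoji_lexicon()
  expect_equal(nrow(lex), 23)
  expect_equal(as.integer(table(lex$valence)[c("positive", "negative",
                                               "neutral")]),
               c(13L, 8L, 2L))
  expect_true(all(c("Grinning face", "Expressionless face") %in% lex$label))
})

test_that("frequency tables are percentages of consumers selecting", {
  arr <- array(0L, dim = c(4, 2, 3),
               dimnames = list(NULL, c("M-C-JH", "H-C-JH"),
                               c("grinning", "angry", "neutral")))
  arr[, 1, "grinning"] <- 1L          # everyone selects for sample 1
  arr[1:2, 2, "angry"] <- 1L          # half select for sample 2
  ft <- frequency_table(arr)
  expect_equal(ft["grinning", "M-C-JH"], 100)
  expect_equal(ft["angry", "H-C-JH"], 50)
  expect_equal(ft["neutral", "M-C-JH"], 0)
  cnt <- frequency_table(arr, basis = "count")
  expect_equal(cnt["grinning", "M-C-JH"], 4)
  arr[1, 1, 1] <- 2L
  expect_error(frequency_table(arr), "binary")
})

test_that("Cochran's Q is zero for identical columns and permutation
           invariant over consumers", {
  m <- matrix(rep(c(1, 0, 1, 0, 1), 3), ncol = 3)
  r <- cochran_q(m)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 1)
  set.seed(7)
  m2 <- matrix(rbinom(60, 1, 0.4), ncol = 4)
  expect_equal(cochran_q(m2)$statistic,
               cochran_q(m2[sample(nrow(m2)), ])$statistic)
  expect_error(cochran_q(matrix(c(0, 2), 1)), "binary")
})

test_that("Cochran's Q at k = 2 collapses to the McNemar statistic", {
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rbinom(40, 1, runif(1, 0.2, 0.8)), ncol = 2)
    b <- sum(m[, 1] == 1 & m[, 2] == 0)
    c_ <- sum(m[, 1] == 0 & m[, 2] == 1)
    expected <- if (b + c_ == 0) 0 else (b - c_)^2 / (b + c_)
    expect_equal(unname(cochran_q(m)$statistic), expected)
    if (b + c_ > 0) {  # cross-check against the stats engine
      xt <- table(factor(m[, 1], 0:1), factor(m[, 2], 0:1))
      expect_equal(unname(cochran_q(m)$statistic),
                   unname(stats::mcnemar.test(xt, correct = FALSE)$statistic))
    }
  }
})

test_that("the exact Q p-value equals exhaustive within-row permutation", {
  m <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0), c(1, 1, 0))
  got <- cochran_q(m, method = "exact")
  # independent oracle: enumerate all 6^4 full row permutations
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  qstat <- function(x) {
    k <- ncol(x); Cj <- colSums(x); Ri <- rowSums(x)
    den <- k * sum(Ri) - sum(Ri^2)
    if (den == 0) 0 else (k - 1) * (k * sum(Cj^2) - sum(Cj)^2) / den
  }
  qs <- c()
  for (a in perms) for (b in perms) for (cc in perms) for (d in perms)
    qs <- c(qs, qstat(rbind(m[1, a], m[2, b], m[3, cc], m[4, d])))
  p_oracle <- mean(qs >= qstat(m) - 1e-12)
  expect_equal(got$p.value, p_oracle, tolerance = 1e-12)
  expect_equal(unname(got$statistic), 3.5)
})

test_that("pairwise McNemar letters separate only significant pairs", {
  set.seed(3)
  same <- matrix(rbinom(30, 1, 0.5), ncol = 1)[, c(1, 1)]
  colnames(same) <- c("A", "B")
  r <- mcnemar_pairwise(same)
  expect_equal(unname(r$letters["A"]), unname(r$letters["B"]))

  # b = 20, c = 0 discordant pairs out of 93: exact p = 2 * 0.5^20
  m <- matrix(0L, 93, 9)
  colnames(m) <- crab_samples()
  m[1:20, 1] <- 1L
  r9 <- mcnemar_pairwise(m, alpha = 0.05)
  expect_equal(nrow(r9$comparisons), 36)
  p12 <- r9$comparisons$p[r9$comparisons$sample1 == "M-C-JH" &
                          r9$comparisons$sample2 == "M-T-JH"]
  expect_equal(p12, 2 * 0.5^20)
  expect_true(p12 < 0.05 / 36)
  expect_true(r9$comparisons$significant[1])
  # the deviant sample gets its own letter
  expect_false(r9$letters["M-C-JH"] %in% r9$letters[-1])
})

test_that("Bonferroni never declares more pairs than uncorrected McNemar", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(rbinom(93 * 4, 1, runif(4, 0.1, 0.6)), ncol = 4)
    r <- mcnemar_pairwise(m)
    uncorrected <- r$comparisons$p < r$alpha
    expect_true(all(r$comparisons$significant <= uncorrected))
  }
})

test_that("chi-square CA reproduces hand-computed inertia", {
  # independence: a rank-1 table has zero inertia
  rank1 <- outer(c(2, 3, 5), c(1, 4, 2, 3))
  ca0 <- correspondence_analysis(rank1)
  expect_equal(ca0$total_inertia, 0, tolerance = 1e-12)

  # hand computation: [[10, 0], [0, 10]] has chi-square 20, N = 20
  ca2 <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ca2$total_inertia, 1, tolerance = 1e-12)
  expect_equal(ca2$inertia_prop, 100)

  expect_error(correspondence_analysis(rbind(c(1, 2), c(0, 0))),
               "all-zero")
})

test_that("CA decomposition is scale invariant and mass balanced", {
  tab <- load_emoji_frequencies()
  ca <- correspondence_analysis(tab)
  ca_scaled <- correspondence_analysis(unclass(tab) * 0.93)
  expect_equal(ca$inertia_prop, ca_scaled$inertia_prop, tolerance = 1e-10)
  expect_equal(sum(ca$eigenvalues), ca$total_inertia, tolerance = 1e-10)
  # the coordinate clouds are centered at the origin under their masses
  expect_equal(max(abs(colSums(ca$row_coord * ca$row_mass))), 0,
               tolerance = 1e-10)
  expect_equal(max(abs(colSums(ca$col_coord * ca$col_mass))), 0,
               tolerance = 1e-10)
  expect_equal(length(ca$eigenvalues), 8)  # min(21, 9) - 1
})

test_that("CA agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  tab <- load_emoji_frequencies()
  ca <- correspondence_analysis(tab)
  ref <- vegan::cca(unclass(as.matrix(tab)))
  expect_equal(unname(ca$eigenvalues), unname(ref$CA$eig),
               tolerance = 1e-8)
})
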