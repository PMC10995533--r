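test_that("Kruskal-Wallis handles complete ties and matches the
          textbook tie-corrected statistic", {
  same <- list(a = c(2, 2, 2), b = c(2, 2), c = c(2, 2, 2))
  kw <- kruskal_wallis(same)
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)

  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, oracle_kw_H(g), tolerance = 1e-12)
  expect_equal(kw$df, 2)

  set.seed(2)
  for (i in 1:30) {
    k <- sample(2:4, 1)
    sizes <- sample(2:4, k, replace = TRUE)
    g <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
    names(g) <- paste0("g", seq_len(k))
    expect_equal(kruskal_wallis(g)$statistic, oracle_kw_H(g),
                 tolerance = 1e-9)
  }

  expect_error(kruskal_wallis(list(a = 1:3)), "two groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("with two groups H equals the squared standardized
          rank-sum statistic", {
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    na <- length(a); nb <- length(b); N <- na + nb
    r <- rank(c(a, b))
    w <- sum(r[seq_len(na)])
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (w - na * (N + 1) / 2) / sqrt(sigma2)
    expect_equal(kruskal_wallis(list(a = a, b = b))$statistic, z^2,
                 tolerance = 1e-9)
  }
})

test_that("exact rank-sum p-values equal brute-force permutation
          enumeration", {
  ts <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ts$method, "exact")
  expect_equal(ts$p.value, 0.1)  # 2 of the 20 rank splits as extreme

  # identical samples give p = 1; swapping samples changes nothing
  expect_equal(rank_sum_test(c(3, 3, 3), c(3, 3))$p.value, 1)
  a <- c(1, 5, 2); b <- c(4, 4, 9, 0)
  expect_equal(rank_sum_test(a, b)$p.value, rank_sum_test(b, a)$p.value)

  set.seed(4)
  for (i in 1:100) {
    na <- sample(2:5, 1); nb <- sample(2:4, 1)
    a <- sample(0:6, na, replace = TRUE)
    b <- sample(0:6, nb, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p.value, oracle_rank_sum_p(a, b),
                 tolerance = 1e-9)
  }

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank tests are invariant under strictly monotone
          transformations", {
  set.seed(5)
  for (i in 1:10) {
    a <- rpois(5, 4); b <- rpois(6, 6); cc <- rpois(4, 5)
    f <- function(x) exp(x / 2) + 1  # strictly increasing
    expect_equal(rank_sum_test(a, b)$p.value,
                 rank_sum_test(f(a), f(b))$p.value)
    g1 <- list(a = a, b = b, c = cc)
    g2 <- lapply(g1, f)
    expect_equal(kruskal_wallis(g1)$statistic,
                 kruskal_wallis(g2)$statistic)
    pw1 <- conover_iman(g1); pw2 <- conover_iman(g2)
    expect_equal(pw1$p.value, pw2$p.value)
  }
})

test_that("Conover-Iman separates distant groups, not close ones, and
          Bonferroni caps at one", {
  same <- list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  pw <- conover_iman(same)
  expect_true(all(pw$p.adjusted == 1))
  expect_false(any(pw$significant))

  g <- list(low1 = c(1, 1, 2, 1), high = c(10, 11, 12, 11),
            low2 = c(1, 2, 2, 2))
  pw <- conover_iman(g)
  sig <- with(pw, significant[!(group1 == "low1" & group2 == "low2")])
  expect_true(all(sig))
  expect_false(pw$significant[pw$group1 == "low1" & pw$group2 == "low2"])

  # the same pattern under an exact permutation oracle: pairwise
  # two-sided rank-sum p-values, Bonferroni over 3 pairs — separated
  # pairs sit at the enumeration minimum, the close pair near 1
  p_sep1 <- oracle_rank_sum_p(g$low1, g$high) * 3
  p_sep2 <- oracle_rank_sum_p(g$high, g$low2) * 3
  p_close <- oracle_rank_sum_p(g$low1, g$low2) * 3
  expect_equal(p_sep1, 3 * 2 / choose(8, 4))
  expect_equal(p_sep2, 3 * 2 / choose(8, 4))
  expect_true(p_close > 0.9)

  # Bonferroni multiplies by the number of pairs, capped at 1
  set.seed(6)
  g5 <- lapply(1:5, function(i) rnorm(4, i / 2))
  names(g5) <- paste0("g", 1:5)
  raw <- conover_iman(g5, bonferroni = FALSE)
  adj <- conover_iman(g5, bonferroni = TRUE)
  expect_equal(adj$p.adjusted, pmin(1, raw$p.value * 10))
  expect_true(all(adj$p.adjusted >= raw$p.value))
})

test_that("compact letter displays satisfy the share-a-letter
          biconditional", {
  # no significant pair: everyone gets 'a'
  pw <- data.frame(group1 = c("x", "x", "y"), group2 = c("y", "z", "z"),
                   significant = FALSE)
  expect_equal(unname(compact_letter_display(pw)), c("a", "a", "a"))

  # all pairs significant: distinct singletons
  pw$significant <- TRUE
  expect_equal(unname(compact_letter_display(pw)), c("a", "b", "c"))

  # the reference-table pattern: candidate and control separated from
  # everything, three nets mutually indistinguishable
  arms <- c("IG2", "Tsara", "PN2.0", "T-LLIN", "control")
  prs <- t(combn(arms, 2))
  sig <- apply(prs, 1, function(p) any(p %in% c("T-LLIN", "control")))
  pw <- data.frame(group1 = prs[, 1], group2 = prs[, 2], significant = sig)
  cld <- compact_letter_display(pw)
  expect_equal(unname(cld[c("IG2", "Tsara", "PN2.0")]), rep("a", 3))
  expect_equal(unname(cld["T-LLIN"]), "b")
  expect_equal(unname(cld["control"]), "c")
  expect_true(cld_consistent(as.list(cld), pw))

  # conflicting duplicate pairs are rejected
  bad <- rbind(pw, data.frame(group1 = "IG2", group2 = "Tsara",
                              significant = TRUE))
  expect_error(compact_letter_display(bad), "conflicting")
  expect_error(compact_letter_display(pw[-1, ]), "cover all pairs")
})

test_that("letter displays stay consistent over random significance
          patterns", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    groups <- paste0("g", seq_len(k))
    prs <- t(combn(groups, 2))
    pw <- data.frame(group1 = prs[, 1], group2 = prs[, 2],
                     significant = runif(nrow(prs)) < 0.4)
    cld <- compact_letter_display(pw)
    expect_true(cld_consistent(as.list(cld), pw))
    expect_true(all(nchar(cld) > 0))
  }
})

test_that("letter-annotated summary table reports group stats", {
  g <- list(a = c(1, 2, 3, 2), b = c(9, 8, 9, 10), c = c(1, 3, 2, 2))
  tab <- letter_summary(g)
  expect_equal(tab$group, c("a", "b", "c"))
  expect_equal(tab$n, c(4L, 4L, 4L))
  expect_equal(tab$mean, vapply(g, mean, numeric(1)), ignore_attr = TRUE)
  expect_true(cld_consistent(as.list(setNames(tab$letters, tab$group)),
                             conover_iman(g)))
})
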