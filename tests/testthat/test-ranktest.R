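# Rank decomposition, tie handling, the Irwin-Hall standardization, and the
# three null back-ends.

test_that("midranks follow the midrank convention and sum to N(N+1)/2", {
  expect_equal(midranks(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(midranks(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_equal(midranks(c(3, 3, 3, 3)), rep(2.5, 4))
  for (i in 1:20) {
    set.seed(i)
    v <- sample(round(rnorm(30), 1), 30, replace = TRUE)
    expect_equal(sum(midranks(v)), length(v) * (length(v) + 1) / 2)
  }
  expect_error(midranks(c(1, NA)), "finite")
  expect_error(midranks(numeric(0)), "nonempty")
})

test_that("tie factor is zero without ties and matches its closed form", {
  expect_equal(tie_factor(rep(1L, 4), 4), 0)
  expect_equal(tie_factor(c(2L, 1L, 1L), 4), 0.5)
  N <- 6
  expect_equal(tie_factor(N, N), N + 1)  # all tied: variance collapses
  expect_error(tie_factor(c(2L, 1L), 4), "sum to")
})

test_that("tie correction reproduces the permutation variance of W", {
  # brute force: empirical variance of the midrank-sum over all C(N, m)
  # assignments equals m*n*(N+1-TF)/12 for a tied sample
  vals <- c(1, 1, 2, 2, 2, 3, 5, 5)  # d = (2, 3, 1, 2)
  N <- length(vals); m <- 3; n <- N - m
  r <- midranks(vals)
  sums <- combn(r, m, sum)
  tf <- tie_factor(as.integer(table(vals)), N)
  v_pop <- mean(sums^2) - mean(sums)^2
  expect_equal(v_pop, m * n * (N + 1 - tf) / 12, tolerance = 1e-12)
  expect_equal(mean(sums), m * (N + 1) / 2)
})

test_that("rank_summary decomposes the two-group sample", {
  s <- rank_summary(c(9, 10), c(1, 2, 3))
  expect_equal(s[c("m", "n", "N", "W")], list(m = 2, n = 3, N = 5, W = 9))
  expect_equal(s$U, 9 - 3)
  expect_equal(s$tf, 0)
  expect_equal(sum(s$tie_counts), s$N)
  expect_error(rank_summary(numeric(0), 1:3), "nonempty")
})

test_that("uniform standardization matches hand arithmetic and its limits", {
  # m=2, n=3, W=9, no ties
  s <- rank_summary(c(9, 10), c(1, 2, 3))
  st <- uniform_standardize(s)
  expect_equal(st$d, sqrt(18))
  expect_equal(st$c, 6 - sqrt(18))
  expect_equal(st$u_upper, (9 - (6 - sqrt(18)) - 0.5) / sqrt(18))
  expect_equal(st$u_upper, 1.58926, tolerance = 1e-5)

  # extreme configuration m=3, N=10000
  ex <- extreme_config(3, 10000)
  st3 <- uniform_standardize(rank_summary(ex$set, ex$complement))
  expect_equal(st3$u_upper, 2.99965, tolerance = 1e-5)

  # W at its null mean maps to the Irwin-Hall mean m/2 (ignoring continuity)
  m <- 4; n <- 21; N <- m + n
  s_mid <- list(m = m, n = n, N = N, W = m * (N + 1) / 2, tf = 0)
  st_mid <- uniform_standardize(s_mid, tf = 0)
  expect_equal((st_mid$u_lower + st_mid$u_upper) / 2, m / 2)

  # c -> m(m+1)/4 as n grows with m fixed
  s_big <- list(m = 3, n = 1e7, N = 3 + 1e7, W = 10, tf = 0)
  expect_equal(uniform_standardize(s_big, tf = 0)$c, 3, tolerance = 1e-3)

  expect_error(uniform_standardize(rank_summary(c(1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("uniform_p matches the closed-form F_2 on a hand example", {
  s <- rank_summary(c(9, 10), c(1, 2, 3))
  res <- uniform_p(s, alternative = "greater")
  u <- (9 - (6 - sqrt(18)) - 0.5) / sqrt(18)
  expect_equal(res$p, (2 - u)^2 / 2, tolerance = 1e-12)
  expect_equal(res$p, 0.08435, tolerance = 1e-4)
})

test_that("normal back-end matches wilcox.test with continuity correction", {
  s <- rank_summary(c(9, 10), c(1, 2, 3))
  res <- normal_p(s, alternative = "greater")
  expect_equal(res$p, pnorm((9 - 6 - 0.5) / sqrt(3), lower.tail = FALSE))
  expect_equal(res$p, 0.07446, tolerance = 1e-4)
  for (i in 1:10) {
    set.seed(100 + i)
    x <- rnorm(6); y <- rnorm(15)
    ours <- wrs_test(x, y, method = "normal")$p
    ref <- suppressWarnings(
      wilcox.test(x, y, correct = TRUE, exact = FALSE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("two-sided p is twice the smaller one-sided p, clamped at 1", {
  set.seed(3)
  x <- rnorm(5); y <- rnorm(40)
  for (method in c("uniform", "normal", "exact")) {
    r <- wrs_test(x, y, method = method)
    expect_equal(r$p, min(1, 2 * min(r$p_one_sided_less,
                                     r$p_one_sided_greater)))
    expect_true(all(c(r$p, r$p_one_sided_less, r$p_one_sided_greater) >= 0))
    expect_true(all(c(r$p, r$p_one_sided_less, r$p_one_sided_greater) <= 1))
  }
  # a median split is two-sided p = 1 after doubling and clamping
  r <- wrs_test(c(1, 4), c(2, 3), method = "exact")
  expect_equal(r$p, 1)
})

test_that("extreme-case exact p is the reciprocal binomial coefficient", {
  expect_equal(extreme_case_exact_p(1, 2), 0.5)
  expect_equal(extreme_case_exact_p(2, 10), 1 / 45)
  expect_equal(extreme_case_exact_p(3, 10000), 6.00e-12, tolerance = 5e-4)
  expect_equal(extreme_case_exact_p(20, 10000), 2.48e-62, tolerance = 5e-3)
  expect_error(extreme_case_exact_p(5, 5), "m < N")
})

test_that("label swap with mirrored alternative is exact for normal/exact", {
  for (i in 1:5) {
    set.seed(200 + i)
    x <- rnorm(4); y <- rnorm(12)
    for (method in c("normal", "exact")) {
      a <- wrs_test(x, y, method = method, alternative = "greater")
      b <- wrs_test(y, x, method = method, alternative = "less")
      expect_equal(a$p, b$p, tolerance = 1e-12)
    }
    # uniform approximates the small group; swapping changes the order of the
    # approximating sum, so symmetry holds only approximately
    a <- wrs_test(x, y, method = "uniform", alternative = "greater")
    b <- wrs_test(y, x, method = "uniform", alternative = "less")
    expect_equal(a$p, b$p, tolerance = 0.02)
  }
})

test_that("auto method picks uniform below 30 set genes, normal at 30+", {
  set.seed(9)
  y <- rnorm(300)
  expect_equal(wrs_test(rnorm(10), y, method = "auto")$method, "uniform")
  expect_equal(wrs_test(rnorm(30), y, method = "auto")$method, "normal")
})

test_that("tidy and glance return broom-shaped tibbles", {
  r <- wrs_test(c(5, 6, 7), 1:20, method = "uniform",
                alternative = "greater")
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$p.value, r$p)
  gl <- glance(r)
  expect_equal(gl$m, 3)
  expect_equal(gl$N, 23)
  expect_output(print(r), "uniform null approximation")
})
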