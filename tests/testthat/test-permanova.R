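test_that("total SS from distances equals the univariate identity", {
  expect_equal(total_ss(dist(1:6)), 17.5)
  expect_equal(total_ss(dist(rep(3, 5))), 0)
  set.seed(2)
  y <- rnorm(12)
  expect_equal(total_ss(dist(c(y, y))), 2 * total_ss(dist(y)))
  D <- as.matrix(dist(y)); D[1, 2] <- 99
  expect_error(total_ss(D), "symmetric")
})

test_that("the SS partition reproduces classical ANOVA", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  g = factor(rep(c("a", "b"), each = 3)))
  p <- ss_partition(y ~ g, d)
  expect_equal(p$SS[p$term == "g"], 13.5)
  expect_equal(p$SS[p$term == "Residual"], 4)
  # response constant within cells of a two-factor design
  d2 <- expand.grid(A = factor(1:2), B = factor(1:3), rep = 1:2)
  d2$y <- as.numeric(interaction(d2$A, d2$B))
  p2 <- ss_partition(y ~ A * B, d2)
  expect_equal(p2$SS[p2$term == "Residual"], 0, tolerance = 1e-12)
})

test_that("term SS plus residual equals total on random three-factor tables", {
  set.seed(5)
  for (rep in 1:5) {
    d <- expand.grid(A = factor(1:3), B = factor(1:2), C = factor(1:2),
                     rep = 1:3)
    d$y <- rnorm(nrow(d))
    p <- ss_partition(y ~ A * B * C, d)
    expect_equal(sum(p$SS[p$term != "Total"]), p$SS[p$term == "Total"],
                 tolerance = 1e-10)
    # pseudo-F identical to aov on the same data
    fit <- permanova(y ~ A * B * C, d, n_perm = 9)
    a <- anova(stats::aov(y ~ A * B * C, d))
    tab <- fit$aov.tab
    for (trm in rownames(a)[rownames(a) != "Residuals"]) {
      expect_lt(abs(tab$pseudo_F[tab$term == trm] - a[trm, "F value"]) /
                  a[trm, "F value"], 1e-8)
    }
  }
})

test_that("exhaustive enumeration reproduces the exact permutation p", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  g = factor(rep(c("a", "b"), each = 3)))
  fit <- permanova(y ~ g, d, exhaustive = TRUE)
  expect_equal(fit$aov.tab$pseudo_F[1], 13.5)
  expect_equal(fit$aov.tab$p_perm[1], 2 / 20)
  # independent exhaustive oracle over the 20 distinct assignments
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(ix) {
    g <- factor(seq_len(6) %in% ix)
    anova(stats::aov(d$y ~ g))[1, "F value"]
  })
  expect_equal(fit$aov.tab$p_perm[1],
               mean(f_all >= 13.5 - 1e-9))
  # exhaustive agreement on random small samples
  set.seed(9)
  for (rep in 1:3) {
    d2 <- data.frame(y = rnorm(7), g = factor(rep(1:2, c(3, 4))))
    fit2 <- permanova(y ~ g, d2, exhaustive = TRUE)
    f_obs <- anova(stats::aov(y ~ g, d2))[1, "F value"]
    combos2 <- utils::combn(7, 3)
    f_all2 <- apply(combos2, 2, function(ix) {
      g <- factor(seq_len(7) %in% ix)
      anova(stats::aov(d2$y ~ g))[1, "F value"]
    })
    expect_equal(fit2$aov.tab$p_perm[1],
                 mean(f_all2 >= f_obs - 1e-9 * abs(f_obs)))
  }
})

test_that("observed pseudo-F agrees with an independent distance-based fit", {
  skip_if_not_installed("vegan")
  set.seed(13)
  d <- data.frame(y = rnorm(24), g = factor(rep(1:3, each = 8)))
  fit <- permanova(y ~ g, d, n_perm = 99)
  v <- vegan::adonis2(dist(d$y) ~ g, data = d, permutations = 99)
  expect_equal(fit$aov.tab$pseudo_F[1], v$F[1], tolerance = 1e-10)
  expect_equal(fit$aov.tab$SS[1], v$SumOfSqs[1], tolerance = 1e-10)
})

test_that("row order of the input table does not change observed F", {
  set.seed(3)
  d <- expand.grid(A = factor(1:3), B = factor(1:2), rep = 1:4)
  d$y <- rnorm(nrow(d))
  f1 <- permanova(y ~ A * B, d, n_perm = 9)$aov.tab$pseudo_F
  d2 <- d[sample(nrow(d)), ]
  f2 <- permanova(y ~ A * B, d2, n_perm = 9)$aov.tab$pseudo_F
  expect_equal(f1, f2)
})

test_that("mixed-model denominators follow expected mean squares", {
  set.seed(7)
  d <- expand.grid(A = factor(1:3), P = factor(1:2), rep = 1:4)
  d$y <- rnorm(nrow(d)) + as.numeric(d$A) * 0.5
  fit <- permanova(y ~ A * P, d, random = "P", n_perm = 99, seed = 1)
  tab <- fit$aov.tab
  expect_equal(tab$denom[tab$term == "A"], "A:P")
  expect_equal(tab$denom[tab$term == "P"], "Residual")
  expect_equal(tab$denom[tab$term == "A:P"], "Residual")
  a <- anova(stats::aov(y ~ A * P, d))
  expect_equal(tab$pseudo_F[tab$term == "A"],
               a["A", "Mean Sq"] / a["A:P", "Mean Sq"], tolerance = 1e-10)
})

test_that("unique permutation counts are multinomial coefficients", {
  expect_equal(count_unique_permutations(rep(c("a", "b"), each = 3)), 20)
  expect_equal(count_unique_permutations(rep("a", 5)), 1)
  expect_equal(count_unique_permutations(rep(c("a", "b"), c(1, 5))), 6)
})

test_that("Monte-Carlo p is the F reference tail", {
  expect_equal(pmc_value(1, 4, 4), 0.5)     # median of F(k, k) is 1
  oracle <- stats::integrate(function(x) stats::df(x, 1, 4), 13.5, Inf,
                             rel.tol = 1e-12)$value
  expect_lt(abs(pmc_value(13.5, 1, 4) - oracle), 1e-10)
  f <- c(0.5, 1, 2, 4, 8, 16)
  expect_true(all(diff(pmc_value(f, 2, 10)) < 0))
  expect_error(pmc_value(1, 0, 4), "df1")
})

test_that("pooling merges non-significant terms into the residual", {
  set.seed(41)
  d <- expand.grid(A = factor(1:3), B = factor(1:2), rep = 1:5)
  d$y <- rnorm(nrow(d)) + as.numeric(d$A)   # strong A, null B and A:B
  fit <- permanova(y ~ A * B, d, n_perm = 199, seed = 2)
  tab <- fit$aov.tab
  pooled <- pool_terms(fit, threshold = 0.25, seed = 5, keep = "A")
  ptab <- pooled$aov.tab
  removed <- vapply(pooled$pooling_log, `[[`, character(1), "term")
  # every pooled term had p >= 0.25; retained non-kept terms have p < 0.25
  for (lg in pooled$pooling_log) expect_gte(lg$p_perm, 0.25)
  expect_true(all(!removed %in% ptab$term))
  expect_true("A" %in% ptab$term)
  # the pooled terms' df went into the residual
  df_moved <- sum(vapply(pooled$pooling_log, `[[`, numeric(1), "df"))
  expect_equal(ptab$df[ptab$term == "Residual"],
               tab$df[tab$term == "Residual"] + df_moved)
  # SS additivity still holds exactly after pooling
  expect_equal(sum(ptab$SS[ptab$term != "Total"]),
               ptab$SS[ptab$term == "Total"], tolerance = 1e-10)
})

test_that("pairwise tests are two-group permanovas with t = sqrt(F)", {
  d <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                  g = factor(rep(c("a", "b"), each = 3)))
  pw <- pairwise_permanova(y ~ g, d, exhaustive = TRUE)
  expect_equal(pw$t, sqrt(13.5))
  expect_equal(pw$p_perm, 0.1)
  expect_equal(pw$n_unique, 20)
  # identical groups: t = 0, p = 1
  d0 <- data.frame(y = rep(c(1, 2, 3), 2), g = factor(rep(1:2, each = 3)))
  d0$y <- rep(2, 6)
  pw0 <- pairwise_permanova(y ~ g, d0)
  expect_equal(pw0$t, 0)
  expect_equal(pw0$p_perm, 1)
  # for a 2-level factor the only pair equals the omnibus test
  set.seed(6)
  d2 <- data.frame(y = rnorm(10), g = factor(rep(1:2, each = 5)))
  fit <- permanova(y ~ g, d2, n_perm = 199, seed = 8)
  pw2 <- pairwise_permanova(y ~ g, d2, n_perm = 199, seed = 8)
  expect_equal(pw2$p_perm, fit$aov.tab$p_perm[1])
  expect_equal(pw2$t^2, fit$aov.tab$pseudo_F[1])
  expect_error(pairwise_permanova(y ~ g,
                                  data.frame(y = 1:3,
                                             g = factor(c(1, 2, 2)))),
               "2 observations")
})

test_that("permutation p-values are deterministic under a fixed seed", {
  set.seed(10)
  d <- data.frame(y = rnorm(18), g = factor(rep(1:3, each = 6)))
  p1 <- permanova(y ~ g, d, n_perm = 199, seed = 42)$aov.tab$p_perm[1]
  p2 <- permanova(y ~ g, d, n_perm = 199, seed = 42)$aov.tab$p_perm[1]
  expect_identical(p1, p2)
  expect_true(p1 >= 1 / 200 && p1 <= 1)
})

test_that("power rises with effect size", {
  reject_rate <- function(shift, n_rep = 150) {
    set.seed(77)
    mean(replicate(n_rep, {
      d <- data.frame(y = rnorm(18) + rep(c(0, shift, 2 * shift), each = 6),
                      g = factor(rep(1:3, each = 6)))
      permanova(y ~ g, d, n_perm = 99)$aov.tab$p_perm[1] <= 0.05
    }))
  }
  pw <- vapply(c(0, 0.8, 2), reject_rate, numeric(1))
  expect_lt(pw[1], 0.15)
  expect_gt(pw[2], pw[1])
  expect_gt(pw[3], pw[2])
  expect_gt(pw[3], 0.9)
})

test_that("degenerate designs and tests raise typed failures", {
  d <- data.frame(y = rnorm(6), A = factor(c(1, 1, 1, 2, 2, 2)),
                  B = factor(c(1, 1, 1, 2, 2, 2)))   # confounded: empty cells
  expect_error(permanova(y ~ A * B, d, n_perm = 9), "degenerate design")
  d0 <- data.frame(y = rep(1, 6), g = factor(rep(1:2, each = 3)))
  expect_error(permanova(y ~ g, d0, n_perm = 9), "degenerate test")
})
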