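# Permutational ANOVA for univariate Euclidean responses with crossed
# fixed/random factors: distance-based SS partition (Gower-centred),
# expected-mean-squares denominators, Freedman-Lane permutation of
# reduced-model residuals, Monte-Carlo asymptotic p-values, pooling of
# non-significant terms and pairwise follow-ups.

#' Total sum of squares from a distance matrix
#'
#' `SS_total = (1/n) * sum_{i<j} d_ij^2`, the standard distance-based
#' partition total.  For Euclidean distances on a univariate response it
#' equals `sum((y - mean(y))^2)`.
#'
#' @param D Symmetric distance matrix with zero diagonal (a `dist` object
#'   is accepted).
#' @return Total sum of squares (numeric scalar).
#' @export
#' @examples
#' total_ss(dist(1:6))   # 17.5
total_ss <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8 * (1 + max(abs(D)))))
    stop("D must be a symmetric distance matrix")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  sum(D^2) / (2 * nrow(D))
}

# Gower-centred inner-product matrix of a distance matrix.
gower_centre <- function(D) {
  A <- -0.5 * as.matrix(D)^2
  n <- nrow(A)
  rm <- rowMeans(A); gm <- mean(A)
  A - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + gm
}

# Design decomposition shared by ss_partition and permanova: model
# matrix, sequentially orthonormalised term subspaces, dfs.
design_decomp <- function(formula, data) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!is.numeric(y)) stop("response must be numeric")
  tt <- attr(mf, "terms")
  labels <- attr(tt, "term.labels")
  if (length(labels) == 0) stop("model must contain at least one term")
  X <- stats::model.matrix(tt, mf)
  assign <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("degenerate design: empty cells in a fitted term (rank-deficient model matrix)")
  Q <- qr.Q(qrX)
  n <- length(y)
  df <- vapply(seq_along(labels), function(t) sum(assign == t), integer(1))
  df_res <- n - 1L - sum(df)
  if (df_res < 1L)
    stop("no residual degrees of freedom: need >= 2 observations per cell")
  list(y = y, X = X, Q = Q, assign = assign, labels = labels,
       order = attr(tt, "order"), df = df, df_res = df_res, n = n)
}

#' Distance-based sum-of-squares partition
#'
#' Partitions the total SS of the Euclidean distance matrix of the
#' response over the model terms by projecting the Gower-centred matrix
#' onto sequentially orthogonalised term subspaces; term df is the
#' product of (levels - 1) over the term's factors, and SS over all terms
#' plus the residual reproduces the total exactly.
#'
#' @param formula Model formula, e.g. `distance_m ~ timing * level`.
#' @param data Data frame of measurements.
#' @return Data frame with one row per term plus `Residual` and `Total`:
#'   columns `term`, `df`, `SS`.
#' @export
ss_partition <- function(formula, data) {
  d <- design_decomp(formula, data)
  G <- gower_centre(stats::dist(d$y))
  ss <- term_ss_from_G(d, G)
  data.frame(
    term = c(d$labels, "Residual", "Total"),
    df = c(d$df, d$df_res, d$n - 1L),
    SS = c(ss$terms, ss$resid, ss$total),
    stringsAsFactors = FALSE)
}

term_ss_from_G <- function(d, G) {
  M <- crossprod(d$Q, G %*% d$Q)
  diagM <- diag(M)
  ss_t <- vapply(seq_along(d$labels),
                 function(t) sum(diagM[d$assign == t]), numeric(1))
  total <- sum(diag(G))
  list(terms = ss_t, resid = total - sum(ss_t), total = total)
}

# Expected-mean-squares denominator for each term: a term containing a
# random factor is tested over the residual; a purely fixed term crossed
# with a random factor is tested over its interaction with that factor
# when present in the model, else over the residual.
denominators <- function(labels, random) {
  fsets <- lapply(strsplit(labels, ":", fixed = TRUE), sort)
  if (length(random) > 1)
    stop("at most one random factor is supported")
  vapply(seq_along(labels), function(i) {
    fs <- fsets[[i]]
    if (length(random) == 0 || any(fs %in% random)) return("Residual")
    want <- sort(c(fs, random))
    hit <- which(vapply(fsets, identical, logical(1), want))
    if (length(hit)) labels[hit[1]] else "Residual"
  }, character(1))
}

# All permutations of 1..n as an n! x n integer matrix.
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  if (n > 9) stop("exhaustive enumeration supported for n <= 9")
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix((seq_len(n))[-i][sub], nrow(sub)))))
}

#' Number of unique permutation assignments for a grouping
#'
#' The number of distinct values the permuted test statistic's underlying
#' assignment can take when all observations are exchangeable: the
#' multinomial coefficient `n! / prod(n_g!)` over the group sizes of the
#' tested term's cells.
#'
#' @param groups Factor (or interaction of factors) defining the tested
#'   term's cells; alternatively a list of factors, which is collapsed
#'   with [interaction()].
#' @return Numeric count (may exceed integer range).
#' @export
#' @examples
#' count_unique_permutations(rep(c("a", "b"), each = 3))  # choose(6,3) = 20
count_unique_permutations <- function(groups) {
  if (is.list(groups)) groups <- interaction(groups, drop = TRUE)
  groups <- as.factor(groups)
  sizes <- table(groups)
  round(exp(lfactorial(sum(sizes)) - sum(lfactorial(sizes))))
}

#' Monte-Carlo asymptotic p-value
#'
#' Upper-tail probability of the F(df1, df2) reference distribution at
#' the observed pseudo-F; used instead of the permutation p-value when
#' too few unique permutations exist (conventionally < 100).  For the
#' Euclidean distance on a univariate Gaussian response used here this
#' reference distribution is asymptotically exact.
#'
#' @param f_observed Observed pseudo-F.
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Tail probability in (0, 1).
#' @export
pmc_value <- function(f_observed, df1, df2) {
  if (df1 < 1 || df2 < 1) stop("df1 and df2 must be >= 1")
  stats::pf(f_observed, df1, df2, lower.tail = FALSE)
}

#' Permutational ANOVA with Freedman-Lane residual permutation
#'
#' Fits a crossed fixed/random-factor model to a univariate response via
#' the Euclidean distance-based SS partition and tests each term's
#' pseudo-F against a null distribution built by unrestricted permutation
#' of the residuals of the reduced model (the model without the tested
#' term): permuted responses are `fitted_reduced + permuted residuals`
#' (Freedman-Lane), and `p_perm = (#{F* >= F_obs} + 1) / (n_perm + 1)`.
#'
#' Denominators follow expected-mean-squares rules for crossed mixed
#' models: a fixed term crossed with the random factor is tested over
#' that interaction's mean square, every other term over the residual.
#' The Monte-Carlo asymptotic p-value (see [pmc_value()]) and the count
#' of unique permutation assignments are always reported, so small
#' designs can be judged on `p_MC` when fewer than ~100 unique
#' permutations exist.
#'
#' @param formula Model formula, e.g.
#'   `distance_m ~ timing * level * pen`.
#' @param data Data frame.
#' @param random Name of the random factor (at most one), e.g. `"pen"`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation draws.
#' @param exhaustive Use all `n!` permutations instead of sampling
#'   (requires `n <= 9`); the p-value is then the exact enumeration
#'   fraction.
#' @return A `permanova` object whose `aov.tab` holds per term: `df`,
#'   `SS`, `MS`, `denom`, `pseudo_F`, `p_perm`, `p_MC`, `n_unique`, plus
#'   `Residual` and `Total` rows.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' permanova(y ~ g, d, exhaustive = TRUE)$aov.tab
permanova <- function(formula, data, random = character(), n_perm = 9999,
                      seed = NULL, exhaustive = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- design_decomp(formula, data)
  G <- gower_centre(stats::dist(d$y))
  obs <- term_ss_from_G(d, G)
  ms <- obs$terms / d$df
  ms_res <- obs$resid / d$df_res
  denom <- denominators(d$labels, random)
  denom_ms <- ifelse(denom == "Residual", ms_res,
                     ms[match(denom, d$labels)])
  denom_df <- ifelse(denom == "Residual", d$df_res,
                     d$df[match(denom, d$labels)])
  if (any(denom_ms <= 0))
    stop("degenerate test: a denominator mean square is zero")
  f_obs <- ms / denom_ms

  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    pm <- t(all_perms(d$n))
    B <- ncol(pm)
  } else {
    B <- n_perm
    pm <- vapply(seq_len(B), function(b) sample.int(d$n), integer(d$n))
  }
  ybar <- mean(d$y)
  p_perm <- numeric(length(d$labels))
  fsets <- lapply(strsplit(d$labels, ":", fixed = TRUE), sort)
  for (t in seq_along(d$labels)) {
    # reduced model: drop the tested term and every term containing it
    # (those include the tested factors, so they would absorb the effect)
    drop_terms <- which(vapply(fsets, function(s)
      all(fsets[[t]] %in% s), logical(1)))
    keep <- !(d$assign %in% drop_terms)
    qr_red <- qr(d$X[, keep, drop = FALSE])
    fitted <- qr.fitted(qr_red, d$y)
    res <- qr.resid(qr_red, d$y)
    Ystar <- fitted + matrix(res[pm], d$n, B)
    QtY <- crossprod(d$Q, Ystar)
    ss_star <- matrix(0, length(d$labels), B)
    for (s in seq_along(d$labels))
      ss_star[s, ] <- colSums(QtY[d$assign == s, , drop = FALSE]^2)
    ss_tot_star <- colSums(Ystar^2) - d$n * ybar^2
    ss_res_star <- ss_tot_star - colSums(ss_star)
    ms_den_star <- if (denom[t] == "Residual") ss_res_star / d$df_res
                   else ss_star[match(denom[t], d$labels), ] / denom_df[t]
    f_star <- (ss_star[t, ] / d$df[t]) / ms_den_star
    tol <- 1e-12 * max(1, abs(f_obs[t]))
    hits <- sum(f_star >= f_obs[t] - tol)
    p_perm[t] <- if (exhaustive) hits / B else (hits + 1) / (B + 1)
  }
  p_mc <- stats::pf(f_obs, d$df, denom_df, lower.tail = FALSE)
  mf <- stats::model.frame(formula, data)
  n_unique <- vapply(d$labels, function(l) {
    fs <- strsplit(l, ":", fixed = TRUE)[[1]]
    count_unique_permutations(mf[fs])
  }, numeric(1))

  tab <- data.frame(
    term = c(d$labels, "Residual", "Total"),
    df = c(d$df, d$df_res, d$n - 1L),
    SS = c(obs$terms, obs$resid, obs$total),
    MS = c(ms, ms_res, NA),
    denom = c(denom, NA, NA),
    pseudo_F = c(f_obs, NA, NA),
    p_perm = c(p_perm, NA, NA),
    p_MC = c(p_mc, NA, NA),
    n_unique = c(n_unique, NA, NA),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(aov.tab = tab, formula = formula, data = data,
                 random = random, n_perm = n_perm, seed = seed,
                 exhaustive = exhaustive, pooling_log = list()),
            class = "permanova")
}

#' @export
print.permanova <- function(x, digits = 4, ...) {
  cat("Permutational ANOVA (Euclidean distance, Freedman-Lane residual permutation)\n")
  cat(sprintf("Permutations: %s%s\n",
              if (x$exhaustive) "exhaustive" else format(x$n_perm),
              if (length(x$random)) paste0("; random factor: ",
                                           paste(x$random, collapse = ", "))
              else ""))
  if (length(x$pooling_log)) {
    cat("Pooled terms:",
        paste(vapply(x$pooling_log, `[[`, character(1), "term"),
              collapse = ", "), "\n")
  }
  tab <- x$aov.tab
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pool non-significant terms into the residual
#'
#' Iteratively removes terms whose permutation p-value is at or above
#' `threshold` (default 25%), merging their SS and df into the residual
#' and re-testing the remaining terms, to increase power.  Pooling starts
#' from the highest-order terms and respects marginality: a term is only
#' pooled while no retained higher-order term contains it.
#'
#' @param result A [permanova()] result.
#' @param threshold Pooling significance threshold (default 0.25).
#' @param n_perm,seed Permutations and seed for each refit; default to
#'   the original fit's settings.
#' @param keep Character vector of term labels that are never pooled
#'   (e.g. the effect of primary interest); defaults to none.
#' @return A `permanova` object for the pooled model; `pooling_log`
#'   records each removed term with its p-value, df and SS.
#' @export
pool_terms <- function(result, threshold = 0.25, n_perm = result$n_perm,
                       seed = result$seed, keep = character()) {
  stopifnot(inherits(result, "permanova"))
  res <- result
  log <- list()
  repeat {
    tab <- res$aov.tab
    trm <- tab[!(tab$term %in% c("Residual", "Total")), ]
    fsets <- lapply(strsplit(trm$term, ":", fixed = TRUE), sort)
    ord <- lengths(fsets)
    contained <- vapply(seq_len(nrow(trm)), function(i)
      any(vapply(seq_len(nrow(trm)), function(j)
        j != i && all(fsets[[i]] %in% fsets[[j]]), logical(1))),
      logical(1))
    cand <- which(trm$p_perm >= threshold & !contained &
                  !(trm$term %in% keep))
    if (length(cand) == 0) break
    pick <- cand[order(-ord[cand], -trm$p_perm[cand])][1]
    log[[length(log) + 1L]] <- list(term = trm$term[pick],
                                    p_perm = trm$p_perm[pick],
                                    df = trm$df[pick], SS = trm$SS[pick])
    remaining <- trm$term[-pick]
    if (length(remaining) == 0)
      stop("degenerate design: pooling would empty the model")
    f <- stats::reformulate(remaining,
                            response = all.vars(res$formula)[1])
    if (!is.null(seed)) seed <- seed + 1L
    res <- permanova(f, result$data, random = result$random,
                     n_perm = n_perm, seed = seed,
                     exhaustive = result$exhaustive)
  }
  res$pooling_log <- log
  res
}

#' Pairwise permutational comparisons for one factor
#'
#' Runs a two-group permutational test for every level pair of `factor`
#' (optionally within a stratum subset), reporting `t = sqrt(pseudo_F)`,
#' the permutation p-value, the Monte-Carlo asymptotic p-value and the
#' count of unique permutation assignments.
#'
#' @param formula Two-sided formula `response ~ factor` with a single
#'   grouping factor.
#' @param data Data frame (pre-subset to the stratum of interest, e.g.
#'   one treatment level).
#' @param n_perm,seed,exhaustive As in [permanova()].
#' @return Data frame with one row per level pair: `level1`, `level2`,
#'   `t`, `p_perm`, `p_MC`, `n_unique`.
#' @export
pairwise_permanova <- function(formula, data, n_perm = 9999, seed = NULL,
                               exhaustive = FALSE) {
  vars <- all.vars(formula)
  if (length(vars) != 2) stop("formula must be response ~ factor")
  fac <- as.factor(data[[vars[2]]])
  levs <- levels(droplevels(fac))
  if (length(levs) < 2) stop("factor must have >= 2 levels")
  if (any(table(droplevels(fac)) < 2))
    stop("degenerate test: every level needs >= 2 observations")
  pairs <- utils::combn(levs, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    sub <- data[fac %in% pairs[, i], , drop = FALSE]
    sub[[vars[2]]] <- droplevels(as.factor(sub[[vars[2]]]))
    if (stats::var(sub[[vars[1]]]) == 0) {
      # identical groups: no variation to test against
      return(data.frame(level1 = pairs[1, i], level2 = pairs[2, i],
                        t = 0, p_perm = 1, p_MC = 1,
                        n_unique = count_unique_permutations(sub[[vars[2]]]),
                        stringsAsFactors = FALSE))
    }
    fit <- permanova(formula, sub, n_perm = n_perm, seed = seed,
                     exhaustive = exhaustive)
    row <- fit$aov.tab[1, ]
    data.frame(level1 = pairs[1, i], level2 = pairs[2, i],
               t = sqrt(row$pseudo_F), p_perm = row$p_perm,
               p_MC = row$p_MC, n_unique = row$n_unique,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
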