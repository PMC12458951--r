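#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend in location across k >= 3 ordered groups.
#' The statistic is the sum over ordered group pairs (i < j) of the
#' between-group Mann-Whitney counts `#\{x in G_i, y in G_j : x < y\}`
#' (ties counted 1/2). The p-value uses the normal approximation with the
#' tie-corrected null variance, or a Monte-Carlo permutation null.
#'
#' @param groups_ordered list of numeric vectors in hypothesized
#'   increasing order
#' @param alternative `"two.sided"`, `"increasing"` or `"decreasing"`
#' @param method `"normal"` (tie-corrected approximation) or
#'   `"permutation"`
#' @param n_perm permutation count when `method = "permutation"`
#' @param seed optional seed for the permutation draw
#' @return A `group_comparison` record: test, statistic, p_value, group
#'   labels, n per group, alternative.
#' @export
jonckheere_terpstra <- function(groups_ordered,
                                alternative = c("two.sided", "increasing",
                                                "decreasing"),
                                method = c("normal", "permutation"),
                                n_perm = 5000, seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  k <- length(groups_ordered)
  if (k < 3) stop("Jonckheere-Terpstra needs at least 3 ordered groups")
  if (any(!vapply(groups_ordered, is.numeric, logical(1))))
    stop("groups must be numeric")
  jt_stat <- function(gs) {
    s <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      xi <- gs[[i]]; yj <- gs[[j]]
      cmp <- outer(xi, yj, "<")
      tie <- outer(xi, yj, "==")
      s <- s + sum(cmp) + 0.5 * sum(tie)
    }
    s
  }
  J <- jt_stat(groups_ordered)
  ni <- lengths(groups_ordered)
  N <- sum(ni)
  if (method == "normal") {
    mu <- (N^2 - sum(ni^2)) / 4
    # tie-corrected variance (Hollander & Wolfe)
    tj <- table(unlist(groups_ordered))
    v1 <- N * (N - 1) * (2 * N + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
    v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
    sig2 <- v1 / 72 + v2 / (36 * N * (N - 1) * (N - 2)) +
      v3 / (8 * N * (N - 1))
    z <- if (sig2 > 0) (J - mu) / sqrt(sig2) else 0
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                increasing = stats::pnorm(z, lower.tail = FALSE),
                decreasing = stats::pnorm(z))
    p <- min(1, p)
    stat_extra <- c(z = z)
  } else {
    pooled <- unlist(groups_ordered)
    idx <- rep(seq_len(k), ni)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        sh <- sample(pooled)
        jt_stat(split(sh, idx))
      }, numeric(1))
    })
    p <- switch(alternative,
                two.sided = mean(abs(perm - mean(perm)) >= abs(J - mean(perm))),
                increasing = (sum(perm >= J) + 1) / (n_perm + 1),
                decreasing = (sum(perm <= J) + 1) / (n_perm + 1))
    stat_extra <- NULL
  }
  group_comparison("jonckheere_terpstra", statistic = J, p_value = p,
                   groups = names(groups_ordered) %||%
                     paste0("G", seq_len(k)),
                   n = ni, alternative = alternative, extra = stat_extra)
}

#' Jensen-Shannon divergence
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`,
#' `0 log 0 = 0`. Inputs are normalized to probability vectors. With the
#' default base 2 the divergence lies in [0, 1] bits.
#'
#' @param p,q nonnegative vectors of equal length, not all zero
#' @param base logarithm base (default 2)
#' @export
jensen_shannon <- function(p, q, base = 2) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0) stop("JSD undefined for an all-zero vector")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz], base = base))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Two-group comparison dispatcher
#'
#' Standard two-sample tests behind one record-shaped interface, each
#' delegated to the established routine: `mann_whitney`
#' ([stats::wilcox.test()]), `levene` (squared-deviation-from-group-mean
#' one-way ANOVA), `paired_t` ([stats::t.test()]), `two_prop_z`
#' (pooled-variance z), `linear_f` (overall F of [stats::lm()] with
#' intercept).
#'
#' @param x,y the two samples. For `two_prop_z`, `x` and `y` are
#'   `c(successes, trials)` pairs; for `linear_f`, `x` is the predictor
#'   and `y` the response.
#' @param test test name
#' @param alternative sidedness, where the test supports it (explicit,
#'   never inferred)
#' @return A `group_comparison` record.
#' @export
group_compare <- function(x, y, test = c("mann_whitney", "levene", "paired_t",
                                         "two_prop_z", "linear_f"),
                          alternative = "two.sided") {
  test <- match.arg(test)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  if (test == "mann_whitney") {
    ht <- stats::wilcox.test(x, y, alternative = alternative, exact = NULL)
    rec <- group_comparison("mann_whitney", statistic = unname(ht$statistic),
                            p_value = ht$p.value, groups = c("x", "y"),
                            n = c(length(x), length(y)),
                            alternative = alternative)
  } else if (test == "levene") {
    # classic Levene: one-way ANOVA on |value - group mean|
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    v <- c(x, y)
    dev <- abs(v - stats::ave(v, g))
    ft <- stats::anova(stats::lm(dev ~ g))
    rec <- group_comparison("levene", statistic = ft$`F value`[1],
                            p_value = ft$`Pr(>F)`[1], groups = c("x", "y"),
                            n = c(length(x), length(y)),
                            alternative = "two.sided")
  } else if (test == "paired_t") {
    if (length(x) != length(y)) stop("paired test needs equal lengths")
    if (all(x == y)) {
      rec <- group_comparison("paired_t", statistic = 0, p_value = 1,
                              groups = c("x", "y"),
                              n = c(length(x), length(y)),
                              alternative = alternative)
    } else {
      ht <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
      rec <- group_comparison("paired_t", statistic = unname(ht$statistic),
                              p_value = ht$p.value, groups = c("x", "y"),
                              n = c(length(x), length(y)),
                              alternative = alternative)
    }
  } else if (test == "two_prop_z") {
    stopifnot(length(x) == 2, length(y) == 2)
    p1 <- x[1] / x[2]; p2 <- y[1] / y[2]
    pp <- (x[1] + y[1]) / (x[2] + y[2])
    se <- sqrt(pp * (1 - pp) * (1 / x[2] + 1 / y[2]))
    z <- (p1 - p2) / se
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    rec <- group_comparison("two_prop_z", statistic = z, p_value = p,
                            groups = c("x", "y"), n = c(x[2], y[2]),
                            alternative = alternative)
  } else {
    if (length(x) != length(y)) stop("regression needs equal-length x and y")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    rec <- group_comparison("linear_f", statistic = unname(fstat[1]),
                            p_value = unname(p), groups = c("x", "y"),
                            n = c(length(x), length(y)),
                            alternative = "two.sided",
                            extra = c(r_squared = sm$r.squared))
  }
  rec
}

group_comparison <- function(test, statistic, p_value, groups, n,
                             alternative, extra = NULL) {
  stopifnot(p_value >= 0, p_value <= 1, all(n >= 1))
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 groups = groups, n = n, alternative = alternative,
                 extra = extra),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %s)\n", x$test,
              x$statistic, x$p_value, x$alternative,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' @rdname group_compare
#' @param comparisons list of `group_comparison` records
#' @param analysis_id label column
#' @export
comparisons_to_df <- function(comparisons, analysis_id = NA_character_) {
  do.call(rbind, lapply(comparisons, function(cc) {
    data.frame(analysis_id = analysis_id, test = cc$test,
               statistic = cc$statistic, p = cc$p_value,
               groups = paste(cc$groups, collapse = "|"),
               n = paste(cc$n, collapse = "|"),
               alternative = cc$alternative)
  }))
}

#' Benjamini-Hochberg adjustment (provided, not applied by default)
#'
#' Analyses report raw p-values; this utility wraps
#' [stats::p.adjust()] for users who want FDR control across a family.
#' @param p numeric p-values
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
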