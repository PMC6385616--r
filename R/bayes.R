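# Default-prior Bayes factors: Jeffreys-Zellner-Siow t tests and nested
# regressions (Zellner-Siow mixture of g), and Dirichlet-multinomial
# contingency tests.

new_bayes_result <- function(bf10, method, prior_scale, n, inputs = NULL) {
  structure(list(bf10 = bf10, method = method, prior_scale = prior_scale,
                 n = n, inputs = inputs), class = "bayes_bf")
}

#' @export
print.bayes_bf <- function(x, ...) {
  cat(sprintf("Bayes factor (H1/H0) = %.4g  [%s%s]\n", x$bf10, x$method,
              if (!is.null(x$prior_scale) && !is.na(x$prior_scale))
                sprintf(", r = %.3g", x$prior_scale) else ""))
  invisible(x)
}

# JZS marginal-likelihood ratio for a t statistic: integrate over g with
# delta | g ~ N(0, g), g ~ InverseGamma(1/2, r^2/2) (i.e. delta ~ Cauchy(0, r)).
jzs_bf_from_t <- function(t, neff, df, r_scale) {
  log_lik_ratio <- function(g) {
    -0.5 * log1p(neff * g) -
      (df + 1) / 2 * (log1p(t ^ 2 / ((1 + neff * g) * df)) -
                        log1p(t ^ 2 / df))
  }
  integrand <- function(g)
    exp(log_lik_ratio(g) + log(r_scale) - 0.5 * log(2 * pi) -
          1.5 * log(g) - r_scale ^ 2 / (2 * g))
  res <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          stop.on.error = FALSE)
  if (res$message != "OK" && res$value <= 0)
    stop("JZS integration failed: ", res$message)
  res$value
}

#' Jeffreys-Zellner-Siow Bayes-factor t test
#'
#' Default-prior Bayes factor for a difference of means: a Cauchy prior with
#' scale `r_scale` on the standardized effect size, evaluated by numerical
#' integration over the mixture parameter. Accepts either raw data or a
#' `(t, n)` summary; `bf10 > 1` favours a nonzero effect.
#'
#' @param x,y Numeric vectors (two groups for `"independent"`, matched
#'   samples for `"paired"`; `y` omitted for a one-sample test of `x`
#'   against 0). Alternatively supply `t` and `n1` (and `n2`).
#' @param t,n1,n2 Summary-statistic input: the t statistic and group sizes
#'   (`n2` only for the independent design).
#' @param design `"independent"` or `"paired"`.
#' @param r_scale Cauchy prior scale (default `sqrt(2) / 2`).
#' @return A `bayes_bf` with `bf10`.
#' @export
jzs_ttest_bf <- function(x = NULL, y = NULL, t = NULL, n1 = NULL, n2 = NULL,
                         design = c("independent", "paired"),
                         r_scale = sqrt(2) / 2) {
  design <- match.arg(design)
  if (r_scale <= 0) stop("r_scale must be > 0")
  if (is.null(t)) {
    if (design == "independent") {
      if (is.null(y)) stop("independent design needs both x and y")
      n1 <- length(x); n2 <- length(y)
      df <- n1 + n2 - 2
      sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
      t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    } else {
      d <- if (is.null(y)) x else x - y
      n1 <- length(d)
      t <- mean(d) / (stats::sd(d) / sqrt(n1))
    }
  }
  if (!is.finite(t)) stop("non-finite t statistic")
  if (design == "independent") {
    if (is.null(n2)) stop("independent summary input needs n1 and n2")
    if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
    neff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  } else {
    if (n1 < 2) stop("need n >= 2")
    neff <- n1
    df <- n1 - 1
  }
  bf <- jzs_bf_from_t(t, neff, df, r_scale)
  new_bayes_result(bf, "jzs-t", r_scale, c(n1 = n1, n2 = if (is.null(n2)) NA else n2),
                   list(t = t, df = df, design = design))
}

#' Pooled t statistic from group summaries
#'
#' Convenience for published tables that print means, SDs, and group sizes.
#'
#' @param m1,s1,n1 Mean, SD, and size of group 1.
#' @param m2,s2,n2 Mean, SD, and size of group 2.
#' @return The pooled-variance two-sample t statistic.
#' @export
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp2 <- ((n1 - 1) * s1 ^ 2 + (n2 - 1) * s2 ^ 2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Dirichlet-multinomial Bayes factor for unequal category probabilities
#'
#' Compares H1, each group has its own category-probability vector, against
#' H0, a shared vector, under symmetric Dirichlet priors. The marginal
#' likelihoods are closed-form Dirichlet-multinomial integrals, so
#' `bf10 = B(a + counts_a) B(a + counts_b) / (B(a) B(a + counts_a + counts_b))`
#' with `B` the multivariate beta function.
#'
#' @param counts_a,counts_b Non-negative integer count vectors over the same
#'   categories.
#' @param concentration Symmetric Dirichlet concentration (default 1).
#' @return A `bayes_bf` with `bf10 > 1` favouring unequal distributions.
#' @export
multinomial_bf <- function(counts_a, counts_b, concentration = 1) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 1)
    stop("need count vectors over the same categories")
  if (any(counts_a < 0) || any(counts_b < 0) ||
      any(counts_a != round(counts_a)) || any(counts_b != round(counts_b)))
    stop("counts must be non-negative integers")
  if (sum(counts_a) + sum(counts_b) == 0) stop("all-zero table")
  al <- rep(concentration, length(counts_a))
  lmbeta <- function(v) sum(lgamma(v)) - lgamma(sum(v))
  lbf <- lmbeta(al + counts_a) + lmbeta(al + counts_b) -
    lmbeta(al) - lmbeta(al + counts_a + counts_b)
  new_bayes_result(exp(lbf), "multinomial", concentration,
                   c(n1 = sum(counts_a), n2 = sum(counts_b)),
                   list(counts_a = counts_a, counts_b = counts_b))
}

# drop columns of X that are linearly redundant given the columns kept so far
drop_aliased <- function(X) {
  qrX <- qr(X)
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

#' Zellner-Siow Bayes factor for nested linear models
#'
#' Evidence for adding predictor columns `X1` to a linear model that already
#' contains nuisance columns `X0` (flat prior on the nuisance coefficients
#' and the error scale; Zellner g-prior on the orthogonalized extra
#' coefficients with a scaled inverse-gamma mixture on g, i.e. a
#' Cauchy prior of scale `r_scale` in unit-information units). Computed by
#' one-dimensional numerical integration of
#' `(1 + g)^((n - p0 - p1) / 2) / (1 + g (1 - R2))^((n - p0) / 2)` against
#' the g prior, with `R2` the proportional SSE reduction.
#'
#' @param y Response vector.
#' @param X0 Nuisance design matrix (include the intercept); redundant
#'   columns are dropped.
#' @param X1 Matrix of extra columns under test.
#' @param r_scale Prior scale (default 1, the unit-information convention).
#' @param method `"zs"` (numerical integration) or `"bic"` (the
#'   Schwarz approximation `exp((BIC0 - BIC1) / 2)`, as a cross-check mode).
#' @return A `bayes_bf`; `bf10 > 1` favours the model with `X1`.
#' @export
zs_regression_bf <- function(y, X0, X1, r_scale = 1,
                             method = c("zs", "bic")) {
  method <- match.arg(method)
  n <- length(y)
  X0 <- drop_aliased(as.matrix(X0))
  X1 <- as.matrix(X1)
  p0 <- ncol(X0)
  fit0x <- qr(X0)
  qr1 <- qr(cbind(X0, X1))
  if (qr1$rank < p0 + ncol(X1)) {
    bad <- setdiff(seq_len(p0 + ncol(X1)), qr1$pivot[seq_len(qr1$rank)])
    stop("rank-deficient design; collinear tested column(s): ",
         paste(colnames(cbind(X0, X1))[bad], collapse = ", "))
  }
  p1 <- ncol(X1)
  sse0 <- sum(qr.resid(fit0x, y) ^ 2)
  sse1 <- sum(qr.resid(qr1, y) ^ 2)
  if (sse0 <= 0) stop("degenerate response: nuisance model fits exactly")
  r2 <- 1 - sse1 / sse0
  if (method == "bic") {
    bic0 <- n * log(sse0 / n) + p0 * log(n)
    bic1 <- n * log(sse1 / n) + (p0 + p1) * log(n)
    return(new_bayes_result(exp((bic0 - bic1) / 2), "bic-approx", NA,
                            c(n = n), list(r2 = r2, p0 = p0, p1 = p1)))
  }
  s <- r_scale ^ 2 * n / 2                     # inverse-gamma scale of g
  log_lik_ratio <- function(g)
    (n - p0 - p1) / 2 * log1p(g) - (n - p0) / 2 * log1p(g * (1 - r2))
  integrand <- function(g)
    exp(log_lik_ratio(g) + 0.5 * log(s) - lgamma(0.5) - 1.5 * log(g) - s / g)
  res <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          stop.on.error = FALSE)
  if (res$message != "OK" && res$value <= 0)
    stop("Zellner-Siow integration failed: ", res$message)
  new_bayes_result(res$value, "jzs-regression", r_scale, c(n = n),
                   list(r2 = r2, p0 = p0, p1 = p1))
}

#' Does baseline power explain the rebound response?
#'
#' Compares regression models for the per-subject-per-session mean response
#' change within a cluster: H0 contains session, group, and per-subject
#' intercepts; H1 adds baseline band power; H2 additionally adds the
#' interactions of baseline power with session and group. Returns
#' `BF(H1/H0)` and `BF(H2/H0)`.
#'
#' @param data Data frame with columns `rebound` (response), `baseline`
#'   (baseline power), `session`, `group`, `subject`.
#' @param r_scale Prior scale passed to [zs_regression_bf()].
#' @param method `"zs"` or `"bic"`.
#' @return List with `bf_h1_h0` and `bf_h2_h0` (`bayes_bf` objects).
#' @export
regression_model_bf <- function(data, r_scale = 1, method = "zs") {
  need <- c("rebound", "baseline", "session", "group", "subject")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  X0 <- stats::model.matrix(~ factor(session) + factor(group) + factor(subject),
                            data)
  bl <- as.numeric(scale(data$baseline))
  X1 <- cbind(baseline = bl)
  ses <- as.numeric(factor(data$session)) - mean(as.numeric(factor(data$session)))
  grp <- as.numeric(factor(data$group)) - mean(as.numeric(factor(data$group)))
  X2 <- cbind(baseline = bl, `baseline:session` = bl * ses,
              `baseline:group` = bl * grp)
  list(bf_h1_h0 = zs_regression_bf(data$rebound, X0, X1, r_scale, method),
       bf_h2_h0 = zs_regression_bf(data$rebound, X0, X2, r_scale, method))
}

#' Bayesian ANOVA-style Bayes factors for kept-trial counts
#'
#' Tests whether the number of usable trials differs by session, group, or
#' their interaction: each effect's Bayes factor compares the model with
#' that term against the model without it (session tested against
#' per-subject intercepts; group against the grand mean; the interaction
#' against both main effects), using [zs_regression_bf()].
#'
#' @param counts Data frame with columns `count`, `subject`, `group`,
#'   `session`.
#' @param r_scale Prior scale (default 1).
#' @return List of `bayes_bf`: `bf_session`, `bf_group`, `bf_interaction`.
#' @export
count_anova_bf <- function(counts, r_scale = 1) {
  need <- c("count", "subject", "group", "session")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  y <- counts$count
  ses <- stats::model.matrix(~ factor(session), counts)[, -1, drop = FALSE]
  grp <- stats::model.matrix(~ factor(group), counts)[, -1, drop = FALSE]
  subj <- stats::model.matrix(~ factor(subject), counts)
  if (ncol(ses) != 1 || ncol(grp) != 1)
    stop("count_anova_bf supports two sessions and two groups")
  inter <- ses * as.vector(grp)
  list(bf_session = zs_regression_bf(y, subj, ses, r_scale),
       bf_group = zs_regression_bf(y, matrix(1, length(y), 1), grp, r_scale),
       bf_interaction = zs_regression_bf(y, cbind(1, ses, grp), inter, r_scale))
}
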