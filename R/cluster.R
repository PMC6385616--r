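# Cluster-based permutation inference on time-frequency grids and 1-D time
# courses: point-wise t-maps, supra-threshold clustering under
# 4-connectivity, and Monte-Carlo / exhaustive max-mass null distributions.

as_grid_array <- function(x) {
  # accept subjects x times matrices (1-D) or subjects x freqs x times arrays
  if (length(dim(x)) == 2) x <- array(x, dim = c(nrow(x), 1L, ncol(x)))
  if (length(dim(x)) != 3) stop("expected a subjects x freqs x times array or a subjects x times matrix")
  x
}

#' Point-wise t-map between two sets of subject grids
#'
#' Computes a per-bin t statistic: the pooled-variance two-sample t for an
#' independent design (`df = n1 + n2 - 2`), or the one-sample t on
#' within-subject differences for a paired design (`df = n - 1`). Bins with
#' zero variance, or missing in any subject, are set to `NA` and excluded
#' from clustering.
#'
#' @param a,b Arrays `subjects x freqs x times` (or `subjects x times`
#'   matrices for 1-D data); in the paired design, rows of `a` and `b` are
#'   matched subjects.
#' @param design `"independent"` or `"paired"`.
#' @return A `tmap`: list with `t` (freqs x times matrix), `df`, `design`,
#'   and `mask` (valid bins).
#' @export
pointwise_tmap <- function(a, b, design = c("independent", "paired")) {
  design <- match.arg(design)
  a <- as_grid_array(a); b <- as_grid_array(b)
  if (!all(dim(a)[-1] == dim(b)[-1])) stop("grid axes differ between groups")
  n1 <- dim(a)[1]; n2 <- dim(b)[1]
  if (design == "independent") {
    if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per group")
    df <- n1 + n2 - 2L
    m1 <- colMeans(a, dims = 1); m2 <- colMeans(b, dims = 1)
    v1 <- (colSums(a ^ 2, dims = 1) - n1 * m1 ^ 2) / (n1 - 1)
    v2 <- (colSums(b ^ 2, dims = 1) - n2 * m2 ^ 2) / (n2 - 1)
    sp2 <- pmax(((n1 - 1) * v1 + (n2 - 1) * v2) / df, 0)
    tmat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    if (n1 != n2) stop("paired design needs matched subjects")
    if (n1 < 2) stop("need >= 2 paired differences")
    df <- n1 - 1L
    d <- a - b
    m <- colMeans(d, dims = 1)
    v <- pmax((colSums(d ^ 2, dims = 1) - n1 * m ^ 2) / df, 0)
    tmat <- m / sqrt(v / n1)
  }
  tmat[!is.finite(tmat)] <- NA_real_
  structure(list(t = tmat, df = df, design = design,
                 mask = is.finite(tmat)), class = "tmap")
}

#' Label connected components of a logical grid (reference implementation)
#'
#' Pure-R 4-connectivity labelling by iterative minimum-label propagation;
#' the compiled labeller used in the permutation loops is cross-checked
#' against this.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of component labels (0 = background), renumbered
#'   consecutively.
#' @keywords internal
#' @export
label_components_ref <- function(mask) {
  nf <- nrow(mask); nt <- ncol(mask)
  l <- matrix(Inf, nf, nt)
  l[mask] <- which(mask)
  repeat {
    l2 <- pmin(l,
               rbind(Inf, l[-nf, , drop = FALSE]),
               rbind(l[-1, , drop = FALSE], Inf),
               cbind(Inf, l[, -nt, drop = FALSE]),
               cbind(l[, -1, drop = FALSE], Inf))
    l2[!mask] <- Inf
    if (identical(l2, l)) break
    l <- l2
  }
  out <- matrix(0L, nf, nt)
  out[mask] <- as.integer(factor(l[mask]))
  out
}

#' Form supra-threshold clusters from a t-map
#'
#' Keeps bins whose two-tailed parametric p-value falls below
#' `cluster_alpha`, then finds connected components separately for positive
#' and negative t under 4-connectivity (frequency and time neighbours;
#' time-only for 1-D maps). Each cluster's mass is the sum of its member
#' t-values.
#'
#' @param tmap A `tmap` from [pointwise_tmap()].
#' @param cluster_alpha Two-tailed cluster-forming threshold (default 0.05).
#' @param freqs,times Optional axes used to annotate cluster extents.
#' @return List of clusters, ordered by decreasing `|mass|`; each has
#'   `members` (two-column bin index matrix), `sign`, `mass`, `freq_range`,
#'   `time_range`.
#' @export
form_clusters <- function(tmap, cluster_alpha = 0.05, freqs = NULL,
                          times = NULL) {
  thr <- stats::qt(1 - cluster_alpha / 2, tmap$df)
  tm <- tmap$t
  clusters <- list()
  for (sgn in c(1, -1)) {
    mask <- !is.na(tm) & sgn * tm > thr
    if (!any(mask)) next
    lab <- cpp_label_components(mask)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      cl <- list(members = idx, sign = sgn,
                 mass = sum(tm[lab == k]),
                 freq_range = if (!is.null(freqs)) range(freqs[idx[, 1]]) else range(idx[, 1]),
                 time_range = if (!is.null(times)) range(times[idx[, 2]]) else range(idx[, 2]))
      clusters[[length(clusters) + 1]] <- cl
    }
  }
  clusters[order(vapply(clusters, function(cl) -abs(cl$mass), numeric(1)))]
}

# enumerate all size-n1 subsets of n subjects (columns = assignments)
all_assignments <- function(n, n1) utils::combn(n, n1)

#' Cluster-based permutation test
#'
#' Tests for group differences on time-frequency grids or 1-D time courses
#' by comparing observed cluster masses against a max-statistic permutation
#' distribution. Independent designs permute group assignments (preserving
#' sizes); paired designs flip within-subject difference signs. Positive
#' and negative clusters are each referred to their own-sign extreme-mass
#' distribution and tested at `alpha / 2`, the two-tailed convention.
#'
#' Monte-Carlo p-values use the +1 correction,
#' `p = (b + 1) / (n_perm + 1)`. When the design space is small
#' (`<= max_exhaustive` assignments or sign patterns) the full enumeration
#' replaces sampling and p-values are exact proportions.
#'
#' @param a,b Subject grids as in [pointwise_tmap()].
#' @param design `"independent"` or `"paired"`.
#' @param n_perm Number of Monte-Carlo permutations (default 1000).
#' @param cluster_alpha Cluster-forming threshold (two-tailed, default 0.05).
#' @param alpha Decision threshold for the cluster test (two-tailed, default
#'   0.05).
#' @param seed Optional RNG seed for the permutation draws.
#' @param method `"auto"` (exhaustive when feasible), `"montecarlo"`, or
#'   `"exhaustive"`.
#' @param max_exhaustive Design-space size up to which `"auto"` enumerates
#'   exhaustively (default 20000).
#' @param freqs,times Optional axes annotating cluster extents.
#' @return A `cluster_test`: observed `tmap`, `clusters` (each with
#'   `monte_carlo_p` and `significant`), the per-sign max-mass permutation
#'   distributions, `n_perm`, `method`, `seed`, `alpha`, `cluster_alpha`.
#' @export
permutation_cluster_test <- function(a, b,
                                     design = c("independent", "paired"),
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     alpha = 0.05, seed = NULL,
                                     method = c("auto", "montecarlo", "exhaustive"),
                                     max_exhaustive = 20000,
                                     freqs = NULL, times = NULL) {
  design <- match.arg(design)
  method <- match.arg(method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  a <- as_grid_array(a); b <- as_grid_array(b)
  obs <- pointwise_tmap(a, b, design)
  clusters <- form_clusters(obs, cluster_alpha, freqs, times)
  nf <- dim(a)[2]; nt <- dim(a)[3]

  # flatten valid bins; grid coordinates for connectivity
  keep <- which(obs$mask)
  grid_idx <- arrayInd(keep, c(nf, nt))
  thr <- stats::qt(1 - cluster_alpha / 2, obs$df)

  if (design == "independent") {
    n1 <- dim(a)[1]; n2 <- dim(b)[1]
    n <- n1 + n2
    X <- rbind(matrix(a, dim(a)[1]), matrix(b, dim(b)[1]))[, keep, drop = FALSE]
    n_space <- choose(n, n1)
    exhaustive <- switch(method, exhaustive = TRUE, montecarlo = FALSE,
                         auto = n_space <= max_exhaustive)
    if (exhaustive) {
      sel <- all_assignments(n, n1)
      Z <- matrix(0, ncol(sel), n)
      Z[cbind(rep(seq_len(ncol(sel)), each = n1), as.vector(sel))] <- 1
    } else {
      if (!is.null(seed)) set.seed(seed)
      Z <- t(vapply(seq_len(n_perm), function(i) {
        z <- numeric(n); z[sample.int(n, n1)] <- 1; z
      }, numeric(n)))
    }
    tot_s <- colSums(X); tot_q <- colSums(X ^ 2)
    S1 <- Z %*% X
    Q1 <- Z %*% X ^ 2
    S2 <- matrix(rep(tot_s, each = nrow(S1)), nrow(S1)) - S1
    Q2 <- matrix(rep(tot_q, each = nrow(Q1)), nrow(Q1)) - Q1
    sp2 <- pmax((Q1 - S1 ^ 2 / n1 + Q2 - S2 ^ 2 / n2) / obs$df, 0)
    tperm <- (S1 / n1 - S2 / n2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    n <- dim(a)[1]
    D <- (matrix(a, n) - matrix(b, n))[, keep, drop = FALSE]
    n_space <- 2 ^ n
    exhaustive <- switch(method, exhaustive = TRUE, montecarlo = FALSE,
                         auto = n_space <= max_exhaustive)
    if (exhaustive) {
      Fm <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    } else {
      if (!is.null(seed)) set.seed(seed)
      Fm <- matrix(sample(c(1, -1), n_perm * n, replace = TRUE), n_perm, n)
    }
    q <- colSums(D ^ 2)
    M <- (Fm %*% D) / n
    Vm <- pmax((matrix(rep(q, each = nrow(M)), nrow(M)) - n * M ^ 2) / obs$df, 0)
    tperm <- M / sqrt(Vm / n)
  }
  tperm[!is.finite(tperm)] <- NA_real_
  masses <- cpp_max_cluster_masses(tperm, grid_idx[, 1] - 1L,
                                   grid_idx[, 2] - 1L, nf, nt, thr)
  n_eff <- nrow(masses)
  for (k in seq_along(clusters)) {
    cl <- clusters[[k]]
    dist <- if (cl$sign > 0) masses[, 1] else masses[, 2]
    # tolerance so the identity assignment always counts despite round-off
    tol <- 1e-9 * max(1, abs(cl$mass))
    bcount <- sum(dist >= abs(cl$mass) - tol)
    p <- if (exhaustive) bcount / n_eff else (bcount + 1) / (n_eff + 1)
    clusters[[k]]$monte_carlo_p <- p
    clusters[[k]]$significant <- p <= alpha / 2
  }
  structure(list(tmap = obs, clusters = clusters,
                 perm_max_pos = masses[, 1], perm_max_neg = masses[, 2],
                 n_perm = n_eff, method = if (exhaustive) "exhaustive" else "montecarlo",
                 seed = seed, alpha = alpha, cluster_alpha = cluster_alpha,
                 freqs = freqs, times = times),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, df = %d, %s, %d permutations)\n",
              x$tmap$design, x$tmap$df, x$method, x$n_perm))
  if (length(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
    return(invisible(x))
  }
  for (k in seq_along(x$clusters)) {
    cl <- x$clusters[[k]]
    cat(sprintf("  cluster %d: sign %+d, mass %.2f, p = %.4g%s", k, cl$sign,
                cl$mass, cl$monte_carlo_p,
                if (cl$significant) " *" else ""))
    if (!is.null(x$times))
      cat(sprintf(", time %.2f-%.2f s", cl$time_range[1], cl$time_range[2]))
    if (!is.null(x$freqs) && !is.null(dim(x$tmap$t)) && nrow(x$tmap$t) > 1)
      cat(sprintf(", freq %g-%g Hz", cl$freq_range[1], cl$freq_range[2]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  cl <- object$clusters
  if (length(cl) == 0)
    return(data.frame(cluster = integer(), sign = integer(), mass = numeric(),
                      p = numeric(), significant = logical()))
  data.frame(cluster = seq_along(cl),
             sign = vapply(cl, `[[`, numeric(1), "sign"),
             mass = vapply(cl, `[[`, numeric(1), "mass"),
             time_min = vapply(cl, function(c) c$time_range[1], numeric(1)),
             time_max = vapply(cl, function(c) c$time_range[2], numeric(1)),
             freq_min = vapply(cl, function(c) c$freq_range[1], numeric(1)),
             freq_max = vapply(cl, function(c) c$freq_range[2], numeric(1)),
             p = vapply(cl, `[[`, numeric(1), "monte_carlo_p"),
             significant = vapply(cl, `[[`, logical(1), "significant"))
}

#' Pseudo-2x2 interaction contrast (group x session)
#'
#' Implements the medication-vs-retest separation: per subject, the
#' session-1 minus session-2 difference grid is formed, re-baselined by
#' subtracting its own per-frequency mean over the baseline window, and the
#' groups are then compared on the differences with an independent-samples
#' cluster permutation test. A session (retest) effect common to both
#' groups cancels; only a group-specific session effect (e.g. medication)
#' survives.
#'
#' @param s1,s2 Arrays `subjects x freqs x times`: per-subject grids for
#'   session 1 and session 2 (log power, baseline-corrected or not; the
#'   difference is re-baselined regardless).
#' @param groups Character/factor vector of length `n_subjects` with two
#'   levels; the first level plays the role of group A.
#' @param times Time axis (needed for re-baselining).
#' @param baseline Baseline window in seconds (default `c(-1.25, -0.2)`,
#'   clipped to the available times).
#' @param freqs Optional frequency axis.
#' @param ... Passed to [permutation_cluster_test()].
#' @return A `cluster_test` on the re-baselined session differences.
#' @export
interaction_contrast <- function(s1, s2, groups, times,
                                 baseline = c(-1.25, -0.2), freqs = NULL,
                                 ...) {
  s1 <- as_grid_array(s1); s2 <- as_grid_array(s2)
  if (dim(s1)[1] != dim(s2)[1]) stop("both sessions required for every subject")
  if (dim(s1)[1] != length(groups)) stop("groups must match subjects")
  d <- s1 - s2
  bsel <- times >= max(baseline[1], min(times)) & times <= baseline[2]
  if (!any(bsel)) stop("baseline window outside the time axis")
  base <- apply(d[, , bsel, drop = FALSE], c(1, 2), mean, na.rm = TRUE)
  d <- sweep(d, c(1, 2), base, "-")
  gl <- unique(as.character(groups))
  if (length(gl) != 2) stop("need exactly two groups")
  permutation_cluster_test(d[groups == gl[1], , , drop = FALSE],
                           d[groups == gl[2], , , drop = FALSE],
                           design = "independent", freqs = freqs,
                           times = times, ...)
}

#' Cluster permutation tests on EMG time courses
#'
#' 1-D cluster tests over time on rectified EMG averages. Three contrasts
#' are supported: `"movement_vs_baseline"` pairs each post-stimulus time
#' point with its counterpart half a second earlier (paired across
#' subjects), `"between_group"` compares two groups on the full window
#' (independent), and `"between_session"` compares two sessions within a
#' group (paired).
#'
#' @param a,b Matrices `subjects x times` of rectified EMG time courses
#'   (for `"movement_vs_baseline"` pass a single matrix as `a` and leave
#'   `b` `NULL`).
#' @param times Time axis in seconds.
#' @param contrast One of `"movement_vs_baseline"`, `"between_group"`,
#'   `"between_session"`.
#' @param move_window,base_window Windows for the movement-vs-baseline
#'   contrast (defaults `[0, 0.5]` and `[-0.5, 0]`; must have equal
#'   lengths).
#' @param ... Passed to [permutation_cluster_test()].
#' @return A `cluster_test`.
#' @export
emg_cluster_tests <- function(a, b = NULL, times,
                              contrast = c("movement_vs_baseline",
                                           "between_group", "between_session"),
                              move_window = c(0, 0.5),
                              base_window = c(-0.5, 0), ...) {
  contrast <- match.arg(contrast)
  if (contrast == "movement_vs_baseline") {
    msel <- which(times >= move_window[1] & times < move_window[2])
    bsel <- which(times >= base_window[1] & times < base_window[2])
    if (length(msel) != length(bsel))
      stop("movement and baseline windows must span equal lengths")
    permutation_cluster_test(a[, msel, drop = FALSE], a[, bsel, drop = FALSE],
                             design = "paired", times = times[msel], ...)
  } else {
    design <- if (contrast == "between_group") "independent" else "paired"
    permutation_cluster_test(a, b, design = design, times = times, ...)
  }
}
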