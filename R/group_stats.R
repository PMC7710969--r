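# Second-level inference: normality screen, one-tailed paired t, simple
# regression, voxel-wise paired contrasts, and sign-flip permutation cluster
# inference with Benjamini-Hochberg correction across clusters.

#' One-tailed paired t-test (post > pre)
#'
#' t = mean(d) / (SD(d) / sqrt(n)) with d = post - pre and the n-1 SD; the
#' p-value is the upper-tail Student probability at n - 1 degrees of freedom
#' (directional hypothesis of an increase).
#'
#' @param pre,post numeric vectors of equal length (n >= 2).
#' @return object of class `test_result`: `t`, `df`, `p`, `tail`,
#'   `mean_diff`, `sd_diff`, `n`.
#' @export
paired_t_one_tailed <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs")
  d <- post - pre
  s <- sd(d)
  if (s == 0) stop("degenerate input: all differences identical")
  t <- mean(d) / (s / sqrt(n))
  structure(list(t = t, df = n - 1, p = pt(t, n - 1, lower.tail = FALSE),
                 tail = "upper", mean_diff = mean(d), sd_diff = s, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, one-tailed p = %.4g (mean diff %.3g +/- %.3g, n = %d)\n",
              x$df, x$t, x$p, x$mean_diff, x$sd_diff, x$n))
  invisible(x)
}

#' Paired t-test from a reported mean and SD of differences
#'
#' Reconstructs a difference vector with exactly the given mean and SD and
#' runs [paired_t_one_tailed()] on it, so that published summary statistics
#' (mean change +/- SD at sample size n) can be checked through the same code
#' path as raw data.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation (n - 1 denominator) of the differences.
#' @param n number of pairs.
#' @return a `test_result`.
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n) {
  stopifnot(n >= 2, sd_diff > 0)
  v <- seq_len(n)
  v <- (v - mean(v)) / sd(v)
  d <- mean_diff + sd_diff * v
  paired_t_one_tailed(rep(0, n), d)
}

#' Shapiro-Wilk normality screen
#' @param values numeric vector, 3 <= n <= 5000, not all identical.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk_screen <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (length(unique(values)) == 1) stop("degenerate input: identical values")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Simple linear regression with correlation-based inference
#'
#' OLS slope and intercept; r-squared is the squared Pearson correlation and
#' the slope t statistic satisfies t^2 = r^2 (n - 2) / (1 - r^2), with a
#' two-tailed p-value.
#'
#' @param x,y numeric vectors, n >= 3, var(x) > 0.
#' @return object of class `regression_result`: `slope`, `intercept`, `r2`,
#'   `t`, `df`, `p`.
#' @export
simple_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 points")
  if (var(x) == 0) stop("constant predictor")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- if (var(y) == 0) 0 else cor(x, y)
  r2 <- r^2
  df <- n - 2
  if (1 - r2 < 1e-15) {
    t <- sign(slope) * Inf; p <- 0
  } else {
    t <- r * sqrt(df / (1 - r2))
    p <- 2 * pt(-abs(t), df)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2, t = t,
                 df = df, p = p, n = n),
            class = "regression_result")
}

#' Construct x, y with an exact sample correlation
#'
#' Builds two length-n vectors whose sample Pearson correlation equals `r`
#' exactly (up to floating point), useful for exercising regression inference
#' at a published r-squared.
#'
#' @param r target correlation in (-1, 1).
#' @param n sample size (>= 3).
#' @return list with `x` and `y`.
#' @export
synth_correlated_xy <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3)
  e1 <- seq_len(n); e1 <- (e1 - mean(e1)) / sqrt(sum((e1 - mean(e1))^2))
  e2 <- (seq_len(n))^2
  e2 <- e2 - mean(e2) - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  list(x = e1, y = r * e1 + sqrt(1 - r^2) * e2)
}

# Vectorised per-voxel paired t on a voxel x subject difference matrix.
# Zero-SD voxels: 0/0 -> 0 (flagged via attribute), c/0 -> signed large value.
paired_tstat_matrix <- function(D) {
  n <- ncol(D)
  m <- rowMeans(D)
  ss <- rowSums(D^2)
  s2 <- pmax((ss - n * m^2) / (n - 1), 0)
  t <- m / sqrt(s2 / n)
  zero <- s2 == 0
  t[zero & m == 0] <- 0
  t[zero & m != 0] <- sign(m[zero & m != 0]) * sqrt(.Machine$double.xmax)
  attr(t, "n_degenerate") <- sum(zero)
  t
}

#' Voxel-wise paired contrast across subjects
#'
#' Per-voxel paired t (post - pre) across subjects. Voxels with zero
#' difference variance get t = 0 when the mean difference is also zero.
#'
#' @param maps_pre,maps_post lists of [conn_map()]s, one per subject, on a
#'   common grid; the analysis mask is the intersection of all masks.
#' @return a `t_map` with `df = n - 1` and attribute `diff_matrix`
#'   (in-mask voxel x subject differences, used by [cluster_inference()]).
#' @export
voxelwise_paired_contrast <- function(maps_pre, maps_post) {
  n <- length(maps_pre)
  if (length(maps_post) != n) stop("unequal subject counts")
  if (n < 2) stop("need at least 2 subjects")
  mask <- Reduce(`&`, c(lapply(maps_pre, `[[`, "mask"),
                        lapply(maps_post, `[[`, "mask")))
  idx <- which(mask)
  D <- vapply(seq_len(n), function(i)
    maps_post[[i]]$values[idx] - maps_pre[[i]]$values[idx],
    numeric(length(idx)))
  t <- paired_tstat_matrix(D)
  vals <- array(NA_real_, dim(mask))
  vals[idx] <- t
  out <- structure(list(values = vals, df = n - 1,
                        contrast = "post > pre", affine = maps_pre[[1]]$affine,
                        mask = mask),
                   class = "t_map")
  attr(out, "diff_matrix") <- D
  attr(out, "mask_index") <- idx
  out
}

# 26-connectivity connected components of a logical 3D array.
# Returns a list of integer vectors of linear indices, one per component.
label_components_26 <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  if (!length(idx)) return(list())
  lab <- array(0L, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  comps <- list()
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      co <- arrayInd(v, d)
      nb <- sweep(off, 2, as.integer(co), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      lin <- lin[supra[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
    comps[[cur]] <- members
  }
  comps
}

# Sizes of suprathreshold clusters of a t vector on the mask grid, positive
# and negative tails clustered separately. Returns max size only when
# max_only.
cluster_sizes <- function(tvec, idx, d, thr, max_only = FALSE) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- array(FALSE, d)
    supra[idx[sgn * tvec > thr]] <- TRUE
    if (!any(supra)) next
    comps <- label_components_26(supra)
    out <- c(out, lapply(comps, function(m) list(voxels = m, sign = sgn)))
  }
  if (max_only) {
    if (!length(out)) return(0L)
    return(max(vapply(out, function(cl) length(cl$voxels), integer(1))))
  }
  out
}

#' Permutation cluster inference for a paired contrast
#'
#' Suprathreshold voxels (two-tailed voxel p below `voxel_p_thresh`, positive
#' and negative tails clustered separately) are grouped by 26-connectivity.
#' The null distribution of the maximum cluster size is built by sign-flipping
#' each subject's difference map (exact under the symmetric null of a paired
#' design); each cluster's p is the proportion of permutations whose largest
#' cluster reaches its size, and Benjamini-Hochberg correction is applied
#' across clusters.
#'
#' @param tmap a `t_map` from [voxelwise_paired_contrast()] (must carry the
#'   subject difference matrix).
#' @param voxel_p_thresh two-tailed voxel-level threshold (default 0.005).
#' @param q_thresh cluster-level FDR threshold (default 0.05).
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed integer permutation seed (default 20201119).
#' @return object of class `cluster_result`: data frame `clusters`
#'   (size, peak voxel, peak t, p, q, sign, survives), list `voxel_sets`,
#'   thresholds used. No suprathreshold voxels gives an empty result.
#' @export
cluster_inference <- function(tmap, voxel_p_thresh = 0.005, q_thresh = 0.05,
                              n_perm = 1000, seed = 20201119) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  D <- attr(tmap, "diff_matrix")
  idx <- attr(tmap, "mask_index")
  if (is.null(D)) stop("tmap must come from voxelwise_paired_contrast()")
  d <- dim(tmap$values)
  n <- ncol(D)
  thr <- qt(1 - voxel_p_thresh / 2, df = n - 1)
  tobs <- tmap$values[idx]
  obs <- cluster_sizes(tobs, idx, d, thr)
  empty <- structure(list(clusters = data.frame(), voxel_sets = list(),
                          voxel_p_thresh = voxel_p_thresh,
                          q_thresh = q_thresh, n_perm = n_perm,
                          t_thresh = thr),
                     class = "cluster_result")
  if (!length(obs)) return(empty)
  ss <- rowSums(D^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.vector(D %*% sgn) / n
    s2 <- pmax((ss - n * m^2) / (n - 1), 0)
    tp <- m / sqrt(s2 / n)
    tp[s2 == 0] <- 0
    null_max[p] <- cluster_sizes(tp, idx, d, thr, max_only = TRUE)
  }
  sizes <- vapply(obs, function(cl) length(cl$voxels), integer(1))
  pvals <- vapply(sizes, function(sz) (1 + sum(null_max >= sz)) / (n_perm + 1),
                  numeric(1))
  qvals <- p.adjust(pvals, "BH")
  peak <- t(vapply(obs, function(cl) {
    tv <- tmap$values[cl$voxels]
    pk <- cl$voxels[which.max(abs(tv))]
    c(pk, tv[which.max(abs(tv))])
  }, numeric(2)))
  ord <- order(pvals, -sizes)
  clusters <- data.frame(
    cluster = seq_along(ord),
    size = sizes[ord],
    peak_index = as.integer(peak[ord, 1]),
    peak_t = peak[ord, 2],
    sign = vapply(obs, `[[`, numeric(1), "sign")[ord],
    p = pvals[ord],
    q = qvals[ord])
  clusters$survives <- clusters$q < q_thresh
  structure(list(clusters = clusters,
                 voxel_sets = lapply(obs[ord], `[[`, "voxels"),
                 voxel_p_thresh = voxel_p_thresh, q_thresh = q_thresh,
                 n_perm = n_perm, t_thresh = thr),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  if (!nrow(x$clusters)) {
    cat("<cluster_result: no suprathreshold voxels>\n")
  } else {
    cat(sprintf("<cluster_result: %d cluster(s), %d surviving q < %g>\n",
                nrow(x$clusters), sum(x$clusters$survives), x$q_thresh))
    print(x$clusters)
  }
  invisible(x)
}
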