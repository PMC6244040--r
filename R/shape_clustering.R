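#' z-normalization of time series
#'
#' Centres a series to mean 0 and scales to standard deviation 1 (sample
#' SD). A constant series has no shape and maps to the all-zero vector.
#' Matrices are normalized row-wise. Idempotent.
#'
#' @param x numeric vector (length >= 2) or matrix of row series.
#' @return object of the same shape.
#' @export
znormalize <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, znormalize)))
  if (length(x) < 2) stop("series must have length >= 2")
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# cross-correlation of x against y over all 2T-1 alignment shifts,
# normalized by the product of the series norms (coefficient normalization)
ncc_c <- function(x, y) {
  t_len <- length(x)
  den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (den == 0) return(rep(0, 2 * t_len - 1))
  cc <- vapply(seq(-(t_len - 1), t_len - 1), function(s) {
    if (s >= 0) sum(x[(1 + s):t_len] * y[1:(t_len - s)])
    else sum(x[1:(t_len + s)] * y[(1 - s):t_len])
  }, 0)
  cc / den
}

#' Shape-based distance
#'
#' `1 - max_s NCCc(x, y, s)`: one minus the maximum, over all `2T - 1`
#' alignment shifts, of the coefficient-normalized cross-correlation of the
#' z-normalized series. Zero iff the series share a shape up to shift and
#' positive affine scaling; at most 2. Symmetric. A series with no shape
#' (constant) is at distance 1 from everything.
#'
#' @param x,y numeric series of equal length.
#' @return distance in `[0, 2]`.
#' @export
sbd <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  1 - max(ncc_c(znormalize(x), znormalize(y)))
}

# stack of all 2T-1 shifted copies of the z-normalized row matrix;
# zs[[w]] holds the rows shifted by s = w - T (zero-padded)
shift_stack <- function(z) {
  t_len <- ncol(z)
  lapply(seq(-(t_len - 1), t_len - 1), function(s) {
    out <- matrix(0, nrow(z), t_len)
    if (s >= 0) out[, 1:(t_len - s)] <- z[, (1 + s):t_len, drop = FALSE]
    else out[, (1 - s):t_len] <- z[, 1:(t_len + s), drop = FALSE]
    out
  })
}

# SBD from every z-normalized row of z to every z-normalized row of cen
# (vectorized over all shifts; equals outer application of sbd())
sbd_cross <- function(z, cen) {
  norms_z <- sqrt(rowSums(z^2))
  norms_c <- sqrt(rowSums(cen^2))
  den <- outer(norms_z, norms_c)
  best <- matrix(-Inf, nrow(z), nrow(cen))
  for (zs in shift_stack(z)) best <- pmax(best, tcrossprod(zs, cen))
  ncc <- ifelse(den > 0, best / den, 0)
  1 - ncc
}

# full pairwise SBD matrix of the rows of a series matrix
sbd_matrix <- function(series) {
  z <- znormalize(as.matrix(series))
  sbd_cross(z, z)
}

# align x to ref by the shift that maximizes NCCc; zero-pad the overhang
align_to <- function(x, ref) {
  zx <- znormalize(x)
  zr <- znormalize(ref)
  if (all(zr == 0)) return(zx)
  s <- which.max(ncc_c(zx, zr)) - length(x)   # shift of x relative to ref
  t_len <- length(x)
  out <- rep(0, t_len)
  if (s >= 0) out[(1 + s):t_len] <- zx[1:(t_len - s)]
  else out[1:(t_len + s)] <- zx[(1 - s):t_len]
  out
}

#' Shape extraction: the k-Shape centroid
#'
#' The cluster centroid under the shape-based distance: members are
#' shift-aligned to the current centroid, and the new centroid is the
#' z-normalized maximizer of the summed squared normalized cross-correlation
#' to the aligned members — the principal eigenvector of the centred
#' member outer-product matrix. The eigenvector's arbitrary sign is fixed
#' by whichever orientation is closer (in total SBD) to the members.
#'
#' @param members numeric matrix, one member series per row (>= 1 row).
#' @param centroid current centroid used for alignment; the zero vector
#'   (default) skips alignment, as on the first iteration.
#' @return z-normalized centroid series.
#' @export
shape_extract_centroid <- function(members,
                                   centroid = rep(0, ncol(members))) {
  members <- as.matrix(members)
  if (!nrow(members)) stop("empty cluster")
  t_len <- ncol(members)
  a <- t(apply(members, 1, align_to, ref = centroid))
  if (nrow(members) == 1) a <- matrix(a, 1, t_len)
  m <- crossprod(a)
  q <- diag(t_len) - matrix(1 / t_len, t_len, t_len)
  s <- q %*% m %*% q
  v <- eigen(s, symmetric = TRUE)$vectors[, 1]
  cand <- rbind(znormalize(v), znormalize(-v))
  tot <- colSums(sbd_cross(znormalize(members), cand))
  cand[which.min(tot), ]
}

#' k-Shape clustering of trait time series
#'
#' Partitional clustering under the shape-based distance: alternates
#' assignment of every series to its nearest centroid (by [sbd()]) with
#' centroid refinement by [shape_extract_centroid()], until the assignment
#' stabilizes or `max_iter` is reached. Because shape extraction maximizes
#' a squared-correlation surrogate, an individual sweep can increase the
#' SBD objective (and the label sequence can oscillate); the algorithm
#' therefore tracks the best state seen and returns it, so the sequence of
#' accepted (improving) objectives — reported as `trace` — is
#' non-increasing by construction. An emptied cluster is reseeded from the
#' globally worst-fitted row. Deterministic for a fixed seed.
#'
#' @param series numeric matrix, one series per row (rows >= k).
#' @param k number of clusters (>= 2, or 1).
#' @param seed integer seed for the random initial assignment.
#' @param max_iter iteration cap.
#' @return object of class `kshape`: list with `k`, `cluster` (assignment
#'   per row), `centroids` (k x T matrix), `iterations`, `objective` (sum
#'   of within-cluster SBD to centroid), `trace` (accepted objective per
#'   sweep), `seed`.
#' @export
kshape_cluster <- function(series, k, seed = 1, max_iter = 100) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of series")
  set.seed(seed)
  labels <- sample(rep_len(seq_len(k), n))
  cen <- matrix(0, k, ncol(series))
  z <- znormalize(series)
  trace <- numeric(0)
  best <- NULL
  iter <- 0
  repeat {
    iter <- iter + 1
    for (j in seq_len(k)) {
      rows <- which(labels == j)
      if (!length(rows)) {
        # reseed from the globally worst-fitted row
        worst <- which.max(sbd_cross(z, cen)[cbind(seq_len(n), labels)])
        labels[worst] <- j
        rows <- worst
      }
      cen[j, ] <- shape_extract_centroid(series[rows, , drop = FALSE],
                                         cen[j, ])
    }
    d <- sbd_cross(z, cen)
    new_labels <- max.col(-d, ties.method = "first")
    obj <- sum(d[cbind(seq_len(n), new_labels)])
    if (is.null(best) || obj < best$objective - 1e-12) {
      best <- list(labels = new_labels, cen = cen, d = d, objective = obj)
      trace <- c(trace, obj)
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged || iter >= max_iter) break
  }
  labels <- best$labels
  cen <- best$cen
  d <- best$d
  # repair any cluster emptied by the best assignment
  for (j in seq_len(k)) {
    if (!any(labels == j)) {
      free <- which(tabulate(labels, k)[labels] > 1)
      labels[free[which.max(d[cbind(free, labels[free])])]] <- j
    }
  }
  structure(
    list(k = k, cluster = labels, centroids = cen, iterations = iter,
         objective = sum(d[cbind(seq_len(n), labels)]), trace = trace,
         seed = seed),
    class = "kshape"
  )
}

#' @export
print.kshape <- function(x, ...) {
  cat(sprintf("<kshape> k = %d, %d series, %d iterations, objective %.4f\n",
              x$k, length(x$cluster), x$iterations, x$objective))
  cat("cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = " "), "\n")
  invisible(x)
}

#' Cluster validity indices under the shape-based distance
#'
#' `davies_bouldin`: mean over clusters of the worst ratio
#' `(S_i + S_j) / M_ij`, where `S_i` is the mean SBD of cluster members to
#' their centroid and `M_ij` the SBD between centroids; lower is better.
#' `dunn_index`: minimum between-cluster member SBD divided by the maximum
#' within-cluster diameter; higher is better. Degenerate configurations
#' (coincident centroids, all-singleton clusters) are flagged with a
#' warning and yield `Inf`/`NaN` as the arithmetic dictates.
#'
#' @param series the clustered series matrix.
#' @param result a [kshape_cluster()] result on it.
#' @return scalar index value.
#' @export
davies_bouldin <- function(series, result) {
  k <- result$k
  if (k < 2) stop("need k >= 2")
  dcen <- sbd_cross(znormalize(as.matrix(series)),
                    znormalize(result$centroids))
  s <- vapply(seq_len(k), function(j)
    mean(dcen[result$cluster == j, j]), 0)
  m <- sbd_cross(znormalize(result$centroids),
                 znormalize(result$centroids))
  diag(m) <- 0
  if (any(m[upper.tri(m)] == 0))
    warning("coincident centroids: Davies-Bouldin index degenerate")
  mean(vapply(seq_len(k), function(i)
    max((s[i] + s[-i]) / m[i, -i]), 0))
}

#' @rdname davies_bouldin
#' @param dmat optional precomputed pairwise SBD matrix of the series,
#'   to amortize the quadratic cost over repeated calls.
#' @export
dunn_index <- function(series, result, dmat = NULL) {
  k <- result$k
  if (k < 2) stop("need k >= 2")
  n <- nrow(series)
  dm <- if (is.null(dmat)) sbd_matrix(series) else dmat
  dm <- pmax(dm, 0)
  lab <- result$cluster
  inter <- min(dm[outer(lab, lab, `!=`)])
  intra <- max(dm[outer(lab, lab, `==`) & upper.tri(dm)], 0)
  if (intra == 0) {
    warning("all clusters are singletons or duplicates: Dunn index degenerate")
    return(Inf)
  }
  inter / intra
}

#' Select the cluster number by joint CVI agreement
#'
#' Clusters the series for every `k` from 2 to `k_max`, computing the
#' Davies-Bouldin and Dunn indices for each. When a single `k` both
#' minimizes DBI and maximizes DI it is selected; otherwise the `k` with
#' the best rank sum (DBI ascending + DI descending) wins, ties going to
#' the smaller `k`. A `k_max` above the number of series is truncated with
#' a warning.
#'
#' @param series numeric matrix of row series.
#' @param k_max largest cluster number scanned (default 20).
#' @param seed seed passed to every [kshape_cluster()] run.
#' @param max_iter per-run iteration cap.
#' @return list with `k_opt`, `method` (`"simultaneous"` or `"rank-sum"`)
#'   and `table` (data.frame `k`, `dbi`, `dunn`, one row per candidate).
#' @export
select_cluster_number <- function(series, k_max = 20, seed = 1,
                                  max_iter = 100) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (k_max < 2) stop("k_max must be >= 2")
  if (k_max > n) {
    warning("k_max exceeds the number of series; truncated to ", n)
    k_max <- n
  }
  ks <- 2:k_max
  tab <- data.frame(k = ks, dbi = NA_real_, dunn = NA_real_)
  fits <- vector("list", length(ks))
  dmat <- sbd_matrix(series)
  for (i in seq_along(ks)) {
    fit <- kshape_cluster(series, ks[i], seed = seed, max_iter = max_iter)
    fits[[i]] <- fit
    tab$dbi[i] <- suppressWarnings(davies_bouldin(series, fit))
    tab$dunn[i] <- suppressWarnings(dunn_index(series, fit, dmat = dmat))
  }
  i_dbi <- which.min(tab$dbi)
  i_dunn <- which.max(tab$dunn)
  if (i_dbi == i_dunn) {
    sel <- i_dbi; method <- "simultaneous"
  } else {
    rs <- rank(tab$dbi, ties.method = "min") +
      rank(-tab$dunn, ties.method = "min")
    sel <- which(rs == min(rs))[1]
    method <- "rank-sum"
  }
  list(k_opt = tab$k[sel], method = method, table = tab,
       fit = fits[[sel]])
}
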