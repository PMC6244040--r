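#' Typical curve of a cluster
#'
#' The per-stage mean trajectory of a cluster's member series, with 95%
#' confidence half-widths `t(0.975, n-1) * sd / sqrt(n)` — the t interval,
#' since clusters are often small. A single-member cluster has `NA`
#' half-widths.
#'
#' @param members numeric matrix, one member series per row.
#' @return list of class `typical_curve`: `mean` (per-stage means),
#'   `ci_halfwidth`, `n`.
#' @export
build_typical_curve <- function(members) {
  members <- as.matrix(members)
  n <- nrow(members)
  if (!n) stop("empty member set")
  mu <- colMeans(members)
  hw <- if (n >= 2) {
    stats::qt(0.975, n - 1) * apply(members, 2, stats::sd) / sqrt(n)
  } else rep(NA_real_, ncol(members))
  structure(list(mean = mu, ci_halfwidth = hw, n = n),
            class = "typical_curve")
}

#' Name a typical curve by its zenith and adjacent point
#'
#' The naming convention for 4-stage growth curves. The zenith point is
#' the stage of the maximum mean (ties broken to the earliest stage),
#' giving `Z1`..`Z4`. The decisive second point is the zenith's neighbour
#' on its longer arm, judged against the straight chord from the zenith to
#' that arm's endpoint: a zenith at S2 is judged by whether the S3 point
#' lies above (`A3`), below (`B3`) or on (`O3`) the Z2-P4 chord; a zenith
#' at S3 by the S2 point against the Z3-P1 chord; a zenith at S4 by the S3
#' point against the Z4-P1 chord; and a zenith at S1 by the S2 point
#' against the Z1-P4 chord. "On the chord" means a vertical offset within
#' `o_tolerance` times the curve's value range, so the classification is
#' invariant to positive affine transforms of the values.
#'
#' @param curve a [build_typical_curve()] result, or a numeric vector of 4
#'   stage means.
#' @param o_tolerance on-the-chord tolerance as a fraction of the curve
#'   range (default 0.02).
#' @return list of class `curve_name`: `name` (e.g. `"Z2A3"`), `zenith`,
#'   `adjacent`, `endpoint`, `relation` (`"A"`, `"B"` or `"O"`).
#' @export
name_typical_curve <- function(curve, o_tolerance = 0.02) {
  mu <- if (inherits(curve, "typical_curve")) curve$mean else curve
  if (length(mu) != 4) stop("naming requires 4 stage means")
  z <- which.max(mu)            # earliest stage on ties
  arm <- switch(z,
                list(adj = 2L, end = 4L),   # Z1: only the right arm
                list(adj = 3L, end = 4L),   # Z2: right arm is longer
                list(adj = 2L, end = 1L),   # Z3: left arm is longer
                list(adj = 3L, end = 1L))   # Z4: only the left arm
  chord_at_adj <- mu[z] + (mu[arm$end] - mu[z]) *
    (arm$adj - z) / (arm$end - z)
  rng <- diff(range(mu))
  off <- mu[arm$adj] - chord_at_adj
  relation <- if (rng == 0 || abs(off) <= o_tolerance * rng) "O"
              else if (off > 0) "A" else "B"
  structure(list(name = sprintf("Z%d%s%d", z, relation, arm$adj),
                 zenith = z, adjacent = arm$adj, endpoint = arm$end,
                 relation = relation),
            class = "curve_name")
}

#' @export
print.curve_name <- function(x, ...) {
  cat(sprintf("%s (zenith S%d, adjacent S%d %s chord to P%d)\n", x$name,
              x$zenith, x$adjacent,
              switch(x$relation, A = "above", B = "below", O = "on"),
              x$endpoint))
  invisible(x)
}

#' Typical curves of every cluster in a clustering result
#'
#' Builds and names the typical curve of each cluster.
#'
#' @param series the clustered series matrix.
#' @param result a [kshape_cluster()] result on it.
#' @param o_tolerance passed to [name_typical_curve()].
#' @return object of class `typical_curves`: data.frame with one row per
#'   cluster (`cluster`, `n`, `name`, `mean_S*`, `ci_S*` columns), plus the
#'   curves as an attribute.
#' @export
typical_curves <- function(series, result, o_tolerance = 0.02) {
  series <- as.matrix(series)
  t_len <- ncol(series)
  curves <- lapply(seq_len(result$k), function(j)
    build_typical_curve(series[result$cluster == j, , drop = FALSE]))
  can_name <- t_len == 4
  tab <- data.frame(
    cluster = seq_len(result$k),
    n = vapply(curves, `[[`, 0, "n"),
    name = if (can_name)
      vapply(curves, function(cv)
        name_typical_curve(cv, o_tolerance)$name, "")
    else NA_character_,
    stringsAsFactors = FALSE
  )
  for (s in seq_len(t_len))
    tab[[sprintf("mean_%d", s)]] <- vapply(curves, function(cv)
      cv$mean[s], 0)
  for (s in seq_len(t_len))
    tab[[sprintf("ci_%d", s)]] <- vapply(curves, function(cv)
      cv$ci_halfwidth[s], 0)
  structure(tab, curves = curves, class = c("typical_curves", "data.frame"))
}

#' Plot typical curves with confidence bands
#'
#' Base-graphics display: one line per cluster over growth stages with a
#' shaded 95% confidence band, labelled by the curve name.
#'
#' @param x a [typical_curves()] result.
#' @param stages x-axis labels.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.typical_curves <- function(x, stages = NULL, ylab = "trait value",
                                ...) {
  curves <- attr(x, "curves")
  t_len <- length(curves[[1]]$mean)
  if (is.null(stages)) stages <- paste0("S", seq_len(t_len))
  mu <- t(vapply(curves, `[[`, numeric(t_len), "mean"))
  hw <- t(vapply(curves, `[[`, numeric(t_len), "ci_halfwidth"))
  cols <- grDevices::hcl.colors(max(3, nrow(mu)), "Dark 3")
  ylim <- range(mu + hw, mu - hw, mu, na.rm = TRUE)
  graphics::matplot(seq_len(t_len), t(mu), type = "n", xaxt = "n",
                    xlab = "growth stage", ylab = ylab, ylim = ylim, ...)
  graphics::axis(1, at = seq_len(t_len), labels = stages)
  for (j in seq_len(nrow(mu))) {
    if (all(is.finite(hw[j, ])))
      graphics::polygon(c(seq_len(t_len), rev(seq_len(t_len))),
                        c(mu[j, ] + hw[j, ], rev(mu[j, ] - hw[j, ])),
                        col = grDevices::adjustcolor(cols[j], 0.2),
                        border = NA)
    graphics::lines(seq_len(t_len), mu[j, ], col = cols[j], lwd = 2)
    graphics::points(seq_len(t_len), mu[j, ], col = cols[j], pch = 16)
  }
  lab <- if (!all(is.na(x$name)))
    sprintf("%d: %s (n=%d)", x$cluster, x$name, x$n)
  else sprintf("%d (n=%d)", x$cluster, x$n)
  graphics::legend("topleft", legend = lab, col = cols[seq_len(nrow(mu))],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Recognition rate of genetic-background groups within scopes
#'
#' For each scope (a cluster, or a pooled curve-name type), the most
#' frequent group label among members and its share of the scope in
#' percent: how well the scope "recognises" one genetic background.
#'
#' @param scope vector of scope ids, one per member (cluster assignments,
#'   or curve names indexed by assignment for name-type pooling).
#' @param groups group label per member.
#' @return data.frame `scope`, `n`, `dominant`, `count`, `rate` (percent).
#' @export
recognition_rate <- function(scope, groups) {
  if (length(scope) != length(groups)) stop("length mismatch")
  if (!length(scope)) stop("empty scope")
  out <- lapply(split(groups, scope), function(g) {
    tab <- sort(table(g), decreasing = TRUE)
    data.frame(n = length(g), dominant = names(tab)[1],
               count = as.integer(tab[1]),
               rate = 100 * as.integer(tab[1]) / length(g),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(data.frame(scope = names(out), stringsAsFactors = FALSE),
               res)
  rownames(res) <- NULL
  res
}

#' Membership overlap between two clusters
#'
#' The shared membership of two member-id sets, as a percentage of the
#' smaller set: `100 * |A intersect B| / min(|A|, |B|)`.
#'
#' @param set_a,set_b member id vectors (non-empty).
#' @return overlap percentage in `[0, 100]`.
#' @export
membership_overlap <- function(set_a, set_b) {
  if (!length(set_a) || !length(set_b)) stop("empty member set")
  set_a <- unique(set_a); set_b <- unique(set_b)
  100 * length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}
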