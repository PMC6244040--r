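#' Normality-gated coefficient of variation
#'
#' The coefficient of variation with the centre chosen by a Shapiro-Wilk
#' normality gate: when the sample passes the test (p > alpha) the CV is
#' `100 * sd / mean`; when normality is rejected (p <= alpha, including
#' exactly alpha) the median replaces the mean, which is robust for the
#' skewed samples that failed the gate.
#'
#' @param sd sample standard deviation.
#' @param mean,median sample centres.
#' @param sw_p Shapiro-Wilk p-value.
#' @param alpha rejection level (default 0.05).
#' @return CV in percent; `NA` (with a warning) when the selected centre
#'   is zero.
#' @export
conditional_cv <- function(sd, mean, median, sw_p, alpha = 0.05) {
  centre <- if (sw_p > alpha) mean else median
  if (is.na(centre) || centre == 0) {
    warning("CV undefined: centre is zero")
    return(NA_real_)
  }
  100 * sd / centre
}

#' Descriptive summary of one trait at one stage
#'
#' The column set of a trait-distribution table: sample size, mean, SD,
#' minimum/maximum, quartiles, adjusted Fisher-Pearson skewness, excess
#' kurtosis, the Shapiro-Wilk p-value, and the normality-gated CV of
#' [conditional_cv()] with its basis recorded.
#'
#' @param values numeric sample, `NA` dropped; at least 3 values required.
#' @param trait,stage labels carried into the output.
#' @param alpha Shapiro-Wilk rejection level.
#' @return one-row data.frame with columns `trait`, `stage`, `n`, `mean`,
#'   `sd`, `minimum`, `maximum`, `cv`, `cv_basis`, `q1`, `q2`, `q3`,
#'   `skewness`, `kurtosis`, `sw_p`.
#' @export
describe_trait_stage <- function(values, trait = "", stage = "",
                                 alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  # Shapiro-Wilk is defined for 3..5000 observations; above that, apply it
  # to 5000 evenly spaced order statistics of the sample
  sw_sample <- if (n > 5000)
    sort(values)[round(seq(1, n, length.out = 5000))] else values
  sw_p <- if (stats::sd(values) == 0) 0
          else stats::shapiro.test(sw_sample)$p.value
  s <- stats::sd(values)
  cv <- if (s == 0) 0
        else conditional_cv(s, mean(values), q[2], sw_p, alpha)
  data.frame(trait = trait, stage = stage, n = n,
             mean = mean(values), sd = s,
             minimum = min(values), maximum = max(values),
             cv = cv,
             cv_basis = if (sw_p > alpha) "mean" else "median",
             q1 = q[1], q2 = q[2], q3 = q[3],
             skewness = e1071::skewness(values, type = 2),
             kurtosis = e1071::kurtosis(values, type = 2),
             sw_p = sw_p, stringsAsFactors = FALSE)
}

#' Trait-distribution table over all traits and stages
#'
#' Applies [describe_trait_stage()] to every trait x stage cell of the long
#' trait table.
#'
#' @param table long trait table from [build_trait_table()].
#' @param traits traits to summarise.
#' @return data.frame, one row per trait x stage.
#' @export
summarize_trait_table <- function(table, traits = c("ph", "ndvi", "cc")) {
  stages <- unique(table$stage[order(table$das)])
  out <- NULL
  for (s in stages) for (tr in traits) {
    v <- table[[tr]][table$stage == s]
    v <- v[!is.na(v)]
    if (length(v) >= 3)
      out <- rbind(out, describe_trait_stage(v, trait = tr, stage = s))
  }
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlations at one stage
#'
#' Pearson correlation between every pair of traits at the given stage,
#' with two-tailed t-test p-values, on pairwise-complete observations.
#'
#' @param table long trait table.
#' @param stage stage id.
#' @param traits trait columns to correlate.
#' @return list with symmetric matrices `r` (unit diagonal) and `p`.
#' @export
correlation_matrix <- function(table, stage,
                               traits = c("cc", "ndvi", "ph")) {
  sub <- table[table$stage == stage, traits, drop = FALSE]
  k <- length(traits)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(traits, traits)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(sub[, c(i, j)])
    if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                          traits[i], " vs ", traits[j])
    ct <- stats::cor.test(sub[ok, i], sub[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  diag(p) <- 0
  list(r = r, p = p)
}

#' Per-stage one-way F-statistics across genetic-background groups
#'
#' For one trait, the classical one-way ANOVA F across groups at each
#' stage, plus the stages sorted by ascending F: the stage label string
#' answers "at which stage is the group difference smallest/largest".
#'
#' @param table long trait table with a `group` column.
#' @param trait trait column name.
#' @return data.frame `stage`, `f`, `p`, with attribute `sorted` (e.g.
#'   `"S4-S3-S1-S2"`, ascending F).
#' @export
group_f_statistics <- function(table, trait) {
  stages <- unique(table$stage[order(table$das)])
  out <- NULL
  for (s in stages) {
    sub <- table[table$stage == s & !is.na(table[[trait]]), ]
    counts <- table(sub$group)
    if (length(counts) < 2 || any(counts < 2))
      stop("need >= 2 groups with >= 2 members at stage ", s)
    fit <- stats::anova(stats::lm(sub[[trait]] ~ factor(sub$group)))
    out <- rbind(out, data.frame(stage = s, f = fit$`F value`[1],
                                 p = fit$`Pr(>F)`[1],
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "sorted") <- sort_stages_by_f(out$f, out$stage)
  out
}

#' @rdname group_f_statistics
#' @param f numeric F-statistics.
#' @param stages matching stage labels.
#' @export
sort_stages_by_f <- function(f, stages = paste0("S", seq_along(f))) {
  paste(stages[order(f)], collapse = "-")
}
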