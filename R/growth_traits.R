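#' Growth-stage calendar
#'
#' Ordered (stage, days-after-sowing) pairs. The default is the four
#' critical maize stages at 24, 44, 57 and 84 DAS.
#'
#' @param stage character stage ids.
#' @param das integer days after sowing, strictly increasing.
#' @return data.frame with columns `stage`, `das`.
#' @export
stage_calendar <- function(stage = c("S1", "S2", "S3", "S4"),
                           das = c(24, 44, 57, 84)) {
  if (length(stage) != length(das) || length(das) < 2)
    stop("stage and das must have equal length >= 2")
  if (any(diff(das) <= 0)) stop("das must be strictly increasing")
  data.frame(stage = as.character(stage), das = as.numeric(das),
             stringsAsFactors = FALSE)
}

#' Average growth rate of plant height
#'
#' For each pair of adjacent stages, the plant-height increment divided by
#' the day increment: `(PH[i+1] - PH[i]) / (DAS[i+1] - DAS[i])`, in cm/day.
#' An interval with a missing endpoint is `NA`.
#'
#' @param ph numeric plant heights (cm), one per stage, in calendar order.
#' @param calendar a [stage_calendar()] matching `ph`.
#' @return named numeric vector of per-interval rates, names like
#'   `"S1-S2"`; the value at interval `i` is keyed to its starting stage.
#' @export
compute_agrph <- function(ph, calendar = stage_calendar()) {
  if (length(ph) != nrow(calendar))
    stop("ph must have one value per calendar stage")
  out <- diff(ph) / diff(calendar$das)
  names(out) <- paste(calendar$stage[-nrow(calendar)],
                      calendar$stage[-1], sep = "-")
  out
}

#' Contribution rate of plant height
#'
#' The per-interval height increment as a percentage of the final height:
#' `(PH[i+1] - PH[i]) / PH[last] * 100`. The three intervals telescope to
#' `(PH[last] - PH[1]) / PH[last] * 100`.
#'
#' @param ph numeric plant heights (cm) per stage; the final value must be
#'   positive.
#' @param stages optional stage ids for interval names.
#' @return named numeric vector of per-interval percentages.
#' @export
compute_crph <- function(ph, stages = paste0("S", seq_along(ph))) {
  final <- ph[length(ph)]
  if (is.na(final) || final <= 0)
    stop("final-stage plant height must be positive")
  out <- diff(ph) / final * 100
  names(out) <- paste(stages[-length(stages)], stages[-1], sep = "-")
  out
}

#' Assemble the multi-stage trait table
#'
#' Joins per-stage extraction tables (as produced by
#' [extract_stage_traits()] or read from CSV) into one long table and
#' populates the derived growth traits. `agrph` and `crph` at a row are
#' keyed to the interval that starts at that row's stage (so the final
#' stage carries `NA`); an interval with a missing height endpoint, or a
#' plot with a missing final height, yields `NA` in the derived columns.
#'
#' @param stage_tables list of per-stage data.frames with columns
#'   `plot_id`, `genotype`, `group`, `stage`, `cc`, `ndvi`, `ph` (a `das`
#'   column is ignored in favour of the calendar).
#' @param calendar a [stage_calendar()] covering every stage present.
#' @return long data.frame ordered by plot then stage, with added columns
#'   `agrph` (cm/day) and `crph` (%).
#' @export
build_trait_table <- function(stage_tables, calendar = stage_calendar()) {
  tab <- do.call(rbind, lapply(stage_tables, function(x)
    x[, intersect(c("plot_id", "genotype", "group", "stage", "cc", "ndvi",
                    "ph", "ph_status"), names(x))]))
  if (anyDuplicated(tab[, c("plot_id", "stage")]))
    stop("duplicate (plot_id, stage) records")
  if (!all(tab$stage %in% calendar$stage))
    stop("table contains stages missing from the calendar")
  tab$das <- calendar$das[match(tab$stage, calendar$stage)]
  tab <- tab[order(tab$plot_id, tab$das), ]
  tab$agrph <- NA_real_
  tab$crph <- NA_real_
  for (pid in unique(tab$plot_id)) {
    rows <- which(tab$plot_id == pid)
    ph <- tab$ph[rows][match(calendar$stage, tab$stage[rows])]
    a <- diff(ph) / diff(calendar$das)
    final <- ph[length(ph)]
    cr <- if (!is.na(final) && final > 0) diff(ph) / final * 100
          else rep(NA_real_, length(ph) - 1)
    here <- match(tab$stage[rows], calendar$stage)
    take <- here < nrow(calendar)
    tab$agrph[rows[take]] <- a[here[take]]
    tab$crph[rows[take]] <- cr[here[take]]
  }
  rownames(tab) <- NULL
  tab
}

#' Screen out lodging and low-emergence plots
#'
#' Two outlier rules, mirroring how anomalous breeding plots corrupt
#' multi-temporal traits: (1) lodging makes the height series decrease
#' between some pair of consecutive stages and increase again later
#' (plants knocked down, then partially recovering); (2) a very low
#' emergence rate shows as an extremely low early-stage canopy cover.
#' Every removed plot is logged with the rule that fired and the offending
#' values.
#'
#' @param table long trait table from [build_trait_table()].
#' @param cc_threshold absolute canopy-cover floor (default 0.05).
#' @param cc_stage stage at which the emergence rule is checked
#'   (default `"S2"`).
#' @return list with `table` (retained rows) and `excluded` (data.frame
#'   `plot_id`, `rule`, `detail`).
#' @export
filter_outlier_plots <- function(table, cc_threshold = 0.05,
                                 cc_stage = "S2") {
  excl <- NULL
  for (pid in unique(table$plot_id)) {
    rows <- table[table$plot_id == pid, ]
    rows <- rows[order(rows$das), ]
    ph <- rows$ph[!is.na(rows$ph)]
    if (length(ph) >= 3) {
      d <- diff(ph)
      dec <- which(d < 0)
      if (length(dec) && any(d[seq_along(d) > min(dec)] > 0)) {
        excl <- rbind(excl, data.frame(
          plot_id = pid, rule = "lodging pattern",
          detail = paste(round(ph, 1), collapse = " -> "),
          stringsAsFactors = FALSE))
        next
      }
    }
    cc <- rows$cc[rows$stage == cc_stage]
    if (length(cc) == 1 && !is.na(cc) && cc < cc_threshold) {
      excl <- rbind(excl, data.frame(
        plot_id = pid, rule = "low emergence",
        detail = sprintf("cc[%s] = %.3f < %.3f", cc_stage, cc,
                         cc_threshold),
        stringsAsFactors = FALSE))
    }
  }
  keep <- if (is.null(excl)) rep(TRUE, nrow(table))
          else !(table$plot_id %in% excl$plot_id)
  list(table = table[keep, ],
       excluded = if (is.null(excl))
         data.frame(plot_id = character(0), rule = character(0),
                    detail = character(0), stringsAsFactors = FALSE)
       else excl)
}

#' Genotype-by-stage matrix of one trait
#'
#' Reshapes the long trait table into the wide numeric matrix that the
#' shape-clustering functions consume: one row per plot/genotype, one
#' column per stage (for the derived traits, per interval). Rows with any
#' missing entry are dropped, since the shape-based distance needs complete
#' series.
#'
#' @param table long trait table.
#' @param trait one of `"ph"`, `"cc"`, `"ndvi"`, `"agrph"`, `"crph"`.
#' @return numeric matrix with plot ids as row names and a `groups`
#'   attribute giving each retained row's group label.
#' @export
trait_matrix_from_table <- function(table,
                                    trait = c("ph", "cc", "ndvi", "agrph",
                                              "crph")) {
  trait <- match.arg(trait)
  stages <- unique(table$stage[order(table$das)])
  if (trait %in% c("agrph", "crph")) stages <- stages[-length(stages)]
  pids <- unique(table$plot_id)
  m <- matrix(NA_real_, length(pids), length(stages),
              dimnames = list(pids, stages))
  for (i in seq_along(pids)) {
    rows <- table[table$plot_id == pids[i], ]
    m[i, ] <- rows[[trait]][match(stages, rows$stage)]
  }
  ok <- stats::complete.cases(m)
  groups <- table$group[match(pids, table$plot_id)]
  out <- m[ok, , drop = FALSE]
  attr(out, "groups") <- groups[ok]
  out
}
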