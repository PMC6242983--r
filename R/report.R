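# Publication-style summary report over analyzed outcomes.

#' Boxplot summary statistics
#'
#' First and third quartiles by linear interpolation (quantile type 7),
#' median, and full-range whiskers — the box convention used for the group
#' summaries.
#' @param x numeric vector
#' @return named numeric vector (min, q1, median, q3, max, n)
#' @export
boxplot_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
    n = length(x))
}

#' Build a markdown summary report of the analyzed outcomes
#'
#' For each outcome present in the table: boxplot-style summaries by group
#' and day, the nested ANOVA table with Tukey HSD, and (when two or more
#' outcomes share mouse/day cells) a Pearson correlation panel of per-
#' (mouse, day) means. Outcomes with no rows are omitted with a log notice.
#' The output is deterministic: regenerating on identical inputs is
#' byte-identical (no timestamps).
#'
#' @param table long-format measurement table
#' @param results named list of \code{\link{nested_anova}} objects keyed by
#'   outcome (missing entries are computed)
#' @param outcomes outcomes to report; default all in the table
#' @param path optional file to write
#' @return character vector of markdown lines, invisibly
#' @export
build_report <- function(table, results = list(),
                         outcomes = unique(table$outcome_name),
                         path = NULL) {
  if (length(outcomes) == 0) stop("no outcomes to report")
  lines <- c("# Wound-edge metabolism summary", "")
  fmtn <- function(x) formatC(x, digits = 4, format = "g")
  for (oc in outcomes) {
    d <- table[table$outcome_name == oc, ]
    if (nrow(d) == 0) {
      message(sprintf("outcome '%s' has no data; omitted", oc))
      next
    }
    lines <- c(lines, sprintf("## %s", oc), "",
               "| group | day | min | q1 | median | q3 | max | n |",
               "|---|---|---|---|---|---|---|---|")
    cells <- split(d$value, list(d$group, d$day), drop = TRUE)
    for (nm in names(cells)) {
      b <- boxplot_stats(cells[[nm]])
      gd <- strsplit(nm, ".", fixed = TRUE)[[1]]
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %d |",
                                gd[1], gd[2], fmtn(b["min"]), fmtn(b["q1"]),
                                fmtn(b["median"]), fmtn(b["q3"]),
                                fmtn(b["max"]), as.integer(b["n"])))
    }
    res <- results[[oc]]
    if (is.null(res)) res <- nested_anova(d)
    lines <- c(lines, "", "ANOVA (type III, Satterthwaite df):", "",
               "| effect | F | df1 | df2 | p |", "|---|---|---|---|---|")
    for (i in seq_len(nrow(res$anova)))
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |",
                                res$anova$effect[i], fmtn(res$anova$F[i]),
                                fmtn(res$anova$df1[i]), fmtn(res$anova$df2[i]),
                                fmtn(res$anova$p[i])))
    if (!is.null(res$tukey)) {
      sig <- res$tukey[res$tukey$p.value < 0.05, , drop = FALSE]
      lines <- c(lines, "",
                 sprintf("Tukey HSD: %d of %d pairwise contrasts with p < 0.05.",
                         nrow(sig), nrow(res$tukey)))
    }
    if (res$fallback) lines <- c(lines, "",
                                 "(mouse-mean two-factor ANOVA fallback)")
    lines <- c(lines, "")
  }
  present <- outcomes[vapply(outcomes, function(oc)
    any(table$outcome_name == oc), logical(1))]
  if (length(present) >= 2) {
    lines <- c(lines, "## Correlations (per mouse-day means)", "",
               "| outcomes | R | p | n |", "|---|---|---|---|")
    wide <- stats::aggregate(value ~ mouse_id + day + outcome_name,
                             data = table[table$outcome_name %in% present, ],
                             FUN = mean)
    for (i in seq_len(length(present) - 1)) for (j in (i + 1):length(present)) {
      a <- wide[wide$outcome_name == present[i], ]
      b <- wide[wide$outcome_name == present[j], ]
      mg <- merge(a, b, by = c("mouse_id", "day"))
      if (nrow(mg) >= 3 && stats::var(mg$value.x) > 0 &&
          stats::var(mg$value.y) > 0) {
        pc <- pearson_correlation(mg$value.x, mg$value.y)
        lines <- c(lines, sprintf("| %s vs %s | %s | %s | %d |",
                                  present[i], present[j], fmtn(pc$R),
                                  fmtn(pc$p), pc$n))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
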