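# Study-design statistics: wound-size normalization, the nested two-factor
# mixed ANOVA with Tukey HSD, Pearson correlations, and per-animal standard
# errors.

#' Normalize wound areas to day 0
#'
#' @param areas numeric vector of wound areas
#' @param days day labels matching \code{areas}; must include day 0 with a
#'   positive area
#' @return data frame with \code{day} and \code{relative_area}
#'   (day 0 maps to 1)
#' @export
normalize_wound_size <- function(areas, days) {
  stopifnot(length(areas) == length(days))
  i0 <- which(days == 0)
  if (length(i0) != 1) stop("exactly one day-0 area is required")
  if (areas[i0] <= 0) stop("day-0 area must be positive")
  data.frame(day = days, relative_area = areas / areas[i0])
}

#' Normalized closure series from digitized tracings
#' @param tracings a \code{\link{generate_wound_tracings}} object
#' @return data frame from \code{\link{normalize_wound_size}}
#' @export
closure_from_tracings <- function(tracings) {
  normalize_wound_size(tracings$areas_mm2, tracings$days)
}

#' Simulate a long-format measurement table
#'
#' Builds per-(mouse, day, location) outcome values under random mouse
#' intercepts, location-within-mouse intercepts and residual noise, with an
#' optional fixed group-by-day effect surface — the generating model matching
#' the nested ANOVA design. With all effects zero this is the null model used
#' for type-I calibration.
#'
#' @param n_mice_per_group mice per group (groups: control, diabetic)
#' @param days imaging days
#' @param locations wound-edge locations nested in mouse
#' @param baseline grand mean
#' @param effect function(group, day) giving the fixed effect added to the
#'   cell mean, or a single number applied to (diabetic, max day)
#' @param sd_mouse,sd_location,sd_residual variance components (sd scale)
#' @param outcome_name label written into the table
#' @param seed RNG seed
#' @return data frame with columns mouse_id, group, day, location,
#'   outcome_name, value
#' @export
simulate_outcome_table <- function(n_mice_per_group = 6,
                                   days = c(1, 3, 5, 7, 10),
                                   locations = c("superior", "inferior",
                                                 "lateral"),
                                   baseline = 0.5, effect = 0,
                                   sd_mouse = 0.05, sd_location = 0.03,
                                   sd_residual = 0.05,
                                   outcome_name = "redox", seed = 1L) {
  set.seed(seed)
  if (!is.function(effect)) {
    delta <- effect
    effect <- function(group, day)
      ifelse(group == "diabetic" & day == max(days), delta, 0)
  }
  mice <- paste0("m", seq_len(2 * n_mice_per_group))
  group <- rep(c("control", "diabetic"), each = n_mice_per_group)
  b_mouse <- stats::rnorm(length(mice), 0, sd_mouse)
  names(b_mouse) <- mice
  tab <- expand.grid(mouse_id = mice, day = days, location = locations,
                     stringsAsFactors = FALSE)
  tab$group <- group[match(tab$mouse_id, mice)]
  loc_key <- interaction(tab$mouse_id, tab$location)
  b_loc <- stats::rnorm(nlevels(loc_key), 0, sd_location)
  tab$value <- baseline + effect(tab$group, tab$day) +
    b_mouse[tab$mouse_id] + b_loc[as.integer(loc_key)] +
    stats::rnorm(nrow(tab), 0, sd_residual)
  tab$outcome_name <- outcome_name
  rownames(tab) <- NULL
  tab[, c("mouse_id", "group", "day", "location", "outcome_name", "value")]
}

#' Two-factor nested mixed ANOVA
#'
#' Fits \code{value ~ group * day} with random intercepts for mouse and for
#' location nested within mouse, tests the fixed effects by type-III F tests
#' with Satterthwaite degrees of freedom, and runs Tukey HSD over the
#' group-by-day cell means. If the mixed model cannot be estimated the
#' analysis falls back (flagged) to a two-factor ANOVA on per-mouse cell
#' means; a constant outcome yields NA statistics without error.
#'
#' @param table long-format measurement table (see
#'   \code{\link{simulate_outcome_table}})
#' @param outcome outcome_name to analyze; \code{NULL} uses all rows
#' @param tukey compute the Tukey HSD table (skip for speed in simulations)
#' @return object of class \code{anova_result}: \code{anova} (effect, F, df,
#'   p), \code{varcomp}, \code{tukey}, \code{fallback}, \code{model}
#' @export
nested_anova <- function(table, outcome = NULL, tukey = TRUE) {
  d <- table
  if (!is.null(outcome)) d <- d[d$outcome_name == outcome, ]
  if (nrow(d) == 0) stop("no rows for the requested outcome")
  d$group <- factor(d$group)
  d$day <- factor(d$day)
  d$mouse_id <- factor(d$mouse_id)
  d$location <- factor(d$location)
  if (nlevels(d$group) < 2 || nlevels(d$day) < 2)
    stop("need at least 2 levels of group and day")
  if (min(table(unique(d[c("mouse_id", "group")])$group)) < 2)
    stop("need at least 2 mice per group")

  if (stats::var(d$value) == 0) {
    an <- data.frame(effect = c("group", "day", "group:day"),
                     F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                     p = NA_real_)
    return(structure(list(anova = an, varcomp = NULL, tukey = NULL,
                          fallback = TRUE, model = NULL,
                          note = "constant outcome; F undefined"),
                     class = "anova_result"))
  }

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ group * day + (1 | mouse_id) +
                       (1 | mouse_id:location), data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular =
                                                   lme4::.makeCC("ignore",
                                                                 tol = 1e-4)))
    )),
    error = function(e) NULL)

  if (!is.null(fit)) {
    av <- suppressMessages(suppressWarnings(stats::anova(fit)))
    an <- data.frame(effect = rownames(av), F = av$`F value`,
                     df1 = av$NumDF, df2 = av$DenDF, p = av$`Pr(>F)`)
    vc <- as.data.frame(lme4::VarCorr(fit))[, c("grp", "vcov")]
    tk <- NULL
    if (tukey) {
      em <- suppressMessages(emmeans::emmeans(fit, ~ group * day))
      tk <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                    adjust = "tukey")))
    }
    return(structure(list(anova = an, varcomp = vc, tukey = tk,
                          fallback = FALSE, model = fit),
                     class = "anova_result"))
  }

  # fallback: two-factor ANOVA on per-mouse cell means
  agg <- stats::aggregate(value ~ mouse_id + group + day, data = d, FUN = mean)
  fit2 <- stats::aov(value ~ group * day, data = agg)
  av <- summary(fit2)[[1]]
  eff <- trimws(rownames(av))
  sel <- eff %in% c("group", "day", "group:day")
  an <- data.frame(effect = eff[sel], F = av$`F value`[sel],
                   df1 = av$Df[sel],
                   df2 = av$Df[!sel][length(av$Df[!sel])],
                   p = av$`Pr(>F)`[sel])
  tk <- NULL
  if (tukey) {
    em <- suppressMessages(emmeans::emmeans(fit2, ~ group * day))
    tk <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                  adjust = "tukey")))
  }
  structure(list(anova = an, varcomp = NULL, tukey = tk, fallback = TRUE,
                 model = fit2),
            class = "anova_result")
}

#' Pearson correlation with the exact t-based test
#'
#' Sample Pearson R with the two-sided p-value from the t transform
#' \code{t = R sqrt((n-2)/(1-R^2))} on n-2 degrees of freedom (the null is
#' R = 0).
#'
#' @param x,y numeric vectors, n >= 3, each with nonzero variance
#' @return list with \code{R}, \code{p}, \code{n}
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Standard error from per-animal means
#'
#' sd of the per-animal mean values divided by the square root of the number
#' of animals — the error definition used for group summaries of repeated
#' within-animal measurements.
#'
#' @param values outcome values
#' @param mouse_id animal labels matching \code{values}
#' @return numeric standard error
#' @export
animal_level_se <- function(values, mouse_id) {
  m <- tapply(values, mouse_id, mean)
  stats::sd(m) / sqrt(length(m))
}
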