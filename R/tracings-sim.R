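# Synthetic wound-outline tracings over the healing time course.

#' Generate digitized wound tracings from a known closure curve
#'
#' Emulates tracing the wound outline onto acetate at each imaging day and
#' digitizing it: each day's outline is a closed polygon (vertices on a
#' jittered circle) whose area relative to day 0 equals the closure-curve
#' value to within the vertex-discretization error (< 1 percent).
#'
#' @param true_closure_curve per-day fraction of day-0 area, in (0, 1],
#'   with day 0 equal to 1
#' @param days integer day labels, must include 0
#' @param wound_diameter_mm day-0 wound diameter (6 mm biopsy punch)
#' @param n_vertices polygon vertices per tracing
#' @param noise_cv radial digitization noise CV
#' @param seed RNG seed
#' @return list of class \code{wound_tracings}: \code{polygons} (named list of
#'   (x, y) matrices, mm), \code{areas_mm2}, \code{days},
#'   \code{true_closure_curve}
#' @export
generate_wound_tracings <- function(true_closure_curve,
                                    days = c(0, 1, 3, 5, 7, 10),
                                    wound_diameter_mm = 6,
                                    n_vertices = 64L, noise_cv = 0.005,
                                    seed = 1L) {
  stopifnot(length(true_closure_curve) == length(days))
  if (!any(days == 0)) stop("days must include day 0")
  if (abs(true_closure_curve[days == 0] - 1) > 1e-12)
    stop("closure curve must equal 1 at day 0")
  if (any(true_closure_curve <= 0 | true_closure_curve > 1))
    stop("closure curve values must lie in (0, 1]")
  set.seed(seed)
  r0 <- wound_diameter_mm / 2
  polys <- vector("list", length(days))
  names(polys) <- paste0("day", days)
  areas <- numeric(length(days))
  for (i in seq_along(days)) {
    r <- r0 * sqrt(true_closure_curve[i])
    th <- 2 * pi * (seq_len(n_vertices) - 1) / n_vertices +
      stats::runif(n_vertices, -0.3, 0.3) * 2 * pi / n_vertices
    th <- sort(th %% (2 * pi))                 # keep the polygon simple
    rr <- r * (1 + stats::rnorm(n_vertices, 0, noise_cv))
    xy <- cbind(x = rr * cos(th), y = rr * sin(th))
    polys[[i]] <- xy
    areas[i] <- polygon_area(xy)
  }
  structure(list(polygons = polys, areas_mm2 = areas, days = days,
                 true_closure_curve = true_closure_curve),
            class = "wound_tracings")
}
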