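#' Water volume needed to reach a target soil-water 18O enrichment
#'
#' In vapor-equilibration labeling, isotopically enriched water placed in the
#' headspace of a sealed vial exchanges with the soil water through the vapor
#' phase until the two pools share one enrichment. The volume of water to add
#' follows from a simple two-pool mass balance:
#' \deqn{V = V_{sw} (at\%_{NA} - at\%_{target}) / (at\%_{target} - at\%_{added})}
#' where \eqn{V_{sw}} is the soil water volume, \eqn{at\%_{NA}} its natural
#' abundance of \eqn{^{18}}O, \eqn{at\%_{target}} the desired common
#' enrichment, and \eqn{at\%_{added}} the enrichment of the water added.
#'
#' @param v_soil_water soil water volume (µl), >= 0.
#' @param at_pct_na natural-abundance \eqn{^{18}}O of the soil water (atom %).
#' @param at_pct_target target soil-water enrichment (atom %).
#' @param at_pct_added enrichment of the added water (atom %).
#'
#' @return Volume of water to add (µl). Vectorized over its arguments.
#' @examples
#' # ~500 mg soil at 31.6% water content, label with 95 atom% water to ~70 atom%
#' water_volume_for_target(100, 0.2, 70, 95)
#' @seealso [mix_enrichment()] for the mass-balance check.
#' @export
water_volume_for_target <- function(v_soil_water, at_pct_na,
                                    at_pct_target, at_pct_added) {
  pct <- c(at_pct_na, at_pct_target, at_pct_added)
  if (any(!is.finite(c(v_soil_water, pct)))) {
    abort("all arguments must be finite numbers")
  }
  if (any(pct < 0 | pct > 100)) {
    abort("atom%% values must lie in [0, 100]")
  }
  if (any(v_soil_water < 0)) {
    abort("`v_soil_water` must be >= 0")
  }
  if (any(at_pct_added == at_pct_target)) {
    abort(paste(
      "degenerate dosing: added water has exactly the target enrichment,",
      "so no finite volume reaches the target"
    ))
  }
  v <- v_soil_water * (at_pct_na - at_pct_target) /
    (at_pct_target - at_pct_added)
  if (any(v < 0)) {
    abort(paste(
      "infeasible target: the requested enrichment cannot be reached by",
      "mixing with the added water (e.g. target above the added water's",
      "enrichment, or below natural abundance)"
    ))
  }
  v
}

#' Enrichment of a mixture of two water pools
#'
#' Volume-weighted mean enrichment, the mass-balance oracle for
#' [water_volume_for_target()].
#'
#' @param v1,v2 volumes (µl), non-negative, not both zero.
#' @param e1,e2 enrichments of the two pools (atom %).
#' @return Mixture enrichment (atom %). Vectorized.
#' @examples
#' mix_enrichment(100, 0.2, 279.2, 95)
#' @export
mix_enrichment <- function(v1, e1, v2, e2) {
  if (any(v1 < 0 | v2 < 0)) abort("volumes must be non-negative")
  if (any(v1 + v2 <= 0)) abort("empty mixture: both volumes are zero")
  (v1 * e1 + v2 * e2) / (v1 + v2)
}

#' Time-averaged enrichment of a saturating exponential curve
#'
#' Closed-form mean of \eqn{e(t) = a (1 - e^{-kt})} over \eqn{[0, T]}:
#' \deqn{\bar e = a \left(1 - \frac{1 - e^{-kT}}{kT}\right)}
#' evaluated by series for \eqn{kT < 10^{-8}} (limit \eqn{a kT / 2}) to avoid
#' 0/0.
#'
#' @param plateau fitted asymptote \eqn{a} (atom %).
#' @param rate fitted rate \eqn{k} (per hour), >= 0.
#' @param duration averaging window \eqn{T} (hours), > 0.
#' @return Mean enrichment (atom %). Vectorized.
#' @examples
#' mean_enrichment(70, 0.1, 120)
#' @export
mean_enrichment <- function(plateau, rate, duration) {
  if (any(rate < 0)) abort("`rate` must be >= 0")
  if (any(duration <= 0)) abort("`duration` must be > 0")
  kt <- rate * duration
  out <- ifelse(
    kt < 1e-8,
    plateau * kt / 2,
    plateau * (1 - (1 - exp(-kt)) / kt)
  )
  out
}

#' Fit soil-water 18O equilibration curves
#'
#' During vapor equilibration the soil-water enrichment rises from natural
#' abundance towards the headspace value following, empirically, a saturating
#' exponential \eqn{e(t) = a(1 - e^{-kt})}. Growth rates are referenced to the
#' *time-averaged* enrichment over the whole incubation, obtained from the
#' integral of the fitted curve. The curve is fitted in excess above zero (the
#' natural-abundance baseline of 0.2 atom% is negligible against labeled
#' values and is not modelled as an offset).
#'
#' One curve is fitted per level of the optional grouping column, mirroring
#' designs with one calibration series per treatment (or per tube).
#'
#' @param data data frame with columns `time_h` (hours, >= 0) and
#'   `atom_pct_18O` (atom %), plus the grouping column if `group` is given.
#' @param duration_h incubation duration over which to average (hours).
#' @param group optional name of a grouping column (string).
#'
#' @return An object of class `enrichment_fit`: a list with `curves`, a tibble
#'   with one row per group (`plateau` a, `rate` k, `mean_enrichment`,
#'   `rss`, `n`), plus `duration_h` and the fitted data. [tidy()] returns the
#'   per-group tibble, [glance()] a one-row summary and [autoplot()] the
#'   fitted curves.
#' @examples
#' tt <- c(3, 6, 24, 48)
#' d <- data.frame(time_h = tt, atom_pct_18O = 70 * (1 - exp(-0.1 * tt)))
#' fit <- fit_enrichment_curve(d, duration_h = 120)
#' tidy(fit)
#' @export
fit_enrichment_curve <- function(data, duration_h, group = NULL) {
  assert_cols(data, c("time_h", "atom_pct_18O"), "calibration data")
  if (!is.null(group)) assert_cols(data, group, "calibration data")
  if (any(data$atom_pct_18O < 0)) abort("enrichment values must be non-negative")
  if (any(data$time_h < 0)) abort("times must be non-negative")
  if (duration_h <= 0) abort("`duration_h` must be > 0")

  grp <- if (is.null(group)) rep("all", nrow(data)) else as.character(data[[group]])

  curves <- purrr::map_dfr(split(data, grp), function(df) {
    df <- df[order(df$time_h), , drop = FALSE]
    if (nrow(df) < 3) {
      abort("insufficient data: need at least 3 time points per curve")
    }
    fit_one_curve(df$time_h, df$atom_pct_18O, duration_h)
  }, .id = "group")

  structure(
    list(curves = tibble::as_tibble(curves), duration_h = duration_h,
         data = tibble::as_tibble(data.frame(group = grp, data))),
    class = "enrichment_fit"
  )
}

fit_one_curve <- function(times, values, duration_h) {
  if (all(values == 0)) {
    return(tibble::tibble(
      plateau = 0, rate = 0, mean_enrichment = 0, rss = 0, n = length(times)
    ))
  }
  if (max(values) - min(values) < .Machine$double.eps^0.5 * max(values)) {
    # flat at a > 0: the k -> Inf limit, mean equals the plateau
    a <- mean(values)
    return(tibble::tibble(
      plateau = a, rate = Inf, mean_enrichment = a,
      rss = sum((values - a)^2), n = length(times)
    ))
  }
  a0 <- max(values)
  k0 <- 1 / median(times[times > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ a * (1 - exp(-k * t)),
      data = data.frame(t = times, v = values),
      start = list(a = a0, k = k0),
      lower = c(a = 0, k = 0),
      upper = c(a = 100, k = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      abort(sprintf(
        "enrichment-curve fit failed (%s); residuals against the start values: %s",
        conditionMessage(e),
        paste(signif(values - a0 * (1 - exp(-k0 * times)), 4), collapse = ", ")
      ))
    }
  )
  cf <- coef(fit)
  tibble::tibble(
    plateau = unname(cf["a"]),
    rate = unname(cf["k"]),
    mean_enrichment = mean_enrichment(unname(cf["a"]), unname(cf["k"]),
                                      duration_h),
    rss = sum(resid(fit)^2),
    n = length(times)
  )
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("18O equilibration fit over %g h (%d curve(s))\n",
              x$duration_h, nrow(x$curves)))
  print(x$curves)
  invisible(x)
}

#' @rdname fit_enrichment_curve
#' @param x an `enrichment_fit` object.
#' @param ... unused.
#' @export
tidy.enrichment_fit <- function(x, ...) x$curves

#' @rdname fit_enrichment_curve
#' @method glance enrichment_fit
#' @export
glance.enrichment_fit <- function(x, ...) {
  tibble::tibble(
    n_curves = nrow(x$curves),
    duration_h = x$duration_h,
    mean_enrichment = mean(x$curves$mean_enrichment),
    total_rss = sum(x$curves$rss)
  )
}

#' @rdname fit_enrichment_curve
#' @param object an `enrichment_fit` object.
#' @method autoplot enrichment_fit
#' @export
autoplot.enrichment_fit <- function(object, ...) {
  tmax <- max(object$data$time_h, object$duration_h)
  pred <- purrr::map_dfr(seq_len(nrow(object$curves)), function(i) {
    cur <- object$curves[i, ]
    t <- seq(0, tmax, length.out = 200)
    tibble::tibble(
      group = cur$group, time_h = t,
      atom_pct_18O = cur$plateau * (1 - exp(-pmin(cur$rate * t, 700)))
    )
  })
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$atom_pct_18O,
                               colour = .data$group)) +
    ggplot2::geom_line(data = pred) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = object$curves,
      ggplot2::aes(yintercept = .data$mean_enrichment, colour = .data$group),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "Time (h)", y = expression({}^18 * O ~ "(atom %)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
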