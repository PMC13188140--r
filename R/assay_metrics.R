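#' Comet-assay tail DNA percentage
#'
#' `100 * tail_intensity / cell_intensity`, the fraction of a cell's DNA
#' fluorescence found in the comet tail.
#'
#' @param tail_intensity Tail DNA fluorescence (a.u., >= 0).
#' @param cell_intensity Whole-cell DNA fluorescence (a.u., > 0);
#'   must be >= `tail_intensity`.
#' @return Tail DNA percentage in \[0, 100\]. Vectorized.
#' @export
tail_dna_percent <- function(tail_intensity, cell_intensity) {
  if (any(cell_intensity <= 0)) stop("cell intensity must be positive", call. = FALSE)
  if (any(tail_intensity < 0)) stop("tail intensity must be non-negative", call. = FALSE)
  if (any(tail_intensity > cell_intensity)) {
    stop("tail intensity cannot exceed cell intensity", call. = FALSE)
  }
  100 * tail_intensity / cell_intensity
}

#' Comet-assay olive tail moment (ratio form)
#'
#' Computed as tail DNA percentage divided by the tail moment length —
#' the ratio form used by this pipeline's source quantification. Note the
#' conventional olive tail moment instead multiplies the tail DNA fraction
#' by the head-to-tail centroid distance; the ratio form is implemented
#' deliberately and is not interchangeable with the product form.
#'
#' @param tail_dna_pct Tail DNA percentage (see [tail_dna_percent()]).
#' @param tail_moment_length Tail moment length in micrometres (> 0).
#' @return Olive tail moment (a.u.). Vectorized.
#' @export
olive_tail_moment <- function(tail_dna_pct, tail_moment_length) {
  if (any(tail_moment_length <= 0)) stop("tail moment length must be positive", call. = FALSE)
  tail_dna_pct / tail_moment_length
}

#' Mitochondrial membrane potential from TMRM fluorescence
#'
#' End-point membrane potential relative to the fully depolarized (FCCP)
#' baseline: `f_treatment - f_fccp`.
#'
#' @param f_treatment TMRM fluorescence of the treated sample (a.u.).
#' @param f_fccp TMRM fluorescence after FCCP depolarization (a.u.).
#' @return Fluorescence difference (a.u.). Vectorized.
#' @export
delta_psi_m <- function(f_treatment, f_fccp) {
  f_treatment - f_fccp
}

#' Nanoparticle loading efficiency
#'
#' `100 * (total - free) / total`: the percentage of the loaded compound
#' retained in the vesicle fraction after removing the free compound
#' measured in the filtrate.
#'
#' @param total_nad Total compound amount (> 0).
#' @param free_nad_in_filtrate Free compound measured in the filtrate
#'   (0 <= free <= total).
#' @return Loading efficiency percentage in \[0, 100\]. Vectorized.
#' @export
loading_efficiency <- function(total_nad, free_nad_in_filtrate) {
  if (any(total_nad <= 0)) stop("total amount must be positive", call. = FALSE)
  if (any(free_nad_in_filtrate < 0)) stop("free amount must be non-negative", call. = FALSE)
  if (any(free_nad_in_filtrate > total_nad)) {
    stop("free amount cannot exceed total", call. = FALSE)
  }
  100 * (total_nad - free_nad_in_filtrate) / total_nad
}

#' Fit a logistic growth curve and the 95%-of-saturation time
#'
#' Least-squares fit of `N(t) = K / (1 + exp(-r (t - t0)))` to a cell-count
#' time series (Levenberg-Marquardt). The replicative-lifespan summary
#' `t95`, the time at which the curve reaches 95% of its carrying capacity,
#' follows in closed form: `0.95 K` implies `exp(-r (t - t0)) = 1/19`, so
#' `t95 = t0 + ln(19) / r`.
#'
#' Starting values: `K0 = 1.05 * max(count)`, `t0` at the time closest to
#' half of `K0`, and `r` from the slope of the logit-linearized early
#' phase.
#'
#' @param time_points Strictly increasing times (days); >= 4 points.
#' @param cell_counts Positive counts, same length.
#' @return Object of class `logistic_growth_fit` with elements `K`, `r`,
#'   `t0`, `t95`, the `nls`-like fit, and the data. Non-convergence and
#'   degenerate flat series raise errors.
#' @export
fit_logistic <- function(time_points, cell_counts) {
  if (length(time_points) != length(cell_counts)) stop("lengths differ", call. = FALSE)
  if (length(time_points) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(diff(time_points) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (any(cell_counts <= 0)) stop("counts must be positive", call. = FALSE)
  if (stats::sd(cell_counts) == 0) stop("degenerate flat series", call. = FALSE)

  K0 <- max(cell_counts) * 1.05
  t00 <- time_points[which.min(abs(cell_counts - K0 / 2))]
  lg <- log(cell_counts / (K0 - cell_counts))
  sl <- stats::coef(stats::lm(lg ~ time_points))[2]
  r0 <- max(as.numeric(sl), 1e-3)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      n ~ K / (1 + exp(-r * (t - t0))),
      data = data.frame(t = time_points, n = cell_counts),
      start = list(K = K0, r = r0, t0 = t00),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("logistic fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  if (!all(is.finite(cf)) || cf[["K"]] <= 0 || cf[["r"]] <= 0) {
    stop("logistic fit did not converge to a growth curve", call. = FALSE)
  }
  structure(list(
    K = unname(cf[["K"]]), r = unname(cf[["r"]]), t0 = unname(cf[["t0"]]),
    t95 = unname(cf[["t0"]] + log(19) / cf[["r"]]),
    fit = fit,
    data = tibble::tibble(time = time_points, count = cell_counts)
  ), class = "logistic_growth_fit")
}

#' @export
print.logistic_growth_fit <- function(x, ...) {
  cat(sprintf("Logistic growth fit: K = %.4g, r = %.4g /day, t0 = %.4g d, t95 = %.4g d\n",
              x$K, x$r, x$t0, x$t95))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `logistic_growth_fit`.
#' @param ... Unused.
#' @method tidy logistic_growth_fit
#' @export
tidy.logistic_growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std_error = s[, "Std. Error"])
}

#' @rdname fit_logistic
#' @method glance logistic_growth_fit
#' @export
glance.logistic_growth_fit <- function(x, ...) {
  tibble::tibble(K = x$K, r = x$r, t0 = x$t0, t95 = x$t95,
                 sigma = summary(x$fit)$sigma,
                 n = nrow(x$data))
}

#' @rdname fit_logistic
#' @method autoplot logistic_growth_fit
#' @export
autoplot.logistic_growth_fit <- function(object, ...) {
  grid <- tibble::tibble(time = seq(min(object$data$time), max(object$data$time),
                                    length.out = 200))
  grid$count <- object$K / (1 + exp(-object$r * (grid$time - object$t0)))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$t95, linetype = "dashed") +
    ggplot2::labs(x = "time (days)", y = "cell count",
                  subtitle = sprintf("t95 = %.2f days", object$t95)) +
    ggplot2::theme_minimal()
}

#' Classify mitochondrial skeleton lengths into morphology classes
#'
#' Fragmented below 3 um, intermediate in \[3, 8) um, elongated at and
#' above 8 um. The 8 um boundary belongs to the elongated class and 3 um to
#' intermediate.
#'
#' @param skeleton_length_um Skeleton lengths in micrometres (>= 0).
#' @return Factor with levels fragmented, intermediate, elongated.
#' @export
classify_mito_length <- function(skeleton_length_um) {
  if (any(skeleton_length_um < 0)) stop("lengths must be non-negative", call. = FALSE)
  cut(skeleton_length_um, breaks = c(-Inf, 3, 8, Inf), right = FALSE,
      labels = c("fragmented", "intermediate", "elongated"))
}

#' Morphology-class proportions of a mitochondrial population
#' @param lengths Non-empty vector of skeleton lengths (um).
#' @return Tibble: class, n, proportion (summing to 1).
#' @export
mito_fractions <- function(lengths) {
  if (!length(lengths)) stop("empty length list", call. = FALSE)
  cls <- classify_mito_length(lengths)
  tb <- table(cls)
  tibble::tibble(class = names(tb), n = as.integer(tb),
                 proportion = as.numeric(tb) / length(lengths))
}
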