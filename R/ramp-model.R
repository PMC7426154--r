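#' Bounded exponential ramp curve
#'
#' `y(x) = A C e^{Bx} / (A + C (e^{Bx} - 1))`: starts at the initial
#' content `C` at `x = 0` and saturates at the carrying capacity `A` as
#' `x` grows (for `B > 0`). Evaluated in a numerically stable form for
#' large `Bx`.
#'
#' @param x codon position, re-indexed so the first analyzed position
#'   (original position 2) is 0.
#' @param A carrying capacity (bonds/codon), > 0.
#' @param B rate (per codon position).
#' @param C initial content (bonds/codon), > 0.
#' @return numeric vector of bonds/codon.
#' @examples
#' bounded_exponential(0, A = 8, B = 0.2, C = 7)  # 7
#' bounded_exponential(5, A = 8, B = 0.2, C = 7)  # 7.600
#' @export
bounded_exponential <- function(x, A, B, C) {
  stopifnot(A > 0, C > 0)
  bx <- B * x
  out <- numeric(length(bx))
  pos <- bx > 0
  # for Bx > 0 divide through by e^{Bx} so nothing overflows
  out[pos] <- A * C / (A * exp(-bx[pos]) + C * (1 - exp(-bx[pos])))
  out[!pos] <- A * C * exp(bx[!pos]) / (A + C * (exp(bx[!pos]) - 1))
  out
}

#' Fit uniform, linear, and bounded exponential models to a profile
#'
#' Models the per-position mean (typically hydrogen bonds per codon) as a
#' function of codon position with three nested-complexity candidates:
#' uniform `y = A`, linear `y = Bx + C`, and the bounded exponential ramp.
#' Positions are re-indexed so the first analyzed position maps to
#' `x = 0`, making `C` the content at the first codon after the start
#' codon. Fits are (weighted) least squares; by default weights are the
#' inverse bootstrap variances of the positional means. The nonlinear fit
#' is initialised by a logistic-style self-start (`A0` = max mean, `C0` =
#' first mean, `B0` from log-linearised early positions) and run with a
#' Levenberg-Marquardt optimiser (max 1000 iterations). A failed nonlinear
#' fit is reported with `converged = FALSE` and parameters filled from
#' [fallback_parameters()].
#'
#' @param profile a `positional_profile` tibble (>= 10 positions).
#' @param weights `"inverse_variance"` (default; uses the profile's
#'   bootstrap `se`) or `"uniform"`.
#' @return an object of class `ramp_fits`: a named list of `ramp_fit`
#'   objects (`uniform`, `linear`, `bounded_exponential`), each with
#'   elements `model`, `params`, `std_errors`, `p_values`, `aic`, `bic`,
#'   `converged`, `fitted`.
#' @export
fit_models <- function(profile, weights = c("inverse_variance", "uniform")) {
  weights <- match.arg(weights)
  if (nrow(profile) < 10) {
    stop("profile too short to fit (need >= 10 positions)", call. = FALSE)
  }
  x <- profile$position - profile$position[1]
  y <- profile$mean
  w <- if (weights == "inverse_variance" && !is.null(profile$se) &&
           all(is.finite(profile$se)) && all(profile$se > 0)) {
    1 / profile$se^2
  } else {
    rep(1, length(y))
  }
  dat <- data.frame(x = x, y = y, w = w)

  fit_uniform <- lm(y ~ 1, data = dat, weights = w)
  fit_linear <- lm(y ~ x, data = dat, weights = w)

  mk <- function(model, params, se, p, obj, converged, fitted) {
    out <- list(model = model, params = params, std_errors = se,
                p_values = p, aic = if (converged) AIC(obj) else NA_real_,
                bic = if (converged) BIC(obj) else NA_real_,
                converged = converged, success = NA,
                fitted = fitted, x = x, positions = profile$position,
                observed = y)
    class(out) <- "ramp_fit"
    out
  }
  lm_fit <- function(obj, model, names_map) {
    sm <- summary(obj)$coefficients
    params <- setNames(sm[, 1], names_map)
    mk(model, params, setNames(sm[, 2], names_map),
       setNames(sm[, 4], names_map), obj, TRUE, unname(stats::fitted(obj)))
  }
  fits <- list(
    uniform = lm_fit(fit_uniform, "uniform", "A"),
    linear = lm_fit(fit_linear, "linear", c("C", "B"))
  )

  # self-start for the bounded exponential
  A0 <- max(y)
  C0 <- y[1]
  Ahat <- A0 * 1.001
  u <- 1 / pmax(y, 1e-9) - 1 / Ahat
  early <- which(u > 0 & x <= max(15, x[5]))
  B0 <- 0.1
  if (length(early) >= 3) {
    sl <- stats::coef(lm(log(u[early]) ~ x[early]))[2]
    if (is.finite(sl) && sl < 0) B0 <- min(max(-sl, 1e-3), 2)
  }
  nls_fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bounded_exponential(x, A, B, C),
      data = dat, weights = w,
      start = list(A = A0, B = B0, C = C0),
      lower = c(A = 1e-6, B = -5, C = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 1000, ptol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(nls_fit) && nls_fit$convInfo$isConv) {
    sm <- summary(nls_fit)$coefficients
    fits$bounded_exponential <- mk(
      "bounded_exponential",
      setNames(sm[, 1], rownames(sm)),
      setNames(sm[, 2], rownames(sm)),
      setNames(sm[, 4], rownames(sm)),
      nls_fit, TRUE, unname(stats::fitted(nls_fit)))
  } else {
    fb <- fallback_parameters(profile)
    fits$bounded_exponential <- mk(
      "bounded_exponential",
      c(A = unname(fb["carrying_capacity"]), B = NA_real_,
        C = unname(fb["initial_content"])),
      c(A = NA_real_, B = NA_real_, C = NA_real_),
      c(A = NA_real_, B = NA_real_, C = NA_real_),
      NULL, FALSE, rep(NA_real_, length(y)))
  }
  class(fits) <- "ramp_fits"
  fits
}

#' Select the best-fitting ramp model
#'
#' Returns the converged fit with the smallest AIC. The bounded
#' exponential's `success` flag is set to `TRUE` only when it converged,
#' wins under both AIC and BIC, and its rate parameter `B` has a Wald
#' p-value below `p_threshold`. An AIC/BIC disagreement is recorded in the
#' `aic_bic_agree` element of the selected fit.
#'
#' @param fits a `ramp_fits` collection from [fit_models()].
#' @param p_threshold Wald p-value threshold for the rate parameter
#'   (default 0.001).
#' @return the selected `ramp_fit`, with `success` and `aic_bic_agree` set.
#' @export
select_model <- function(fits, p_threshold = 0.001) {
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) < 1) stop("no converged fit", call. = FALSE)
  aics <- vapply(conv, function(f) f$aic, numeric(1))
  bics <- vapply(conv, function(f) f$bic, numeric(1))
  best_aic <- names(conv)[which.min(aics)]
  best_bic <- names(conv)[which.min(bics)]
  chosen <- conv[[best_aic]]
  chosen$aic_bic_agree <- identical(best_aic, best_bic)
  bexp <- fits$bounded_exponential
  chosen$success <-
    isTRUE(bexp$converged) &&
    identical(best_aic, "bounded_exponential") &&
    identical(best_bic, "bounded_exponential") &&
    is.finite(bexp$p_values["B"]) && bexp$p_values["B"] < p_threshold
  chosen
}

#' Fallback ramp parameters from a positional profile
#'
#' When the bounded exponential cannot be fitted, the initial content is
#' taken as the minimum positional mean and the carrying capacity as the
#' trimmed mean of positional means after dropping 10% of positions from
#' each end (10 + 10 positions on a 100-position profile).
#'
#' @param profile a `positional_profile` over at least 21 positions.
#' @return named numeric vector `initial_content`, `carrying_capacity`.
#' @export
fallback_parameters <- function(profile) {
  m <- profile$mean
  n <- length(m)
  if (n < 21) stop("profile too short to trim", call. = FALSE)
  trim <- if (n == 100) 10L else max(1L, floor(0.1 * n))
  kept <- m[(trim + 1):(n - trim)]
  c(initial_content = min(m), carrying_capacity = mean(kept))
}

#' @exportS3Method generics::tidy
tidy.ramp_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$std_errors[names(x$params)]),
    p.value = unname(x$p_values[names(x$params)])
  )
}

#' @exportS3Method generics::glance
glance.ramp_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    aic = x$aic,
    bic = x$bic,
    converged = x$converged,
    success = isTRUE(x$success)
  )
}

#' @exportS3Method generics::tidy
tidy.ramp_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), tidy))
}

#' @exportS3Method generics::glance
glance.ramp_fits <- function(x, ...) {
  dplyr::bind_rows(lapply(unclass(x), glance))
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat("ramp_fit:", x$model,
      if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  print(round(x$params, 4))
  cat("AIC:", format(x$aic), " BIC:", format(x$bic), "\n")
  invisible(x)
}

#' @export
print.ramp_fits <- function(x, ...) {
  print(glance(x))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ramp_fits <- function(object, ...) {
  obs <- tibble::tibble(position = object$uniform$positions,
                        mean = object$uniform$observed)
  curves <- dplyr::bind_rows(lapply(unclass(object), function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    tibble::tibble(position = f$positions, fitted = f$fitted,
                   model = f$model)
  }))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$position, y = .data$mean)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$fitted, colour = .data$model)) +
    ggplot2::labs(x = "codon position", y = "mean hydrogen bonds / codon",
                  colour = "model") +
    ggplot2::theme_minimal()
}
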