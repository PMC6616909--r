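#' Equilibrium moisture content dataset
#'
#' Container for (water activity, moisture) observations at one temperature.
#'
#' @param a_w Water activities, distinct, each strictly inside (0, 1).
#' @param moisture Equilibrium moisture contents, \% dry basis, > 0.
#' @param temperature_C Temperature of the isotherm, degrees Celsius.
#' @param label Dataset label.
#' @return An object of class \code{"isotherm_data"}: a data frame with
#'   columns \code{a_w} and \code{moisture_db_percent}, sorted by \code{a_w}.
#' @export
isotherm_data <- function(a_w, moisture, temperature_C = NA_real_,
                          label = "dataset") {
  a_w <- as.numeric(a_w); moisture <- as.numeric(moisture)
  if (length(a_w) != length(moisture))
    stop("a_w and moisture must have equal length", call. = FALSE)
  if (anyNA(a_w) || anyNA(moisture))
    stop("missing values are not allowed", call. = FALSE)
  if (any(a_w <= 0) || any(a_w >= 1))
    stop("a_w values must lie strictly inside (0, 1)", call. = FALSE)
  if (anyDuplicated(a_w))
    stop("a_w values must be distinct", call. = FALSE)
  if (any(moisture <= 0))
    stop("moisture values must be > 0 (% dry basis)", call. = FALSE)
  o <- order(a_w)
  out <- data.frame(a_w = a_w[o], moisture_db_percent = moisture[o])
  attr(out, "temperature_C") <- temperature_C
  attr(out, "label") <- label
  class(out) <- c("isotherm_data", "data.frame")
  out
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SSE/SST} with the total sum of squares taken about the
#' mean of the observations (the convention also used for nonlinear fits).
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A single number \eqn{\le 1}.
#' @export
r_squared <- function(y, yhat) {
  .check_pair(y, yhat, min_n = 2L)
  sst <- sum((y - mean(y))^2)
  if (sst == 0)
    stop("undefined variance: observations are constant", call. = FALSE)
  1 - sum((y - yhat)^2) / sst
}

#' Standard error of the model
#'
#' \eqn{s = \sqrt{\sum (y_i - \hat y_i)^2 / (n - 2)}}, in \% dry basis. The
#' divisor is held at \eqn{n - 2} for every model, including the
#' three-parameter GAB, matching the single printed formula used for all
#' seven equations.
#'
#' @inheritParams r_squared
#' @return Standard error, \% dry basis.
#' @export
std_error <- function(y, yhat) {
  .check_pair(y, yhat, min_n = 3L)
  sqrt(sum((y - yhat)^2) / (length(y) - 2))
}

#' Mean relative error
#'
#' \eqn{MRE = \frac{100}{n} \sum |y_i - \hat y_i| / y_i}, in percent, with
#' the measured value in the denominator. Fits with MRE below about 10\% are
#' conventionally considered good.
#'
#' @inheritParams r_squared
#' @return MRE in percent.
#' @export
mean_relative_error <- function(y, yhat) {
  .check_pair(y, yhat, min_n = 1L)
  if (any(y == 0))
    stop("mean relative error is undefined for zero observations",
         call. = FALSE)
  100 / length(y) * sum(abs((y - yhat) / y))
}

.check_pair <- function(y, yhat, min_n) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) < min_n)
    stop("need at least ", min_n, " observations", call. = FALSE)
  invisible(TRUE)
}

# Penalized residual vector for the optimizer: out-of-domain or non-finite
# predictions get a large finite penalty so Levenberg-Marquardt backs off.
.residual_fun <- function(model, a_w, y) {
  function(theta) {
    ok <- model$domain(a_w, theta)
    pred <- rep(NA_real_, length(a_w))
    if (any(ok)) pred[ok] <- model$fun(a_w[ok], theta)
    r <- y - pred
    bad <- !is.finite(r)
    r[bad] <- 1e6
    r
  }
}

# Deterministic jitter factors for multi-start (no RNG involvement).
.jitter_factors <- rbind(c(0.5, 0.5, 0.5), c(2, 2, 2), c(0.5, 2, 0.5),
                         c(2, 0.5, 2), c(1.5, 0.75, 1.5))

.lm_converged <- function(info) info %in% c(1L, 2L, 3L)

.run_nls <- function(model, a_w, y, init) {
  fn <- .residual_fun(model, a_w, y)
  fit <- minpack.lm::nls.lm(
    par = init, lower = model$lower, upper = model$upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxfev = 2000L, maxiter = 1000L, ftol = 1e-10, ptol = 1e-10))
  list(par = fit$par, sse = sum(fn(fit$par)^2),
       converged = .lm_converged(fit$info))
}

#' Fit an isotherm equation to EMC data
#'
#' Minimizes \eqn{\sum_i (y_i - M(a_{w,i}; \theta))^2} by bounded
#' Levenberg-Marquardt least squares, starting from \code{init} (default:
#' the model's default start). If the first attempt does not converge, five
#' deterministically jittered starts are tried and the best sum of squares
#' kept. All four comparison criteria and the residual-pattern verdict are
#' computed at the solution.
#'
#' @param model An \code{\link{isotherm_model}} or its name.
#' @param data An \code{\link{isotherm_data}} (or data frame with columns
#'   \code{a_w} and \code{moisture_db_percent}).
#' @param init Optional starting parameter vector within the model bounds.
#' @param compute_press Compute leave-one-out PRESS (default TRUE); requires
#'   \eqn{n \ge} number of parameters + 2.
#' @return An object of class \code{"isotherm_fit"}: list with elements
#'   \code{model}, \code{params} (named), \code{r_squared}, \code{std_error},
#'   \code{mre}, \code{press}, \code{residuals} (ordered by \eqn{a_w}),
#'   \code{pattern_verdict} (\code{"uniform"} or \code{"pattern"}, NA when
#'   fewer than 6 nonzero residuals), \code{converged}, \code{fitted},
#'   \code{data}.
#' @examples
#' d <- simulate_isotherm("caurie", c(2, 3), n = 12, noise_sd = 0.2,
#'                        seed = 42)[[1]]
#' fit_isotherm("caurie", d)
#' @export
fit_isotherm <- function(model, data, init = NULL, compute_press = TRUE) {
  model <- .as_model(model)
  data <- .as_isotherm_data(data)
  a_w <- data$a_w
  y <- data$moisture_db_percent
  n <- length(y)
  if (n < model$n_params + 1L)
    stop("need at least ", model$n_params + 1L, " points to fit the ",
         model$name, " model", call. = FALSE)
  if (is.null(init)) {
    init <- model$default_init
  } else {
    init <- .check_params(model, init)
    if (any(init < model$lower) || any(init > model$upper))
      stop("init is outside the model bounds", call. = FALSE)
  }

  best <- .run_nls(model, a_w, y, init)
  if (!best$converged) {
    for (j in seq_len(nrow(.jitter_factors))) {
      fac <- .jitter_factors[j, seq_len(model$n_params)]
      start <- pmin(pmax(init * fac, model$lower), model$upper)
      cand <- .run_nls(model, a_w, y, start)
      if (cand$converged && (!best$converged || cand$sse < best$sse))
        best <- cand
      if (!cand$converged && cand$sse < best$sse && !best$converged)
        best <- cand
    }
  }

  theta <- stats::setNames(best$par, model$param_names)
  ok <- model$domain(a_w, theta)
  fitted <- rep(NA_real_, n)
  if (any(ok)) fitted[ok] <- model$fun(a_w[ok], theta)
  res <- y - fitted

  verdict <- NA_character_
  nz <- res[is.finite(res) & res != 0]
  if (length(nz) >= 6L) verdict <- residual_pattern(nz)

  out <- structure(list(
    model = model, params = theta,
    r_squared = r_squared(y, fitted),
    std_error = std_error(y, fitted),
    mre = mean_relative_error(y, fitted),
    press = NA_real_,
    residuals = res, pattern_verdict = verdict,
    converged = best$converged, fitted = fitted, data = data
  ), class = "isotherm_fit")
  if (compute_press && n >= model$n_params + 2L)
    out$press <- press(model, data, out)
  out
}

.as_isotherm_data <- function(data) {
  if (inherits(data, "isotherm_data")) return(data)
  if (is.data.frame(data) &&
      all(c("a_w", "moisture_db_percent") %in% names(data)))
    return(isotherm_data(data$a_w, data$moisture_db_percent))
  stop("data must be an isotherm_data object or a data frame with ",
       "columns a_w and moisture_db_percent", call. = FALSE)
}

#' @export
print.isotherm_fit <- function(x, digits = 4, ...) {
  cat("Isotherm fit:", x$model$name,
      if (!x$converged) "(optimizer did not report convergence)", "\n")
  print(round(x$params, digits))
  cat(sprintf("R2 = %.4f  s = %.4f %%d.b.  MRE = %.4f %%  PRESS = %s\n",
              x$r_squared, x$std_error, x$mre,
              ifelse(is.na(x$press), "NA", sprintf("%.4f", x$press))))
  cat("residual plot:", ifelse(is.na(x$pattern_verdict), "n/a",
                               x$pattern_verdict), "\n")
  invisible(x)
}

#' Leave-one-out PRESS
#'
#' Predicted error sum of squares: each observation is withheld in turn, the
#' model refit on the remaining \eqn{n - 1} points (warm-started at the
#' full-data parameters), and the withheld point predicted; PRESS is the sum
#' of squared leave-one-out prediction errors
#' \eqn{\sum_i (y_i - \hat y_{-i})^2}.
#'
#' @inheritParams fit_isotherm
#' @param fitted An \code{isotherm_fit} for the same model and data (fit
#'   internally when omitted).
#' @return PRESS in (\% dry basis)^2, with attribute
#'   \code{"loo_converged"} (logical vector of refit statuses).
#' @export
press <- function(model, data, fitted = NULL) {
  model <- .as_model(model)
  data <- .as_isotherm_data(data)
  n <- nrow(data)
  if (n < model$n_params + 2L)
    stop("PRESS needs at least ", model$n_params + 2L, " points",
         call. = FALSE)
  if (is.null(fitted))
    fitted <- fit_isotherm(model, data, compute_press = FALSE)
  warm <- as.numeric(fitted$params)
  e <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    fi <- .run_nls(model, data$a_w[-i], data$moisture_db_percent[-i], warm)
    conv[i] <- fi$converged
    th <- fi$par
    pred <- if (model$domain(data$a_w[i], th))
      model$fun(data$a_w[i], th) else NA_real_
    e[i] <- data$moisture_db_percent[i] - pred
  }
  if (anyNA(e))
    stop("a leave-one-out refit predicted outside the model domain",
         call. = FALSE)
  structure(sum(e^2), loo_converged = conv)
}

#' Runs test for residual sign patterns
#'
#' Wald-Wolfowitz runs test on the signs of residuals ordered by water
#' activity. Under a correctly specified model the signs are exchangeable;
#' lack of fit shows up as sign clustering, i.e. too few runs. For fewer
#' than 20 nonzero residuals the exact conditional null distribution of the
#' number of runs given the sign counts is used; otherwise the normal
#' approximation with continuity correction.
#'
#' @param x Residuals ordered by \eqn{a_w}; exact zeros are dropped.
#' @param alternative \code{"fewer"} (default, clustering / lack of fit) or
#'   \code{"two.sided"}.
#' @return List with \code{runs}, \code{n_pos}, \code{n_neg},
#'   \code{p_value}.
#' @export
runs_test <- function(x, alternative = c("fewer", "two.sided")) {
  alternative <- match.arg(alternative)
  s <- sign(x[x != 0])
  n <- length(s)
  if (n < 6L)
    stop("runs test needs at least 6 nonzero residuals", call. = FALSE)
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  r <- 1L + sum(s[-1] != s[-n])
  if (n1 == 0L || n2 == 0L)
    return(list(runs = r, n_pos = n1, n_neg = n2, p_value = 0))
  if (n < 20L) {
    pmf <- .runs_pmf(n1, n2)
    lower <- sum(pmf[as.integer(names(pmf)) <= r])
    upper <- sum(pmf[as.integer(names(pmf)) >= r])
    p <- if (alternative == "fewer") lower else min(1, 2 * min(lower, upper))
  } else {
    mu <- 2 * n1 * n2 / n + 1
    sg <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
    z <- (r + 0.5 - mu) / sg
    p <- if (alternative == "fewer") stats::pnorm(z)
    else min(1, 2 * min(stats::pnorm(z),
                        stats::pnorm((r - 0.5 - mu) / sg,
                                     lower.tail = FALSE)))
  }
  list(runs = r, n_pos = n1, n_neg = n2, p_value = p)
}

# Exact conditional pmf of the number of runs given n1 positives and n2
# negatives; names are the run counts.
.runs_pmf <- function(n1, n2) {
  rs <- 2:(n1 + n2)
  p <- vapply(rs, function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (r - 1) / 2
      choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
        choose(n1 - 1, k) * choose(n2 - 1, k - 1)
    }
  }, numeric(1)) / choose(n1 + n2, n1)
  stats::setNames(p, rs)
}

#' Residual-pattern adequacy verdict
#'
#' Operationalizes the visual residual-plot criterion: a model is adequate
#' when its residuals, ordered by water activity, scatter without systematic
#' sign clustering. Residual signs with all one sign, or significantly fewer
#' runs than expected under exchangeability (runs test, \eqn{\alpha = 0.05}),
#' yield \code{"pattern"}; otherwise \code{"uniform"}.
#'
#' @param residuals Residuals ordered by \eqn{a_w}; exact zeros are dropped.
#' @param alpha Significance level, default 0.05.
#' @return \code{"uniform"} or \code{"pattern"}.
#' @examples
#' residual_pattern(c(1, -1, 1, -1, 1, -1, 1, -1))   # uniform
#' residual_pattern(c(1, 1, 1, 1, -1, -1, -1, -1))   # pattern
#' @export
residual_pattern <- function(residuals, alpha = 0.05) {
  rt <- runs_test(residuals, alternative = "fewer")
  if (rt$n_pos == 0L || rt$n_neg == 0L) return("pattern")
  if (rt$p_value < alpha) "pattern" else "uniform"
}

#' Fit and rank all candidate models
#'
#' Fits each model to the dataset and tabulates parameters, the four
#' criteria and the residual verdict, ranked by PRESS ascending with ties
#' broken by MRE then standard error.
#'
#' @param data An \code{\link{isotherm_data}}.
#' @param models Character vector of model names; default all seven.
#' @return A data frame of class \code{"model_comparison"} with columns
#'   \code{model}, \code{parameters}, \code{r_squared}, \code{std_error},
#'   \code{mre}, \code{press}, \code{residual_plot}, \code{converged}; the
#'   individual \code{isotherm_fit} objects are attached as attribute
#'   \code{"fits"}.
#' @examples
#' d <- simulate_isotherm("caurie", c(1.87, 2.60), n = 12, noise_sd = 0.2,
#'                        seed = 7)[[1]]
#' compare_models(d, c("caurie", "henderson", "oswin"))
#' @export
compare_models <- function(data, models = model_names()) {
  data <- .as_isotherm_data(data)
  if (length(models) < 1L) stop("need at least one model", call. = FALSE)
  fits <- lapply(models, function(m) fit_isotherm(m, data))
  names(fits) <- models
  tab <- data.frame(
    model = models,
    parameters = vapply(fits, function(f)
      paste(names(f$params), round(f$params, 4), sep = " = ",
            collapse = ", "), character(1)),
    r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
    std_error = vapply(fits, function(f) f$std_error, numeric(1)),
    mre = vapply(fits, function(f) f$mre, numeric(1)),
    press = vapply(fits, function(f) f$press, numeric(1)),
    residual_plot = vapply(fits, function(f)
      ifelse(is.na(f$pattern_verdict), "n/a", f$pattern_verdict),
      character(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$press, tab$mre, tab$std_error), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Isotherm model comparison (ranked by PRESS):\n")
  y <- as.data.frame(x)
  y$r_squared <- round(y$r_squared, digits)
  y$std_error <- round(y$std_error, digits)
  y$mre <- round(y$mre, digits)
  y$press <- round(y$press, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
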