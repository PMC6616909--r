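#' The seven classical EMC/water-activity equations
#'
#' Moisture sorption isotherm equations relating equilibrium moisture
#' content M (\% dry basis) to water activity \eqn{a_w} (decimal):
#' \describe{
#'   \item{henderson}{\eqn{M = a_0 (-\ln(1-a_w))^{a_1}}}
#'   \item{chung_pfost}{\eqn{M = b_0 + b_1 \ln(-\ln a_w)}}
#'   \item{halsey}{\eqn{M = c_0 (-1/\ln a_w)^{c_1}}}
#'   \item{oswin}{\eqn{M = d_0 (a_w/(1-a_w))^{d_1}}}
#'   \item{white_eirig}{\eqn{M = 1/(e_0 + e_1 a_w)}}
#'   \item{caurie}{\eqn{M = f_0 e^{f_1 a_w}}}
#'   \item{gab}{\eqn{M = A B C a_w / ((1-B a_w)(1-B a_w + B C a_w))}}
#' }
#' All are two-parameter except GAB (three). Each specification carries its
#' parameter names, default starting values for least-squares fitting,
#' box bounds and an \eqn{a_w} domain.
#'
#' @param name Model name (partial matching is not performed).
#' @return An object of class \code{"isotherm_model"}: a list with elements
#'   \code{name}, \code{param_names}, \code{n_params}, \code{default_init},
#'   \code{lower}, \code{upper} and the closed forms \code{fun(a_w, theta)}
#'   and \code{inverse(M, theta)}.
#' @examples
#' m <- isotherm_model("caurie")
#' m$fun(0.5, c(1.8739, 2.6012))
#' @seealso [evaluate_isotherm()], [inverse_aw()], [fit_isotherm()]
#' @export
isotherm_model <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% model_names())
    stop("unknown isotherm model '", paste(name, collapse = ","),
         "'; available: ", paste(model_names(), collapse = ", "),
         call. = FALSE)
  spec <- .model_registry[[name]]
  structure(c(list(name = name), spec,
              list(n_params = length(spec$param_names))),
            class = "isotherm_model")
}

#' @rdname isotherm_model
#' @export
model_names <- function() names(.model_registry)

#' @export
print.isotherm_model <- function(x, ...) {
  cat("Isotherm model:", x$name, "\n")
  cat("parameters:", paste(x$param_names, collapse = ", "),
      " (default start:", paste(x$default_init, collapse = ", "), ")\n")
  invisible(x)
}

# Domain guards return TRUE where a_w is admissible for the parameter set.
.model_registry <- list(
  henderson = list(
    param_names = c("a0", "a1"),
    default_init = c(10, 1), lower = c(1e-8, 1e-8), upper = c(Inf, Inf),
    domain = function(a_w, th) a_w >= 0 & a_w < 1,
    fun = function(a_w, th) th[1] * (-log1p(-a_w))^th[2],
    inverse = function(M, th) -expm1(-(M / th[1])^(1 / th[2]))
  ),
  chung_pfost = list(
    param_names = c("b0", "b1"),
    default_init = c(5, -6), lower = c(-Inf, -Inf), upper = c(Inf, Inf),
    domain = function(a_w, th) a_w > 0 & a_w < 1,
    fun = function(a_w, th) th[1] + th[2] * log(-log(a_w)),
    inverse = function(M, th) exp(-exp((M - th[1]) / th[2]))
  ),
  halsey = list(
    param_names = c("c0", "c1"),
    default_init = c(6, 0.7), lower = c(1e-8, 1e-8), upper = c(Inf, Inf),
    domain = function(a_w, th) a_w > 0 & a_w < 1,
    fun = function(a_w, th) th[1] * (-1 / log(a_w))^th[2],
    inverse = function(M, th) exp(-(th[1] / M)^(1 / th[2]))
  ),
  oswin = list(
    param_names = c("d0", "d1"),
    default_init = c(7, 0.6), lower = c(1e-8, 1e-8), upper = c(Inf, Inf),
    domain = function(a_w, th) a_w >= 0 & a_w < 1,
    fun = function(a_w, th) th[1] * (a_w / (1 - a_w))^th[2],
    inverse = function(M, th) {
      r <- (M / th[1])^(1 / th[2])
      r / (1 + r)
    }
  ),
  white_eirig = list(
    param_names = c("e0", "e1"),
    default_init = c(0.25, -0.2), lower = c(-Inf, -Inf), upper = c(Inf, Inf),
    domain = function(a_w, th) abs(th[1] + th[2] * a_w) > 1e-12,
    fun = function(a_w, th) 1 / (th[1] + th[2] * a_w),
    inverse = function(M, th) (1 / M - th[1]) / th[2]
  ),
  caurie = list(
    param_names = c("f0", "f1"),
    default_init = c(2, 3), lower = c(1e-8, -Inf), upper = c(Inf, Inf),
    domain = function(a_w, th) a_w >= 0 & a_w < 1,
    fun = function(a_w, th) th[1] * exp(th[2] * a_w),
    inverse = function(M, th) log(M / th[1]) / th[2]
  ),
  gab = list(
    param_names = c("A", "B", "C"),
    default_init = c(8, 0.7, 10), lower = c(1e-8, 1e-6, 1e-8),
    upper = c(Inf, 1.2, Inf),
    domain = function(a_w, th) th[2] * a_w < 1,
    fun = function(a_w, th) {
      u <- th[2] * a_w
      th[1] * th[3] * u / ((1 - u) * (1 - u + th[3] * u))
    },
    # M is quadratic in u = B * a_w; take the root in (0, 1)
    inverse = function(M, th) {
      A <- th[1]; B <- th[2]; C <- th[3]
      qa <- M * (1 - C)
      qb <- -(2 * M - M * C + A * C)
      qc <- M
      if (abs(qa) < 1e-14) {
        u <- -qc / qb
      } else {
        disc <- qb^2 - 4 * qa * qc
        if (disc < 0) stop("M outside the range of the GAB model",
                           call. = FALSE)
        roots <- (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
        u <- roots[roots > 0 & roots < 1]
        if (length(u) != 1L) u <- min(roots[roots > 0])
      }
      u / B
    }
  )
)

#' Evaluate an isotherm equation
#'
#' Closed-form equilibrium moisture content of one of the seven models at
#' given water activities, with the model's \eqn{a_w} domain enforced
#' (e.g. \eqn{B a_w < 1} for GAB, \eqn{a_w \in (0,1)} for Chung-Pfost).
#'
#' @param model An \code{\link{isotherm_model}} or its name.
#' @param params Numeric parameter vector in the model's parameter order.
#' @param a_w Water activities (decimal).
#' @return Moisture content, \% dry basis.
#' @examples
#' evaluate_isotherm("chung_pfost", c(5.5080, -6.1120), exp(-1))
#' @export
evaluate_isotherm <- function(model, params, a_w) {
  model <- .as_model(model)
  params <- .check_params(model, params)
  ok <- model$domain(a_w, params)
  if (!all(ok))
    stop("a_w = ", paste(format(a_w[!ok]), collapse = ", "),
         " violates the domain of the ", model$name, " model",
         call. = FALSE)
  model$fun(a_w, params)
}

#' Invert an isotherm equation
#'
#' Water activity at which the model takes moisture content \code{M}. All
#' seven equations invert in closed form; the result round-trips through
#' [evaluate_isotherm()] to near machine precision.
#'
#' @inheritParams evaluate_isotherm
#' @param M Moisture content, \% dry basis, inside the model's range.
#' @return Water activity (decimal).
#' @export
inverse_aw <- function(model, params, M) {
  model <- .as_model(model)
  params <- .check_params(model, params)
  a <- vapply(M, function(m) model$inverse(m, params), numeric(1))
  bad <- !is.finite(a) | a < 0 | a >= 1
  if (any(bad))
    stop("M = ", paste(format(M[bad]), collapse = ", "),
         " is outside the range of the ", model$name, " model",
         call. = FALSE)
  a
}

.as_model <- function(model) {
  if (inherits(model, "isotherm_model")) model else isotherm_model(model)
}

.check_params <- function(model, params) {
  params <- as.numeric(params)
  if (length(params) != model$n_params || any(!is.finite(params)))
    stop(model$name, " expects ", model$n_params,
         " finite parameters (", paste(model$param_names, collapse = ", "),
         ")", call. = FALSE)
  params
}

#' Published fitted parameter sets
#'
#' Long-format table of the fitted parameters of all seven models for the
#' two herbs at five temperatures, as shipped in
#' \code{inst/extdata/fitted_parameters.csv}: columns \code{product},
#' \code{temperature_C}, \code{model}, \code{param}, \code{value}.
#'
#' @param product,model,temperature_C Optional filters.
#' @return A data frame.
#' @examples
#' fitted_parameter_table(product = "C. morifolium flower",
#'                        model = "caurie", temperature_C = 5)
#' @export
fitted_parameter_table <- function(product = NULL, model = NULL,
                                   temperature_C = NULL) {
  path <- system.file("extdata", "fitted_parameters.csv",
                      package = "isocomp", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(product)) df <- df[df$product %in% product, ]
  if (!is.null(model)) df <- df[df$model %in% model, ]
  if (!is.null(temperature_C)) df <- df[df$temperature_C %in% temperature_C, ]
  rownames(df) <- NULL
  df
}

#' @rdname fitted_parameter_table
#' @details \code{published_params()} returns one parameter vector (ordered
#'   as the model expects) for a single product/model/temperature.
#' @export
published_params <- function(product, model, temperature_C) {
  df <- fitted_parameter_table(product, model, temperature_C)
  spec <- isotherm_model(model)
  if (nrow(df) != spec$n_params)
    stop("no unique published parameter set for ", product, " / ", model,
         " / ", temperature_C, " degC", call. = FALSE)
  stats::setNames(df$value[match(spec$param_names, df$param)],
                  spec$param_names)
}
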