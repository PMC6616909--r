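#' Simulate equilibrium-relative-humidity datasets
#'
#' Generates (water activity, moisture) datasets with the statistical
#' structure the fitting tools assume: moisture from a generating isotherm
#' plus additive homoscedastic Gaussian noise, truncated at 0.01 \% dry
#' basis so moistures stay positive. This emulates hygrometric (ERH)
#' measurements, whose dominant error is sensor scatter mapping to the
#' moisture axis; it does not emulate temperature drift, hysteresis or
#' heteroscedastic high-humidity error.
#'
#' @param model An \code{\link{isotherm_model}} or its name.
#' @param params Generating parameter vector.
#' @param a_w_grid Explicit water-activity grid; overrides
#'   \code{a_w_range}/\code{n}.
#' @param a_w_range Two-element range of the grid; default \code{c(0.1,
#'   0.9)}, the span typical of ERH studies.
#' @param n Number of evenly spaced grid points; default 15.
#' @param noise_sd Gaussian noise standard deviation, \% dry basis; default
#'   0.3, the moisture-axis scatter implied by a calibrated hygrometer
#'   (about \eqn{\pm 0.7} \%RH) through a typical isotherm slope.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param replicates Number of datasets to generate.
#' @param temperature_C Temperature recorded on the datasets.
#' @return A list of \code{replicates} \code{\link{isotherm_data}} objects.
#' @examples
#' simulate_isotherm("caurie", c(2, 3), n = 9, noise_sd = 0, seed = 1)[[1]]
#' @export
simulate_isotherm <- function(model, params, a_w_grid = NULL,
                              a_w_range = c(0.1, 0.9), n = 15,
                              noise_sd = 0.3, seed = NULL, replicates = 1,
                              temperature_C = 25) {
  model <- .as_model(model)
  params <- .check_params(model, params)
  grid <- .build_grid(a_w_grid, a_w_range, n)
  ok <- model$domain(grid, params)
  if (!all(ok))
    stop("grid point a_w = ", paste(format(grid[!ok]), collapse = ", "),
         " is outside the domain of the ", model$name, " generator",
         call. = FALSE)
  truth <- model$fun(grid, params)
  .simulate_noise(grid, truth, noise_sd, seed, replicates, temperature_C,
                  label = paste0("simulated:", model$name))
}

#' Simulate data from the component model
#'
#' Same noise contract as [simulate_isotherm()], with the composition-driven
#' component model as the generating curve. Enables end-to-end comparisons
#' of composition-based predictions against equation fits.
#'
#' @param comp A \code{\link{composition}}.
#' @inheritParams simulate_isotherm
#' @inheritParams predict_isotherm
#' @return A list of \code{replicates} \code{\link{isotherm_data}} objects.
#' @export
simulate_from_composition <- function(comp, a_w_grid = NULL,
                                      a_w_range = c(0.1, 0.9), n = 15,
                                      noise_sd = 0.3, seed = NULL,
                                      replicates = 1, temperature_C = 25,
                                      exp_sign = c("pos", "neg")) {
  stopifnot(inherits(comp, "composition"))
  exp_sign <- match.arg(exp_sign)
  grid <- .build_grid(a_w_grid, a_w_range, n)
  truth <- predict_isotherm(comp, grid, exp_sign = exp_sign)$h_total
  .simulate_noise(grid, truth, noise_sd, seed, replicates, temperature_C,
                  label = paste0("simulated:", comp$label))
}

.build_grid <- function(a_w_grid, a_w_range, n) {
  grid <- if (!is.null(a_w_grid)) as.numeric(a_w_grid)
  else seq(a_w_range[1], a_w_range[2], length.out = n)
  if (any(grid <= 0) || any(grid >= 1))
    stop("grid point a_w = ",
         paste(format(grid[grid <= 0 | grid >= 1]), collapse = ", "),
         " lies outside (0, 1)", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("a_w grid must be strictly increasing", call. = FALSE)
  grid
}

.simulate_noise <- function(grid, truth, noise_sd, seed, replicates,
                            temperature_C, label) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lapply(seq_len(replicates), function(r) {
    m <- truth
    if (noise_sd > 0)
      m <- m + stats::rnorm(length(grid), sd = noise_sd)
    m <- pmax(m, 0.01)  # preserve M > 0 invariant
    isotherm_data(grid, m, temperature_C = temperature_C,
                  label = sprintf("%s (rep %d)", label, r))
  })
}
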