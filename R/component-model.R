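#' @title Component sorption model internals
#' @description Constants of the component sub-isotherms. All are empirical
#'   and fixed; they are exposed read-only for documentation and testing.
#' @keywords internal
#' @name component-constants
NULL

# Vacuole (solution) component: Norrish-type solute activities combined by
# the Ross product. mole coefficients are the W_i * A_i multipliers of the
# water mole-fraction formula (A_i = M_water / M_solute as printed, kept
# verbatim even though 18.02/180.16 would give 0.100 for glucose);
# act coefficients are the base-10 exponential depression constants.
.vacuole_const <- list(
  mole_coeff = c(glucose = 0.08326, sucrose = 0.08764, ash = 0.16981),
  act_coeff  = c(glucose = 0.858,   sucrose = 2.772,   ash = 0.716),
  act_exponent = 2.0
)

# Fiber component: Kelsey water-cellulose-moist air correction.
.fiber_const <- list(c1 = 0.076, c2 = 0.28546, c3 = 1.878,
                     c4 = 0.16137, c5 = 0.43684)

# Starch (Henderson-type, % dry basis) and protein (power law, decimal d.b.).
.starch_const  <- list(scale = 18.19182, exponent = 0.41181)
.protein_const <- list(scale = 0.090614, exponent = -0.62)

#' Water activity of a single vacuole solute
#'
#' Norrish-type activity of water in a binary aqueous solution of glucose,
#' sucrose or ash: \eqn{a_w = x \cdot 10^{-k (1 - x)^2}} where \eqn{x} is the
#' water mole fraction and \eqn{k} the solute's empirical depression
#' coefficient (glucose 0.858, sucrose 2.772, ash 0.716).
#'
#' @param solute One of \code{"glucose"}, \code{"sucrose"}, \code{"ash"}.
#' @param x_mole Water mole fraction, in \[0, 1\].
#' @return Water activity in \[0, \code{x_mole}\].
#' @examples
#' solute_activity("glucose", 0.5)
#' @export
solute_activity <- function(solute, x_mole) {
  solute <- match.arg(solute, c("glucose", "sucrose", "ash"))
  if (any(x_mole < 0) || any(x_mole > 1))
    stop("water mole fraction must lie in [0, 1]", call. = FALSE)
  k <- .vacuole_const$act_coeff[[solute]]
  x_mole * 10^(-k * (1 - x_mole)^.vacuole_const$act_exponent)
}

#' Water mole fraction in a vacuole solute solution
#'
#' \eqn{x = X_v / (X_v + c \cdot W)} where \eqn{X_v} is the vacuole water
#' content (g water per g vacuole solids), \eqn{W} the weight fraction of the
#' solute within vacuole solids and \eqn{c} its mole coefficient.
#'
#' @param x_v Vacuole water content, >= 0 (decimal dry basis).
#' @param w_solute Weight fraction of the solute within vacuole solids.
#' @param mole_coeff Positive mole coefficient of the solute.
#' @return Water mole fraction in \[0, 1\]; 1 when the solute is absent.
#' @export
water_mole_fraction <- function(x_v, w_solute, mole_coeff) {
  if (x_v < 0) stop("x_v must be >= 0", call. = FALSE)
  if (w_solute < 0 || w_solute > 1)
    stop("w_solute must lie in [0, 1]", call. = FALSE)
  if (mole_coeff <= 0) stop("mole_coeff must be > 0", call. = FALSE)
  denom <- x_v + mole_coeff * w_solute
  if (denom == 0)
    stop("degenerate vacuole: no water and no solute", call. = FALSE)
  x_v / denom
}

# Within-vacuole weight fractions of glucose, sucrose and ash, normalized to
# sum 1 over vacuole solids.
.vacuole_weights <- function(comp) {
  solids <- comp$sugar + comp$ash
  if (solids <= 0)
    stop("degenerate vacuole: sugar + ash must be > 0", call. = FALSE)
  c(glucose = comp$glucose_share * comp$sugar,
    sucrose = (1 - comp$glucose_share) * comp$sugar,
    ash = comp$ash) / solids
}

#' Water activity of the vacuole component
#'
#' Combines the glucose, sucrose and ash solute activities by the Ross
#' product \eqn{a_{w,v} = a_{w,g} \, a_{w,s} \, a_{w,a}}, each activity
#' evaluated at the water mole fraction implied by the vacuole water content
#' \code{x_v}. A solute with zero weight fraction contributes activity 1: an
#' absent solute cannot depress water activity.
#'
#' @param x_v Vacuole water content (g water per g vacuole solids), >= 0.
#' @param comp A \code{\link{composition}} with \code{sugar + ash > 0}.
#' @return Water activity in \[0, 1\], strictly increasing in \code{x_v}.
#' @export
vacuole_aw <- function(x_v, comp) {
  stopifnot(inherits(comp, "composition"))
  if (x_v < 0) stop("x_v must be >= 0", call. = FALSE)
  w <- .vacuole_weights(comp)
  aw <- 1
  for (s in names(w)) {
    if (w[[s]] == 0) next  # absent solute: activity 1
    x <- water_mole_fraction(x_v, w[[s]], .vacuole_const$mole_coeff[[s]])
    aw <- aw * solute_activity(s, x)
  }
  aw
}

#' Invert the vacuole isotherm
#'
#' Finds the vacuole water content \code{x_v} whose Ross-product water
#' activity equals \code{a_w}, by bracketing root search (the forward map is
#' strictly increasing from 0 towards 1).
#'
#' @param a_w Target water activity, strictly inside (0, 1).
#' @param comp A \code{\link{composition}} with \code{sugar + ash > 0}.
#' @param tol Absolute tolerance on \code{a_w}; default \code{1e-8}.
#' @return Vacuole water content (decimal dry basis, per g vacuole solids).
#' @export
vacuole_moisture <- function(a_w, comp, tol = 1e-8) {
  .invert_monotone(function(x) vacuole_aw(x, comp), a_w, tol = tol,
                   what = "vacuole")
}

#' Water activity of the fiber component
#'
#' Kelsey's empirical correction for the water-cellulose-moist-air system:
#' an auxiliary bound-water variable
#' \eqn{y = (0.076 + X_f - \sqrt{(0.076 + X_f)^2 - 0.28546 X_f}) / 1.878}
#' feeds
#' \eqn{a_w = \frac{X_f - y}{X_f} \exp\!\left(\frac{0.16137}{X_f + 0.43684}\right)},
#' clamped to \[0, 1\]. The printed positive exponent is the default; with it
#' the map is strictly increasing and reaches saturation (\eqn{a_w = 1}) near
#' \eqn{X_f \approx 0.45}, so every water activity in (0, 1) corresponds to a
#' unique fiber moisture. \code{exp_sign = "neg"} selects the alternative
#' reading with a negative exponent, which saturates only asymptotically.
#'
#' @param x_f Fiber water content (g water per g fiber), > 0.
#' @param exp_sign \code{"pos"} (default) or \code{"neg"}: sign of the
#'   exponential argument.
#' @return Water activity in \[0, 1\].
#' @export
fiber_aw <- function(x_f, exp_sign = c("pos", "neg")) {
  exp_sign <- match.arg(exp_sign)
  if (any(x_f <= 0)) stop("x_f must be > 0", call. = FALSE)
  k <- .fiber_const
  disc <- (k$c1 + x_f)^2 - k$c2 * x_f
  if (any(disc < 0))
    stop("negative discriminant in fiber equation at x_f = ",
         paste(format(x_f[disc < 0]), collapse = ", "), call. = FALSE)
  y <- (k$c1 + x_f - sqrt(disc)) / k$c3
  arg <- k$c4 / (x_f + k$c5)
  if (exp_sign == "neg") arg <- -arg
  pmin(pmax((x_f - y) / x_f * exp(arg), 0), 1)
}

#' Invert the fiber isotherm
#'
#' Fiber water content at a given water activity, by bracketing root search
#' on the strictly increasing branch of [fiber_aw()].
#'
#' @inheritParams fiber_aw
#' @param a_w Target water activity, strictly inside (0, 1).
#' @param tol Absolute tolerance on \code{a_w}; default \code{1e-8}.
#' @return Fiber water content (decimal, per g fiber).
#' @export
fiber_moisture <- function(a_w, exp_sign = c("pos", "neg"), tol = 1e-8) {
  exp_sign <- match.arg(exp_sign)
  .invert_monotone(function(x) fiber_aw(x, exp_sign), a_w, tol = tol,
                   what = "fiber")
}

#' Starch sub-isotherm
#'
#' Henderson-form equilibrium moisture of the starch component:
#' \eqn{H_s = 18.19182 \, (-\ln(1 - a_w))^{0.41181}} in \% dry basis.
#'
#' @param a_w Water activity in \[0, 1).
#' @return Moisture content, \% dry basis.
#' @export
starch_moisture <- function(a_w) {
  if (any(a_w < 0) || any(a_w >= 1))
    stop("a_w must lie in [0, 1) for the starch equation", call. = FALSE)
  .starch_const$scale * (-log1p(-a_w))^.starch_const$exponent
}

#' Protein sub-isotherm
#'
#' Power-law equilibrium moisture of the protein component:
#' \eqn{H_p = 0.090614 \, (-\ln a_w)^{-0.62}} in decimal dry basis. It
#' vanishes as \eqn{a_w \to 0} and diverges as \eqn{a_w \to 1}.
#'
#' @param a_w Water activity strictly inside (0, 1).
#' @return Moisture content, decimal dry basis (g water per g protein).
#' @export
protein_moisture <- function(a_w) {
  if (any(a_w <= 0) || any(a_w >= 1))
    stop("a_w must lie strictly inside (0, 1) for the protein equation",
         call. = FALSE)
  .protein_const$scale * (-log(a_w))^.protein_const$exponent
}

# Bracketing root search for a strictly increasing forward map f with
# f(0+) = 0. Upper bracket grown by doubling from 1; solution polished by
# uniroot to |f(x) - a_w| <= tol.
.invert_monotone <- function(f, a_w, tol = 1e-8, what = "forward map") {
  if (length(a_w) != 1L || !is.finite(a_w) || a_w <= 0 || a_w >= 1)
    stop("a_w must be a single value strictly inside (0, 1)", call. = FALSE)
  lo <- 1e-12
  hi <- 1
  it <- 0L
  while (f(hi) < a_w) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L)
      stop("a_w = ", a_w, " is outside the attainable range of the ",
           what, " isotherm (max ~ ", format(f(hi)), ")", call. = FALSE)
  }
  r <- stats::uniroot(function(x) f(x) - a_w, lower = lo, upper = hi,
                      tol = .Machine$double.eps^0.75, maxiter = 2000L)
  x <- r$root
  if (abs(f(x) - a_w) > tol)
    stop("inversion of the ", what, " isotherm did not reach tolerance ",
         tol, call. = FALSE)
  x
}

#' Predict a sorption isotherm from proximate composition
#'
#' Evaluates the four component sub-isotherms (vacuole solution, fiber,
#' starch, protein) at each water activity on the grid, converts every
#' component to \% dry basis, and combines them into the total moisture
#' \deqn{H_t = w_v H_v + w_f H_f + w_s H_s + w_p H_p,}
#' where the weights are the composition fractions normalized over non-oil
#' dry matter and the vacuole weight is the sugar plus ash fraction. Oil is
#' excluded: its sorption is negligible. A component with zero weight
#' contributes zero regardless of its sub-model's domain.
#'
#' @param comp A \code{\link{composition}}.
#' @param a_w_grid Strictly increasing water activities inside (0, 1).
#' @param exp_sign Sign convention for the fiber equation (see
#'   [fiber_aw()]).
#' @return An object of class \code{"component_curve"}: a data frame with
#'   columns \code{a_w}, \code{h_vacuole}, \code{h_fiber}, \code{h_starch},
#'   \code{h_protein} (per-component moisture, \% d.b. per gram of that
#'   component) and \code{h_total} (\% d.b. of the whole material), with the
#'   composition and weights attached as attributes.
#' @examples
#' comp <- sample_compositions()[["C. morifolium flower"]]
#' head(predict_isotherm(comp, seq(0.1, 0.9, by = 0.1)))
#' @export
predict_isotherm <- function(comp, a_w_grid = seq(0.05, 0.95, by = 0.05),
                             exp_sign = c("pos", "neg")) {
  stopifnot(inherits(comp, "composition"))
  exp_sign <- match.arg(exp_sign)
  a_w_grid <- as.numeric(a_w_grid)
  if (length(a_w_grid) < 1L || any(a_w_grid <= 0) || any(a_w_grid >= 1))
    stop("a_w grid values must lie strictly inside (0, 1)", call. = FALSE)
  if (is.unsorted(a_w_grid, strictly = TRUE))
    stop("a_w grid must be strictly increasing", call. = FALSE)

  w_raw <- c(vacuole = comp$sugar + comp$ash, fiber = comp$fiber,
             starch = comp$starch, protein = comp$protein)
  if (sum(w_raw) <= 0)
    stop("degenerate composition: all non-oil fractions are zero",
         call. = FALSE)
  w <- w_raw / sum(w_raw)

  n <- length(a_w_grid)
  h_v <- h_f <- h_s <- h_p <- numeric(n)
  for (i in seq_len(n)) {
    a <- a_w_grid[i]
    if (w[["vacuole"]] > 0) h_v[i] <- 100 * vacuole_moisture(a, comp)
    if (w[["fiber"]] > 0)   h_f[i] <- 100 * fiber_moisture(a, exp_sign)
    if (w[["starch"]] > 0)  h_s[i] <- starch_moisture(a)
    if (w[["protein"]] > 0) h_p[i] <- 100 * protein_moisture(a)
  }
  h_t <- w[["vacuole"]] * h_v + w[["fiber"]] * h_f +
    w[["starch"]] * h_s + w[["protein"]] * h_p

  out <- data.frame(a_w = a_w_grid, h_vacuole = h_v, h_fiber = h_f,
                    h_starch = h_s, h_protein = h_p, h_total = h_t)
  attr(out, "composition") <- comp
  attr(out, "weights") <- w
  attr(out, "exp_sign") <- exp_sign
  class(out) <- c("component_curve", "data.frame")
  out
}

#' @export
print.component_curve <- function(x, ...) {
  comp <- attr(x, "composition")
  cat("Component-model sorption isotherm:", comp$label, "\n")
  cat("non-oil component weights:",
      paste(names(attr(x, "weights")),
            round(attr(x, "weights"), 4), sep = " = ", collapse = ", "),
      "\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write a predicted curve to CSV
#'
#' Writes the six-column curve (\code{a_w,h_vacuole,h_fiber,h_starch,
#' h_protein,h_total}, \% dry basis) produced by [predict_isotherm()].
#'
#' @param curve A \code{component_curve}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "component_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
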