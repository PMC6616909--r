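#' Proximate composition of a plant material
#'
#' Bundles the weight fractions of the six proximate components used by the
#' component sorption model: sugar, ash, fiber, starch, protein and oil, all
#' as decimals on a dry basis. Sugar and ash together form the vacuole
#' (solute) component; oil does not sorb water in this model and is carried
#' only so that compositions can be read verbatim from published tables.
#'
#' Printed composition tables rarely sum exactly to one. Fractions are kept
#' as given; the component model normalizes the non-oil fractions internally.
#' A warning is emitted when the six fractions sum to more than 1.05 or the
#' non-oil fractions deviate from 1 by more than 0.05, as a nudge that the
#' table likely reports per-total rather than per-dry-matter values.
#'
#' @param sugar,ash,fiber,starch,protein,oil Weight fractions (decimal, dry
#'   basis), each in \[0, 1\].
#' @param glucose_share Fraction of the sugar pool treated as glucose, the
#'   remainder being sucrose. Published tables give a single "sugar" figure,
#'   so the split is a modelling choice; default 0.5.
#' @param label Product name used in printing and output files.
#' @return An object of class \code{"composition"}: a named list with the six
#'   fractions, \code{glucose_share} and \code{label}.
#' @examples
#' comp <- composition(sugar = 0.4923, ash = 0.077, fiber = 0.13384,
#'                     starch = 0.07692, protein = 0.1892, oil = 0.0311,
#'                     label = "C. morifolium flower")
#' comp
#' @seealso [predict_isotherm()], [read_composition_csv()],
#'   [sample_compositions()]
#' @export
composition <- function(sugar = 0, ash = 0, fiber = 0, starch = 0,
                        protein = 0, oil = 0, glucose_share = 0.5,
                        label = "unnamed") {
  fr <- c(sugar = sugar, ash = ash, fiber = fiber, starch = starch,
          protein = protein, oil = oil)
  if (!is.numeric(fr) || anyNA(fr))
    stop("composition fractions must be non-missing numbers", call. = FALSE)
  if (any(fr < 0) || any(fr > 1))
    stop("each weight fraction must lie in [0, 1]", call. = FALSE)
  tot <- sum(fr)
  if (tot <= 0 || tot > 1.05)
    stop("weight fractions must sum to a value in (0, 1.05]; got ",
         format(tot), call. = FALSE)
  if (!is.numeric(glucose_share) || length(glucose_share) != 1L ||
      glucose_share < 0 || glucose_share > 1)
    stop("glucose_share must be a single number in [0, 1]", call. = FALSE)
  non_oil <- tot - fr[["oil"]]
  if (abs(non_oil - 1) > 0.05 + 1e-9)
    warning("non-oil fractions of '", label, "' sum to ", format(non_oil),
            "; the component model renormalizes them to 1", call. = FALSE)
  structure(c(as.list(fr),
              list(glucose_share = glucose_share, label = label)),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Proximate composition:", x$label, "\n")
  fr <- unlist(x[c("sugar", "ash", "fiber", "starch", "protein", "oil")])
  print(round(fr, 5))
  cat("glucose share of sugar:", x$glucose_share, "\n")
  invisible(x)
}

#' Read compositions from CSV
#'
#' Reads a table with columns \code{label,sugar,ash,fiber,starch,protein,oil}
#' (decimal weight fractions) and returns a named list of
#' \code{\link{composition}} objects.
#'
#' @param path Path to a CSV file.
#' @param glucose_share Glucose share applied to every row (see
#'   [composition()]).
#' @return Named list of \code{composition} objects.
#' @export
read_composition_csv <- function(path, glucose_share = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "sugar", "ash", "fiber", "starch", "protein", "oil")
  if (!all(need %in% names(df)))
    stop("composition CSV must have columns ",
         paste(need, collapse = ","), call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    composition(sugar = df$sugar[i], ash = df$ash[i], fiber = df$fiber[i],
                starch = df$starch[i], protein = df$protein[i],
                oil = df$oil[i], glucose_share = glucose_share,
                label = df$label[i]))
  names(out) <- df$label
  out
}

#' Bundled product compositions
#'
#' Proximate compositions of the seven products used throughout the package
#' documentation and tests: two herbs (*Chrysanthemum morifolium* flower and
#' *Anoectochilus formosanus* Hayata) and five agricultural products (raw
#' bamboo, elecampe and three corn varieties), as published in the
#' composition tables shipped in \code{inst/extdata/compositions.csv}.
#'
#' @param glucose_share Glucose share applied to every product.
#' @return Named list of \code{\link{composition}} objects.
#' @examples
#' names(sample_compositions())
#' @export
sample_compositions <- function(glucose_share = 0.5) {
  path <- system.file("extdata", "compositions.csv", package = "isocomp",
                      mustWork = TRUE)
  suppressWarnings(read_composition_csv(path, glucose_share = glucose_share))
}
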