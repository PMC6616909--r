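#' Read an EMC dataset from CSV
#'
#' Expects columns \code{a_w,moisture_db_percent} and optionally
#' \code{temperature_C}; dot decimal separator, header row, UTF-8.
#'
#' @param path CSV path.
#' @return An \code{\link{isotherm_data}}.
#' @export
read_emc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("cannot parse ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  need <- c("a_w", "moisture_db_percent")
  if (!all(need %in% names(df)))
    stop("EMC CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  bad <- which(!is.finite(df$a_w) | !is.finite(df$moisture_db_percent))
  if (length(bad))
    stop("non-numeric EMC values at data line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  temp <- if ("temperature_C" %in% names(df)) df$temperature_C[1] else
    NA_real_
  isotherm_data(df$a_w, df$moisture_db_percent, temperature_C = temp,
                label = basename(path))
}

#' Write an EMC dataset to CSV
#'
#' @param data An \code{\link{isotherm_data}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_emc_csv <- function(data, path) {
  data <- .as_isotherm_data(data)
  df <- as.data.frame(data)
  temp <- attr(data, "temperature_C")
  if (!is.null(temp) && !is.na(temp)) df$temperature_C <- temp
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a model-comparison report
#'
#' @param report A \code{model_comparison} from [compare_models()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "model_comparison"))
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
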