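#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rlnorm rpois runif qnorm plogis t.test setNames median
#' @importFrom utils head modifyList
NULL

GENOTYPES <- c("MUT", "CTRL")
BAITS <- c("VCP", "IGG")

# condition constructors -------------------------------------------------

stop_silac <- function(msg, class, ...) {
  abort(msg, class = c(class, "silac_error"), ...)
}

stop_parse <- function(msg, row = NULL, column = NULL) {
  loc <- c(
    if (!is.null(row)) paste0("row ", row),
    if (!is.null(column)) paste0("column '", column, "'")
  )
  if (length(loc)) msg <- paste0(msg, " (", paste(loc, collapse = ", "), ")")
  stop_silac(msg, "silac_parse_error", row = row, column = column)
}

stop_schema <- function(msg) stop_silac(msg, "silac_schema_error")
stop_validation <- function(msg, row = NULL) {
  if (!is.null(row)) msg <- paste0(msg, " (row ", row, ")")
  stop_silac(msg, "silac_validation_error", row = row)
}
stop_duplicate <- function(msg) stop_silac(msg, "silac_duplicate_error")
stop_config <- function(msg) stop_silac(msg, "silac_config_error")
stop_insufficient <- function(msg) stop_silac(msg, "silac_insufficient_data_error")

# numeric parsing: strict, locale-independent ----------------------------

# Parse a character vector as doubles with a C-locale decimal point.
# Returns NA where unparseable; callers turn that into a structured error.
strict_double <- function(x) {
  x <- trimws(x)
  ok <- grepl("^[+-]?(\\d+\\.?\\d*|\\.\\d+)([eE][+-]?\\d+)?$", x)
  out <- rep(NA_real_, length(x))
  out[ok] <- as.numeric(x[ok])
  out
}

strict_integer <- function(x) {
  x <- trimws(x)
  ok <- grepl("^[+-]?\\d+$", x)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(x[ok])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
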