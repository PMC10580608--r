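#' ACE-R and CHC domain names
#'
#' The five ACE-R subdomains (fixed order) and the nine CHC broad cognitive
#' domains (fixed order) used throughout the package. Lower-case CHC codes are
#' used as column names in every tibble the package returns.
#'
#' @return A character vector of domain names.
#' @export
#' @examples
#' acer_domains()
#' chc_domains()
acer_domains <- function() {
  c("attention_orientation", "memory", "fluency", "language", "visuospatial")
}

#' @rdname acer_domains
#' @export
chc_domains <- function() {
  c("gc", "gf", "grw", "gq", "gsm", "glr", "gv", "gs", "ga")
}

# Published level-table header spells visual processing "GW"; the domain list
# uses GV. Normalised on input everywhere.
normalize_chc_alias <- function(x) {
  out <- tolower(x)
  out[out == "gw"] <- "gv"
  out
}

#' ACE-R scoring schema
#'
#' Maximum raw points per ACE-R subdomain, used to normalise raw subscores to
#' the unit interval. The defaults are the standard ACE-R subscale maxima
#' (attention & orientation 18, memory 26, fluency 14, language 26,
#' visuospatial 16, totalling 100); pass other maxima for local scoring
#' variants.
#'
#' @param attention_orientation,memory,fluency,language,visuospatial Positive
#'   integer maximum raw points for each subdomain.
#' @return A named numeric vector of class `acer_schema`.
#' @export
#' @examples
#' acer_schema()
acer_schema <- function(attention_orientation = 18, memory = 26, fluency = 14,
                        language = 26, visuospatial = 16) {
  maxima <- c(
    attention_orientation = attention_orientation, memory = memory,
    fluency = fluency, language = language, visuospatial = visuospatial
  )
  if (any(!is.finite(maxima)) || any(maxima <= 0)) {
    abort("All ACE-R domain maxima must be finite and > 0.",
      class = "chclevels_validation_error"
    )
  }
  structure(maxima, class = c("acer_schema", "numeric"))
}

#' @export
print.acer_schema <- function(x, ...) {
  cat("<acer_schema> maximum raw points per ACE-R domain\n")
  print(unclass(x))
  invisible(x)
}

# Validate a numeric vector/matrix of normalized ACE-R values in [0,1].
validate_unit_interval <- function(x, what = "value") {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    abort(
      sprintf(
        "%s out of range: %d value(s) not in [0, 1] (first offender: %s).",
        what, sum(bad), format(x[bad][1])
      ),
      class = "chclevels_validation_error"
    )
  }
  invisible(x)
}

# Extract the five normalized ACE-R columns (suffix _norm) from a data frame
# as an n x 5 matrix in canonical order, validating the range.
acer_profile_matrix <- function(data) {
  cols <- paste0(acer_domains(), "_norm")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("Missing normalized ACE-R column(s): ", paste(missing, collapse = ", ")),
      class = "chclevels_validation_error"
    )
  }
  m <- as.matrix(data[cols])
  storage.mode(m) <- "double"
  colnames(m) <- acer_domains()
  validate_unit_interval(m, "Normalized ACE-R score")
  m
}

# Derive a reproducible per-stage seed from a global seed and a stage name,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647L)
}
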