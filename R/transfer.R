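#' Expert ACE-R to CHC transfer matrix
#'
#' The transfer matrix distributes each ACE-R subdomain's contribution across
#' the nine CHC broad domains as percentage weights. Rows are ACE-R domains,
#' columns are CHC domains; each row sums to 100.
#'
#' `transfer_matrix()` validates and classes a 5 x 9 numeric matrix;
#' `default_transfer_matrix()` returns the package's default expert matrix.
#' The default row percentages follow the published factor-analysis transfer
#' (attention & orientation 28/28/28/16, memory 15/39/46, fluency 25/25/50,
#' language 61/8/31, visuospatial 12/12/13/63); the attachment of each row
#' percentage to a specific CHC column is a configuration choice (the
#' published rendering of the table does not pin it down unambiguously), so
#' the whole matrix can be replaced via [read_transfer_matrix()].
#'
#' @param weights A 5 x 9 numeric matrix of percentage weights with rows in
#'   [acer_domains()] order and columns in [chc_domains()] order.
#' @return A `transfer_matrix` object (numeric matrix with dimnames).
#' @export
#' @examples
#' m <- default_transfer_matrix()
#' rowSums(m)
transfer_matrix <- function(weights) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (!all(dim(weights) == c(5L, 9L))) {
    abort("A transfer matrix must be 5 x 9 (ACE-R rows x CHC columns).",
      class = "chclevels_validation_error"
    )
  }
  rownames(weights) <- acer_domains()
  colnames(weights) <- chc_domains()
  if (any(!is.finite(weights)) || any(weights < 0)) {
    abort("Transfer weights must be finite and >= 0.",
      class = "chclevels_validation_error"
    )
  }
  rs <- rowSums(weights)
  if (any(abs(rs - 100) > 1e-9)) {
    bad <- acer_domains()[which(abs(rs - 100) > 1e-9)[1]]
    abort(
      sprintf("Transfer matrix row '%s' sums to %s, expected 100.", bad,
        format(rs[bad])),
      class = "chclevels_validation_error"
    )
  }
  zero_cols <- colSums(weights) == 0
  if (any(zero_cols)) {
    abort(
      sprintf(
        "CHC column(s) with no contributing ACE-R domain: %s (saturation undefined).",
        paste(chc_domains()[zero_cols], collapse = ", ")
      ),
      class = "chclevels_config_error"
    )
  }
  structure(weights, class = c("transfer_matrix", "matrix", "array"))
}

#' @rdname transfer_matrix
#' @export
default_transfer_matrix <- function() {
  w <- matrix(0, 5, 9, dimnames = list(acer_domains(), chc_domains()))
  w["attention_orientation", c("gc", "gsm", "gs", "ga")] <- c(28, 28, 28, 16)
  w["memory", c("gc", "gsm", "glr")] <- c(15, 39, 46)
  w["fluency", c("gc", "gf", "glr")] <- c(25, 25, 50)
  w["language", c("gc", "grw", "ga")] <- c(61, 8, 31)
  w["visuospatial", c("gf", "gq", "gsm", "gv")] <- c(12, 12, 13, 63)
  transfer_matrix(w)
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("<transfer_matrix> ACE-R rows -> CHC columns, percent weights\n")
  print(unclass(x))
  invisible(x)
}

#' Read or write a transfer matrix configuration
#'
#' The on-disk format is JSON with fields `rows` (ACE-R domain names),
#' `columns` (CHC domain names) and `weights` (a 5 x 9 array of percentages,
#' row-major by ACE-R domain). Column aliases are normalised on read
#' (`"GW"` is accepted for `"gv"`); rows and columns may appear in any order.
#'
#' @param path File path of the JSON document.
#' @param matrix A [transfer_matrix()] object.
#' @return `read_transfer_matrix()` returns a validated `transfer_matrix`;
#'   `write_transfer_matrix()` returns `path` invisibly.
#' @export
#' @examples
#' cfg <- system.file("extdata", "transfer_matrix_default.json",
#'   package = "chclevels"
#' )
#' read_transfer_matrix(cfg)
read_transfer_matrix <- function(path) {
  doc <- jsonlite::fromJSON(path)
  for (field in c("rows", "columns", "weights")) {
    if (is.null(doc[[field]])) {
      abort(sprintf("Transfer matrix config is missing field '%s'.", field),
        class = "chclevels_config_error"
      )
    }
  }
  rows <- tolower(doc$rows)
  cols <- normalize_chc_alias(doc$columns)
  w <- as.matrix(doc$weights)
  if (!setequal(rows, acer_domains()) || !setequal(cols, chc_domains())) {
    abort("Transfer matrix config must name all five ACE-R rows and nine CHC columns.",
      class = "chclevels_config_error"
    )
  }
  dimnames(w) <- list(rows, cols)
  transfer_matrix(w[acer_domains(), chc_domains()])
}

#' @rdname read_transfer_matrix
#' @export
write_transfer_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "transfer_matrix"))
  doc <- list(
    rows = rownames(matrix),
    columns = colnames(matrix),
    weights = unclass(matrix)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
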