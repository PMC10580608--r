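#' Normalise raw ACE-R subscores
#'
#' Divides each raw subscore by its schema maximum, adding `*_norm` columns to
#' the data. Raw scores must lie in `[0, maximum]` for their domain.
#'
#' @param data A data frame with one row per patient and the five raw ACE-R
#'   columns named as in [acer_domains()].
#' @param schema An [acer_schema()] of per-domain maxima.
#' @return `data` as a tibble with the five `*_norm` columns appended
#'   (replaced if already present).
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   id = 1, attention_orientation = 9, memory = 13, fluency = 7,
#'   language = 13, visuospatial = 8
#' )
#' acer_normalize(pts)
acer_normalize <- function(data, schema = acer_schema()) {
  data <- as_tibble(data)
  missing <- setdiff(acer_domains(), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing raw ACE-R column(s): ", paste(missing, collapse = ", ")),
      class = "chclevels_validation_error"
    )
  }
  for (d in acer_domains()) {
    raw <- data[[d]]
    bad <- which(!is.finite(raw) | raw < 0 | raw > schema[[d]])
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Raw score out of range in column '%s', row %d: %s (allowed [0, %s]).",
          d, bad[1], format(raw[bad[1]]), format(schema[[d]])
        ),
        class = "chclevels_validation_error"
      )
    }
    data[[paste0(d, "_norm")]] <- raw / schema[[d]]
  }
  data
}

#' CHC domain saturations from normalised ACE-R scores
#'
#' For each CHC domain `c`, the saturation is the column-normalised weighted
#' mean of the contributing ACE-R subscores:
#' `s_c = sum_d w[d,c] x_d / sum_d w[d,c]`, with `w` the transfer-matrix
#' percentages and `x` the normalised ACE-R profile. The saturation is
#' guaranteed to lie in `[0, 1]`, equals 0 for an all-zero profile and 1 for a
#' perfect one, and is nondecreasing in every subscore.
#'
#' @param data A data frame with the five `*_norm` ACE-R columns (see
#'   [acer_normalize()]); other columns are carried through.
#' @param matrix A [transfer_matrix()].
#' @return A tibble: the non-score columns of `data` followed by nine
#'   saturation columns named as in [chc_domains()].
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   id = 1, attention_orientation = 12, memory = 20, fluency = 9,
#'   language = 20, visuospatial = 12
#' )
#' pts |> acer_normalize() |> chc_saturation()
chc_saturation <- function(data, matrix = default_transfer_matrix()) {
  stopifnot(inherits(matrix, "transfer_matrix"))
  x <- acer_profile_matrix(data)
  sat <- chc_saturation_matrix(x, matrix)
  keep <- setdiff(names(data), c(chc_domains(), paste0(acer_domains(), "_norm")))
  dplyr::bind_cols(as_tibble(data)[keep], as_tibble(sat))
}

# Core computation on an n x 5 matrix of normalized profiles -> n x 9 matrix.
chc_saturation_matrix <- function(x, matrix) {
  w <- unclass(matrix)
  sat <- x %*% sweep(w, 2, colSums(w), "/")
  colnames(sat) <- chc_domains()
  # weighted means of values in [0,1]; clamp away rounding dust only
  pmin(pmax(sat, 0), 1)
}

#' Segment a saturation into a game level
#'
#' Splits the unit interval into six equal segments, one per game difficulty
#' level: level `1 + floor(6 v)`, with the top level capped at 6 so that
#' `v = 1` maps to level 6. Segments are half-open `[k/6, (k+1)/6)` with the
#' top segment closed; a value exactly on a boundary takes the higher level.
#'
#' @param v Numeric vector of saturations in `[0, 1]`.
#' @return Integer vector of levels in `1:6`.
#' @export
#' @examples
#' saturation_to_level(c(0, 0.5, 1))
saturation_to_level <- function(v) {
  validate_unit_interval(v, "Saturation")
  pmin(1L + as.integer(floor(6 * v)), 6L)
}

#' Recommend rehabilitation game levels
#'
#' Composes [chc_saturation()] and [saturation_to_level()]: one starting game
#' level per CHC domain for every patient. This expert conversion is the
#' deterministic reference that the neural-network and fuzzy-rule predictors
#' are trained on and measured against.
#'
#' @inheritParams chc_saturation
#' @return A tibble: non-score columns of `data` plus nine integer level
#'   columns named as in [chc_domains()].
#' @export
#' @examples
#' pts <- tibble::tibble(id = 1, attention_orientation = 12, memory = 20,
#'   fluency = 9, language = 20, visuospatial = 12)
#' recommend_levels(acer_normalize(pts))
recommend_levels <- function(data, matrix = default_transfer_matrix()) {
  sat <- chc_saturation(data, matrix)
  dplyr::mutate(sat, dplyr::across(dplyr::all_of(chc_domains()), saturation_to_level))
}

# Extract the nine level columns as an n x 9 integer matrix, validating range.
level_matrix <- function(data) {
  missing <- setdiff(chc_domains(), names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing CHC level column(s): ", paste(missing, collapse = ", ")),
      class = "chclevels_validation_error"
    )
  }
  m <- as.matrix(data[chc_domains()])
  storage.mode(m) <- "integer"
  if (any(is.na(m)) || any(m < 1L) || any(m > 6L)) {
    abort("Levels must be integers in 1..6.", class = "chclevels_validation_error")
  }
  m
}
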