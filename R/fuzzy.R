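#' Linguistic context of a variable
#'
#' Evaluative linguistic expressions ("very small", "roughly big", ...) are
#' always interpreted against a context: the range of the variable and its
#' central, typical value. All package variables live on `[0, 1]` by default.
#'
#' @param lower,upper Range bounds, `lower < upper`.
#' @param center Typical value, strictly between the bounds (default
#'   midpoint).
#' @return A list of class `linguistic_context`.
#' @export
linguistic_context <- function(lower = 0, upper = 1,
                               center = (lower + upper) / 2) {
  if (!(lower < center && center < upper)) {
    abort("Context requires lower < center < upper.",
      class = "chclevels_validation_error"
    )
  }
  structure(list(lower = lower, upper = upper, center = center),
    class = "linguistic_context"
  )
}

# Modifier table: hedges ordered from narrowing to widening. `factor` scales
# kernel and support widths; `rank` is the specificity (higher = more
# specific, the bare expression sits between narrowing and widening hedges).
modifier_table <- function() {
  tibble(
    modifier = c(
      "extremely", "significantly", "very", "", "more-or-less", "roughly",
      "quite-roughly", "very-roughly"
    ),
    factor = c(0.4, 0.6, 0.8, 1.0, 1.25, 1.5, 1.75, 2.0),
    rank = 8:1
  )
}

base_terms <- function() c("small", "medium", "big")

#' Catalogue of evaluative expressions
#'
#' All 24 evaluative expressions the engine uses: each of the three basic
#' terms (`small`, `medium`, `big`) under each of eight linguistic modifiers
#' (`extremely`, `significantly`, `very`, none, `more-or-less`, `roughly`,
#' `quite-roughly`, `very-roughly`). `rank` orders expressions by
#' specificity (narrowing hedges are more specific than the bare term,
#' widening ones less).
#'
#' @return A tibble with columns `label`, `base`, `modifier`, `factor`,
#'   `rank`.
#' @export
#' @examples
#' expression_catalog()
expression_catalog <- function() {
  tidyr::expand_grid(base = base_terms(), modifier_table()) |>
    dplyr::mutate(
      label = ifelse(.data$modifier == "", .data$base,
        paste(.data$modifier, .data$base)
      )
    ) |>
    dplyr::select("label", "base", "modifier", "factor", "rank")
}

# Parse an expression label into base term + modifier factor. Errors on
# unknown labels. Vectorised.
parse_expression <- function(label) {
  cat_tbl <- expression_catalog()
  idx <- match(label, cat_tbl$label)
  if (anyNA(idx)) {
    abort(
      sprintf("Unknown evaluative expression: '%s'.", label[is.na(idx)][1]),
      class = "chclevels_validation_error"
    )
  }
  cat_tbl[idx, ]
}

# Trapezoid helper: membership 1 on [k_lo, k_hi], linear to 0 at the support
# bounds [s_lo, s_hi], 0 outside. Degenerate slopes handled.
trapezoid <- function(v, s_lo, k_lo, k_hi, s_hi) {
  up <- if (k_lo > s_lo) (v - s_lo) / (k_lo - s_lo) else as.numeric(v >= k_lo)
  down <- if (s_hi > k_hi) (s_hi - v) / (s_hi - k_hi) else as.numeric(v <= k_hi)
  pmin(pmax(pmin(up, down), 0), 1)
}

# Kernel (degree-1 interval) of an expression on a context. Shapes:
#   small : kernel [lo, lo + 0.2*r*f], support to lo + 0.5*r*f
#   big   : mirror image of small
#   medium: kernel center +/- 0.05*r*g, support center +/- 0.25*r*g with
#           g = min(f, 1) -- the "typical" region is anchored at the centre,
#           so widening hedges widen small/big horizons but not medium.
# f is the modifier factor. Constants are package defaults chosen so that the
# defuzzified values of the expression set tile the six level segments.
expression_geometry <- function(label, ctx) {
  p <- parse_expression(label)
  r <- ctx$upper - ctx$lower
  f <- p$factor
  g <- pmin(f, 1)
  out <- tibble(
    label = p$label, base = p$base, rank = p$rank,
    s_lo = NA_real_, k_lo = NA_real_, k_hi = NA_real_, s_hi = NA_real_
  )
  sm <- p$base == "small"
  bg <- p$base == "big"
  md <- p$base == "medium"
  out$s_lo[sm] <- ctx$lower
  out$k_lo[sm] <- ctx$lower
  out$k_hi[sm] <- ctx$lower + 0.2 * r * f[sm]
  out$s_hi[sm] <- ctx$lower + 0.5 * r * f[sm]
  out$s_hi[bg] <- ctx$upper
  out$k_hi[bg] <- ctx$upper
  out$k_lo[bg] <- ctx$upper - 0.2 * r * f[bg]
  out$s_lo[bg] <- ctx$upper - 0.5 * r * f[bg]
  out$k_lo[md] <- ctx$center - 0.05 * r * g[md]
  out$k_hi[md] <- ctx$center + 0.05 * r * g[md]
  out$s_lo[md] <- ctx$center - 0.25 * r * g[md]
  out$s_hi[md] <- ctx$center + 0.25 * r * g[md]
  out
}

#' Membership degree of an evaluative expression
#'
#' Trapezoidal membership of `v` in the expression's extension on the given
#' context. `small`-type expressions are nonincreasing in `v`, `big`-type
#' nondecreasing, `medium` unimodal around the centre. Narrowing modifiers
#' give pointwise smaller-or-equal degrees than the bare term, widening ones
#' pointwise greater-or-equal.
#'
#' @param label Expression label, e.g. `"very small"`, `"medium"`,
#'   `"roughly big"`, or the wildcard `"any"` (degree 1 everywhere).
#' @param v Numeric vector of values within the context bounds.
#' @param ctx A [linguistic_context()].
#' @return Degrees in `[0, 1]`, same length as `v`.
#' @export
#' @examples
#' membership("big", c(0, 0.5, 1))
membership <- function(label, v, ctx = linguistic_context()) {
  if (any(v < ctx$lower | v > ctx$upper | !is.finite(v))) {
    abort("Value outside the linguistic context bounds.",
      class = "chclevels_validation_error"
    )
  }
  if (identical(label, "any")) {
    return(rep(1, length(v)))
  }
  g <- expression_geometry(label, ctx)
  trapezoid(v, g$s_lo, g$k_lo, g$k_hi, g$s_hi)
}

#' Best-fitting evaluative expression
#'
#' Returns, for each value, the expression from [expression_catalog()] with
#' the highest membership degree; degree ties (within `1e-9`) go to the more
#' specific expression, then to the fixed base-term order small < medium <
#' big. This is the perception step used when learning rules from
#' observations.
#'
#' @param v Numeric vector within the context bounds.
#' @param ctx A [linguistic_context()].
#' @return Character vector of expression labels.
#' @export
#' @examples
#' best_expression(c(0, 0.45, 1))
best_expression <- function(v, ctx = linguistic_context()) {
  cat_tbl <- expression_catalog()
  geo <- expression_geometry(cat_tbl$label, ctx)
  # catalogue order is small, medium, big blocks; within each, rank descends
  # with widening, so order rows by (rank desc, base order) for tie-breaking.
  base_ord <- match(geo$base, base_terms())
  pref <- order(-geo$rank, base_ord)
  deg <- vapply(
    pref,
    function(i) trapezoid(v, geo$s_lo[i], geo$k_lo[i], geo$k_hi[i], geo$s_hi[i]),
    numeric(length(v))
  )
  deg <- matrix(deg, nrow = length(v))
  pick <- apply(deg, 1, function(row) which(row >= max(row) - 1e-9)[1])
  geo$label[pref][pick]
}

#' Defuzzification of evaluative expressions
#'
#' Maps an evaluative expression back to a crisp representative value on its
#' context: the kernel endpoint facing the centre for `small` (kernel
#' supremum) and `big` (kernel infimum), and the kernel midpoint (the context
#' centre) for `medium`. The defuzzified value therefore grades with the
#' modifier: `dee_defuzzify("very small") < dee_defuzzify("small") <
#' dee_defuzzify("roughly small")`.
#'
#' @param label Expression label (vectorised).
#' @param ctx A [linguistic_context()].
#' @return Numeric vector within the context bounds.
#' @export
#' @examples
#' dee_defuzzify(c("extremely small", "small", "medium", "big"))
dee_defuzzify <- function(label, ctx = linguistic_context()) {
  g <- expression_geometry(label, ctx)
  out <- numeric(nrow(g))
  out[g$base == "small"] <- g$k_hi[g$base == "small"]
  out[g$base == "big"] <- g$k_lo[g$base == "big"]
  out[g$base == "medium"] <- (g$k_lo + g$k_hi)[g$base == "medium"] / 2
  pmin(pmax(out, ctx$lower), ctx$upper)
}
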