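# Short variable names used in serialized rules, in ACE-R domain order.
acer_short <- function() c("ao", "mem", "flu", "lan", "vis")

new_rulebase <- function(rules, output, ctx) {
  structure(as_tibble(rules),
    output = output, context = ctx,
    class = c("chc_rulebase", class(tibble()))
  )
}

#' Learn linguistic IF-THEN rules from observations
#'
#' One raw rule is read off every observation: the best-fitting evaluative
#' expression for each of the five input values forms the antecedent, the
#' best-fitting expression for the output value the consequent. The raw
#' rules are then passed through [filter_rules()] to drop duplicates and
#' resolve inconsistencies.
#'
#' @param observations A data frame with the five `*_norm` ACE-R columns and
#'   an output column of values in `[0, 1]`.
#' @param output Name of the output column (default `"value"`); also used as
#'   the consequent variable name when rules are serialised.
#' @param ctx A [linguistic_context()] shared by inputs and output.
#' @return A `chc_rulebase`: a tibble with antecedent columns `ao`, `mem`,
#'   `flu`, `lan`, `vis`, a `consequent` column, and a support count `n`.
#' @export
#' @examples
#' obs <- mlp_training_set(20, seed = 1) |> dplyr::rename(value = gc)
#' learn_rules(obs)
learn_rules <- function(observations, output = "value",
                        ctx = linguistic_context()) {
  if (nrow(observations) == 0) {
    abort("Cannot learn rules from an empty observation set.",
      class = "chclevels_validation_error"
    )
  }
  x <- acer_profile_matrix(observations)
  y <- observations[[output]]
  if (is.null(y)) {
    abort(sprintf("Missing output column '%s'.", output),
      class = "chclevels_validation_error"
    )
  }
  validate_unit_interval(y, "Rule output value")
  rules <- tibble::as_tibble(
    setNames(
      lapply(seq_len(5), function(j) best_expression(x[, j], ctx)),
      acer_short()
    )
  )
  rules$consequent <- best_expression(y, ctx)
  filter_rules(new_rulebase(rules, output, ctx))
}

#' Filter a rule base
#'
#' Removes duplicate rules and resolves inconsistencies: rules sharing an
#' identical antecedent but different consequents are reduced to the most
#' frequent consequent; frequency ties are broken in favour of the
#' consequent with the lower defuzzified value, i.e. the easier game level
#' (clinically conservative). Idempotent; never increases the rule count.
#'
#' @param rules A `chc_rulebase` or a tibble with the antecedent columns,
#'   `consequent`, and optionally a prior support count `n`.
#' @param ctx Context used to defuzzify consequents for tie-breaking.
#' @return A `chc_rulebase` with one row per surviving rule and its support
#'   count `n`.
#' @export
filter_rules <- function(rules, ctx = attr(rules, "context") %||% linguistic_context()) {
  output <- attr(rules, "output") %||% "value"
  rules <- as_tibble(rules)
  ante <- intersect(acer_short(), names(rules))
  if (nrow(rules) == 0) {
    return(new_rulebase(rules, output, ctx))
  }
  if (!"n" %in% names(rules)) rules$n <- 1L
  out <- rules |>
    dplyr::count(dplyr::across(dplyr::all_of(c(ante, "consequent"))),
      wt = .data$n, name = "n"
    ) |>
    dplyr::mutate(.dee = dee_defuzzify(.data$consequent, ctx)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ante))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$.dee, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".dee")
  new_rulebase(out, output, ctx)
}

# Antecedent firing degrees of every rule at every query row.
# x: n x 5 matrix of normalized inputs; returns n x R matrix.
rule_degrees <- function(rulebase, x, ctx) {
  ante <- as.matrix(as_tibble(rulebase)[acer_short()])
  n <- nrow(x)
  deg <- matrix(1, n, nrow(ante))
  for (j in seq_len(5)) {
    labels <- ante[, j]
    for (lab in unique(labels)) {
      mem <- membership(lab, x[, j], ctx)
      deg[, labels == lab] <- pmin(deg[, labels == lab, drop = FALSE], mem)
    }
  }
  deg
}

# Specificity of each rule's antecedent: sum of expression ranks
# (wildcard "any" contributes 0).
rule_specificity <- function(rulebase) {
  ante <- as.matrix(as_tibble(rulebase)[acer_short()])
  cat_tbl <- expression_catalog()
  rk <- matrix(cat_tbl$rank[match(ante, cat_tbl$label)], nrow = nrow(ante))
  rk[is.na(rk)] <- 0
  rowSums(rk)
}

#' Perception-based logical deduction
#'
#' Fires the rule whose antecedent best matches the observation: the firing
#' degree of a rule is the minimum membership over its five antecedent
#' expressions (Goedel conjunction); among rules within `1e-9` of the
#' maximal degree, the most specific antecedent wins (sum of expression
#' specificity ranks), ties then going to the earliest rule.
#'
#' @param rulebase A `chc_rulebase` from [learn_rules()].
#' @param observation Numeric vector of the five normalised ACE-R values, or
#'   a one-row data frame with the `*_norm` columns.
#' @param ctx A [linguistic_context()].
#' @return A list with `rule` (one-row tibble), `index`, and `degree`.
#'   Signals an error of class `chclevels_no_perception` when every rule
#'   fires at degree 0 (the observation lies outside learned experience).
#' @export
pbld_infer <- function(rulebase, observation,
                       ctx = attr(rulebase, "context") %||% linguistic_context()) {
  if (nrow(rulebase) == 0) {
    abort("Rule base is empty.", class = "chclevels_validation_error")
  }
  if (is.data.frame(observation)) {
    observation <- drop(acer_profile_matrix(observation))
  }
  x <- matrix(observation, nrow = 1)
  deg <- drop(rule_degrees(rulebase, x, ctx))
  if (max(deg) <= 0) {
    abort("No perception: every rule fires at degree 0 for this observation.",
      class = "chclevels_no_perception"
    )
  }
  cand <- which(deg >= max(deg) - 1e-9)
  spec <- rule_specificity(rulebase)
  winner <- cand[order(-spec[cand], cand)][1]
  list(
    rule = as_tibble(rulebase)[winner, ], index = winner,
    degree = deg[winner]
  )
}

#' Learn the full fuzzy expert model
#'
#' Learns one rule base per CHC domain from observations of normalised
#' ACE-R profiles and per-domain output saturations. When the CHC columns
#' are absent they are generated with the expert conversion, so
#' `fes_learn(profiles)` learns a linguistic surrogate of the transfer
#' calculation.
#'
#' @param data A data frame with the five `*_norm` columns; optionally the
#'   nine CHC saturation columns to learn from (otherwise computed from
#'   `matrix`).
#' @param matrix A [transfer_matrix()], used for missing targets and as the
#'   fallback predictor for out-of-experience observations.
#' @param ctx A [linguistic_context()].
#' @return An object of class `chc_fes`: list of nine `chc_rulebase`s plus
#'   the matrix and context.
#' @export
#' @examples
#' fes <- fes_learn(mlp_training_set(25, seed = 1))
#' glance(fes)
fes_learn <- function(data, matrix = default_transfer_matrix(),
                      ctx = linguistic_context()) {
  data <- as_tibble(data)
  if (!all(chc_domains() %in% names(data))) {
    x <- acer_profile_matrix(data)
    sat <- as_tibble(chc_saturation_matrix(x, matrix))
    data <- dplyr::bind_cols(
      data[setdiff(names(data), chc_domains())], sat
    )
  }
  rulebases <- lapply(chc_domains(), function(dom) {
    learn_rules(data, output = dom, ctx = ctx)
  })
  names(rulebases) <- chc_domains()
  structure(list(rulebases = rulebases, matrix = matrix, ctx = ctx),
    class = "chc_fes"
  )
}

#' @export
print.chc_fes <- function(x, ...) {
  cat(sprintf(
    "<chc_fes> linguistic fuzzy model: %s rules over 9 CHC domains\n",
    sum(vapply(x$rulebases, nrow, integer(1)))
  ))
  invisible(x)
}

#' Predict with the fuzzy expert model
#'
#' Per CHC domain: perception-based logical deduction selects the firing
#' rule, its consequent is defuzzified, and (for `type = "level"`) the crisp
#' value is segmented into a game level. Observations at which no rule fires
#' (degree 0 everywhere) fall back to the expert conversion for that domain;
#' a warning reports how many fallbacks occurred.
#'
#' @param object A `chc_fes` model.
#' @param newdata A data frame with the five `*_norm` columns.
#' @param type `"saturation"` or `"level"`.
#' @param ... Unused.
#' @return A tibble: non-score columns of `newdata` plus nine CHC columns.
#' @export
predict.chc_fes <- function(object, newdata,
                            type = c("saturation", "level"), ...) {
  type <- match.arg(type)
  x <- acer_profile_matrix(newdata)
  oracle <- chc_saturation_matrix(x, object$matrix)
  n_fallback <- 0L
  out <- matrix(NA_real_, nrow(x), 9, dimnames = list(NULL, chc_domains()))
  for (dom in chc_domains()) {
    rb <- object$rulebases[[dom]]
    deg <- rule_degrees(rb, x, object$ctx)
    spec <- rule_specificity(rb)
    dee <- dee_defuzzify(rb$consequent, object$ctx)
    winner <- apply(deg, 1, function(row) {
      m <- max(row)
      if (m <= 0) {
        return(NA_integer_)
      }
      cand <- which(row >= m - 1e-9)
      cand[order(-spec[cand], cand)][1]
    })
    vals <- dee[winner]
    miss <- is.na(winner)
    n_fallback <- n_fallback + sum(miss)
    vals[miss] <- oracle[miss, dom]
    out[, dom] <- vals
  }
  if (n_fallback > 0) {
    warn(sprintf(
      "No perception for %d (patient, domain) observation(s); expert conversion used as fallback.",
      n_fallback
    ))
  }
  out <- as_tibble(out)
  if (type == "level") {
    out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), saturation_to_level))
  }
  keep <- setdiff(names(newdata), c(chc_domains(), paste0(acer_domains(), "_norm")))
  dplyr::bind_cols(as_tibble(newdata)[keep], out)
}

#' @method tidy chc_fes
#' @export
tidy.chc_fes <- function(x, ...) {
  purrr::imap(x$rulebases, function(rb, dom) {
    dplyr::mutate(as_tibble(rb), domain = dom, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' @method glance chc_fes
#' @export
glance.chc_fes <- function(x, ...) {
  tibble(
    domain = chc_domains(),
    n_rules = vapply(x$rulebases, nrow, integer(1))
  )
}

format_rule_line <- function(rule, output) {
  ante <- paste(
    sprintf("%s is %s", acer_short(), unlist(rule[acer_short()])),
    collapse = " AND "
  )
  sprintf("IF %s THEN %s is %s", ante, output, rule$consequent)
}

#' Serialise fuzzy rule bases as text
#'
#' One plain-text file per CHC domain (`rules_gc.txt`, ...), one rule per
#' line in the form
#' `IF ao is <expr> AND mem is <expr> ... THEN gc is <expr>`.
#' Reading back a written directory reproduces the model exactly.
#'
#' @param object A `chc_fes` model.
#' @param dir Directory to write into (created if absent).
#' @param matrix Transfer matrix to attach to the restored model (fallback
#'   predictor).
#' @return `write_fes()` returns `dir` invisibly; `read_fes()` a `chc_fes`.
#' @export
write_fes <- function(object, dir) {
  stopifnot(inherits(object, "chc_fes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (dom in chc_domains()) {
    rb <- object$rulebases[[dom]]
    lines <- vapply(
      seq_len(nrow(rb)),
      function(i) format_rule_line(rb[i, ], dom), character(1)
    )
    writeLines(lines, file.path(dir, paste0("rules_", dom, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_fes
#' @export
read_fes <- function(dir, matrix = default_transfer_matrix()) {
  ctx <- linguistic_context()
  pattern <- paste0(
    "^IF ", paste(sprintf("%s is (.+)", acer_short()), collapse = " AND "),
    " THEN [a-z]+ is (.+)$"
  )
  rulebases <- lapply(chc_domains(), function(dom) {
    path <- file.path(dir, paste0("rules_", dom, ".txt"))
    if (!file.exists(path)) {
      abort(sprintf("Missing rule file: %s", path),
        class = "chclevels_config_error"
      )
    }
    lines <- readLines(path)
    m <- regmatches(lines, regexec(pattern, lines))
    bad <- vapply(m, length, integer(1)) != 7
    if (any(bad)) {
      abort(sprintf("Unparseable rule in %s, line %d.", path, which(bad)[1]),
        class = "chclevels_config_error"
      )
    }
    parts <- do.call(rbind, lapply(m, `[`, -1))
    rules <- as_tibble(setNames(
      as.data.frame(parts, stringsAsFactors = FALSE),
      c(acer_short(), "consequent")
    ))
    rules$n <- 1L
    new_rulebase(rules, dom, ctx)
  })
  names(rulebases) <- chc_domains()
  structure(list(rulebases = rulebases, matrix = matrix, ctx = ctx),
    class = "chc_fes"
  )
}
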