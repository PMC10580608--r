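#' Simulate a patient cohort
#'
#' Generates a synthetic cohort with the demographic structure of a
#' neurorehabilitation clinic population: exact sex and education counts,
#' uniform integer ages, and ACE-R subscores from a one-latent-factor
#' severity model. Each patient has a severity `u ~ Uniform(0, 1)`; every
#' normalised subscore is `u` plus independent Gaussian noise, clipped to
#' `[0, 1]`, so the five subscores are positively correlated within patient.
#' Raw scores are the normalised scores scaled to the schema maxima and
#' rounded to whole points. Expert level labels come from
#' [simulate_expert_labels()].
#'
#' Defaults reproduce the reference study population: 703 patients (351 men,
#' 352 women), ages 19-97, education counts 126 primary / 182 vocational /
#' 254 secondary / 141 university.
#'
#' @param n Number of patients.
#' @param male Number of male patients (`<= n`).
#' @param age_range Integer age bounds, inclusive.
#' @param education Counts for the four education strata (primary,
#'   vocational, secondary, university); must sum to `n`.
#' @param severity_sd Standard deviation of the per-subscore Gaussian noise
#'   around the latent severity (default 0.1).
#' @param label_noise Probability that an expert label deviates one level
#'   from the conversion (see [simulate_expert_labels()]).
#' @param schema An [acer_schema()] for raw-point scaling.
#' @param matrix A [transfer_matrix()] for the expert labels.
#' @param seed Integer seed; the whole cohort is reproducible under it.
#' @return A tibble with columns `id`, `sex`, `age`, `education`, five raw
#'   ACE-R columns, five `*_norm` columns, and nine expert level columns.
#' @export
#' @examples
#' coh <- simulate_cohort(n = 20, male = 10, education = c(5, 5, 5, 5), seed = 1)
#' dplyr::count(coh, sex)
simulate_cohort <- function(n = 703, male = 351, age_range = c(19, 97),
                            education = c(
                              primary = 126, vocational = 182,
                              secondary = 254, university = 141
                            ),
                            severity_sd = 0.1, label_noise = 0.05,
                            schema = acer_schema(),
                            matrix = default_transfer_matrix(), seed = NULL) {
  if (male > n || male < 0) {
    abort("male count must be between 0 and n.",
      class = "chclevels_validation_error"
    )
  }
  if (length(education) != 4 || sum(education) != n) {
    abort("education must hold four counts summing to n.",
      class = "chclevels_validation_error"
    )
  }
  if (label_noise < 0 || label_noise > 1) {
    abort("label_noise must be a probability.",
      class = "chclevels_validation_error"
    )
  }
  if (!is.null(seed)) set.seed(derive_seed(seed, "cohort"))
  edu_levels <- c("primary", "vocational", "secondary", "university")
  cohort <- tibble(
    id = seq_len(n),
    sex = sample(rep(c("male", "female"), times = c(male, n - male))),
    age = sample(seq(age_range[1], age_range[2]), n, replace = TRUE),
    education = sample(rep(edu_levels, times = education))
  )
  u <- runif(n)
  norm <- pmin(pmax(u + matrix(rnorm(n * 5, 0, severity_sd), n, 5), 0), 1)
  colnames(norm) <- paste0(acer_domains(), "_norm")
  raw <- round(sweep(norm, 2, as.numeric(schema), "*"))
  colnames(raw) <- acer_domains()
  cohort <- dplyr::bind_cols(cohort, as_tibble(raw), as_tibble(norm))
  labels <- simulate_expert_labels(cohort, matrix,
    noise_p = label_noise,
    seed = if (!is.null(seed)) derive_seed(seed, "labels")
  )
  dplyr::bind_cols(cohort, labels[chc_domains()])
}

#' Simulate expert-assigned levels
#'
#' Stands in for clinicians' level assignments: the expert conversion's
#' recommended levels, each independently shifted by one level up or down
#' (equiprobably, clipped to 1-6) with probability `noise_p`. With
#' `noise_p = 0` the labels reproduce the conversion exactly.
#'
#' @param cohort A data frame with the five `*_norm` ACE-R columns.
#' @param matrix A [transfer_matrix()].
#' @param noise_p Per-(patient, domain) disagreement probability.
#' @param seed Integer seed.
#' @return A tibble with the `id` column of `cohort` (if present) and nine
#'   integer level columns.
#' @export
simulate_expert_labels <- function(cohort, matrix = default_transfer_matrix(),
                                   noise_p = 0, seed = NULL) {
  if (noise_p < 0 || noise_p > 1) {
    abort("noise_p must be a probability.", class = "chclevels_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  base <- recommend_levels(cohort, matrix)
  lv <- level_matrix(base)
  flip <- matrix(runif(length(lv)) < noise_p, nrow(lv))
  delta <- matrix(sample(c(-1L, 1L), length(lv), replace = TRUE), nrow(lv))
  lv <- pmin(pmax(lv + flip * delta, 1L), 6L)
  out <- as_tibble(lv)
  if ("id" %in% names(cohort)) {
    out <- dplyr::bind_cols(tibble(id = cohort$id), out)
  }
  out
}
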