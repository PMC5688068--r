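#' Specify a synthetic two-group VOC cohort
#'
#' Describes the statistical structure of a simulated SPME GC-MS urine
#' profiling study: two groups of subjects, log-normal feature abundances with
#' feature-specific spread, a planted subset of discriminating features whose
#' group-2 log-mean is shifted, per-subject presence/absence driven by
#' occurrence probabilities, and multiplicative technical-replicate noise.
#' Defaults mirror a 28 vs 21 child cohort profiled under alkaline headspace
#' conditions (83 features, triplicate injections).
#'
#' @param n_group1,n_group2 Subjects per group (group 1 = "NW", group 2 =
#'   "OW/Ob").
#' @param n_features Number of VOC features (internal-standard channels are
#'   added on top, see [generate_cohort()]).
#' @param n_informative How many features carry a real group difference.
#' @param effect_size Log-scale mean shift of informative features in group 2,
#'   in units of the feature's own log-SD.
#' @param occurrence_probs Per-feature probability that a feature is present
#'   (detectable) in a given subject; scalar values are recycled. In (0, 1].
#' @param n_replicates Technical replicates (injections) per subject.
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   replicate noise (0 disables it).
#' @param seed Integer seed; identical specs generate identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [generate_null()]
#' @export
#' @examples
#' cohort_spec(n_features = 50, n_informative = 5, effect_size = 2, seed = 7)
cohort_spec <- function(n_group1 = 28, n_group2 = 21, n_features = 83,
                        n_informative = 14, effect_size = 1.5,
                        occurrence_probs = 1, n_replicates = 3,
                        replicate_cv = 0.15, seed = 1L) {
  n_group1 <- .check_count(n_group1, "n_group1", min = 2L)
  n_group2 <- .check_count(n_group2, "n_group2", min = 2L)
  n_features <- .check_count(n_features, "n_features")
  n_informative <- .check_count(n_informative, "n_informative", min = 0L)
  n_replicates <- .check_count(n_replicates, "n_replicates")
  if (n_informative > n_features) {
    abort("`n_informative` must not exceed `n_features`.",
          class = "voclearn_error_parameter")
  }
  if (!is.numeric(effect_size) || length(effect_size) != 1 || is.na(effect_size)) {
    abort("`effect_size` must be a single real number.",
          class = "voclearn_error_parameter")
  }
  .check_prob(occurrence_probs, "occurrence_probs")
  if (!length(occurrence_probs) %in% c(1L, n_features)) {
    abort("`occurrence_probs` must have length 1 or `n_features`.",
          class = "voclearn_error_parameter")
  }
  if (!is.numeric(replicate_cv) || length(replicate_cv) != 1 || replicate_cv < 0) {
    abort("`replicate_cv` must be a single nonnegative number.",
          class = "voclearn_error_parameter")
  }
  structure(
    list(
      n_group1 = n_group1, n_group2 = n_group2, n_features = n_features,
      n_informative = n_informative, effect_size = effect_size,
      occurrence_probs = rep_len(occurrence_probs, n_features),
      n_replicates = n_replicates, replicate_cv = replicate_cv,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %d + %d subjects, %d features (%d informative, effect %.2f), %d replicate(s), cv %.2f, seed %d\n",
    x$n_group1, x$n_group2, x$n_features, x$n_informative, x$effect_size,
    x$n_replicates, x$replicate_cv, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic VOC cohort
#'
#' Simulates a two-group cohort under the model of [cohort_spec()]. Each
#' feature j has a log-normal abundance with log-mean drawn uniform in
#' \[1, 4\] and log-SD drawn uniform in \[0.3, 1\] (the right-skew typical of
#' GC-MS peak-area ratios, for which log + autoscale is the natural
#' preprocessing). Informative features get their group-2 log-mean shifted by
#' `effect_size` log-SD units *before* replicate noise, so the signal
#' survives the median-of-replicates step. A feature is absent in a subject
#' (all of that subject's replicates `NA`) with probability
#' `1 - occurrence_prob`. Six internal-standard channels (`IS_1`..`IS_6`,
#' mirroring a six-compound spike) are appended: always present, no group
#' effect, low biological spread.
#'
#' @param spec A [cohort_spec()].
#'
#' @return An object of class `voc_cohort`: a list with
#'   * `table`: tibble with columns `subject_id`, `group` (factor `NW`,
#'     `OW/Ob`), `replicate`, feature columns `V...` and `IS_1`..`IS_6`;
#'   * `truth`: character vector of informative feature ids;
#'   * `is_mapping`: named character vector mapping each feature to its
#'     internal standard (round-robin), for
#'     [normalize_to_internal_standard()];
#'   * `spec`: the input spec.
#' @export
#' @examples
#' ch <- generate_cohort(cohort_spec(n_features = 20, n_informative = 3, seed = 1))
#' ch$truth
#' dplyr::glimpse(ch$table[, 1:6])
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be created by cohort_spec().",
          class = "voclearn_error_parameter")
  }
  .with_seed(spec$seed, {
    p <- spec$n_features
    n1 <- spec$n_group1
    n2 <- spec$n_group2
    n <- n1 + n2
    feature_ids <- sprintf("V%03d", seq_len(p))
    is_ids <- sprintf("IS_%d", 1:6)

    log_mu <- runif(p, 1, 4)
    log_sd <- runif(p, 0.3, 1.0)
    informative <- if (spec$n_informative > 0) {
      sort(sample.int(p, spec$n_informative))
    } else {
      integer(0)
    }

    group <- factor(rep(c("NW", "OW/Ob"), c(n1, n2)), levels = c("NW", "OW/Ob"))
    # subject-level true log abundances
    Z <- matrix(rnorm(n * p, mean = rep(log_mu, each = n),
                      sd = rep(log_sd, each = n)), n, p)
    if (length(informative)) {
      shift <- spec$effect_size * log_sd[informative]
      Z[group == "OW/Ob", informative] <-
        Z[group == "OW/Ob", informative, drop = FALSE] +
        rep(shift, each = n2)
    }
    # per-subject presence mask
    present <- matrix(runif(n * p) <= rep(spec$occurrence_probs, each = n), n, p)
    Z[!present] <- NA_real_

    # internal standards: same spike in every subject, small variability
    ZIS <- matrix(rnorm(n * 6, mean = log(100), sd = 0.05), n, 6)

    r <- spec$n_replicates
    sdlog <- if (spec$replicate_cv > 0) sqrt(log(1 + spec$replicate_cv^2)) else 0
    rep_noise <- function(k) {
      if (sdlog == 0) return(matrix(1, n, k))
      matrix(rlnorm(n * k, meanlog = -sdlog^2 / 2, sdlog = sdlog), n, k)
    }
    rows <- vector("list", r)
    for (ri in seq_len(r)) {
      A <- exp(Z) * rep_noise(p)
      AIS <- exp(ZIS) * rep_noise(6)
      rows[[ri]] <- tibble::tibble(
        subject_id = sprintf("S%03d", seq_len(n)),
        group = group,
        replicate = ri
      ) |>
        dplyr::bind_cols(
          tibble::as_tibble(`colnames<-`(A, feature_ids)),
          tibble::as_tibble(`colnames<-`(AIS, is_ids))
        )
    }
    table <- dplyr::arrange(dplyr::bind_rows(rows), .data$subject_id,
                            .data$replicate)
    structure(
      list(
        table = table,
        truth = feature_ids[informative],
        is_mapping = setNames(is_ids[(seq_len(p) - 1L) %% 6L + 1L], feature_ids),
        spec = spec
      ),
      class = "voc_cohort"
    )
  })
}

#' Generate a null cohort (no informative features)
#'
#' Same generative model as [generate_cohort()] with `n_informative` forced to
#' zero, so group labels are exchangeable. Used for permutation-test and
#' selection calibration.
#'
#' @inheritParams generate_cohort
#' @return A `voc_cohort` whose `truth` set is empty.
#' @export
generate_null <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be created by cohort_spec().",
          class = "voclearn_error_parameter")
  }
  spec$n_informative <- 0L
  generate_cohort(spec)
}

#' @export
print.voc_cohort <- function(x, ...) {
  cat(sprintf(
    "<voc_cohort> %d injections x %d features (+6 IS), %d informative\n",
    nrow(x$table), x$spec$n_features, length(x$truth)
  ))
  invisible(x)
}
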