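#' Define a permutation exchange scheme
#'
#' A scheme names the exchangeable units of a permutation test and supplies
#' the function that produces one randomized copy of the data. Presets are
#' provided for the analyses' schemes: [scheme_image_conditions()],
#' [scheme_areas()], [scheme_areas_conditions()], [scheme_voxel_groups()],
#' [scheme_voxels_predictors()], all of which shuffle the stated label
#' column(s) jointly across rows of a tibble.
#'
#' @param name Scheme identifier recorded in results.
#' @param permute Function `data -> data` returning one randomization.
#' @return Object of class `rnc_perm_scheme`.
#' @export
perm_scheme <- function(name, permute) {
  stopifnot(is.function(permute))
  structure(list(name = name, permute = permute), class = "rnc_perm_scheme")
}

scheme_shuffle_labels <- function(name, cols) {
  perm_scheme(name, function(data) {
    ix <- sample.int(nrow(data))
    data[cols] <- data[ix, cols, drop = FALSE]
    data
  })
}

#' @rdname perm_scheme
#' @export
scheme_image_conditions <- function() {
  scheme_shuffle_labels("image_conditions", "condition")
}

#' @rdname perm_scheme
#' @export
scheme_areas <- function() scheme_shuffle_labels("areas", "area")

#' @rdname perm_scheme
#' @export
scheme_areas_conditions <- function() {
  scheme_shuffle_labels("areas_conditions", c("area", "condition"))
}

#' @rdname perm_scheme
#' @export
scheme_voxel_groups <- function() {
  scheme_shuffle_labels("voxel_groups", "voxel_group")
}

#' @rdname perm_scheme
#' @export
scheme_voxels_predictors <- function() {
  scheme_shuffle_labels("voxels_predictors", c("voxel", "predictor"))
}

#' Within-participant permutation test
#'
#' Computes the observed statistic, rebuilds it under `n_perm` random
#' permutations of the data defined by the exchange scheme, and reports the
#' plain-proportion p-value: the fraction of randomized statistics as or
#' more extreme than the observed one (one-sided: `>=` on the statistic;
#' two-sided: `>=` on its absolute value). An optional add-one smoothing is
#' available but off by default. Permutations on which the statistic is
#' undefined (`NA`) are rejected and redrawn, with a message.
#'
#' @param data A tibble (or any object the statistic and scheme accept).
#' @param statistic Function `data -> scalar`.
#' @param scheme An [perm_scheme()] or a bare permute function.
#' @param n_perm Number of permutations (default 1e5).
#' @param sidedness `"two"` or `"one"`.
#' @param seed Integer seed.
#' @param smoothing Add-one smoothing `(sum + 1) / (n_perm + 1)` if `TRUE`.
#' @return Object of class `rnc_perm` with fields `observed`, `p`,
#'   `n_perm`, `sidedness`, `scheme`.
#' @export
permutation_test <- function(data, statistic, scheme, n_perm = 1e5,
                             sidedness = c("two", "one"), seed = 1,
                             smoothing = FALSE) {
  sidedness <- match.arg(sidedness)
  if (is.function(scheme)) scheme <- perm_scheme("custom", scheme)
  stopifnot(inherits(scheme, "rnc_perm_scheme"))
  observed <- statistic(data)
  stopifnot(is.finite(observed))
  set.seed(seed)
  perms <- numeric(n_perm)
  rejected <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      s <- statistic(scheme$permute(data))
      if (!is.na(s)) break
      rejected <- rejected + 1L
    }
    perms[i] <- s
  }
  if (rejected > 0) {
    message(sprintf("%d permutation(s) with undefined statistic were redrawn.",
                    rejected))
  }
  extreme <- if (sidedness == "two") sum(abs(perms) >= abs(observed)) else
    sum(perms >= observed)
  p <- if (smoothing) (extreme + 1) / (n_perm + 1) else extreme / n_perm
  structure(list(observed = observed, p = p, n_perm = as.integer(n_perm),
                 sidedness = sidedness, scheme = scheme$name,
                 seed = as.integer(seed)),
            class = "rnc_perm")
}

#' @export
print.rnc_perm <- function(x, ...) {
  cat(sprintf("<rnc_perm> observed %.4g, p = %.4g (%s-sided, %d permutations, scheme %s)\n",
              x$observed, x$p, x$sidedness, x$n_perm, x$scheme))
  invisible(x)
}

#' @export
tidy.rnc_perm <- function(x, ...) {
  tibble::tibble(observed = x$observed, p = x$p, n_perm = x$n_perm,
                 sidedness = x$sidedness, scheme = x$scheme)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; significance at the conventional
#' 0.05 level is assessed on the adjusted values.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same length, clipped to 1).
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Population prevalence p-value
#'
#' Second-level inference on the count of within-participant-significant
#' participants: `P = 1 - BinomCDF(k; n, a)`, the probability of observing
#' more than `k` significant participants by chance under the null of no
#' effect in any member of the population.
#'
#' @param k Significant participants (0 <= k <= n).
#' @param n Total participants.
#' @param a Per-participant alpha (default 0.05).
#' @return Object of class `rnc_prevalence` with fields `k`, `n`, `a`, `p`.
#' @export
prevalence_pvalue <- function(k, n, a = 0.05) {
  if (length(k) != 1 || length(n) != 1 || k < 0 || k > n || n < 1) {
    stop("need 0 <= k <= n with n >= 1.", call. = FALSE)
  }
  # upper tail of the binomial CDF, computed without 1 - CDF cancellation
  p <- stats::pbinom(k, n, a, lower.tail = FALSE)
  structure(list(k = as.integer(k), n = as.integer(n), a = a, p = p),
            class = "rnc_prevalence")
}

#' @export
print.rnc_prevalence <- function(x, ...) {
  cat(sprintf("<rnc_prevalence> %d/%d significant at alpha %.2f: P = %.4g\n",
              x$k, x$n, x$a, x$p))
  invisible(x)
}

#' @export
tidy.rnc_prevalence <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, a = x$a, p = x$p)
}

#' Bootstrap confidence interval over participants
#'
#' Resamples participants with replacement `n_boot` times, recomputes the
#' statistic (default: mean) on every resample, and reads the interval off
#' the empirical percentiles.
#'
#' @param values Per-participant statistic values (length >= 2).
#' @param n_boot Bootstrap samples (default 1e5).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param statistic Function applied to each resample (default `mean`).
#' @return Object of class `rnc_boot` with `lower`, `upper`, `estimate`.
#' @export
bootstrap_ci <- function(values, n_boot = 1e5, level = 0.95, seed = 1,
                         statistic = mean) {
  stopifnot(length(values) >= 2, level > 0, level < 1)
  set.seed(seed)
  n <- length(values)
  if (identical(statistic, mean)) {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n_boot, n)
    boot <- rowMeans(matrix(values[idx], n_boot, n))
  } else {
    boot <- vapply(seq_len(n_boot), function(i) {
      statistic(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  }
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(estimate = statistic(values), lower = qs[1], upper = qs[2],
                 n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed)),
            class = "rnc_boot")
}

#' @export
print.rnc_boot <- function(x, ...) {
  cat(sprintf("<rnc_boot> estimate %.4g, %g%% CI [%.4g, %.4g] (%d resamples)\n",
              x$estimate, 100 * x$level, x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' @export
tidy.rnc_boot <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, lower = x$lower, upper = x$upper,
                 level = x$level, n_boot = x$n_boot)
}
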