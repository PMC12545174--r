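#' Construct a pluggable encoding model
#'
#' An encoding model maps a stimulus batch to an in silico response matrix
#' (stimuli by voxels, z-units). The mapping must be deterministic. Trained
#' deep encoders, linearizing feature models and the package's toy
#' image-computable encoders all satisfy the same contract.
#'
#' @param participant,area Identifiers.
#' @param voxel_count Number of voxels the model predicts.
#' @param predict Function `(model, stimuli) -> matrix[stimuli x voxels]`.
#'   `stimuli` may be image ids with feature vectors or pixel arrays,
#'   depending on the model.
#' @param ... Extra fields stored on the model (e.g. weights, windows).
#' @return An object of class `rnc_encoding_model`.
#' @export
encoding_model <- function(participant, area, voxel_count, predict, ...) {
  stopifnot(is.function(predict), voxel_count >= 1)
  structure(list(participant = as.character(participant),
                 area = as.character(area),
                 voxel_count = as.integer(voxel_count),
                 predict = predict, ...),
            class = "rnc_encoding_model")
}

#' Generate in silico responses from an encoding model
#'
#' @param model An [encoding_model()].
#' @param stimuli The stimulus batch in whatever form the model accepts.
#' @return Matrix, stimuli by `model$voxel_count`.
#' @export
predict_responses <- function(model, stimuli) {
  stopifnot(inherits(model, "rnc_encoding_model"))
  out <- model$predict(model, stimuli)
  if (ncol(out) != model$voxel_count) {
    stop("encoding model returned wrong voxel count.", call. = FALSE)
  }
  out
}

#' @export
print.rnc_encoding_model <- function(x, ...) {
  cat(sprintf("<rnc_encoding_model> participant %s, area %s, %d voxels\n",
              x$participant, x$area, x$voxel_count))
  invisible(x)
}

#' Noise-ceiling signal-to-noise ratio per voxel
#'
#' From z-scored trial betas with repeated image presentations, estimates per
#' voxel the noise sd (square root of the across-repeat variance, n-1
#' estimator, averaged over images), the signal sd (positive half-wave
#' rectified `sqrt(1 - sigma_noise^2)`, valid because z-scored betas have
#' unit total variance), and their ratio NCSNR. A zero noise sd maps to
#' `ncsnr = Inf`.
#'
#' @param trials z-scored [trial_betas()]; every image needs >= 2 repeats.
#' @return A tibble of class `rnc_noise_profile` with columns `voxel`,
#'   `sigma_noise`, `sigma_signal`, `ncsnr`.
#' @export
compute_ncsnr <- function(trials) {
  stopifnot(inherits(trials, "rnc_trial_betas"))
  ids <- unique(trials$image_id)
  reps <- table(trials$image_id)
  if (any(reps < 2)) {
    stop("every image needs at least 2 repeats to estimate noise variance.",
         call. = FALSE)
  }
  total_var <- apply(trials$betas, 2, stats::var)
  if (any(abs(total_var - 1) > 0.25)) {
    warning("per-voxel overall variance is far from 1; betas may not be z-scored.",
            call. = FALSE)
  }
  nv <- ncol(trials$betas)
  var_sum <- numeric(nv)
  for (id in ids) {
    rows <- trials$betas[trials$image_id == id, , drop = FALSE]
    mu <- colMeans(rows)
    var_sum <- var_sum + colSums(sweep(rows, 2, mu)^2) / (nrow(rows) - 1)
  }
  sigma_noise <- sqrt(var_sum / length(ids))
  sigma_signal <- sqrt(pmax(1 - sigma_noise^2, 0))
  ncsnr <- ifelse(sigma_noise == 0, Inf, sigma_signal / sigma_noise)
  structure(tibble::tibble(voxel = seq_len(nv), sigma_noise = sigma_noise,
                           sigma_signal = sigma_signal, ncsnr = ncsnr),
            class = c("rnc_noise_profile", class(tibble::tibble())))
}

#' Noise ceiling from NCSNR and number of averaged trials
#'
#' `NC = 100 * NCSNR^2 / (NCSNR^2 + 1/n)`, in percent: the maximum variance
#' any model can explain in responses averaged over `n` trials, given the
#' voxel's measurement noise. `NC(Inf) = 100` by the limit.
#'
#' @param ncsnr Dimensionless NCSNR (vectorized, >= 0, may be `Inf`).
#' @param n Number of trials averaged in the target responses (>= 1).
#' @return Noise ceiling in percent, in `[0, 100]`.
#' @export
noise_ceiling <- function(ncsnr, n) {
  if (length(n) != 1 || n < 1) stop("`n` must be a single integer >= 1.",
                                    call. = FALSE)
  stopifnot(all(ncsnr >= 0))
  ifelse(is.infinite(ncsnr), 100, 100 * ncsnr^2 / (ncsnr^2 + 1 / n))
}

#' Noise-ceiling-normalized encoding accuracy
#'
#' Correlates prediction and target per voxel across stimuli, rectifies
#' negative correlations to zero, squares, and divides the explained
#' variance by each voxel's noise ceiling for `n` averaged trials:
#' `nnev = 100 * r^2 / (NC/100)`, capped at 100.
#'
#' @param pred,target Matrices, stimuli by voxels, matching shapes, >= 3
#'   stimuli. Zero-variance columns yield `r = 0` (reported via a message).
#' @param noise An `rnc_noise_profile` from [compute_ncsnr()], or a numeric
#'   vector of NCSNR values.
#' @param n Trials averaged in `target`.
#' @return A tibble of class `rnc_encoding_eval` with columns `voxel`, `r`,
#'   `r2`, `nc`, `nnev`; the voxel-mean nnev is in attribute
#'   `area_mean_nnev` and via [glance()].
#' @export
evaluate_encoding <- function(pred, target, noise, n) {
  pred <- as.matrix(pred); target <- as.matrix(target)
  stopifnot(identical(dim(pred), dim(target)), nrow(pred) >= 3)
  ncsnr <- if (inherits(noise, "rnc_noise_profile")) noise$ncsnr else as.numeric(noise)
  stopifnot(length(ncsnr) == ncol(pred))
  sd_p <- apply(pred, 2, stats::sd)
  sd_t <- apply(target, 2, stats::sd)
  degenerate <- sd_p == 0 | sd_t == 0
  r <- numeric(ncol(pred))
  ok <- which(!degenerate)
  if (length(ok)) {
    r[ok] <- vapply(ok, function(j) stats::cor(pred[, j], target[, j]),
                    numeric(1))
  }
  if (any(degenerate)) {
    message(sprintf("%d voxel(s) with zero-variance prediction or target; r set to 0.",
                    sum(degenerate)))
  }
  r2 <- pmax(r, 0)^2
  nc <- noise_ceiling(ncsnr, n)
  nnev <- ifelse(nc == 0, 0, pmin(100 * r2 / (nc / 100), 100))
  out <- tibble::tibble(voxel = seq_len(ncol(pred)), r = r, r2 = r2,
                        nc = nc, nnev = nnev)
  structure(out, area_mean_nnev = mean(nnev),
            class = c("rnc_encoding_eval", class(tibble::tibble())))
}

#' @export
glance.rnc_encoding_eval <- function(x, ...) {
  tibble::tibble(n_voxels = nrow(x), area_mean_nnev = attr(x, "area_mean_nnev"))
}

#' Compare single-trial, trial-average and in silico predictors
#'
#' For data with exactly three repeats per image, explains each left-out
#' single trial with three predictors and the single-trial (`n = 1`) noise
#' ceiling: (a) one of the two other trials (6 ordered target/predictor
#' pairs), (b) the average of the two other trials (3 targets), (c) the in
#' silico responses (3 targets). In silico responses explaining more variance
#' than in vivo trials indicates they carry less noise.
#'
#' @param trials z-scored [trial_betas()] with exactly 3 repeats per image.
#' @param insilico An [response_set()] of model responses for the same images.
#' @param noise `rnc_noise_profile` (or NCSNR vector) for these voxels.
#' @return Tibble with columns `predictor` (`single_trial`, `trial_average`,
#'   `insilico`), `mean_nnev`, `n_predictions`.
#' @export
noise_comparison <- function(trials, insilico, noise) {
  stopifnot(inherits(trials, "rnc_trial_betas"),
            inherits(insilico, "rnc_response_set"))
  reps <- table(trials$image_id)
  if (!all(reps == 3)) {
    stop("noise_comparison requires exactly 3 repeats per image.", call. = FALSE)
  }
  ids <- unique(trials$image_id)
  stopifnot(all(ids %in% insilico$image_ids))
  nv <- ncol(trials$betas)
  # trial-index matrix: images x 3, in repeat order of appearance
  tri <- t(vapply(ids, function(id) which(trials$image_id == id),
                  integer(3)))
  trial_mat <- function(k) trials$betas[tri[, k], , drop = FALSE]
  silico <- insilico$responses[match(ids, insilico$image_ids), , drop = FALSE]
  mean_eval <- function(pred, target) {
    attr(suppressMessages(evaluate_encoding(pred, target, noise, n = 1)),
         "area_mean_nnev")
  }
  # (a) single other trial: 6 ordered (target, predictor) pairs
  pairs <- list(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  a <- mean(vapply(pairs, function(p) mean_eval(trial_mat(p[2]), trial_mat(p[1])),
                   numeric(1)))
  # (b) mean of the two other trials: 3 targets
  b <- mean(vapply(1:3, function(t) {
    others <- setdiff(1:3, t)
    mean_eval((trial_mat(others[1]) + trial_mat(others[2])) / 2, trial_mat(t))
  }, numeric(1)))
  # (c) in silico responses: 3 targets
  cc <- mean(vapply(1:3, function(t) mean_eval(silico, trial_mat(t)),
                    numeric(1)))
  tibble::tibble(predictor = c("single_trial", "trial_average", "insilico"),
                 mean_nnev = c(a, b, cc),
                 n_predictions = c(6L, 3L, 3L))
}
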