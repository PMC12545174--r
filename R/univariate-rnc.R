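#' Random-batch null distribution and baseline for univariate control
#'
#' Draws `n_samples` batches of `batch_size` images (uniformly, without
#' replacement within a batch), scores each by its mean univariate response,
#' and takes as baseline the sampled batch whose score is closest to the
#' null-distribution mean. The baseline score is the reference level that
#' controlling images must beat by the margin.
#'
#' @param profile An `rnc_profile` (see [univariate_profile()]).
#' @param batch_size Images per batch (default 25).
#' @param n_samples Number of sampled batches (default 1e6; analyses at
#'   reduced scale use fewer through the identical code path).
#' @param seed Integer seed.
#' @return An object of class `rnc_null` with fields `sample_scores`,
#'   `baseline_image_ids`, `baseline_score`.
#' @export
build_univariate_null <- function(profile, batch_size = 25, n_samples = 1e6,
                                  seed = 1) {
  n_images <- nrow(profile)
  if (batch_size > n_images) {
    stop("`batch_size` exceeds the number of images.", call. = FALSE)
  }
  values <- profile$value
  chunk <- 100000L
  batches_of_chunk <- function(m) {
    matrix(vapply(seq_len(m), function(i) sample.int(n_images, batch_size),
                  integer(batch_size)), nrow = batch_size)
  }
  # pass 1: scores only (batches are replayed from the seed in pass 2,
  # so a 1e6-sample null never holds all batches in memory)
  set.seed(seed)
  scores <- numeric(n_samples)
  done <- 0L
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    idx <- batches_of_chunk(m)                       # batch_size x m
    scores[(done + 1):(done + m)] <-
      colMeans(matrix(values[idx], batch_size, m))
    done <- done + m
  }
  null_mean <- mean(scores)
  best <- which.min(abs(scores - null_mean))
  # pass 2: replay the RNG to recover the winning batch
  set.seed(seed)
  done <- 0L
  best_batch <- NULL
  while (is.null(best_batch)) {
    m <- min(chunk, n_samples - done)
    idx <- batches_of_chunk(m)
    if (best <= done + m) best_batch <- idx[, best - done]
    done <- done + m
  }
  structure(list(kind = "univariate",
                 area = attr(profile, "area"),
                 batch_size = as.integer(batch_size),
                 n_samples = as.integer(n_samples),
                 sample_scores = scores,
                 baseline_image_ids = profile$image_id[best_batch],
                 baseline_score = scores[best]),
            class = "rnc_null")
}

#' @export
print.rnc_null <- function(x, ...) {
  cat(sprintf("<rnc_null> %s: %d batches of %d, mean %.4f, baseline %.4f\n",
              x$kind, x$n_samples, x$batch_size, mean(x$sample_scores),
              x$baseline_score))
  invisible(x)
}

#' @export
tidy.rnc_null <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$sample_scores), score = x$sample_scores)
}

#' @export
glance.rnc_null <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_samples = x$n_samples,
                 batch_size = x$batch_size,
                 null_mean = mean(x$sample_scores),
                 null_sd = stats::sd(x$sample_scores),
                 baseline_score = x$baseline_score)
}

#' @export
autoplot.rnc_null <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$baseline_score,
                        colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "batch score", y = "count",
                  title = sprintf("%s null distribution (baseline dashed)",
                                  object$kind))
}

uni_conditions <- c("drive_both", "suppress_both",
                    "drive_A_suppress_B", "drive_B_suppress_A")

condition_spec <- function(condition) {
  switch(condition,
    drive_both = list(dir_a = +1, dir_b = +1, score = "sum", decreasing = TRUE),
    suppress_both = list(dir_a = -1, dir_b = -1, score = "sum", decreasing = FALSE),
    drive_A_suppress_B = list(dir_a = +1, dir_b = -1, score = "diff", decreasing = TRUE),
    drive_B_suppress_A = list(dir_a = -1, dir_b = +1, score = "diff", decreasing = FALSE),
    stop(sprintf("unknown condition '%s'.", condition), call. = FALSE))
}

#' Select controlling images for one univariate control condition
#'
#' Candidate images must clear each area's baseline by the margin in the
#' condition's direction (drive: value above baseline + margin; suppress:
#' value below baseline - margin). Candidates are then ranked by the sum of
#' the two areas' responses (alignment conditions) or their difference A - B
#' (disentanglement conditions), and the best `n_select` returned. Ties are
#' broken by image id for determinism. If fewer than `n_select` qualify the
#' solution is flagged incomplete; an empty candidate set yields an empty,
#' flagged solution rather than an error.
#'
#' @param prof_a,prof_b `rnc_profile`s over identical image sets.
#' @param base_a,base_b Baseline scores (z-units) for the two areas, e.g.
#'   from [build_univariate_null()].
#' @param condition One of `"drive_both"`, `"suppress_both"`,
#'   `"drive_A_suppress_B"`, `"drive_B_suppress_A"`.
#' @param margin Margin in z-units (default 0.04).
#' @param n_select Maximum images to return (default 25).
#' @return An object of class `rnc_control_solution`: a tibble with columns
#'   `image_id`, `value_a`, `value_b`, `score`, ordered best first, with
#'   attributes `condition`, `complete`, `n_requested`.
#' @export
select_univariate_controls <- function(prof_a, prof_b, base_a, base_b,
                                       condition, margin = 0.04,
                                       n_select = 25) {
  stopifnot(margin >= 0)
  cs <- condition_spec(condition)
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(prof_a), value_a = "value"),
    dplyr::rename(tibble::as_tibble(prof_b), value_b = "value"),
    by = "image_id")
  if (nrow(joined) != nrow(prof_a) || nrow(joined) != nrow(prof_b)) {
    stop("profiles must be indexed by identical image sets.", call. = FALSE)
  }
  ok_a <- if (cs$dir_a > 0) joined$value_a > base_a + margin else
    joined$value_a < base_a - margin
  ok_b <- if (cs$dir_b > 0) joined$value_b > base_b + margin else
    joined$value_b < base_b - margin
  cand <- joined[ok_a & ok_b, ]
  cand$score <- if (cs$score == "sum") cand$value_a + cand$value_b else
    cand$value_a - cand$value_b
  ord <- order(if (cs$decreasing) -cand$score else cand$score, cand$image_id)
  sel <- cand[utils::head(ord, n_select), ]
  structure(sel,
            condition = condition, margin = margin,
            n_requested = as.integer(n_select),
            complete = nrow(sel) == n_select,
            class = c("rnc_control_solution", class(tibble::tibble())))
}

#' @export
tidy.rnc_control_solution <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.rnc_control_solution <- function(x, ...) {
  tibble::tibble(condition = attr(x, "condition"),
                 n_selected = nrow(x),
                 n_requested = attr(x, "n_requested"),
                 complete = attr(x, "complete"))
}

average_profiles <- function(profiles) {
  ref <- profiles[[1]]$image_id
  vals <- vapply(profiles, function(p) {
    stopifnot(identical(p$image_id, ref))
    p$value
  }, numeric(length(ref)))
  new_profile(tibble::tibble(image_id = ref, value = rowMeans(vals)),
              participant = "average", area = attr(profiles[[1]], "area"))
}

#' Participant-wise leave-one-out cross-validation of univariate control
#'
#' For each fold, image selection (and the random-batch baseline) is built
#' on the profiles averaged over the training participants, and the held-out
#' participant's mean response over the selected images evaluates the
#' solution. With n participants this yields n cross-validated solutions.
#'
#' @param profiles_a,profiles_b Named lists of `rnc_profile`s, one per
#'   participant, areas A and B respectively.
#' @param condition Control condition label (see
#'   [select_univariate_controls()]).
#' @param margin,n_select Selection parameters.
#' @param batch_size,n_samples Null-distribution parameters per fold.
#' @param seed Integer seed (fold f uses `seed + f` for its nulls).
#' @return An object of class `rnc_uni_cv`: list with `folds` (per-fold
#'   solutions) and `eval`, a tibble with one row per fold and area holding
#'   the left-out mean response over selected images and the left-out
#'   baseline response.
#' @export
crossval_univariate <- function(profiles_a, profiles_b, condition,
                                margin = 0.04, n_select = 25,
                                batch_size = 25, n_samples = 10000,
                                seed = 1) {
  stopifnot(length(profiles_a) == length(profiles_b),
            length(profiles_a) >= 2)
  participants <- names(profiles_a)
  if (is.null(participants)) participants <- as.character(seq_along(profiles_a))
  folds <- list()
  evals <- list()
  for (f in seq_along(participants)) {
    train <- setdiff(seq_along(participants), f)
    avg_a <- average_profiles(profiles_a[train])
    avg_b <- average_profiles(profiles_b[train])
    null_a <- build_univariate_null(avg_a, batch_size, n_samples,
                                    seed = seed + f)
    null_b <- build_univariate_null(avg_b, batch_size, n_samples,
                                    seed = seed + f + 1000L)
    sol <- select_univariate_controls(avg_a, avg_b, null_a$baseline_score,
                                      null_b$baseline_score, condition,
                                      margin, n_select)
    attr(sol, "fold") <- participants[f]
    folds[[f]] <- sol
    held_a <- profiles_a[[f]]; held_b <- profiles_b[[f]]
    eval_mean <- function(prof, ids) mean(prof$value[match(ids, prof$image_id)])
    evals[[f]] <- tibble::tibble(
      fold = participants[f],
      area = c("A", "B"),
      control_mean = c(eval_mean(held_a, sol$image_id),
                       eval_mean(held_b, sol$image_id)),
      baseline_mean = c(eval_mean(held_a, null_a$baseline_image_ids),
                        eval_mean(held_b, null_b$baseline_image_ids)),
      n_selected = nrow(sol))
  }
  structure(list(condition = condition, folds = folds,
                 eval = dplyr::bind_rows(evals)),
            class = "rnc_uni_cv")
}

#' @export
print.rnc_uni_cv <- function(x, ...) {
  cat(sprintf("<rnc_uni_cv> condition %s, %d folds\n", x$condition,
              length(x$folds)))
  print(x$eval)
  invisible(x)
}

#' @export
tidy.rnc_uni_cv <- function(x, ...) x$eval

#' Correlation between two areas' univariate profiles
#'
#' @param prof_a,prof_b `rnc_profile`s sharing at least 3 images.
#' @return Pearson r over shared images; `NaN` with a warning when either
#'   profile has zero variance.
#' @export
profile_correlation <- function(prof_a, prof_b) {
  shared <- intersect(prof_a$image_id, prof_b$image_id)
  if (length(shared) < 3) {
    stop("profiles share fewer than 3 images.", call. = FALSE)
  }
  a <- prof_a$value[match(shared, prof_a$image_id)]
  b <- prof_b$value[match(shared, prof_b$image_id)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance profile; correlation undefined.", call. = FALSE)
    return(NaN)
  }
  stats::cor(a, b)
}

#' Average a pairwise statistic over pair groups
#'
#' Aggregates a per-area-pair statistic (e.g. absolute control-minus-baseline
#' response, RSA score, profile correlation) by a pair grouping such as
#' stepwise hierarchy distance or within/between categorical group.
#'
#' @param pair_stats Tibble with columns `area_x`, `area_y`, `stat`.
#' @param grouping A named grouping of pairs: either
#'   [pair_grouping_stepwise()] or [pair_grouping_within_between()] output,
#'   i.e. a tibble with columns `area_x`, `area_y`, `group`. Every pair in
#'   `pair_stats` must be mapped (orientation-insensitively).
#' @return Tibble with columns `group`, `mean_stat`, `n_pairs`.
#' @export
aggregate_by_pair_group <- function(pair_stats, grouping) {
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "|")
  gkey <- key(grouping$area_x, grouping$area_y)
  skey <- key(pair_stats$area_x, pair_stats$area_y)
  hit <- match(skey, gkey)
  if (anyNA(hit)) {
    stop(sprintf("unmapped pair(s): %s.",
                 paste(skey[is.na(hit)], collapse = ", ")), call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(pair_stats, group = grouping$group[hit]), .data$group),
    mean_stat = mean(.data$stat), n_pairs = dplyr::n(), .groups = "drop")
}

#' Stepwise-distance grouping of an ordered area chain
#'
#' @param areas Ordered character vector of chain areas (positions 1..k).
#' @return Tibble with `area_x`, `area_y`, `group` (= stepwise distance) for
#'   all pairs; a 4-area chain yields 3 pairs at distance 1, 2 at 2, 1 at 3.
#' @export
pair_grouping_stepwise <- function(areas) {
  pairs <- utils::combn(seq_along(areas), 2)
  tibble::tibble(area_x = areas[pairs[1, ]], area_y = areas[pairs[2, ]],
                 group = as.character(pairs[2, ] - pairs[1, ]))
}

#' Within/between grouping for two categorical area groups
#'
#' @param groups Named character vector mapping area to group label.
#' @return Tibble with `area_x`, `area_y`, `group` in
#'   `{"within", "between"}` over all pairs.
#' @export
pair_grouping_within_between <- function(groups) {
  areas <- names(groups)
  pairs <- utils::combn(areas, 2)
  tibble::tibble(
    area_x = pairs[1, ], area_y = pairs[2, ],
    group = ifelse(groups[pairs[1, ]] == groups[pairs[2, ]],
                   "within", "between"))
}

#' Mean response per image-subset by voxel-subset block
#'
#' Supports block analyses such as sky/no-sky images crossed with lower/upper
#' visual-field voxels: for every combination of image label and voxel label
#' the mean of the corresponding response block is returned.
#'
#' @param rs An [response_set()].
#' @param image_labels Labels, one per image (partition of the images).
#' @param voxel_labels Labels, one per voxel (partition of the voxels).
#' @return Tibble with columns `image_subset`, `voxel_subset`,
#'   `mean_response` (NaN, with a warning, for empty blocks).
#' @export
subset_contrast <- function(rs, image_labels, voxel_labels) {
  stopifnot(inherits(rs, "rnc_response_set"),
            length(image_labels) == nrow(rs$responses),
            length(voxel_labels) == ncol(rs$responses))
  ils <- unique(image_labels); vls <- unique(voxel_labels)
  out <- tidyr::expand_grid(image_subset = ils, voxel_subset = vls)
  out$mean_response <- purrr::map2_dbl(out$image_subset, out$voxel_subset,
    function(il, vl) {
      block <- rs$responses[image_labels == il, voxel_labels == vl,
                            drop = FALSE]
      if (!length(block)) {
        warning(sprintf("empty block (%s, %s).", il, vl), call. = FALSE)
        return(NaN)
      }
      mean(block)
    })
  out
}
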