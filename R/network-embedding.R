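# SMACOF metric MDS (stress majorization with Guttman transforms), with
# random restarts. Input is a full symmetric dissimilarity matrix.
smacof_mds <- function(D, k = 2, n_init = 10, max_iter = 1000, eps = 1e-3,
                       seed = 1) {
  n <- nrow(D)
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    X <- matrix(stats::rnorm(n * k), n, k)
    old_stress <- Inf
    for (it in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(X))
      stress <- sum((D[lower.tri(D)] - d[lower.tri(d)])^2)
      if (old_stress - stress < eps * old_stress || stress == 0) {
        old_stress <- stress
        break
      }
      old_stress <- stress
      ratio <- ifelse(d > 0, D / d, 0)
      B <- -ratio
      diag(B) <- 0
      diag(B) <- -rowSums(B)
      X <- B %*% X / n
    }
    if (is.null(best) || old_stress < best$stress) {
      best <- list(coords = X, stress = old_stress)
    }
  }
  best
}

canonical_align <- function(coords) {
  coords <- sweep(coords, 2, colMeans(coords))
  v <- coords[1, ]
  if (sqrt(sum(v^2)) > 1e-12) {
    ang <- atan2(v[2], v[1])
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    coords <- coords %*% rot
  }
  if (nrow(coords) > 1 && coords[2, 2] < 0) coords[, 2] <- -coords[, 2]
  coords
}

new_embedding <- function(areas, coords, D, stress) {
  coords <- canonical_align(coords)
  dimnames(coords) <- NULL
  emb_d <- as.matrix(stats::dist(coords))
  dimnames(D) <- dimnames(emb_d) <- list(areas, areas)
  structure(list(areas = areas,
                 coords = tibble::tibble(area = areas,
                                         dim1 = coords[, 1],
                                         dim2 = coords[, 2]),
                 input_distances = D, embedded_distances = emb_d,
                 stress = stress),
            class = "rnc_embedding")
}

embed_feature_matrix <- function(features, areas, n_init, max_iter, eps,
                                 seed) {
  if (length(areas) < 3) stop("need at least 3 areas to embed.", call. = FALSE)
  D <- as.matrix(stats::dist(features))
  fit <- smacof_mds(D, 2, n_init, max_iter, eps, seed)
  new_embedding(areas, fit$coords, D, fit$stress)
}

#' MDS embedding of areas from univariate profiles
#'
#' Computes Euclidean distances between the areas' (participant-averaged)
#' univariate profile vectors and embeds them in two dimensions with metric
#' MDS (SMACOF, random restarts, best stress kept). Comparisons should be
#' made on embedded distances, never raw coordinates, which are only
#' determined up to rotation/reflection (a canonical alignment is applied
#' for plotting).
#'
#' @param profiles Named list of `rnc_profile`s (one per area, shared image
#'   set) or a long tibble with columns `area`, `image_id`, `value`.
#' @param n_init Random restarts (default 10).
#' @param max_iter Maximum majorization iterations (default 1000).
#' @param eps Relative stress-improvement tolerance (default 1e-3).
#' @param seed Integer seed.
#' @return Object of class `rnc_embedding` with a coordinates tibble,
#'   input/embedded distance matrices and the final stress.
#' @export
embed_univariate <- function(profiles, n_init = 10, max_iter = 1000,
                             eps = 1e-3, seed = 1) {
  if (inherits(profiles, "data.frame")) {
    wide <- tidyr::pivot_wider(profiles, names_from = "image_id",
                               values_from = "value")
    areas <- wide$area
    features <- as.matrix(wide[, -1])
  } else {
    areas <- names(profiles)
    ref <- profiles[[1]]$image_id
    features <- t(vapply(profiles, function(p) {
      stopifnot(identical(p$image_id, ref))
      p$value
    }, numeric(length(ref))))
  }
  embed_feature_matrix(features, areas, n_init, max_iter, eps, seed)
}

#' MDS embedding of areas from RSM lower triangles
#'
#' Vectorizes each area's (participant-averaged) RSM strictly-lower
#' triangle and embeds the areas as in [embed_univariate()].
#'
#' @param rsms Named list of `rnc_rsm`s over the identical image batch.
#' @inheritParams embed_univariate
#' @return An `rnc_embedding`.
#' @export
embed_rsm <- function(rsms, n_init = 10, max_iter = 1000, eps = 1e-3,
                      seed = 1) {
  areas <- names(rsms)
  ref <- rsms[[1]]$image_ids
  features <- t(vapply(rsms, function(r) {
    if (!identical(r$image_ids, ref)) {
      stop("all RSMs must share the identical image batch.", call. = FALSE)
    }
    r$matrix[lower.tri(r$matrix)]
  }, numeric(sum(lower.tri(rsms[[1]]$matrix)))))
  embed_feature_matrix(features, areas, n_init, max_iter, eps, seed)
}

#' @export
print.rnc_embedding <- function(x, ...) {
  cat(sprintf("<rnc_embedding> %d areas, stress %.4g\n", length(x$areas),
              x$stress))
  print(x$coords)
  invisible(x)
}

#' @export
tidy.rnc_embedding <- function(x, ...) x$coords

#' @export
glance.rnc_embedding <- function(x, ...) {
  tibble::tibble(n_areas = length(x$areas), stress = x$stress)
}

#' @export
autoplot.rnc_embedding <- function(object, ...) {
  ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                              label = .data$area)) +
    ggplot2::geom_point(size = 3, colour = "steelblue") +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "area embedding (metric MDS)")
}

#' Map pairwise distances to plotting opacities
#'
#' Linear rescale of pairwise embedding distances to opacities: the minimum
#' pairwise distance maps to 1 (fully opaque, highest proximity) and the
#' maximum to 0.1 (almost transparent), independently per embedding. Scaling
#' all distances by a constant leaves opacities unchanged.
#'
#' @param distances Symmetric non-negative distance matrix (the zero
#'   diagonal is ignored) or a plain vector of pairwise distances.
#' @return Opacities of the same shape (matrix diagonal set to `NA`); all
#'   equal distances yield all-1 opacities with a warning.
#' @export
proximity_opacity <- function(distances) {
  is_mat <- is.matrix(distances)
  vals <- if (is_mat) distances[row(distances) != col(distances)] else distances
  stopifnot(all(vals >= 0))
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) {
    warning("all pairwise distances equal; opacities set to 1.", call. = FALSE)
    op <- function(x) rep(1, length(x))
  } else {
    op <- function(x) 1 + (x - lo) / (hi - lo) * (0.1 - 1)
  }
  if (is_mat) {
    out <- matrix(op(as.vector(distances)), nrow(distances))
    diag(out) <- NA_real_
    dimnames(out) <- dimnames(distances)
    out
  } else {
    op(distances)
  }
}
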