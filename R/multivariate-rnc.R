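#' Representational similarity matrix for an image batch
#'
#' Pearson-correlates every pair of images' voxel patterns within a batch,
#' giving a symmetric, unit-diagonal S x S matrix that captures the area's
#' representational geometry on that batch. Batches must be duplicate-free.
#'
#' @param rs An [response_set()] with >= 2 voxels.
#' @param batch Image ids forming the batch (subset of `rs$image_ids`).
#' @return Object of class `rnc_rsm`: list with `matrix` and `image_ids`.
#' @export
compute_rsm <- function(rs, batch) {
  stopifnot(inherits(rs, "rnc_response_set"))
  if (anyDuplicated(batch)) {
    stop("batch contains repeated images; batches must be duplicate-free.",
         call. = FALSE)
  }
  pos <- match(batch, rs$image_ids)
  if (anyNA(pos)) stop("batch contains unknown image ids.", call. = FALSE)
  if (ncol(rs$responses) < 2) {
    stop("RSM needs at least 2 voxels.", call. = FALSE)
  }
  patt <- rs$responses[pos, , drop = FALSE]
  sds <- apply(patt, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance voxel pattern for image '%s'.",
                 batch[which(sds == 0)[1]]), call. = FALSE)
  }
  m <- stats::cor(t(patt))
  dimnames(m) <- NULL
  diag(m) <- 1
  structure(list(matrix = m, image_ids = batch), class = "rnc_rsm")
}

#' @export
print.rnc_rsm <- function(x, ...) {
  cat(sprintf("<rnc_rsm> %d x %d images\n", nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' RSA score between two areas' RSMs
#'
#' Pearson correlation over the strictly-lower-triangle entries (the
#' constant unit diagonal is excluded). High r means aligned geometries; low
#' absolute r means disentangled geometries.
#'
#' @param rsm_a,rsm_b `rnc_rsm`s over the identical image batch and order.
#' @return A single Pearson r in `[-1, 1]`; `NaN` with a warning when a
#'   triangle vector is constant (e.g. batch size 2).
#' @export
rsa_score <- function(rsm_a, rsm_b) {
  stopifnot(inherits(rsm_a, "rnc_rsm"), inherits(rsm_b, "rnc_rsm"))
  if (!identical(rsm_a$image_ids, rsm_b$image_ids)) {
    stop("RSMs must share the identical image batch and order.", call. = FALSE)
  }
  lt <- lower.tri(rsm_a$matrix)
  a <- rsm_a$matrix[lt]; b <- rsm_b$matrix[lt]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant lower-triangle vector; RSA score undefined.",
            call. = FALSE)
    return(NaN)
  }
  stats::cor(a, b)
}

# Full image-by-image pattern-correlation matrix. Any batch RSM is a
# submatrix of this, which makes null sampling and genetic search cheap on
# in-memory image pools.
pattern_similarity <- function(rs) {
  stopifnot(inherits(rs, "rnc_response_set"), ncol(rs$responses) >= 2)
  sds <- apply(rs$responses, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance voxel pattern for image '%s'.",
                 rs$image_ids[which(sds == 0)[1]]), call. = FALSE)
  }
  m <- stats::cor(t(rs$responses))
  diag(m) <- 1
  list(matrix = m, image_ids = rs$image_ids)
}

rsa_from_sim <- function(sim_a, sim_b, idx, lt) {
  stats::cor(sim_a[idx, idx][lt], sim_b[idx, idx][lt])
}

#' Random-batch null distribution and baseline for multivariate control
#'
#' Samples `n_samples` duplicate-free batches, scores each by the RSA
#' between the two areas' batch RSMs, and takes as baseline the batch whose
#' score is closest to the null mean.
#'
#' @param rs_a,rs_b [response_set()]s over a shared image set.
#' @param batch_size Images per batch (default 50).
#' @param n_samples Sampled batches (default 1e6).
#' @param seed Integer seed.
#' @return An `rnc_null` (see [build_univariate_null()]) with
#'   `kind = "multivariate"`.
#' @export
build_multivariate_null <- function(rs_a, rs_b, batch_size = 50,
                                    n_samples = 1e6, seed = 1) {
  stopifnot(identical(rs_a$image_ids, rs_b$image_ids))
  n_images <- length(rs_a$image_ids)
  if (batch_size > n_images) {
    stop("`batch_size` exceeds the number of images.", call. = FALSE)
  }
  sim_a <- pattern_similarity(rs_a)$matrix
  sim_b <- pattern_similarity(rs_b)$matrix
  lt <- lower.tri(matrix(0, batch_size, batch_size))
  set.seed(seed)
  scores <- numeric(n_samples)
  batches <- matrix(0L, batch_size, n_samples)
  for (i in seq_len(n_samples)) {
    idx <- sample.int(n_images, batch_size)
    batches[, i] <- idx
    scores[i] <- rsa_from_sim(sim_a, sim_b, idx, lt)
  }
  best <- which.min(abs(scores - mean(scores)))
  structure(list(kind = "multivariate", area = NULL,
                 batch_size = as.integer(batch_size),
                 n_samples = as.integer(n_samples),
                 sample_scores = scores,
                 baseline_image_ids = rs_a$image_ids[batches[, best]],
                 baseline_score = scores[best]),
            class = "rnc_null")
}

#' Configuration of the genetic batch search
#'
#' Population layout per generation: `n_elite` retained batches, one mutated
#' copy of each elite per entry of `mutation_counts` (that many images
#' replaced by fresh pool draws), and `n_random` new random batches, so
#' `n_elite * (1 + length(mutation_counts)) + n_random` must equal
#' `population`.
#'
#' @param objective `"align"` (maximize RSA r) or `"disentangle"` (minimize
#'   absolute RSA r).
#' @param population Batches per generation (default 2400).
#' @param batch_size Images per batch (default 50).
#' @param n_elite Retained best batches (default 200).
#' @param mutation_counts Images replaced in each graded mutation (default
#'   1, 5, 12, 25, 38; all < `batch_size`).
#' @param n_random Fresh random batches per generation (default 1200).
#' @param generations Number of generations (default 2000).
#' @param seed Integer seed.
#' @return List of class `rnc_batch_config`.
#' @export
batch_search_config <- function(objective = c("align", "disentangle"),
                                population = 2400, batch_size = 50,
                                n_elite = 200,
                                mutation_counts = c(1, 5, 12, 25, 38),
                                n_random = 1200, generations = 2000,
                                seed = 1) {
  objective <- match.arg(objective)
  if (n_elite * (1 + length(mutation_counts)) + n_random != population) {
    stop("inconsistent sizes: n_elite * (1 + length(mutation_counts)) + n_random must equal population.",
         call. = FALSE)
  }
  if (any(mutation_counts >= batch_size)) {
    stop("mutation_counts must be smaller than batch_size.", call. = FALSE)
  }
  structure(list(objective = objective, population = as.integer(population),
                 batch_size = as.integer(batch_size),
                 n_elite = as.integer(n_elite),
                 mutation_counts = as.integer(mutation_counts),
                 n_random = as.integer(n_random),
                 generations = as.integer(generations),
                 seed = as.integer(seed)),
            class = "rnc_batch_config")
}

random_batches <- function(m, n_images, batch_size) {
  vapply(seq_len(m), function(i) sample.int(n_images, batch_size),
         integer(batch_size))
}

mutate_batch <- function(batch, m, n_images) {
  pos <- sample.int(length(batch), m)
  # draw replacements avoiding duplicates within the batch
  keep <- batch[-pos]
  repl <- integer(0)
  while (length(repl) < m) {
    cand <- sample.int(n_images, m - length(repl) + 8L)
    cand <- setdiff(cand, c(keep, repl))
    repl <- c(repl, utils::head(cand, m - length(repl)))
  }
  batch[pos] <- repl
  batch
}

search_core <- function(sim_a, sim_b, image_ids, cfg) {
  n_images <- length(image_ids)
  if (n_images < cfg$batch_size) {
    stop("image pool smaller than batch_size.", call. = FALSE)
  }
  lt <- lower.tri(matrix(0, cfg$batch_size, cfg$batch_size))
  score_pop <- function(pop) {
    vapply(seq_len(ncol(pop)), function(i) {
      rsa_from_sim(sim_a, sim_b, pop[, i], lt)
    }, numeric(1))
  }
  rank_key <- function(r) if (cfg$objective == "align") -r else abs(r)
  set.seed(cfg$seed)
  pop <- random_batches(cfg$population, n_images, cfg$batch_size)
  trace <- numeric(cfg$generations)
  best_batch <- NULL; best_r <- NA_real_
  for (g in seq_len(cfg$generations)) {
    r <- score_pop(pop)
    hash <- vapply(seq_len(ncol(pop)), function(i) {
      paste(sort(pop[, i]), collapse = "-")
    }, character(1))
    ord <- order(rank_key(r), hash)
    elite <- pop[, ord[seq_len(cfg$n_elite)], drop = FALSE]
    best_batch <- elite[, 1]
    best_r <- r[ord[1]]
    trace[g] <- best_r
    if (g == cfg$generations) break
    mutated <- do.call(cbind, lapply(cfg$mutation_counts, function(m) {
      apply(elite, 2, mutate_batch, m = m, n_images = n_images)
    }))
    fresh <- random_batches(cfg$n_random, n_images, cfg$batch_size)
    pop <- cbind(elite, mutated, fresh)
  }
  structure(list(objective = cfg$objective,
                 best_image_ids = image_ids[best_batch],
                 best_score = best_r,
                 trace = tibble::tibble(generation = seq_len(cfg$generations),
                                        best_score = trace),
                 config = cfg),
            class = "rnc_batch_search")
}

#' Genetic search for controlling image batches
#'
#' Elitist genetic optimization over duplicate-free image batches: each
#' generation scores every batch by the RSA between the two areas' batch
#' RSMs, keeps the `n_elite` best (highest r for alignment, lowest absolute
#' r for disentanglement), adds graded mutated copies of every elite and
#' fresh random batches, and repeats. Elite retention makes the
#' best-of-generation score monotone in the objective direction.
#'
#' @param rs_a,rs_b [response_set()]s over a shared image pool.
#' @param cfg A [batch_search_config()].
#' @return An object of class `rnc_batch_search` with `best_image_ids`,
#'   `best_score` and the per-generation `trace`.
#' @export
search_controlling_batches <- function(rs_a, rs_b, cfg) {
  stopifnot(identical(rs_a$image_ids, rs_b$image_ids),
            inherits(cfg, "rnc_batch_config"))
  sim_a <- pattern_similarity(rs_a)$matrix
  sim_b <- pattern_similarity(rs_b)$matrix
  search_core(sim_a, sim_b, rs_a$image_ids, cfg)
}

#' @export
print.rnc_batch_search <- function(x, ...) {
  cat(sprintf("<rnc_batch_search> objective %s: best RSA %.4f after %d generations\n",
              x$objective, x$best_score, nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.rnc_batch_search <- function(x, ...) x$trace

#' @export
glance.rnc_batch_search <- function(x, ...) {
  tibble::tibble(objective = x$objective, generations = nrow(x$trace),
                 best_score = x$best_score,
                 batch_size = x$config$batch_size)
}

#' @export
autoplot.rnc_batch_search <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_score)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(y = "best RSA score",
                  title = sprintf("genetic batch search (%s)", object$objective))
}

#' Participant-wise leave-one-out cross-validation of multivariate control
#'
#' Per fold, the search (and the random-batch baseline) runs on RSMs
#' averaged entry-wise over the training participants; the RSA of the
#' left-out participant's two RSMs on the selected batch evaluates the
#' solution.
#'
#' @param rs_list_a,rs_list_b Named lists of [response_set()]s, one per
#'   participant, for areas A and B.
#' @param cfg A [batch_search_config()] (fold f runs with `cfg$seed + f`).
#' @param null_samples Random batches for the per-fold baseline.
#' @return Object of class `rnc_multi_cv`: `folds` (per-fold searches) and
#'   `eval` tibble (fold, control_rsa, baseline_rsa).
#' @export
crossval_multivariate <- function(rs_list_a, rs_list_b, cfg,
                                  null_samples = 1000) {
  stopifnot(length(rs_list_a) == length(rs_list_b), length(rs_list_a) >= 2)
  participants <- names(rs_list_a)
  if (is.null(participants)) participants <- as.character(seq_along(rs_list_a))
  ids <- rs_list_a[[1]]$image_ids
  sims_a <- lapply(rs_list_a, function(rs) pattern_similarity(rs)$matrix)
  sims_b <- lapply(rs_list_b, function(rs) pattern_similarity(rs)$matrix)
  lt <- lower.tri(matrix(0, cfg$batch_size, cfg$batch_size))
  folds <- list(); evals <- list()
  for (f in seq_along(participants)) {
    train <- setdiff(seq_along(participants), f)
    avg_a <- Reduce(`+`, sims_a[train]) / length(train)
    avg_b <- Reduce(`+`, sims_b[train]) / length(train)
    fold_cfg <- cfg; fold_cfg$seed <- cfg$seed + f
    sol <- search_core(avg_a, avg_b, ids, fold_cfg)
    attr(sol, "fold") <- participants[f]
    folds[[f]] <- sol
    # per-fold baseline on the training average
    set.seed(cfg$seed + f + 5000L)
    bscores <- numeric(null_samples)
    bbatches <- matrix(0L, cfg$batch_size, null_samples)
    for (i in seq_len(null_samples)) {
      idx <- sample.int(length(ids), cfg$batch_size)
      bbatches[, i] <- idx
      bscores[i] <- rsa_from_sim(avg_a, avg_b, idx, lt)
    }
    bbest <- bbatches[, which.min(abs(bscores - mean(bscores)))]
    sel <- match(sol$best_image_ids, ids)
    evals[[f]] <- tibble::tibble(
      fold = participants[f],
      control_rsa = rsa_from_sim(sims_a[[f]], sims_b[[f]], sel, lt),
      baseline_rsa = rsa_from_sim(sims_a[[f]], sims_b[[f]], bbest, lt),
      train_score = sol$best_score)
  }
  structure(list(objective = cfg$objective, folds = folds,
                 eval = dplyr::bind_rows(evals)),
            class = "rnc_multi_cv")
}

#' @export
print.rnc_multi_cv <- function(x, ...) {
  cat(sprintf("<rnc_multi_cv> objective %s, %d folds\n", x$objective,
              length(x$folds)))
  print(x$eval)
  invisible(x)
}

#' @export
tidy.rnc_multi_cv <- function(x, ...) x$eval
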