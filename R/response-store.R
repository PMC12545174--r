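#' Trial-level beta responses for one participant and area
#'
#' Bundles a trials-by-voxels matrix of (GLM beta) responses with the image
#' and session label of every trial. Trial order is arbitrary; sessions are
#' addressed by label, never by contiguity.
#'
#' @param betas Numeric matrix, trials by voxels. All values must be finite.
#' @param image_id Vector of image identifiers, one per trial. Every image
#'   that occurs must have at least one trial.
#' @param session_id Vector of session labels, one per trial.
#' @param participant,area Identifiers for the participant and cortical area.
#' @return An object of class `rnc_trial_betas`.
#' @export
trial_betas <- function(betas, image_id, session_id, participant, area) {
  betas <- as.matrix(betas)
  stopifnot(is.numeric(betas), nrow(betas) == length(image_id),
            nrow(betas) == length(session_id))
  if (!all(is.finite(betas))) {
    stop("`betas` must be finite everywhere.", call. = FALSE)
  }
  structure(
    list(betas = unname(betas),
         image_id = as.vector(image_id),
         session_id = as.vector(session_id),
         participant = as.character(participant),
         area = as.character(area)),
    class = "rnc_trial_betas")
}

#' Image-level response set for one participant and area
#'
#' The canonical container for z-scored image-level responses: an
#' images-by-voxels matrix plus unique image identifiers and per-voxel
#' metadata (NCSNR and an optional visual-field tag). Image order inside the
#' container is the canonical order for all downstream indexing; selections
#' elsewhere in the package always return image ids, never positions.
#'
#' @param responses Numeric matrix, images by voxels, finite.
#' @param image_ids Unique image identifiers, one per row.
#' @param ncsnr Optional per-voxel noise-ceiling signal-to-noise ratios
#'   (dimensionless, >= 0; may be `Inf`).
#' @param visual_field Optional per-voxel tag, one of `"lower"`, `"upper"`,
#'   `"none"`.
#' @param participant,area Identifiers.
#' @return An object of class `rnc_response_set` with a `voxel_meta` tibble.
#' @export
response_set <- function(responses, image_ids, ncsnr = NULL,
                         visual_field = NULL, participant, area) {
  responses <- as.matrix(responses)
  stopifnot(is.numeric(responses), nrow(responses) == length(image_ids))
  if (anyDuplicated(image_ids)) {
    stop("`image_ids` must be unique.", call. = FALSE)
  }
  if (length(responses) && !all(is.finite(responses))) {
    stop("`responses` must be finite everywhere.", call. = FALSE)
  }
  nv <- ncol(responses)
  if (is.null(ncsnr)) ncsnr <- rep(NA_real_, nv)
  if (is.null(visual_field)) visual_field <- rep("none", nv)
  stopifnot(length(ncsnr) == nv, length(visual_field) == nv)
  structure(
    list(responses = unname(responses),
         image_ids = as.vector(image_ids),
         voxel_meta = tibble::tibble(voxel = seq_len(nv),
                                     ncsnr = as.numeric(ncsnr),
                                     visual_field = as.character(visual_field)),
         participant = as.character(participant),
         area = as.character(area)),
    class = "rnc_response_set")
}

#' @export
print.rnc_response_set <- function(x, ...) {
  cat(sprintf("<rnc_response_set> participant %s, area %s: %d images x %d voxels\n",
              x$participant, x$area, nrow(x$responses), ncol(x$responses)))
  invisible(x)
}

#' @export
print.rnc_trial_betas <- function(x, ...) {
  cat(sprintf("<rnc_trial_betas> participant %s, area %s: %d trials x %d voxels, %d images, %d sessions\n",
              x$participant, x$area, nrow(x$betas), ncol(x$betas),
              length(unique(x$image_id)), length(unique(x$session_id))))
  invisible(x)
}

#' z-score betas across all trials of every session
#'
#' Each voxel is centred and scaled independently within every acquisition
#' session, removing session-specific offset and gain. The scale divisor is
#' configurable: `"population"` divides by the trial count n,
#' `"sample"` by n - 1.
#'
#' @param trials An [trial_betas()] object.
#' @param convention `"population"` (default) or `"sample"` sd divisor.
#' @return A new `rnc_trial_betas` with, per (voxel, session), mean 0 and the
#'   chosen-convention sd equal to 1.
#' @export
zscore_per_session <- function(trials, convention = c("population", "sample")) {
  stopifnot(inherits(trials, "rnc_trial_betas"))
  convention <- match.arg(convention)
  out <- trials$betas
  for (s in unique(trials$session_id)) {
    rows <- which(trials$session_id == s)
    if (length(rows) < 2) {
      stop(sprintf("session '%s' has fewer than 2 trials.", s), call. = FALSE)
    }
    sl <- out[rows, , drop = FALSE]
    mu <- colMeans(sl)
    centred <- sweep(sl, 2, mu)
    ss <- colSums(centred^2)
    nn <- if (convention == "population") length(rows) else length(rows) - 1L
    sdv <- sqrt(ss / nn)
    bad <- which(sdv == 0)
    if (length(bad)) {
      stop(sprintf("zero-variance slice: voxel %d in session '%s'.",
                   bad[1], s), call. = FALSE)
    }
    out[rows, ] <- sweep(centred, 2, sdv, "/")
  }
  trials$betas <- out
  trials
}

#' Average repeated trials into one image-level response per image
#'
#' @param trials An [trial_betas()] object.
#' @return An [response_set()] with one row per distinct image id (mean over
#'   that image's trials), in first-appearance order. Voxel NCSNR is left
#'   unset; see [compute_ncsnr()].
#' @export
average_repeats <- function(trials) {
  stopifnot(inherits(trials, "rnc_trial_betas"))
  ids <- unique(trials$image_id)
  resp <- matrix(0, length(ids), ncol(trials$betas))
  for (i in seq_along(ids)) {
    rows <- which(trials$image_id == ids[i])
    resp[i, ] <- colMeans(trials$betas[rows, , drop = FALSE])
  }
  response_set(resp, ids, participant = trials$participant, area = trials$area)
}

#' Univariate response profile of an area
#'
#' Reduces an images-by-voxels response set to its univariate profile: the
#' mean response across all voxels, per image.
#'
#' @param rs An [response_set()].
#' @return A tibble of class `rnc_profile` with columns `image_id`, `value`,
#'   carrying `participant` and `area` attributes.
#' @export
univariate_profile <- function(rs) {
  stopifnot(inherits(rs, "rnc_response_set"))
  if (ncol(rs$responses) < 1) {
    stop("response set has zero voxels (empty area).", call. = FALSE)
  }
  new_profile(tibble::tibble(image_id = rs$image_ids,
                             value = rowMeans(rs$responses)),
              rs$participant, rs$area)
}

new_profile <- function(tbl, participant = NA_character_, area = NA_character_) {
  structure(tbl, participant = as.character(participant),
            area = as.character(area),
            class = c("rnc_profile", class(tibble::as_tibble(tbl))))
}

#' Drop voxels at or below an NCSNR threshold
#'
#' Retains exactly the voxels whose NCSNR is strictly above `threshold`
#' (order preserved). The conventional threshold is 0.5; when no voxel in an
#' area clears it the error advises lowering the threshold (the conventional
#' fallback is 0.4).
#'
#' @param rs An [response_set()] whose `voxel_meta$ncsnr` is set.
#' @param threshold Dimensionless NCSNR cutoff (strict inequality).
#' @return The filtered response set; the number of retained voxels is
#'   recorded in attribute `n_retained`.
#' @export
filter_voxels_by_ncsnr <- function(rs, threshold = 0.5) {
  stopifnot(inherits(rs, "rnc_response_set"))
  ncsnr <- rs$voxel_meta$ncsnr
  if (anyNA(ncsnr)) {
    stop("voxel_meta NCSNR is not set for this response set.", call. = FALSE)
  }
  keep <- which(ncsnr > threshold)
  if (!length(keep)) {
    stop(sprintf(paste0("no voxel has NCSNR above %g; consider lowering the ",
                        "threshold (e.g. to 0.4)."), threshold), call. = FALSE)
  }
  rs$responses <- rs$responses[, keep, drop = FALSE]
  rs$voxel_meta <- rs$voxel_meta[keep, ]
  rs$voxel_meta$voxel <- seq_along(keep)
  attr(rs, "n_retained") <- length(keep)
  rs
}

# ---- plain-text store ------------------------------------------------------
#
# Directory container: manifest.json (schema_version, groups) plus one
# subdirectory per (participant, area) group holding TSV datasets. Values
# round-trip within 1e-12; identifiers round-trip exactly.

STORE_SCHEMA <- "rnc-store/1"

group_dir <- function(participant, area) {
  paste0(gsub("[^A-Za-z0-9_.-]", "_", participant), "__",
         gsub("[^A-Za-z0-9_.-]", "_", area))
}

#' Write response sets or trial betas to a directory store
#'
#' Persists one or many containers into a directory laid out as one group per
#' (participant, area), each with named TSV datasets, plus a JSON manifest
#' carrying a schema version string.
#'
#' @param objects A single [response_set()]/[trial_betas()] or a list of them.
#' @param path Directory to create or extend.
#' @return `path`, invisibly.
#' @export
write_response_store <- function(objects, path) {
  if (inherits(objects, c("rnc_response_set", "rnc_trial_betas"))) {
    objects <- list(objects)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  groups <- list()
  for (ob in objects) {
    gd <- file.path(path, group_dir(ob$participant, ob$area))
    dir.create(gd, showWarnings = FALSE)
    if (inherits(ob, "rnc_response_set")) {
      resp <- tibble::as_tibble(as.data.frame(ob$responses,
                                              optional = TRUE), .name_repair = "minimal")
      names(resp) <- paste0("v", seq_len(ncol(ob$responses)))
      readr::write_tsv(dplyr::bind_cols(
        tibble::tibble(image_id = ob$image_ids), resp),
        file.path(gd, "responses.tsv"), progress = FALSE)
      readr::write_tsv(ob$voxel_meta, file.path(gd, "voxels.tsv"),
                       progress = FALSE)
      type <- "response_set"
    } else if (inherits(ob, "rnc_trial_betas")) {
      bet <- tibble::as_tibble(as.data.frame(ob$betas, optional = TRUE),
                               .name_repair = "minimal")
      names(bet) <- paste0("v", seq_len(ncol(ob$betas)))
      readr::write_tsv(dplyr::bind_cols(
        tibble::tibble(image_id = ob$image_id, session_id = ob$session_id),
        bet), file.path(gd, "betas.tsv"), progress = FALSE)
      type <- "trial_betas"
    } else {
      stop("unsupported object type in store write.", call. = FALSE)
    }
    groups[[length(groups) + 1L]] <-
      list(participant = ob$participant, area = ob$area, type = type,
           dir = basename(gd))
  }
  manifest_path <- file.path(path, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    keep <- Filter(function(g) {
      !any(vapply(groups, function(h) identical(h$dir, g$dir), logical(1)))
    }, old$groups)
    groups <- c(keep, groups)
  }
  jsonlite::write_json(list(schema_version = STORE_SCHEMA, groups = groups),
                       manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' List the groups of a response store
#'
#' @param path Store directory.
#' @return A tibble with columns `participant`, `area`, `type`.
#' @export
response_store_groups <- function(path) {
  man <- read_manifest(path)
  purrr::map_dfr(man$groups, function(g) {
    tibble::tibble(participant = g$participant, area = g$area, type = g$type)
  })
}

read_manifest <- function(path) {
  mp <- file.path(path, "manifest.json")
  if (!file.exists(mp)) {
    stop(sprintf("not a response store (no manifest.json at '%s').", path),
         call. = FALSE)
  }
  man <- jsonlite::read_json(mp)
  if (!identical(man$schema_version, STORE_SCHEMA)) {
    stop(sprintf("store schema mismatch: expected '%s', found '%s'.",
                 STORE_SCHEMA, man$schema_version), call. = FALSE)
  }
  man
}

#' Read one group back from a directory store
#'
#' @param path Store directory.
#' @param participant,area Group to read.
#' @return The stored [response_set()] or [trial_betas()].
#' @export
read_response_store <- function(path, participant, area) {
  man <- read_manifest(path)
  hit <- Filter(function(g) identical(g$participant, as.character(participant)) &&
                  identical(g$area, as.character(area)), man$groups)
  if (!length(hit)) {
    stop(sprintf("no group (participant '%s', area '%s') in store.",
                 participant, area), call. = FALSE)
  }
  g <- hit[[1]]
  gd <- file.path(path, g$dir)
  if (identical(g$type, "response_set")) {
    resp <- readr::read_tsv(file.path(gd, "responses.tsv"),
                            show_col_types = FALSE, progress = FALSE)
    vox <- readr::read_tsv(file.path(gd, "voxels.tsv"),
                           show_col_types = FALSE, progress = FALSE)
    mat <- as.matrix(resp[, -1, drop = FALSE])
    storage.mode(mat) <- "double"            # 0-row stores read back typeless
    if (ncol(mat) != nrow(vox)) {
      stop(sprintf("store shape mismatch: %d response columns vs %d voxel rows.",
                   ncol(mat), nrow(vox)), call. = FALSE)
    }
    response_set(mat, resp$image_id, ncsnr = vox$ncsnr,
                 visual_field = vox$visual_field,
                 participant = g$participant, area = g$area)
  } else {
    bet <- readr::read_tsv(file.path(gd, "betas.tsv"),
                           show_col_types = FALSE, progress = FALSE)
    trial_betas(as.matrix(bet[, -(1:2), drop = FALSE]),
                bet$image_id, bet$session_id,
                participant = g$participant, area = g$area)
  }
}
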