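# Small builders used across test files.

make_profile <- function(values, ids = paste0("img", seq_along(values)),
                         participant = "p1", area = "A") {
  rnc:::new_profile(tibble::tibble(image_id = ids, value = values),
                    participant, area)
}

make_rs <- function(responses, ids = paste0("img", seq_len(nrow(responses))),
                    participant = "p1", area = "A", ncsnr = NULL) {
  response_set(responses, ids, ncsnr = ncsnr, participant = participant,
               area = area)
}

# symmetric unit-diagonal RSM from a strictly-lower-triangle vector
rsm_from_lower <- function(lower, ids = paste0("img", 1:3)) {
  s <- length(ids)
  m <- diag(s)
  m[lower.tri(m)] <- lower
  m <- m + t(m) - diag(s)
  structure(list(matrix = m, image_ids = ids), class = "rnc_rsm")
}

uniform_image <- function(value = 128L, size = 64) {
  array(as.integer(value), c(size, size, 3))
}

checkerboard_image <- function(size = 64, period = 4) {
  m <- (outer(seq_len(size) - 1, seq_len(size) - 1,
              function(i, j) (i %/% (period / 2)) + (j %/% (period / 2))) %% 2) * 255
  img <- array(0L, c(size, size, 3))
  for (c in 1:3) img[, , c] <- m
  img
}

disks_image <- function(size = 64, radius = 5) {
  g <- matrix(128, size, size)
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  centers <- list(c(16, 16), c(16, 48), c(48, 16), c(48, 48), c(32, 32))
  for (cc in centers) g[(xs - cc[1])^2 + (ys - cc[2])^2 <= radius^2] <- 255
  img <- array(0L, c(size, size, 3))
  for (c in 1:3) img[, , c] <- g
  img
}

# shared toy encoders/generator (construction standardizes against the
# frozen reference set, so build once per test run)
toy_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- toy_image_encoders()
    cache
  }
})
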