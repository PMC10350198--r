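#' @keywords internal
"_PACKAGE"

# Local RNG scope: evaluate expr under a given seed and restore the caller's
# RNG state afterwards, so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Named substream: derive a child seed from a master seed and a stream label
# so every subject/stage draws from an independent, reproducible stream.
# Kept strictly below 2^31 (R integers are 32-bit).
substream_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

# Linear index <-> (i,j,k) helpers for 3D arrays (column-major)
lin_to_ijk <- function(idx, dm) {
  idx0 <- idx - 1L
  i <- idx0 %% dm[1]
  j <- (idx0 %/% dm[1]) %% dm[2]
  k <- idx0 %/% (dm[1] * dm[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dm) {
  (ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dm[1] + (ijk[, 3] - 1L) * dm[1] * dm[2] + 1L
}

# 6-neighbourhood linear indices with boundary handling; returns integer vector
neighbors6 <- function(idx, dm) {
  ijk <- lin_to_ijk(idx, dm)
  out <- integer(0)
  for (ax in 1:3) for (d in c(-1L, 1L)) {
    nb <- ijk
    nb[, ax] <- nb[, ax] + d
    ok <- nb[, ax] >= 1L & nb[, ax] <= dm[ax]
    out <- c(out, ijk_to_lin(nb[ok, , drop = FALSE], dm))
  }
  out
}

# Binary dilation of a logical 3D array by one step of the 6-neighbourhood
dilate6 <- function(mask) {
  dm <- dim(mask)
  out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-dm[1], , ]
  out[-dm[1], , ] <- out[-dm[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -dm[2], ]
  out[, -dm[2], ] <- out[, -dm[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -dm[3]]
  out[, , -dm[3]] <- out[, , -dm[3]] | mask[, , -1]
  out
}

# Mirror a 3D array across the midsagittal plane (first axis)
mirror_x <- function(arr) {
  arr[dim(arr)[1]:1, , , drop = FALSE]
}
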