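# Internal helpers shared across the package.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

clamp01 <- function(x) clamp(x, 0, 1)

vnorm <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fv_verbose <- function() isTRUE(getOption("fluovol.verbose", FALSE))

log_msg <- function(level, ...) {
  if (level == "DEBUG" && !fv_verbose()) return(invisible(NULL))
  message(sprintf("[%s] %s", level, sprintf(...)))
  invisible(NULL)
}

#' Trilinearly interpolate a 3D field at continuous voxel coordinates
#'
#' Coordinates are zero-based voxel-center coordinates: the center of voxel
#' `(i, j, k)` (zero-based) sits at coordinate `(i, j, k)`.  Coordinates are
#' clamped to the valid interpolation support (clamp-to-edge), so callers
#' decide separately which samples count as inside the volume.
#'
#' @param vol 3D numeric array.
#' @param x,y,z numeric vectors of equal length, continuous coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
#' @noRd
trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  x <- clamp(x, 0, d[1] - 1)
  y <- clamp(y, 0, d[2] - 1)
  z <- clamp(z, 0, d[3] - 1)
  x0 <- pmin(floor(x), d[1] - 2L + (d[1] == 1L))
  y0 <- pmin(floor(y), d[2] - 2L + (d[2] == 1L))
  z0 <- pmin(floor(z), d[3] - 2L + (d[3] == 1L))
  x0 <- pmax(x0, 0)
  y0 <- pmax(y0, 0)
  z0 <- pmax(z0, 0)
  fx <- x - x0
  fy <- y - y0
  fz <- z - z0
  i0 <- as.integer(x0) + 1L
  j0 <- as.integer(y0) + 1L
  k0 <- as.integer(z0) + 1L
  i1 <- pmin(i0 + 1L, d[1])
  j1 <- pmin(j0 + 1L, d[2])
  k1 <- pmin(k0 + 1L, d[3])

  c000 <- vol[cbind(i0, j0, k0)]
  c100 <- vol[cbind(i1, j0, k0)]
  c010 <- vol[cbind(i0, j1, k0)]
  c110 <- vol[cbind(i1, j1, k0)]
  c001 <- vol[cbind(i0, j0, k1)]
  c101 <- vol[cbind(i1, j0, k1)]
  c011 <- vol[cbind(i0, j1, k1)]
  c111 <- vol[cbind(i1, j1, k1)]

  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}
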