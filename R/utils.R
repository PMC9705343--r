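# Internal geometry and RNG helpers shared across modules.

#' Evaluate an expression with a local, restored RNG state
#'
#' All generators take an explicit integer seed; the caller's global RNG
#' stream is left untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation (keeps results < 2^31).
deriveSeed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483563
  for (k in ix) s <- (s * 69069 + as.double(k) * 1013 + 1) %% 2147483563
  as.integer(s)
}

# Shoelace area of a closed polygon given vertex coordinates (not repeated).
polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Minimum distance from points (px, py) to a closed polygon boundary.
distToPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vx[i]; ay <- vy[i]
    bx <- vx[j]; by <- vy[j]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- pmin(d2, (px - qx)^2 + (py - qy)^2)
  }
  sqrt(d2)
}

# Per-triangle areas (mm^2) of a mesh: nodes n x 3, triangles m x 3 (1-based).
triangleAreas <- function(nodes, triangles) {
  a <- nodes[triangles[, 1L], , drop = FALSE]
  b <- nodes[triangles[, 2L], , drop = FALSE]
  c <- nodes[triangles[, 3L], , drop = FALSE]
  u <- b - a; v <- c - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# Barycentric node areas: one third of each incident triangle's area.
nodeAreasFromMesh <- function(nodes, triangles) {
  ta <- triangleAreas(nodes, triangles)
  na <- numeric(nrow(nodes))
  for (k in 1:3) {
    acc <- tapply(ta, triangles[, k], sum)
    idx <- as.integer(names(acc))
    na[idx] <- na[idx] + acc
  }
  na / 3
}

# Angular difference helper: is angle a (deg, [0,360)) inside [lo, hi) span
# that may wrap around 360?
angleInSpan <- function(a, lo, hi) {
  a <- a %% 360; lo <- lo %% 360; hi2 <- hi
  span <- (hi - lo)
  if (span >= 360) return(rep(TRUE, length(a)))
  rel <- (a - lo) %% 360
  rel < span
}
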