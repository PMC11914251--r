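# internal helpers shared across modules

# run code with a temporary RNG state seeded by `seed`; restores the
# caller's .Random.seed afterwards so simulations compose deterministically
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# derive a stream of child seeds from one master seed (kept < 2^31)
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# physical coordinate (um) of voxel centers along one axis: index i -> (i-.5)*s
axisCenters <- function(n, s) (seq_len(n) - 0.5) * s

label3d <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  out <- .label3d_cpp(as.logical(mask), d[1], d[2], d[3],
                      as.integer(connectivity))
  array(out, d)
}

edt3d <- function(mask, spacing) {
  d <- dim(mask)
  array(.edt3d_cpp(as.logical(mask), d[1], d[2], d[3],
                   as.numeric(spacing)), d)
}

#' Exact distance from interior points to an axis-aligned ellipsoid surface
#'
#' Computes, for each point, the shortest Euclidean distance to the surface
#' of the ellipsoid \eqn{(x/a)^2 + (y/b)^2 + (z/c)^2 = 1} centered at
#' `center`. Points are expected inside (or on) the ellipsoid; this is the
#' analytic ground-truth distance used by the simulator. The foot point
#' satisfies the Lagrange condition \eqn{q_i = a_i^2 p_i / (a_i^2 + t)} and
#' the unique root t in \eqn{(-\min a_i^2, 0]} is found by bisection.
#'
#' @param points Numeric matrix (n x 3) of coordinates, columns (x, y, z) um.
#' @param center Ellipsoid center (x, y, z) in um.
#' @param semiAxes Semi-axes (a, b, c) in um.
#' @return Numeric vector of distances (um).
#' @examples
#' ellipsoidSurfaceDistance(cbind(0, 0, 0), c(0, 0, 0), c(4, 3, 2))  # = 2
#' @export
ellipsoidSurfaceDistance <- function(points, center, semiAxes) {
  p <- sweep(matrix(as.numeric(points), ncol = 3), 2, as.numeric(center))
  a <- as.numeric(semiAxes)
  stopifnot(length(a) == 3, all(a > 0))
  a2 <- a^2
  amin2 <- min(a2)
  n <- nrow(p)
  # f(t) = sum_i (a_i p_i / (a_i^2 + t))^2 - 1, strictly decreasing on
  # (-amin2, Inf); interior points have the nearest-surface root in
  # (-amin2, 0]. Vectorized bisection.
  fval <- function(t) {
    (a2[1] * p[, 1]^2) / (a2[1] + t)^2 +
    (a2[2] * p[, 2]^2) / (a2[2] + t)^2 +
    (a2[3] * p[, 3]^2) / (a2[3] + t)^2 - 1
  }
  eps <- amin2 * 1e-10
  lo <- rep(-amin2 + eps, n)
  hi <- rep(0, n)
  # rows with f(lo) <= 0 have their foot point on the t = -amin2 branch
  # (points close to the short-axis midplane, inside the evolute)
  branchB <- fval(lo) <= 0
  for (k in seq_len(90)) {
    mid <- (lo + hi) / 2
    f <- fval(mid)
    up <- !is.na(f) & f > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  t <- (lo + hi) / 2
  q <- cbind(a2[1] * p[, 1] / (a2[1] + t),
             a2[2] * p[, 2] / (a2[2] + t),
             a2[3] * p[, 3] / (a2[3] + t))
  d <- sqrt(rowSums((q - p)^2))
  if (any(branchB)) {
    m <- which.min(a2)               # the short axis
    oth <- setdiff(1:3, m)
    pb <- p[branchB, , drop = FALSE]
    qo <- cbind(a2[oth[1]] * pb[, oth[1]] / (a2[oth[1]] - amin2),
                a2[oth[2]] * pb[, oth[2]] / (a2[oth[2]] - amin2))
    s2 <- pmax(0, 1 - (qo[, 1] / a[oth[1]])^2 - (qo[, 2] / a[oth[2]])^2)
    qm <- a[m] * sqrt(s2)
    d[branchB] <- sqrt((qo[, 1] - pb[, oth[1]])^2 +
                       (qo[, 2] - pb[, oth[2]])^2 +
                       (qm - abs(pb[, m]))^2)
  }
  d
}
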