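# Internal geometry and RNG helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions do not clobber the global random stream.
#' A `NULL` seed runs the code against the current stream unchanged.
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce points to an n x 3 numeric matrix. Accepts matrices and data frames;
# data frames may name columns x/y/z (any case), otherwise the first three
# numeric columns are taken.
.as_points3 <- function(p, what = "points") {
  if (is.data.frame(p)) {
    nm <- tolower(names(p))
    if (all(c("x", "y", "z") %in% nm)) {
      p <- as.matrix(p[, match(c("x", "y", "z"), nm)])
    } else {
      num <- vapply(p, is.numeric, logical(1))
      if (sum(num) < 3) stop(what, ": need x/y/z columns", call. = FALSE)
      p <- as.matrix(p[, which(num)[1:3]])
    }
  }
  p <- as.matrix(p)
  if (ncol(p) != 3) stop(what, ": expected 3 columns, got ", ncol(p), call. = FALSE)
  storage.mode(p) <- "double"
  unname(p)
}

# Minimum Euclidean distance from each row of `a` to the set `b`, chunked so
# the distance matrix never exceeds ~8e6 doubles.
.min_dist_to_set <- function(a, b) {
  a <- .as_points3(a); b <- .as_points3(b)
  if (nrow(b) == 0L) return(rep(Inf, nrow(a)))
  out <- numeric(nrow(a))
  bb <- rowSums(b^2)
  chunk <- max(1L, floor(8e6 / nrow(b)))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(nrow(a), i + chunk - 1L)
    aa <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(aa^2), bb, "+") - 2 * aa %*% t(b)
    out[i:j] <- sqrt(pmax(0, apply(d2, 1L, min)))
    i <- j + 1L
  }
  out
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); mu in radians.
.rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return((runif(n, -pi, pi) + mu) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (u[2] < cc * (2 - cc) || log(cc) - log(u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

# Uniform draws inside a 3D ball of radius r, as an n x 3 matrix.
.runif_ball <- function(n, r) {
  if (n == 0L) return(matrix(0, 0, 3))
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  rad <- r * runif(n)^(1 / 3)
  dir * rad
}
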