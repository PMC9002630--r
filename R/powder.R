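#' Crystallite orientation sets for powder averaging
#'
#' Builds a weighted set of `{alpha, beta, gamma}` Euler angles (ZYZ, active,
#' radians) describing crystallite orientations in the rotor frame. The
#' `{alpha, beta}` pairs sample the sphere either by the REPULSION algorithm
#' (electrostatic repulsion of points on the unit sphere, started from a
#' seeded random configuration, or loaded from an embedded precomputed set
#' for the common sizes 66, 168 and 616) or by the ZCW quasi-uniform
#' construction; `gamma` is sampled regularly on `[0, 2pi)`. Weights are
#' equal and sum to 1.
#'
#' @param scheme `"repulsion"`, `"zcw"` or `"explicit"`.
#' @param n_ab Number of `{alpha, beta}` pairs (for `"zcw"` this is rounded
#'   to the nearest Fibonacci number). Must be >= 1.
#' @param n_gamma Number of regular gamma angles. Must be >= 1.
#' @param seed Integer seed for the REPULSION random start (ignored when an
#'   embedded set of the requested size exists or for other schemes).
#' @param angles For `scheme = "explicit"`: a matrix or data frame with
#'   columns `alpha`, `beta` (and optionally `gamma`, `weight`).
#' @return An object of class `orientation_set`: a data frame with columns
#'   `alpha`, `beta`, `gamma`, `weight`.
#' @export
#' @examples
#' p <- powder_set("repulsion", 168, 11)
#' nrow(p)               # 1848 orientations
#' sum(p$weight)         # 1
powder_set <- function(scheme = c("repulsion", "zcw", "explicit"),
                       n_ab = 168L, n_gamma = 11L, seed = 1L,
                       angles = NULL) {
  scheme <- match.arg(scheme)
  if (scheme != "explicit") {
    n_ab <- as.integer(n_ab); n_gamma <- as.integer(n_gamma)
    if (n_ab < 1L || n_gamma < 1L) stop("n_ab and n_gamma must be >= 1")
  }
  ab <- switch(scheme,
    repulsion = repulsion_ab(n_ab, seed = seed),
    zcw = zcw_ab(n_ab),
    explicit = {
      if (is.null(angles)) stop("scheme 'explicit' requires `angles`")
      a <- as.data.frame(angles)
      if (!all(c("alpha", "beta") %in% names(a)))
        stop("explicit angles need columns alpha and beta")
      a
    })
  if (scheme == "explicit") {
    if (!"gamma" %in% names(ab)) ab$gamma <- 0
    if (!"weight" %in% names(ab)) ab$weight <- 1 / nrow(ab)
    out <- ab[c("alpha", "beta", "gamma", "weight")]
  } else {
    gammas <- 2 * pi * (seq_len(n_gamma) - 1L) / n_gamma
    out <- data.frame(
      alpha = rep(ab$alpha, times = n_gamma),
      beta = rep(ab$beta, times = n_gamma),
      gamma = rep(gammas, each = nrow(ab)),
      weight = rep(ab$weight / n_gamma, times = n_gamma))
  }
  out$weight <- out$weight / sum(out$weight)
  out$alpha <- out$alpha %% (2 * pi)
  out$gamma <- out$gamma %% (2 * pi)
  structure(out, class = c("orientation_set", "data.frame"))
}

#' @export
print.orientation_set <- function(x, ...) {
  cat(sprintf("<orientation_set> %d crystallite orientations, sum(weight) = %g\n",
              nrow(x), sum(x$weight)))
  invisible(x)
}

## {alpha, beta} pairs by electrostatic repulsion on the unit sphere.
## Embedded precomputed sets are used for the sizes shipped with the package.
repulsion_ab <- function(n, seed = 1L, iterations = 400L) {
  file <- system.file("extdata", sprintf("repulsion%d.csv", n),
                      package = "spinmix")
  if (nzchar(file)) {
    tab <- read.table(file, header = TRUE, sep = ",")
    return(data.frame(alpha = tab$alpha, beta = tab$beta,
                      weight = rep(1 / n, n)))
  }
  xyz <- repulsion_points(n, seed = seed, iterations = iterations)
  data.frame(alpha = atan2(xyz[, 2], xyz[, 1]) %% (2 * pi),
             beta = acos(pmin(1, pmax(-1, xyz[, 3]))),
             weight = rep(1 / n, n))
}

## Iterative electrostatic-repulsion optimization of n points on the sphere.
repulsion_points <- function(n, seed = 1L, iterations = 400L) {
  set.seed(as.integer(seed))
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  p <- cbind(s * cos(phi), s * sin(phi), z)
  step <- 1 / n
  for (it in seq_len(iterations)) {
    dx <- outer(p[, 1], p[, 1], "-")
    dy <- outer(p[, 2], p[, 2], "-")
    dz <- outer(p[, 3], p[, 3], "-")
    r2 <- dx * dx + dy * dy + dz * dz
    diag(r2) <- Inf
    inv <- 1 / (r2 * sqrt(r2))
    f <- cbind(rowSums(dx * inv), rowSums(dy * inv), rowSums(dz * inv))
    ## project force onto the tangent plane and take a damped step
    rad <- rowSums(f * p)
    f <- f - p * rad
    p <- p + step * f / max(1, max(abs(f)))
    p <- p / sqrt(rowSums(p * p))
    if (it %% 100L == 0L) step <- step * 0.5
  }
  p
}

## ZCW quasi-uniform {alpha, beta} set over the full sphere.
## n is rounded to the nearest Fibonacci number F_M; the generator is F_{M-2}.
zcw_ab <- function(n) {
  fib <- c(1, 2, 3, 5, 8, 13, 21, 34, 55, 89, 144, 233, 377, 610, 987,
           1597, 2584, 4181, 6765, 10946)
  m <- which.min(abs(fib - n))
  if (m < 3L) m <- 3L
  N <- fib[m]; g <- fib[m - 2L]
  j <- seq_len(N) - 1L
  data.frame(alpha = 2 * pi * ((j * g / N) %% 1),
             beta = acos(2 * ((j + 0.5) / N) - 1),
             weight = rep(1 / N, N))
}
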