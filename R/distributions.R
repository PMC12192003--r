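#' Built-in reputation distribution cases
#'
#' Names of the six built-in reputation densities on \eqn{[0,1]}:
#' \describe{
#'   \item{uniform}{\eqn{p_q(x) = 1}}
#'   \item{linear_increasing}{\eqn{p_q(x) = 2x} — cooperative societies}
#'   \item{linear_decreasing}{\eqn{p_q(x) = 2 - 2x} — mostly defecting}
#'   \item{exp_decreasing}{\eqn{p_q(x) \propto e^{-ax} - e^{-a}}, slope
#'     \eqn{a > 0}; the \eqn{e^{-a}} offset forces \eqn{p_q(1) = 0}}
#'   \item{hump}{\eqn{p_q(x) = 6x(1-x)} — mass concentrated at \eqn{q = 1/2}}
#'   \item{ushape}{\eqn{p_q(x) = -12x(1-x) + 3} — mass at both extremes}
#' }
#'
#' @return Character vector of case names accepted by
#'   [reputation_distribution()].
#' @export
builtin_cases <- function() {
  c("uniform", "linear_increasing", "linear_decreasing",
    "exp_decreasing", "hump", "ushape")
}

#' Reputation distribution on the unit interval
#'
#' Constructs a probability distribution of agent reputations, i.e. of
#' cooperation probabilities \eqn{q \in [0,1]}. Six named densities are
#' built in (see [builtin_cases()]); arbitrary densities can be supplied
#' as tabulated `(x, density)` pairs with `name = "custom"` and are
#' linearly interpolated. A tabulated density whose trapezoid integral is
#' off unity by less than `1e-3` is renormalized; a larger deviation is an
#' error, on the view that silently fixing a badly wrong density hides
#' user mistakes.
#'
#' @param name Case name, one of [builtin_cases()] or `"custom"`.
#' @param a Slope of the exponential decrease (only `exp_decreasing`);
#'   must be positive. Default 5.
#' @param x,density Numeric vectors of tabulated support points (must
#'   cover \eqn{[0,1]}, strictly increasing) and nonnegative density
#'   values (only `name = "custom"`).
#' @return An object of class `"rep_dist"`: a list with elements `name`,
#'   `params`, and vectorized functions `pdf(x)`, `cdf(x)`,
#'   `quantile(p)`, plus the precomputed `mean`.
#' @examples
#' d <- reputation_distribution("exp_decreasing", a = 5)
#' d$pdf(c(0, 0.5, 1))
#' integrate(d$pdf, 0, 1)$value # 1
#' @export
reputation_distribution <- function(name = "uniform", a = 5,
                                    x = NULL, density = NULL) {
  name <- match.arg(name, c(builtin_cases(), "custom"))
  if (name == "custom") {
    return(custom_distribution(x, density))
  }
  dist <- switch(name,
    uniform = list(
      pdf = function(x) ifelse(x >= 0 & x <= 1, 1, 0),
      cdf = function(x) pmin(pmax(x, 0), 1),
      quantile = function(p) p,
      mean = 1 / 2
    ),
    linear_increasing = list(
      pdf = function(x) ifelse(x >= 0 & x <= 1, 2 * x, 0),
      cdf = function(x) pmin(pmax(x, 0), 1)^2,
      quantile = function(p) sqrt(p),
      mean = 2 / 3
    ),
    linear_decreasing = list(
      pdf = function(x) ifelse(x >= 0 & x <= 1, 2 - 2 * x, 0),
      cdf = function(x) { z <- pmin(pmax(x, 0), 1); 2 * z - z^2 },
      quantile = function(p) 1 - sqrt(1 - p),
      mean = 1 / 3
    ),
    exp_decreasing = exp_decreasing_dist(a),
    hump = list(
      pdf = function(x) ifelse(x >= 0 & x <= 1, 6 * x * (1 - x), 0),
      cdf = function(x) { z <- pmin(pmax(x, 0), 1); 3 * z^2 - 2 * z^3 },
      quantile = NULL,
      mean = 1 / 2
    ),
    ushape = list(
      pdf = function(x) ifelse(x >= 0 & x <= 1, -12 * x * (1 - x) + 3, 0),
      cdf = function(x) { z <- pmin(pmax(x, 0), 1); 4 * z^3 - 6 * z^2 + 3 * z },
      quantile = NULL,
      mean = 1 / 2
    )
  )
  params <- if (name == "exp_decreasing") list(a = a) else list()
  new_rep_dist(name, params, dist$pdf, dist$cdf, dist$quantile, dist$mean)
}

# Normalized exponential decrease: p(x) = C (e^{-ax} - e^{-a}) with
# C = a e^a / (e^a - a - 1), so that the density integrates to 1 and
# vanishes at x = 1.
exp_decreasing_dist <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("'a' must be a single positive number", call. = FALSE)
  }
  C <- a * exp(a) / (exp(a) - a - 1)
  pdf <- function(x) ifelse(x >= 0 & x <= 1, C * (exp(-a * x) - exp(-a)), 0)
  cdf <- function(x) {
    z <- pmin(pmax(x, 0), 1)
    C * ((1 - exp(-a * z)) / a - z * exp(-a))
  }
  # mean = C * (int x e^{-ax} dx - e^{-a}/2)
  mean <- C * ((1 - (1 + a) * exp(-a)) / a^2 - exp(-a) / 2)
  list(pdf = pdf, cdf = cdf, quantile = NULL, mean = mean)
}

custom_distribution <- function(x, density) {
  if (is.null(x) || is.null(density)) {
    stop("custom distribution requires 'x' and 'density' vectors",
         call. = FALSE)
  }
  stopifnot(is.numeric(x), is.numeric(density), length(x) == length(density))
  if (length(x) < 2L || is.unsorted(x, strictly = TRUE)) {
    stop("'x' must be strictly increasing with at least two points",
         call. = FALSE)
  }
  if (abs(x[1L]) > 1e-12 || abs(x[length(x)] - 1) > 1e-12) {
    stop("tabulated 'x' must cover [0, 1] exactly", call. = FALSE)
  }
  if (any(density < 0)) stop("density values must be nonnegative", call. = FALSE)
  total <- sum(diff(x) * (utils::head(density, -1) + utils::tail(density, -1)) / 2)
  if (abs(total - 1) >= 1e-3) {
    stop(sprintf(
      "tabulated density integrates to %.6f, not 1 (tolerance 1e-3)", total),
      call. = FALSE)
  }
  density <- density / total
  pdf_in <- stats::approxfun(x, density, rule = 2)
  # piecewise-quadratic CDF of the piecewise-linear density
  Fknots <- c(0, cumsum(diff(x) * (utils::head(density, -1) +
                                   utils::tail(density, -1)) / 2))
  Fknots <- Fknots / Fknots[length(Fknots)]
  cdf_in <- function(z) {
    i <- findInterval(z, x, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(x) - 1L)
    dx <- z - x[i]
    slope <- (density[i + 1L] - density[i]) / (x[i + 1L] - x[i])
    Fknots[i] + density[i] * dx + slope * dx^2 / 2
  }
  pdf <- function(z) ifelse(z >= 0 & z <= 1, pdf_in(pmin(pmax(z, 0), 1)), 0)
  cdf <- function(z) pmin(pmax(cdf_in(pmin(pmax(z, 0), 1)), 0), 1)
  mean <- stats::integrate(function(z) z * pdf(z), 0, 1,
                           abs.tol = 1e-12, subdivisions = 500L)$value
  new_rep_dist("custom", list(x = x, density = density), pdf, cdf, NULL, mean)
}

new_rep_dist <- function(name, params, pdf, cdf, quantile, mean) {
  if (is.null(quantile)) quantile <- numeric_quantile(cdf, pdf)
  structure(
    list(name = name, params = params, pdf = pdf, cdf = cdf,
         quantile = quantile, mean = mean),
    class = "rep_dist"
  )
}

# Monotone numerical inversion of the CDF for cases without a closed-form
# quantile: a dense tabulated inverse bracketed on [0,1], sharpened by a
# few damped Newton steps (skipped where the density vanishes, e.g. the
# flat CDF point of the U-shaped case, where the tabulated value is
# already adequate). Fully vectorized; no rejection loops.
numeric_quantile <- function(cdf, pdf) {
  g <- seq(0, 1, length.out = 8193L)
  Fg <- cdf(g)
  inv <- stats::approxfun(Fg, g, ties = "ordered", rule = 2)
  function(p) {
    p <- pmin(pmax(p, 0), 1)
    q <- inv(p)
    for (k in 1:3) {
      f <- pdf(q)
      step <- ifelse(f > 1e-8, (cdf(q) - p) / pmax(f, 1e-8), 0)
      q <- pmin(pmax(q - step, 0), 1)
    }
    q
  }
}

#' @export
print.rep_dist <- function(x, ...) {
  cat("Reputation distribution on [0,1]\n")
  cat("  case:", x$name, "\n")
  if (length(x$params) && x$name != "custom") {
    cat("  params:",
        paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
        "\n")
  }
  if (x$name == "custom") {
    cat("  tabulated at", length(x$params$x), "points\n")
  }
  cat("  mean reputation:", format(x$mean, digits = 6), "\n")
  invisible(x)
}

#' @export
plot.rep_dist <- function(x, n = 1L, grid_size = 401L, ...) {
  g <- seq(0, 1, length.out = grid_size)
  graphics::plot(g, x$pdf(g), type = "l", xlab = "reputation q",
                 ylab = "density", ...)
  if (n > 1L) {
    graphics::lines(g, max_reputation_density(x, n, g), lty = 2)
    graphics::legend("top", bty = "n", lty = 1:2,
                     legend = c("p(q)", sprintf("max of n = %d", n)))
  }
  invisible(x)
}

#' Sample agent reputations
#'
#' Draws independent reputations from a [reputation_distribution()] by
#' inversion: a closed-form quantile function where the CDF is invertible
#' analytically, otherwise monotone-bracketing numerical inversion. No
#' rejection loops, so the draw count is exact and reproducible.
#'
#' @param dist A `"rep_dist"` object.
#' @param count Number of draws, a positive integer.
#' @param seed Optional integer seed; when supplied the RNG state is set
#'   (and the previous state restored on exit) so draws are reproducible.
#' @return Numeric vector of `count` reputations in \eqn{[0,1]}.
#' @examples
#' d <- reputation_distribution("hump")
#' mean(sample_reputations(d, 1e4, seed = 1)) # about 0.5
#' @export
sample_reputations <- function(dist, count, seed = NULL) {
  stopifnot(inherits(dist, "rep_dist"))
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("'count' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  dist$quantile(stats::runif(count))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
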