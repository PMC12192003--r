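#' Reputation-based partner-choice model of a trading society
#'
#' Instantiates the analytic model of a large society of agents playing
#' the one-shot Prisoner's Dilemma under reputation-based matching. The
#' first player of each game is drawn uniformly; the second is the most
#' reputable of `n` uniformly sampled candidates, so its reputation
#' follows the max order-statistic density \eqn{n F(x)^{n-1} p_q(x)}.
#' In the large-population limit an agent's expected income per sweep is
#' \deqn{I(q) = I_1(q) + n F(q)^{n-1} I_2(q),}
#' the two terms being the expected gains from playing first and second
#' (with the \eqn{0^0 = 1} convention so that `n = 1` gives
#' \eqn{I_1 + I_2}).
#'
#' Because the expected game payoff is linear in the opponent's
#' reputation, \eqn{I_1} and \eqn{I_2} reduce to affine functions of `q`
#' through two moments of the reputation density — its mean and the mean
#' of the max of `n` draws — which are computed once here (closed form
#' for the uniform and linear-increasing cases, adaptive quadrature at
#' absolute tolerance 1e-12 otherwise).
#'
#' @param dist A [reputation_distribution()].
#' @param n Candidate-group size for partner choice, integer \eqn{\ge 1}.
#' @param payoffs A [pd_payoffs()] object.
#' @return An object of class `"ipd_model"` with methods [print()],
#'   [summary()], [coef()], [predict()], [plot()] and [simulate()].
#' @examples
#' m <- ipd_model(reputation_distribution("uniform"), n = 2)
#' predict(m, q = c(0, 13/18, 1))
#' summary(m)
#' @export
ipd_model <- function(dist, n = 2L, payoffs = pd_payoffs()) {
  stopifnot(inherits(dist, "rep_dist"), inherits(payoffs, "pd_payoffs"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  m_max <- mean_max_reputation(dist, n)
  structure(
    list(dist = dist, n = n, payoffs = payoffs,
         mean_rep = dist$mean, mean_max = m_max),
    class = "ipd_model"
  )
}

# E[max of n draws]; closed form where the CDF power integrates trivially.
mean_max_reputation <- function(dist, n) {
  if (dist$name == "uniform") return(n / (n + 1))
  if (dist$name == "linear_increasing") return(2 * n / (2 * n + 1))
  stats::integrate(function(x) x * max_reputation_density(dist, n, x),
                   0, 1, abs.tol = 1e-12, subdivisions = 500L)$value
}

#' Density of the highest reputation among n sampled candidates
#'
#' The max order-statistic density \eqn{p_{q_{max}}(x) = n F(x)^{n-1}
#' p_q(x)}, where \eqn{F} is the reputation CDF. For `n = 1` this is the
#' reputation density itself.
#'
#' @param dist A [reputation_distribution()].
#' @param n Sample size, integer \eqn{\ge 1}.
#' @param x Evaluation points in \eqn{[0,1]} (vectorized).
#' @return Density values; the function integrates to 1 over \eqn{[0,1]}.
#' @examples
#' u <- reputation_distribution("uniform")
#' max_reputation_density(u, 3, 0.5) # 3 * 0.25
#' @export
max_reputation_density <- function(dist, n, x) {
  stopifnot(inherits(dist, "rep_dist"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be an integer >= 1", call. = FALSE)
  check_reputation(x)
  if (n == 1L) return(dist$pdf(x))
  n * dist$cdf(x)^(n - 1L) * dist$pdf(x)
}

# Affine coefficients of G1(q, x) in the opponent reputation x:
# G1(q, x) = c0(q) + c1(q) x.
g1_coefs <- function(q, payoffs) {
  list(c0 = q * payoffs$S + (1 - q) * payoffs$P,
       c1 = q * (payoffs$R - payoffs$S) + (1 - q) * (payoffs$T - payoffs$P))
}

#' Expected income from playing as the first-chosen agent
#'
#' \eqn{I_1(q) = \int_0^1 p_{q_{max}}(x) G_1(q, x)\,dx}: the expected
#' game payoff of a reputation-`q` agent against an opponent drawn from
#' the max order-statistic density.
#'
#' @param q Reputation(s) in \eqn{[0,1]}.
#' @param model An [ipd_model()].
#' @return Expected payoff(s).
#' @export
expected_income_first <- function(q, model) {
  stopifnot(inherits(model, "ipd_model"))
  check_reputation(q)
  co <- g1_coefs(q, model$payoffs)
  co$c0 + co$c1 * model$mean_max
}

#' Expected income from playing as the second-chosen agent
#'
#' \eqn{I_2(q) = \int_0^1 p_q(x) G_1(q, x)\,dx}: the expected game payoff
#' against a uniformly drawn first player. For `n = 1` it coincides with
#' [expected_income_first()].
#'
#' @inheritParams expected_income_first
#' @return Expected payoff(s).
#' @export
expected_income_second <- function(q, model) {
  stopifnot(inherits(model, "ipd_model"))
  check_reputation(q)
  co <- g1_coefs(q, model$payoffs)
  co$c0 + co$c1 * model$mean_rep
}

#' Total expected income of a reputation-q agent
#'
#' The large-population expected income per sweep,
#' \eqn{I(q) = I_1(q) + n F(q)^{n-1} I_2(q)}; the second factor is the
#' probability that a reputation-`q` agent is the most reputable of the
#' `n` sampled candidates (\eqn{0^0 = 1}, so `n = 1` gives
#' \eqn{I_1 + I_2}).
#'
#' @inheritParams expected_income_first
#' @return Expected income(s).
#' @examples
#' m <- ipd_model(reputation_distribution("uniform"), n = 1)
#' total_income(c(0, 0.5, 1), m) # the line 6 - 3q
#' @export
total_income <- function(q, model) {
  stopifnot(inherits(model, "ipd_model"))
  check_reputation(q)
  sel <- if (model$n == 1L) 1 else model$n * model$dist$cdf(q)^(model$n - 1L)
  expected_income_first(q, model) + sel * expected_income_second(q, model)
}

#' Closed-form income curve, uniform reputation density
#'
#' Polynomial form of the expected income for \eqn{p_q(x) = 1}:
#' \deqn{I(q) = \tfrac12 n q^{n-1}(-Pq + P + qR + qS - qT + T) +
#'   \frac{nqR - nqT + nT - Pq + P + qS}{n + 1},}
#' which for the default payoffs reduces to
#' \eqn{\tfrac12 n (6-3q) q^{n-1} + (-2nq + 5n - q + 1)/(n+1)}.
#' Serves as an exact oracle for [total_income()].
#'
#' @param q Reputation(s) in \eqn{[0,1]}.
#' @param n Candidate-group size.
#' @param payoffs A [pd_payoffs()] object.
#' @return Income value(s).
#' @export
closed_form_income_uniform <- function(q, n, payoffs = pd_payoffs()) {
  check_reputation(q)
  T <- payoffs$T; R <- payoffs$R; P <- payoffs$P; S <- payoffs$S
  first <- if (n == 1L) {
    0.5 * (-P * q + P + q * R + q * S - q * T + T)
  } else {
    0.5 * n * q^(n - 1) * (-P * q + P + q * R + q * S - q * T + T)
  }
  first + (n * q * R - n * q * T + n * T - P * q + P + q * S) / (n + 1)
}

#' Closed-form income curve, linearly increasing reputation density
#'
#' Polynomial form of the expected income for \eqn{p_q(x) = 2x}:
#' \deqn{I(q) = \tfrac13 n q^{2(n-1)}(-Pq + P + 2qR + qS - 2qT + 2T) +
#'   \frac{2nqR - 2nqT + 2nT - Pq + P + qS}{2n + 1}.}
#'
#' @inheritParams closed_form_income_uniform
#' @return Income value(s).
#' @export
closed_form_income_linear <- function(q, n, payoffs = pd_payoffs()) {
  check_reputation(q)
  T <- payoffs$T; R <- payoffs$R; P <- payoffs$P; S <- payoffs$S
  first <- if (n == 1L) {
    (1 / 3) * (-P * q + P + 2 * q * R + q * S - 2 * q * T + 2 * T)
  } else {
    (1 / 3) * n * q^(2 * (n - 1)) *
      (-P * q + P + 2 * q * R + q * S - 2 * q * T + 2 * T)
  }
  first + (2 * n * q * R - 2 * n * q * T + 2 * n * T - P * q + P + q * S) /
    (2 * n + 1)
}

#' Expected income of an always-defecting agent
#'
#' For \eqn{n \ge 2} a reputation-0 agent is never chosen as the second
#' player, so its whole income comes from being drawn first:
#' \eqn{I(0) = I_1(0) = \int_0^1 p_q(x)[xT + (1-x)P]\,dx} evaluated
#' against the max order-statistic density. It grows with `n` because a
#' larger candidate pool raises the expected reputation of the opponent,
#' making the temptation payoff more likely. At `n = 1` the premise
#' fails (the lone candidate is chosen regardless of reputation), so
#' `n = 1` is rejected.
#'
#' @param model An [ipd_model()] with `n >= 2`.
#' @return The income \eqn{I(0)}; for the uniform density it equals
#'   \eqn{(1 + 5n)/(1 + n)} and for the linear-increasing one
#'   \eqn{(1 + 10n)/(1 + 2n)} at default payoffs.
#' @export
defector_income <- function(model) {
  stopifnot(inherits(model, "ipd_model"))
  if (model$n < 2L) {
    stop("defector_income() requires n >= 2: with a single candidate the q = 0 agent can still be chosen second",
         call. = FALSE)
  }
  total_income(0, model)
}

#' Expected-income curve on a reputation grid
#'
#' @param model An [ipd_model()].
#' @param grid_size Number of equally spaced grid points on \eqn{[0,1]}.
#' @return A data frame of class `"income_curve"` with columns `q` and
#'   `income`; the generating model is attached as attribute `"model"`.
#' @export
income_curve <- function(model, grid_size = 1001L) {
  stopifnot(inherits(model, "ipd_model"))
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 2L) {
    stop("'grid_size' must be an integer >= 2", call. = FALSE)
  }
  q <- seq(0, 1, length.out = grid_size)
  out <- data.frame(q = q, income = total_income(q, model))
  attr(out, "model") <- model
  class(out) <- c("income_curve", "data.frame")
  out
}

#' Locate extrema of the expected-income curve
#'
#' Scans [total_income()] on a dense grid, brackets interior sign changes
#' of the discrete derivative, and refines each extremum by
#' derivative-free local search ([stats::optimize()]) to a location
#' precision of about 1e-6. The two boundary points `q = 0` and `q = 1`
#' are always reported separately (placement `"boundary"`), so curves
#' whose maximum sits at `q = 1` are classified as boundary maxima.
#'
#' @param model An [ipd_model()].
#' @param grid_size Scan grid size, integer \eqn{\ge 100}.
#' @return A data frame of class `"extremum_report"` with columns
#'   `location`, `value`, `kind` (`"maximum"`/`"minimum"`) and
#'   `placement` (`"interior"`/`"boundary"`).
#' @examples
#' m <- ipd_model(reputation_distribution("uniform"), n = 2)
#' find_extrema(m) # interior maximum at q = 13/18
#' @export
find_extrema <- function(model, grid_size = 1001L) {
  stopifnot(inherits(model, "ipd_model"))
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 100L) {
    stop("'grid_size' must be an integer >= 100", call. = FALSE)
  }
  g <- seq(0, 1, length.out = grid_size)
  v <- total_income(g, model)
  eps <- 1e-12 * max(1, max(abs(v)))
  d <- diff(v)
  rows <- list()
  for (i in seq_len(length(d) - 1L)) {
    rising <- d[i] > eps
    falling <- d[i] < -eps
    rising_next <- d[i + 1L] > eps
    falling_next <- d[i + 1L] < -eps
    kind <- if (rising && falling_next) "maximum"
            else if (falling && rising_next) "minimum"
            else next
    lo <- g[i]; hi <- g[i + 2L]
    opt <- stats::optimize(function(z) total_income(z, model),
                           c(lo, hi), maximum = kind == "maximum",
                           tol = 1e-10)
    loc <- if (kind == "maximum") opt$maximum else opt$minimum
    rows[[length(rows) + 1L]] <- data.frame(
      location = loc, value = opt$objective, kind = kind,
      placement = "interior", stringsAsFactors = FALSE)
  }
  bkind <- function(at, nb) if (at >= nb) "maximum" else "minimum"
  rows[[length(rows) + 1L]] <- data.frame(
    location = 0, value = v[1L], kind = bkind(v[1L], v[2L]),
    placement = "boundary", stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    location = 1, value = v[grid_size], kind = bkind(v[grid_size], v[grid_size - 1L]),
    placement = "boundary", stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("extremum_report", "data.frame")
  out
}

#' Society-level income summary
#'
#' The expected income of a randomly drawn society member,
#' \eqn{E(I) = \int_0^1 p_q(x) I(x)\,dx}, and its dispersion, reported as
#' the standard deviation
#' \eqn{\sigma(I) = \sqrt{\int_0^1 p_q(x)[I(x) - E(I)]^2\,dx}}.
#'
#' @param model An [ipd_model()].
#' @return A list of class `"society_summary"` with elements
#'   `expected_income` and `dispersion`.
#' @examples
#' m <- ipd_model(reputation_distribution("uniform"), n = 1)
#' society_summary(m) # mean 4.5, dispersion sqrt(3)/2
#' @export
society_summary <- function(model) {
  stopifnot(inherits(model, "ipd_model"))
  E <- stats::integrate(function(x) model$dist$pdf(x) * total_income(x, model),
                        0, 1, abs.tol = 1e-10, subdivisions = 500L)$value
  V <- stats::integrate(
    function(x) model$dist$pdf(x) * (total_income(x, model) - E)^2,
    0, 1, abs.tol = 1e-10, subdivisions = 500L)$value
  structure(list(expected_income = E, dispersion = sqrt(max(V, 0))),
            class = "society_summary")
}

#' @export
print.society_summary <- function(x, digits = 4, ...) {
  cat("Society income: mean", format(x$expected_income, digits = digits),
      " dispersion", format(x$dispersion, digits = digits), "\n")
  invisible(x)
}

# ---- standard model methods -------------------------------------------------

#' @export
print.ipd_model <- function(x, ...) {
  cat("Reputation-based partner-choice PD model (large-N limit)\n")
  cat("  reputation density:", x$dist$name,
      if (length(x$dist$params) && x$dist$name != "custom")
        paste0("(", paste(names(x$dist$params), unlist(x$dist$params),
                          sep = " = ", collapse = ", "), ")"),
      "\n")
  cat("  candidate-group size n:", x$n, "\n")
  cat("  payoffs (T, R, P, S):",
      paste(unlist(x$payoffs[c("T", "R", "P", "S")]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.ipd_model <- function(object, ...) {
  c(n = object$n,
    T = object$payoffs$T, R = object$payoffs$R,
    P = object$payoffs$P, S = object$payoffs$S,
    unlist(object$dist$params[names(object$dist$params) == "a"]))
}

#' Predict expected incomes from the analytic model
#'
#' @param object An [ipd_model()].
#' @param q Reputations at which to evaluate (default: 101-point grid).
#' @param type `"total"` for \eqn{I(q)}, `"first"` for \eqn{I_1(q)},
#'   `"second"` for \eqn{I_2(q)}.
#' @param ... Unused.
#' @return Numeric vector of expected incomes.
#' @export
predict.ipd_model <- function(object, q = seq(0, 1, length.out = 101L),
                              type = c("total", "first", "second"), ...) {
  type <- match.arg(type)
  switch(type,
         total = total_income(q, object),
         first = expected_income_first(q, object),
         second = expected_income_second(q, object))
}

#' @export
summary.ipd_model <- function(object, grid_size = 1001L, ...) {
  structure(
    list(model = object,
         society = society_summary(object),
         extrema = find_extrema(object, grid_size)),
    class = "summary.ipd_model")
}

#' @export
print.summary.ipd_model <- function(x, digits = 4, ...) {
  print(x$model)
  print(x$society, digits = digits)
  cat("Extrema of I(q):\n")
  print(as.data.frame(x$extrema), digits = digits)
  invisible(x)
}

#' @export
plot.ipd_model <- function(x, grid_size = 401L, ...) {
  cur <- income_curve(x, grid_size)
  graphics::plot(cur$q, cur$income, type = "l",
                 xlab = "reputation q", ylab = "expected income I(q)",
                 main = sprintf("%s density, n = %d", x$dist$name, x$n), ...)
  invisible(cur)
}

#' @export
plot.income_curve <- function(x, ...) {
  graphics::plot(x$q, x$income, type = "l",
                 xlab = "reputation q", ylab = "expected income I(q)", ...)
  invisible(x)
}
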