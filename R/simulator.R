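#' Agent-based Monte Carlo simulation of the society
#'
#' Finite-population realization of the matching-and-play process behind
#' an [ipd_model()]. Reputations are drawn once at the start and frozen.
#' Each iteration: a first agent is chosen uniformly; `n` distinct
#' candidates are drawn uniformly from the other `agents - 1` (self-play
#' impossible); the candidate of highest reputation plays second, ties
#' broken uniformly at random; both players cooperate independently with
#' probability equal to their own reputation and collect the realized
#' matrix payoffs.
#'
#' @param object An [ipd_model()].
#' @param nsim Number of independent replicate runs (default 1).
#' @param seed Optional integer seed; RNG state is restored on exit, as
#'   for [stats::simulate()].
#' @param agents Population size N (default 10000).
#' @param iterations Number of games played (default `agents`, the
#'   one-sweep convention under which accumulated income estimates
#'   \eqn{I(q)} directly).
#' @param reputations Optional fixed reputation vector of length
#'   `agents`, bypassing sampling (useful for degenerate checks).
#' @param ... Unused.
#' @return For `nsim = 1` an object of class `"ipd_sim"`: a list with
#'   `reputations`, accumulated `incomes`, selection counts
#'   `first_count` / `second_count`, and the generating configuration.
#'   For `nsim > 1`, a list of such objects.
#' @examples
#' m <- ipd_model(reputation_distribution("uniform"), n = 2)
#' s <- simulate(m, seed = 1, agents = 500, iterations = 500)
#' sum(s$incomes) # total wealth created
#' @export
simulate.ipd_model <- function(object, nsim = 1L, seed = NULL,
                               agents = 10000L, iterations = agents,
                               reputations = NULL, ...) {
  agents <- as.integer(agents)
  iterations <- as.integer(iterations)
  if (is.na(agents) || agents < 2L) stop("'agents' must be >= 2", call. = FALSE)
  if (object$n > agents - 1L) {
    stop("'n' must satisfy n <= agents - 1", call. = FALSE)
  }
  if (is.na(iterations) || iterations < 1L) {
    stop("'iterations' must be >= 1", call. = FALSE)
  }
  if (!is.null(reputations)) {
    check_reputation(reputations)
    if (length(reputations) != agents) {
      stop("'reputations' must have length 'agents'", call. = FALSE)
    }
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  runs <- lapply(seq_len(max(1L, as.integer(nsim))), function(k) {
    run_one_simulation(object, agents, iterations, reputations, seed, k)
  })
  if (nsim == 1L) runs[[1L]] else runs
}

run_one_simulation <- function(model, agents, iterations, reputations,
                               seed, replicate) {
  n <- model$n
  rep_ <- if (is.null(reputations)) {
    model$dist$quantile(stats::runif(agents))
  } else reputations

  first <- sample.int(agents, iterations, replace = TRUE)
  # n distinct candidates per game from the other agents - 1; indices in
  # 1..agents-1 shifted past the first player's own index
  cand <- vapply(seq_len(iterations),
                 function(i) sample.int(agents - 1L, n),
                 integer(n))
  cand <- matrix(cand, nrow = n)
  cand <- cand + (cand >= rep(first, each = n))
  # second player: candidate of maximal reputation, random tie-break
  pick <- max.col(matrix(rep_[cand], ncol = n, byrow = TRUE),
                  ties.method = "random")
  second <- cand[cbind(pick, seq_len(iterations))]

  a1 <- stats::rbinom(iterations, 1L, rep_[first])   # 1 = cooperate
  a2 <- stats::rbinom(iterations, 1L, rep_[second])
  po <- model$payoffs
  idx <- 2L * a1 + a2 + 1L                           # (D,D),(D,C),(C,D),(C,C)
  pay1 <- c(po$P, po$T, po$S, po$R)[idx]
  pay2 <- c(po$P, po$S, po$T, po$R)[idx]

  incomes <- numeric(agents)
  s1 <- rowsum(pay1, first)
  incomes[as.integer(rownames(s1))] <- s1
  s2 <- rowsum(pay2, second)
  incomes[as.integer(rownames(s2))] <-
    incomes[as.integer(rownames(s2))] + s2

  structure(
    list(reputations = rep_, incomes = incomes,
         first_count = tabulate(first, agents),
         second_count = tabulate(second, agents),
         agents = agents, iterations = iterations,
         n = n, dist_name = model$dist$name, dist_params = model$dist$params,
         payoffs = unlist(model$payoffs[c("T", "R", "P", "S")]),
         seed = seed, replicate = replicate),
    class = "ipd_sim")
}

#' @export
print.ipd_sim <- function(x, ...) {
  cat("Agent-based PD simulation\n")
  cat("  agents:", x$agents, " iterations:", x$iterations,
      " n:", x$n, " density:", x$dist_name, "\n")
  cat("  total income:", format(sum(x$incomes), digits = 8),
      " (mean per agent, rescaled:",
      format(mean(x$incomes) * x$agents / x$iterations, digits = 5), ")\n")
  invisible(x)
}

#' Bin simulated incomes by reputation
#'
#' Groups agents into `bin_count` equal-width reputation bins and returns
#' the per-bin mean accumulated income rescaled by
#' `agents / iterations`, so each bin estimates the analytic expected
#' income \eqn{I(q)} under the one-sweep convention (N iterations for N
#' agents). Empty bins are kept with `NA` values and `count = 0`.
#'
#' @param result An `"ipd_sim"` object.
#' @param bin_count Number of bins, integer \eqn{\ge 2}.
#' @return A data frame with columns `q_lo`, `q_hi`, `q_mid`, `count`,
#'   `income` (rescaled bin mean) and `se` (standard error of the bin
#'   mean, `NA` for bins with fewer than 2 agents).
#' @export
binned_income_curve <- function(result, bin_count = 20L) {
  stopifnot(inherits(result, "ipd_sim"))
  bin_count <- as.integer(bin_count)
  if (is.na(bin_count) || bin_count < 2L) {
    stop("'bin_count' must be an integer >= 2", call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = bin_count + 1L)
  bin <- findInterval(result$reputations, breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
  scale <- result$agents / result$iterations
  scaled <- result$incomes * scale
  count <- tabulate(bin, bin_count)
  if (all(count == 0L)) stop("all bins are empty", call. = FALSE)
  mean_b <- rep(NA_real_, bin_count)
  se_b <- rep(NA_real_, bin_count)
  agg <- rowsum(scaled, bin)
  ids <- as.integer(rownames(agg))
  mean_b[ids] <- agg / count[ids]
  sq <- rowsum(scaled^2, bin)
  has2 <- ids[count[ids] >= 2L]
  v <- (sq[match(has2, ids)] - count[has2] * mean_b[has2]^2) /
    (count[has2] - 1L)
  se_b[has2] <- sqrt(pmax(v, 0) / count[has2])
  data.frame(q_lo = breaks[-(bin_count + 1L)], q_hi = breaks[-1L],
             q_mid = (breaks[-1L] + breaks[-(bin_count + 1L)]) / 2,
             count = count, income = mean_b, se = se_b)
}

#' Society summary estimated from a simulation
#'
#' Mean and standard deviation of the rescaled per-agent incomes; the
#' empirical counterpart of [society_summary()]. The dispersion includes
#' game and selection noise on top of the reputation-driven spread, so it
#' converges to the analytic value only as `iterations` grows faster
#' than `agents`.
#'
#' @param result An `"ipd_sim"` object.
#' @return A `"society_summary"` list with an extra element `se_mean`,
#'   the standard error of the estimated mean.
#' @export
simulated_society_summary <- function(result) {
  stopifnot(inherits(result, "ipd_sim"))
  scaled <- result$incomes * result$agents / result$iterations
  structure(list(expected_income = mean(scaled),
                 dispersion = stats::sd(scaled),
                 se_mean = stats::sd(scaled) / sqrt(length(scaled))),
            class = "society_summary")
}
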