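# Shared fixtures: every built-in reputation distribution (exponential
# slope a = 5 throughout, the value used in all reported results).
all_distributions <- function(a = 5) {
  out <- lapply(builtin_cases(), function(cs) {
    if (cs == "exp_decreasing") reputation_distribution(cs, a = a)
    else reputation_distribution(cs)
  })
  names(out) <- builtin_cases()
  out
}

# Direct quadrature of an integrand over [0,1]; the independent route
# used to cross-check the moment-based income implementation.
quad01 <- function(f) {
  stats::integrate(f, 0, 1, abs.tol = 1e-12, subdivisions = 500L)$value
}

# Income via direct quadrature of the order-statistic / reputation
# densities against the expected game payoff (independent of the
# moment-based path inside the package).
quad_income_first <- function(q, dist, n, payoffs = pd_payoffs()) {
  quad01(function(x) max_reputation_density(dist, n, x) *
           expected_game_payoff(q, x, payoffs))
}

quad_income_second <- function(q, dist, n, payoffs = pd_payoffs()) {
  quad01(function(x) dist$pdf(x) * expected_game_payoff(q, x, payoffs))
}

quad_total_income <- function(q, dist, n, payoffs = pd_payoffs()) {
  sel <- if (n == 1) 1 else n * dist$cdf(q)^(n - 1)
  quad_income_first(q, dist, n, payoffs) +
    sel * quad_income_second(q, dist, n, payoffs)
}
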