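# Row order and labels of the society summary table: the six built-in
# densities as studied (the decreasing case has a linear and an
# exponential variant).
table_cases <- function(a = 5) {
  list(
    list(label = "case 1",               case = "uniform"),
    list(label = "case 2",               case = "linear_increasing"),
    list(label = "case 3 (linear)",      case = "linear_decreasing"),
    list(label = "case 3 (exponential)", case = "exp_decreasing", a = a),
    list(label = "case 4",               case = "hump"),
    list(label = "case 5",               case = "ushape")
  )
}

#' Society income table across all built-in densities
#'
#' Computes [society_summary()] for every built-in reputation density and
#' each requested candidate-group size `n`: the society-wide expected
#' income with its dispersion (standard deviation) in full precision and
#' rounded to two decimals.
#'
#' @param n_values Candidate-group sizes (default `c(1, 2, 3, 5, 10)`).
#' @param payoffs A [pd_payoffs()] object.
#' @param a Slope of the exponential decreasing density (default 5).
#' @return A long data frame with columns `label`, `case`, `n`, `mean`,
#'   `dispersion`, `mean_2dp`, `dispersion_2dp`.
#' @examples
#' tab <- reproduce_table1(n_values = c(1, 2))
#' subset(tab, label == "case 1")
#' @export
reproduce_table1 <- function(n_values = c(1L, 2L, 3L, 5L, 10L),
                             payoffs = pd_payoffs(), a = 5) {
  rows <- lapply(table_cases(a), function(cs) {
    dist <- if (cs$case == "exp_decreasing") {
      reputation_distribution(cs$case, a = cs$a)
    } else {
      reputation_distribution(cs$case)
    }
    do.call(rbind, lapply(n_values, function(n) {
      s <- society_summary(ipd_model(dist, n, payoffs))
      data.frame(label = cs$label, case = cs$case, n = as.integer(n),
                 mean = s$expected_income, dispersion = s$dispersion,
                 mean_2dp = round(s$expected_income, 2),
                 dispersion_2dp = round(s$dispersion, 2),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expected-income curves for figure reproduction
#'
#' Evaluates the analytic income curve of one built-in density for a set
#' of candidate-group sizes on a shared reputation grid, in long format
#' ready for CSV export and replotting.
#'
#' @param case A built-in case name (see [builtin_cases()]).
#' @param n_values Candidate-group sizes, nonempty integer vector.
#' @param grid_size Grid points on \eqn{[0,1]} (default 1001).
#' @param payoffs A [pd_payoffs()] object.
#' @param a Slope of the exponential decreasing density.
#' @return A data frame with columns `case`, `n`, `q`, `income`.
#' @export
curve_report <- function(case, n_values, grid_size = 1001L,
                         payoffs = pd_payoffs(), a = 5) {
  case <- match.arg(case, builtin_cases())
  if (length(n_values) < 1L) stop("'n_values' must be nonempty", call. = FALSE)
  dist <- if (case == "exp_decreasing") {
    reputation_distribution(case, a = a)
  } else {
    reputation_distribution(case)
  }
  out <- do.call(rbind, lapply(n_values, function(n) {
    cur <- income_curve(ipd_model(dist, n, payoffs), grid_size)
    data.frame(case = case, n = as.integer(n), q = cur$q,
               income = cur$income, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare a simulation against the analytic income curve
#'
#' Runs (or accepts) an agent-based simulation, bins agents by
#' reputation, and compares per-bin mean rescaled income against the
#' analytic expectation. The analytic reference of each bin is the mean
#' of \eqn{I(q_i)} over the agents actually in the bin, so no midpoint
#' bias enters. Reports a z-score per occupied bin and an overall pass
#' flag at the 3-standard-error level.
#'
#' @param model An [ipd_model()].
#' @param sim An existing `"ipd_sim"` object, or `NULL` to simulate here.
#' @param agents,iterations,seed Simulation settings used when `sim` is
#'   `NULL`.
#' @param bins Number of reputation bins (default 20).
#' @param z_limit Per-bin pass threshold in standard errors (default 3).
#' @param pass_fraction Required fraction of occupied bins within
#'   `z_limit` (default 0.95).
#' @return A data frame with per-bin columns `q_mid`, `count`,
#'   `analytic`, `empirical`, `se`, `z`, `pass`; attributes
#'   `"pass_rate"` and `"pass"` summarize the check.
#' @export
compare_report <- function(model, sim = NULL, agents = 10000L,
                           iterations = agents, seed = NULL, bins = 20L,
                           z_limit = 3, pass_fraction = 0.95) {
  stopifnot(inherits(model, "ipd_model"))
  if (is.null(sim)) {
    sim <- simulate(model, seed = seed, agents = agents,
                    iterations = iterations)
  }
  stopifnot(inherits(sim, "ipd_sim"))
  bc <- binned_income_curve(sim, bins)
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- findInterval(sim$reputations, breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
  ana <- rep(NA_real_, bins)
  Iq <- total_income(sim$reputations, model)
  agg <- rowsum(Iq, bin)
  ids <- as.integer(rownames(agg))
  ana[ids] <- agg / bc$count[ids]
  z <- (bc$income - ana) / bc$se
  occupied <- bc$count >= 2L
  pass_bin <- abs(z) < z_limit
  out <- data.frame(q_mid = bc$q_mid, count = bc$count, analytic = ana,
                    empirical = bc$income, se = bc$se, z = z,
                    pass = pass_bin)
  rate <- mean(pass_bin[occupied])
  attr(out, "pass_rate") <- rate
  attr(out, "pass") <- is.finite(rate) && rate >= pass_fraction
  out
}

#' Write and read a JSON run manifest
#'
#' Serializes a configuration (any named list of scalars and simple
#' vectors, e.g. the full parameter set plus seed of a run) to JSON, and
#' reads it back so that every reported number is regenerable from the
#' manifest alone. Round-trips exactly for flat configurations.
#'
#' @param config Named list.
#' @param path File path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the configuration list.
#' @export
write_manifest <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
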