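#' Prisoner's Dilemma payoff matrix
#'
#' The four payoffs of the one-shot Prisoner's Dilemma: temptation `T`
#' (defect against a cooperator), reward `R` (mutual cooperation),
#' punishment `P` (mutual defection) and sucker `S` (cooperate against a
#' defector). By default the strict PD orderings \eqn{T > R > P > S} and
#' \eqn{2R > T + S} are enforced; set `strict = FALSE` to allow other
#' dilemma matrices (e.g. Snowdrift or Stag Hunt orderings) without
#' mislabeling them as PD.
#'
#' @param T,R,P,S Payoffs; defaults are the standard 5, 3, 1, 0.
#' @param strict Validate the PD inequalities (default `TRUE`).
#' @return An object of class `"pd_payoffs"`.
#' @examples
#' pd_payoffs()            # the canonical 5, 3, 1, 0 matrix
#' pd_payoffs(3, 2, 1, 0)  # another strict PD
#' @export
pd_payoffs <- function(T = 5, R = 3, P = 1, S = 0, strict = TRUE) {
  vals <- c(T = T, R = R, P = P, S = S)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals))) {
    stop("payoffs T, R, P, S must be finite numbers", call. = FALSE)
  }
  if (strict) {
    if (!(T > R && R > P && P > S)) {
      stop("strict PD requires T > R > P > S; use strict = FALSE for other orderings",
           call. = FALSE)
    }
    if (!(2 * R > T + S)) {
      stop("strict PD requires 2R > T + S; use strict = FALSE for other orderings",
           call. = FALSE)
    }
  }
  structure(list(T = T, R = R, P = P, S = S, strict = strict),
            class = "pd_payoffs")
}

#' @export
print.pd_payoffs <- function(x, ...) {
  cat("Prisoner's Dilemma payoffs",
      if (!x$strict) "(strict ordering not enforced)", "\n")
  m <- matrix(c(x$R, x$S, x$T, x$P), 2, byrow = TRUE,
              dimnames = list(c("C", "D"), c("C", "D")))
  print(m)
  invisible(x)
}

#' Expected one-shot payoff between two reputation-parameterized agents
#'
#' Each agent cooperates independently with probability equal to its own
#' reputation, so the first player's expected payoff is the bilinear form
#' \deqn{G_1(q_1, q_2) = q_1[q_2 R + (1-q_2) S] + (1-q_1)[q_2 T + (1-q_2) P].}
#' The second player's expectation is \eqn{G_2(q_1,q_2) = G_1(q_2,q_1)}.
#'
#' @param q1,q2 Reputations (cooperation probabilities) in \eqn{[0,1]};
#'   vectorized, recycled to a common length.
#' @param payoffs A [pd_payoffs()] object.
#' @return Expected payoff of player 1, bounded by the payoff range.
#' @examples
#' expected_game_payoff(0, 1, pd_payoffs())   # defector meets cooperator: T = 5
#' expected_game_payoff(0.5, 0.5, pd_payoffs()) # 2.25
#' @export
expected_game_payoff <- function(q1, q2, payoffs = pd_payoffs()) {
  stopifnot(inherits(payoffs, "pd_payoffs"))
  check_reputation(q1)
  check_reputation(q2)
  q1 * (q2 * payoffs$R + (1 - q2) * payoffs$S) +
    (1 - q1) * (q2 * payoffs$T + (1 - q2) * payoffs$P)
}

check_reputation <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0 | q > 1)) {
    stop("reputations must lie in [0, 1]", call. = FALSE)
  }
  invisible(q)
}

#' Realized payoffs of a single game
#'
#' Maps a pair of played actions onto the payoff pair of the matrix:
#' (C,C) gives (R,R), (D,D) gives (P,P), (C,D) gives (S,T) and (D,C)
#' gives (T,S).
#'
#' @param action1,action2 `"C"` (cooperate) or `"D"` (defect).
#' @param payoffs A [pd_payoffs()] object.
#' @return Named numeric vector `c(first = ..., second = ...)`.
#' @examples
#' realized_payoffs("C", "D") # sucker vs temptation: c(0, 5)
#' @export
realized_payoffs <- function(action1, action2, payoffs = pd_payoffs()) {
  stopifnot(inherits(payoffs, "pd_payoffs"))
  if (!action1 %in% c("C", "D") || !action2 %in% c("C", "D")) {
    stop("actions must be \"C\" or \"D\"", call. = FALSE)
  }
  first <- if (action1 == "C") {
    if (action2 == "C") payoffs$R else payoffs$S
  } else {
    if (action2 == "C") payoffs$T else payoffs$P
  }
  second <- if (action2 == "C") {
    if (action1 == "C") payoffs$R else payoffs$S
  } else {
    if (action1 == "C") payoffs$T else payoffs$P
  }
  c(first = first, second = second)
}
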