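# state space for up to three drugs bound to one ribosome: subsets of
# {A, B, C}, encoded as bit masks 0..7
triple_states <- function() 0:7

#' Three-drug relative growth in the slow-growth limit
#'
#' Solves the linear steady-state balance over the ribosome occupancy
#' states (unbound, three single-bound, three double-bound, triple-bound)
#' under the slow-growth assumptions: growth proportional to unblocked
#' ribosomes, near-zero dilution, intracellular drug set by transport
#' (\eqn{a_i = a_{ex,i} p_{in,i}/p_{out,i}}), independent first-order
#' binding with odds \eqn{c_i'} per drug.  Pairs listed in
#' `competitive_pairs` cannot co-occupy a ribosome; the corresponding
#' states are removed from the diagram.  With no competition the solution
#' is the product form
#' \eqn{y = (\lambda_{max}/\lambda_0)/[(1+c_A')(1+c_B')(1+c_C')]}; with
#' exactly BC competitive it is
#' \eqn{(\lambda_{max}/\lambda_0)/[(1+c_A')(1+c_B'+c_C')]}.
#'
#' @param c_prime length-3 vector of rescaled concentrations
#'   `(c_A', c_B', c_C')`, all >= 0.
#' @param competitive_pairs character vector, subset of
#'   `c("AB", "AC", "BC")`.
#' @param laws a [growth_laws()] object.
#' @return Relative growth `y` (carries the
#'   \eqn{\lambda_{max}/\lambda_0} prefactor of the slow-growth limit).
#' @examples
#' laws <- growth_laws(lambda0 = growth_laws()$lambda_max)  # prefactor 1
#' triple_slow_growth(c(1, 1, 1), character(), laws)        # 1/8
#' @export
triple_slow_growth <- function(c_prime, competitive_pairs = character(),
                               laws = growth_laws()) {
  stopifnot(length(c_prime) == 3, all(c_prime >= 0),
            all(competitive_pairs %in% c("AB", "AC", "BC")))
  pair_mask <- c(AB = 3L, AC = 5L, BC = 6L)
  forbidden_mask <- pair_mask[competitive_pairs]
  states <- triple_states()
  allowed <- vapply(states, function(s)
    !any(bitwAnd(s, forbidden_mask) == forbidden_mask), logical(1))
  states <- states[allowed]
  n <- length(states)
  idx <- stats::setNames(seq_len(n), states)
  # master-equation rate matrix: binding of drug i at rate c_prime[i],
  # unbinding at unit rate (only ratios matter in steady state)
  Q <- matrix(0, n, n)
  for (si in seq_len(n)) {
    s <- states[si]
    for (d in 1:3) {
      bit <- bitwShiftL(1L, d - 1L)
      if (bitwAnd(s, bit) == 0) {
        s2 <- bitwOr(s, bit)
        if (as.character(s2) %in% names(idx)) {
          Q[idx[[as.character(s2)]], si] <- Q[idx[[as.character(s2)]], si] +
            c_prime[d]
          Q[si, si] <- Q[si, si] - c_prime[d]
        }
      } else {
        s2 <- bitwAnd(s, bitwNot(bit))
        Q[idx[[as.character(s2)]], si] <- Q[idx[[as.character(s2)]], si] + 1
        Q[si, si] <- Q[si, si] - 1
      }
    }
  }
  # steady state: Q pi = 0 with sum(pi) = 1
  A <- rbind(Q, rep(1, n))
  b <- c(rep(0, n), 1)
  pi_ss <- qr.solve(A, b)
  (laws$lambda_max / laws$lambda0) * pi_ss[idx[["0"]]]
}

#' Mechanism-independent maximum-entropy prediction for a drug triple
#'
#' The pairwise-interaction formula
#' \deqn{y_{ABC} = y_A y_{BC} + y_B y_{AC} + y_C y_{AB} - 2 y_A y_B y_C,}
#' which predicts the triple response from single-drug and pairwise
#' responses alone.  Symmetric under drug permutation.
#'
#' @param y_A,y_B,y_C single-drug relative responses in `[0, 1]`.
#' @param y_AB,y_AC,y_BC pairwise relative responses in `[0, 1]`.
#' @return Predicted triple response `y_ABC`.
#' @export
maxent_triple <- function(y_A, y_B, y_C, y_AB, y_AC, y_BC) {
  vals <- c(y_A, y_B, y_C, y_AB, y_AC, y_BC)
  stopifnot(all(vals >= 0), all(vals <= 1))
  y_A * y_BC + y_B * y_AC + y_C * y_AB - 2 * y_A * y_B * y_C
}

#' Consistency of the occupancy-diagram model with the maxent formula
#'
#' For each sampled concentration triple, computes the single and pairwise
#' marginals of the slow-growth occupancy model (by zeroing the other
#' concentrations), feeds them through [maxent_triple()], and compares with
#' the model's own triple response.  Marginals and responses are
#' normalised by the drug-free value so they are genuine relative growths.
#'
#' @param c_prime_samples numeric matrix with 3 columns (one row per
#'   sampled `c'` triple), or a single length-3 vector.
#' @param competitive_pairs as in [triple_slow_growth()].
#' @param laws a [growth_laws()] object.
#' @return List with `max_abs_deviation` and the per-sample deviations.
#' @export
consistency_report <- function(c_prime_samples,
                               competitive_pairs = character(),
                               laws = growth_laws()) {
  if (is.null(dim(c_prime_samples)))
    c_prime_samples <- matrix(c_prime_samples, nrow = 1)
  stopifnot(ncol(c_prime_samples) == 3, nrow(c_prime_samples) >= 1)
  k <- laws$lambda_max / laws$lambda0
  yfun <- function(cp) triple_slow_growth(cp, competitive_pairs, laws) / k
  dev <- apply(c_prime_samples, 1, function(cp) {
    y1 <- c(yfun(c(cp[1], 0, 0)), yfun(c(0, cp[2], 0)), yfun(c(0, 0, cp[3])))
    yAB <- yfun(c(cp[1], cp[2], 0))
    yAC <- yfun(c(cp[1], 0, cp[3]))
    yBC <- yfun(c(0, cp[2], cp[3]))
    abs(maxent_triple(y1[1], y1[2], y1[3], yAB, yAC, yBC) - yfun(cp))
  })
  list(max_abs_deviation = max(dev), deviations = dev)
}
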