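# Exact conditional contingency-table tests (fixed margins). The two-sided
# p-value follows the probability-mass rule: the sum of probabilities of
# all tables with the observed margins whose probability does not exceed
# that of the observed table (with a small relative slack for ties).

TIE_SLACK <- 1e-7

check_table <- function(tab, min_dim = 2L) {
  if (!is.matrix(tab) || !is.numeric(tab))
    vs_validation("table must be a numeric matrix")
  if (nrow(tab) < min_dim || ncol(tab) < 2L)
    vs_validation(sprintf("table must be at least %d x 2", min_dim))
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab)))
    vs_validation("table cells must be non-negative integers")
  if (sum(tab) == 0) vs_validation("table must have a positive total")
  storage.mode(tab) <- "double"
  tab
}

#' Exact conditional test for a 2x2 table
#'
#' Two-sided Fisher exact test: conditional on both margins, the p-value
#' is the sum of hypergeometric probabilities of all tables whose
#' probability is no greater than the observed table's (ties included with
#' a `1e-7` relative slack).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2, 2))   # 1.0
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_table(tab)
  if (!all(dim(tab) == 2L)) vs_validation("table must be 2 x 2")
  m <- sum(tab[1, ])                 # row-1 margin
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])                 # column-1 margin
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, k, sum(tab) - k, m)
  p_obs <- stats::dhyper(tab[1, 1], k, sum(tab) - k, m)
  min(1, sum(probs[probs <= p_obs * (1 + TIE_SLACK)]))
}

# log multivariate hypergeometric probability of a table with fixed margins
log_table_prob <- function(tab, lg_const) {
  lg_const - sum(lgamma(tab + 1))
}

# Enumerate all r x c tables with the given margins, calling fun(tab) on
# each. Cells are filled row-major; the last column/row are forced.
enumerate_tables <- function(row_sums, col_sums, fun, budget) {
  r <- length(row_sums); c <- length(col_sums)
  tab <- matrix(0, r, c)
  count <- 0L
  rec <- function(i, j, row_rem, col_rem) {
    if (i == r) {
      # last row forced
      if (any(col_rem < 0)) return()
      tab[r, ] <<- col_rem
      count <<- count + 1L
      if (count > budget)
        vs_budget(sprintf(
          "enumeration exceeded budget of %d tables; use monte_carlo = TRUE",
          budget))
      fun(tab)
      return()
    }
    if (j == c) {
      # last cell of row i forced
      v <- row_rem
      if (v < 0 || v > col_rem[c]) return()
      tab[i, c] <<- v
      col2 <- col_rem; col2[c] <- col2[c] - v
      rec(i + 1L, 1L, row_sums[i + 1L], col2)
      return()
    }
    for (v in 0:min(row_rem, col_rem[j])) {
      tab[i, j] <<- v
      col2 <- col_rem; col2[j] <- col2[j] - v
      rec(i, j + 1L, row_rem - v, col2)
    }
  }
  rec(1L, 1L, row_sums[1L], col_sums)
  invisible(count)
}

#' Exact conditional test for an r x c table
#'
#' Generalizes [fisher_exact_2x2()]: all tables sharing the observed
#' margins are enumerated under the multivariate hypergeometric
#' distribution and the probabilities of tables no more probable than the
#' observed one are summed. When the enumeration would exceed `budget`
#' tables, an error suggests the seeded Monte Carlo fallback
#' (`monte_carlo = TRUE`), which samples tables with the observed margins
#' via Patefield's algorithm.
#'
#' @param tab r x c matrix of non-negative integer counts (r, c >= 2).
#' @param budget Maximum number of tables to enumerate.
#' @param monte_carlo Use Monte Carlo estimation instead of enumeration.
#' @param n_sim Number of Monte Carlo tables.
#' @param seed Seed for the Monte Carlo fallback.
#' @return The two-sided p-value.
#' @export
fisher_exact_rxc <- function(tab, budget = 1e6, monte_carlo = FALSE,
                             n_sim = 1e5, seed = 1L) {
  tab <- check_table(tab)
  row_sums <- rowSums(tab); col_sums <- colSums(tab)
  n <- sum(tab)
  lg_const <- sum(lgamma(row_sums + 1)) + sum(lgamma(col_sums + 1)) -
    lgamma(n + 1)
  lp_obs <- log_table_prob(tab, lg_const)
  cut <- lp_obs + log1p(TIE_SLACK)

  if (monte_carlo) {
    set.seed(seed)
    sims <- stats::r2dtable(n_sim, row_sums, col_sums)
    lps <- vapply(sims, log_table_prob, numeric(1), lg_const = lg_const)
    return(mean(lps <= cut))
  }

  p <- 0
  total <- 0
  enumerate_tables(row_sums, col_sums, function(t2) {
    lp <- log_table_prob(t2, lg_const)
    pr <- exp(lp)
    total <<- total + pr
    if (lp <= cut) p <<- p + pr
  }, budget)
  # normalize against accumulated mass to absorb rounding in the tail
  min(1, p / total)
}
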