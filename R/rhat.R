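# Split-R-hat convergence diagnostic.

#' Split-R-hat of a set of MCMC chains
#'
#' Each chain is split in half (doubling the number of chains) and the
#' classic potential-scale-reduction factor is computed from the between- and
#' within-chain variances of the split chains:
#' `sqrt(((n - 1)/n * W + B/n) / W)`. Optional rank-normalization (off by
#' default) replaces the draws by normal scores before the computation,
#' making the diagnostic robust to heavy tails.
#'
#' @param draws Iterations x chains numeric matrix (>= 2 chains, >= 4
#'   iterations each).
#' @param rank_normalize Apply rank-normalization first.
#' @return Scalar R-hat (>= 1 up to Monte-Carlo error for mixed chains);
#'   `NA_real_` with a warning when the within-chain variance is zero.
#' @export
compute_rhat <- function(draws, rank_normalize = FALSE) {
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) >= 2, nrow(draws) >= 4)
  if (rank_normalize) {
    r <- rank(draws, ties.method = "average")
    draws <- matrix(stats::qnorm((r - 3 / 8) / (length(draws) + 1 / 4)),
                    nrow(draws), ncol(draws))
  }
  h <- floor(nrow(draws) / 2)
  n <- nrow(draws)
  sub <- cbind(draws[seq_len(h), , drop = FALSE],
               draws[(n - h + 1):n, , drop = FALSE])
  m <- ncol(sub); nn <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  if (W == 0) {
    warning("zero within-chain variance: R-hat undefined")
    return(NA_real_)
  }
  B <- nn * stats::var(mu)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}
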