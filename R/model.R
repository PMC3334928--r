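# GTR+gamma+I substitution model: construction, eigendecomposition,
# transition probabilities and the rate-category mixture.

#' GTR+gamma+I substitution model
#'
#' @param rates six positive exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT (normalized so GT = 1 internally).
#' @param base_freq four stationary base frequencies (A, C, G, T), sum 1.
#' @param alpha shape of the discrete gamma distribution of site rates;
#'   `Inf` means equal rates.
#' @param p_inv proportion of invariant sites in `[0, 0.95]`.
#' @param k number of gamma categories (category means; default 4).
#' @param rate partition-specific rate multiplier (relative rate of this
#'   partition when several partitions share branch lengths).
#' @return A list of class `subst_model`.
#' @export
subst_model <- function(rates = rep(1, 6), base_freq = rep(0.25, 4),
                        alpha = Inf, p_inv = 0, k = 4L, rate = 1) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(base_freq) == 4L, all(base_freq > 0),
            alpha > 0, p_inv >= 0, p_inv < 1, k >= 1L, rate > 0)
  if (abs(sum(base_freq) - 1) > 1e-9) stop("base_freq must sum to 1")
  structure(list(rates = rates / rates[6], base_freq = base_freq,
                 alpha = alpha, p_inv = p_inv, k = as.integer(k),
                 rate = rate),
            class = "subst_model")
}

#' Jukes-Cantor-like special case
#' @param ... passed to [subst_model()].
#' @return A `subst_model` with equal rates and frequencies.
#' @export
jc_model <- function(...) subst_model(rates = rep(1, 6),
                                      base_freq = rep(0.25, 4), ...)

#' Discrete gamma rate categories (category means)
#'
#' Splits the Gamma(shape, rate = shape) distribution (mean 1) into `k`
#' equal-probability slices and uses the conditional mean of each slice as
#' its representative rate.
#'
#' @param shape gamma shape; `Inf` returns all-1 rates.
#' @param k number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (!is.finite(shape)) return(rep(1, k))
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = shape, rate = shape)
  p <- c(0, stats::pgamma(q, shape = shape + 1, rate = shape), 1)
  k * diff(p)
}

#' Rate mixture of a GTR+gamma+I model
#'
#' The invariant-site class is an extra zero-rate category with weight
#' `p_inv`; gamma rates are rescaled by `1/(1 - p_inv)` so the mixture mean
#' stays 1, and the whole mixture is multiplied by the partition `rate`.
#'
#' @param model a [subst_model()].
#' @return List with `rates` and `weights` of equal length.
#' @export
gamma_invariant_mixture <- function(model) {
  g <- discrete_gamma_rates(model$alpha, model$k)
  if (model$p_inv > 0) {
    list(rates = c(0, g / (1 - model$p_inv)) * model$rate,
         weights = c(model$p_inv, rep((1 - model$p_inv) / model$k, model$k)))
  } else {
    list(rates = g * model$rate, weights = rep(1 / model$k, model$k))
  }
}

#' Eigendecomposition of the normalized GTR rate matrix
#'
#' Builds Q with `q_ij = s_ij pi_j`, rows summing to zero, scaled so the
#' mean substitution rate is 1, and decomposes it via the symmetrized form
#' (numerically stable for a reversible chain).
#'
#' @param model a [subst_model()].
#' @return List with `U`, `Uinv`, `lambda` such that
#'   `Q = U diag(lambda) Uinv`, plus `pi`.
#' @export
gtr_eigen <- function(model) {
  pi <- model$base_freq
  s <- model$rates
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- s[1] * pi[2]; Q[1, 3] <- s[2] * pi[3]; Q[1, 4] <- s[3] * pi[4]
  Q[2, 1] <- s[1] * pi[1]; Q[2, 3] <- s[4] * pi[3]; Q[2, 4] <- s[5] * pi[4]
  Q[3, 1] <- s[2] * pi[1]; Q[3, 2] <- s[4] * pi[2]; Q[3, 4] <- s[6] * pi[4]
  Q[4, 1] <- s[3] * pi[1]; Q[4, 2] <- s[5] * pi[2]; Q[4, 3] <- s[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / d) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(d)
  list(U = U, Uinv = Uinv, lambda = e$values, pi = pi)
}

#' Transition probability matrix P(t)
#'
#' @param eig result of [gtr_eigen()].
#' @param t branch length times rate (expected substitutions per site).
#' @return 4x4 matrix with rows summing to 1.
#' @export
pmat <- function(eig, t) {
  P <- eig$U %*% (exp(eig$lambda * t) * eig$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}
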