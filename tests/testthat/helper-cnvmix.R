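# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written from first principles (explicit sums, factorials,
# Bayes' rule) so they stay independent of the implementation they check.

default_params <- function(lambda = 10,
                           alpha = c(.02, .02, .90, .02, .02, .02),
                           beta = c(0, .5, 1, 1, 1, 1),
                           epsilon = 0.01, max_copy = 5L) {
  mixture_params(alpha, beta, lambda, cnv_states(max_copy, epsilon))
}

# Poisson pmf via explicit log-factorial summation (independent of dpois)
oracle_pois <- function(f, rate) {
  lfact <- if (f > 0) sum(log(seq_len(f))) else 0
  exp(-rate + f * log(rate) - lfact)
}

# Binomial pmf by direct enumeration of the coefficient
oracle_binom <- function(n1, n2, p) {
  choose(n1 + n2, n1) * p^n1 * (1 - p)^n2
}

# Eq.-by-eq brute-force mixture density: explicit double loop, closed forms
oracle_mixture <- function(f, n1, n2, params) {
  st <- params$states
  tot <- 0
  for (i in st$states) {
    th <- if (i == 0) st$epsilon else i / 2
    po <- oracle_pois(f, th * params$lambda)
    bi <- exp(lgamma(n1 + n2 + 1) - lgamma(n1 + 1) - lgamma(n2 + 1)) *
      params$beta[i + 1]^n1 * (1 - params$beta[i + 1])^n2
    if (n1 + n2 == 0) bi <- 1
    tot <- tot + params$alpha[i + 1] * po * bi
  }
  tot
}

# Bayes-rule responsibilities for one sample, term by term
oracle_responsibilities <- function(f, n1, n2, params) {
  st <- params$states
  beta <- pmin(pmax(params$beta, 1e-6), 1 - 1e-6)
  num <- sapply(st$states, function(i) {
    th <- if (i == 0) st$epsilon else i / 2
    params$alpha[i + 1] * oracle_pois(f, th * params$lambda) *
      exp(lgamma(n1 + n2 + 1) - lgamma(n1 + 1) - lgamma(n2 + 1) +
            n1 * log(beta[i + 1]) + n2 * log(1 - beta[i + 1]))
  })
  num / sum(num)
}

# small simulated segment: k samples with given true states
make_segment <- function(k, states_true, lambda_true = 30, eta = 10,
                         mu = 500, sigma = 50, shift = 2000,
                         epsilon = 0.01) {
  beta_star <- c(0, 0.5, 1, 1, 1, 1)
  theta <- c(epsilon, (1:5) / 2)
  obs <- vector("list", k)
  for (j in seq_len(k)) {
    i <- states_true[j]
    f <- rpois(1, theta[i + 1] * lambda_true)
    n <- rpois(1, eta)
    n1 <- rbinom(1, n, beta_star[i + 1])
    sizes <- c(rnorm(n1, mu, sigma), rnorm(n - n1, mu + shift, sigma))
    obs[[j]] <- segment_observation(f, pmax(sizes, 0), sample = j, segment = 1L)
  }
  obs
}

test_library <- function(mu = 500, sigma = 50) insert_library(mu, sigma)

flat_priors <- function(max_copy = 5L)
  cnv_priors(max_copy, gamma = rep(1, max_copy + 1),
             nu1 = rep(1, max_copy + 1), nu2 = rep(1, max_copy + 1))
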