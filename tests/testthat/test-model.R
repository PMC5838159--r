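# Probability model: emission terms, mixture density, priors.

test_that("poisson emission matches closed-form values and the log-factorial oracle", {
  p <- default_params(lambda = 2)
  expect_equal(poisson_emission(0, 2, p), exp(-2), tolerance = 1e-12)

  p3 <- default_params(lambda = 3)
  expect_equal(poisson_emission(3, 2, p3), oracle_pois(3, 3), tolerance = 1e-12)
  expect_equal(round(poisson_emission(3, 2, p3), 5), 0.22404)

  p2 <- default_params(lambda = 2)
  expect_equal(poisson_emission(4, 4, p2), oracle_pois(4, 4), tolerance = 1e-12)
  expect_equal(round(poisson_emission(4, 4, p2), 5), 0.19537)

  # state 0 uses the leakage rate epsilon * lambda, not epsilon * lambda^2
  expect_equal(poisson_emission(0, 0, p2), exp(-0.01 * 2), tolerance = 1e-12)

  expect_error(poisson_emission(-1, 2, p2), "non-negative")
  expect_error(poisson_emission(2, 7, p2), "one of")
})

test_that("poisson emission is a proper pmf over read counts", {
  p <- default_params(lambda = 17)
  for (i in 0:5)
    expect_equal(sum(poisson_emission(0:500, i, p)), 1, tolerance = 1e-6)
})

test_that("binomial insert term matches enumeration and handles edge cases", {
  expect_equal(binomial_insert_term(5, 0, 1), 1)
  expect_equal(binomial_insert_term(1, 1, 0.5), 0.5)
  expect_equal(binomial_insert_term(3, 2, 0.7), oracle_binom(3, 2, 0.7),
               tolerance = 1e-12)
  expect_equal(binomial_insert_term(3, 2, 0.7), 0.3087, tolerance = 1e-10)
  expect_equal(binomial_insert_term(0, 0, 0.3), 1)   # no spanning pairs
  expect_equal(binomial_insert_term(2, 0, 0), 0)     # impossible under beta=0
  expect_equal(binomial_insert_term(0, 3, 1), 0)
  expect_error(binomial_insert_term(1, 1, 1.2), "probability")
  expect_error(binomial_insert_term(-1, 1, 0.5), ">= 0")
})

test_that("binomial insert term sums to one over integer splits", {
  for (p in c(0.2, 0.5, 0.9)) for (n in c(1, 5, 17)) {
    tot <- sum(vapply(0:n, function(n1)
      binomial_insert_term(n1, n - n1, p), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("mixture density equals brute-force summation on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    a <- runif(6); a <- a / sum(a)
    p <- mixture_params(a, runif(6), runif(1, 1, 40), cnv_states())
    f <- rpois(1, 15)
    n <- rpois(1, 6)
    n1 <- runif(1, 0, n)  # expected counts may be non-integer
    got <- mixture_density(f, n1, n - n1, p)
    ref <- oracle_mixture(f, n1, n - n1, p)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("degenerate mixtures reduce to their single component", {
  p <- mixture_params(c(0, 0, 1, 0, 0, 0), c(0, .5, .8, 1, 1, 1), 12,
                      cnv_states())
  f <- 9; n1 <- 3; n2 <- 1
  expect_equal(mixture_density(f, n1, n2, p),
               poisson_emission(f, 2, p) * binomial_insert_term(n1, n2, 0.8),
               tolerance = 1e-12)
  # with no spanning pairs the density is Poisson-only
  pm <- default_params(lambda = 10)
  expect_equal(mixture_density(4, 0, 0, pm),
               sum(sapply(0:5, function(i)
                 pm$alpha[i + 1] * poisson_emission(4, i, pm))),
               tolerance = 1e-12)
})

test_that("log-space and linear-space evaluations agree", {
  set.seed(12)
  for (rep in 1:25) {
    a <- runif(6); a <- a / sum(a)
    p <- mixture_params(a, runif(6), runif(1, 1, 50), cnv_states())
    f <- rpois(1, 20); n <- rpois(1, 8); n1 <- runif(1, 0, n)
    lin <- mixture_density(f, n1, n - n1, p)
    if (lin > 1e-300)
      expect_equal(exp(mixture_density(f, n1, n - n1, p, log = TRUE)), lin,
                   tolerance = 1e-8)
  }
})

test_that("log prior density follows the Dirichlet/Beta/uniform forms", {
  p <- default_params(lambda = 10)
  expect_equal(log_prior_density(p, flat_priors()), 0)

  pri <- cnv_priors(gamma = c(2, 2, 100, 2, 2, 2), nu1 = rep(1, 6),
                    nu2 = rep(1, 6))
  expect_equal(log_prior_density(p, pri),
               sum((c(2, 2, 100, 2, 2, 2) - 1) * log(p$alpha)),
               tolerance = 1e-12)

  # beta_i = 0 with nu_i1 = 1: 0 * log(0) convention gives 0, not NaN
  pz <- mixture_params(p$alpha, c(0, .5, 1, 1, 1, 1), 10, cnv_states())
  expect_true(is.finite(log_prior_density(pz, flat_priors())))

  # lambda outside its uniform support
  big <- mixture_params(p$alpha, p$beta, 10, cnv_states())
  pri2 <- cnv_priors(lambda_upper = 5)
  expect_identical(log_prior_density(big, pri2), -Inf)

  # alpha_i = 0 with gamma_i > 1
  pa <- mixture_params(c(0, 0, 1, 0, 0, 0), p$beta, 10, cnv_states())
  expect_identical(log_prior_density(pa, cnv_priors()), -Inf)
})

test_that("parameter containers validate their invariants", {
  expect_error(cnv_states(1), ">= 2")
  expect_error(cnv_states(5, 0.7), "0, 0.5")
  expect_error(mixture_params(rep(0.2, 6), rep(0.5, 6), 10), "sum to 1")
  expect_error(mixture_params(c(.5, .5, 0, 0, 0, 0), rep(1.5, 6), 10), "beta")
  expect_error(mixture_params(c(.5, .5, 0, 0, 0, 0), rep(.5, 6), -1), "positive")
  expect_error(cnv_priors(gamma = c(0, 1, 1, 1, 1, 1)), "> 0")
  st <- cnv_states(5, 0.01)
  expect_identical(st$states, 0:5)
  expect_equal(st$theta, c(0.01, 0.5, 1, 1.5, 2, 2.5))
})
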