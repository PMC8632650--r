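# Independent oracles and fixture builders shared across test files.

# Poisson log-likelihood written independently of the package internals.
oracle_loglik <- function(theta, D, n, x) {
  mu <- n * (theta[1] + theta[2] * D + theta[3] * D^2)
  if (any(mu < 0) || any(mu == 0 & x > 0)) return(-Inf)
  ok <- mu > 0
  sum(dpois(x[ok], mu[ok], log = TRUE))
}

# Brute-force maximizer: coarse grid around a moment estimate, then
# repeated Nelder-Mead refinement (soft-penalised, scaled) with an
# L-BFGS-B polish inside the box. Knows nothing about the package's
# Fisher-scoring path.
oracle_fit_lq <- function(D, n, x) {
  # finite penalty keeps the simplex well-behaved near the boundary
  objective <- function(th) {
    pen <- sum(pmin(th, 0)^2) * 1e8
    ll <- oracle_loglik(pmax(th, 0), D, n, x)
    if (!is.finite(ll)) ll <- -1e12
    -(ll - pen)
  }
  y <- x / n
  V <- cbind(1, D, D^2)
  ls <- tryCatch(as.vector(solve(crossprod(V, V * n), crossprod(V, y * n))),
                 error = function(e) c(mean(y), mean(y), mean(y)))
  centers <- pmax(ls, 1e-4)
  grid <- expand.grid(C = centers[1] * c(0.25, 1, 4),
                      alpha = centers[2] * c(0.25, 1, 4),
                      beta = centers[3] * c(0.25, 1, 4))
  ll <- apply(grid, 1, function(th) -objective(as.numeric(th)))
  par <- as.numeric(grid[which.max(ll), ])
  for (r in 1:4) {
    opt <- optim(par, objective, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-15,
                                parscale = pmax(abs(par), 1e-3)))
    par <- opt$par
  }
  polish <- optim(pmax(par, 1e-12), objective, method = "L-BFGS-B",
                  lower = 0, upper = Inf,
                  control = list(maxit = 1000, factr = 10))
  if (polish$value < opt$value) par <- polish$par
  theta <- pmax(par, 0)
  list(theta = theta, loglik = oracle_loglik(theta, D, n, x))
}

# Random interior-optimum fixture: doses away from 0 and all counts
# positive, so the brute-force search is well-behaved.
random_fit_instance <- function() {
  k <- sample(3:5, 1)
  D <- sort(sample(seq(0.25, 4, by = 0.25), k))
  n <- sample(100:1000, k, replace = TRUE)
  theta <- c(runif(1, 0.01, 0.08), runif(1, 0.05, 0.3),
             runif(1, 0.02, 0.15))
  x <- rpois(k, n * (theta[1] + theta[2] * D + theta[3] * D^2))
  x <- pmax(x, 1L)
  list(D = D, n = n, x = x, theta = theta)
}

# Exact two-sided binomial p by full enumeration (minimum-likelihood
# rule), independent of stats::binom.test.
oracle_binom_two_sided <- function(x, size, p) {
  probs <- dbinom(0:size, size, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# A small hand-written tally row.
make_tally <- function(dic = 0, cring = 0, aring = 0, ace_4tel = 0,
                       ace_2tel = 0, ace_0tel = 0, teldel = 0,
                       n_cells = 100, dose_gy = 1, group_id = "g") {
  data.frame(group_id = group_id, dose_gy = dose_gy, n_cells = n_cells,
             dic = dic, cring = cring, aring = aring,
             ace_4tel = ace_4tel, ace_2tel = ace_2tel,
             ace_0tel = ace_0tel, teldel = teldel,
             stringsAsFactors = FALSE)
}

# A small hand-written per-metaphase record.
make_record <- function(centromere_count = 46, dose_gy = 1,
                        group_id = "g", donor_id = "d1", dic = 0,
                        cring = 0, aring = 0, ace_4tel = 0, ace_2tel = 0,
                        ace_0tel = 0, teldel = 0) {
  data.frame(donor_id = donor_id, group_id = group_id, dose_gy = dose_gy,
             centromere_count = centromere_count, dic = dic,
             cring = cring, aring = aring, ace_4tel = ace_4tel,
             ace_2tel = ace_2tel, ace_0tel = ace_0tel, teldel = teldel,
             stringsAsFactors = FALSE)
}
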