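test_that("Hi-C signal is the off-diagonal row sum", {
  cm <- toy_cm(matrix(c(5, 3, 3, 7), 2, 2))
  expect_equal(hic_signal(cm), c(A = 3, B = 3))
  cm0 <- toy_cm(diag(c(4, 5, 6)))
  expect_equal(unname(hic_signal(cm0)), c(0, 0, 0))
  # 3-contig toy, brute-force row sums: (2+4, 2+1, 4+1)
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 2; m[1, 3] <- m[3, 1] <- 4; m[2, 3] <- m[3, 2] <- 1
  diag(m) <- c(5, 6, 7)
  expect_equal(unname(hic_signal(toy_cm(m))), c(6, 3, 5))
  expect_equal(unname(within_contacts(toy_cm(m))), c(5, 6, 7))
})

test_that("the NB regression recovers known coefficients and agrees with glm.nb", {
  skip_if_not_installed("MASS")
  cfg <- sim_config(n_genomes = 25L, contigs_per_genome = c(200L, 200L),
                    seed = 101L)
  catalog <- simulate_catalog(cfg)
  truth_beta <- c(1.0, 0.4, 0.6, 0.3)
  sig <- simulate_signal(catalog, beta = truth_beta, theta = 2, config = cfg)
  fit <- fit_normcc_glm(sig$s, sig$l, sig$N, sig$M)
  # slope coefficients are well identified at this n; the intercept is an
  # extrapolation with reference SE ~0.3 and is checked via glm.nb below
  expect_true(all(abs(fit$coefficients[2:4] - truth_beta[2:4]) < 0.1))
  expect_lt(abs(fit$theta - 2), 0.2)
  # independent ML cross-check
  ref <- MASS::glm.nb(M ~ log(s) + log(l) + log(N), data = sig)
  expect_true(all(abs(fit$coefficients - unname(stats::coef(ref))) < 1e-3))
  expect_lt(abs(fit$theta - ref$theta) / ref$theta, 0.01)
  # model invariants
  expect_equal(fit$c_hat, max(fit$mu_hat))
  expect_equal(fit$mu_hat,
               as.numeric(exp(fit$coefficients[1]) * sig$s^fit$coefficients[2] *
                            sig$l^fit$coefficients[3] * sig$N^fit$coefficients[4]),
               tolerance = 1e-10)
})

test_that("a degenerate constant design collapses to an intercept-only fit", {
  n <- 20
  fit <- fit_normcc_glm(s = rep(4, n), l = rep(1500, n), N = rep(7, n),
                        M = rep(12, n))
  expect_equal(unname(fit$coefficients[c("beta_s", "beta_l", "beta_N")]),
               c(0, 0, 0))
  expect_equal(unname(fit$coefficients["beta0"]), log(12), tolerance = 1e-6)
})

test_that("the returned estimate is a local ML optimum (perturbation probe)", {
  cfg <- sim_config(n_genomes = 2L, contigs_per_genome = c(10L, 10L),
                    seed = 33L)
  catalog <- simulate_catalog(cfg)
  sig <- simulate_signal(catalog, beta = c(0.5, 0.3, 0.5, 0.4), theta = 3,
                         config = cfg)
  fit <- fit_normcc_glm(sig$s, sig$l, sig$N, sig$M)
  ll <- function(beta, theta) {
    mu <- exp(beta[1] + beta[2] * log(sig$s) + beta[3] * log(sig$l) +
                beta[4] * log(sig$N))
    sum(stats::dnbinom(sig$M, size = theta, mu = mu, log = TRUE))
  }
  expect_equal(ll(fit$coefficients, fit$theta), fit$loglik, tolerance = 1e-8)
  set.seed(99)
  for (i in 1:100) {
    beta_p <- fit$coefficients + stats::rnorm(4, sd = 0.05)
    theta_p <- fit$theta * exp(stats::rnorm(1, sd = 0.05))
    expect_lte(ll(beta_p, theta_p), fit$loglik + 1e-9)
  }
})

test_that("normalization follows the geometric-mean rescaling formula", {
  m <- matrix(0, 2, 2); m[1, 2] <- m[2, 1] <- 10; diag(m) <- c(3, 4)
  cm <- toy_cm(m)
  # hand evaluation: 10 / sqrt(4 * 9) * 9 = 15
  nm <- normalize_contacts(cm, toy_model(c(4, 9)))
  expect_equal(as.numeric(nm$mat["A", "B"]), 15)
  expect_equal(as.numeric(Matrix::diag(nm$mat)), c(0, 0))
  expect_identical(nm$state, "normalized")
  # identity case: mu_i = mu_j = c_hat leaves the contact unchanged
  nm2 <- normalize_contacts(cm, toy_model(c(7, 7)))
  expect_equal(as.numeric(nm2$mat["A", "B"]), 10)
  # zeros stay zero
  m3 <- matrix(0, 3, 3); m3[1, 2] <- m3[2, 1] <- 2
  nm3 <- normalize_contacts(toy_cm(m3), toy_model(c(1, 2, 3)))
  expect_equal(as.numeric(nm3$mat["A", "C"]), 0)
  expect_error(normalize_contacts(cm, toy_model(c(-1, 2))), "positive")
})

test_that("normalization is equivariant to bias fully attributed to one contig", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 8; m[1, 3] <- m[3, 1] <- 6; m[2, 3] <- m[3, 2] <- 4
  mu <- c(2, 4, 8)
  base <- normalize_contacts(toy_cm(m), toy_model(mu))
  # multiply all contacts of contig A by 3 and attribute it to mu_A (x9)
  m2 <- m; m2[1, ] <- m[1, ] * 3; m2[, 1] <- m[, 1] * 3; m2[1, 1] <- 0
  mu2 <- mu; mu2[1] <- mu[1] * 9
  scaled <- normalize_contacts(toy_cm(m2), toy_model(mu2, c_hat = max(mu)))
  expect_equal(as.matrix(scaled$mat), as.matrix(base$mat), tolerance = 1e-12)
})

test_that("spurious removal discards exactly the lowest p percent", {
  # 15 contigs, 105 upper-triangle slots; 100 distinct values 1..100
  n <- 15
  m <- matrix(0, n, n)
  vals <- 1:100
  slots <- which(upper.tri(m))[seq_along(vals)]
  m[slots] <- vals
  m <- m + t(m)
  cm <- toy_cm(m, ids = sprintf("c%02d", 1:n), state = "normalized")
  dn <- remove_spurious(cm, spurious_removal_policy(5))
  left <- Matrix::mat2triplet(dn$mat)
  kept <- sort(unique(left$x))
  expect_identical(kept, as.numeric(6:100)) # exactly the 5 smallest removed
  expect_identical(dn$state, "denoised")
  # nonzero count after = ceil((1 - p/100) * before)
  expect_equal(sum(Matrix::triu(dn$mat) != 0), ceiling(0.95 * 100))
  # p -> 0+: only the single minimum is removed (<= t rule)
  dn0 <- remove_spurious(cm, spurious_removal_policy(1e-6))
  expect_equal(sum(Matrix::triu(dn0$mat) != 0), 99)
  expect_false(1 %in% Matrix::mat2triplet(dn0$mat)$x)
})

test_that("ties at the threshold are all removed", {
  # 10 values with ties: (1,1,1,2,3,4,5,6,7,8); p=20 -> t = 1 -> all three 1s go
  n <- 5
  m <- matrix(0, n, n)
  m[which(upper.tri(m))] <- c(1, 1, 1, 2, 3, 4, 5, 6, 7, 8)
  m <- m + t(m)
  cm <- toy_cm(m, ids = letters[1:n], state = "normalized")
  dn <- remove_spurious(cm, spurious_removal_policy(20))
  expect_equal(dn$threshold, 1)
  expect_equal(sum(Matrix::triu(dn$mat) != 0), 7)
  expect_false(any(Matrix::mat2triplet(dn$mat)$x <= 1))
  # removal never increases any entry
  expect_true(all(as.matrix(dn$mat) <= as.matrix(cm$mat)))
})

test_that("spurious removal requires nonzero contacts and a normalized matrix", {
  empty <- toy_cm(matrix(0, 2, 2), state = "normalized")
  expect_error(remove_spurious(empty), "nonzero")
  raw <- toy_cm(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(remove_spurious(raw), "normalized")
  expect_error(spurious_removal_policy(0), "between")
  expect_error(spurious_removal_policy(100), "between")
})

test_that("fitting demands filtered input", {
  catalog <- toy_catalog(sprintf("c%02d", 1:12))
  m <- diag(0, 12)
  m[1, 2] <- m[2, 1] <- 3
  cm <- toy_cm(m, ids = catalog$contig_id)
  expect_error(fit_normcc(catalog, cm), "filter")
  expect_error(fit_normcc_glm(1:5, 1:5, 1:5, 1:5), "at least 10")
})

test_that("model files round-trip through the key-value format", {
  cfg <- sim_config(n_genomes = 2L, contigs_per_genome = c(15L, 15L),
                    seed = 5L)
  catalog <- simulate_catalog(cfg)
  sig <- simulate_signal(catalog, beta = c(1, 0.3, 0.4, 0.5), theta = 2,
                         config = cfg)
  fit <- fit_normcc_glm(sig$s, sig$l, sig$N, sig$M)
  path <- tempfile()
  write_normcc_model(fit, path)
  back <- read_normcc_model(path)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_equal(back$c_hat, fit$c_hat, tolerance = 1e-12)
  mu <- predict_mu(back, catalog, sig$N)
  expect_equal(unname(mu), fit$mu_hat, tolerance = 1e-10)
})
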