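#' Negative-binomial regression core of the normalization model
#'
#' Fits, by maximum likelihood, the negative-binomial regression of the
#' across-contig Hi-C signal \eqn{M_i} on \eqn{\log s_i}, \eqn{\log l_i} and
#' \eqn{\log N_i} with a log link:
#' \deqn{M_i \sim \mathrm{NB}(\mu_i, \theta), \quad
#'   \log \mu_i = \beta_0 + \beta_s \log s_i + \beta_l \log l_i +
#'   \beta_N \log N_i,}
#' with variance \eqn{\mu + \mu^2/\theta}. The within-contig contact count
#' \eqn{N_i} stands in for the (unobserved) contig coverage: under a
#' companion negative-binomial model of \eqn{N_i} on sites, length and
#' coverage, the coverage term can be eliminated algebraically, and its
#' coefficients are absorbed into the \eqn{\beta} estimated here — so only
#' this regression is ever fitted.
#'
#' Estimation alternates iteratively reweighted least squares for the
#' coefficients at fixed \eqn{\theta} with a one-dimensional profile-likelihood
#' update of \eqn{\theta}, from a Poisson-regression initialisation, until the
#' relative log-likelihood change falls below `tol`. Predictors with zero
#' variance are dropped from the design and their coefficients reported as 0.
#'
#' @param s,l,N positive numeric vectors: restriction sites, length (bp) and
#'   within-contig contacts per contig.
#' @param M nonnegative numeric vector: across-contig Hi-C signal (response).
#' @param max_iter maximum outer iterations (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @return A list of class `NormCCModel`: `coefficients` (named
#'   `beta0, beta_s, beta_l, beta_N`), `theta`, `mu_hat`, `c_hat`
#'   (\eqn{\hat C = \max_k \hat\mu_k}), `loglik`, `iterations`, `converged`
#'   and the per-iteration `trace`.
#' @export
fit_normcc_glm <- function(s, l, N, M, max_iter = 100L, tol = 1e-8) {
  n <- length(M)
  if (length(s) != n || length(l) != n || length(N) != n) {
    stop("s, l, N and M must have equal length")
  }
  if (n < 10) stop("at least 10 contigs are required to fit the model")
  if (any(N < 1)) {
    stop("within-contig contacts N must be >= 1; apply contig filters ",
         "(min_within >= 1) before fitting")
  }
  if (any(s < 1) || any(l < 1)) stop("s and l must be >= 1 (log predictors)")
  X_full <- cbind(beta0 = 1, beta_s = log(s), beta_l = log(l), beta_N = log(N))
  active <- c(TRUE, apply(X_full[, -1, drop = FALSE], 2,
                          function(col) stats::var(col) > 0))
  X <- X_full[, active, drop = FALSE]

  nb_loglik <- function(mu, theta) sum(stats::dnbinom(M, size = theta, mu = mu,
                                                      log = TRUE))
  irls <- function(beta, theta) {
    for (it in seq_len(25L)) {
      eta <- drop(X %*% beta)
      mu <- pmax(exp(eta), 1e-10)
      w <- mu^2 / (mu + mu^2 / theta)
      z <- eta + (M - mu) / mu
      fit <- stats::lm.wfit(X, z, w)
      new_beta <- fit$coefficients
      if (anyNA(new_beta)) stop("singular design in the NB regression")
      if (max(abs(new_beta - beta)) < 1e-10) {
        beta <- new_beta
        break
      }
      beta <- new_beta
    }
    beta
  }

  # Poisson initialisation for the coefficients
  pois <- suppressWarnings(
    stats::glm.fit(X, M, family = stats::poisson(link = "log")))
  beta <- pois$coefficients
  mu <- pmax(exp(drop(X %*% beta)), 1e-10)
  # method-of-moments dispersion from the Poisson fit, floored at 0.01
  denom <- sum((M - mu)^2 - mu)
  theta <- if (denom > 0) max(sum(mu^2) / denom, 0.01) else 1e4

  ll <- nb_loglik(mu, theta)
  trace <- data.frame(iteration = 0L, theta = theta, loglik = ll)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    beta <- irls(beta, theta)
    mu <- pmax(exp(drop(X %*% beta)), 1e-10)
    opt <- stats::optimize(function(lt) nb_loglik(mu, exp(lt)),
                           interval = c(log(1e-4), log(1e6)),
                           maximum = TRUE, tol = 1e-10)
    theta <- exp(opt$maximum)
    new_ll <- nb_loglik(mu, theta)
    trace <- rbind(trace,
                   data.frame(iteration = iter, theta = theta, loglik = new_ll))
    if (abs(new_ll - ll) < tol * (abs(ll) + tol)) {
      ll <- new_ll
      converged <- TRUE
      break
    }
    ll <- new_ll
  }
  if (!converged) {
    stop("NB regression did not converge after ", max_iter,
         " iterations; last log-likelihoods: ",
         paste(sprintf("%.6f", utils::tail(trace$loglik, 5)), collapse = ", "))
  }
  coefs <- c(beta0 = 0, beta_s = 0, beta_l = 0, beta_N = 0)
  coefs[colnames(X)] <- beta
  mu_hat <- as.numeric(exp(drop(X_full %*% coefs)))
  structure(list(coefficients = coefs, theta = theta, mu_hat = mu_hat,
                 c_hat = max(mu_hat), loglik = ll, iterations = iter,
                 converged = converged, trace = trace),
            class = "NormCCModel")
}

#' Fit the normalization model on a catalog and raw contact matrix
#'
#' Extracts \eqn{s_i}, \eqn{l_i} from the catalog and \eqn{M_i}, \eqn{N_i}
#' from the raw contact matrix, then calls [fit_normcc_glm()]. The fitted
#' per-contig means \eqn{\hat\mu_i = e^{\hat\beta_0} s_i^{\hat\beta_s}
#' l_i^{\hat\beta_l} N_i^{\hat\beta_N}} quantify each contig's propensity to
#' generate proximity ligations attributable to the bias factors alone.
#'
#' @param catalog a `ContigCatalog` (already contig-filtered).
#' @param cm the matching raw `ContactMatrix`.
#' @param ... passed to [fit_normcc_glm()].
#' @return A `NormCCModel` with `mu_hat` named by contig id.
#' @export
fit_normcc <- function(catalog, cm, ...) {
  validate_catalog(catalog)
  if (!identical(catalog$contig_id, contact_ids(cm))) {
    stop("contact matrix is not aligned to the catalog")
  }
  if (cm$state != "raw") stop("the model is fitted on the raw contact matrix")
  model <- fit_normcc_glm(s = catalog$n_sites, l = catalog$length,
                          N = within_contacts(cm), M = hic_signal(cm), ...)
  names(model$mu_hat) <- catalog$contig_id
  model
}

#' @export
print.NormCCModel <- function(x, ...) {
  cat("NormCC negative-binomial normalization model\n")
  cat(sprintf("  coefficients: %s\n",
              paste(sprintf("%s=%.4f", names(x$coefficients), x$coefficients),
                    collapse = ", ")))
  cat(sprintf("  theta=%.4f  c_hat=%.4f  loglik=%.2f (%d iterations)\n",
              x$theta, x$c_hat, x$loglik, x$iterations))
  invisible(x)
}

#' Bias-correct a raw contact matrix
#'
#' Each across-contig contact is divided by the scaled geometric mean of the
#' fitted per-contig means and rescaled:
#' \deqn{H^{norm}_{ij} = \frac{H_{ij}}{\sqrt{\hat\mu_i \hat\mu_j}} \cdot
#'   \hat C, \quad \hat C = \max_k \hat\mu_k,}
#' so the residual signal reflects spatial proximity rather than the bias
#' factors. Within-contig counts are consumed by the model as a predictor and
#' the diagonal of the normalized matrix is set to zero.
#'
#' @param cm a raw `ContactMatrix`.
#' @param model a `NormCCModel` fitted on the same catalog.
#' @return A `ContactMatrix` in state `"normalized"`.
#' @export
normalize_contacts <- function(cm, model) {
  if (cm$state != "raw") stop("normalization expects a raw contact matrix")
  mu <- model$mu_hat
  if (length(mu) != nrow(cm$mat)) stop("model does not match the matrix size")
  if (any(mu <= 0)) stop("fitted means must be strictly positive")
  trip <- Matrix::mat2triplet(cm$mat)
  off <- trip$i != trip$j & trip$x != 0
  i <- trip$i[off]; j <- trip$j[off]
  x <- trip$x[off] / sqrt(mu[i] * mu[j]) * model$c_hat
  mat <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = dim(cm$mat),
                              dimnames = dimnames(cm$mat))
  contact_matrix(mat, state = "normalized")
}

#' Spurious-contact removal policy
#'
#' @param percentile_p percentile of nonzero normalized contacts to discard,
#'   strictly between 0 and 100 (default 5).
#' @return A list of class `SpuriousRemovalPolicy`.
#' @export
spurious_removal_policy <- function(percentile_p = 5) {
  if (!is.finite(percentile_p) || percentile_p <= 0 || percentile_p >= 100) {
    stop("percentile_p must lie strictly between 0 and 100")
  }
  structure(list(percentile_p = as.numeric(percentile_p)),
            class = "SpuriousRemovalPolicy")
}

#' Discard the weakest normalized contacts as spurious
#'
#' Proximity ligations within a species occur orders of magnitude more often
#' than ligations across species, so after bias correction the weakest
#' contacts are predominantly inter-species noise. The threshold `t` is the
#' `percentile_p`-th percentile (linear interpolation between order
#' statistics) of the *nonzero* off-diagonal values — structural zeros are
#' absence, not observations — and every entry with value <= `t` is set to
#' zero (ties at the threshold are discarded).
#'
#' @param cm a normalized `ContactMatrix`.
#' @param policy a `SpuriousRemovalPolicy` (default: discard the lowest 5%).
#' @return A `ContactMatrix` in state `"denoised"` with the threshold stored
#'   in `$threshold`.
#' @export
remove_spurious <- function(cm, policy = spurious_removal_policy()) {
  if (cm$state != "normalized") {
    stop("spurious removal expects a normalized contact matrix")
  }
  trip <- Matrix::mat2triplet(cm$mat)
  upper <- trip$i < trip$j & trip$x > 0
  vals <- trip$x[upper]
  if (length(vals) == 0) stop("no nonzero off-diagonal contacts to threshold")
  t <- as.numeric(stats::quantile(vals, policy$percentile_p / 100,
                                  type = 7, names = FALSE))
  keep <- trip$i != trip$j & trip$x > t
  mat <- Matrix::sparseMatrix(i = trip$i[keep], j = trip$j[keep],
                              x = trip$x[keep], dims = dim(cm$mat),
                              dimnames = dimnames(cm$mat))
  contact_matrix(mat, state = "denoised", threshold = t)
}

#' Write / read a fitted normalization model as a key-value text file
#'
#' Stores the coefficients, dispersion and rescaling constant; the per-contig
#' means are recoverable from a catalog and within-contig counts via
#' [predict_mu()].
#'
#' @param model a `NormCCModel`.
#' @param path output path.
#' @return `write_normcc_model` returns `path` invisibly; `read_normcc_model`
#'   returns a `NormCCModel` without `mu_hat`.
#' @export
write_normcc_model <- function(model, path) {
  kv <- c(sprintf("beta0\t%.15g", model$coefficients[["beta0"]]),
          sprintf("beta_s\t%.15g", model$coefficients[["beta_s"]]),
          sprintf("beta_l\t%.15g", model$coefficients[["beta_l"]]),
          sprintf("beta_N\t%.15g", model$coefficients[["beta_N"]]),
          sprintf("theta\t%.15g", model$theta),
          sprintf("c_hat\t%.15g", model$c_hat))
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_normcc_model
#' @export
read_normcc_model <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"))
  kv <- stats::setNames(df$value, df$key)
  structure(list(coefficients = c(beta0 = kv[["beta0"]],
                                  beta_s = kv[["beta_s"]],
                                  beta_l = kv[["beta_l"]],
                                  beta_N = kv[["beta_N"]]),
                 theta = kv[["theta"]], mu_hat = NULL,
                 c_hat = kv[["c_hat"]]),
            class = "NormCCModel")
}

#' Fitted per-contig means from stored coefficients
#'
#' @param model a `NormCCModel` (possibly read back from disk).
#' @param catalog a `ContigCatalog`.
#' @param N within-contig contact counts aligned to `catalog`.
#' @return Named numeric vector of \eqn{\hat\mu_i}.
#' @export
predict_mu <- function(model, catalog, N) {
  b <- model$coefficients
  mu <- exp(b[["beta0"]]) * catalog$n_sites^b[["beta_s"]] *
    catalog$length^b[["beta_l"]] * N^b[["beta_N"]]
  stats::setNames(as.numeric(mu), catalog$contig_id)
}
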