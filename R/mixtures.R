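#' @name mixtures
#' @title Two-component mixture models for HTO counts
#'
#' @description
#' The demultiplexing engines model each HTO's counts as a mixture of a
#' low "background" component (ambient tags) and a high "signal" component
#' (bound tags). Two families are supported: Gaussian mixtures on
#' transformed counts and negative-binomial mixtures on raw counts
#' (parameterized by mean \eqn{\mu} and size \eqn{\theta}, variance
#' \eqn{\mu + \mu^2/\theta}). Fits are `MixtureFit` objects with components
#' ordered so `params0` has the lower mean.
NULL

new_mixture_fit <- function(family, weights, params0, params1, loglik,
                            loglik_trace, n_iter, converged,
                            flags = character()) {
  ## enforce lower-mean component first
  if (params1[["mean"]] < params0[["mean"]]) {
    tmp <- params0; params0 <- params1; params1 <- tmp
    weights <- rev(weights)
  }
  structure(list(family = family,
                 weights = as.numeric(weights),
                 params0 = params0, params1 = params1,
                 loglik = loglik, loglik_trace = loglik_trace,
                 n_iter = n_iter, converged = converged, flags = flags),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  sc <- if (x$family == "gaussian") "sd" else "theta"
  cat(sprintf("MixtureFit [%s]: w = (%.3f, %.3f); mu = (%.3f, %.3f); %s = (%.3g, %.3g)\n",
              x$family, x$weights[1], x$weights[2],
              x$params0[["mean"]], x$params1[["mean"]],
              sc, x$params0[["scale"]], x$params1[["scale"]]))
  cat(sprintf("loglik %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

.MIN_VAR <- 1e-10
.THETA_RANGE <- c(1e-3, 1e6)

#' Fit a two-component Gaussian mixture by EM
#'
#' Initialized from a deterministic one-dimensional k-means split; the
#' log-likelihood is non-decreasing across iterations. A component whose
#' variance collapses below 1e-10 is floored there and flagged
#' `"variance_floored"`.
#'
#' @param values numeric vector (>= 10 finite values, >= 2 distinct).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @param seed kept for API stability; initialization is deterministic.
#' @param init_labels optional 0/1 vector overriding the k-means
#'   initialization (EM is sensitive to its start when components overlap
#'   heavily; callers may fit from several starts and keep the best
#'   log-likelihood).
#' @return A `MixtureFit` (family `"gaussian"`, scale = sd).
#' @export
fit_gaussian_mixture2 <- function(values, tol = 1e-6, max_iter = 1000L,
                                  seed = 0L, init_labels = NULL) {
  x <- values[is.finite(values)]
  if (length(x) < 10L) stop("need >= 10 finite values", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("all values identical: mixture is undefined", call. = FALSE)
  }
  lab <- if (is.null(init_labels)) kmeans2(x, seed = seed) else
    as.integer(rep_len(init_labels, length(x)))
  if (length(unique(lab)) < 2L) {
    stop("initialization must populate both components", call. = FALSE)
  }
  flags <- character()
  mu <- c(mean(x[lab == 0L]), mean(x[lab == 1L]))
  sd0 <- c(stats::sd(x[lab == 0L]), stats::sd(x[lab == 1L]))
  sd0[!is.finite(sd0) | sd0 < sqrt(.MIN_VAR)] <- max(stats::sd(x) / 10,
                                                     sqrt(.MIN_VAR))
  w <- c(mean(lab == 0L), mean(lab == 1L))
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + stats::dnorm(x, mu[1], sd0[1], log = TRUE)
    lb <- log(w[2]) + stats::dnorm(x, mu[2], sd0[2], log = TRUE)
    m <- pmax(la, lb)
    ll <- sum(m + log(exp(la - m) + exp(lb - m)))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- 1 / (1 + exp(la - lb))  # responsibility of component 2
    r0 <- 1 - r1
    n0 <- sum(r0); n1 <- sum(r1)
    w <- c(n0, n1) / length(x)
    mu <- c(sum(r0 * x) / n0, sum(r1 * x) / n1)
    v0 <- sum(r0 * (x - mu[1])^2) / n0
    v1 <- sum(r1 * (x - mu[2])^2) / n1
    if (v0 < .MIN_VAR || v1 < .MIN_VAR) flags <- union(flags, "variance_floored")
    sd0 <- sqrt(pmax(c(v0, v1), .MIN_VAR))
  }
  new_mixture_fit("gaussian", w,
                  c(mean = mu[1], scale = sd0[1]),
                  c(mean = mu[2], scale = sd0[2]),
                  trace[length(trace)], trace, it, converged, flags)
}

## weighted NB log-likelihood profile score in theta (for Newton updates)
nb_theta_score <- function(theta, x, mu, r) {
  sum(r * (digamma(x + theta) - digamma(theta) + log(theta / (theta + mu)) +
             1 - (x + theta) / (theta + mu)))
}

nb_theta_newton <- function(x, mu, r, theta_start, iter = 25L) {
  th <- min(max(theta_start, .THETA_RANGE[1]), .THETA_RANGE[2])
  for (i in seq_len(iter)) {
    sc <- nb_theta_score(th, x, mu, r)
    dsc <- sum(r * (trigamma(x + th) - trigamma(th) + 1 / th -
                      2 / (th + mu) + (x + th) / (th + mu)^2))
    if (!is.finite(sc) || !is.finite(dsc) || dsc == 0) break
    step <- sc / dsc
    new <- th - step
    if (!is.finite(new) || new <= 0) new <- th / 2
    new <- min(max(new, .THETA_RANGE[1]), .THETA_RANGE[2])
    if (abs(new - th) < 1e-8 * (1 + th)) {
      th <- new
      break
    }
    th <- new
  }
  th
}

nb_moment_theta <- function(x, r) {
  n <- sum(r)
  mu <- sum(r * x) / n
  v <- sum(r * (x - mu)^2) / n
  if (v > mu) mu^2 / (v - mu) else .THETA_RANGE[2]
}

nb_mix_loglik <- function(x, w, mu, theta) {
  la <- log(w[1]) + stats::dnbinom(x, mu = mu[1], size = theta[1], log = TRUE)
  lb <- log(w[2]) + stats::dnbinom(x, mu = mu[2], size = theta[2], log = TRUE)
  m <- pmax(la, lb)
  sum(m + log(exp(la - m) + exp(lb - m)))
}

#' Fit a two-component negative-binomial mixture by EM
#'
#' EM on raw counts: the E-step computes responsibilities, the M-step updates
#' each component mean as the responsibility-weighted average (the exact
#' conditional MLE) and refines the dispersion \eqn{\theta} by Newton
#' iterations on the profile score from a moment-based start. A dispersion
#' update is only accepted if the observed log-likelihood does not decrease
#' (generalized EM), so the log-likelihood is monotone. If neither initial
#' cluster is overdispersed the fit falls back to a near-Poisson
#' \eqn{\theta = 10^6}, flagged `"poisson_like"`.
#'
#' @param counts non-negative integer vector (>= 20 values, not all zero).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap.
#' @param seed kept for API stability; initialization is deterministic.
#' @return A `MixtureFit` (family `"negbin"`, scale = theta).
#' @export
fit_negbin_mixture2 <- function(counts, tol = 1e-6, max_iter = 500L,
                                seed = 0L) {
  x <- counts[is.finite(counts)]
  if (length(x) < 20L) stop("need >= 20 counts", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (all(x == 0)) stop("all counts are zero", call. = FALSE)
  x <- as.numeric(x)
  flags <- character()
  if (length(unique(x)) < 2L) {
    stop("all counts identical: mixture is undefined", call. = FALSE)
  }
  lab <- kmeans2(x, seed = seed)
  r0 <- as.numeric(lab == 0L)
  mu <- c(max(sum(r0 * x) / sum(r0), 1e-3),
          max(sum((1 - r0) * x) / sum(1 - r0), 1e-3))
  theta <- c(nb_moment_theta(x, r0), nb_moment_theta(x, 1 - r0))
  if (all(theta >= .THETA_RANGE[2])) flags <- union(flags, "poisson_like")
  w <- c(mean(lab == 0L), mean(lab == 1L))
  w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + stats::dnbinom(x, mu = mu[1], size = theta[1], log = TRUE)
    lb <- log(w[2]) + stats::dnbinom(x, mu = mu[2], size = theta[2], log = TRUE)
    m <- pmax(la, lb)
    ll <- m + log(exp(la - m) + exp(lb - m))
    ll_total <- sum(ll)
    trace <- c(trace, ll_total)
    if (is.finite(ll_old) && abs(ll_total - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll_total
    r1 <- 1 / (1 + exp(la - lb))
    r0 <- 1 - r1
    n0 <- sum(r0); n1 <- sum(r1)
    w <- pmin(pmax(c(n0, n1) / length(x), 1e-6), 1 - 1e-6)
    mu <- c(max(sum(r0 * x) / n0, 1e-3), max(sum(r1 * x) / n1, 1e-3))
    ## theta update, accepted only if the loglik does not decrease
    cand <- c(nb_theta_newton(x, mu[1], r0, theta[1]),
              nb_theta_newton(x, mu[2], r1, theta[2]))
    if (nb_mix_loglik(x, w, mu, cand) >= nb_mix_loglik(x, w, mu, theta)) {
      theta <- cand
    }
  }
  new_mixture_fit("negbin", w,
                  c(mean = mu[1], scale = theta[1]),
                  c(mean = mu[2], scale = theta[2]),
                  trace[length(trace)], trace, it, converged, flags)
}

#' Posterior probability of the upper mixture component
#'
#' `p1(v) = w1 f1(v) / (w0 f0(v) + w1 f1(v))`, computed in log space.
#'
#' @param fit a `MixtureFit`.
#' @param values numeric vector (counts for the negbin family).
#' @return Probabilities in `[0, 1]`, one per value.
#' @export
posterior <- function(fit, values) {
  stopifnot(inherits(fit, "MixtureFit"))
  if (fit$family == "gaussian") {
    la <- log(fit$weights[1]) +
      stats::dnorm(values, fit$params0[["mean"]], fit$params0[["scale"]],
                   log = TRUE)
    lb <- log(fit$weights[2]) +
      stats::dnorm(values, fit$params1[["mean"]], fit$params1[["scale"]],
                   log = TRUE)
  } else {
    la <- log(fit$weights[1]) +
      stats::dnbinom(values, mu = fit$params0[["mean"]],
                     size = fit$params0[["scale"]], log = TRUE)
    lb <- log(fit$weights[2]) +
      stats::dnbinom(values, mu = fit$params1[["mean"]],
                     size = fit$params1[["scale"]], log = TRUE)
  }
  p <- 1 / (1 + exp(la - lb))
  p[la == -Inf & lb == -Inf] <- 0.5
  p
}

#' Deterministic two-group 1-D k-means
#'
#' Lloyd iterations from quantile-based centres (25th and 75th percentiles);
#' the lower-mean cluster is labelled 0. Equidistant points join the lower
#' cluster. Deterministic and invariant to input order.
#'
#' @param values numeric vector, length >= 2 with >= 2 distinct values.
#' @param seed kept for API stability; the algorithm is deterministic.
#' @return Integer vector of labels in `{0, 1}`.
#' @export
kmeans2 <- function(values, seed = 0L) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop("need >= 2 values", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("all values identical: cannot split into 2 clusters", call. = FALSE)
  }
  cen <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  if (cen[1] == cen[2]) cen <- range(x)
  for (i in 1:100) {
    lab <- as.integer(abs(x - cen[2]) < abs(x - cen[1]))  # ties -> lower
    new <- c(mean(x[lab == 0L]), mean(x[lab == 1L]))
    if (any(!is.finite(new))) break
    if (isTRUE(all.equal(new, cen))) break
    cen <- new
  }
  if (mean(x[lab == 1L]) < mean(x[lab == 0L])) lab <- 1L - lab
  lab
}

#' k-medoids clustering (PAM)
#'
#' Partitioning around medoids with a deterministic initialization: the first
#' medoid is the point farthest from the data centroid, the rest follow by
#' greedy farthest-point selection; the PAM swap phase then runs to a local
#' optimum. Deterministic and equivariant under row permutation (up to
#' exact distance ties).
#'
#' @param x numeric matrix, observations in rows.
#' @param k number of clusters (>= 2, <= nrow(x)).
#' @param seed kept for API stability; initialization is deterministic.
#' @return Integer vector of cluster labels in `1..k`.
#' @export
kmedoids <- function(x, k, seed = 0L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k observations (n = ", n, ", k = ", k, ")",
                  call. = FALSE)
  centroid <- colMeans(x)
  d2c <- rowSums(sweep(x, 2, centroid, "-")^2)
  med <- which.max(d2c)
  mind <- rowSums(sweep(x, 2, x[med, ], "-")^2)
  while (length(med) < k) {
    nxt <- which.max(mind)
    med <- c(med, nxt)
    mind <- pmin(mind, rowSums(sweep(x, 2, x[nxt, ], "-")^2))
  }
  fit <- cluster::pam(x, k = k, medoids = sort(med), do.swap = TRUE,
                      pamonce = 5, cluster.only = TRUE)
  as.integer(fit)
}
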