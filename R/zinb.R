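#' Sample from a zero-inflated negative binomial
#'
#' With probability \code{pi} a draw is a structural zero; otherwise it is
#' negative binomial with mean \code{mu} and dispersion \code{theta}
#' (variance \code{mu + mu^2 / theta}). \code{mu} may be a vector, recycled
#' to \code{size}, so domain-specific means are drawn in one call.
#'
#' @param mu NB mean(s), positive.
#' @param theta NB dispersion, positive (small theta = heavy overdispersion).
#' @param pi structural zero probability in \code{[0, 1]}.
#' @param size number of draws.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @return integer vector of length \code{size}.
#' @export
zinb_sample <- function(mu, theta, pi, size, seed = NULL) {
  if (any(mu <= 0) || theta <= 0 || pi < 0 || pi > 1 || size < 0)
    stop("invalid ZINB parameters (need mu > 0, theta > 0, pi in [0,1])",
         call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
    set.seed(as.integer(seed))
  }
  x <- stats::rnbinom(size, size = theta, mu = mu)
  if (pi > 0) x[stats::runif(size) < pi] <- 0L
  as.integer(x)
}

#' Maximum-likelihood fit of a zero-inflated negative binomial
#'
#' Fits the two-component ZINB (structural-zero proportion \code{pi}, NB mean
#' \code{mu}, dispersion \code{theta}) by direct likelihood maximization over
#' the unconstrained parametrization \code{(log mu, log theta, logit pi)}
#' with \code{optim(method = "BFGS")}. Standard errors on the natural scale
#' come from the inverse observed information via the delta method.
#'
#' @param x non-negative integer vector.
#' @param start optional list with elements \code{mu}, \code{theta},
#'   \code{pi}; defaults use moment-style guesses.
#' @return list with \code{mu}, \code{theta}, \code{pi}, their standard
#'   errors \code{se_mu}, \code{se_theta}, \code{se_pi}, \code{loglik} and
#'   \code{convergence} (0 = success).
#' @export
fit_zinb <- function(x, start = NULL) {
  if (any(x < 0) || any(x != round(x)))
    stop("x must be non-negative integers", call. = FALSE)
  n0 <- sum(x == 0)
  xnz <- x[x > 0]
  if (!length(xnz)) stop("all values are zero; ZINB is unidentifiable",
                         call. = FALSE)
  if (is.null(start)) {
    mu0 <- max(mean(xnz), 0.1)
    v0 <- stats::var(x)
    th0 <- if (v0 > mu0) max(mu0^2 / (v0 - mu0), 0.05) else 1
    pi0 <- min(max(n0 / length(x) / 2, 0.01), 0.95)
    start <- list(mu = mu0, theta = th0, pi = pi0)
  }
  nll <- function(par) {
    mu <- exp(par[1]); th <- exp(par[2]); p0 <- stats::plogis(par[3])
    v <- suppressWarnings({
      lz <- log(p0 + (1 - p0) * stats::dnbinom(0, size = th, mu = mu))
      lnz <- log(1 - p0) +
        stats::dnbinom(xnz, size = th, mu = mu, log = TRUE)
      -(n0 * lz + sum(lnz))
    })
    if (!is.finite(v)) 1e10 else v
  }
  fit <- stats::optim(c(log(start$mu), log(start$theta),
                        stats::qlogis(start$pi)),
                      nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500))
  mu <- exp(fit$par[1]); th <- exp(fit$par[2]); p0 <- stats::plogis(fit$par[3])
  se <- rep(NA_real_, 3)
  vc <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (!is.null(vc) && all(diag(vc) > 0)) se <- sqrt(diag(vc))
  list(mu = mu, theta = th, pi = p0,
       se_mu = mu * se[1], se_theta = th * se[2],
       se_pi = p0 * (1 - p0) * se[3],
       loglik = -fit$value, convergence = fit$convergence)
}
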