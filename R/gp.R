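# Gaussian-process regression with a Matérn (nu = 0.5/1.5/2.5) or RBF kernel
# plus a white-noise kernel. Hyperparameters (length-scale, signal sd, noise
# sd) are chosen by maximising the log marginal likelihood (multi-start
# L-BFGS-B on log parameters). Scores are z-scored internally before fitting
# and predictions are un-standardised on output.

kernel_matern <- function(r, ell, nu) {
  s <- r / ell
  if (nu == 0.5) {
    exp(-s)
  } else if (nu == 1.5) {
    a <- sqrt(3) * s
    (1 + a) * exp(-a)
  } else if (nu == 2.5) {
    a <- sqrt(5) * s
    (1 + a + a^2 / 3) * exp(-a)
  } else {
    abort("Supported Matern smoothness values: 0.5, 1.5, 2.5.")
  }
}

kernel_rbf <- function(r, ell) exp(-0.5 * (r / ell)^2)

gp_kernel <- function(r, theta, kernel) {
  ell <- exp(theta[1L])
  sf2 <- exp(2 * theta[2L])
  base <- if (kernel$name == "rbf") kernel_rbf(r, ell) else kernel_matern(r, ell, kernel$nu)
  sf2 * base
}

gp_nll <- function(theta, r_train, y, kernel, jitter = 1e-8) {
  n <- length(y)
  K <- gp_kernel(r_train, theta, kernel)
  sn2 <- if (kernel$white) exp(2 * theta[3L]) else 0
  diag(K) <- diag(K) + sn2 + jitter
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * crossprod(y, alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

#' Fit a Gaussian process to pipeline coordinates and scores
#'
#' @param coords Numeric matrix (points x dimensions) of embedded pipeline
#'   coordinates, or a data frame with `dim*` columns.
#' @param scores Numeric vector of pipeline scores.
#' @param kernel List: `name` (`"matern"` or `"rbf"`), `nu` (Matérn
#'   smoothness, default 2.5) and `white` (include a white-noise kernel,
#'   default TRUE).
#' @param n_restarts Number of seeded random restarts for hyperparameter
#'   optimisation (in addition to a heuristic start).
#' @param seed Seed for the restarts.
#' @param prev_theta Optional hyperparameters used as fallback (and as an
#'   extra start) if optimisation fails.
#' @param fixed_theta Optional hyperparameters (log length-scale, log signal
#'   sd, log noise sd) to use as-is, skipping marginal-likelihood
#'   optimisation; useful for posterior-variance studies at a fixed kernel.
#' @return A `gp_model` list with fitted hyperparameters, training data and
#'   the Cholesky factor needed for prediction.
#' @export
fit_gp <- function(coords, scores, kernel = list(name = "matern", nu = 2.5, white = TRUE),
                   n_restarts = 2L, seed = 1L, prev_theta = NULL,
                   fixed_theta = NULL) {
  x <- if (is.matrix(coords)) coords else space_coords(coords)
  y <- as.numeric(scores)
  if (nrow(x) < 2L) abort("At least two points are required to fit a GP.")
  kernel <- modifyList(list(name = "matern", nu = 2.5, white = TRUE), kernel)

  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  z <- (y - mu_y) / sd_y

  r_train <- as.matrix(stats::dist(x))
  med_d <- stats::median(r_train[upper.tri(r_train)])
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  n_par <- if (kernel$white) 3L else 2L
  starts <- list(c(log(med_d), 0, log(0.3))[seq_len(n_par)])
  if (!is.null(prev_theta)) starts <- c(starts, list(prev_theta[seq_len(n_par)]))
  if (n_restarts > 0L) {
    extra <- with_preserved_seed(derive_seed(seed, 17L), {
      lapply(seq_len(n_restarts), function(i) {
        c(log(med_d) + rnorm(1, sd = 1), rnorm(1, sd = 0.5),
          log(0.3) + rnorm(1, sd = 1))[seq_len(n_par)]
      })
    })
    starts <- c(starts, extra)
  }
  lower <- c(log(med_d) - 7, -5, -7)[seq_len(n_par)]
  upper <- c(log(med_d) + 5, 4, 2)[seq_len(n_par)]

  best <- NULL
  if (!is.null(fixed_theta)) {
    best <- list(par = fixed_theta[seq_len(n_par)],
                 value = gp_nll(fixed_theta[seq_len(n_par)], r_train, z, kernel))
    starts <- list()
  }
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, gp_nll, r_train = r_train, y = z, kernel = kernel,
                   method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    if (is.null(prev_theta)) abort("GP hyperparameter optimisation failed.")
    inform("GP optimisation failed; falling back to previous hyperparameters.")
    best <- list(par = prev_theta, value = gp_nll(prev_theta, r_train, z, kernel))
  }

  theta <- best$par
  K <- gp_kernel(r_train, theta, kernel)
  sn2 <- if (kernel$white) exp(2 * theta[3L]) else 0
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), z))

  structure(
    list(x = x, y = y, z = z, mu_y = mu_y, sd_y = sd_y,
         theta = theta, kernel = kernel, chol = ch, alpha = alpha,
         noise_sd = sqrt(sn2) * sd_y, log_marginal_likelihood = -best$value),
    class = "gp_model"
  )
}

#' Posterior mean and sd of a fitted GP
#'
#' @param object A `gp_model`.
#' @param newdata Matrix (or `embedded_space`) of coordinates to predict at.
#' @param ... Unused.
#' @return Tibble with `mu` and `sigma` (posterior sd of the latent function,
#'   on the original score scale).
#' @export
predict.gp_model <- function(object, newdata, ...) {
  xs <- if (is.matrix(newdata)) newdata else space_coords(newdata)
  p <- gp_posterior(object, xs)
  tibble(mu = p$mu, sigma = p$sigma)
}

# Posterior mean/sd without tibble overhead; the hot path of acquisition
# optimisation.
gp_posterior <- function(object, xs) {
  d2 <- outer(rowSums(xs^2), rowSums(object$x^2), "+") - 2 * tcrossprod(xs, object$x)
  r_cross <- sqrt(pmax(d2, 0))
  ks <- gp_kernel(r_cross, object$theta, object$kernel)
  mu <- as.numeric(ks %*% object$alpha)
  v <- forwardsolve(object$chol, t(ks), upper.tri = TRUE, transpose = TRUE)
  kss <- gp_kernel(matrix(0, 1, 1), object$theta, object$kernel)[1L]
  var <- pmax(kss - colSums(v^2), 0)
  list(mu = mu * object$sd_y + object$mu_y, sigma = sqrt(var) * object$sd_y)
}

#' Upper confidence bound acquisition
#'
#' `mu + kappa * sigma`: high kappa explores (favouring uncertain regions),
#' low kappa exploits (favouring high posterior mean).
#' @param mu Posterior mean.
#' @param sigma Posterior sd (non-negative).
#' @param kappa Non-negative exploration weight.
#' @return Acquisition value(s).
#' @export
#' @examples
#' ucb(0.5, 0.1, 2)  # 0.7
ucb <- function(mu, sigma, kappa) {
  if (any(sigma < 0)) abort("`sigma` must be non-negative.")
  if (!is_scalar_num(kappa) || kappa < 0) abort("`kappa` must be non-negative.")
  mu + kappa * sigma
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> %d points, %s kernel%s, log ML = %.3f\n",
              nrow(x$x),
              if (x$kernel$name == "rbf") "RBF" else sprintf("Matern(nu=%.1f)", x$kernel$nu),
              if (x$kernel$white) " + white noise" else "",
              x$log_marginal_likelihood))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy gp_model
#' @export
tidy.gp_model <- function(x, ...) {
  nms <- c("log_length_scale", "log_signal_sd", "log_noise_sd")[seq_along(x$theta)]
  tibble(term = nms, estimate = x$theta)
}

#' @method glance gp_model
#' @export
glance.gp_model <- function(x, ...) {
  tibble(n = nrow(x$x), log_marginal_likelihood = x$log_marginal_likelihood,
         noise_sd = x$noise_sd)
}
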