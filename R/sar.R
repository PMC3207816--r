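# Maximum-likelihood spatial-lag (SAR) models with kernel-matched
# weights: y = rho W y + X beta + eps, eps ~ N(0, sigma^2 I).
#
# The log-determinant ln|I - rho W| is evaluated from the eigenvalues of
# W, precomputed once per weight structure.  For a row-standardized
# matrix W = D^-1 B with B the symmetric kernel matrix and D the row
# sums, W is similar to the symmetric D^-1/2 B D^-1/2, so its spectrum is
# real and is computed from that symmetric form.

#' Eigenvalues of a spatial weight matrix
#'
#' Real spectrum of `W`, computed from the similar symmetric form when
#' `W` is row-standardized (guaranteeing real eigenvalues) and directly
#' from the symmetric kernel matrix otherwise.  Used for the SAR
#' log-determinant and the admissible interval of the autoregressive
#' parameter; compute once and pass to [fit_sar_lag()] when fitting many
#' models on the same weights.
#'
#' @param weights a `spatial_weights` object with zero diagonal.
#' @return Sorted numeric eigenvalues.
#' @export
sar_eigenvalues <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (weights$include_self) {
    stop("SAR weights must have a zero diagonal", call. = FALSE)
  }
  W <- weights$W
  if (weights$row_standardized) {
    r <- weights$row_sums
    # S = D^1/2 W D^-1/2 = D^-1/2 B D^-1/2, symmetric and similar to W
    S <- sqrt(r) * W * rep(1 / sqrt(r), each = length(r))
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  } else {
    asym <- max(abs(W - t(W)))
    if (asym > 1e-8) {
      stop("non-row-standardized weights must be symmetric", call. = FALSE)
    }
    ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  sort(ev)
}

#' Fit a spatial-lag SAR model by maximum likelihood
#'
#' Profile likelihood over the autoregressive parameter `rho`: for fixed
#' `rho`, `beta(rho)` solves the OLS problem on `y - rho W y`,
#' `sigma^2(rho) = e'e/n`, and the profile log-likelihood is
#' `-(n/2)(ln 2 pi + ln sigma^2 + 1) + sum(ln(1 - rho lambda_i))` with
#' `lambda_i` the eigenvalues of `W`.  `rho` is maximized by bounded
#' scalar search (tolerance 1e-8) inside the admissible interval
#' `(1/lambda_min, 1/lambda_max)`; a maximizer within 1e-6 of a boundary
#' is flagged as non-converged.  Standard errors for `beta` are the
#' asymptotic values conditional on the estimated `rho`
#' (`sigma_hat^2 (X'X)^-1`), with two-sided z-tests.
#'
#' @param y response vector.
#' @param X design matrix including the intercept column.
#' @param weights a `spatial_weights` object, zero diagonal; the
#'   row-standardized form is the default convention (upper interval
#'   bound 1), but a symmetric raw-kernel matrix is accepted for
#'   sensitivity runs.
#' @param ev optional precomputed eigenvalues from [sar_eigenvalues()].
#' @return An object of class `sar_fit`: `rho`, `beta`, `se_beta`,
#'   `z_values`, `p_values`, `sigma2`, `log_lik`, `rho_interval`,
#'   `converged`, `n`.
#' @export
fit_sar_lag <- function(y, X, weights, ev = NULL) {
  stopifnot(inherits(weights, "spatial_weights"))
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, weights$n == n)
  if (n <= ncol(X) + 2) stop("too few observations for SAR", call. = FALSE)
  if (is.null(ev)) ev <- sar_eigenvalues(weights)
  lo <- 1 / min(ev)
  hi <- 1 / max(ev)
  if (lo >= hi) stop("degenerate eigenvalue interval", call. = FALSE)
  W <- weights$W
  Wy <- drop(W %*% y)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("singular X'X in SAR fit", call. = FALSE)

  profile_ll <- function(rho) {
    ys <- y - rho * Wy
    e <- qr.resid(qrx, ys)
    sigma2 <- sum(e^2) / n
    -(n / 2) * (log(2 * pi) + log(sigma2) + 1) + sum(log(1 - rho * ev))
  }

  eps <- 1e-9 * (hi - lo)
  opt <- optimize(profile_ll, interval = c(lo + eps, hi - eps),
                  maximum = TRUE, tol = 1e-8)
  rho <- opt$maximum
  converged <- (rho - lo) > 1e-6 && (hi - rho) > 1e-6

  ys <- y - rho * Wy
  beta <- qr.coef(qrx, ys)
  e <- ys - drop(X %*% beta)
  sigma2 <- sum(e^2) / n
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- names(beta)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  structure(list(rho = rho,
                 beta = beta,
                 se_beta = se,
                 z_values = z,
                 p_values = p,
                 sigma2 = sigma2,
                 log_lik = opt$objective,
                 rho_interval = c(lo, hi),
                 converged = converged,
                 n = n),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("Spatial-lag SAR fit (n = ", x$n, ")\n",
      "  rho = ", signif(x$rho, 5),
      " in (", signif(x$rho_interval[1], 4), ", ",
      signif(x$rho_interval[2], 4), ")",
      if (!x$converged) "  [NOT CONVERGED]" else "",
      "\n  logLik = ", signif(x$log_lik, 7),
      ", sigma2 = ", signif(x$sigma2, 5), "\n", sep = "")
  tab <- data.frame(beta = x$beta, se = x$se_beta,
                    z = x$z_values, p = signif(x$p_values, 3))
  print(tab)
  invisible(x)
}

#' Export a SAR fit summary as JSON
#'
#' @param x a `sar_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sar_fit <- function(x, path) {
  stopifnot(inherits(x, "sar_fit"))
  jsonlite::write_json(
    list(rho = x$rho, beta = as.list(x$beta), se = as.list(x$se_beta),
         z = as.list(x$z_values), p = as.list(x$p_values),
         sigma2 = x$sigma2, log_lik = x$log_lik,
         rho_interval = x$rho_interval, converged = x$converged, n = x$n),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
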