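# Geographically weighted regression: local weighted least squares per
# cell, hat-matrix trace, corrected AIC, all-subsets model selection, and
# the matched global OLS fit.

.COND_TOL <- 1e10

#' One local weighted least-squares fit
#'
#' Solves `beta = (X'WX)^-1 X'W y` through a rank-revealing SVD of the
#' sqrt(w)-scaled design (no explicit inversion; singular values below
#' 1e-10 of the largest are truncated).  The local coefficient of
#' determination uses the weighted total sum of squares around the
#' weighted mean.  The fit is flagged unreliable - coefficients and local
#' R^2 withheld as `NA` - when fewer than `ncol(X) + 1` observations carry
#' positive weight or the condition number of the weighted design exceeds
#' 1e10; this is a flag, not an error.
#'
#' @param X design matrix including an intercept column.
#' @param y response vector.
#' @param w non-negative weight vector.
#' @return A list: `coefficients`, `local_R2`, `n_nonzero`, `reliable`,
#'   and `fitted` (fitted values over all rows of `X`).
#' @export
local_wls <- function(X, y, w) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  w <- as.numeric(w)
  stopifnot(nrow(X) == length(y), length(w) == length(y))
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  k <- ncol(X)
  n_pos <- sum(w > 0)
  sw <- sqrt(w)
  sv <- svd(X * sw)
  cond <- if (min(sv$d) > 0) max(sv$d) / min(sv$d) else Inf
  keep <- sv$d > 1e-10 * max(sv$d)
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  beta <- sv$v %*% (d_inv * crossprod(sv$u, y * sw))
  beta <- drop(beta)
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  ybar_w <- sum(w * y) / sum(w)
  rss <- sum(w * (y - fitted)^2)
  tss <- sum(w * (y - ybar_w)^2)
  reliable <- (n_pos >= k + 1) && is.finite(cond) && cond <= .COND_TOL
  r2 <- if (reliable && tss > 0) 1 - rss / tss else NA_real_
  if (!reliable) beta[] <- NA_real_
  list(coefficients = beta,
       local_R2 = r2,
       n_nonzero = n_pos,
       reliable = reliable,
       fitted = fitted)
}

.design_matrix <- function(table, members) {
  missing_cols <- setdiff(members, names(table))
  if (length(missing_cols) > 0) {
    stop("predictor column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(table)[members]))
  storage.mode(X) <- "double"
  X
}

# GWR small-sample corrected AIC with effective parameter count trace_S
# (the standard GWR convention; for global OLS trace_S = p + 1):
#   AICc = 2 n ln(sigma_hat) + n ln(2 pi) + n (n + tr(S)) / (n - 2 - tr(S))
# with sigma_hat^2 = RSS / n.
.gwr_aicc <- function(rss, n, trace_s) {
  if (trace_s >= n - 2) {
    stop("effective parameter count tr(S) = ", signif(trace_s, 6),
         " >= n - 2 = ", n - 2,
         "; AICc undefined (bandwidth too small)", call. = FALSE)
  }
  sigma2 <- rss / n
  2 * n * log(sqrt(sigma2)) + n * log(2 * pi) +
    n * (n + trace_s) / (n - 2 - trace_s)
}

#' Fit a geographically weighted regression
#'
#' One weighted least-squares fit per cell, weighting all cells by the
#' kernel evaluated at their great-circle distance from the focal cell
#' (the focal cell itself is included with weight 1 at distance 0).  The
#' hat diagonal `s_ii = x_i'(X'W_i X)^- X'W_i e_i` accumulates into the
#' effective parameter count `tr(S)`, which enters the small-sample
#' corrected AIC (see [aicc_ols()] for the matched global formula).
#'
#' @param table a filtered `cell_table` with a `richness` response.
#' @param predictors a [variable_set()] or character vector of predictor
#'   column names.
#' @param kernel a [kernel_spec()].
#' @param distances optional precomputed distance matrix in km.
#' @return An object of class `gwr_fit`: per-cell `locals` data frame
#'   (`cell_id`, coordinates, coefficients, `local_R2`, `n_nonzero`,
#'   `reliable`), focal `residuals`, `trace_S`, `aicc`, `rss`, `n`,
#'   `predictors` and `kernel`.  Cells with unreliable local fits keep
#'   their pseudo-inverse residual and leverage (so the global statistics
#'   remain defined) but carry `NA` coefficients and local R^2 and are
#'   excluded from downstream trend responses.
#' @export
fit_gwr <- function(table, predictors, kernel, distances = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"))
  members <- .members(predictors)
  if (length(members) == 0) stop("predictors must be non-empty", call. = FALSE)
  X <- .design_matrix(table, members)
  y <- as.numeric(table$richness)
  n <- nrow(X)
  D <- if (is.null(distances)) {
    distance_matrix_km(table$lat_deg, table$lon_deg)
  } else {
    stopifnot(nrow(distances) == n, ncol(distances) == n)
    distances
  }
  kern_code <- if (kernel$family == "bisquare") 0L else 1L
  core <- gwr_local_fits(X, y, D, kernel$bandwidth_km, kern_code, .COND_TOL)
  beta <- core$beta
  colnames(beta) <- colnames(X)
  reliable <- core$reliable == 1L
  trace_s <- sum(core$s_ii)
  rss <- sum(core$resid^2)
  aicc <- .gwr_aicc(rss, n, trace_s)
  locals <- data.frame(cell_id = table$cell_id,
                       lat_deg = table$lat_deg,
                       lon_deg = table$lon_deg,
                       beta,
                       local_R2 = core$local_r2,
                       n_nonzero = core$n_nonzero,
                       reliable = reliable,
                       check.names = FALSE)
  structure(list(predictors = members,
                 kernel = kernel,
                 locals = locals,
                 residuals = core$resid,
                 trace_S = trace_s,
                 rss = rss,
                 aicc = aicc,
                 n = n,
                 n_unreliable = sum(!reliable)),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat("GWR fit: richness ~ ", paste(x$predictors, collapse = " + "),
      "\n  kernel ", format(x$kernel), ", n = ", x$n,
      ", tr(S) = ", signif(x$trace_S, 5),
      ", AICc = ", signif(x$aicc, 7), "\n", sep = "")
  if (x$n_unreliable > 0) {
    cat("  ", x$n_unreliable, " unreliable local fit(s)\n", sep = "")
  }
  r2 <- x$locals$local_R2
  cat("  local R^2: min ", signif(min(r2, na.rm = TRUE), 3),
      ", median ", signif(stats::median(r2, na.rm = TRUE), 3),
      ", max ", signif(max(r2, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Global OLS with the GWR-comparable corrected AIC
#'
#' Ordinary least squares on the same design, with the identical AICc
#' formula but the effective parameter count replaced by `p + 1`, so that
#' `AICc(OLS) - AICc(GWR)` measures spatial non-stationarity like for
#' like.
#'
#' @inheritParams fit_gwr
#' @return A list of class `ols_fit`: `coefficients`, `aicc`, `r2`,
#'   `residuals`, `rss`, `n`, `predictors`.
#' @export
aicc_ols <- function(table, predictors) {
  members <- .members(predictors)
  X <- .design_matrix(table, members)
  y <- as.numeric(table$richness)
  n <- nrow(X)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient design in global OLS", call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  resid <- y - drop(X %*% beta)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  structure(list(coefficients = beta,
                 aicc = .gwr_aicc(rss, n, ncol(X)),
                 r2 = 1 - rss / tss,
                 residuals = resid,
                 rss = rss,
                 n = n,
                 predictors = members),
            class = "ols_fit")
}

#' All-subsets GWR model selection by corrected AIC
#'
#' Fits all 7 non-empty subsets of a 3-member variable set (3 singletons,
#' 3 pairs, the triple) by GWR and ranks them by AICc.  The matched global
#' OLS AICc is reported per subset, so the table also carries the
#' `AICc(OLS) - AICc(GWR)` non-stationarity gap.
#'
#' @param table a filtered `cell_table`.
#' @param vset a [variable_set()] with 3 members (water or energy).
#' @param kernel a [kernel_spec()].
#' @param distances optional precomputed distance matrix.
#' @return A data frame of class `model_selection` with one row per
#'   subset: `subset`, `k`, `aicc`, `delta_aicc` (vs. the minimum),
#'   `aicc_ols`, `delta_vs_ols`, `best`.  The winning subset's members
#'   and `gwr_fit` are attached as attributes `best_members` and
#'   `best_fit`.
#' @export
select_model <- function(table, vset, kernel, distances = NULL) {
  members <- .members(vset)
  if (length(members) != 3) {
    stop("model selection expects a 3-member variable set", call. = FALSE)
  }
  if (is.null(distances)) {
    distances <- distance_matrix_km(table$lat_deg, table$lon_deg)
  }
  subsets <- unlist(lapply(1:3, function(k) {
    combn(members, k, simplify = FALSE)
  }), recursive = FALSE)
  fits <- lapply(subsets, function(s) fit_gwr(table, s, kernel, distances))
  ols <- lapply(subsets, function(s) aicc_ols(table, s))
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  out <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+"),
    k = lengths(subsets),
    aicc = aiccs,
    delta_aicc = aiccs - min(aiccs),
    aicc_ols = vapply(ols, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  out$delta_vs_ols <- out$aicc_ols - out$aicc
  out$best <- out$delta_aicc == 0
  if (sum(out$best) > 1) {   # exact tie: keep the smallest subset, then order
    first <- which(out$best)[1]
    out$best <- seq_len(nrow(out)) == first
  }
  best_idx <- which(out$best)
  attr(out, "best_members") <- subsets[[best_idx]]
  attr(out, "best_fit") <- fits[[best_idx]]
  attr(out, "set_name") <- if (inherits(vset, "variable_set")) vset$name else NA
  class(out) <- c("model_selection", "data.frame")
  out
}

#' Combine the best water and best energy subsets
#'
#' Ordered, de-duplicated union of two selected predictor subsets, water
#' members first; this is the "combined" model whose local R^2 anchors the
#' variation partitioning.
#'
#' @param best_water,best_energy [variable_set()]s, character vectors, or
#'   `model_selection` tables (their `best_members` attribute is used).
#' @return A `variable_set` named `"combined"`.
#' @export
combined_model <- function(best_water, best_energy) {
  pick <- function(x) {
    if (inherits(x, "model_selection")) attr(x, "best_members")
    else .members(x)
  }
  members <- unique(c(pick(best_water), pick(best_energy)))
  if (length(members) == 0) stop("combined model is empty", call. = FALSE)
  structure(list(name = "combined", members = members),
            class = "variable_set")
}
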