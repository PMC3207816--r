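# Latitudinal trends of local explained-variance fractions: the headline
# test.  Each response (R_w, R_e, R_pw, R_pe) is regressed on absolute
# latitude per hemisphere, with OLS and with spatial-lag SAR models whose
# weights reuse the GWR kernel, and across kernels.

.TREND_RESPONSES <- c("R_e", "R_pe", "R_w", "R_pw")

#' Regress a local explained-variance fraction on absolute latitude
#'
#' Within one hemisphere, the response and absolute latitude are both
#' standardized (zero mean, unit sample sd) and regressed: OLS with a
#' two-sided t-test on the slope, or a spatial-lag SAR model whose
#' weights are rebuilt on the hemisphere's cells with the same kernel
#' family and bandwidth as the GWR that produced the response
#' (cross-hemisphere neighbors are cut, since the hemispheres are
#' analyzed separately).  Cells with `NA` responses (unreliable local
#' fits) are dropped listwise.
#'
#' @param partition a `partition_table`.
#' @param response one of `"R_w"`, `"R_e"`, `"R_pw"`, `"R_pe"`.
#' @param hemisphere `"north"` (`lat_deg >= 0`) or `"south"`.
#' @param method `"ols"` or `"sar"`.
#' @param kernel a [kernel_spec()]; defaults to the partition's kernel.
#' @param weights,ev optional precomputed `spatial_weights` (zero
#'   diagonal, row-standardized, on exactly the retained subset cells)
#'   and their eigenvalues, to avoid rebuilding across responses.
#' @return A one-row data frame: `response`, `hemisphere`, `method`,
#'   `kernel`, `bandwidth_km`, `slope` (standardized), `p_value`, `rho`
#'   (`NA` for OLS), `n_cells`, `significant` (`p < 0.05`), `converged`.
#' @export
fit_latitudinal_trend <- function(partition, response,
                                  hemisphere = c("north", "south"),
                                  method = c("ols", "sar"),
                                  kernel = NULL,
                                  weights = NULL, ev = NULL) {
  stopifnot(inherits(partition, "partition_table"))
  hemisphere <- match.arg(hemisphere)
  method <- match.arg(method)
  if (!response %in% .TREND_RESPONSES) {
    stop("response must be one of ",
         paste(.TREND_RESPONSES, collapse = ", "), call. = FALSE)
  }
  if (is.null(kernel)) kernel <- attr(partition, "kernel")
  stopifnot(inherits(kernel, "kernel_spec"))
  sub <- if (hemisphere == "north") {
    partition[partition$lat_deg >= 0, , drop = FALSE]
  } else {
    partition[partition$lat_deg < 0, , drop = FALSE]
  }
  sub <- sub[!is.na(sub[[response]]), , drop = FALSE]
  n <- nrow(sub)
  if (n < 10) {
    stop("fewer than 10 usable cells in the ", hemisphere,
         " hemisphere for response ", response, call. = FALSE)
  }
  yz <- zscore(sub[[response]])
  xz <- zscore(abs(sub$lat_deg))
  rho <- NA_real_
  converged <- TRUE
  if (method == "ols") {
    fit <- lm(yz ~ xz)
    sm <- summary(fit)$coefficients
    slope <- sm["xz", "Estimate"]
    p <- sm["xz", "Pr(>|t|)"]
  } else {
    if (is.null(weights)) {
      weights <- build_weights(sub, kernel, include_self = FALSE,
                               row_standardize = TRUE)
    }
    fit <- fit_sar_lag(yz, cbind(`(Intercept)` = 1, xz = xz), weights,
                       ev = ev)
    slope <- unname(fit$beta["xz"])
    p <- unname(fit$p_values["xz"])
    rho <- fit$rho
    converged <- fit$converged
    if (!converged) {
      warning("SAR fit did not converge for ", response, " / ",
              hemisphere, " / ", format(kernel), call. = FALSE)
    }
  }
  data.frame(response = response,
             hemisphere = hemisphere,
             method = method,
             kernel = kernel$family,
             bandwidth_km = kernel$bandwidth_km,
             slope = slope,
             p_value = p,
             rho = rho,
             n_cells = n,
             significant = p < 0.05,
             converged = converged,
             stringsAsFactors = FALSE)
}

#' Trend summary across responses, hemispheres, kernels and methods
#'
#' Runs [fit_latitudinal_trend()] for every combination of the four
#' responses, the two hemispheres, the supplied kernels and the chosen
#' methods.  SAR weights and eigenvalues are built once per
#' (kernel, hemisphere, usable-cell subset) and shared across responses.
#'
#' @param partitions a named list of `partition_table`s, one per kernel
#'   configuration (names like `"bisquare_1200"`).
#' @param methods subset of `c("ols", "sar")`.
#' @return A data frame of trend rows (4 responses x 2 hemispheres x
#'   kernels x methods) with a `config` column naming the kernel
#'   configuration; `significant` flags `p < 0.05`.
#' @export
trend_grid <- function(partitions, methods = c("ols", "sar")) {
  stopifnot(is.list(partitions), length(partitions) > 0)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(partitions))) {
    names(partitions) <- vapply(partitions, function(p) {
      format(attr(p, "kernel"))
    }, character(1))
  }
  rows <- list()
  for (cfg in names(partitions)) {
    part <- partitions[[cfg]]
    kernel <- attr(part, "kernel")
    for (hemi in c("north", "south")) {
      # cache SAR weights per usable-subset pattern within this hemisphere
      w_cache <- list()
      for (resp in .TREND_RESPONSES) {
        for (m in methods) {
          w <- NULL; ev <- NULL
          if (m == "sar") {
            sub <- if (hemi == "north") {
              part[part$lat_deg >= 0, , drop = FALSE]
            } else part[part$lat_deg < 0, , drop = FALSE]
            keep <- !is.na(sub[[resp]])
            key <- paste(which(keep), collapse = ",")
            if (is.null(w_cache[[key]])) {
              w_new <- build_weights(sub[keep, , drop = FALSE], kernel,
                                     include_self = FALSE,
                                     row_standardize = TRUE)
              w_cache[[key]] <- list(w = w_new,
                                     ev = sar_eigenvalues(w_new))
            }
            w <- w_cache[[key]]$w
            ev <- w_cache[[key]]$ev
          }
          row <- fit_latitudinal_trend(part, resp, hemi, m,
                                       kernel = kernel,
                                       weights = w, ev = ev)
          row$config <- cfg
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reshape trend results into the wide per-method table
#'
#' One row per (response, hemisphere), one column per kernel
#' configuration, values the standardized slopes with `*` marking
#' `p < 0.05` -- the familiar summary layout for reporting latitudinal
#' trends across kernels.
#'
#' @param grid output of [trend_grid()].
#' @param method `"ols"` or `"sar"`.
#' @return A data frame: `Model`, `Hemisphere`, then one slope column per
#'   kernel configuration.
#' @export
trend_table_wide <- function(grid, method = c("ols", "sar")) {
  method <- match.arg(method)
  g <- grid[grid$method == method, , drop = FALSE]
  if (nrow(g) == 0) stop("no rows for method ", method, call. = FALSE)
  labels <- c(R_e = "Energy (total)", R_pe = "Energy (pure)",
              R_w = "Water (total)", R_pw = "Water (pure)")
  configs <- unique(g$config)
  combos <- expand.grid(hemisphere = c("north", "south"),
                        response = names(labels),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$hemisphere == "south"), ]
  out <- data.frame(Model = labels[combos$response],
                    Hemisphere = ifelse(combos$hemisphere == "north",
                                        "North", "South"),
                    stringsAsFactors = FALSE)
  for (cfg in configs) {
    vals <- mapply(function(resp, hemi) {
      r <- g[g$response == resp & g$hemisphere == hemi & g$config == cfg, ]
      if (nrow(r) != 1) return(NA_character_)
      paste0(signif(r$slope, 3), if (r$significant) "*" else "")
    }, combos$response, combos$hemisphere)
    out[[cfg]] <- vals
  }
  rownames(out) <- NULL
  out
}
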