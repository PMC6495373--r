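# Logistic growth-curve fingerprinting: fit OD600 trajectories to the
# three-parameter logistic model, compare growth rates to a modern control
# strain, project fitted parameters by PCA and correlate the classification
# with vessel origin.

logistic_model <- function(t, K, N0, r) K / (1 + ((K - N0) / N0) * exp(-r * t))

#' Fit the three-parameter logistic growth model to an OD600 series
#'
#' Nonlinear least squares of
#' \deqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-r t})}
#' with carrying capacity `K` (OD600), initial size `N0` (OD600) and
#' intrinsic growth rate `r` (per hour). Initialization: `K` from the maximum
#' reading, `N0` from the first reading (clipped to >= 1e-6), `r` from the
#' slope of a linear fit to `log(N/(K - N))` over readings strictly between
#' 0 and `K`. Optimisation runs until the relative RSS change drops below
#' 1e-10 or 500 iterations ([minpack.lm::nlsLM]); non-convergence returns the
#' best point found with `converged = FALSE`.
#'
#' @param time numeric vector of times (hours), strictly increasing, >= 5 points.
#' @param od numeric vector of OD600 readings (>= 0), same length.
#' @param blank_correct subtract the first reading then clip at 1e-6 before
#'   fitting (baseline correction); default FALSE.
#' @return object of class `"logistic_fit"`: fields `K`, `N0`, `r`, `rss`,
#'   `converged`, `degenerate` (TRUE when the readings are constant and `r`
#'   is unidentifiable), plus the data. Methods: `print`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' t <- seq(0, 24, 2)
#' od <- 1.2 / (1 + ((1.2 - 0.05) / 0.05) * exp(-0.5 * t))
#' fit <- fit_logistic(t, od)
#' coef(fit)
#' @export
fit_logistic <- function(time, od, blank_correct = FALSE) {
  stopifnot(is.numeric(time), is.numeric(od))
  if (length(time) != length(od))
    stop_domain("fit_logistic: time and od lengths differ")
  if (length(time) < 5L)
    stop_domain("fit_logistic: need at least 5 time points")
  if (any(diff(time) <= 0))
    stop_domain("fit_logistic: times must be strictly increasing")
  if (any(!is.finite(time)) || any(!is.finite(od)) || any(od < 0))
    stop_domain("fit_logistic: readings must be finite and >= 0")
  if (blank_correct) od <- pmax(od - od[1L], 1e-6)

  out <- list(time = time, od = od, blank_correct = blank_correct)
  if (diff(range(od)) < .Machine$double.eps^0.5) {
    out <- c(out, list(K = od[1L], N0 = od[1L], r = NA_real_,
                       rss = 0, converged = FALSE, degenerate = TRUE))
    class(out) <- "logistic_fit"
    return(out)
  }

  K0 <- max(od)
  N00 <- max(od[1L], 1e-6)
  inside <- od > 0 & od < K0
  r0 <- if (sum(inside) >= 2L) {
    z <- log(od[inside] / (K0 - od[inside]))
    stats::coef(stats::lm(z ~ time[inside]))[[2L]]
  } else 0.5
  if (!is.finite(r0) || r0 <= 0) r0 <- 0.5

  fit <- tryCatch(
    minpack.lm::nlsLM(
      od ~ K / (1 + ((K - N0) / N0) * exp(-r * time)),
      start = list(K = K0 * 1.05, N0 = N00, r = r0),
      lower = c(K = 1e-8, N0 = 1e-8, r = -10),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)

  if (is.null(fit)) {
    out <- c(out, list(K = K0, N0 = N00, r = r0, rss = sum((od - logistic_model(
      time, K0, N00, r0))^2), converged = FALSE, degenerate = FALSE))
  } else {
    cf <- stats::coef(fit)
    out <- c(out, list(K = unname(cf["K"]), N0 = unname(cf["N0"]),
                       r = unname(cf["r"]),
                       rss = sum(stats::residuals(fit)^2),
                       converged = fit$convInfo$isConv %||% TRUE,
                       degenerate = FALSE))
  }
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic growth fit\n")
  if (x$degenerate) {
    cat("  degenerate: constant readings at", format(x$K), "(r unidentifiable)\n")
  } else {
    cat(sprintf("  K = %.4g OD600, N0 = %.4g OD600, r = %.4g /h\n",
                x$K, x$N0, x$r))
    cat(sprintf("  RSS = %.4g over %d points; converged: %s\n",
                x$rss, length(x$time), x$converged))
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(K = object$K, N0 = object$N0, r = object$r)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time else
    if (is.list(newdata)) newdata$time else newdata
  if (object$degenerate) return(rep(object$K, length(t)))
  logistic_model(t, object$K, object$N0, object$r)
}

#' @export
fitted.logistic_fit <- function(object, ...) predict(object)

#' @export
residuals.logistic_fit <- function(object, ...) object$od - fitted(object)

#' @export
plot.logistic_fit <- function(x, ...) {
  plot(x$time, x$od, xlab = "time (h)", ylab = "OD600", ...)
  tt <- seq(min(x$time), max(x$time), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Fit every strain x replicate growth curve in a long table
#'
#' @param curves data.frame with columns `strain`, `replicate`, `time_h`,
#'   `od600`.
#' @inheritParams fit_logistic
#' @return data.frame, one row per strain x replicate, with fitted `K`, `N0`,
#'   `r`, `rss`, and `converged`/`degenerate` flags.
#' @export
fit_growth_curves <- function(curves, blank_correct = FALSE) {
  need <- c("strain", "replicate", "time_h", "od600")
  if (!all(need %in% names(curves)))
    stop_domain("fit_growth_curves: curves must have columns ",
                paste(need, collapse = ", "))
  key <- interaction(curves$strain, curves$replicate, drop = TRUE)
  rows <- lapply(split(curves, key), function(g) {
    g <- g[order(g$time_h), ]
    f <- fit_logistic(g$time_h, g$od600, blank_correct = blank_correct)
    data.frame(strain = g$strain[1L], replicate = g$replicate[1L],
               K = f$K, N0 = f$N0, r = f$r, rss = f$rss,
               converged = f$converged, degenerate = f$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$strain, out$replicate), ]
}

#' Compare replicate growth rates of a strain against the control
#'
#' Two-sided Welch t test on the replicate-level fitted growth rates `r`.
#' Each side needs at least 3 replicates (each growth curve is backed by at
#' least 3 independent colonies).
#'
#' @param r_strain,r_control numeric vectors of replicate `r` values (per hour).
#' @return p-value in (0, 1].
#' @export
growth_rate_test <- function(r_strain, r_control) {
  r_strain <- r_strain[is.finite(r_strain)]
  r_control <- r_control[is.finite(r_control)]
  if (length(r_strain) < 3L || length(r_control) < 3L)
    stop_domain("growth_rate_test: need >= 3 replicates on each side")
  if (stats::var(r_strain) == 0 && stats::var(r_control) == 0) {
    return(if (isTRUE(all.equal(mean(r_strain), mean(r_control)))) 1 else
      .Machine$double.xmin)
  }
  stats::t.test(r_strain, r_control)$p.value
}

#' PCA of fitted growth parameters
#'
#' Centered principal-component decomposition of the per-strain parameter
#' vectors (K, N0, r); components are ordered by decreasing explained
#' variance. By default the covariance PCA of the raw parameters is used
#' (the stock `prcomp()` behaviour this analysis was built on), so the
#' parameter with the largest spread — the growth rate, under fermentation
#' screening conditions — dominates the distances; set `scale = TRUE` for
#' correlation PCA on standardized columns when the parameters should
#' contribute equally. Sign convention: within each component the
#' largest-magnitude loading is made positive, so scores are reproducible
#' across platforms. Zero-variance columns are dropped with a warning.
#'
#' @param params numeric matrix, strains (rows, named) x parameters (columns).
#' @param scale standardize columns to unit variance first; default FALSE.
#' @return list: `scores` (strains x components), `loadings` (orthonormal),
#'   `explained` (variance fractions summing to 1).
#' @export
pca_parameters <- function(params, scale = FALSE) {
  stopifnot(is.matrix(params))
  if (nrow(params) < 3L)
    stop_domain("pca_parameters: need >= 3 strains")
  sds <- apply(params, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(params)[sds == 0], collapse = ", "), call. = FALSE)
    params <- params[, sds > 0, drop = FALSE]
  }
  if (ncol(params) == 0L)
    stop_domain("pca_parameters: all columns have zero variance")
  pc <- stats::prcomp(params, center = TRUE, scale. = scale)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  list(scores = scores, loadings = rot,
       explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Classify strains by PCA distance to the control strain
#'
#' Euclidean distance in PCA score space to the control strain, combined
#' with the growth-rate p-value: a strain is called `"similar"` to the
#' control iff its p-value exceeds `alpha` (default 0.01), `"different"`
#' otherwise; both the distance and the p-value are reported.
#'
#' @param scores PCA score matrix from [pca_parameters()] (strains as rows).
#' @param control_strain row id of the control.
#' @param p_values named numeric vector of growth-rate p-values per strain
#'   (the control may be absent or NA).
#' @param alpha similarity threshold on p; default 0.01.
#' @return data.frame: `strain`, `distance`, `p_value`, `call`.
#' @export
distance_classify <- function(scores, control_strain, p_values, alpha = 0.01) {
  stopifnot(is.matrix(scores))
  if (!control_strain %in% rownames(scores))
    stop_domain("distance_classify: control strain '", control_strain,
                "' not in scores")
  delta <- sweep(scores, 2L, scores[control_strain, ], `-`)
  dist <- sqrt(rowSums(delta^2))
  p <- p_values[rownames(scores)]
  call <- ifelse(is.na(p), NA_character_,
                 ifelse(p > alpha, "similar", "different"))
  call[rownames(scores) == control_strain] <- "similar"
  data.frame(strain = rownames(scores), distance = unname(dist),
             p_value = unname(p), call = unname(call),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlation between growth-curve distance and vessel origin
#'
#' Point-biserial correlation between the (negated) distance to the control
#' strain and the binary beverage/non-beverage origin label, so strains that
#' grow like the modern beer control score high for beverage vessels.
#'
#' @param distance numeric vector of distances to the control.
#' @param beverage logical (or 0/1) vector: isolated from a putative
#'   beverage vessel?
#' @return correlation in \[-1, 1\].
#' @export
origin_correlation <- function(distance, beverage) {
  stopifnot(length(distance) == length(beverage))
  if (length(distance) < 3L)
    stop_domain("origin_correlation: need >= 3 strains")
  y <- as.numeric(beverage)
  if (length(unique(y)) < 2L)
    stop_domain("origin_correlation: both origin classes must be present")
  if (stats::sd(distance) == 0)
    stop_domain("origin_correlation: distances have zero variance")
  stats::cor(-distance, y)
}
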