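# Post-fermentation analytics: GC-MS relative peak areas, compound-matrix
# scaling, Ward clustering with bootstrap node support, beer colour scales,
# phenol-sulfuric carbohydrate quantitation, taste-sheet aggregation.

#' Ethanol-normalized relative GC-MS peak area
#'
#' The internal standard is the sample's ethanol peak, itself normalized by
#' the ethanol concentration determined by distillation: normalized ethanol
#' = `ethanol_area / ethanol_percent`. The relative peak area of a compound
#' is `compound_area / normalized ethanol x 1000` (the x1000 gives more
#' presentable numbers). Vectorized over `compound_area`.
#'
#' @param compound_area raw integrated peak area(s) of the compound (>= 0).
#' @param ethanol_area raw ethanol peak area (> 0).
#' @param ethanol_percent ethanol concentration in percent (> 0).
#' @return relative peak area(s), dimensionless.
#' @export
relative_peak_area <- function(compound_area, ethanol_area, ethanol_percent) {
  assert_scalar_number(ethanol_area, "ethanol_area")
  assert_scalar_number(ethanol_percent, "ethanol_percent")
  if (ethanol_area <= 0 || ethanol_percent <= 0)
    stop_domain("relative_peak_area: ethanol area and percent must be > 0")
  if (any(!is.finite(compound_area)) || any(compound_area < 0))
    stop_domain("relative_peak_area: compound areas must be finite and >= 0")
  compound_area / (ethanol_area / ethanol_percent) * 1000
}

#' Scale a compound matrix as percent of each compound's maximum
#'
#' Each compound (column) is divided by its maximum across samples and
#' multiplied by 100, putting all compounds on a common 0-100 scale for
#' heat maps and clustering. An all-zero compound column is left unchanged
#' and flagged with a warning.
#'
#' @param m numeric matrix, samples (rows) x compounds (columns), values >= 0.
#' @return matrix of the same shape with values in \[0, 100\]; attribute
#'   `"zero_columns"` lists any all-zero compounds.
#' @export
percent_of_max <- function(m) {
  stopifnot(is.matrix(m))
  if (any(!is.finite(m)) || any(m < 0))
    stop_domain("percent_of_max: values must be finite and >= 0")
  mx <- apply(m, 2L, max)
  zero <- mx == 0
  if (any(zero))
    warning("percent_of_max: all-zero compound column(s) left unchanged: ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  scale_by <- ifelse(zero, 1, mx)
  out <- sweep(m, 2L, scale_by, `/`) * 100
  out[, zero] <- m[, zero]
  attr(out, "zero_columns") <- colnames(m)[zero]
  out
}

#' Beer colour on the SRM and EBC scales
#'
#' Both scales are linear in the absorbance at 430 nm (10-mm cuvette):
#' SRM = absorbance x 12.7 and EBC = absorbance x 25.0.
#'
#' @param absorbance_430 absorbance reading(s) at 430 nm, >= 0.
#' @return list with `srm` and `ebc` (same length as the input).
#' @export
beer_color <- function(absorbance_430) {
  if (any(!is.finite(absorbance_430)) || any(absorbance_430 < 0))
    stop_domain("beer_color: absorbance must be finite and >= 0")
  list(srm = 12.7 * absorbance_430, ebc = 25.0 * absorbance_430)
}

#' Total carbohydrates by the phenol-sulfuric method
#'
#' Fits an ordinary least-squares calibration line of 485-nm absorbance on
#' glucose standard concentration, inverts the unknown's absorbance through
#' the line, and multiplies by the dilution factor (1 ml of beer made up to
#' 1 liter gives 1000). Standards are in ug/ml, so the diluted concentration
#' times the dilution factor divided by 1000 is reported in g/liter glucose
#' equivalents.
#'
#' @param standard_conc glucose standard concentrations (ug/ml), >= 2 distinct.
#' @param standard_abs matching 485-nm absorbances.
#' @param unknown_abs absorbance(s) of the diluted sample.
#' @param dilution_factor fold dilution of the original beverage; default 1000.
#' @return list: `g_per_liter`, `extrapolated` (readings outside the standard
#'   absorbance range), `slope`, `intercept`, `r_squared`.
#' @export
phenol_sulfuric_quantify <- function(standard_conc, standard_abs, unknown_abs,
                                     dilution_factor = 1000) {
  stopifnot(length(standard_conc) == length(standard_abs))
  if (length(unique(standard_conc)) < 2L)
    stop_domain("phenol_sulfuric_quantify: need >= 2 distinct standards")
  fit <- stats::lm(standard_abs ~ standard_conc)
  slope <- stats::coef(fit)[[2L]]
  intercept <- stats::coef(fit)[[1L]]
  if (abs(slope) < .Machine$double.eps)
    stop_domain("phenol_sulfuric_quantify: zero calibration slope")
  conc <- (unknown_abs - intercept) / slope            # ug/ml in the dilution
  extrap <- unknown_abs < min(standard_abs) | unknown_abs > max(standard_abs)
  if (any(extrap))
    warning("phenol_sulfuric_quantify: reading(s) outside the calibration ",
            "range; extrapolated", call. = FALSE)
  ss_tot <- sum((standard_abs - mean(standard_abs))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(g_per_liter = conc * dilution_factor / 1000,
       extrapolated = extrap, slope = slope, intercept = intercept,
       r_squared = r2)
}

#' Ward hierarchical clustering of a compound matrix
#'
#' Agglomerative clustering with the Ward variance-minimization criterion on
#' Euclidean distances (the `ward.D2` convention: distances enter the
#' criterion squared, merge heights stay on the Euclidean scale and are
#' monotone non-decreasing).
#'
#' @param m numeric matrix, samples x compounds.
#' @param axis cluster `"samples"` (rows, default) or `"compounds"` (columns).
#' @return an object of class `"hclust"`.
#' @export
ward_dendrogram <- function(m, axis = c("samples", "compounds")) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(m))
  x <- if (axis == "samples") m else t(m)
  if (nrow(x) < 2L)
    stop_domain("ward_dendrogram: need >= 2 items on the clustered axis")
  if (anyNA(x))
    stop_domain("ward_dendrogram: missing values; impute before clustering")
  stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
}

# leaf label set under each internal node of an hclust tree, in merge order
hclust_clades <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) hc$labels[-j] else sets[[j]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L])))
  }
  sets
}

#' Bootstrap support for dendrogram nodes (BP and AU)
#'
#' Resamples the features (the non-clustered axis) with replacement,
#' reclusters, and scores each internal node of the observed dendrogram.
#' `"bp"` support is the percentage of bootstrap dendrograms containing the
#' identical leaf set. `"au"` (approximately unbiased) support extends this
#' by multiscale bootstrap: the feature count is resampled at several scale
#' factors (0.5-1.4 of the original), the probit-transformed bootstrap
#' probabilities are regressed on the scale signature, and the support is
#' extrapolated from the fitted curvature; AU corrects the known bias of BP
#' for clusters with many competitors.
#'
#' @inheritParams ward_dendrogram
#' @param B bootstrap replicates (per scale for `"au"`); >= 100.
#' @param method `"bp"` (default) or `"au"`.
#' @param scales scale factors for the multiscale bootstrap (AU only).
#' @param seed optional integer seed for the resampling.
#' @return list of class `"cluster_support"`: `hclust` (the observed tree),
#'   `support` data.frame with the leaf set, support percentage in \[0,100\],
#'   and a `strong` flag for support > 95, plus `method` and `B`.
#' @export
cluster_support <- function(m, axis = c("samples", "compounds"), B = 1000,
                            method = c("bp", "au"),
                            scales = seq(0.5, 1.4, by = 0.1), seed = NULL) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (!is.numeric(B) || B < 100)
    stop_domain("cluster_support: B must be >= 100")
  x <- if (axis == "samples") m else t(m)
  if (ncol(x) < 2L)
    stop_domain("cluster_support: need >= 2 features to resample")
  if (!is.null(seed)) set.seed(seed)

  hc <- ward_dendrogram(m, axis = axis)
  clades <- hclust_clades(hc)
  keys <- vapply(clades, paste, character(1), collapse = "\r")

  boot_counts <- function(n_feat) {
    hits <- numeric(length(keys))
    for (b in seq_len(B)) {
      idx <- sample.int(ncol(x), n_feat, replace = TRUE)
      hb <- stats::hclust(stats::dist(x[, idx, drop = FALSE]), method = "ward.D2")
      kb <- vapply(hclust_clades(hb), paste, character(1), collapse = "\r")
      hits <- hits + (keys %in% kb)
    }
    hits / B
  }

  if (method == "bp") {
    support <- boot_counts(ncol(x)) * 100
  } else {
    n_feats <- pmax(2L, round(scales * ncol(x)))
    bp <- vapply(n_feats, boot_counts, numeric(length(keys)))
    rho <- n_feats / ncol(x)                 # realized scales
    support <- vapply(seq_along(keys), function(i) {
      if (all(bp[i, ] >= 1)) return(100)   # present in every replicate at
      if (all(bp[i, ] <= 0)) return(0)     # every scale: probit fit degenerate
      p <- pmin(pmax(bp[i, ], 1 / (2 * B)), 1 - 1 / (2 * B))
      z <- stats::qnorm(1 - p)               # z(rho) = v/sqrt(rho) + c*sqrt(rho)
      X <- cbind(1 / sqrt(rho), sqrt(rho))
      cf <- tryCatch(stats::coef(stats::lm.fit(X, z)), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) return(mean(bp[i, rho == 1]) * 100)
      100 * (1 - stats::pnorm(cf[1L] - cf[2L]))
    }, numeric(1))
  }
  structure(list(hclust = hc,
                 support = data.frame(
                   node = seq_along(keys),
                   leaves = vapply(clades, paste, character(1), collapse = ","),
                   support = support, strong = support > 95,
                   stringsAsFactors = FALSE),
                 method = method, B = B),
            class = "cluster_support")
}

#' @export
print.cluster_support <- function(x, ...) {
  cat(sprintf("Dendrogram node support (%s, B = %d)\n", x$method, x$B))
  print(x$support, row.names = FALSE)
  invisible(x)
}

#' Aggregate taste sheets into a mean score per attribute
#'
#' Scores are on the 1-5 tasting scale; attribute names are normalized
#' case-insensitively (trimmed, lowercased) before averaging across tasters.
#'
#' @param sheets data.frame with columns `taster`, `attribute`, `score`.
#' @return list: `profile` (named numeric, mean score per attribute, sorted
#'   by attribute) and `coverage` (attribute x taster logical matrix of who
#'   scored what).
#' @export
taste_profile <- function(sheets) {
  need <- c("taster", "attribute", "score")
  if (!all(need %in% names(sheets)) || nrow(sheets) == 0L)
    stop_domain("taste_profile: need >= 1 row with columns ",
                paste(need, collapse = ", "))
  bad <- which(!is.finite(sheets$score) | sheets$score < 1 | sheets$score > 5 |
                 sheets$score != round(sheets$score))
  if (length(bad)) {
    i <- bad[1L]
    stop_domain("taste_profile: invalid score ", sheets$score[i],
                " from taster '", sheets$taster[i], "' on attribute '",
                sheets$attribute[i], "' (must be an integer in 1..5)")
  }
  attr_norm <- tolower(trimws(sheets$attribute))
  profile <- tapply(sheets$score, attr_norm, mean)
  profile <- profile[order(names(profile))]
  coverage <- table(attr_norm, sheets$taster) > 0
  list(profile = c(profile), coverage = coverage)
}
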