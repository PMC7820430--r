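# Soil health index construction: standardization, correlation-matrix PCA,
# PC retention, minimum-data-set (MDS) indicator selection by the
# within-10%-of-top-loading rule, linear 0-1 scoring, PC-variance weighting
# and the weighted additive index SHI = sum(w_i * s_i).

#' Standardize trial attributes to z-scores
#'
#' Centers and scales each attribute column to mean 0, SD 1 (denominator
#' n - 1), the prerequisite for correlation-matrix PCA.
#'
#' @param table A trial table or data frame (typically one season's rows).
#' @param attributes Attribute columns to use; default all 14.
#' @return Numeric matrix (observations x attributes).
#' @export
standardize <- function(table, attributes = soil_attributes()) {
  df <- as.data.frame(table)
  missing_cols <- setdiff(attributes, names(df))
  if (length(missing_cols) > 0L) {
    stop("unknown attribute(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(df[attributes])
  if (!is.numeric(x) || anyNA(x)) {
    stop("attributes must be complete numeric columns", call. = FALSE)
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance attribute(s): ",
         paste(attributes[sds == 0], collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Principal component analysis of standardized attributes
#'
#' Eigendecomposition of the sample correlation matrix. Eigenvalues come
#' out descending and sum to the number of attributes; loadings are unit
#' eigenvectors with the sign convention that each PC's largest-magnitude
#' loading is positive, so selections are reproducible across eigensolvers.
#'
#' @param z Standardized matrix from [standardize()].
#' @return Object of class `"shi_pca"`: `eigenvalues`, `proportion`,
#'   `cumulative`, `loadings` (attribute x PC), `n_obs`, `correlation`.
#' @export
run_pca <- function(z) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) stop("non-finite entries in z", call. = FALSE)
  if (nrow(z) <= ncol(z)) {
    warning("fewer observations than attributes + 1; PCA is rank-deficient")
  }
  C <- stats::cor(z)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  V <- e$vectors
  for (k in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, k])), k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(z), paste0("PC", seq_len(ncol(V))))
  structure(list(eigenvalues = lam, proportion = lam / sum(lam),
                 cumulative = cumsum(lam / sum(lam)), loadings = V,
                 n_obs = nrow(z), correlation = C),
            class = "shi_pca")
}

#' @export
print.shi_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA of %d attributes (n = %d)\n",
              length(x$eigenvalues), x$n_obs))
  print(data.frame(PC = seq_along(x$eigenvalues),
                   eigenvalue = round(x$eigenvalues, 3),
                   proportion = round(x$proportion, 3),
                   cumulative = round(x$cumulative, 3)), row.names = FALSE)
  invisible(x)
}

#' Retain principal components by eigenvalue and variance share
#'
#' Keeps PCs whose eigenvalue reaches `eigen_min` and whose variance share
#' strictly exceeds `var_min`. The defaults (eigenvalue >= 1, share > 5%)
#' are the usual index-construction retention rule; `eigen_min = 0.99`
#' reproduces a slightly laxer "eigenvalue > 0.99" run.
#'
#' @param pca A [run_pca()] result.
#' @param eigen_min Minimum eigenvalue (inclusive), default 1.0.
#' @param var_min Variance-share threshold (exclusive), default 0.05.
#' @return Integer vector of retained PC indices, in order; empty (with a
#'   warning) if nothing qualifies.
#' @export
retain_pcs <- function(pca, eigen_min = 1.0, var_min = 0.05) {
  stopifnot(inherits(pca, "shi_pca"), eigen_min > 0, var_min > 0)
  keep <- which(pca$eigenvalues >= eigen_min & pca$proportion > var_min)
  if (length(keep) == 0L) warning("no principal component meets the ",
                                  "retention thresholds")
  keep
}

#' Select minimum-data-set indicators from retained PCs
#'
#' Per retained PC (in order), the attribute with the highest absolute
#' loading is selected together with every attribute whose absolute loading
#' is within `within_frac` of that maximum (|loading| >= (1 - within_frac)
#' x max, inclusive at the boundary; ties keep input-attribute order). An
#' attribute already selected from an earlier PC is excluded from later
#' PCs' candidate sets. If `redundancy_r` is set, co-selected attributes of
#' one PC correlated above it (in `pca$correlation`) are pruned down to the
#' highest-loading one.
#'
#' @param pca A [run_pca()] result.
#' @param retained PC indices from [retain_pcs()]; must be non-empty.
#' @param within_frac Loading proximity fraction, default 0.10.
#' @param redundancy_r Optional absolute-correlation cutoff for within-PC
#'   redundancy pruning; `NULL` (default) disables pruning.
#' @return Object of class `"mds_selection"`: data frame `indicator`, `pc`,
#'   `loading`, `weight` (NA until [compute_weights()]), with the
#'   thresholds as attributes.
#' @export
select_indicators <- function(pca, retained, within_frac = 0.10,
                              redundancy_r = NULL) {
  stopifnot(inherits(pca, "shi_pca"))
  if (length(retained) == 0L) {
    stop("no retained PCs to select indicators from", call. = FALSE)
  }
  attrs <- rownames(pca$loadings)
  chosen <- character(0)
  rows <- list()
  for (k in retained) {
    cand <- setdiff(attrs, chosen)
    if (length(cand) == 0L) break
    lo <- abs(pca$loadings[cand, k])
    top <- max(lo)
    sel <- cand[lo >= (1 - within_frac) * top]   # inclusive boundary
    sel <- sel[order(match(sel, attrs))]          # stable input order
    if (!is.null(redundancy_r) && length(sel) > 1L) {
      keep <- sel[which.max(abs(pca$loadings[sel, k]))]
      for (a in setdiff(sel, keep)) {
        if (all(abs(pca$correlation[a, keep]) <= redundancy_r)) {
          keep <- c(keep, a)
        }
      }
      sel <- sel[sel %in% keep]
    }
    for (a in sel) {
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = a, pc = k, loading = unname(pca$loadings[a, k]),
        weight = NA_real_, stringsAsFactors = FALSE)
    }
    chosen <- c(chosen, sel)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("mds_selection", "data.frame"),
            within_frac = within_frac, redundancy_r = redundancy_r,
            retained = retained)
}

#' @export
print.mds_selection <- function(x, ...) {
  cat("Minimum data set (within-", 100 * attr(x, "within_frac"),
      "% loading rule)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Scoring directions for the MDS indicators
#'
#' Direction of each indicator's linear scoring function: `more_is_better`
#' (score rises with the value), `less_is_better` (falls), or `optimum`
#' (peaks at a midpoint). Defaults: salinity (`ec_e`) and alkalinity
#' (`ph_s`) are less-is-better stressors; nutrients, organic C, microbial
#' biomass and enzyme activities are more-is-better; the `mbcn` ratio is
#' scored `optimum` at the observed median (a balanced microbial C:N is
#' taken as healthiest; flagged in output since the convention is a
#' package default, not a measured property).
#'
#' @param directions Named character vector overriding defaults.
#' @param optimum_midpoints Named numeric vector of fixed midpoints for
#'   `optimum` indicators; indicators not named here use the data median.
#' @return Object of class `"scoring_spec"`.
#' @export
scoring_spec <- function(directions = NULL, optimum_midpoints = NULL) {
  dir <- c(ph_s = "less_is_better", ec_e = "less_is_better",
           wboc = "more_is_better", kmno4_n = "more_is_better",
           olsen_p = "more_is_better", nh4oac_k = "more_is_better",
           mbc = "more_is_better", mbn = "more_is_better",
           mbcn = "optimum", dha = "more_is_better",
           alp = "more_is_better", ur = "more_is_better",
           alpha_glu = "more_is_better", beta_glu = "more_is_better")
  if (!is.null(directions)) {
    ok <- c("more_is_better", "less_is_better", "optimum")
    if (!all(directions %in% ok)) {
      stop("directions must be one of: ", paste(ok, collapse = ", "),
           call. = FALSE)
    }
    dir[names(directions)] <- directions
  }
  structure(list(directions = dir,
                 optimum_midpoints = optimum_midpoints),
            class = "scoring_spec")
}

#' Linear 0-1 scores for the selected indicators
#'
#' Transforms each MDS indicator onto a normalized 0-1 scale with a linear
#' scoring function. With `method = "minmax"` (default):
#' more-is-better `s = (x - min) / (max - min)`, less-is-better
#' `s = (max - x) / (max - min)`, optimum `s = max(0, 1 - |x - mid| / h)`
#' with `h` the larger distance from the midpoint to either bound. The
#' `"ratio"` variant (`x / max`, `min / x`) is provided for sensitivity
#' analysis. Bounds default to the observed minimum/maximum of the table
#' (per season, i.e. of whatever rows are passed in) and can be fixed via
#' `bounds`.
#'
#' @param table Trial table (or one season's rows).
#' @param selection An `"mds_selection"`.
#' @param spec A [scoring_spec()].
#' @param method `"minmax"` (default) or `"ratio"`.
#' @param bounds Optional named list `indicator -> c(min, max)` overriding
#'   observed bounds.
#' @return Matrix (observations x indicators) of scores in `[0, 1]`,
#'   classed `"score_table"`, with the bounds used as an attribute.
#' @export
score_indicators <- function(table, selection, spec = scoring_spec(),
                             method = c("minmax", "ratio"), bounds = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(selection, "mds_selection"))
  df <- as.data.frame(table)
  inds <- selection$indicator
  miss <- setdiff(inds, names(df))
  if (length(miss) > 0L) {
    stop("table lacks selected indicator(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  no_dir <- setdiff(inds, names(spec$directions))
  if (length(no_dir) > 0L) {
    stop("no scoring direction for: ", paste(no_dir, collapse = ", "),
         call. = FALSE)
  }
  scores <- matrix(NA_real_, nrow(df), length(inds),
                   dimnames = list(NULL, inds))
  used_bounds <- list()
  for (a in inds) {
    x <- df[[a]]
    b <- if (!is.null(bounds) && a %in% names(bounds)) bounds[[a]]
         else range(x)
    lo <- b[1L]; hi <- b[2L]
    if (hi <= lo) {
      stop("degenerate scoring bounds for '", a, "' (max <= min)",
           call. = FALSE)
    }
    used_bounds[[a]] <- c(min = lo, max = hi)
    d <- spec$directions[[a]]
    s <- switch(d,
      more_is_better = if (method == "minmax") (x - lo) / (hi - lo)
                       else x / hi,
      less_is_better = if (method == "minmax") (hi - x) / (hi - lo)
                       else lo / x,
      optimum = {
        mid <- if (!is.null(spec$optimum_midpoints) &&
                   a %in% names(spec$optimum_midpoints))
          spec$optimum_midpoints[[a]] else stats::median(x)
        h <- max(mid - lo, hi - mid)
        pmax(0, 1 - abs(x - mid) / h)
      })
    scores[, a] <- pmin(pmax(s, 0), 1)
  }
  structure(scores, class = c("score_table", class(scores)),
            bounds = used_bounds, method = method)
}

#' Assign PC-variance weights to the selected indicators
#'
#' Every indicator selected from a PC receives that PC's full variance
#' share as its weight `w_i` (weights are not split among co-selected
#' indicators). With `normalize = FALSE` (default) the weight is the raw
#' proportion of total variance the source PC explains, so the weights of
#' an index need not sum to 1; with `normalize = TRUE` shares are divided
#' by the cumulative share of all retained PCs, making the distinct PC
#' weights sum to 1.
#'
#' @param pca A [run_pca()] result.
#' @param selection An `"mds_selection"` from [select_indicators()].
#' @param normalize Rescale by the retained PCs' cumulative share.
#' @return The selection with its `weight` column filled in.
#' @export
compute_weights <- function(pca, selection, normalize = FALSE) {
  stopifnot(inherits(pca, "shi_pca"), inherits(selection, "mds_selection"))
  if (nrow(selection) == 0L) stop("empty selection", call. = FALSE)
  prop <- pca$proportion
  w <- prop[selection$pc]
  if (normalize) {
    retained <- attr(selection, "retained")
    w <- w / sum(prop[retained])
  }
  selection$weight <- as.numeric(w)
  selection
}

#' Weighted additive soil health index
#'
#' Per observation, `SHI = sum_i w_i * s_i` over the selected indicators,
#' so SHI lies in `[0, sum(w_i)]` (the upper bound is attained when every
#' score is 1).
#'
#' @param scores A `"score_table"` from [score_indicators()].
#' @param selection A weighted `"mds_selection"` (after
#'   [compute_weights()]).
#' @return Numeric vector of per-observation SHI values, with the total
#'   weight `sum(w)` as attribute `"max_shi"`.
#' @export
compute_shi <- function(scores, selection) {
  stopifnot(inherits(selection, "mds_selection"))
  if (anyNA(selection$weight)) {
    stop("selection has no weights; run compute_weights() first",
         call. = FALSE)
  }
  miss <- setdiff(selection$indicator, colnames(scores))
  if (length(miss) > 0L) {
    stop("scores missing for indicator(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- unclass(scores)[, selection$indicator, drop = FALSE]
  shi <- as.numeric(s %*% selection$weight)
  attr(shi, "max_shi") <- sum(selection$weight)
  shi
}

#' Ordinary least squares of yield on the soil health index
#'
#' Simple linear regression `yield = intercept + slope * SHI`, reporting
#' the slope, intercept, coefficient of determination and the slope's
#' p-value.
#'
#' @param shi Numeric SHI vector.
#' @param yield Numeric yield vector of equal length (NA pairs dropped).
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
shi_yield_regression <- function(shi, yield) {
  ok <- is.finite(shi) & is.finite(yield)
  shi <- shi[ok]; yield <- yield[ok]
  if (length(shi) < 3L) stop("need at least 3 paired observations",
                             call. = FALSE)
  if (stats::var(shi) == 0) stop("SHI has zero variance", call. = FALSE)
  fit <- stats::lm(yield ~ shi)
  n <- length(shi)
  slope <- unname(stats::coef(fit)[2L])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((yield - mean(yield))^2)
  # R^2 and the slope test computed directly: a constant yield has R^2 = 0
  # by convention, and an exact fit must not trip lm's near-singular summary
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  ssx <- sum((shi - mean(shi))^2)
  se2 <- ss_res / (n - 2L) / ssx
  p <- if (ss_tot == 0) 1
       else if (se2 == 0) 0
       else 2 * stats::pt(-abs(slope / sqrt(se2)), n - 2L)
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, p_value = p, n = n)
}

#' End-to-end soil health index for one season
#'
#' Runs the full construction on one season's rows: standardize the 14
#' attributes, correlation-matrix PCA, PC retention, MDS selection, PC
#' variance weighting, linear scoring and the weighted sum.
#'
#' @inheritParams retain_pcs
#' @inheritParams select_indicators
#' @inheritParams score_indicators
#' @inheritParams compute_weights
#' @param table A trial table covering the season.
#' @param season `"sorghum"` or `"wheat"`.
#' @return Object of class `"shi_result"`: the season subset (`data`, with
#'   an appended `shi` column), `pca`, `retained`, `selection`, `scores`,
#'   `shi` and `season`.
#' @export
build_shi <- function(table, season, eigen_min = 1.0, var_min = 0.05,
                      within_frac = 0.10, redundancy_r = NULL,
                      spec = scoring_spec(), method = "minmax",
                      normalize = FALSE) {
  df <- as.data.frame(table)
  season <- match.arg(season, design_levels()$season)
  df <- df[as.character(df$season) == season, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for season '", season, "'", call. = FALSE)
  z <- standardize(df)
  pca <- run_pca(z)
  retained <- retain_pcs(pca, eigen_min = eigen_min, var_min = var_min)
  if (length(retained) == 0L) {
    stop("no PCs retained at eigen_min = ", eigen_min, ", var_min = ",
         var_min, "; cannot build an index", call. = FALSE)
  }
  sel <- select_indicators(pca, retained, within_frac = within_frac,
                           redundancy_r = redundancy_r)
  sel <- compute_weights(pca, sel, normalize = normalize)
  scores <- score_indicators(df, sel, spec = spec, method = method)
  shi <- compute_shi(scores, sel)
  df$shi <- shi
  structure(list(data = df, pca = pca, retained = retained, selection = sel,
                 scores = scores, shi = shi, season = season,
                 max_shi = attr(shi, "max_shi")),
            class = "shi_result")
}

#' @export
print.shi_result <- function(x, ...) {
  cat(sprintf("Soil health index, %s season (n = %d)\n", x$season,
              nrow(x$data)))
  cat(sprintf("  retained PCs: %s (%.1f%% of variance)\n",
              paste(x$retained, collapse = ", "),
              100 * sum(x$pca$proportion[x$retained])))
  cat("  MDS: ", paste(sprintf("%s (PC%d, w = %.3f)", x$selection$indicator,
                               x$selection$pc, x$selection$weight),
                       collapse = ", "), "\n", sep = "")
  cat(sprintf("  SHI range %.3f-%.3f of maximum %.3f\n",
              min(x$shi), max(x$shi), x$max_shi))
  invisible(x)
}
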