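# Split-factorial (split-plot) ANOVA with whole-plot and subplot error
# strata, Tukey HSD compact letters and LSD interaction comparisons.
#
# Main plots carry tillage (within blocks, crossed with year); the
# irrigation x mulch factorial sits on subplots. Replication, year, tillage
# and year x tillage are tested against the whole-plot residual ("Error (a)");
# every term involving irrigation or mulch against the subplot residual.

anova_term_order <- function(has_year) {
  wp <- c("Replication", if (has_year) c("Year", "Tillage", "Year:Tillage")
          else "Tillage")
  sp <- c("Irrigation", "Mulch", "Irrigation:Mulch")
  if (has_year) {
    sp <- c(sp, "Year:Irrigation", "Tillage:Irrigation",
            "Year:Tillage:Irrigation", "Year:Mulch", "Tillage:Mulch",
            "Year:Tillage:Mulch", "Year:Irrigation:Mulch",
            "Tillage:Irrigation:Mulch", "Year:Tillage:Irrigation:Mulch")
  } else {
    sp <- c(sp, "Tillage:Irrigation", "Tillage:Mulch",
            "Tillage:Irrigation:Mulch")
  }
  list(whole_plot = wp, subplot = sp)
}

#' Degrees-of-freedom skeleton of the split-factorial ANOVA
#'
#' Computes every term's degrees of freedom for a balanced split-factorial
#' design from the standard counting rules: main effects have (levels - 1),
#' interactions the product of their components, the whole-plot error
#' ("Error (a)") takes (whole-plot units - 1) minus the whole-plot term df,
#' and the subplot error absorbs the remainder of N - 1. For the reference
#' design (3 blocks, 2 years, 3 tillage, 3 irrigation, 2 mulch) Error (a)
#' has 10 df and the subplot error 60.
#'
#' @param n_blocks,n_years,n_tillage,n_irrigation,n_mulch Level counts.
#'   `n_years = 1` drops the year terms; all other factors and the
#'   replication count must have at least 2 levels.
#' @return Data frame with columns `term`, `df`, `stratum`
#'   (`whole_plot` / `subplot` / `error`).
#' @export
build_anova_skeleton <- function(n_blocks = 3, n_years = 2, n_tillage = 3,
                                 n_irrigation = 3, n_mulch = 2) {
  if (n_blocks < 2 || n_tillage < 2 || n_irrigation < 2 || n_mulch < 2) {
    stop("degenerate design: blocks, tillage, irrigation and mulch all ",
         "need at least 2 levels", call. = FALSE)
  }
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  has_year <- n_years > 1
  n <- c(Replication = n_blocks, Year = n_years, Tillage = n_tillage,
         Irrigation = n_irrigation, Mulch = n_mulch)
  term_df <- function(term) {
    prod(n[strsplit(term, ":")[[1]]] - 1L)
  }
  ord <- anova_term_order(has_year)
  wp_df <- vapply(ord$whole_plot, term_df, numeric(1))
  sp_df <- vapply(ord$subplot, term_df, numeric(1))
  n_wp_units <- n_blocks * n_years * n_tillage
  err_a <- (n_wp_units - 1) - sum(wp_df)
  N <- n_wp_units * n_irrigation * n_mulch
  err_b <- (N - 1) - sum(wp_df) - err_a - sum(sp_df)
  if (err_a < 1 || err_b < 1) {
    stop("design leaves no residual degrees of freedom in an error stratum",
         call. = FALSE)
  }
  data.frame(
    term = c(ord$whole_plot, "Error (a)", ord$subplot, "Error (b)"),
    df = as.integer(c(wp_df, err_a, sp_df, err_b)),
    stratum = c(rep("whole_plot", length(wp_df)), "error",
                rep("subplot", length(sp_df)), "error"),
    stringsAsFactors = FALSE
  )
}

# canonical term label from an aov term string like "year:tillage"
canonical_term <- function(x) {
  pretty <- c(block = "Replication", year = "Year", tillage = "Tillage",
              irrigation = "Irrigation", mulch = "Mulch")
  parts <- pretty[strsplit(x, ":")[[1]]]
  ord <- c("Replication", "Year", "Tillage", "Irrigation", "Mulch")
  paste(parts[order(match(parts, ord))], collapse = ":")
}

#' Significance stars for p-values
#'
#' `***`, `**`, `*` at 0.001, 0.01, 0.05 and `NS` above 0.05.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
p_stars <- function(p) {
  out <- ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "NS")))
  out[is.na(p)] <- ""
  out
}

#' Fit the split-factorial ANOVA for one response
#'
#' Decomposes a balanced trial's response into the full set of design terms
#' via `stats::aov` with an `Error(block:year:tillage)` whole-plot stratum.
#' Replication, year, tillage and year x tillage are tested against the
#' whole-plot residual mean square; all terms involving irrigation or mulch
#' against the subplot residual. Only balanced complete data are supported;
#' imbalance is an error.
#'
#' @param table A `trial_table` (or validatable data frame).
#' @param response Attribute or yield column to analyse.
#' @param season `"sorghum"` or `"wheat"`.
#' @return Object of class `"split_anova"`: a data frame `table` with
#'   columns `term`, `df`, `ss`, `ms`, `F`, `p`, `stars`, `stratum`, plus
#'   the error mean squares/df of both strata and the grand design counts.
#' @export
fit_split_factorial_anova <- function(table, response, season) {
  df <- as.data.frame(table)
  season <- match.arg(season, design_levels()$season)
  if (!response %in% names(df)) {
    stop("unknown response column: ", response, call. = FALSE)
  }
  df <- df[as.character(df$season) == season, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for season '", season, "'", call. = FALSE)
  for (f in c("block", "year", "tillage", "irrigation", "mulch")) {
    df[[f]] <- factor(as.character(df[[f]]))
  }
  counts <- table(df$block, df$year, df$tillage, df$irrigation, df$mulch)
  if (any(counts != 1L)) {
    stop("unbalanced table: every block x year x tillage x irrigation x ",
         "mulch cell must appear exactly once", call. = FALSE)
  }
  if (anyNA(df[[response]])) {
    stop("response '", response, "' has missing values", call. = FALSE)
  }
  has_year <- nlevels(df$year) > 1
  y <- df[[response]]
  if (has_year) {
    fml <- y ~ block + year * tillage * irrigation * mulch +
      Error(block:year:tillage)
  } else {
    fml <- y ~ block + tillage * irrigation * mulch + Error(block:tillage)
  }
  # block enters both as a fixed term and inside the error structure, which
  # aov flags as a singular Error() model; the projection is still the
  # standard balanced split-plot decomposition, so silence that warning only
  fit <- withCallingHandlers(
    stats::aov(fml, data = df),
    warning = function(w) {
      if (grepl("Error() model is singular", conditionMessage(w),
                fixed = TRUE)) invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  rows <- list()
  err <- list()
  for (stratum_name in names(sm)) {
    tab <- sm[[stratum_name]][[1L]]
    terms_raw <- trimws(rownames(tab))
    is_wp <- grepl("block:", gsub("Error: ", "", stratum_name), fixed = TRUE)
    for (i in seq_along(terms_raw)) {
      tn <- terms_raw[i]
      if (tn == "Residuals") {
        key <- if (is_wp) "a" else "b"
        err[[key]] <- list(ss = tab[i, "Sum Sq"], df = tab[i, "Df"],
                           ms = tab[i, "Sum Sq"] / tab[i, "Df"])
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          term = canonical_term(tn), df = tab[i, "Df"],
          ss = tab[i, "Sum Sq"],
          stratum = if (is_wp) "whole_plot" else "subplot",
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  ord <- anova_term_order(has_year)
  res <- res[match(c(ord$whole_plot, ord$subplot), res$term), ]
  res$ms <- res$ss / res$df
  ms_err <- ifelse(res$stratum == "whole_plot", err$a$ms, err$b$ms)
  df_err <- ifelse(res$stratum == "whole_plot", err$a$df, err$b$df)
  res$F <- res$ms / ms_err
  res$p <- stats::pf(res$F, res$df, df_err, lower.tail = FALSE)
  res$stars <- p_stars(res$p)
  err_rows <- data.frame(
    term = c("Error (a)", "Error (b)"), df = c(err$a$df, err$b$df),
    ss = c(err$a$ss, err$b$ss), stratum = "error",
    ms = c(err$a$ms, err$b$ms), F = NA_real_, p = NA_real_, stars = "",
    stringsAsFactors = FALSE)
  # interleave Error (a) after the whole-plot terms, as trial reports do
  n_wp <- sum(res$stratum == "whole_plot")
  out <- rbind(res[seq_len(n_wp), ], err_rows[1L, names(res)],
               res[-seq_len(n_wp), ], err_rows[2L, names(res)])
  rownames(out) <- NULL
  structure(list(table = out, response = response, season = season,
                 n = nrow(df),
                 ms_error_a = err$a$ms, df_error_a = err$a$df,
                 ms_error_b = err$b$ms, df_error_b = err$b$df,
                 ss_total = sum(out$ss)),
            class = "split_anova")
}

#' @export
print.split_anova <- function(x, ...) {
  cat(sprintf("Split-factorial ANOVA: %s (%s season, n = %d)\n",
              x$response, x$season, x$n))
  tab <- x$table
  tab$ss <- signif(tab$ss, 5)
  tab$ms <- signif(tab$ms, 5)
  tab$F <- round(tab$F, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

# compact letter display for a common significance threshold: on means
# sorted descending, non-significance is an interval property, so maximal
# runs of mutually non-separated means become the letter groups
cld_from_threshold <- function(means, threshold) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  groups <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && abs(m[i] - m[j + 1L]) <= threshold) j <- j + 1L
    groups[[length(groups) + 1L]] <- i:j
  }
  # absorb intervals contained in an earlier one
  keep <- rep(TRUE, length(groups))
  for (g in seq_along(groups)) {
    for (h in seq_along(groups)) {
      if (g != h && keep[h] &&
          all(groups[[g]] %in% groups[[h]]) &&
          length(groups[[g]]) < length(groups[[h]])) keep[g] <- FALSE
    }
  }
  groups <- unique(groups[keep])
  letters_out <- character(k)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    letters_out[idx] <- paste0(letters_out[idx], LETTERS[g])
  }
  res <- character(k)
  res[ord] <- letters_out
  res
}

#' Tukey HSD mean separation with compact letters
#'
#' Computes the honest significant difference
#' `HSD = q(1 - alpha; k, df_error) * sqrt(ms_error / n_per_level)` from a
#' caller-supplied error stratum and assigns compact letters: levels whose
#' means differ by more than the HSD get different letters; letters run A,
#' B, ... in descending-mean order.
#'
#' @param means Named numeric vector of level means (display order kept).
#' @param ms_error Error mean square of the appropriate stratum (> 0).
#' @param df_error Its degrees of freedom (>= 1).
#' @param n_per_level Observations per level mean (>= 2).
#' @param alpha Family-wise significance level, default 0.05.
#' @return Object of class `"mean_separation"`: data frame `level`, `mean`,
#'   `letter` plus attributes `hsd`, `alpha`, `ms_error`, `df_error`.
#' @export
tukey_hsd <- function(means, ms_error, df_error, n_per_level, alpha = 0.05) {
  if (!all(is.finite(means)) || !is.finite(ms_error) || ms_error <= 0 ||
      !is.finite(df_error) || df_error < 1 || n_per_level < 2) {
    stop("tukey_hsd needs finite means, ms_error > 0, df_error >= 1 and ",
         "n_per_level >= 2", call. = FALSE)
  }
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("L", seq_len(k))
  hsd <- stats::qtukey(1 - alpha, k, df_error) * sqrt(ms_error / n_per_level)
  letter <- if (k == 1L) "A" else cld_from_threshold(means, hsd)
  out <- data.frame(level = names(means), mean = unname(means),
                    letter = letter, stringsAsFactors = FALSE)
  structure(out, class = c("mean_separation", "data.frame"),
            hsd = hsd, alpha = alpha, ms_error = ms_error,
            df_error = df_error, n_per_level = n_per_level)
}

#' @export
print.mean_separation <- function(x, ...) {
  cat(sprintf("Tukey HSD separation (alpha = %g, HSD = %.4g)\n",
              attr(x, "alpha"), attr(x, "hsd")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' LSD pairwise comparisons for interaction cell means
#'
#' Fisher's least significant difference
#' `LSD = t(1 - alpha/2; df_error) * sqrt(2 * ms_error / n_per_cell)`;
#' a cell pair is flagged significant iff its absolute mean difference
#' exceeds the LSD.
#'
#' @param cell_means Named numeric vector of interaction cell means.
#' @inheritParams tukey_hsd
#' @param n_per_cell Observations per cell mean.
#' @return List with `lsd`, the `difference` matrix (row - column) and the
#'   logical `significant` matrix.
#' @export
lsd_interaction <- function(cell_means, ms_error, df_error, n_per_cell,
                            alpha = 0.05) {
  if (!all(is.finite(cell_means)) || !is.finite(ms_error) || ms_error <= 0 ||
      !is.finite(df_error) || df_error < 1 || n_per_cell < 2) {
    stop("lsd_interaction needs finite means, ms_error > 0, df_error >= 1 ",
         "and n_per_cell >= 2", call. = FALSE)
  }
  lsd <- stats::qt(1 - alpha / 2, df_error) * sqrt(2 * ms_error / n_per_cell)
  d <- outer(cell_means, cell_means, "-")
  list(lsd = lsd, difference = d, significant = abs(d) > lsd)
}

#' Treatment means with Tukey letters from a fitted ANOVA
#'
#' Convenience wrapper: level means of `response` per `factor_name` with
#' compact letters from [tukey_hsd()], using the stratum-appropriate error
#' mean square of a fitted [fit_split_factorial_anova()] (whole-plot error
#' for block/year/tillage, subplot error otherwise). The effective n per
#' level counts all plot-level observations contributing to each mean.
#'
#' @inheritParams treatment_means
#' @param fit A `"split_anova"` for the same response and season.
#' @param alpha Significance level.
#' @return A `"mean_separation"`.
#' @export
tukey_letters <- function(table, response, factor_name, season, fit = NULL,
                          alpha = 0.05) {
  if (is.null(fit)) fit <- fit_split_factorial_anova(table, response, season)
  stopifnot(inherits(fit, "split_anova"))
  tm <- treatment_means(table, response, factor_name, season)
  whole_plot <- factor_name %in% c("block", "year", "tillage")
  ms <- if (whole_plot) fit$ms_error_a else fit$ms_error_b
  dfe <- if (whole_plot) fit$df_error_a else fit$df_error_b
  means <- stats::setNames(tm$mean, tm$level)
  tukey_hsd(means, ms, dfe, n_per_level = tm$n[1L], alpha = alpha)
}
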