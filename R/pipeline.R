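# End-to-end orchestration: simulate/load -> validate -> per-response ANOVA
# -> PCA/MDS/scoring/SHI -> SHI ANOVA + yield regression, with every
# intermediate written as delimited text and a JSON run manifest.

#' Run configuration for the full pipeline
#'
#' Bundles and validates everything [run_pipeline()] needs: the input
#' (a delimited table or a synthetic-trial configuration), output
#' directory, seasons and ANOVA responses, significance level, index
#' thresholds, scoring specification and RNG seed.
#'
#' @param out_dir Output directory (created if absent).
#' @param table_path Optional input table; when `NULL` (default) the trial
#'   is simulated from `synthetic`.
#' @param schema Optional column schema for [read_trial_table()].
#' @param synthetic A [synthetic_config()] used when `table_path` is NULL.
#' @param seasons Seasons to analyse.
#' @param responses Attribute/yield columns to run the ANOVA on.
#' @param alpha Significance level in (0, 0.5].
#' @param eigen_min,var_min,within_frac,redundancy_r Index thresholds, see
#'   [retain_pcs()] and [select_indicators()].
#' @param scoring A [scoring_spec()].
#' @param method Scoring method, `"minmax"` or `"ratio"`.
#' @param normalize Weight normalization flag, see [compute_weights()].
#' @param rng_seed Integer seed for simulation.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(out_dir, table_path = NULL, schema = NULL,
                       synthetic = synthetic_config(),
                       seasons = c("sorghum", "wheat"),
                       responses = c("ec_e", "kmno4_n", "olsen_p", "mbc",
                                     "mbn"),
                       alpha = 0.05, eigen_min = 1.0, var_min = 0.05,
                       within_frac = 0.10, redundancy_r = NULL,
                       scoring = scoring_spec(), method = "minmax",
                       normalize = FALSE, rng_seed = 42L) {
  if (!is.null(table_path) && !file.exists(table_path)) {
    stop("input table not found: ", table_path, call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 0.5, eigen_min > 0, var_min > 0,
            var_min < 1, within_frac >= 0, within_frac < 1)
  seasons <- match.arg(seasons, design_levels()$season, several.ok = TRUE)
  structure(list(out_dir = out_dir, table_path = table_path, schema = schema,
                 synthetic = synthetic, seasons = seasons,
                 responses = responses, alpha = alpha, eigen_min = eigen_min,
                 var_min = var_min, within_frac = within_frac,
                 redundancy_r = redundancy_r, scoring = scoring,
                 method = method, normalize = normalize,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Execute the full analysis pipeline
#'
#' Simulates or loads the trial, validates it, fits the split-factorial
#' ANOVA for each configured response and season, builds the soil health
#' index (PCA, MDS, scoring, weighting), runs the SHI ANOVA with Tukey
#' letter displays per design factor, regresses yield on SHI, and writes
#' every intermediate artifact plus a JSON manifest into `out_dir`. All
#' outputs are delimited UTF-8 text with deterministic column order; two
#' runs with the same configuration and seed produce identical bundles.
#' Any stage failure writes a `FAILED` marker naming the stage and aborts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the trial table, per-season ANOVA fits,
#'   `shi_result`s, letter displays, regressions and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(paste("stage:", name), conditionMessage(e)), failed)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  trial <- stage("load", {
    if (is.null(config$table_path)) {
      generate_trial(config$synthetic, seed = config$rng_seed)
    } else {
      read_trial_table(config$table_path, schema = config$schema)
    }
  })
  paths <- c(table = write_tsv(as.data.frame(trial),
                               file.path(config$out_dir, "trial_table.tsv")))

  fits <- list(); letter_sets <- list(); shi_results <- list()
  regressions <- list()
  for (season in config$seasons) {
    fits[[season]] <- stage(paste0("anova_", season), {
      out <- list()
      for (r in config$responses) {
        fit <- fit_split_factorial_anova(trial, r, season)
        p <- file.path(config$out_dir,
                       sprintf("anova_%s_%s.tsv", season, r))
        write_tsv(fit$table, p)
        paths[[paste0("anova_", season, "_", r)]] <- p
        out[[r]] <- fit
      }
      out
    })

    res <- stage(paste0("shi_", season), {
      build_shi(trial, season, eigen_min = config$eigen_min,
                var_min = config$var_min, within_frac = config$within_frac,
                redundancy_r = config$redundancy_r, spec = config$scoring,
                method = config$method, normalize = config$normalize)
    })
    shi_results[[season]] <- res
    stage(paste0("report_shi_", season), {
      pca_tab <- data.frame(pc = seq_along(res$pca$eigenvalues),
                            eigenvalue = res$pca$eigenvalues,
                            proportion = res$pca$proportion,
                            cumulative = res$pca$cumulative)
      paths[[paste0("pca_", season)]] <-
        write_tsv(pca_tab, file.path(config$out_dir,
                                     sprintf("pca_%s.tsv", season)))
      paths[[paste0("loadings_", season)]] <-
        write_tsv(cbind(attribute = rownames(res$pca$loadings),
                        as.data.frame(res$pca$loadings)),
                  file.path(config$out_dir,
                            sprintf("pca_loadings_%s.tsv", season)))
      paths[[paste0("mds_", season)]] <-
        write_tsv(as.data.frame(res$selection),
                  file.path(config$out_dir, sprintf("mds_%s.tsv", season)))
      per_plot <- cbind(res$data[design_columns()],
                        as.data.frame(unclass(res$scores)),
                        shi = res$shi)
      paths[[paste0("shi_plots_", season)]] <-
        write_tsv(per_plot, file.path(config$out_dir,
                                      sprintf("shi_plots_%s.tsv", season)))
    })

    letter_sets[[season]] <- stage(paste0("shi_anova_", season), {
      fit <- fit_split_factorial_anova(res$data, "shi", season)
      paths[[paste0("anova_", season, "_shi")]] <-
        write_tsv(fit$table, file.path(config$out_dir,
                                       sprintf("anova_%s_shi.tsv", season)))
      seps <- list()
      for (f in c("tillage", "irrigation", "mulch")) {
        seps[[f]] <- list(shi = tukey_letters(res$data, "shi", f, season,
                                              fit = fit,
                                              alpha = config$alpha))
      }
      rep_tab <- format_treatment_table(seps, "shi")
      paths[[paste0("shi_means_", season)]] <-
        write_tsv(rep_tab, file.path(config$out_dir,
                                     sprintf("shi_means_%s.tsv", season)))
      seps
    })

    regressions[[season]] <- stage(paste0("regression_", season), {
      ycol <- if (season == "sorghum") "dfy" else "grain"
      reg <- shi_yield_regression(res$shi, res$data[[ycol]])
      reg_df <- data.frame(season = season, yield = ycol,
                           slope = reg$slope, intercept = reg$intercept,
                           r_squared = reg$r_squared, p_value = reg$p_value,
                           n = reg$n)
      paths[[paste0("regression_", season)]] <-
        write_tsv(reg_df, file.path(config$out_dir,
                                    sprintf("shi_yield_%s.tsv", season)))
      reg
    })
  }

  stage("manifest", {
    manifest <- list(
      package = "soilhealth",
      version = as.character(utils::packageVersion("soilhealth")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      rng_seed = config$rng_seed,
      input = if (is.null(config$table_path)) "synthetic"
              else config$table_path,
      seasons = config$seasons, responses = config$responses,
      alpha = config$alpha, eigen_min = config$eigen_min,
      var_min = config$var_min, within_frac = config$within_frac,
      redundancy_r = config$redundancy_r, method = config$method,
      normalize = config$normalize,
      artifacts = unname(vapply(paths, basename, character(1)))
    )
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths[["manifest"]] <- file.path(config$out_dir, "manifest.json")
  })

  invisible(list(trial = trial, anova = fits, shi = shi_results,
                 letters = letter_sets, regressions = regressions,
                 paths = paths))
}

#' Format treatment means with letters as a report table
#'
#' Lays out per-factor letter displays the way trial reports print them:
#' one row per factor level with `mean^letter` per response column, and a
#' standard-error-of-the-mean row (`SE_m` = sqrt(error MS / n)) closing
#' each factor block.
#'
#' @param separations Named list: factor name -> named list of
#'   `"mean_separation"` objects keyed by response.
#' @param responses Character vector of response names (column order). An
#'   empty vector yields a header-only table.
#' @param digits Decimal places for the displayed means, default 2.
#' @return Data frame with columns `factor`, `level`, then one column per
#'   response.
#' @export
format_treatment_table <- function(separations, responses, digits = 2) {
  cols <- c("factor", "level", responses)
  if (length(responses) == 0L) {
    out <- data.frame(factor = character(0), level = character(0))
    return(out)
  }
  rows <- list()
  for (f in names(separations)) {
    block <- separations[[f]]
    lev <- block[[responses[1L]]]$level
    for (i in seq_along(lev)) {
      row <- list(factor = f, level = lev[i])
      for (r in responses) {
        sep <- block[[r]]
        row[[r]] <- sprintf("%.*f%s", digits, sep$mean[i], sep$letter[i])
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                stringsAsFactors = FALSE)
    }
    se_row <- list(factor = f, level = "SE_m")
    for (r in responses) {
      sep <- block[[r]]
      se <- sqrt(attr(sep, "ms_error") / attr(sep, "n_per_level"))
      se_row[[r]] <- sprintf("%.*f", digits, se)
    }
    rows[[length(rows) + 1L]] <- as.data.frame(se_row,
                                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out) <- cols
  out
}
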