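# Synthetic split-factorial saline-irrigation trial generator.
#
# One latent "salinity" variable per plot-season drives the negative
# correlations between EC_e and the microbial/enzymatic attributes; every
# attribute i is
#   baseline_i + sum(factor effects) + block intercept
#              + c_i * sd_i * latent + sqrt(1 - c_i^2) * sd_i * noise
# so the residual SD stays sd_i and the implied residual correlation between
# attributes i and j is exactly c_i * c_j.

default_baselines <- function() {
  # grand means per season; pH/EC/OC/N/P/K anchored to printed treatment
  # tables, microbial and enzyme baselines field-typical (assay units)
  list(
    sorghum = c(ph_s = 7.93, ec_e = 4.537, wboc = 3.94, kmno4_n = 87.6,
                olsen_p = 23.53, nh4oac_k = 245.9, mbc = 185, mbn = 23,
                dha = 24, alp = 62, ur = 30, alpha_glu = 8.5, beta_glu = 19),
    wheat   = c(ph_s = 7.77, ec_e = 7.637, wboc = 4.29, kmno4_n = 91.4,
                olsen_p = 21.27, nh4oac_k = 223.6, mbc = 155, mbn = 20,
                dha = 18, alp = 55, ur = 28, alpha_glu = 9.5, beta_glu = 25)
  )
}

default_resid_sd <- function() {
  # residual SD = reported standard error of a treatment mean x sqrt(n)
  # where printed (n = 36 plots per irrigation level); others proportional
  list(
    sorghum = c(ph_s = 0.24, ec_e = 1.08, wboc = 0.90, kmno4_n = 9.7,
                olsen_p = 3.9, nh4oac_k = 32.3, mbc = 22, mbn = 3.0,
                dha = 4.0, alp = 8.0, ur = 4.5, alpha_glu = 1.3,
                beta_glu = 2.8),
    wheat   = c(ph_s = 0.24, ec_e = 1.38, wboc = 0.96, kmno4_n = 10.0,
                olsen_p = 6.1, nh4oac_k = 30.1, mbc = 20, mbn = 2.8,
                dha = 3.5, alp = 8.0, ur = 4.5, alpha_glu = 1.4,
                beta_glu = 3.4)
  )
}

default_effects <- function() {
  # additive treatment deviations (centered to zero-sum at validation);
  # directions and magnitudes follow the printed treatment means
  list(
    sorghum = list(
      ec_e = list(irrigation = c(CWR100 = 0.433, CWR80 = -0.137,
                                 CWR60 = -0.297),
                  year = c("1" = 0.4, "2" = -0.4)),
      olsen_p = list(tillage = c(CT = -0.533, RT = 1.467, ZT = -0.933)),
      kmno4_n = list(mulch = c(none = -2.4, mulch = 2.4)),
      nh4oac_k = list(irrigation = c(CWR100 = -4.1, CWR80 = -5.2,
                                     CWR60 = 9.3)),
      mbc = list(irrigation = c(CWR100 = -8, CWR80 = 0, CWR60 = 8)),
      mbn = list(tillage = c(CT = -1.2, RT = 0.2, ZT = 1.0),
                 irrigation = c(CWR100 = -1.0, CWR80 = 0, CWR60 = 1.0),
                 mulch = c(none = -0.8, mulch = 0.8),
                 year = c("1" = -0.8, "2" = 0.8)),
      dha = list(tillage = c(CT = 2.0, RT = -1.0, ZT = -1.0),
                 irrigation = c(CWR100 = -1.5, CWR80 = 0, CWR60 = 1.5),
                 mulch = c(none = -1.2, mulch = 1.2)),
      alp = list(tillage = c(CT = 3.0, RT = -1.5, ZT = -1.5),
                 irrigation = c(CWR100 = -2.0, CWR80 = 0, CWR60 = 2.0),
                 mulch = c(none = 2.0, mulch = -2.0)),
      ur = list(mulch = c(none = -1.5, mulch = 1.5)),
      alpha_glu = list(mulch = c(none = -0.4, mulch = 0.4)),
      beta_glu = list(mulch = c(none = -0.9, mulch = 0.9))
    ),
    wheat = list(
      ec_e = list(irrigation = c(CWR100 = 0.59, CWR80 = 0.01, CWR60 = -0.60),
                  mulch = c(none = 0.285, mulch = -0.285),
                  tillage = c(CT = 0.263, RT = 0.193, ZT = -0.457),
                  year = c("1" = 0.4, "2" = -0.4)),
      olsen_p = list(tillage = c(CT = -1.833, RT = 2.067, ZT = -0.233),
                     irrigation = c(CWR100 = -0.567, CWR80 = -1.267,
                                    CWR60 = 1.833),
                     year = c("1" = -2.85, "2" = 2.85)),
      nh4oac_k = list(tillage = c(CT = -9.167, RT = 2.633, ZT = 6.533),
                      mulch = c(none = -5.55, mulch = 5.55)),
      kmno4_n = list(irrigation = c(CWR100 = 2.97, CWR80 = -1.53,
                                    CWR60 = -1.43),
                     mulch = c(none = -3.35, mulch = 3.35)),
      mbc = list(irrigation = c(CWR100 = -8, CWR80 = 0, CWR60 = 8)),
      mbn = list(tillage = c(CT = -1.0, RT = 0.1, ZT = 0.9),
                 irrigation = c(CWR100 = -0.9, CWR80 = 0, CWR60 = 0.9),
                 year = c("1" = -0.8, "2" = 0.8)),
      dha = list(irrigation = c(CWR100 = -1.2, CWR80 = 0, CWR60 = 1.2),
                 mulch = c(none = -1.0, mulch = 1.0)),
      alp = list(irrigation = c(CWR100 = -1.8, CWR80 = 0, CWR60 = 1.8),
                 mulch = c(none = 1.8, mulch = -1.8)),
      ur = list(mulch = c(none = -1.3, mulch = 1.3))
    )
  )
}

default_coupling <- function() {
  # loading of each attribute on the latent plot salinity, as a fraction of
  # its residual SD; implied residual corr(i, j) = c_i * c_j, e.g.
  # corr(ec_e, mbn) = 0.7 * -0.50 = -0.35
  c(ph_s = 0, ec_e = 0.7, wboc = 0, kmno4_n = 0, olsen_p = 0, nh4oac_k = 0,
    mbc = -0.45, mbn = -0.50, dha = -0.45, alp = -0.30, ur = -0.35,
    alpha_glu = 0, beta_glu = -0.40)
}

default_yield_model <- function() {
  # yield = intercept + sum(coef * (attribute - baseline)) + N(0, sd)
  list(
    gfy   = list(intercept = 55.0, coef = c(ec_e = -1.2, mbc = 0.04),
                 sd = 3.5),
    dfy   = list(intercept = 13.6, coef = c(ec_e = -0.45, mbc = 0.012),
                 sd = 0.9),
    grain = list(intercept = 5.9, coef = c(ec_e = -0.10, olsen_p = 0.01),
                 sd = 0.45),
    straw = list(intercept = 8.6, coef = c(ec_e = -0.15), sd = 0.8)
  )
}

#' Configuration for the synthetic trial generator
#'
#' Assembles and validates the parameters of the synthetic saline-irrigation
#' trial: design size, per-season attribute baselines and residual SDs,
#' additive treatment effects (zero-sum deviations per factor), the
#' latent-salinity coupling coefficients that induce negative correlations
#' between `ec_e` and the microbial/enzymatic attributes, the linear yield
#' model, and the RNG seed. Defaults reproduce the reference 3 tillage x
#' 3 irrigation x 2 mulch x 3 block x 2 year design.
#'
#' @param n_blocks Number of replicate blocks (default 3).
#' @param n_years Number of years (default 2).
#' @param baselines,resid_sd Named lists (`sorghum`, `wheat`) of named
#'   numeric vectors over the sampled attributes (all but `mbcn`, which is
#'   recomputed as `mbc / mbn`).
#' @param effects Nested list: season -> attribute -> factor -> named
#'   effect vector over that factor's levels. Each vector is centered to
#'   sum to zero (effects are deviations from the baseline).
#' @param coupling Named vector of latent-salinity loadings in (-1, 1),
#'   expressed as a fraction of each attribute's residual SD.
#' @param block_sd_frac SD of the random block intercept as a fraction of
#'   the attribute residual SD (default 0.3).
#' @param yield_model Named list per yield column with `intercept`, `coef`
#'   (named attribute coefficients applied to baseline deviations) and `sd`.
#' @param rng_seed Integer seed (default 42).
#' @return A validated object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_blocks = 3, n_years = 2,
                             baselines = default_baselines(),
                             resid_sd = default_resid_sd(),
                             effects = default_effects(),
                             coupling = default_coupling(),
                             block_sd_frac = 0.3,
                             yield_model = default_yield_model(),
                             rng_seed = 42L) {
  stopifnot(n_blocks >= 2, n_years >= 1, block_sd_frac >= 0)
  attrs <- setdiff(soil_attributes(), "mbcn")
  for (s in c("sorghum", "wheat")) {
    if (!all(attrs %in% names(baselines[[s]]))) {
      stop("baselines$", s, " must name every sampled attribute",
           call. = FALSE)
    }
    if (!all(attrs %in% names(resid_sd[[s]]))) {
      stop("resid_sd$", s, " must name every sampled attribute",
           call. = FALSE)
    }
    if (any(resid_sd[[s]][attrs] <= 0)) {
      stop("residual SDs must be positive", call. = FALSE)
    }
  }
  if (any(abs(coupling[attrs]) >= 1)) {
    stop("coupling coefficients must lie in (-1, 1) for a positive-definite ",
         "implied covariance", call. = FALSE)
  }
  lv <- design_levels()
  lv$block <- as.character(seq_len(n_blocks))
  lv$year <- as.character(seq_len(n_years))
  for (s in names(effects)) {
    for (a in names(effects[[s]])) {
      for (f in names(effects[[s]][[a]])) {
        e <- effects[[s]][[a]][[f]]
        if (!setequal(names(e), lv[[f]])) {
          stop(sprintf("effects$%s$%s$%s must name levels {%s}",
                       s, a, f, paste(lv[[f]], collapse = ", ")),
               call. = FALSE)
        }
        effects[[s]][[a]][[f]] <- e[lv[[f]]] - mean(e)  # zero-sum deviations
      }
    }
  }
  structure(list(n_blocks = n_blocks, n_years = n_years, levels = lv,
                 baselines = baselines, resid_sd = resid_sd,
                 effects = effects, coupling = coupling,
                 block_sd_frac = block_sd_frac, yield_model = yield_model,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic split-factorial trial configuration\n")
  cat(sprintf("  design: %d blocks x %d years x %d tillage x %d irrigation x %d mulch\n",
              x$n_blocks, x$n_years, length(x$levels$tillage),
              length(x$levels$irrigation), length(x$levels$mulch)))
  cat(sprintf("  rows/season: %d; seed: %d\n",
              x$n_blocks * x$n_years * length(x$levels$tillage) *
                length(x$levels$irrigation) * length(x$levels$mulch),
              x$rng_seed))
  nz <- names(x$coupling)[x$coupling != 0]
  cat("  latent-salinity coupled attributes:", paste(nz, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic trial table
#'
#' Draws a balanced plot-level table for both crop seasons under `config`.
#' Each attribute value is baseline + treatment deviations + a Gaussian
#' block intercept + the latent-salinity component + independent Gaussian
#' noise; `mbcn` is computed as `mbc / mbn`; yields follow the configured
#' linear model. Negative draws are truncated at zero (with a message when
#' any occur). Identical config and seed give an identical table.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer overriding `config$rng_seed`.
#' @return A validated `trial_table` with
#'   `n_blocks * n_years * 18` rows per season.
#' @export
generate_trial <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(seed)) seed <- config$rng_seed
  set.seed(as.integer(seed))
  lv <- config$levels
  attrs <- setdiff(soil_attributes(), "mbcn")
  rows <- list()
  n_trunc <- 0L
  for (s in c("sorghum", "wheat")) {
    grid <- expand.grid(block = lv$block, year = lv$year,
                        tillage = lv$tillage, irrigation = lv$irrigation,
                        mulch = lv$mulch, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    grid$season <- s
    n <- nrow(grid)
    latent <- stats::rnorm(n)
    # block intercepts per attribute, shared across plots of a block
    blk <- matrix(stats::rnorm(length(lv$block) * length(attrs),
                               sd = config$block_sd_frac),
                  nrow = length(lv$block),
                  dimnames = list(lv$block, attrs))
    for (a in attrs) {
      mu <- config$baselines[[s]][[a]]
      sd_a <- config$resid_sd[[s]][[a]]
      eff <- rep(0, n)
      for (f in names(config$effects[[s]][[a]])) {
        eff <- eff + config$effects[[s]][[a]][[f]][grid[[f]]]
      }
      c_a <- config$coupling[[a]]
      x <- mu + eff + sd_a * blk[grid$block, a] + c_a * sd_a * latent +
        sqrt(1 - c_a^2) * sd_a * stats::rnorm(n)
      n_trunc <- n_trunc + sum(x < 0)
      grid[[a]] <- pmax(x, 0)
    }
    grid$mbcn <- grid$mbc / grid$mbn
    for (y in yield_columns()) grid[[y]] <- NA_real_
    for (y in yield_columns(s)) {
      ym <- config$yield_model[[y]]
      val <- rep(ym$intercept, n)
      for (a in names(ym$coef)) {
        val <- val + ym$coef[[a]] * (grid[[a]] - config$baselines[[s]][[a]])
      }
      val <- val + stats::rnorm(n, sd = ym$sd)
      n_trunc <- n_trunc + sum(val < 0)
      grid[[y]] <- pmax(val, 0)
    }
    rows[[s]] <- grid
  }
  if (n_trunc > 0L) {
    message(n_trunc, " negative draw(s) truncated at 0")
  }
  out <- do.call(rbind, rows)
  out <- out[c(design_columns(), soil_attributes(), yield_columns())]
  validate_trial_table(out)
}

#' Ground truth of a synthetic configuration
#'
#' Echoes the exact design effects and the implied residual correlation
#' matrix of the one-factor latent-salinity model
#' (`corr(i, j) = c_i * c_j` for distinct attributes), for use as recovery
#' targets when testing the downstream analysis.
#'
#' @param config A [synthetic_config()].
#' @return List with `effects` (the centered effect vectors per season),
#'   `implied_correlation` (attribute x attribute matrix over the sampled
#'   attributes), and `contrast(season, attribute, factor, level_a,
#'   level_b)`, a helper returning the true mean difference between two
#'   factor levels.
#' @export
ground_truth <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  attrs <- setdiff(soil_attributes(), "mbcn")
  cc <- config$coupling[attrs]
  rho <- outer(cc, cc)
  diag(rho) <- 1
  dimnames(rho) <- list(attrs, attrs)
  contrast <- function(season, attribute, factor_name, level_a, level_b) {
    e <- config$effects[[season]][[attribute]][[factor_name]]
    if (is.null(e)) return(0)
    unname(e[[level_a]] - e[[level_b]])
  }
  list(effects = config$effects, implied_correlation = rho,
       contrast = contrast)
}
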