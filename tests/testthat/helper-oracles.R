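# Independent oracles and small fixture builders used across the suite.

# all subsets of a character vector (including the empty set)
all_subsets <- function(x) {
  out <- list(character(0))
  for (k in seq_along(x)) {
    out <- c(out, utils::combn(x, k, simplify = FALSE))
  }
  out
}

# brute-force balanced-design sum of squares for one term, by Moebius
# inversion over marginal means: effect(t) = sum_{S subset T} (-1)^{|T|-|S|}
# mean_S(t_S); SS = replicates_per_combo * sum(effect^2)
bf_term_ss <- function(df, response, term_factors) {
  y <- df[[response]]
  N <- length(y)
  combos <- unique(df[term_factors])
  eff <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    tot <- 0
    for (S in all_subsets(term_factors)) {
      if (length(S) == 0L) {
        m <- mean(y)
      } else {
        sel <- rep(TRUE, N)
        for (f in S) sel <- sel & df[[f]] == combos[i, f]
        m <- mean(y[sel])
      }
      tot <- tot + (-1)^(length(term_factors) - length(S)) * m
    }
    eff[i] <- tot
  }
  (N / nrow(combos)) * sum(eff^2)
}

# between-whole-plot-unit sum of squares (units defined by `unit_factors`)
bf_between_unit_ss <- function(df, response, unit_factors) {
  y <- df[[response]]
  key <- do.call(paste, df[unit_factors])
  means <- tapply(y, key, mean)
  counts <- tapply(y, key, length)
  sum(counts * (means - mean(y))^2)
}

# closed-form simple OLS via the normal equations
bf_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(intercept = beta[1L], slope = beta[2L], r_squared = r2)
}

# a tiny balanced one-year design: 2 blocks x 2 tillage (whole plots) x
# 2 irrigation x 2 mulch, with a caller-supplied response
toy_design <- function(response) {
  grid <- expand.grid(block = c("1", "2"), tillage = c("CT", "RT"),
                      irrigation = c("CWR100", "CWR80"),
                      mulch = c("none", "mulch"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$year <- "1"
  grid$season <- "sorghum"
  grid$resp <- response
  grid
}

# null synthetic configuration: no treatment effects, no latent coupling,
# no block intercepts -- pure Gaussian noise around the baselines
null_config <- function(...) {
  synthetic_config(effects = list(sorghum = list(), wheat = list()),
                   coupling = stats::setNames(
                     rep(0, 13), setdiff(soil_attributes(), "mbcn")),
                   block_sd_frac = 0, ...)
}

# a minimal fake PCA object for threshold-rule tests
fake_pca <- function(eigenvalues, loadings = NULL) {
  prop <- eigenvalues / sum(eigenvalues)
  if (is.null(loadings)) {
    loadings <- diag(length(eigenvalues))
    dimnames(loadings) <- list(paste0("a", seq_along(eigenvalues)),
                               paste0("PC", seq_along(eigenvalues)))
  }
  structure(list(eigenvalues = eigenvalues, proportion = prop,
                 cumulative = cumsum(prop), loadings = loadings,
                 n_obs = 100L,
                 correlation = diag(nrow(loadings))),
            class = "shi_pca")
}
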