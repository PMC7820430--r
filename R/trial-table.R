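#' @keywords internal
"_PACKAGE"

# Canonical column vocabulary ------------------------------------------------

#' Canonical soil attribute names
#'
#' The 14 chemical and biological soil attributes a trial table carries:
#' saturation-paste pH (`ph_s`), saturation-extract electrical conductivity
#' (`ec_e`, dS/m), Walkley-Black oxidizable organic C (`wboc`, g/kg),
#' KMnO4-oxidizable N, Olsen's P and NH4OAc-extractable K (kg/ha), microbial
#' biomass C and N (`mbc`, `mbn`), their ratio (`mbcn`), and the enzyme
#' activities dehydrogenase (`dha`), alkaline phosphatase (`alp`), urease
#' (`ur`), and alpha-/beta-glucosidase. Enzyme activities are treated as
#' internally consistent assay units.
#'
#' @return Character vector of the 14 attribute column names, in canonical
#'   order.
#' @export
soil_attributes <- function() {
  c("ph_s", "ec_e", "wboc", "kmno4_n", "olsen_p", "nh4oac_k",
    "mbc", "mbn", "mbcn", "dha", "alp", "ur", "alpha_glu", "beta_glu")
}

#' Design factor levels of the reference trial
#'
#' The reference split-factorial design: 3 blocks x 2 years x 2 crop seasons,
#' with tillage (conventional/reduced/zero) on main plots and a saline
#' deficit-irrigation (100/80/60% of wheat crop water requirement) x rice
#' straw mulch factorial on subplots. Sorghum is rainfed; irrigation levels
#' label the preceding/following wheat irrigation regime of the same subplot.
#'
#' @return Named list of factor levels for `block`, `year`, `season`,
#'   `tillage`, `irrigation` and `mulch`.
#' @export
design_levels <- function() {
  list(
    block      = c("1", "2", "3"),
    year       = c("1", "2"),
    season     = c("sorghum", "wheat"),
    tillage    = c("CT", "RT", "ZT"),
    irrigation = c("CWR100", "CWR80", "CWR60"),
    mulch      = c("none", "mulch")
  )
}

#' @rdname design_levels
#' @export
design_columns <- function() names(design_levels())

#' Yield columns by crop season
#'
#' Sorghum rows carry green and dry fodder yield (`gfy`, `dfy`); wheat rows
#' carry `grain` and `straw` yield, all in Mg/ha. Yields of the other season
#' are stored as `NA`.
#'
#' @param season `"sorghum"`, `"wheat"`, or `NULL` for all four columns.
#' @return Character vector of yield column names.
#' @export
yield_columns <- function(season = NULL) {
  cols <- list(sorghum = c("gfy", "dfy"), wheat = c("grain", "straw"))
  if (is.null(season)) return(unlist(cols, use.names = FALSE))
  season <- match.arg(season, names(cols))
  cols[[season]]
}

design_key <- function(df) {
  do.call(paste, c(df[design_columns()], sep = "\r"))
}

# Validation -----------------------------------------------------------------

#' Validate a plot-level trial table
#'
#' Checks the invariants a downstream analysis assumes: all design and
#' attribute columns present; enum columns drawn from [design_levels()];
#' the design key (block, year, season, tillage, irrigation, mulch) unique;
#' the design balanced within each season; `ec_e`, `mbc`, `mbn` and yields
#' non-negative; attributes complete (no `NA`); and `mbcn` consistent with
#' `mbc / mbn` to 1% relative tolerance (it is recomputed from `mbc / mbn`,
#' with a warning if a supplied column disagrees beyond tolerance).
#'
#' @param df Data frame with design, attribute and yield columns.
#' @param drop_incomplete Drop rows with missing attribute values (with a
#'   warning) instead of erroring. Default `FALSE`.
#' @return The validated table, invisibly classed `"trial_table"`.
#' @export
validate_trial_table <- function(df, drop_incomplete = FALSE) {
  lv <- design_levels()
  needed <- c(design_columns(), soil_attributes())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (y in yield_columns()) if (!y %in% names(df)) df[[y]] <- NA_real_

  # block and year are open-ended integer labels (a simulated trial may
  # carry any number of blocks/years); the other enums are canonical
  for (f in c("block", "year")) {
    vals <- trimws(as.character(df[[f]]))
    num <- suppressWarnings(as.integer(vals))
    if (anyNA(num) || any(num < 1)) {
      stop(sprintf("column '%s' must hold positive integer labels", f),
           call. = FALSE)
    }
    lv[[f]] <- as.character(sort(unique(num)))
    df[[f]] <- factor(as.character(num), levels = lv[[f]])
  }
  for (f in c("season", "tillage", "irrigation", "mulch")) {
    vals <- as.character(df[[f]])
    idx <- match(tolower(vals), tolower(lv[[f]]))
    if (anyNA(idx)) {
      bad <- unique(vals[is.na(idx)])
      stop(sprintf("column '%s' contains value(s) outside {%s}: %s",
                   f, paste(lv[[f]], collapse = ", "),
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    df[[f]] <- factor(lv[[f]][idx], levels = lv[[f]])
  }

  num_cols <- c(soil_attributes(), yield_columns())
  for (a in num_cols) {
    if (!is.numeric(df[[a]])) df[[a]] <- as.numeric(df[[a]])
  }

  incomplete <- rowSums(is.na(df[soil_attributes()])) > 0L
  if (any(incomplete)) {
    if (drop_incomplete) {
      warning(sum(incomplete), " row(s) with missing attribute values dropped")
      df <- df[!incomplete, , drop = FALSE]
    } else {
      stop("missing attribute values in ", sum(incomplete),
           " row(s); set drop_incomplete = TRUE to drop them", call. = FALSE)
    }
  }

  key <- design_key(df)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicated design key (block, year, season, tillage, irrigation, ",
         "mulch): ", gsub("\r", "/", dup), call. = FALSE)
  }

  if (any(df$ec_e < 0)) stop("ec_e must be non-negative", call. = FALSE)
  if (any(df$mbc < 0) || any(df$mbn < 0)) {
    stop("mbc and mbn must be non-negative", call. = FALSE)
  }
  for (y in yield_columns()) {
    if (any(df[[y]] < 0, na.rm = TRUE)) {
      stop("yield column '", y, "' must be non-negative", call. = FALSE)
    }
  }

  ok <- df$mbn > 0
  if (any(ok)) {
    implied <- df$mbc[ok] / df$mbn[ok]
    rel <- abs(df$mbcn[ok] - implied) / pmax(abs(implied), .Machine$double.eps)
    if (any(rel > 0.01)) {
      warning(sum(rel > 0.01), " mbcn value(s) differ from mbc/mbn by >1%; ",
              "recomputed from mbc/mbn")
    }
    df$mbcn[ok] <- implied
  }

  # wrong-season yields must be absent
  for (s in lv$season) {
    other <- setdiff(lv$season, s)
    wrong <- yield_columns(other)
    in_s <- df$season == s
    for (y in wrong) df[[y]][in_s] <- NA_real_
  }

  # balance: with unique design keys, a season whose row count equals the
  # product of its level counts holds every factor combination exactly once
  for (s in unique(as.character(df$season))) {
    sub <- df[df$season == s, , drop = FALSE]
    expected <- prod(lengths(lv[c("block", "year", "tillage",
                                  "irrigation", "mulch")]))
    if (nrow(sub) != expected) {
      stop(sprintf("season '%s' has %d rows; a balanced design needs %d",
                   s, nrow(sub), expected), call. = FALSE)
    }
  }

  rownames(df) <- NULL
  class(df) <- unique(c("trial_table", class(df)))
  invisible(df)
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("Plot-level trial table: %d rows (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$season)),
                            as.integer(table(x$season))), collapse = ", ")))
  cat("Design: ", paste(design_columns(), collapse = ", "), "\n", sep = "")
  cat("Attributes: ", paste(soil_attributes(), collapse = ", "), "\n", sep = "")
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("... ", nrow(x) - 4L, " more rows\n", sep = "")
  invisible(x)
}

# I/O ------------------------------------------------------------------------

#' Read a plot-level trial table from delimited text
#'
#' Reads a comma- (default) or tab-delimited UTF-8 file with a header row,
#' renames columns through an optional schema map, and validates the result
#' with [validate_trial_table()]. Enum columns are parsed case-insensitively;
#' numeric parsing is locale-independent (dot decimal separator).
#'
#' @param path File to read.
#' @param schema Optional named character vector mapping canonical column
#'   names (names) to the file's column names (values), e.g.
#'   `c(ec_e = "ECe")`. Unmapped canonical names are looked up directly.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param drop_incomplete Passed to [validate_trial_table()].
#' @return A validated `trial_table`.
#' @export
read_trial_table <- function(path, schema = NULL, sep = ",",
                             drop_incomplete = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop("schema column '", src, "' (for '", canon,
             "') not found in file header", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(c(design_columns(), soil_attributes()), names(raw))
  if (length(missing_cols) > 0L) {
    stop("file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (a in intersect(c(soil_attributes(), yield_columns()), names(raw))) {
    v <- trimws(raw[[a]])
    v[v == ""] <- NA_character_
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad) > 0L) {
      stop(sprintf("unparseable numeric value '%s' at row %d, column '%s'",
                   v[bad[1L]], bad[1L], a), call. = FALSE)
    }
    raw[[a]] <- parsed
  }
  validate_trial_table(raw, drop_incomplete = drop_incomplete)
}

#' Write a trial table to delimited text
#'
#' Inverse of [read_trial_table()]: numeric values are written at full
#' precision (up to 15 significant digits) so that write-then-read round
#' trips within 1e-9 relative error; `NA` yields are written as empty cells.
#'
#' @param table A trial table (validated or validatable data frame).
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path, sep = ",") {
  df <- as.data.frame(table)
  out <- df[intersect(c(design_columns(), soil_attributes(), yield_columns()),
                      names(df))]
  for (a in names(out)) {
    if (is.numeric(out[[a]])) {
      v <- formatC(out[[a]], digits = 15, format = "g")
      v[is.na(out[[a]])] <- ""
      out[[a]] <- v
    } else {
      out[[a]] <- as.character(out[[a]])
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) {
    stop("cannot write trial table to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}

# Laboratory conversions -----------------------------------------------------

#' Microbial biomass C from the fumigation C flush
#'
#' Chloroform fumigation-extraction conversion `MBC = c_flush / k_ec`, with
#' the usual extraction-efficiency calibration factor K_EC = 0.38.
#'
#' @param c_flush Difference in extractable C between fumigated and
#'   non-fumigated samples (same mass units as the result). Must be >= 0.
#' @param k_ec Calibration factor in (0, 1]; default 0.38.
#' @return Microbial biomass C, `c_flush / k_ec`.
#' @export
mbc_from_flush <- function(c_flush, k_ec = 0.38) {
  stopifnot(is.numeric(c_flush), is.numeric(k_ec))
  if (any(k_ec <= 0) || any(k_ec > 1)) {
    stop("k_ec must lie in (0, 1]", call. = FALSE)
  }
  if (any(c_flush < 0)) stop("C flush must be non-negative", call. = FALSE)
  c_flush / k_ec
}

#' Microbial biomass N from the fumigation N difference
#'
#' `MBN = n_diff / k_ec`, where `n_diff` is the N difference between
#' fumigated and non-fumigated extracts and K_EC = 0.38 by default.
#'
#' @param n_diff Fumigated-minus-nonfumigated extractable N; must be >= 0.
#' @inheritParams mbc_from_flush
#' @return Microbial biomass N.
#' @export
mbn_from_flush <- function(n_diff, k_ec = 0.38) {
  stopifnot(is.numeric(n_diff), is.numeric(k_ec))
  if (any(k_ec <= 0) || any(k_ec > 1)) {
    stop("k_ec must lie in (0, 1]", call. = FALSE)
  }
  if (any(n_diff < 0)) stop("N difference must be non-negative", call. = FALSE)
  n_diff / k_ec
}

# Treatment summaries --------------------------------------------------------

#' Per-level treatment means of a response
#'
#' Arithmetic mean of `response` per level of one design factor, averaging
#' over blocks, years and the remaining factors, within one crop season.
#' Level order follows [design_levels()].
#'
#' @param table A trial table.
#' @param response Attribute or yield column name.
#' @param factor_name One of `"tillage"`, `"irrigation"`, `"mulch"`,
#'   `"block"`, `"year"`.
#' @param season `"sorghum"` or `"wheat"`.
#' @return Data frame with columns `level`, `mean`, `n`.
#' @export
treatment_means <- function(table, response, factor_name, season) {
  df <- as.data.frame(table)
  if (!response %in% names(df)) {
    stop("unknown response column: ", response, call. = FALSE)
  }
  if (!factor_name %in% design_columns()) {
    stop("unknown design factor: ", factor_name, call. = FALSE)
  }
  season <- match.arg(season, design_levels()$season)
  df <- df[as.character(df$season) == season, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for season '", season, "'", call. = FALSE)
  lv <- if (factor_name %in% c("block", "year")) {
    as.character(sort(unique(as.integer(as.character(df[[factor_name]])))))
  } else {
    intersect(design_levels()[[factor_name]],
              unique(as.character(df[[factor_name]])))
  }
  f <- factor(as.character(df[[factor_name]]), levels = lv)
  m <- tapply(df[[response]], f, mean)
  data.frame(level = names(m), mean = as.numeric(m),
             n = as.integer(table(f)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Difference of two treatment means
#'
#' @param mean_a,mean_b Finite numeric means.
#' @return `mean_a - mean_b` (sign preserved).
#' @export
mean_difference <- function(mean_a, mean_b) {
  if (!all(is.finite(mean_a)) || !all(is.finite(mean_b))) {
    stop("means must be finite", call. = FALSE)
  }
  mean_a - mean_b
}

#' Percent change of a mean relative to a reference
#'
#' @param mean_new New value.
#' @param mean_ref Reference value; must be nonzero.
#' @return `100 * (mean_new - mean_ref) / mean_ref`.
#' @export
percent_change <- function(mean_new, mean_ref) {
  if (any(mean_ref == 0)) stop("reference mean must be nonzero", call. = FALSE)
  100 * (mean_new - mean_ref) / mean_ref
}
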