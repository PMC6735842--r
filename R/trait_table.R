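# Species-level trait table: I/O, validation and derived traits.
#
# The central container is a plain data.frame (class "trait_table") with one
# row per species: taxonomy (family, order), endosperm presence (E/N),
# dormancy class (ND/PD/PY), the longevity estimate p50 (days) with its
# standard error, and optional continuous seed traits (thousand-seed weight,
# dimensions, shape variance, mean seed-coat thickness). Missing continuous
# values are explicit NA, never zero.

TRAIT_REQUIRED_COLS <- c("species", "family", "order", "endosperm",
                         "dormancy", "p50", "p50_se")
TRAIT_OPTIONAL_COLS <- c("pretreatment", "germ_temp", "rank", "tsw_mg",
                         "length_mm", "width_mm", "height_mm", "vs", "mct_mm")

#' Seed shape variance from seed dimensions
#'
#' Shape is the population variance (divisor n = 3) of the three seed
#' dimensions after dividing each by the longest one, so that a perfectly
#' spherical seed scores 0 and a needle- or disk-shaped seed approaches the
#' algebraic maximum 2/9. The statistic is dimensionless and invariant to
#' uniform rescaling of the seed.
#'
#' If `length` is not the largest of the three dimensions the values are
#' reordered (with a warning) so that the largest axis is the reference.
#'
#' @param length,width,height Seed dimensions in mm (any common unit works;
#'   only ratios enter the statistic). All must be > 0.
#' @return Shape variance, a number in \[0, 2/9\].
#' @examples
#' seed_shape_variance(1, 1, 1)    # 0, spherical
#' seed_shape_variance(2, 1, 1)    # 1/18, ellipsoid
#' @export
seed_shape_variance <- function(length, width, height) {
  dims <- c(length = length, width = width, height = height)
  if (length(dims) != 3L) {
    stop_seedspan("provide scalar length, width and height", "seedspan_invalid_input")
  }
  assert_positive(dims, "dimensions")
  if (max(dims) != dims[["length"]]) {
    warning("`length` is not the largest dimension; reordering so the ",
            "largest axis is the reference", call. = FALSE)
  }
  x <- sort(dims, decreasing = TRUE)
  x <- x / x[1]
  sum((x - mean(x))^2) / 3
}

#' Base-10 log transform for positive traits
#'
#' Continuous seed traits and p50 are log10-transformed before analysis to
#' approximate normality; non-positive input is an error rather than a
#' silent NaN.
#'
#' @param value Positive numeric vector.
#' @return `log10(value)`.
#' @export
log10_trait <- function(value) {
  assert_positive(value, "value")
  log10(value)
}

#' Read a species trait table from CSV
#'
#' Expects a UTF-8 CSV with a header row and one species per row; required
#' columns are `species, family, order, endosperm, dormancy, p50, p50_se`.
#' Optional columns (`pretreatment`, `germ_temp`, `rank`, `tsw_mg`,
#' `length_mm`, `width_mm`, `height_mm`, `vs`, `mct_mm`) are carried through.
#' Missing values use the token `NA`.
#'
#' @param path CSV file path.
#' @param quiet Suppress the per-category count message.
#' @return A `trait_table` data.frame.
#' @seealso [grassland_p50_table()] for the packaged 39-species dataset.
#' @export
load_trait_table <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop_seedspan(sprintf("file not found: %s", path), "seedspan_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  validate_trait_table(df)
  class(df) <- c("trait_table", "data.frame")
  if (!quiet) {
    message(sprintf(
      "%d species; endosperm E/N = %d/%d; dormancy ND/PD/PY = %d/%d/%d",
      nrow(df), sum(df$endosperm == "E"), sum(df$endosperm == "N"),
      sum(df$dormancy == "ND"), sum(df$dormancy == "PD"),
      sum(df$dormancy == "PY")))
  }
  df
}

validate_trait_table <- function(df) {
  missing_cols <- setdiff(TRAIT_REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop_seedspan(sprintf("missing required column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "seedspan_schema_error")
  }
  if (nrow(df) == 0L) {
    stop_seedspan("trait table has no rows", "seedspan_schema_error")
  }
  dup <- df$species[duplicated(df$species)]
  if (length(dup)) {
    stop_seedspan(sprintf("duplicate species: %s",
                          paste(unique(dup), collapse = ", ")),
                  "seedspan_schema_error")
  }
  bad_e <- which(!df$endosperm %in% c("E", "N"))
  if (length(bad_e)) {
    stop_seedspan(sprintf("unknown endosperm level '%s' in row %d (column 'endosperm')",
                          df$endosperm[bad_e[1]], bad_e[1]),
                  "seedspan_schema_error")
  }
  bad_d <- which(!df$dormancy %in% c("ND", "PD", "PY"))
  if (length(bad_d)) {
    stop_seedspan(sprintf("unknown dormancy level '%s' in row %d (column 'dormancy')",
                          df$dormancy[bad_d[1]], bad_d[1]),
                  "seedspan_schema_error")
  }
  if (any(!is.finite(df$p50) | df$p50 <= 0)) {
    stop_seedspan("p50 must be finite and > 0 for every species (column 'p50')",
                  "seedspan_schema_error")
  }
  if (any(!is.finite(df$p50_se) | df$p50_se < 0)) {
    stop_seedspan("p50_se must be finite and >= 0 (column 'p50_se')",
                  "seedspan_schema_error")
  }
  for (col in c("tsw_mg", "length_mm", "width_mm", "height_mm", "mct_mm")) {
    if (col %in% names(df) && any(df[[col]] <= 0, na.rm = TRUE)) {
      stop_seedspan(sprintf("column '%s' must be positive where present", col),
                    "seedspan_schema_error")
    }
  }
  if ("vs" %in% names(df) &&
      any(df$vs < 0 | df$vs > 2 / 9 + 1e-12, na.rm = TRUE)) {
    stop_seedspan("column 'vs' must lie in [0, 2/9]", "seedspan_schema_error")
  }
  invisible(df)
}

#' Write a species trait table to CSV
#'
#' Inverse of [load_trait_table()]; a load/write round trip reproduces the
#' file field-for-field (missing values as `NA`).
#'
#' @param df A `trait_table` data.frame.
#' @param path Output CSV path.
#' @export
write_trait_table <- function(df, path) {
  validate_trait_table(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Rank species by longevity
#'
#' Adds (or overwrites) a `rank` column: 1 for the largest p50. Ties are
#' broken alphabetically by species name, with a message.
#'
#' @param df A `trait_table` data.frame.
#' @return The table with a `rank` column.
#' @export
rank_by_p50 <- function(df) {
  validate_trait_table(df)
  if (anyDuplicated(df$p50)) {
    message("tied p50 values; breaking ties by species name")
  }
  ord <- order(-df$p50, df$species)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  df
}

#' Build the analysis matrix for model fitting
#'
#' Converts a trait table into the per-species design used by the
#' regression stage: response `log10_p50`, optional log10-transformed
#' continuous predictors (`log10_tsw`, `log10_vs`, `log10_mct`) and the
#' binary indicators `non_endospermic`, `py`, `pd`. Continuous traits that
#' are missing stay NA here; model fitting drops incomplete rows and
#' reports the retained n.
#'
#' @param df A `trait_table` data.frame.
#' @return A data.frame (class `analysis_matrix`) with rownames = species.
#' @export
build_analysis_matrix <- function(df) {
  validate_trait_table(df)
  am <- data.frame(
    species = df$species,
    log10_p50 = log10(df$p50),
    non_endospermic = as.integer(df$endosperm == "N"),
    py = as.integer(df$dormancy == "PY"),
    pd = as.integer(df$dormancy == "PD"),
    stringsAsFactors = FALSE
  )
  am$log10_tsw <- if ("tsw_mg" %in% names(df)) log10(df$tsw_mg) else NA_real_
  am$log10_vs <- if ("vs" %in% names(df)) log10(df$vs) else NA_real_
  am$log10_mct <- if ("mct_mm" %in% names(df)) log10(df$mct_mm) else NA_real_
  rownames(am) <- gsub(" ", "_", df$species)
  class(am) <- c("analysis_matrix", "data.frame")
  am
}

#' The packaged 39-species grassland longevity dataset
#'
#' Fitted p50 (days) with standard errors, endosperm presence, dormancy
#' class, germination conditions and taxonomy for 39 calcareous dry
#' grassland species aged at 45 degrees C and 60 % eRH. This is the
#' package's worked fixture; it carries no continuous trait columns
#' (those measurements were never published).
#'
#' @param quiet Suppress the count message.
#' @return A `trait_table` data.frame with 39 rows.
#' @export
grassland_p50_table <- function(quiet = TRUE) {
  load_trait_table(seedspan_example("table1.csv"), quiet = quiet)
}
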