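## Phenotype tables: one row per strain/condition with measured growth
## rate, glucose uptake and acetate excretion (plus replicate SDs).
## Column contract shared by the reader, writer and synthetic generator.
PHENOTYPE_COLS <- c("strain_id", "dataset", "mu", "mu_sd",
                    "q_glc", "q_glc_sd", "q_ac", "q_ac_sd")
DATASET_TAGS <- c("ale", "wildtype", "chemostat", "titration", "synthetic")

#' Read a phenotype table from delimited text
#'
#' Expects the documented column contract (`strain_id`, `dataset`, `mu`,
#' `mu_sd`, `q_glc`, `q_glc_sd`, `q_ac`, `q_ac_sd`); the SD columns may
#' be empty. Uptake (`q_glc`) and secretion (`q_ac`) are both positive.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param sep Field separator (default comma).
#' @return A validated tibble of phenotype records.
#' @export
read_phenotypes <- function(path, sep = ",") {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character")
  missing_cols <- setdiff(PHENOTYPE_COLS, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  df <- as_tibble(raw[PHENOTYPE_COLS])
  num_cols <- setdiff(PHENOTYPE_COLS, c("strain_id", "dataset"))
  problems <- character()
  for (cc in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.na(df[[cc]]) & df[[cc]] != "" & is.na(vals))
    if (length(bad) > 0)
      problems <- c(problems, paste0(
        "non-numeric '", cc, "' at line(s) ",
        paste(bad + 1L, collapse = ", ")))  # +1 for the header line
    df[[cc]] <- vals
  }
  if (length(problems) > 0)
    abort(paste0("malformed phenotype table:\n  ",
                 paste(problems, collapse = "\n  ")))
  validate_phenotypes(df)
}

#' Validate phenotype records
#'
#' Enforces the record invariants: `mu >= 0`, `q_glc > 0` for growing
#' records (`mu > 0`), nonnegative SDs, known dataset tags. Violations
#' are reported with row numbers.
#'
#' @param df Phenotype tibble.
#' @return `df`, invisibly validated (returned unchanged).
#' @export
validate_phenotypes <- function(df) {
  problems <- character()
  flag <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad) > 0)
      problems <<- c(problems, paste0(msg, " at row(s) ",
                                      paste(bad, collapse = ", ")))
  }
  flag(is.na(df$mu) | df$mu < 0, "mu missing or negative")
  flag(df$mu > 0 & (is.na(df$q_glc) | df$q_glc <= 0),
       "q_glc not positive for growing record")
  flag(!is.na(df$q_ac) & df$q_ac < 0, "negative q_ac")
  for (cc in c("mu_sd", "q_glc_sd", "q_ac_sd"))
    flag(!is.na(df[[cc]]) & df[[cc]] < 0, paste0("negative ", cc))
  flag(!df$dataset %in% DATASET_TAGS,
       paste0("dataset tag not in {", paste(DATASET_TAGS, collapse = ", "),
              "}"))
  if (length(problems) > 0)
    abort(paste0("invalid phenotype records:\n  ",
                 paste(problems, collapse = "\n  ")))
  df
}

#' Write a phenotype table
#'
#' @param df Phenotype tibble (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(df, path) {
  validate_phenotypes(df)
  write.csv(df[PHENOTYPE_COLS], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Growth yield from growth rate and glucose uptake
#'
#' `Y = mu / (M_glc * q_glc)` in gDW per g glucose, with `M_glc` in
#' g/mmol so that `q_glc` (mmol gDW^-1 h^-1) and `mu` (h^-1) combine to
#' gram yield. `mu = 0` gives `Y = 0`; `q_glc = 0` with `mu > 0` is an
#' error (yield undefined).
#'
#' @param mu Growth rate(s), h^-1.
#' @param q_glc Glucose uptake rate(s), mmol gDW^-1 h^-1.
#' @param M_glc Molecular weight of glucose, g/mmol.
#' @return Numeric vector of yields.
#' @seealso [add_yield()] for the data-frame verb.
#' @export
compute_yield <- function(mu, q_glc, M_glc = MGLC_DEFAULT) {
  stopifnot(length(mu) == length(q_glc))
  if (any(mu > 0 & q_glc <= 0, na.rm = TRUE))
    abort("yield undefined: q_glc <= 0 with mu > 0")
  ifelse(mu == 0, 0, mu / (M_glc * q_glc))
}

#' Add a yield column to a phenotype table
#'
#' @param df Data frame with `mu` and `q_glc` columns.
#' @param M_glc Molecular weight of glucose, g/mmol.
#' @return `df` with a `Y` column appended.
#' @export
add_yield <- function(df, M_glc = MGLC_DEFAULT) {
  dplyr::mutate(df, Y = compute_yield(.data$mu, .data$q_glc, M_glc))
}

## Fixed-growth regression bins: strains within each narrow band are
## compared at (near-)constant mu.
DEFAULT_GROWTH_BINS <- tibble::tibble(
  lo = c(0.95, 1.00, 1.08),
  hi = c(0.97, 1.04, 1.10))

#' Assign records to growth-rate bins
#'
#' Bins are closed on both ends; a record falling on a shared boundary of
#' two touching bins goes to the lower bin. Overlapping bins are
#' rejected. Unassigned records get `NA`.
#'
#' @param df Phenotype data frame with a `mu` column.
#' @param bins Data frame with `lo` and `hi` columns (default: the three
#'   narrow high-growth bands 0.95-0.97, 1.00-1.04, 1.08-1.10 h^-1).
#' @return `df` with a `growth_bin` factor column (`"[lo,hi]"` labels).
#' @export
bin_by_growth <- function(df, bins = DEFAULT_GROWTH_BINS) {
  stopifnot(is.data.frame(bins), all(c("lo", "hi") %in% names(bins)),
            all(bins$lo <= bins$hi))
  bins <- dplyr::arrange(bins, .data$lo)
  if (nrow(bins) > 1) {
    overlap <- bins$lo[-1] < bins$hi[-nrow(bins)]
    if (any(overlap)) abort("overlapping growth bins")
  }
  labels <- sprintf("[%g,%g]", bins$lo, bins$hi)
  assign_one <- function(m) {
    if (is.na(m)) return(NA_character_)
    hits <- which(m >= bins$lo & m <= bins$hi)
    if (length(hits) == 0) NA_character_ else labels[hits[1]]  # lower bin wins
  }
  df$growth_bin <- factor(vapply(df$mu, assign_one, character(1)),
                          levels = labels)
  df
}

#' Fit the fixed-growth q_ac ~ q_glc regression (the d2 edge)
#'
#' Ordinary least squares of acetate excretion on glucose uptake within
#' one growth bin, the linear signature of the second tradeoff
#' dimension. `r_squared` is the squared Pearson correlation (symmetric
#' in the two axes) and the p-value is the two-sided Pearson correlation
#' t-test. With exactly 2 points the fit is exact (`r_squared = 1`) and
#' the p-value is undefined (`NA`, flagged degenerate); zero variance in
#' `q_glc` is also flagged.
#'
#' @param df Records of one group (columns `q_glc`, `q_ac`; >= 2 rows).
#' @return One-row tibble: `n`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `degenerate`.
#' @export
fit_d2_line <- function(df) {
  stopifnot(all(c("q_glc", "q_ac") %in% names(df)))
  n <- nrow(df)
  if (n < 2) abort("need at least 2 records for a d2 fit")
  if (sd(df$q_glc) < 1e-12)
    return(tibble(n = n, slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, p_value = NA_real_,
                  degenerate = TRUE))
  fit <- lm(q_ac ~ q_glc, data = df)
  r <- stats::cor(df$q_glc, df$q_ac)
  p <- if (n >= 3 && sd(df$q_ac) > 1e-12)
    cor.test(df$q_glc, df$q_ac)$p.value else NA_real_
  tibble(n = n, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r^2, p_value = p, degenerate = n < 3)
}

#' Per-bin d2 regressions
#'
#' @param df Binned phenotype records (see [bin_by_growth()]).
#' @return Tibble with one row per occupied bin with >= 2 records.
#' @export
fit_d2_lines <- function(df) {
  if (!"growth_bin" %in% names(df)) df <- bin_by_growth(df)
  keep <- dplyr::filter(df, !is.na(.data$growth_bin))
  groups <- split(keep, keep$growth_bin, drop = TRUE)
  groups <- groups[vapply(groups, nrow, integer(1)) >= 2]
  empty <- tibble(growth_bin = character(), n = integer(),
                  slope = numeric(), intercept = numeric(),
                  r_squared = numeric(), p_value = numeric(),
                  degenerate = logical())
  if (length(groups) == 0) return(empty)
  out <- purrr::imap(groups, function(g, nm)
    dplyr::bind_cols(tibble(growth_bin = nm), fit_d2_line(g)))
  dplyr::bind_rows(out)
}

#' Combined rate-yield tradeoff report
#'
#' Assembles the per-strain phenotypes (with yields), the per-bin d2
#' regressions, and optional model curves (yield-maximized curve and/or
#' envelopes) into one overlay-ready object.
#'
#' @param records Phenotype records.
#' @param model_curves Optional tibble of model curves (e.g. from
#'   [phenotype_curve()]); omitted gracefully when `NULL`.
#' @param bins Growth bins for the d2 fits.
#' @return An object of class `tradeoff_report`: list with `records`
#'   (with `Y` and `growth_bin`), `d2_fits`, `curves`.
#' @export
tradeoff_report <- function(records, model_curves = NULL,
                            bins = DEFAULT_GROWTH_BINS) {
  recs <- records |> add_yield() |> bin_by_growth(bins)
  structure(list(records = recs, d2_fits = fit_d2_lines(recs),
                 curves = model_curves),
            class = "tradeoff_report")
}

#' @export
print.tradeoff_report <- function(x, ...) {
  cat("<tradeoff_report> ", nrow(x$records), " records, ",
      nrow(x$d2_fits), " d2 fits",
      if (is.null(x$curves)) ", no model overlay" else ", with model overlay",
      "\n", sep = "")
  print(x$d2_fits)
  invisible(x)
}
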