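#' Configure a synthetic phenotype dataset
#'
#' Presets emulate the statistical structure of the measured phenotype
#' tables so every downstream stage is testable without external data:
#' \describe{
#'   \item{wildtype}{a single unevolved point on the yield-maximized
#'     curve (defaults echo a typical wild-type: `mu` 0.7 h^-1, `q_ac`
#'     3.9 mmol gDW^-1 h^-1).}
#'   \item{chemostat}{a low-growth series on the yield-maximized curve,
#'     where the NGAM demand drives the yield rise with `mu`.}
#'   \item{titration}{an uptake-titration series on the yield-maximized
#'     curve spanning the acetate threshold, following the
#'     threshold-linear acetate line up to near maximum growth.}
#'   \item{ale}{endpoint strains of growth-rate selection: near-constant
#'     `mu` in a narrow band with widely varying `q_glc`/`q_ac` along a
#'     linear `q_glc`-`q_ac` (d2) edge. Model-free. Defaults are
#'     illustrative, echoing the published ranges (`mu` band
#'     0.95-1.10 h^-1, `q_ac` spanning about 3.9-11.4).}
#' }
#' Noise is multiplicative Gaussian with per-variable coefficient of
#' variation `cv` (rates span an order of magnitude, so relative noise is
#' the natural replicate model); the replicate-SD columns are populated
#' from the same noise model (`sd = cv * value`).
#'
#' @param preset One of `"wildtype"`, `"chemostat"`, `"titration"`,
#'   `"ale"`.
#' @param n Number of records.
#' @param seed Mandatory integer seed.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (applied to `mu`, `q_glc`, `q_ac`).
#' @param ... Preset parameter overrides: for `ale`: `mu_mean`, `mu_sd`,
#'   `mu_range`, `qglc_range`, `d2_slope`, `d2_intercept`; for
#'   `chemostat`/`titration`: `mu_frac_range` (fractions of `mu_max`
#'   spanned); for `wildtype`: `mu_frac`.
#' @return A `synth_config` list.
#' @export
synth_config <- function(preset = c("ale", "wildtype", "chemostat",
                                    "titration"),
                         n = NULL, seed, cv = 0.02, ...) {
  preset <- match.arg(preset)
  if (missing(seed)) abort("`seed` is mandatory for synthetic data")
  stopifnot(cv >= 0)
  defaults <- switch(preset,
    ale = list(n = 8L, mu_mean = 1.025, mu_sd = 0.05,
               mu_range = c(0.9, 1.2), qglc_range = c(8.6, 13.6),
               d2_slope = 1.5, d2_intercept = -9.0),
    wildtype = list(n = 1L, mu_frac = 0.61),
    chemostat = list(n = 10L, mu_frac_range = c(0.04, 0.45)),
    titration = list(n = 20L, mu_frac_range = c(0.30, 0.995)))
  cfg <- modifyList(defaults, list(...))
  if (!is.null(n)) cfg$n <- as.integer(n)
  stopifnot(cfg$n >= 1)
  structure(c(list(preset = preset, seed = as.integer(seed), cv = cv), cfg),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic phenotype dataset
#'
#' Model-based presets (`wildtype`, `chemostat`, `titration`) sample the
#' yield-maximized curve of the supplied model (via the closed-form
#' coarse phenotypes); the `ale` preset draws strains along a specified
#' d2 edge with near-constant growth rate. Identical configurations
#' (including seed) produce identical datasets.
#'
#' @param config A [synth_config()].
#' @param model An `ssme_model`; required for model-based presets.
#' @return A phenotype tibble in the [read_phenotypes()] column contract,
#'   with `dataset` set to the preset tag.
#' @export
generate_phenotypes <- function(config, model = NULL) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  needs_model <- cfg$preset %in% c("wildtype", "chemostat", "titration")
  if (needs_model && is.null(model))
    abort(paste0("preset '", cfg$preset, "' requires a model"))
  with_seed(cfg$seed, {
    if (cfg$preset == "ale") {
      mu <- rnorm(cfg$n, cfg$mu_mean, cfg$mu_sd)
      mu <- pmin(pmax(mu, cfg$mu_range[1]), cfg$mu_range[2])
      q_glc <- if (cfg$n == 1) mean(cfg$qglc_range) else
        seq(cfg$qglc_range[1], cfg$qglc_range[2], length.out = cfg$n)
      q_ac <- cfg$d2_slope * q_glc + cfg$d2_intercept
    } else {
      cp <- coarse_params(model)
      mu_max <- analytic_acetate_line(cp)$mu_max
      fr <- if (cfg$preset == "wildtype") rep(cfg$mu_frac, cfg$n) else
        seq(cfg$mu_frac_range[1], cfg$mu_frac_range[2], length.out = cfg$n)
      mu <- fr * mu_max
      ph <- analytic_phenotype(cp, mu)
      q_glc <- ph$q_glc
      q_ac <- ph$q_ac
    }
    jitter <- function(x) x * (1 + cfg$cv * rnorm(length(x)))
    out <- tibble(
      strain_id = sprintf("%s_%02d", cfg$preset, seq_len(cfg$n)),
      dataset = cfg$preset,
      mu = jitter(mu), mu_sd = cfg$cv * mu,
      q_glc = jitter(q_glc), q_glc_sd = cfg$cv * q_glc,
      q_ac = pmax(0, jitter(q_ac)), q_ac_sd = cfg$cv * q_ac)
    validate_phenotypes(out)
  })
}
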