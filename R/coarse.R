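#' Map an SSME model to coarse-grained proteome-allocation parameters
#'
#' The three-pathway SSME model is a reformulation of the coarse-grained
#' proteome-allocation model of overflow metabolism, and the two are
#' related by a bijective parameter map. Writing `phi_i = e_i / P_total`
#' for the proteome fraction of pathway `i`, the coupling
#' `v_i <= k_eff_i * e_i` becomes `v_i <= eps_i * phi_i` with proteome
#' efficiency `eps_i = k_eff_i * P_total`; the proteome budget becomes
#' `sum(phi_i) <= phi_max0 = 1 - UPF`; and the biomass coupling
#' `mu <= k_eff_bms * e_bms` charges a proteome fraction `b * mu` with
#' `b = 1 / (k_eff_bms * P_total)` (the enzyme-dilution /
#' translation-machinery cost per unit growth). Maintenance terms map
#' identically (`sigma = GAM`, `ngam = NGAM`).
#'
#' @param ssme An `ssme_model` with the default three-pathway topology
#'   (no extensions or leak reactions).
#' @return An object of class `coarse_params`: named list with `eps_res`,
#'   `eps_fer`, `phi_max0`, `b`, `sigma`, `ngam`, `a_res`, `a_fer`,
#'   `n_ac`, `M_glc`, `c_bms`, `P_total`.
#' @seealso [coarse_to_ssme()] for the inverse map,
#'   [analytic_phenotype()] for the closed-form phenotypes.
#' @export
coarse_params <- function(ssme) {
  stopifnot(inherits(ssme, "ssme_model"))
  if (!setequal(ssme$reactions$id,
                c("EX_glc", "RES", "FER", "BMS", "EX_ac", "EX_o2",
                  "EX_co2", "NGAM")))
    abort(paste0("coarse mapping supports only the default three-pathway ",
                 "topology; remove extensions/leak reactions first"))
  p <- ssme_params(ssme)
  structure(list(
    eps_res = p$k_eff_res * p$P_total,
    eps_fer = p$k_eff_fer * p$P_total,
    phi_max0 = 1 - p$UPF,
    b = 1 / (p$k_eff_bms * p$P_total),
    sigma = p$GAM, ngam = p$NGAM,
    a_res = p$a_res, a_fer = p$a_fer, n_ac = p$n_ac,
    M_glc = p$M_glc, c_bms = p$c_bms, P_total = p$P_total),
    class = "coarse_params")
}

#' Inverse of the coarse parameter map
#'
#' @param params A `coarse_params` object.
#' @param ... Further arguments passed to [ssme_model()]
#'   (e.g. `o2_per_glc`).
#' @return The `ssme_model` whose [coarse_params()] equal `params`.
#' @export
coarse_to_ssme <- function(params, ...) {
  stopifnot(inherits(params, "coarse_params"))
  ssme_model(
    k_eff_res = params$eps_res / params$P_total,
    k_eff_fer = params$eps_fer / params$P_total,
    k_eff_bms = 1 / (params$b * params$P_total),
    UPF = 1 - params$phi_max0, GAM = params$sigma, NGAM = params$ngam,
    P_total = params$P_total, M_glc = params$M_glc,
    a_res = params$a_res, a_fer = params$a_fer, n_ac = params$n_ac,
    c_bms = params$c_bms, ...)
}

#' Closed-form yield-maximized phenotypes of the coarse model
#'
#' The yield-maximized (minimum `q_glc`) solution at fixed `mu` is
#' determined by at most two binding constraints, giving a closed form.
#' Below the overflow threshold `mu_t`, ATP demand
#' `D = sigma * mu + ngam` is met by respiration alone
#' (`J_res = D / a_res`) with proteome slack. Above `mu_t` the proteome
#' budget `phi_max0 - b * mu` also binds, and demand is met by the mix of
#' respiration (highest ATP per glucose) and fermentation (highest ATP per
#' proteome), so fermentation - and with it acetate excretion
#' `q_ac = n_ac * J_fer` - grows linearly in `mu` up to the
#' proteome-exhaustion maximum `mu_max` (pure fermentation). Glucose
#' uptake adds the biomass carbon demand: `q_glc = J_res + J_fer +
#' c_bms * mu`, and `Y = mu / (M_glc * q_glc)`.
#'
#' @param params A `coarse_params` object.
#' @param mu Growth rate(s), h^-1 (vectorized).
#' @return Tibble with columns `mu`, `q_glc`, `q_ac`, `Y`, `regime`
#'   (`"respiration"` or `"overflow"`), `status` (`"optimal"` or
#'   `"infeasible"` beyond `mu_max`). `Y` is `NA` where `q_glc = 0`.
#' @export
analytic_phenotype <- function(params, mu) {
  stopifnot(inherits(params, "coarse_params"))
  core <- analytic_phenotype_core(params, mu)
  tibble(mu = mu, q_glc = core$q_glc, q_ac = core$q_ac, Y = core$Y,
         regime = core$regime,
         status = ifelse(core$feasible, "optimal", "infeasible"))
}

## Vectorized numeric kernel of the closed form (no data-frame
## overhead); used directly by the calibration loss.
analytic_phenotype_core <- function(p, mu) {
  A <- p$a_res * p$eps_res  # ATP per proteome fraction per h, respiration
  F_ <- p$a_fer * p$eps_fer
  mu_max <- (F_ * p$phi_max0 - p$ngam) / (p$sigma + F_ * p$b)
  feasible <- mu >= 0 & mu <= mu_max + 1e-12
  D <- p$sigma * mu + p$ngam
  avail <- p$phi_max0 - p$b * mu
  denom <- p$a_fer - p$a_res * p$eps_res / p$eps_fer
  overflow <- D > A * avail + 1e-15
  J_fer <- ifelse(overflow, (D - A * avail) / denom, 0)
  J_res <- ifelse(overflow, p$eps_res * (avail - J_fer / p$eps_fer),
                  D / p$a_res)
  q_glc <- J_res + J_fer + p$c_bms * mu
  out <- list(q_glc = q_glc, q_ac = p$n_ac * J_fer,
              Y = ifelse(q_glc > 0, mu / (p$M_glc * q_glc), NA_real_),
              regime = ifelse(overflow, "overflow", "respiration"),
              feasible = feasible, mu_max = mu_max)
  for (nm in c("q_glc", "q_ac", "Y")) out[[nm]][!feasible] <- NA_real_
  out$regime[!feasible] <- NA_character_
  out
}

#' Closed-form acetate line of the coarse model
#'
#' The acetate overflow response of the yield-maximized solution is
#' threshold-linear: `q_ac(mu) = max(0, slope * (mu - mu_threshold))`,
#' with `mu_threshold = (A * phi_max0 - ngam) / (sigma + A * b)` (where
#' `A = a_res * eps_res` is the ATP supply per proteome fraction of pure
#' respiration), `slope = n_ac * (sigma + A * b) / (a_fer - a_res *
#' eps_res / eps_fer)`, and proteome-exhaustion maximum growth rate
#' `mu_max = (F * phi_max0 - ngam) / (sigma + F * b)` with
#' `F = a_fer * eps_fer` (pure fermentation, the proteome-cheapest ATP
#' source).
#'
#' @param params A `coarse_params` object.
#' @return List with `mu_threshold`, `slope`, `mu_max`.
#' @export
analytic_acetate_line <- function(params) {
  stopifnot(inherits(params, "coarse_params"))
  p <- params
  A <- p$a_res * p$eps_res
  F_ <- p$a_fer * p$eps_fer
  denom <- p$a_fer - p$a_res * p$eps_res / p$eps_fer
  if (abs(denom) < 1e-12 && abs(p$a_res - p$a_fer) < 1e-12)
    abort("degenerate parameters: pathways indistinguishable, no unique acetate line")
  if (F_ <= A)
    abort(paste0("fermentation must be the proteome-cheaper ATP source ",
                 "(a_fer * eps_fer > a_res * eps_res) for a threshold-linear ",
                 "acetate response"))
  mu_t <- (A * p$phi_max0 - p$ngam) / (p$sigma + A * p$b)
  mu_max <- (F_ * p$phi_max0 - p$ngam) / (p$sigma + F_ * p$b)
  list(mu_threshold = max(0, mu_t),
       slope = p$n_ac * (p$sigma + A * p$b) / denom,
       mu_max = mu_max)
}
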