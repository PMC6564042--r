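## Growth-rate maximization and solution-space machinery. The SSME
## constraints are linear only at fixed mu (mu multiplies the biomass
## pinning and the GAM demand), so mu_max is found by bisection over LP
## feasibility, and envelopes/contours are per-point LPs.

#' Solve one phenotype LP and package the result
#'
#' @param model An `ssme_model`.
#' @param mu Growth rate, h^-1.
#' @param objective `"max_yield"` (minimize `q_glc`, the yield-maximized
#'   solution), `"min_yield"`, `"max_qac"` or `"min_qac"`.
#' @param fix_fluxes Optional named vector pinning fluxes (see
#'   [build_lp()]).
#' @return A `flux_solution`: list with `mu`, `fluxes`, `enzymes`,
#'   `q_glc`, `q_ac`, `Y`, `split_fraction`, `po_proxy`, `status`,
#'   `objective`. Infeasible growth rates give `status = "infeasible"`
#'   with no error.
#' @export
phenotype_at <- function(model, mu,
                         objective = c("max_yield", "min_yield",
                                       "max_qac", "min_qac"),
                         fix_fluxes = NULL) {
  objective <- match.arg(objective)
  lp_obj <- switch(objective,
    max_yield = "min_qglc", min_yield = "max_qglc",
    max_qac = "max_qac", min_qac = "min_qac")
  lp <- build_lp(model, mu, lp_obj, fix_fluxes = fix_fluxes)
  res <- solve_lp(lp)
  as_flux_solution(model, mu, res, objective)
}

as_flux_solution <- function(model, mu, res, objective) {
  g <- model$globals
  if (res$status != "optimal") {
    return(structure(list(mu = mu, fluxes = NULL, enzymes = NULL,
                          q_glc = NA_real_, q_ac = NA_real_, Y = NA_real_,
                          split_fraction = NA_real_, po_proxy = NA_real_,
                          status = res$status, objective = objective),
                     class = "flux_solution"))
  }
  v <- res$fluxes
  q_glc <- unname(v["EX_glc"])
  q_ac <- unname(v["EX_ac"])
  d <- solution_diagnostics(model, v)
  structure(list(
    mu = mu, fluxes = v, enzymes = res$enzymes,
    q_glc = q_glc, q_ac = q_ac,
    Y = if (q_glc > 1e-12) mu / (g$M_glc * q_glc) else NA_real_,
    split_fraction = d$split_fraction, po_proxy = d$po_proxy,
    status = "optimal", objective = objective),
    class = "flux_solution")
}

## P/O proxy and acetyl-CoA-equivalent split fraction of a flux vector.
## po_proxy = (ATP made by O2-consuming pathways - leak drain) per 2
## electron-pair-equivalents of O2 flux; the genome-scale P/O is a
## specific ATPS/O2 flux ratio, this is its aggregate analog.
solution_diagnostics <- function(model, fluxes) {
  rx <- model$reactions
  atp_of <- function(i) {
    a <- rx$stoich[[i]]["atp"]; if (is.na(a)) 0 else unname(a)
  }
  uses_o2 <- vapply(rx$stoich, function(s) !is.na(s["o2"]) && s["o2"] < 0,
                    logical(1))
  makes_ac <- vapply(rx$stoich, function(s) !is.na(s["ac"]) && s["ac"] > 0,
                     logical(1))
  catalyzed <- !is.na(rx$k_eff)
  v <- fluxes[rx$id]
  resp_flux <- sum(v[uses_o2 & catalyzed])
  ferm_flux <- sum(v[makes_ac & catalyzed])
  resp_atp <- sum(v[uses_o2] * vapply(which(uses_o2), atp_of, numeric(1)))
  leak <- rx$tag == "leak"
  leak_drain <- if (any(leak))
    -sum(v[leak] * vapply(which(leak), atp_of, numeric(1))) else 0
  q_o2 <- unname(fluxes["EX_o2"])
  list(
    split_fraction = if (resp_flux + ferm_flux > 1e-12)
      resp_flux / (resp_flux + ferm_flux) else NA_real_,
    po_proxy = if (!is.na(q_o2) && q_o2 > 1e-12)
      (resp_atp - leak_drain) / (2 * q_o2) else NA_real_)
}

#' Derived metrics of an optimal flux solution
#'
#' @param sol A `flux_solution` with `status == "optimal"`.
#' @param model The `ssme_model` it was solved on.
#' @return One-row tibble with `mu`, `q_glc`, `q_ac`, `Y`,
#'   `split_fraction` (respiratory share of acetyl-CoA-equivalent carbon)
#'   and `po_proxy` (ATP per 2 electron-pair-equivalents of O2; `NA` when
#'   there is no O2 flux).
#' @export
diagnostics <- function(sol, model) {
  stopifnot(inherits(sol, "flux_solution"))
  if (sol$status != "optimal") abort("diagnostics require an optimal solution")
  d <- solution_diagnostics(model, sol$fluxes)
  tibble(mu = sol$mu, q_glc = sol$q_glc, q_ac = sol$q_ac, Y = sol$Y,
         split_fraction = d$split_fraction, po_proxy = d$po_proxy)
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status=", x$status, " objective=", x$objective,
      "\n", sep = "")
  if (x$status == "optimal")
    cat(sprintf("  mu=%.4f q_glc=%.4f q_ac=%.4f Y=%.4f split=%.3f\n",
                x$mu, x$q_glc, x$q_ac, x$Y, x$split_fraction))
  invisible(x)
}

#' @export
tidy.flux_solution <- function(x, ...) {
  if (x$status != "optimal")
    return(tibble(variable = character(), kind = character(),
                  value = numeric()))
  dplyr::bind_rows(
    tibble(variable = names(x$fluxes), kind = "flux",
           value = unname(x$fluxes)),
    tibble(variable = names(x$enzymes), kind = "enzyme",
           value = unname(x$enzymes)))
}

#' @export
glance.flux_solution <- function(x, ...) {
  tibble(mu = x$mu, q_glc = x$q_glc, q_ac = x$q_ac, Y = x$Y,
         split_fraction = x$split_fraction, po_proxy = x$po_proxy,
         status = x$status, objective = x$objective)
}

#' Maximum growth rate by bisection over LP feasibility
#'
#' Feasibility of the SSME constraints is monotone in `mu` (growing
#' faster never relaxes a constraint), so the proteome-exhaustion maximum
#' growth rate is located by bisection: the bracket is initialized at
#' `[0, mu_hi]` with geometric expansion of `mu_hi` until infeasible,
#' then halved to tolerance.
#'
#' @param model An `ssme_model`.
#' @param tol Bisection tolerance on `mu`, h^-1.
#' @param mu_hi Initial upper bracket guess.
#' @return `mu_max` (h^-1): feasible, with `mu_max + tol` infeasible.
#' @export
max_growth <- function(model, tol = 1e-6, mu_hi = 1) {
  feasible <- function(m)
    solve_lp(build_lp(model, m, "min_qglc"))$status == "optimal"
  if (!feasible(0))
    abort("model infeasible at mu = 0 (maintenance demand unsatisfiable)")
  lo <- 0
  expansions <- 0L
  while (feasible(mu_hi)) {
    lo <- mu_hi
    mu_hi <- mu_hi * 2
    expansions <- expansions + 1L
    if (expansions > 20L)
      abort("growth rate appears unbounded; check model constraints")
  }
  while (mu_hi - lo > tol) {
    mid <- (lo + mu_hi) / 2
    if (feasible(mid)) lo <- mid else mu_hi <- mid
  }
  lo
}

#' Yield-maximized phenotype curve over a growth-rate grid
#'
#' @param model An `ssme_model`.
#' @param mu_grid Growth rates; default 50 points on
#'   `[0, mu_max - 1e-6]` (half-open at the exhaustion point to avoid the
#'   degenerate pinch vertex).
#' @param objective Objective passed to [phenotype_at()].
#' @return Tibble with one row per `mu`: `mu`, `q_glc`, `q_ac`, `Y`,
#'   `split_fraction`, `po_proxy`, `status`, `objective`.
#' @export
phenotype_curve <- function(model, mu_grid = NULL, objective = "max_yield") {
  if (is.null(mu_grid)) {
    mu_max <- max_growth(model)
    mu_grid <- seq(0, mu_max - 1e-6, length.out = 50)
  }
  purrr::map_dfr(mu_grid, function(m)
    glance(phenotype_at(model, m, objective)))
}

#' Feasible solution-space envelope over growth rate
#'
#' For each `mu` on the grid, the feasible `[min, max]` interval of the
#' chosen phenotype variable, computed by a pair of LPs per point. For
#' `variable = "Y"` the interval is derived from the `q_glc` interval
#' (`Y_max` from `q_glc_min` and vice versa). Infeasible grid points are
#' kept with `status = "infeasible"`, not dropped.
#'
#' @param model An `ssme_model`.
#' @param mu_grid Growth-rate grid; default 40 points up to
#'   `mu_max - 1e-6`.
#' @param variable `"q_ac"` or `"Y"`.
#' @return A tibble of class `ssme_envelope` with columns `mu`,
#'   `<variable>_min`, `<variable>_max` (plus `q_glc_min`, `q_glc_max`
#'   for `"Y"`) and `status`; attributes `variable` and `provenance`.
#' @export
envelope_over_mu <- function(model, mu_grid = NULL,
                             variable = c("q_ac", "Y")) {
  variable <- match.arg(variable)
  if (is.null(mu_grid)) {
    mu_max <- max_growth(model)
    mu_grid <- seq(0, mu_max - 1e-6, length.out = 40)
  }
  if (length(mu_grid) == 0) abort("empty mu grid")
  g <- model$globals
  rows <- purrr::map_dfr(mu_grid, function(m) {
    lo <- phenotype_at(model, m, if (variable == "q_ac") "min_qac" else "min_yield")
    hi <- phenotype_at(model, m, if (variable == "q_ac") "max_qac" else "max_yield")
    if (lo$status != "optimal" || hi$status != "optimal")
      return(tibble(mu = m, vmin = NA_real_, vmax = NA_real_,
                    q_glc_min = NA_real_, q_glc_max = NA_real_,
                    status = "infeasible"))
    if (variable == "q_ac") {
      tibble(mu = m, vmin = lo$q_ac, vmax = hi$q_ac,
             q_glc_min = NA_real_, q_glc_max = NA_real_, status = "optimal")
    } else {
      ## hi solved min q_glc (max yield), lo solved max q_glc (min yield)
      tibble(mu = m,
             vmin = if (lo$q_glc > 1e-12) m / (g$M_glc * lo$q_glc) else NA_real_,
             vmax = if (hi$q_glc > 1e-12) m / (g$M_glc * hi$q_glc) else NA_real_,
             q_glc_min = hi$q_glc, q_glc_max = lo$q_glc, status = "optimal")
    }
  })
  names(rows)[names(rows) == "vmin"] <- paste0(variable, "_min")
  names(rows)[names(rows) == "vmax"] <- paste0(variable, "_max")
  if (variable == "q_ac") rows$q_glc_min <- rows$q_glc_max <- NULL
  structure(rows,
            class = c("ssme_envelope", class(tibble())),
            variable = variable,
            provenance = list(model_hash = rlang::hash(model)))
}

#' Fixed-growth-rate solution-space contour over glucose uptake
#'
#' At a fixed `mu`, sweeps `q_glc` over its feasible range and computes
#' the feasible `[q_ac_min, q_ac_max]` interval with `q_glc` pinned.
#' Attaches `Y = mu / (M_glc * q_glc)` (yield falls inversely as uptake
#' rises: the second, fixed-`mu` dimension of the rate-yield tradeoff)
#' and, from the `q_ac`-maximized edge solution, the acetyl-CoA split
#' fraction and P/O proxy. Grid points outside the feasible `q_glc` range
#' are flagged, not dropped.
#'
#' @param model An `ssme_model`.
#' @param mu Fixed growth rate (must be feasible).
#' @param qglc_grid Optional `q_glc` grid; default `n` points spanning
#'   the feasible range.
#' @param n Grid size when `qglc_grid` is `NULL`.
#' @return A tibble of class `ssme_contour`: `mu`, `q_glc`, `q_ac_min`,
#'   `q_ac_max`, `Y`, `split_fraction`, `po_proxy`, `status`.
#' @export
contour_at_mu <- function(model, mu, qglc_grid = NULL, n = 25) {
  lo <- phenotype_at(model, mu, "max_yield")
  hi <- phenotype_at(model, mu, "min_yield")
  if (lo$status != "optimal")
    abort(sprintf("mu = %g is infeasible for this model", mu))
  q_min <- lo$q_glc; q_max <- hi$q_glc
  if (is.null(qglc_grid)) {
    ## pull the default grid a hair inside the pinch endpoints, where
    ## pinning q_glc at its exact optimum leaves a fully degenerate LP
    eps <- 1e-7 * max(q_max - q_min, 1e-3)
    qglc_grid <- seq(q_min + eps, q_max - eps, length.out = n)
  }
  g <- model$globals
  rows <- purrr::map_dfr(qglc_grid, function(q) {
    amin <- phenotype_at(model, mu, "min_qac", fix_fluxes = c(EX_glc = q))
    amax <- phenotype_at(model, mu, "max_qac", fix_fluxes = c(EX_glc = q))
    if (amin$status != "optimal" || amax$status != "optimal")
      return(tibble(mu = mu, q_glc = q, q_ac_min = NA_real_,
                    q_ac_max = NA_real_, Y = NA_real_,
                    split_fraction = NA_real_, po_proxy = NA_real_,
                    status = "infeasible"))
    tibble(mu = mu, q_glc = q, q_ac_min = amin$q_ac, q_ac_max = amax$q_ac,
           Y = mu / (g$M_glc * q),
           split_fraction = amax$split_fraction, po_proxy = amax$po_proxy,
           status = "optimal")
  })
  structure(rows,
            class = c("ssme_contour", class(tibble())),
            mu = mu,
            provenance = list(model_hash = rlang::hash(model)))
}
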