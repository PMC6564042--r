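## LP embodiment of the SSME model at a fixed growth rate.
##
## Variables: one flux per reaction plus one mass variable per enzyme
## species (all >= 0; uptake/secretion sign conventions are carried by the
## stoichiometry, so every variable is nonnegative). Constraints:
##   * steady-state mass balance per metabolite-role species (the ATP row
##     is the energy balance: pathway ATP production minus GAM*mu, NGAM and
##     any leak/futile drains equals zero),
##   * coupling v_i <= k_eff_i * e_i per catalyzed reaction (the biomass
##     coupling mu <= k_eff_bms * e_bms carries the enzyme-dilution charge),
##   * proteome budget sum(e_i) <= (1 - UPF) * P_total,
##   * the biomass flux pinned to mu, fixed-flux pseudo reactions (NGAM,
##     leak) pinned to their level, and any finite reaction bounds.

LP_TOL <- 1e-9

#' Assemble the linear program of an SSME model at fixed growth rate
#'
#' @param model An `ssme_model`.
#' @param mu Growth rate, h^-1 (`mu >= 0`).
#' @param objective One of `"min_qglc"`, `"max_qglc"`, `"min_qac"`,
#'   `"max_qac"`, or a list `list(coef = <named numeric over variables>,
#'   maximize = <logical>)`.
#' @param fix_fluxes Optional named numeric vector pinning reaction fluxes
#'   (e.g. `c(EX_glc = 8)` for a fixed glucose uptake).
#' @return An object of class `ssme_lp`: list with variable names `vars`,
#'   objective `obj`/`maximize`, inequality system `A1 x <= b1`,
#'   equality system `A3 x = b3`, and row labels.
#' @seealso [solve_lp()]
#' @export
build_lp <- function(model, mu, objective = "min_qglc", fix_fluxes = NULL) {
  stopifnot(inherits(model, "ssme_model"))
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0)
    abort("`mu` must be a single nonnegative growth rate")
  sp <- model$species; rx <- model$reactions; g <- model$globals
  enzymes <- sp$id[sp$role == "enzyme"]
  mets <- sp$id[sp$role == "metabolite"]
  vars <- c(rx$id, enzymes)
  n <- length(vars)
  ix <- setNames(seq_len(n), vars)

  ## equalities: mass balances + pinned fluxes
  eq_rows <- list(); eq_rhs <- c(); eq_lab <- c()
  for (m in mets) {
    row <- numeric(n)
    for (i in seq_len(nrow(rx))) {
      coefm <- rx$stoich[[i]][m]
      if (!is.na(coefm)) row[ix[rx$id[i]]] <- coefm
    }
    eq_rows[[length(eq_rows) + 1L]] <- row
    eq_rhs <- c(eq_rhs, 0); eq_lab <- c(eq_lab, paste0("mass_", m))
  }
  pin <- c(BMS = unname(mu))
  fixed <- rx$id[is.finite(rx$lb) & rx$lb == rx$ub & rx$id != "BMS"]
  for (f in fixed) pin[f] <- rx$lb[rx$id == f]
  if (!is.null(fix_fluxes)) {
    unknown <- setdiff(names(fix_fluxes), rx$id)
    if (length(unknown) > 0)
      abort(paste0("fix_fluxes names not in model: ",
                   paste(unknown, collapse = ", ")))
    pin[names(fix_fluxes)] <- fix_fluxes
  }
  for (f in names(pin)) {
    row <- numeric(n); row[ix[f]] <- 1
    eq_rows[[length(eq_rows) + 1L]] <- row
    eq_rhs <- c(eq_rhs, pin[[f]]); eq_lab <- c(eq_lab, paste0("fix_", f))
  }

  ## inequalities: couplings, budget, finite upper/lower bounds
  le_rows <- list(); le_rhs <- c(); le_lab <- c()
  for (i in seq_len(nrow(rx))) {
    if (!is.na(rx$k_eff[i])) {
      row <- numeric(n)
      row[ix[rx$id[i]]] <- 1
      row[ix[rx$enzyme[i]]] <- -rx$k_eff[i]
      le_rows[[length(le_rows) + 1L]] <- row
      le_rhs <- c(le_rhs, 0); le_lab <- c(le_lab, paste0("cpl_", rx$id[i]))
    }
    free <- !(rx$id[i] %in% names(pin))
    if (free && is.finite(rx$ub[i])) {
      row <- numeric(n); row[ix[rx$id[i]]] <- 1
      le_rows[[length(le_rows) + 1L]] <- row
      le_rhs <- c(le_rhs, rx$ub[i]); le_lab <- c(le_lab, paste0("ub_", rx$id[i]))
    }
    if (free && rx$lb[i] > 0 && rx$lb[i] < rx$ub[i]) {
      row <- numeric(n); row[ix[rx$id[i]]] <- -1
      le_rows[[length(le_rows) + 1L]] <- row
      le_rhs <- c(le_rhs, -rx$lb[i]); le_lab <- c(le_lab, paste0("lb_", rx$id[i]))
    }
  }
  row <- numeric(n); row[ix[enzymes]] <- 1
  le_rows[[length(le_rows) + 1L]] <- row
  le_rhs <- c(le_rhs, (1 - g$UPF) * g$P_total)
  le_lab <- c(le_lab, "budget")

  obj <- parse_objective(objective, ix)
  structure(list(
    vars = vars, obj = obj$coef, maximize = obj$maximize,
    A1 = do.call(rbind, le_rows), b1 = le_rhs, le_lab = le_lab,
    A3 = do.call(rbind, eq_rows), b3 = eq_rhs, eq_lab = eq_lab,
    mu = mu, model = model), class = "ssme_lp")
}

parse_objective <- function(objective, ix) {
  n <- length(ix)
  if (is.character(objective) && length(objective) == 1L) {
    spec <- switch(objective,
      min_qglc = list(var = "EX_glc", maximize = FALSE),
      max_qglc = list(var = "EX_glc", maximize = TRUE),
      min_qac  = list(var = "EX_ac", maximize = FALSE),
      max_qac  = list(var = "EX_ac", maximize = TRUE),
      abort(paste0("unknown objective: ", objective)))
    coef <- numeric(n); coef[ix[spec$var]] <- 1
    return(list(coef = coef, maximize = spec$maximize))
  }
  if (is.list(objective) && !is.null(objective$coef)) {
    unknown <- setdiff(names(objective$coef), names(ix))
    if (length(unknown) > 0)
      abort(paste0("objective references unknown variables: ",
                   paste(unknown, collapse = ", ")))
    coef <- numeric(n)
    coef[ix[names(objective$coef)]] <- objective$coef
    return(list(coef = coef, maximize = isTRUE(objective$maximize)))
  }
  abort("`objective` must be a known name or list(coef=, maximize=)")
}

#' Solve an assembled SSME linear program
#'
#' Runs the simplex method ([boot::simplex()]) and re-verifies the
#' returned vertex against all constraints at 1e-8 before reporting it.
#' Degenerate optima are resolved by reporting the solver's vertex; only
#' objective values, never flux vectors, are asserted unique.
#'
#' @param lp An `ssme_lp` from [build_lp()].
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"unsolved"`), `objective` value, and the primal solution split into
#'   `fluxes` and `enzymes` (named numeric vectors).
#' @export
solve_lp <- function(lp) {
  stopifnot(inherits(lp, "ssme_lp"))
  ## boot::simplex requires nonnegative right-hand sides
  A1 <- lp$A1; b1 <- lp$b1; A3 <- lp$A3; b3 <- lp$b3
  A2 <- NULL; b2 <- NULL
  neg <- which(b1 < 0)
  if (length(neg) > 0) {
    A2 <- -A1[neg, , drop = FALSE]; b2 <- -b1[neg]
    A1 <- A1[-neg, , drop = FALSE]; b1 <- b1[-neg]
  }
  neg3 <- which(b3 < 0)
  if (length(neg3) > 0) {
    A3[neg3, ] <- -A3[neg3, , drop = FALSE]
    b3[neg3] <- -b3[neg3]
  }
  ## the simplex can hit NaN pivots on fully degenerate vertices (e.g. a
  ## flux pinned exactly at its optimum); treat that as unsolved rather
  ## than crashing
  res <- tryCatch(
    boot::simplex(a = lp$obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                  A3 = A3, b3 = b3, maxi = lp$maximize,
                  eps = LP_TOL / 10, n.iter = 200 + 20 * length(lp$obj)),
    error = function(e) list(solved = -2))
  if (res$solved == -2)
    return(list(status = "unsolved", objective = NA_real_,
                fluxes = NULL, enzymes = NULL))
  if (res$solved == -1)
    return(list(status = "infeasible", objective = NA_real_,
                fluxes = NULL, enzymes = NULL))
  if (res$solved != 1)
    return(list(status = "unsolved", objective = NA_real_,
                fluxes = NULL, enzymes = NULL))
  x <- setNames(as.numeric(res$soln), lp$vars)
  ok <- verify_lp_solution(lp, x)
  if (!ok)
    return(list(status = "unsolved", objective = NA_real_,
                fluxes = NULL, enzymes = NULL))
  enzymes <- lp$model$species$id[lp$model$species$role == "enzyme"]
  list(status = "optimal", objective = as.numeric(res$value),
       fluxes = x[setdiff(lp$vars, enzymes)], enzymes = x[enzymes])
}

## Post-hoc check of a primal vector against the assembled constraints.
verify_lp_solution <- function(lp, x, tol = 1e-8) {
  all(abs(lp$A3 %*% x - lp$b3) <= tol) &&
    all(lp$A1 %*% x - lp$b1 <= tol) &&
    all(x >= -tol)
}
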