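#' Fit a threshold-linear acetate line to (mu, q_ac) data
#'
#' Fits the continuous hinge `q_ac = max(0, slope * (mu - mu_threshold))`
#' by least squares. For a candidate threshold `t` the optimal slope is
#' the closed-form regression-through-origin coefficient on the hinge
#' basis `(mu - t)+`, so the breakpoint is found by a 1-D scan over
#' candidate thresholds followed by golden-section refinement of the best
#' cell. Noiseless hinge data are recovered exactly.
#'
#' @param data Data frame with columns `mu` and `q_ac` (at least 4
#'   points spanning both regimes for a meaningful fit).
#' @param n_scan Number of scan candidates across the `mu` range.
#' @return An object of class `acetate_line`: list with `mu_threshold`,
#'   `slope`, `mu_end` (maximum observed `mu`), `sse`, `degenerate`
#'   (TRUE when all `q_ac` are zero, in which case the slope is 0 and
#'   the threshold is `mu_end`), and `n`.
#' @export
extract_acetate_line <- function(data, n_scan = 201) {
  stopifnot(is.data.frame(data), all(c("mu", "q_ac") %in% names(data)))
  mu <- data$mu; qac <- data$q_ac
  if (length(mu) < 4) abort("need at least 4 (mu, q_ac) points")
  mu_end <- max(mu)
  if (all(qac <= 0)) {
    return(structure(list(mu_threshold = mu_end, slope = 0,
                          mu_end = mu_end, sse = sum(qac^2),
                          degenerate = TRUE, n = length(mu)),
                     class = "acetate_line"))
  }
  sse_at <- function(t) {
    h <- pmax(0, mu - t)
    denom <- sum(h^2)
    s <- if (denom > 0) max(0, sum(qac * h) / denom) else 0
    sum((qac - s * h)^2)
  }
  cand <- seq(min(mu), mu_end, length.out = n_scan)
  sse <- vapply(cand, sse_at, numeric(1))
  i <- which.min(sse)
  lo <- cand[max(1L, i - 1L)]; hi <- cand[min(length(cand), i + 1L)]
  opt <- optimize(sse_at, c(lo, hi), tol = 1e-12)
  t_hat <- if (opt$objective <= sse[i]) opt$minimum else cand[i]
  h <- pmax(0, mu - t_hat)
  s_hat <- max(0, sum(qac * h) / sum(h^2))
  structure(list(mu_threshold = t_hat, slope = s_hat, mu_end = mu_end,
                 sse = sse_at(t_hat), degenerate = FALSE, n = length(mu)),
            class = "acetate_line")
}

#' @export
print.acetate_line <- function(x, ...) {
  cat(sprintf("<acetate_line> threshold=%.4f slope=%.3f mu_end=%.4f%s\n",
              x$mu_threshold, x$slope, x$mu_end,
              if (x$degenerate) " [degenerate: all q_ac = 0]" else ""))
  invisible(x)
}

#' @export
tidy.acetate_line <- function(x, ...) {
  tibble(term = c("mu_threshold", "slope", "mu_end"),
         estimate = c(x$mu_threshold, x$slope, x$mu_end))
}

## Weighted SSE of model-predicted (q_ac, Y) against observed records.
## Infeasible observations (mu beyond the parameterization's mu_max) are
## charged a large smooth penalty so the optimizer is pushed back toward
## parameter regions covering the data.
fit_loss <- function(theta, base_cp, obs) {
  ## theta overrides the four fitted globals on the mapped coarse scale
  ## (eps_res = k_eff_res * P_total, phi_max0 = 1 - UPF, sigma = GAM,
  ## ngam = NGAM); identical to refitting the SSME model and re-mapping
  cp <- base_cp
  cp$eps_res <- theta[["k_eff_res"]] * cp$P_total
  cp$phi_max0 <- 1 - theta[["UPF"]]
  cp$sigma <- theta[["GAM"]]
  cp$ngam <- theta[["NGAM"]]
  ## outside the overflow-capable regime (respiration proteome-cheaper
  ## than fermentation) there is no acetate line; penalize smoothly so
  ## the optimizer is steered back rather than stopped
  A <- cp$a_res * cp$eps_res; F_ <- cp$a_fer * cp$eps_fer
  if (F_ <= A * (1 + 1e-9))
    return(1e8 * (1 + A / F_))
  mu_max <- (F_ * cp$phi_max0 - cp$ngam) / (cp$sigma + F_ * cp$b)
  over <- pmax(0, obs$mu - mu_max + 1e-9)
  ph <- analytic_phenotype_core(cp, pmin(obs$mu, mu_max))
  y_pred <- ifelse(is.na(ph$Y), 0, ph$Y)
  sum(obs$w_qac * (ph$q_ac - obs$q_ac)^2) +
    sum(obs$w_y * (y_pred - obs$Y)^2) +
    1e4 * sum(over^2) + 1e2 * sum(over)
}

collect_obs <- function(datasets, M_glc) {
  df <- dplyr::bind_rows(datasets, .id = "group")
  stopifnot(all(c("mu", "q_glc", "q_ac") %in% names(df)))
  df$Y <- compute_yield(df$mu, df$q_glc, M_glc)
  ## inverse-variance weights from replicate SDs where present, with a
  ## variance floor at the median positive SD of the variable so that
  ## zero- or near-zero-SD records (e.g. exact zero acetate below the
  ## overflow threshold, whose multiplicative SD vanishes with the value)
  ## get large finite weights instead of degenerate infinite ones
  w_from_sd <- function(sd_col, value, fallback_w) {
    if (is.null(sd_col) || any(is.na(sd_col)) || !any(sd_col > 0))
      return(rep(fallback_w, length(value)))
    floor_sd <- median(sd_col[sd_col > 0])
    1 / pmax(sd_col, floor_sd)^2
  }
  df$w_qac <- w_from_sd(df$q_ac_sd, df$q_ac, 1)
  ## Y inherits its SD from q_glc (Y ~ mu/(M q)); without SDs, scale unit
  ## weights by the squared dynamic-range ratio so both variables
  ## contribute comparably
  y_sd <- if (!is.null(df$q_glc_sd)) df$Y * df$q_glc_sd / df$q_glc else NULL
  df$w_y <- w_from_sd(y_sd, df$Y, (max(df$q_ac) / max(df$Y))^2)
  df
}

#' Fit SSME global parameters to phenotype data
#'
#' Calibrates `k_eff_res`, `UPF`, `GAM` and `NGAM` against phenotype
#' datasets (typically an uptake-titration series spanning the acetate
#' threshold, a low-growth chemostat series, and a wild-type point) by
#' weighted least squares on `(q_ac, Y)` at the observed growth rates.
#' The staged logic mirrors how each parameter shapes the curves:
#' `k_eff_res` sets the acetate-line slope and threshold, `UPF` the line
#' extent and maximum growth rate, `GAM` the high-growth yield level,
#' and `NGAM` the low-growth yield rise. The stages are implemented as
#' coordinate descent (1-D minimizations of the full loss in that
#' order), followed by a joint Nelder-Mead polish on a transformed
#' unconstrained scale. The forward model is the closed-form
#' yield-maximized phenotype of the mapped coarse parameters, which the
#' LP path provably equals. Deterministic given data and options.
#'
#' @param model Base `ssme_model` providing all non-fitted parameters
#'   and the starting point.
#' @param datasets Named list of phenotype data frames (columns `mu`,
#'   `q_glc`, `q_ac`, optional `*_sd` columns used as inverse-variance
#'   weights), e.g. `list(titration = , chemostat = , wildtype = )`.
#' @param bounds Named list of `c(lower, upper)` for each of
#'   `k_eff_res`, `UPF`, `GAM`, `NGAM`.
#' @param sweeps Coordinate-descent sweeps before the joint polish.
#' @param polish_maxit Maximum Nelder-Mead iterations.
#' @return An object of class `ssme_fit`: list with `par` (named fitted
#'   values), `loss`, `residuals` (tibble per observation), `model`
#'   (the refitted `ssme_model`), `convergence`, `at_bound` (named
#'   logical), `bounds`, `n_obs`.
#' @export
fit_global_params <- function(model, datasets,
                              bounds = list(k_eff_res = c(0.5, 50),
                                            UPF = c(0.01, 0.9),
                                            GAM = c(1, 150),
                                            NGAM = c(0, 20)),
                              sweeps = 3, polish_maxit = 2000) {
  stopifnot(inherits(model, "ssme_model"), length(datasets) >= 1)
  obs <- collect_obs(datasets, model$globals$M_glc)
  base_cp <- coarse_params(model)
  p0 <- ssme_params(model)
  theta <- c(k_eff_res = p0$k_eff_res, UPF = p0$UPF,
             GAM = p0$GAM, NGAM = p0$NGAM)
  for (nm in names(theta))
    theta[nm] <- min(max(theta[nm], bounds[[nm]][1]), bounds[[nm]][2])

  ## staged coordinate descent, one parameter at a time
  order_ <- c("k_eff_res", "UPF", "GAM", "NGAM")
  for (s in seq_len(sweeps)) {
    for (nm in order_) {
      f1 <- function(v) { th <- theta; th[nm] <- v; fit_loss(th, base_cp, obs) }
      o <- optimize(f1, bounds[[nm]], tol = 1e-10)
      if (o$objective < fit_loss(theta, base_cp, obs)) theta[nm] <- o$minimum
    }
  }

  ## joint polish on an unconstrained scale (logit for UPF, log for the
  ## rest; NGAM offset so 0 stays reachable)
  to_u <- function(th) c(
    log(th[["k_eff_res"]]), stats::qlogis(th[["UPF"]]),
    log(th[["GAM"]]), log(th[["NGAM"]] + 1e-3))
  from_u <- function(u) {
    th <- c(k_eff_res = exp(u[1]), UPF = stats::plogis(u[2]),
            GAM = exp(u[3]), NGAM = max(0, exp(u[4]) - 1e-3))
    for (nm in names(th))
      th[nm] <- min(max(th[nm], bounds[[nm]][1]), bounds[[nm]][2])
    th
  }
  obj_u <- function(u) fit_loss(from_u(u), base_cp, obs)
  op <- optim(to_u(theta), obj_u, method = "Nelder-Mead",
              control = list(maxit = polish_maxit, reltol = 1e-14))
  op2 <- optim(op$par, obj_u, method = "Nelder-Mead",
               control = list(maxit = polish_maxit, reltol = 1e-14))
  theta_hat <- from_u(op2$par)
  loss <- fit_loss(theta_hat, base_cp, obs)

  fitted_model <- ssme_set_params(model,
    k_eff_res = theta_hat[["k_eff_res"]], UPF = theta_hat[["UPF"]],
    GAM = theta_hat[["GAM"]], NGAM = theta_hat[["NGAM"]])
  cp <- coarse_params(fitted_model)
  mu_cap <- analytic_acetate_line(cp)$mu_max
  ph <- analytic_phenotype(cp, pmin(obs$mu, mu_cap))
  residuals <- tibble(
    group = obs$group, mu = obs$mu,
    q_ac_obs = obs$q_ac, q_ac_fit = ph$q_ac,
    Y_obs = obs$Y, Y_fit = ph$Y)
  at_bound <- vapply(names(theta_hat), function(nm) {
    b <- bounds[[nm]]
    theta_hat[[nm]] <= b[1] + 1e-8 || theta_hat[[nm]] >= b[2] - 1e-8
  }, logical(1))
  structure(list(par = as.list(theta_hat), loss = loss,
                 residuals = residuals, model = fitted_model,
                 convergence = op2$convergence, at_bound = at_bound,
                 bounds = bounds, n_obs = nrow(obs)),
            class = "ssme_fit")
}

#' @export
print.ssme_fit <- function(x, ...) {
  cat("<ssme_fit> loss=", format(x$loss, digits = 6),
      " n_obs=", x$n_obs, "\n", sep = "")
  for (nm in names(x$par))
    cat(sprintf("  %-10s %.6g%s\n", nm, x$par[[nm]],
                if (x$at_bound[[nm]]) " [at bound]" else ""))
  invisible(x)
}

#' @export
tidy.ssme_fit <- function(x, ...) {
  tibble(term = names(x$par),
         estimate = unlist(x$par),
         lower = vapply(names(x$par), function(n) x$bounds[[n]][1], 1),
         upper = vapply(names(x$par), function(n) x$bounds[[n]][2], 1),
         at_bound = unname(x$at_bound[names(x$par)]))
}

#' @export
glance.ssme_fit <- function(x, ...) {
  tibble(loss = x$loss, n_obs = x$n_obs, convergence = x$convergence,
         any_at_bound = any(x$at_bound))
}
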