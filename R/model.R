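#' Build the default three-pathway SSME model
#'
#' Constructs the small-scale metabolism-and-expression (SSME) model of
#' aerobic glucose metabolism: a respiration pathway (high ATP per glucose,
#' low flux per enzyme), an acetate-fermentation pathway (low ATP per
#' glucose, high flux per enzyme), and a biomass-synthesis pathway, each
#' coupled to a dedicated enzyme through an effective turnover rate
#' `k_eff` (flux <= k_eff * enzyme). A shared proteome budget caps the sum
#' of enzyme mass fractions at `(1 - UPF) * P_total`, and an ATP balance
#' carries the growth-associated (`GAM`) and non-growth-associated (`NGAM`)
#' maintenance demands. At any fixed growth rate `mu` the model is a linear
#' program; across `mu` it reproduces the threshold-linear acetate
#' overflow response.
#'
#' All fluxes are in mmol gDW^-1 h^-1, enzymes in g gDW^-1, and `k_eff` in
#' mmol per g enzyme per h. Uptakes (`q_glc`, O2) and secretions (`q_ac`,
#' CO2) are both reported as positive fluxes.
#'
#' @param k_eff_res,k_eff_fer,k_eff_bms Effective turnover rates of the
#'   respiration, fermentation and biomass-synthesis enzymes.
#' @param UPF Unmodeled protein fraction in `[0, 1)`: the share of the
#'   proteome unavailable to the three modeled pathways.
#' @param GAM Growth-associated maintenance, mmol ATP per gDW.
#' @param NGAM Non-growth-associated maintenance, mmol ATP gDW^-1 h^-1.
#' @param P_total Total protein mass fraction of biomass, g per gDW.
#' @param M_glc Molecular weight of glucose, g per mmol (0.180156).
#' @param a_res,a_fer ATP produced per mmol glucose through respiration and
#'   fermentation. Respiration must be the metabolically more efficient
#'   route (`a_res > a_fer`).
#' @param n_ac mmol acetate per mmol glucose fermented.
#' @param o2_per_glc mmol O2 consumed per mmol glucose respired.
#' @param c_bms Biomass carbon requirement, mmol glucose-equivalent per gDW.
#' @param atp_per_leak ATP-equivalents drained per unit proton-leak flux
#'   (default 0.25, i.e. roughly four translocated protons per ATP).
#'
#' @return An object of class `ssme_model` with elements `species`
#'   (tibble: `id`, `role`, `carbon`), `reactions` (tibble: `id`, `stoich`
#'   list-column of named coefficient vectors, `k_eff`, `enzyme`, `lb`,
#'   `ub`, `tag`) and `globals` (named list).
#' @seealso [validate_model()], [ssme_set_params()], [max_growth()],
#'   [phenotype_at()]
#' @export
#' @examples
#' model <- ssme_model()
#' validate_model(model)$pass
ssme_model <- function(k_eff_res = 4.7, k_eff_fer = 21.2, k_eff_bms = 6,
                       UPF = 0.36, GAM = 35, NGAM = 1, P_total = 0.55,
                       M_glc = MGLC_DEFAULT, a_res = 26, a_fer = 12,
                       n_ac = 2, o2_per_glc = 6, c_bms = 6.7,
                       atp_per_leak = 0.25) {
  stopifnot(UPF >= 0, UPF < 1, GAM >= 0, NGAM >= 0, P_total > 0,
            a_res > a_fer, a_fer > 0, n_ac > 0, c_bms >= 0,
            k_eff_res > 0, k_eff_fer > 0, k_eff_bms > 0)
  species <- tibble(
    id     = c("glc", "ac", "o2", "co2", "atp", "biomass",
               "E_res", "E_fer", "E_bms"),
    role   = c(rep("metabolite", 5L), "sink", rep("enzyme", 3L)),
    carbon = c(6L, 2L, 0L, 1L, 0L, 0L, 0L, 0L, 0L))
  ## fermentation: glc -> n_ac acetate, remaining carbon to CO2
  co2_fer <- 6 - 2 * n_ac
  reactions <- tibble(
    id = c("EX_glc", "RES", "FER", "BMS", "EX_ac", "EX_o2", "EX_co2", "NGAM"),
    stoich = list(
      c(glc = 1),
      c(glc = -1, o2 = -o2_per_glc, co2 = 6, atp = a_res),
      c(glc = -1, ac = n_ac, co2 = co2_fer, atp = a_fer),
      c(glc = -c_bms, atp = -GAM, biomass = 1),
      c(ac = -1),
      c(o2 = 1),
      c(co2 = -1),
      c(atp = -1)),
    k_eff  = c(NA, k_eff_res, k_eff_fer, k_eff_bms, NA, NA, NA, NA),
    enzyme = c(NA, "E_res", "E_fer", "E_bms", NA, NA, NA, NA),
    lb = c(0, 0, 0, 0, 0, 0, 0, NGAM),
    ub = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, NGAM),
    tag = "core")
  globals <- list(UPF = UPF, GAM = GAM, NGAM = NGAM, P_total = P_total,
                  M_glc = M_glc, a_res = a_res, a_fer = a_fer, n_ac = n_ac,
                  o2_per_glc = o2_per_glc, c_bms = c_bms,
                  atp_per_leak = atp_per_leak)
  structure(list(species = species, reactions = reactions,
                 globals = globals),
            class = "ssme_model")
}

#' @export
print.ssme_model <- function(x, ...) {
  g <- x$globals
  cat("<ssme_model> ", nrow(x$species), " species, ",
      nrow(x$reactions), " reactions (",
      sum(!is.na(x$reactions$k_eff)), " catalyzed)\n", sep = "")
  cat(sprintf("  UPF=%.3g GAM=%.3g NGAM=%.3g P_total=%.3g a_res=%.3g a_fer=%.3g\n",
              g$UPF, g$GAM, g$NGAM, g$P_total, g$a_res, g$a_fer))
  invisible(x)
}

#' Extract the tunable global parameters of an SSME model
#'
#' @param model An `ssme_model`.
#' @return Named list with the globals plus the `k_eff` of each core
#'   catalyzed pathway (`k_eff_res`, `k_eff_fer`, `k_eff_bms`).
#' @export
ssme_params <- function(model) {
  stopifnot(inherits(model, "ssme_model"))
  keff <- function(id) model$reactions$k_eff[model$reactions$id == id]
  c(model$globals,
    list(k_eff_res = keff("RES"), k_eff_fer = keff("FER"),
         k_eff_bms = keff("BMS")))
}

#' Update global parameters of an SSME model
#'
#' Returns a modified copy; stoichiometric entries that depend on globals
#' (the GAM term of the biomass reaction, the fixed NGAM drain, the ATP and
#' acetate coefficients of respiration/fermentation) are kept in step.
#' Only the core three-pathway stoichiometry is rewritten; perturbation
#' reactions (leak, extensions) are left untouched.
#'
#' @param model An `ssme_model`.
#' @param ... Any of `k_eff_res`, `k_eff_fer`, `k_eff_bms`, `UPF`, `GAM`,
#'   `NGAM`, `P_total`, `M_glc`, `a_res`, `a_fer`, `n_ac`, `c_bms`,
#'   `atp_per_leak`.
#' @return The updated `ssme_model`.
#' @export
ssme_set_params <- function(model, ...) {
  stopifnot(inherits(model, "ssme_model"))
  upd <- list(...)
  allowed <- c(names(model$globals), "k_eff_res", "k_eff_fer", "k_eff_bms")
  bad <- setdiff(names(upd), allowed)
  if (length(bad) > 0)
    abort(paste0("unknown SSME parameter(s): ", paste(bad, collapse = ", ")))
  g <- modifyList(model$globals, upd[intersect(names(upd), names(model$globals))])
  r <- model$reactions
  set_keff <- function(r, id, val) { r$k_eff[r$id == id] <- val; r }
  if (!is.null(upd$k_eff_res)) r <- set_keff(r, "RES", upd$k_eff_res)
  if (!is.null(upd$k_eff_fer)) r <- set_keff(r, "FER", upd$k_eff_fer)
  if (!is.null(upd$k_eff_bms)) r <- set_keff(r, "BMS", upd$k_eff_bms)
  ## rebuild globals-dependent stoichiometry
  i <- match(c("RES", "FER", "BMS", "NGAM"), r$id)
  r$stoich[[i[1]]] <- c(glc = -1, o2 = -g$o2_per_glc, co2 = 6, atp = g$a_res)
  r$stoich[[i[2]]] <- c(glc = -1, ac = g$n_ac, co2 = 6 - 2 * g$n_ac,
                        atp = g$a_fer)
  r$stoich[[i[3]]] <- c(glc = -g$c_bms, atp = -g$GAM, biomass = 1)
  r$lb[i[4]] <- g$NGAM
  r$ub[i[4]] <- g$NGAM
  model$reactions <- r
  model$globals <- g
  model
}

## Reaction classification used by validation and the carbon-balance check.
## "interior" reactions convert metabolites among themselves and must be
## carbon-balanced; boundary reactions (exchanges, maintenance drains) and
## sink-coupled reactions (biomass) legitimately move carbon across the
## system boundary and are exempt.
reaction_is_interior <- function(stoich, species) {
  ids <- names(stoich)
  roles <- species$role[match(ids, species$id)]
  mets <- ids[!is.na(roles) & roles == "metabolite"]
  length(mets) >= 2L && !any(roles == "sink", na.rm = TRUE)
}

#' Validate an SSME model
#'
#' Checks structural consistency: unique identifiers, enzyme references
#' pointing at enzyme-role species, positive `k_eff` on catalyzed
#' reactions, ordered flux bounds, species that appear in no reaction, and
#' per-reaction carbon balance. The carbon residual of a reaction is
#' `sum(coefficient * carbon)` over its metabolite participants; it must be
#' zero for interior conversions, while exchange/drain and sink-coupled
#' (biomass) reactions are exempt because carbon crosses the boundary
#' there by construction.
#'
#' @param model An `ssme_model`.
#' @return An object of class `ssme_validation`: list with `checks` (a
#'   tibble of `check`, `subject`, `value`, `ok`) and `pass` (logical).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "ssme_model"))
  sp <- model$species; rx <- model$reactions
  checks <- list()
  add <- function(check, subject, value, ok)
    checks[[length(checks) + 1L]] <<- tibble(
      check = check, subject = subject, value = value, ok = ok)

  add("unique_species_ids", "model", anyDuplicated(sp$id), !anyDuplicated(sp$id))
  add("unique_reaction_ids", "model", anyDuplicated(rx$id), !anyDuplicated(rx$id))
  add("carbon_nonnegative", "model", min(sp$carbon), all(sp$carbon >= 0))
  for (i in seq_len(nrow(rx))) {
    id <- rx$id[i]
    add("bounds_ordered", id, rx$ub[i] - rx$lb[i], rx$lb[i] <= rx$ub[i])
    has_k <- !is.na(rx$k_eff[i]); has_e <- !is.na(rx$enzyme[i])
    add("coupling_consistent", id, NA_real_, has_k == has_e)
    if (has_k)
      add("k_eff_positive", id, rx$k_eff[i], rx$k_eff[i] > 0)
    if (has_e) {
      role <- sp$role[match(rx$enzyme[i], sp$id)]
      add("enzyme_reference", id, NA_real_,
          !is.na(role) && identical(role, "enzyme"))
    }
    unknown <- setdiff(names(rx$stoich[[i]]), sp$id)
    add("species_known", id, length(unknown), length(unknown) == 0)
    if (reaction_is_interior(rx$stoich[[i]], sp)) {
      st <- rx$stoich[[i]]
      carb <- sp$carbon[match(names(st), sp$id)]
      resid <- sum(st * ifelse(is.na(carb), 0, carb))
      add("carbon_balance", id, resid, abs(resid) < 1e-9)
    }
  }
  used <- unique(c(unlist(lapply(rx$stoich, names)),
                   rx$enzyme[!is.na(rx$enzyme)]))
  for (s in setdiff(sp$id, used))
    add("dangling_species", s, NA_real_, FALSE)
  checks <- dplyr::bind_rows(checks)
  structure(list(checks = checks, pass = all(checks$ok)),
            class = "ssme_validation")
}

#' @export
print.ssme_validation <- function(x, ...) {
  cat("<ssme_validation> ", if (x$pass) "PASS" else "FAIL",
      " (", sum(!x$checks$ok), " failing of ", nrow(x$checks), " checks)\n",
      sep = "")
  if (!x$pass) print(dplyr::filter(x$checks, !.data$ok), n = 20)
  invisible(x)
}

#' Write / read an SSME model as YAML
#'
#' Round-trips the full model (species, reactions with stoichiometry maps,
#' bounds and tags, global parameters) losslessly through a structured
#' text config.
#'
#' @param model An `ssme_model`.
#' @param path File path.
#' @return `ssme_write_model` returns `path` invisibly; `ssme_read_model`
#'   returns the `ssme_model`.
#' @export
ssme_write_model <- function(model, path) {
  stopifnot(inherits(model, "ssme_model"))
  rx <- model$reactions
  obj <- list(
    species = lapply(seq_len(nrow(model$species)), function(i)
      list(id = model$species$id[i], role = model$species$role[i],
           carbon = model$species$carbon[i])),
    reactions = lapply(seq_len(nrow(rx)), function(i)
      list(id = rx$id[i], stoichiometry = as.list(rx$stoich[[i]]),
           k_eff = if (is.na(rx$k_eff[i])) NULL else rx$k_eff[i],
           enzyme = if (is.na(rx$enzyme[i])) NULL else rx$enzyme[i],
           lb = rx$lb[i], ub = if (is.finite(rx$ub[i])) rx$ub[i] else ".inf",
           tag = rx$tag[i])),
    globals = model$globals)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname ssme_write_model
#' @export
ssme_read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  species <- dplyr::bind_rows(lapply(obj$species, function(s)
    tibble(id = s$id, role = s$role, carbon = as.integer(s$carbon))))
  reactions <- dplyr::bind_rows(lapply(obj$reactions, function(r)
    tibble(id = r$id, stoich = list(unlist(r$stoichiometry)),
           k_eff = r$k_eff %||% NA_real_, enzyme = r$enzyme %||% NA_character_,
           lb = as.numeric(r$lb),
           ub = if (identical(r$ub, ".inf")) Inf else as.numeric(r$ub),
           tag = r$tag)))
  structure(list(species = species, reactions = reactions,
                 globals = obj$globals),
            class = "ssme_model")
}
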