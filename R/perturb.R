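## Model perturbations creating the second tradeoff dimension. All are
## pure functions: the input model is never modified.

add_reaction <- function(model, id, stoich, k_eff = NA_real_,
                         enzyme = NA_character_, lb = 0, ub = Inf,
                         tag = "core", new_species = NULL) {
  if (id %in% model$reactions$id)
    abort(paste0("reaction already in model: ", id))
  if (!is.null(new_species)) {
    new_species <- dplyr::anti_join(new_species, model$species, by = "id")
    model$species <- dplyr::bind_rows(model$species, new_species)
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble(id = id, stoich = list(stoich), k_eff = k_eff, enzyme = enzyme,
           lb = lb, ub = ub, tag = tag))
  model
}

#' Add a proton-leak pseudo reaction
#'
#' Adds an uncatalyzed reaction that drains `atp_per_leak` ATP-equivalents
#' per unit leak flux, with the flux pinned at `leak_flux` (the induced
#' leak levels 0/50/100 mmol gDW^-1 h^-1). Draining the proton gradient
#' without making ATP lowers the effective P/O ratio, so the
#' yield-maximized solution at fixed `mu` shifts to higher `q_glc`,
#' higher `q_ac` and lower `Y`. With `leak_flux = 0` the model is
#' returned unchanged. Set `fixed = FALSE` for a free leak bounded above
#' by `leak_flux` instead of pinned.
#'
#' @param model An `ssme_model`.
#' @param leak_flux Leak flux level, mmol gDW^-1 h^-1 (>= 0).
#' @param atp_per_leak ATP-equivalents drained per unit leak; defaults to
#'   the model's `atp_per_leak` global (0.25, ~4 protons per ATP).
#' @param fixed Pin the flux at `leak_flux` (default) or only bound it.
#' @return A new `ssme_model` (pure function).
#' @export
add_proton_leak <- function(model, leak_flux,
                            atp_per_leak = model$globals$atp_per_leak,
                            fixed = TRUE) {
  stopifnot(inherits(model, "ssme_model"), leak_flux >= 0)
  if (leak_flux == 0) return(model)
  add_reaction(model, "LEAK", c(atp = -atp_per_leak),
               lb = if (fixed) leak_flux else 0, ub = leak_flux,
               tag = "leak")
}

## Default parameters of the four alternative-pathway classes. Each is
## placed off the minimum-glucose Pareto frontier spanned by respiration
## (highest ATP per glucose) and fermentation (highest ATP per proteome),
## so none can enter the yield-maximized vertex; this is re-verified
## against the base curve after construction.
extension_defaults <- function(g) {
  list(
    ## (1) non-acetate byproduct at reduced ATP; proteome-cheaper than
    ##     respiration, so it opens a low-q_ac route at high mu
    `1` = list(id = "EXT1", a = 10, k_eff = 9 / g$P_total,
               stoich = function(a) c(glc = -1, byp = 2, atp = a),
               species = tibble(id = c("byp", "E_ext1"),
                                role = c("metabolite", "enzyme"),
                                carbon = c(3L, 0L)),
               exchange = c(id = "EX_byp", met = "byp"),
               enzyme = "E_ext1"),
    ## (2) acetate plus byproduct at reduced ATP: more acetate per ATP
    ##     than fermentation, opening high-q_ac solutions at all mu
    `2` = list(id = "EXT2", a = 4, k_eff = 15,
               stoich = function(a) c(glc = -1, ac = 2, fmt = 2, atp = a),
               species = tibble(id = c("fmt", "E_ext2"),
                                role = c("metabolite", "enzyme"),
                                carbon = c(1L, 0L)),
               exchange = c(id = "EX_fmt", met = "fmt"),
               enzyme = "E_ext2"),
    ## (3) alternative respiration at lower ATP per glucose (lower
    ##     effective P/O) but proteome-cheaper ATP than main respiration
    `3` = list(id = "EXT3", a = 14, k_eff = 10,
               stoich = function(a) c(glc = -1, o2 = -g$o2_per_glc,
                                      co2 = 6, atp = a),
               species = tibble(id = "E_ext3", role = "enzyme", carbon = 0L),
               exchange = NULL, enzyme = "E_ext3"),
    ## (4) futile ATP-dissipating cycle
    `4` = list(id = "EXT4", a = -1, k_eff = 50,
               stoich = function(a) c(atp = a),
               species = tibble(id = "E_ext4", role = "enzyme", carbon = 0L),
               exchange = NULL, enzyme = "E_ext4"))
}

#' Add an alternative-pathway extension
#'
#' Adds one of four classes of metabolically inefficient reactions, each
#' with its own enzyme and `k_eff`, that enlarge the solution space
#' without touching the yield-maximized curve: (1) glucose to a
#' non-acetate byproduct at reduced ATP; (2) glucose to acetate plus a
#' byproduct at reduced ATP; (3) alternative respiration with lower ATP
#' per glucose (lower effective P/O); (4) a futile ATP-dissipating cycle.
#' Classes (1) and (3) open low-`q_ac` solutions at high `mu`; classes
#' (2) and (4) open high-`q_ac` solutions across all `mu`.
#'
#' By construction the added reaction is never active in the
#' yield-maximized solution; this is verified post hoc by comparing the
#' minimum-`q_glc` curve of the extended model against the base model on
#' a `mu` grid, and parameters that would make the extension
#' yield-optimal are rejected.
#'
#' @param model An `ssme_model`.
#' @param kind Extension class, 1-4.
#' @param a ATP stoichiometry of the extension (per mmol glucose;
#'   for kind 4, the ATP consumed per unit cycle flux is 1).
#' @param k_eff Turnover rate of the extension enzyme.
#' @param verify Check that the yield-maximized curve is unchanged
#'   (default TRUE).
#' @return A new `ssme_model` (pure function).
#' @export
add_extension <- function(model, kind, a = NULL, k_eff = NULL,
                          verify = TRUE) {
  stopifnot(inherits(model, "ssme_model"))
  if (!kind %in% 1:4) abort("`kind` must be 1, 2, 3 or 4")
  def <- extension_defaults(model$globals)[[as.character(kind)]]
  a <- a %||% def$a
  k_eff <- k_eff %||% def$k_eff
  out <- add_reaction(model, def$id, def$stoich(a), k_eff = k_eff,
                      enzyme = def$enzyme,
                      tag = paste0("extension-", kind),
                      new_species = def$species)
  if (!is.null(def$exchange))
    out <- add_reaction(out, def$exchange[["id"]],
                        setNames(-1, def$exchange[["met"]]), tag = "core")
  if (verify) {
    mu_probe <- seq(0.15, 0.95, by = 0.2) * max_growth(model)
    for (m in mu_probe) {
      q0 <- phenotype_at(model, m, "max_yield")$q_glc
      q1 <- phenotype_at(out, m, "max_yield")$q_glc
      if (!isTRUE(abs(q0 - q1) <= 1e-9))
        abort(sprintf(paste0("extension %d with a=%g, k_eff=%g alters the ",
                             "yield-maximized solution at mu=%.3f ",
                             "(q_glc %g -> %g); choose parameters that keep ",
                             "it off the optimal frontier"),
                      kind, a, k_eff, m, q0, q1))
    }
  }
  out
}

#' Knock out a reaction
#'
#' Sets both flux bounds of the target reaction to zero.
#'
#' @param model An `ssme_model`.
#' @param reaction_id Reaction to block.
#' @return A new `ssme_model` (pure function).
#' @export
knockout <- function(model, reaction_id) {
  stopifnot(inherits(model, "ssme_model"))
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(paste0("unknown reaction: ", reaction_id))
  model$reactions$lb[i] <- 0
  model$reactions$ub[i] <- 0
  model
}
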