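
#' Carbon-fate partitioning of the substrate carbon
#'
#' Splits the carbon entering through the uptake reactions over the sink
#' categories: biomass synthesis, CO2 loss, and each excreted product.
#' Fractions are per substrate carbon atom and must sum to 1 at steady state.
#'
#' @param net an `mfa_network`.
#' @param flux a steady-state [flux_state()].
#' @param co2_pattern regular expression identifying CO2 species ids.
#' @return object of class `carbon_fates`: named fractions plus the absolute
#'   carbon flows.
#' @export
carbon_fates <- function(net, flux, co2_pattern = "^CO2") {
  nc <- stats::setNames(net$metabolites$carbons, net$metabolites$id)
  # carbon counts come from the metabolite table: biomass precursors carry
  # no atom maps (they are exempt from atom balancing) but still drain carbon
  carbons_of <- function(terms) sum(vapply(terms, function(t)
    t$coef * nc[[t$met]], numeric(1)))
  c_in <- 0; sinks <- c(biomass = 0, co2 = 0)
  for (r in net$reactions) {
    v <- flux$net[[r$id]]
    if (r$kind == "uptake") {
      c_in <- c_in + v * carbons_of(r$reactants)
    } else if (r$kind == "biomass") {
      sinks[["biomass"]] <- sinks[["biomass"]] + v * carbons_of(r$reactants)
    } else if (r$kind == "excretion") {
      for (t in r$products) {
        cc <- v * t$coef * nchar(t$map)
        if (grepl(co2_pattern, t$met)) {
          sinks[["co2"]] <- sinks[["co2"]] + cc
        } else {
          key <- paste0("product:", t$met)
          sinks[key] <- (if (key %in% names(sinks)) sinks[[key]] else 0) + cc
        }
      }
    }
  }
  if (c_in <= 0) stop("no substrate carbon uptake; cannot partition carbon")
  fr <- sinks / c_in
  if (abs(sum(fr) - 1) > 1e-3)
    stop("carbon imbalance: sink fractions sum to ", round(sum(fr), 6),
         "; flux state is not at steady state or the network leaks carbon")
  structure(list(fractions = fr, carbon_in = c_in, carbon_out = sinks),
            class = "carbon_fates")
}

#' @export
print.carbon_fates <- function(x, ...) {
  cat("<carbon_fates> (fraction of substrate carbon)\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' ATP and redox-cofactor account of a flux state
#'
#' Sums cofactor production over the fitted fluxes: substrate-level ATP from
#' all non-biomass, non-maintenance reactions; oxidative ATP as P/O ratios
#' times the net NADH and FADH2 available for respiration (NADPH is treated
#' as biosynthetic currency and excluded); growth-associated consumption from
#' the biomass reaction. The excess,
#' `maintenance = substrate_level + oxphos - biosynthesis`, is the
#' non-growth-associated maintenance cost. Units follow the flux units
#' (per 100 substrate uptake); [energy_per_gdw()] converts given a yield.
#'
#' @param net an `mfa_network` with cofactor coefficients.
#' @param flux a [flux_state()].
#' @param po_nadh ATP per NADH oxidized.
#' @param po_fadh2 ATP per FADH2 oxidized (default 2/3 of `po_nadh`).
#' @return object of class `energy_account`.
#' @export
atp_account <- function(net, flux, po_nadh = 2, po_fadh2 = po_nadh * 2 / 3) {
  cof <- vapply(net$reactions, `[[`, numeric(4), "cofactors")
  if (all(cof == 0))
    stop("no cofactor annotations on any reaction; cannot build energy account")
  v <- flux$net[colnames(cof)]
  kinds <- vapply(net$reactions, `[[`, character(1), "kind")
  is_bio <- kinds == "biomass"
  is_maint <- kinds == "maintenance"
  atp <- cof["ATP", ]; nadh <- cof["NADH", ]
  nadph <- cof["NADPH", ]; fadh2 <- cof["FADH2", ]

  substrate_level <- sum(v[!is_bio & !is_maint] * atp[!is_bio & !is_maint])
  biosynthesis <- -sum(v[is_bio] * atp[is_bio])
  nadh_net <- sum(v * nadh)
  nadph_net <- sum(v * nadph)
  fadh2_net <- sum(v * fadh2)
  oxphos <- po_nadh * nadh_net + po_fadh2 * fadh2_net
  maintenance <- substrate_level + oxphos - biosynthesis
  structure(list(atp_substrate_level = substrate_level,
                 atp_oxphos = oxphos,
                 atp_consumed_biosynthesis = biosynthesis,
                 atp_maintenance = maintenance,
                 maintenance_flux = if (any(is_maint)) sum(v[is_maint] * -atp[is_maint]) else NA_real_,
                 nadh_net = nadh_net, nadph_net = nadph_net,
                 fadh2_net = fadh2_net,
                 po_nadh = po_nadh, po_fadh2 = po_fadh2),
            class = "energy_account")
}

#' @export
print.energy_account <- function(x, ...) {
  cat("<energy_account> (flux units, production positive)\n")
  for (f in c("atp_substrate_level", "atp_oxphos",
              "atp_consumed_biosynthesis", "atp_maintenance",
              "nadh_net", "nadph_net", "fadh2_net"))
    cat(sprintf("  %-26s %10.3f\n", f, x[[f]]))
  invisible(x)
}

#' Convert an energy account to mmol ATP per gram dry weight
#'
#' @param account an [atp_account()] result.
#' @param biomass_yield grams dry weight formed per 100 mmol substrate taken
#'   up (same basis as the fluxes).
#' @return named numeric vector of the ATP categories in mmol/g DW.
#' @export
energy_per_gdw <- function(account, biomass_yield) {
  if (biomass_yield <= 0) stop("biomass yield must be positive")
  f <- c("atp_substrate_level", "atp_oxphos",
         "atp_consumed_biosynthesis", "atp_maintenance")
  vapply(f, function(k) account[[k]] / biomass_yield, numeric(1))
}

find_maintenance <- function(net) {
  ids <- names(net$reactions)[vapply(net$reactions, function(r)
    r$kind == "maintenance" && r$cofactors[["ATP"]] < 0, logical(1))]
  if (!length(ids))
    stop("network has no maintenance (ATP hydrolysis) pseudo-reaction")
  ids[1]
}

# linear ATP-balance row at a given P/O ratio: sum over reactions of
# (ATP + po_nadh*NADH + po_fadh2*FADH2) * v = 0
atp_balance_row <- function(net, po_nadh, po_fadh2) {
  co <- vapply(net$reactions, function(r)
    r$cofactors[["ATP"]] + po_nadh * r$cofactors[["NADH"]] +
      po_fadh2 * r$cofactors[["FADH2"]], numeric(1))
  list(coeffs = co[co != 0], rhs = 0)
}

#' P/O-ratio sensitivity scan
#'
#' Refits the fluxes at each P/O ratio with the ATP balance closed: total ATP
#' production (substrate-level plus oxidative at the given ratio) equals
#' growth-associated consumption plus the maintenance flux. In `unbalanced`
#' mode the maintenance pseudo-reaction is unconstrained, so it absorbs
#' any ATP excess and the carbon flux fit is insensitive to the ratio; in
#' `balanced` mode maintenance is fixed to zero, which constrains the carbon
#' fluxes and makes the fit ratio-dependent.
#'
#' @param problem a [flux_problem()] whose network contains a maintenance
#'   reaction.
#' @param ratios numeric vector of P/O (NADH) ratios to scan.
#' @param mode `"unbalanced"` or `"balanced"`.
#' @param options a [fit_options()].
#' @param po_fadh2_factor FADH2 ratio as a multiple of the NADH ratio.
#' @return data.frame with one row per ratio: `ratio`, `mode`, `ssr`,
#'   `maintenance`, `feasible`, plus one column per reaction net flux; fitted
#'   states in `attr(, "fits")`.
#' @export
po_ratio_scan <- function(problem, ratios = c(1, 1.5, 2),
                          mode = c("unbalanced", "balanced"),
                          options = fit_options(),
                          po_fadh2_factor = 2 / 3) {
  mode <- match.arg(mode)
  if (any(ratios <= 0)) stop("P/O ratios must be positive")
  maint <- find_maintenance(problem$net)
  rows <- list(); fits <- list()
  for (po in ratios) {
    net2 <- modify_network(problem$net, set_bounds = stats::setNames(
      list(if (mode == "balanced") c(0, 0) else c(-1000, 1000)), maint))
    row <- atp_balance_row(net2, po, po * po_fadh2_factor)
    entry <- tryCatch({
      p2 <- flux_problem(net2, problem$recipe, problem$measurements,
                         problem$fixed, problem$table,
                         extra_rows = c(problem$extra_rows, list(row)))
      fit <- fit_fluxes(p2, options)
      acct <- atp_account(net2, fit$best_flux, po, po * po_fadh2_factor)
      list(fit = fit, maintenance = acct$maintenance_flux, feasible = TRUE)
    }, error = function(e) list(fit = NULL, maintenance = NA_real_,
                                feasible = FALSE, msg = conditionMessage(e)))
    fits[[as.character(po)]] <- entry$fit
    base <- data.frame(ratio = po, mode = mode,
                       ssr = if (entry$feasible) entry$fit$ssr else NA_real_,
                       maintenance = entry$maintenance,
                       feasible = entry$feasible)
    if (entry$feasible) {
      nf <- as.list(entry$fit$best_flux$net)
      names(nf) <- paste0("net.", names(nf))
      base <- cbind(base, as.data.frame(nf))
    }
    rows[[length(rows) + 1L]] <- base
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad infeasible rows to common columns
    allcols <- unique(unlist(lapply(rows, names)))
    for (cc in setdiff(allcols, names(r))) r[[cc]] <- NA_real_
    r[allcols]
  }))
  attr(out, "fits") <- fits
  out
}

#' Rescale a flux state to a reference uptake
#'
#' Scales all net and exchange fluxes by a common factor so that the summed
#' uptake flux equals `basis` (conventionally 100). Labeling is invariant
#' under this rescaling.
#'
#' @param flux a [flux_state()].
#' @param net the `mfa_network`.
#' @param basis target summed uptake flux.
#' @return rescaled [flux_state()].
#' @export
normalize_to_uptake <- function(flux, net, basis = 100) {
  kinds <- vapply(net$reactions, `[[`, character(1), "kind")
  upt <- sum(flux$net[kinds == "uptake"])
  if (upt <= 0) stop("total uptake flux is zero; cannot normalize")
  k <- basis / upt
  flux$net <- flux$net * k
  flux$exchange <- flux$exchange * k
  flux
}
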