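
#' Construct a metabolic network
#'
#' Assembles reactions and a metabolite table into a network object. Reaction
#' kinds left as `internal` are inferred: a reaction consuming an external
#' metabolite is an uptake, one producing only external metabolites is an
#' excretion.
#'
#' @param reactions list of `mfa_reaction` objects (see [parse_reaction()]).
#' @param metabolites data.frame with columns `id`, `carbons`, `balanced`,
#'   `symmetric`, `substrate`.
#' @return object of class `mfa_network` with elements `reactions`,
#'   `metabolites`, `substrates`.
#' @export
metabolic_network <- function(reactions, metabolites) {
  stopifnot(all(c("id", "carbons", "balanced", "symmetric") %in% names(metabolites)))
  if (is.null(metabolites$substrate)) metabolites$substrate <- FALSE
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate reaction ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(reactions) <- ids
  ext <- metabolites$id[!metabolites$balanced]
  reactions <- lapply(reactions, function(r) {
    if (r$kind == "internal") {
      rmets <- vapply(r$reactants, `[[`, character(1), "met")
      pmets <- vapply(r$products, `[[`, character(1), "met")
      if (length(rmets) && any(rmets %in% ext) && !all(rmets %in% ext))
        r$kind <- "internal"  # mixed sides stay internal
      else if (length(rmets) && all(rmets %in% ext)) r$kind <- "uptake"
      else if (length(pmets) && all(pmets %in% ext) && length(rmets)) r$kind <- "excretion"
    }
    r
  })
  structure(list(reactions = reactions, metabolites = metabolites,
                 substrates = metabolites$id[metabolites$substrate]),
            class = "mfa_network")
}

#' @export
print.mfa_network <- function(x, ...) {
  cat("<mfa_network> ", length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$balanced), " balanced)\n", sep = "")
  invisible(x)
}

reaction_ids <- function(net) names(net$reactions)

reversible_ids <- function(net)
  names(net$reactions)[vapply(net$reactions, `[[`, logical(1), "reversible")]

metabolite_carbons <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop("unknown metabolite: ", id)
  net$metabolites$carbons[i]
}

#' Validate a metabolic network
#'
#' Checks structural usability: every referenced metabolite is declared, atom
#' maps match declared carbon counts, atom labels balance per reaction, every
#' balanced metabolite is both produced and consumed (no dead ends), and no
#' substrate is marked balanced.
#'
#' @param net an `mfa_network`.
#' @return character vector of violation messages; empty when the network is
#'   usable.
#' @export
validate_network <- function(net) {
  v <- character(0)
  mets <- net$metabolites
  produced <- consumed <- character(0)
  for (r in net$reactions) {
    for (t in c(r$reactants, r$products)) {
      i <- match(t$met, mets$id)
      if (is.na(i)) {
        v <- c(v, paste0("reaction ", r$id, ": undeclared metabolite ", t$met))
      } else if (nchar(t$map) > 0 && nchar(t$map) != mets$carbons[i]) {
        v <- c(v, paste0("reaction ", r$id, ": atom map length ", nchar(t$map),
                         " != ", mets$carbons[i], " carbons of ", t$met))
      }
    }
    if (r$kind != "biomass") {
      rl <- sort(unlist(lapply(r$reactants, function(t) strsplit(t$map, "")[[1]])))
      pl <- sort(unlist(lapply(r$products, function(t) strsplit(t$map, "")[[1]])))
      if (!identical(rl, pl))
        v <- c(v, paste0("reaction ", r$id, ": atom labels unbalanced"))
    }
    # a knocked-out reaction (bounds fixed at 0) neither produces nor consumes
    active <- !(r$lb == 0 && r$ub == 0)
    if (active) {
      consumed <- c(consumed, vapply(r$reactants, `[[`, character(1), "met"))
      produced <- c(produced, vapply(r$products, `[[`, character(1), "met"))
      if (r$reversible) {
        consumed <- c(consumed, vapply(r$products, `[[`, character(1), "met"))
        produced <- c(produced, vapply(r$reactants, `[[`, character(1), "met"))
      }
    }
  }
  for (i in seq_len(nrow(mets))) {
    if (mets$balanced[i]) {
      if (!(mets$id[i] %in% produced))
        v <- c(v, paste0("balanced metabolite ", mets$id[i], " is never produced"))
      if (!(mets$id[i] %in% consumed))
        v <- c(v, paste0("balanced metabolite ", mets$id[i], " is never consumed"))
    }
    if (mets$substrate[i] && mets$balanced[i])
      v <- c(v, paste0("substrate ", mets$id[i], " is marked balanced"))
  }
  v
}

#' Stoichiometric matrix of the balanced metabolites
#'
#' @param net an `mfa_network`.
#' @return numeric matrix, rows = balanced metabolites, columns = reactions;
#'   entry (m, r) is the net signed stoichiometric coefficient of m in r.
#' @export
stoichiometric_matrix <- function(net) {
  bal <- net$metabolites$id[net$metabolites$balanced]
  S <- matrix(0, nrow = length(bal), ncol = length(net$reactions),
              dimnames = list(bal, reaction_ids(net)))
  for (r in net$reactions) {
    for (t in r$reactants) {
      i <- match(t$met, bal)
      if (!is.na(i)) S[i, r$id] <- S[i, r$id] - t$coef
    }
    for (t in r$products) {
      i <- match(t$met, bal)
      if (!is.na(i)) S[i, r$id] <- S[i, r$id] + t$coef
    }
  }
  S
}

#' Construct a flux state
#'
#' @param net an `mfa_network`.
#' @param net_flux named numeric vector of net fluxes (one per reaction; a
#'   plain numeric in reaction order is accepted).
#' @param exchange named numeric vector of non-negative exchange fluxes for
#'   reversible reactions (missing entries default to 0).
#' @return object of class `flux_state`.
#' @export
flux_state <- function(net, net_flux, exchange = NULL) {
  ids <- reaction_ids(net)
  if (is.null(names(net_flux))) {
    stopifnot(length(net_flux) == length(ids))
    names(net_flux) <- ids
  }
  net_flux <- net_flux[ids]
  rev_ids <- reversible_ids(net)
  ex <- stats::setNames(numeric(length(rev_ids)), rev_ids)
  if (!is.null(exchange)) {
    bad <- setdiff(names(exchange), rev_ids)
    if (length(bad)) stop("exchange given for irreversible reactions: ",
                          paste(bad, collapse = ", "))
    if (any(exchange < 0)) stop("exchange fluxes must be non-negative")
    ex[names(exchange)] <- exchange
  }
  structure(list(net = net_flux, exchange = ex), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state>\n")
  print(round(x$net, 4))
  if (length(x$exchange)) {
    cat("exchange:\n"); print(round(x$exchange, 4))
  }
  invisible(x)
}

#' Free-flux parameterization of the steady-state solution space
#'
#' Builds the affine map from a small vector of free fluxes onto the full
#' steady-state flux space: the constraint system stacks `S v = 0` over the
#' balanced metabolites with one row per fixed flux, plus any extra linear
#' equality rows. Pivoting the QR factorization selects a set of dependent
#' reactions; the remaining (free) reactions parameterize the null space, so
#' the free coordinates are actual reaction fluxes with interpretable bounds.
#'
#' @param net an `mfa_network`.
#' @param fixed named numeric vector of fixed reaction fluxes (typically the
#'   substrate uptake, e.g. `c(vupt = 100)`).
#' @param extra_rows optional list of `list(coeffs = named numeric, rhs =
#'   value)` linear equality constraints on the net flux vector (used e.g. for
#'   an ATP balance).
#' @return object of class `flux_basis` with `n_free`, `free_ids`, and
#'   `$embed(free_values, exchange)` returning a [flux_state()].
#' @export
free_flux_basis <- function(net, fixed = NULL, extra_rows = NULL) {
  S <- stoichiometric_matrix(net)
  ids <- reaction_ids(net)
  n <- length(ids)
  A <- S
  b <- rep(0, nrow(S))
  if (!is.null(fixed) && length(fixed)) {
    for (k in names(fixed)) {
      if (!k %in% ids) stop("fixed flux for unknown reaction: ", k)
      row <- rep(0, n); row[match(k, ids)] <- 1
      A <- rbind(A, row); b <- c(b, fixed[[k]])
    }
  }
  if (!is.null(extra_rows)) {
    for (er in extra_rows) {
      row <- rep(0, n)
      row[match(names(er$coeffs), ids)] <- er$coeffs
      A <- rbind(A, row); b <- c(b, er$rhs)
    }
  }
  rownames(A) <- NULL
  qa <- qr(A)
  r <- qa$rank
  # feasibility of the fixed set: least-squares residual of A v = b
  v_ls <- qr.coef(qa, b)
  v_ls[is.na(v_ls)] <- 0
  if (max(abs(A %*% v_ls - b)) > 1e-6 * max(1, max(abs(b))))
    stop("infeasible fixed-flux set: constraints S v = 0 cannot be satisfied")
  dep <- qa$pivot[seq_len(r)]
  free <- sort(setdiff(seq_len(n), dep))
  dep <- sort(dep)
  qa_dep <- qr(A[, dep, drop = FALSE])
  if (qa_dep$rank < length(dep)) stop("internal error: dependent block rank-deficient")
  A_free <- A[, free, drop = FALSE]
  rev_ids <- reversible_ids(net)

  embed <- function(free_values = numeric(0), exchange = NULL) {
    if (length(free_values) != length(free))
      stop("expected ", length(free), " free flux values, got ", length(free_values))
    v <- stats::setNames(numeric(n), ids)
    if (length(free)) v[free] <- free_values
    rhs <- b - if (length(free)) A_free %*% free_values else 0
    v[dep] <- qr.coef(qa_dep, rhs)
    flux_state(net, v, exchange)
  }

  structure(list(net = net, n_free = length(free),
                 free_ids = ids[free], dep_ids = ids[dep],
                 fixed = fixed, embed = embed,
                 reversible_ids = rev_ids),
            class = "flux_basis")
}

#' @export
print.flux_basis <- function(x, ...) {
  cat("<flux_basis> n_free =", x$n_free,
      if (x$n_free) paste0("(", paste(x$free_ids, collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Edit a network without mutating it
#'
#' Applies knockouts, bound changes and reaction additions, returning a new
#' network. A knockout fixes both bounds to zero but keeps the reaction, so
#' flux-vector indexing stays aligned across edits.
#'
#' @param net an `mfa_network`.
#' @param knockout character vector of reaction ids to knock out.
#' @param set_bounds named list of `c(lb, ub)` per reaction id.
#' @param add_reaction character vector of reaction lines (see
#'   [parse_reaction()]).
#' @return a new `mfa_network`.
#' @export
modify_network <- function(net, knockout = NULL, set_bounds = NULL,
                           add_reaction = NULL) {
  rxns <- net$reactions
  for (id in knockout) {
    if (!id %in% names(rxns)) stop("knockout of unknown reaction: ", id)
    rxns[[id]]$lb <- 0
    rxns[[id]]$ub <- 0
  }
  for (id in names(set_bounds)) {
    if (!id %in% names(rxns)) stop("set_bounds on unknown reaction: ", id)
    bb <- set_bounds[[id]]
    if (bb[1] > bb[2]) stop("set_bounds(", id, "): lb > ub")
    rxns[[id]]$lb <- bb[1]
    rxns[[id]]$ub <- bb[2]
  }
  for (line in add_reaction) {
    r <- parse_reaction(line, metabolites = net$metabolites)
    rxns[[r$id]] <- r
  }
  metabolic_network(rxns, net$metabolites)
}

#' Load a packaged network template
#'
#' Available templates: `toy1` (6-reaction branched toy network with a
#' decarboxylation, a CO2 refixation and a reversible isomerization),
#' `central_carbon` (generic bacterial central metabolism: glycolysis, pentose
#' phosphate pathway, TCA cycle, glyoxylate shunt, anaplerosis, acetate
#' overflow, biomass drain, ATP maintenance), and `tca_micro` (10-metabolite
#' cyclic fixture with a cleavage, a condensation, a reversible step and a
#' symmetric metabolite, sized for full-isotopomer cross-checks).
#'
#' @param name template name.
#' @return a validated `mfa_network`.
#' @export
load_template <- function(name) {
  path <- system.file("extdata", "templates", paste0(name, ".net"),
                      package = "emuflux")
  if (path == "")
    stop("unknown template '", name, "'; available: toy1, central_carbon, tca_micro")
  net <- read_network(path)
  issues <- validate_network(net)
  if (length(issues)) stop("template ", name, " failed validation: ",
                           paste(issues, collapse = "; "))
  net
}
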