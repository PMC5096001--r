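
# ---- full-isotopomer reference simulator ------------------------------------
#
# Direct steady-state balance over all 2^n positional isotopomers of every
# balanced metabolite. Exponential in carbon count, so only usable on small
# networks, but entirely independent of the EMU machinery: it serves as the
# cross-check oracle for simulate_mids() and for user-modified networks.

# isotopomer index: atom k labeled contributes bit 2^(k-1); index = bits + 1

# full isotopomer distribution of a substrate under a tracer recipe
substrate_isotopomers <- function(recipe, n_carbons, table = isotope_table()) {
  p13 <- table$C[2]
  out <- numeric(2^n_carbons)
  for (cmp in recipe$components) {
    p <- rep(p13, n_carbons)
    p[cmp$positions] <- cmp$purity
    d <- 1
    for (k in seq_len(n_carbons)) d <- c(d * (1 - p[k]), d * p[k])
    out <- out + cmp$fraction * d
  }
  out
}

mirror_perm <- function(n) {
  # permutation of isotopomer indices under carbon-skeleton reversal
  idx <- 0:(2^n - 1)
  out <- integer(length(idx))
  for (k in seq_len(n)) {
    bit <- bitwAnd(idx, bitwShiftL(1L, k - 1L)) > 0
    out <- out + ifelse(bit, bitwShiftL(1L, n - k), 0L)
  }
  out + 1L
}

#' Brute-force isotopomer simulation (reference oracle)
#'
#' Solves the steady-state positional-isotopomer balance over all `2^n`
#' labeling patterns of every balanced metabolite by damped fixed-point
#' iteration, fully independently of the EMU decomposition. Marginalizing any
#' EMU's atoms from the result must reproduce [simulate_mids()].
#'
#' @param net an `mfa_network` whose balanced metabolites have at most 12
#'   carbons each.
#' @param flux a [flux_state()] at steady state.
#' @param recipe a [tracer_recipe()] or named list of recipes per substrate.
#' @param table an [isotope_table()].
#' @param tol fixed-point convergence tolerance (max absolute change).
#' @param max_iter iteration cap.
#' @return named list: metabolite id -> full isotopomer distribution (length
#'   `2^carbons`, indexed by label bit pattern; atom 1 is the lowest bit).
#' @export
brute_force_mids <- function(net, flux, recipe, table = isotope_table(),
                             tol = 1e-12, max_iter = 50000L) {
  mets <- net$metabolites
  bal <- mets$id[mets$balanced]
  nc <- stats::setNames(mets$carbons, mets$id)
  if (any(nc[bal] > 12))
    stop("brute-force state space too large: a balanced metabolite exceeds 12 carbons")

  recipes <- if (inherits(recipe, "tracer_recipe"))
    stats::setNames(list(recipe), recipe$substrate) else recipe

  # fixed distributions of external metabolites
  ext_dist <- list()
  for (i in seq_len(nrow(mets))) {
    if (mets$balanced[i] || mets$carbons[i] == 0) next
    id <- mets$id[i]
    rc <- recipes[[id]]
    ext_dist[[id]] <- if (!is.null(rc))
      substrate_isotopomers(rc, mets$carbons[i], table)
    else substrate_isotopomers(
      list(components = list(list(positions = integer(0), fraction = 1, purity = 0))),
      mets$carbons[i], table)
  }

  dirs <- directed_reactions(net)
  f_dir <- directed_fluxes(dirs, flux)

  # precompute, per product occurrence: source term ids, and the grouping of
  # the joint source-isotopomer space onto the product isotopomer index
  occs <- list()
  for (di in seq_along(dirs)) {
    d <- dirs[[di]]
    if (f_dir[di] <= 0) { } # keep structure; flux may change between calls
    src_mets <- vapply(d$from, `[[`, character(1), "met")
    src_len <- vapply(d$from, function(t) nchar(t$map), integer(1))
    if (sum(src_len) > 14)
      stop("brute-force joint source space too large in reaction ", d$rxn)
    joint <- 0:(2^sum(src_len) - 1)
    offs <- cumsum(c(0, src_len))
    for (oi in seq_along(d$to)) {
      term <- d$to[[oi]]
      if (nchar(term$map) == 0 || !(term$met %in% bal)) next
      labels <- strsplit(term$map, "")[[1]]
      tgt <- integer(length(joint))
      for (k in seq_along(labels)) {
        hit <- FALSE
        for (ti in seq_along(d$from)) {
          p <- regexpr(labels[k], d$from[[ti]]$map, fixed = TRUE)
          if (p > 0) {
            gbit <- offs[ti] + p - 1
            bit <- bitwAnd(joint, bitwShiftL(1L, gbit)) > 0
            tgt <- tgt + ifelse(bit, bitwShiftL(1L, k - 1L), 0L)
            hit <- TRUE
            break
          }
        }
        if (!hit) stop("reaction ", d$rxn, ": unsourced product atom label")
      }
      occs[[length(occs) + 1L]] <- list(
        di = di, met = term$met, coef = term$coef,
        src_mets = src_mets, src_len = src_len,
        grp = tgt + 1L)
    }
  }

  mirrors <- lapply(stats::setNames(nm = bal[mets$symmetric[match(bal, mets$id)]]),
                    function(m) mirror_perm(nc[[m]]))

  # initialize balanced pools unlabeled
  p <- lapply(stats::setNames(nm = bal), function(m) {
    d <- numeric(2^nc[[m]]); d[1] <- 1; d
  })

  get_dist <- function(m, cur) if (m %in% bal) cur[[m]] else ext_dist[[m]]

  for (it in seq_len(max_iter)) {
    acc <- lapply(stats::setNames(nm = bal), function(m) numeric(2^nc[[m]]))
    tot <- stats::setNames(numeric(length(bal)), bal)
    for (oc in occs) {
      f <- f_dir[oc$di] * oc$coef
      if (f <= 0) next
      joint <- 1
      for (ti in seq_along(oc$src_mets)) {
        if (oc$src_len[ti] == 0) next
        joint <- as.vector(outer(joint, get_dist(oc$src_mets[ti], p)))
      }
      td <- rowsum(joint, oc$grp)[, 1]
      full <- numeric(2^nc[[oc$met]])
      full[sort(unique(oc$grp))] <- td
      acc[[oc$met]] <- acc[[oc$met]] + f * full
      tot[[oc$met]] <- tot[[oc$met]] + f
    }
    delta <- 0
    for (m in bal) {
      if (tot[[m]] <= 1e-12) next  # unproduced pool: keep placeholder
      newd <- acc[[m]] / tot[[m]]
      # renormalize: condensations amplify rounding drift of the sum mode
      # around cycles, so project back onto the unit-sum simplex each sweep
      newd <- newd / sum(newd)
      if (!is.null(mirrors[[m]])) newd <- 0.5 * (newd + newd[mirrors[[m]]])
      delta <- max(delta, max(abs(newd - p[[m]])))
      p[[m]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("brute-force iteration did not reach tolerance (", delta, ")")
  p
}

#' Marginal MID of an EMU from a full isotopomer distribution
#'
#' @param dist isotopomer distribution as returned by [brute_force_mids()].
#' @param atoms 1-based carbon positions of the EMU.
#' @return MID vector of length `length(atoms) + 1`.
#' @export
isotopomer_marginal <- function(dist, atoms) {
  idx <- 0:(length(dist) - 1)
  wt <- integer(length(idx))
  for (a in atoms) wt <- wt + (bitwAnd(idx, bitwShiftL(1L, a - 1L)) > 0)
  as.vector(rowsum(dist, wt))
}
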