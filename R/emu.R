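
# ---- directed-reaction view --------------------------------------------------
#
# Labeling propagation works on directed reactions: every reaction contributes
# its forward direction, and every reversible reaction additionally its
# backward direction (sides swapped). Effective fluxes follow the standard
# convention forward = max(net, 0) + exchange, backward = max(-net, 0) +
# exchange. Biomass and carbon-free (maintenance) reactions never carry label.

directed_reactions <- function(net) {
  out <- list()
  for (r in net$reactions) {
    has_carbon <- any(vapply(c(r$reactants, r$products),
                             function(t) nchar(t$map) > 0, logical(1)))
    if (!has_carbon || r$kind %in% c("biomass", "maintenance")) next
    out[[length(out) + 1L]] <- list(rxn = r$id, dir = "f",
                                    from = r$reactants, to = r$products)
    if (r$reversible)
      out[[length(out) + 1L]] <- list(rxn = r$id, dir = "b",
                                      from = r$products, to = r$reactants)
  }
  out
}

# flux carried by each directed reaction under a flux_state
directed_fluxes <- function(dirs, flux) {
  vapply(dirs, function(d) {
    v <- flux$net[[d$rxn]]
    ex <- if (d$rxn %in% names(flux$exchange)) flux$exchange[[d$rxn]] else 0
    if (d$dir == "f") max(v, 0) + ex else max(-v, 0) + ex
  }, numeric(1))
}

emu_key <- function(met, atoms) paste0(met, "|", paste(atoms, collapse = ","))

# trace the atoms of one product occurrence back to reactant-side positions;
# returns list of parts, each part = list(met, atoms) on one reactant term
trace_atoms <- function(d, occ_idx, atoms) {
  term <- d$to[[occ_idx]]
  labels <- strsplit(term$map, "")[[1]][atoms]
  src_term <- integer(length(labels)); src_pos <- integer(length(labels))
  for (k in seq_along(labels)) {
    found <- FALSE
    for (ti in seq_along(d$from)) {
      p <- regexpr(labels[k], d$from[[ti]]$map, fixed = TRUE)
      if (p > 0) { src_term[k] <- ti; src_pos[k] <- p; found <- TRUE; break }
    }
    if (!found) stop("reaction ", d$rxn, ": atom label '", labels[k],
                     "' of product has no reactant source")
  }
  parts <- list()
  for (ti in sort(unique(src_term))) {
    sel <- src_term == ti
    parts[[length(parts) + 1L]] <-
      list(met = d$from[[ti]]$met, atoms = sort(src_pos[sel]))
  }
  parts
}

#' Decompose a network into the EMU system for target fragments
#'
#' Backward-traces each target elementary metabolite unit (EMU) through the
#' atom maps to the substrate EMUs: cleavage reactions shrink the traced atom
#' set, condensation reactions split it into a convolution of smaller EMUs,
#' and rotationally symmetric metabolites contribute both skeleton
#' orientations at weight one half. The result is minimal (only EMUs reachable
#' backward from the targets) and stratified by EMU size, so the labeling
#' state can be solved as a cascade of small linear systems.
#'
#' @param net an `mfa_network`.
#' @param targets list of `list(met = <id>, atoms = <integer positions>)`.
#' @return object of class `emu_system`.
#' @export
emu_decompose <- function(net, targets) {
  mets <- net$metabolites
  dirs <- directed_reactions(net)
  balanced <- mets$id[mets$balanced]

  # producer index: met -> list of (dir index, occurrence index)
  prod_index <- list()
  for (di in seq_along(dirs)) {
    for (oi in seq_along(dirs[[di]]$to)) {
      m <- dirs[[di]]$to[[oi]]$met
      if (nchar(dirs[[di]]$to[[oi]]$map) == 0) next
      prod_index[[m]] <- c(prod_index[[m]], list(c(di, oi)))
    }
  }

  emus <- list()      # key -> list(met, atoms, size, balanced)
  producers <- list() # key -> list of list(di, weight, parts = keys)
  queue <- list()
  push <- function(met, atoms) {
    i <- match(met, mets$id)
    if (is.na(i)) stop("unknown metabolite in EMU target: ", met)
    if (any(atoms < 1 | atoms > mets$carbons[i]))
      stop("EMU atoms of ", met, " exceed its ", mets$carbons[i], " carbons")
    key <- emu_key(met, atoms)
    if (is.null(emus[[key]])) {
      emus[[key]] <<- list(met = met, atoms = atoms, size = length(atoms),
                           balanced = mets$balanced[i])
      if (mets$balanced[i]) queue[[length(queue) + 1L]] <<- key
    }
    key
  }
  for (t in targets) push(t$met, sort(unique(t$atoms)))

  while (length(queue)) {
    key <- queue[[1L]]; queue <- queue[-1L]
    e <- emus[[key]]
    prods <- prod_index[[e$met]]
    if (is.null(prods))
      stop("balanced metabolite ", e$met, " has no producing reaction")
    ncarb <- mets$carbons[match(e$met, mets$id)]
    orientations <- if (mets$symmetric[match(e$met, mets$id)]) {
      list(list(atoms = e$atoms, w = 0.5),
           list(atoms = sort(ncarb + 1L - e$atoms), w = 0.5))
    } else list(list(atoms = e$atoms, w = 1))
    plist <- list()
    for (p in prods) {
      d <- dirs[[p[1]]]
      coef <- d$to[[p[2]]]$coef
      for (or in orientations) {
        parts <- trace_atoms(d, p[2], or$atoms)
        keys <- vapply(parts, function(pt) push(pt$met, pt$atoms), character(1))
        plist[[length(plist) + 1L]] <-
          list(di = p[1], weight = coef * or$w, parts = keys)
      }
    }
    producers[[key]] <- plist
  }

  sys <- structure(list(net = net, dirs = dirs, emus = emus,
                        producers = producers,
                        targets = vapply(targets, function(t)
                          emu_key(t$met, sort(unique(t$atoms))), character(1))),
                   class = "emu_system")
  sys$compiled <- emu_compile(sys)
  sys
}

#' @export
print.emu_system <- function(x, ...) {
  sz <- vapply(x$emus, `[[`, integer(1), "size")
  cat("<emu_system> ", length(x$emus), " EMUs (sizes ",
      paste(sort(unique(sz)), collapse = ","), "), ",
      length(x$targets), " targets\n", sep = "")
  invisible(x)
}

# Precompute the per-size linear systems: index triplets for the production
# totals (diagonal), same-size unknown couplings, and known-source loadings,
# plus recipes to evaluate the known MIDs (substrate EMUs and convolutions).
emu_compile <- function(sys) {
  emus <- sys$emus
  keys <- names(emus)
  sizes <- vapply(emus, `[[`, integer(1), "size")
  balanced <- vapply(emus, `[[`, logical(1), "balanced")
  levels <- sort(unique(sizes[balanced]))

  comp <- list()
  for (s in levels) {
    unk <- keys[balanced & sizes == s]
    idx <- stats::setNames(seq_along(unk), unk)
    known_nodes <- list(); known_idx <- list()
    get_known <- function(kkey, recipe) {
      if (is.null(known_idx[[kkey]])) {
        known_nodes[[length(known_nodes) + 1L]] <<- recipe
        known_idx[[kkey]] <<- length(known_nodes)
      }
      known_idx[[kkey]]
    }
    prod_i <- integer(0); prod_d <- integer(0); prod_w <- numeric(0)
    in_i <- integer(0); in_j <- integer(0); in_d <- integer(0); in_w <- numeric(0)
    kn_i <- integer(0); kn_k <- integer(0); kn_d <- integer(0); kn_w <- numeric(0)
    for (key in unk) {
      i <- idx[[key]]
      for (pr in sys$producers[[key]]) {
        prod_i <- c(prod_i, i); prod_d <- c(prod_d, pr$di); prod_w <- c(prod_w, pr$weight)
        if (length(pr$parts) == 1L) {
          pk <- pr$parts[[1L]]
          if (balanced[[pk]]) {
            # single source EMU has the same size: in-level coupling
            in_i <- c(in_i, i); in_j <- c(in_j, idx[[pk]])
            in_d <- c(in_d, pr$di); in_w <- c(in_w, pr$weight)
          } else {
            k <- get_known(pk, list(type = "ext", key = pk))
            kn_i <- c(kn_i, i); kn_k <- c(kn_k, k)
            kn_d <- c(kn_d, pr$di); kn_w <- c(kn_w, pr$weight)
          }
        } else {
          parts <- lapply(pr$parts, function(pk) {
            if (balanced[[pk]]) list(type = "emu", size = sizes[[pk]], key = pk)
            else list(type = "ext", key = pk)
          })
          ck <- paste(pr$parts, collapse = "*")
          k <- get_known(ck, list(type = "conv", parts = parts))
          kn_i <- c(kn_i, i); kn_k <- c(kn_k, k)
          kn_d <- c(kn_d, pr$di); kn_w <- c(kn_w, pr$weight)
        }
      }
    }
    n <- length(unk)
    in_cell <- if (length(in_i)) (in_j - 1L) * n + in_i else integer(0)
    kn_cell <- if (length(kn_i)) (kn_k - 1L) * n + kn_i else integer(0)
    comp[[as.character(s)]] <- list(
      size = s, keys = unk, n = n, n_known = length(known_nodes),
      prod = list(i = prod_i, d = prod_d, w = prod_w),
      inlev = list(d = in_d, w = in_w,
                   grp = if (length(in_cell)) match(in_cell, unique(in_cell)) else integer(0),
                   ucell = unique(in_cell)),
      known = list(d = kn_d, w = kn_w,
                   grp = if (length(kn_cell)) match(kn_cell, unique(kn_cell)) else integer(0),
                   ucell = unique(kn_cell), nodes = known_nodes)
    )
  }
  # resolve row indices of unknown-EMU references inside convolution nodes
  resolve <- function(node) {
    if (node$type == "emu") {
      node$row <- match(node$key, comp[[as.character(node$size)]]$keys)
    } else if (node$type == "conv") {
      node$parts <- lapply(node$parts, resolve)
    }
    node
  }
  for (sc in names(comp))
    comp[[sc]]$known$nodes <- lapply(comp[[sc]]$known$nodes, resolve)
  list(levels = comp, level_sizes = levels)
}

#' Simulate mass isotopomer distributions through an EMU system
#'
#' Solves the size-stratified EMU balance cascade at a given flux state: at
#' each EMU size the steady-state label balance is a linear system `A X = K Y`
#' whose coefficients are the directed-reaction fluxes, with `Y` the MIDs of
#' substrate EMUs and of convolution products assembled from smaller sizes.
#'
#' @param sys an [emu_decompose()] result.
#' @param flux a [flux_state()] satisfying the steady-state constraint.
#' @param substrate_mids named list mapping external EMU keys
#'   (`"MET|1,2"`-style) to MID vectors; see [substrate_labeling()].
#' @return object of class `labeling_state`: named list EMU key -> MID.
#' @export
simulate_mids <- function(sys, flux, substrate_mids) {
  f_dir <- directed_fluxes(sys$dirs, flux)
  if (any(f_dir < -1e-9))
    stop("negative effective directed flux; flux state violates the convention")
  comp <- sys$compiled
  results <- list()  # per size: matrix n x (s+1), rows keyed

  get_mid <- function(node, s_res) {
    if (node$type == "ext") {
      m <- substrate_mids[[node$key]]
      if (is.null(m)) stop("no substrate labeling provided for EMU ", node$key)
      m
    } else if (node$type == "emu") {
      s_res[[as.character(node$size)]][node$row, ]
    } else {
      out <- 1
      for (p in node$parts) out <- convolve_mid(out, get_mid(p, s_res))
      out
    }
  }

  for (sc in names(comp$levels)) {
    lv <- comp$levels[[sc]]
    n <- lv$n; s <- lv$size
    fp <- f_dir[lv$prod$d] * lv$prod$w
    tot <- rowsum(fp, lv$prod$i, reorder = TRUE)[, 1]
    tot_full <- numeric(n); tot_full[sort(unique(lv$prod$i))] <- tot
    A <- matrix(0, n, n)
    A[cbind(seq_len(n), seq_len(n))] <- tot_full
    if (length(lv$inlev$grp)) {
      fv <- f_dir[lv$inlev$d] * lv$inlev$w
      agg <- rowsum(fv, lv$inlev$grp)[, 1]  # sorted by group id = ucell order
      A[lv$inlev$ucell] <- A[lv$inlev$ucell] - agg
    }
    nk <- lv$n_known
    RHS <- matrix(0, n, s + 1L)
    if (nk) {
      K <- matrix(0, n, nk)
      fv <- f_dir[lv$known$d] * lv$known$w
      K[lv$known$ucell] <- rowsum(fv, lv$known$grp)[, 1]
      Y <- matrix(0, nk, s + 1L)
      for (k in seq_len(nk)) Y[k, ] <- get_mid(lv$known$nodes[[k]], results)
      RHS <- K %*% Y
    }
    # zero-production EMUs: inert placeholder (their downstream weight is 0)
    dead <- tot_full < 1e-12
    if (any(dead)) {
      A[dead, ] <- 0
      A[cbind(which(dead), which(dead))] <- 1
      RHS[dead, ] <- rep(c(1, numeric(s)), each = sum(dead))
    }
    X <- tryCatch(solve(A, RHS),
                  error = function(e) stop("singular EMU system at size ", s,
                                           ": ", conditionMessage(e)))
    # iterative refinement guards against ill-conditioned level systems
    res <- A %*% X - RHS
    if (max(abs(res)) > 1e-10) X <- X - solve(A, res)
    rownames(X) <- lv$keys
    results[[sc]] <- X
  }

  out <- list()
  for (sc in names(results)) {
    X <- results[[sc]]
    for (i in seq_len(nrow(X))) out[[rownames(X)[i]]] <- X[i, ]
  }
  for (key in names(substrate_mids)) out[[key]] <- substrate_mids[[key]]
  structure(out, class = "labeling_state")
}

#' Substrate labeling for an EMU system
#'
#' Computes the MID of every external (substrate-side) EMU in the system from
#' a tracer recipe; external metabolites without a recipe entry are assigned
#' natural abundance.
#'
#' @param sys an `emu_system`.
#' @param recipe a [tracer_recipe()] (or a named list of them keyed by
#'   substrate metabolite).
#' @param table an [isotope_table()].
#' @return named list EMU key -> MID.
#' @export
substrate_labeling <- function(sys, recipe, table = isotope_table()) {
  recipes <- if (inherits(recipe, "tracer_recipe")) {
    stats::setNames(list(recipe), recipe$substrate)
  } else recipe
  out <- list()
  for (key in names(sys$emus)) {
    e <- sys$emus[[key]]
    if (e$balanced) next
    rc <- recipes[[e$met]]
    out[[key]] <- if (!is.null(rc))
      tracer_substrate_mids(rc, e$atoms, table)
    else natural_mid(e$size, table)
  }
  out
}

#' Extract fragment MIDs from a labeling state
#'
#' @param state a [simulate_mids()] result.
#' @param fragments list of [fragment_spec()] objects.
#' @return named list fragment_id -> MID.
#' @export
measured_fragment_mids <- function(state, fragments) {
  out <- list()
  for (fr in fragments) {
    key <- emu_key(fr$metabolite_id, fr$backbone_atoms)
    m <- state[[key]]
    if (is.null(m))
      stop("EMU ", key, " for fragment ", fr$fragment_id,
           " is not part of the labeling state; re-run emu_decompose with it as a target")
    out[[fr$fragment_id]] <- m
  }
  out
}

#' Export an EMU system as a DOT graph
#'
#' @param sys an `emu_system`.
#' @return character scalar with the DOT document.
#' @export
emu_dot <- function(sys) {
  lines <- c("digraph emu {", "  rankdir=LR;", "  node [shape=box];")
  for (key in names(sys$emus)) {
    e <- sys$emus[[key]]
    style <- if (e$balanced) "" else " style=filled fillcolor=lightgrey"
    lines <- c(lines, sprintf('  "%s" [label="%s"%s];', key, key, style))
  }
  for (key in names(sys$producers)) {
    for (pr in sys$producers[[key]]) {
      d <- sys$dirs[[pr$di]]
      lab <- paste0(d$rxn, if (d$dir == "b") " (rev)", " w=", signif(pr$weight, 3))
      if (length(pr$parts) == 1L) {
        lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                  pr$parts[[1]], key, lab))
      } else {
        cnode <- paste(pr$parts, collapse = " x ")
        lines <- c(lines, sprintf('  "%s" [shape=point];', cnode))
        for (p in pr$parts)
          lines <- c(lines, sprintf('  "%s" -> "%s" [style=dashed];', p, cnode))
        lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];', cnode, key, lab))
      }
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
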