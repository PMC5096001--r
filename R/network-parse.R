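
# ---- reaction / network text format -----------------------------------------
#
# A model file is UTF-8 text, one declaration per line:
#
#   // comment
#   # MET <id> <carbons> [balanced|external] [symmetric] [substrate]
#   <rxn_id>: [coef] MET (map) + ... ->|<-> [coef] MET (map) + ...
#            [| ATP:<x> NADH:<x> NADPH:<x> FADH2:<x>] [@ <kind>] [[lb, ub]]
#
# Atom maps are single-character labels (a-z, A-Z), one character per carbon of
# the metabolite occurrence, unique within each side of a reaction; identical
# labels on the two sides identify the same carbon atom. Carbon-free species
# (ATP pseudo-metabolites, biomass sinks) use an empty map `()` or none.

COFACTOR_IDS <- c("ATP", "NADH", "NADPH", "FADH2")
REACTION_KINDS <- c("internal", "uptake", "excretion", "biomass", "maintenance")

new_term <- function(met, coef, map) list(met = met, coef = coef, map = map)

parse_side <- function(txt, rxn_id) {
  txt <- trimws(txt)
  if (txt == "") return(list())
  parts <- strsplit(txt, "+", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    p <- trimws(p)
    map <- ""
    m <- regmatches(p, regexec("^(.*?)\\s*\\(([A-Za-z]*)\\)$", p))[[1]]
    if (length(m)) {
      map <- m[3]
      p <- trimws(m[2])
    }
    toks <- strsplit(p, "\\s+")[[1]]
    if (length(toks) == 2L) {
      coef <- suppressWarnings(as.numeric(toks[1]))
      if (is.na(coef) || coef <= 0)
        stop("reaction ", rxn_id, ": bad stoichiometric coefficient '", toks[1], "'")
      new_term(toks[2], coef, map)
    } else if (length(toks) == 1L && nzchar(toks)) {
      new_term(toks, 1, map)
    } else {
      stop("reaction ", rxn_id, ": cannot parse term '", p, "'")
    }
  })
}

#' Parse a reaction line
#'
#' Parses one line of the model grammar into a reaction record and checks the
#' carbon atom balance: the multiset of atom labels on the reactant side must
#' equal the multiset on the product side (biomass reactions are exempt; their
#' precursor carbons leave the traced system).
#'
#' @param line reaction text, e.g. `"v2: B (abc) -> C (ab) + CO2 (c)"`.
#'   Reversibility is written `<->`; a `| ATP:-1 NADH:2` suffix carries signed
#'   cofactor coefficients (production positive); `@ kind` tags one of
#'   internal, uptake, excretion, biomass, maintenance; `[lb, ub]` sets bounds.
#' @param metabolites optional metabolite table (as in [metabolic_network()]);
#'   when given, atom-map lengths are checked against declared carbon counts.
#' @return a list of class `mfa_reaction`.
#' @export
parse_reaction <- function(line, metabolites = NULL) {
  line <- trimws(line)
  m <- regmatches(line, regexec("^([^:]+):(.*)$", line))[[1]]
  if (!length(m)) stop("cannot parse reaction line: '", line, "'")
  id <- trimws(m[2])
  rest <- m[3]

  lb <- NA_real_; ub <- NA_real_
  bm <- regmatches(rest, regexec("\\[\\s*([-0-9.eE+]+)\\s*,\\s*([-0-9.eE+Inf]+)\\s*\\]\\s*$", rest))[[1]]
  if (length(bm)) {
    lb <- as.numeric(bm[2]); ub <- as.numeric(bm[3])
    rest <- sub("\\[[^]]*\\]\\s*$", "", rest)
  }
  kind <- NA_character_
  km <- regmatches(rest, regexec("@\\s*([A-Za-z_]+)\\s*$", rest))[[1]]
  if (length(km)) {
    kind <- km[2]
    if (!kind %in% REACTION_KINDS)
      stop("reaction ", id, ": unknown kind '", kind, "'")
    rest <- sub("@\\s*[A-Za-z_]+\\s*$", "", rest)
  }
  cof <- stats::setNames(numeric(length(COFACTOR_IDS)), COFACTOR_IDS)
  if (grepl("|", rest, fixed = TRUE)) {
    cp <- strsplit(rest, "|", fixed = TRUE)[[1]]
    if (length(cp) != 2L) stop("reaction ", id, ": malformed cofactor suffix")
    rest <- cp[1]
    for (tok in strsplit(trimws(cp[2]), "\\s+")[[1]]) {
      if (!nzchar(tok)) next
      kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L || !kv[1] %in% COFACTOR_IDS)
        stop("reaction ", id, ": bad cofactor token '", tok, "'")
      cof[kv[1]] <- as.numeric(kv[2])
    }
  }

  reversible <- grepl("<->", rest, fixed = TRUE)
  sides <- strsplit(rest, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop("reaction ", id, ": expected one '->' or '<->'")
  reactants <- parse_side(sides[1], id)
  products <- parse_side(sides[2], id)

  if (is.na(kind)) kind <- "internal"
  if (is.na(lb)) lb <- if (reversible) -1000 else 0
  if (is.na(ub)) ub <- 1000
  if (lb > ub) stop("reaction ", id, ": lower bound exceeds upper bound")
  if (!reversible && lb < 0) stop("reaction ", id, ": irreversible with negative lower bound")

  for (side in list(reactants, products)) {
    labs <- unlist(lapply(side, function(t) strsplit(t$map, "")[[1]]))
    if (anyDuplicated(labs))
      stop("reaction ", id, ": duplicate atom label on one side")
  }
  if (kind != "biomass") {
    rl <- sort(unlist(lapply(reactants, function(t) strsplit(t$map, "")[[1]])))
    pl <- sort(unlist(lapply(products, function(t) strsplit(t$map, "")[[1]])))
    if (!identical(rl, pl))
      stop("reaction ", id, ": atom balance violated ({",
           paste(rl, collapse = ""), "} vs {", paste(pl, collapse = ""), "})")
  }
  if (!is.null(metabolites)) {
    for (t in c(reactants, products)) {
      i <- match(t$met, metabolites$id)
      if (!is.na(i) && nchar(t$map) != metabolites$carbons[i] && nchar(t$map) > 0)
        stop("reaction ", id, ": atom map of ", t$met, " has ", nchar(t$map),
             " labels but metabolite declares ", metabolites$carbons[i], " carbons")
    }
  }

  structure(list(id = id, reactants = reactants, products = products,
                 reversible = reversible, lb = lb, ub = ub,
                 cofactors = cof, kind = kind),
            class = "mfa_reaction")
}

#' Serialize a reaction back to its text form
#'
#' Inverse of [parse_reaction()] up to whitespace; `parse_reaction(serialize_reaction(r))`
#' reproduces `r`.
#'
#' @param rxn an `mfa_reaction`.
#' @return single character string.
#' @export
serialize_reaction <- function(rxn) {
  fmt_side <- function(side) {
    if (!length(side)) return("")
    paste(vapply(side, function(t) {
      coef <- if (t$coef != 1) paste0(format(t$coef), " ") else ""
      paste0(coef, t$met, " (", t$map, ")")
    }, character(1)), collapse = " + ")
  }
  arrow <- if (rxn$reversible) "<->" else "->"
  s <- paste0(rxn$id, ": ", fmt_side(rxn$reactants), " ", arrow, " ",
              fmt_side(rxn$products))
  cof <- rxn$cofactors[rxn$cofactors != 0]
  if (length(cof))
    s <- paste0(s, " | ", paste(names(cof), cof, sep = ":", collapse = " "))
  s <- paste0(s, " @ ", rxn$kind)
  def_lb <- if (rxn$reversible) -1000 else 0
  if (rxn$lb != def_lb || rxn$ub != 1000)
    s <- paste0(s, " [", rxn$lb, ", ", rxn$ub, "]")
  s
}

#' Read a carbon-mapped network model from a file
#'
#' @param path path to a model file in the grammar described in
#'   [parse_reaction()], with `# MET` metabolite declarations.
#' @return a validated [metabolic_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "//")]
  metlines <- lines[startsWith(lines, "#")]
  rxnlines <- lines[!startsWith(lines, "#")]

  mets <- do.call(rbind, lapply(metlines, function(l) {
    toks <- strsplit(trimws(sub("^#\\s*MET\\s+", "", l)), "\\s+")[[1]]
    if (length(toks) < 2L) stop("bad metabolite declaration: '", l, "'")
    flags <- toks[-(1:2)]
    data.frame(id = toks[1], carbons = as.integer(toks[2]),
               balanced = !any(flags %in% c("external", "substrate")),
               symmetric = "symmetric" %in% flags,
               substrate = "substrate" %in% flags,
               stringsAsFactors = FALSE)
  }))
  reactions <- lapply(rxnlines, parse_reaction, metabolites = mets)
  metabolic_network(reactions, mets)
}

#' Write a network model to a file
#'
#' @param net a [metabolic_network()].
#' @param path output path.
#' @export
write_network <- function(net, path) {
  mets <- net$metabolites
  metlines <- vapply(seq_len(nrow(mets)), function(i) {
    flags <- c(if (!mets$balanced[i]) "external" else "balanced",
               if (mets$symmetric[i]) "symmetric",
               if (mets$substrate[i]) "substrate")
    paste("# MET", mets$id[i], mets$carbons[i], paste(flags, collapse = " "))
  }, character(1))
  rxnlines <- vapply(net$reactions, serialize_reaction, character(1))
  writeLines(c(metlines, rxnlines), path)
}
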