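
#' Tracer recipe for a labeled substrate
#'
#' Describes the isotopic composition of one fed substrate as a mixture of
#' positionally labeled species. Each nominally labeled position carries 13C
#' with probability `purity` (atom-% isotopic purity); all other positions are
#' 13C at natural abundance. An explicitly unlabeled mixture component is a
#' component with no labeled positions.
#'
#' @param substrate metabolite id of the substrate.
#' @param components data.frame with columns `positions` (comma-separated
#'   1-based carbon positions, `"U"` for uniform labeling, `""` for
#'   unlabeled), `fraction` (molar fraction), `purity` (atom purity of the
#'   labeled positions).
#' @param n_carbons carbon count of the substrate (needed to expand `"U"`).
#' @return object of class `tracer_recipe`.
#' @examples
#' # 50 % [1-13C] + 50 % [U-13C6] glucose at 99 % purity
#' tracer_recipe("GLC", data.frame(positions = c("1", "U"),
#'                                 fraction = c(0.5, 0.5),
#'                                 purity = c(0.99, 0.99)), n_carbons = 6)
#' @export
tracer_recipe <- function(substrate, components, n_carbons) {
  if (abs(sum(components$fraction) - 1) > 1e-9)
    stop("tracer molar fractions for ", substrate, " must sum to 1")
  if (any(components$purity < 0 | components$purity > 1))
    stop("atom purity must lie in [0, 1]")
  comps <- lapply(seq_len(nrow(components)), function(i) {
    ps <- trimws(as.character(components$positions[i]))
    pos <- if (toupper(ps) == "U") seq_len(n_carbons)
           else if (ps == "" || is.na(ps)) integer(0)
           else as.integer(strsplit(ps, ",")[[1]])
    if (any(pos < 1 | pos > n_carbons))
      stop("labeled position outside 1..", n_carbons, " for ", substrate)
    list(positions = pos, fraction = components$fraction[i],
         purity = components$purity[i])
  })
  structure(list(substrate = substrate, n_carbons = n_carbons,
                 components = comps),
            class = "tracer_recipe")
}

#' MID of a substrate EMU under a tracer recipe
#'
#' Atoms are independent Bernoulli labels within each mixture component: a
#' nominally labeled position is 13C with probability equal to the component's
#' atom purity, any other position at natural 13C abundance. The returned MID
#' is the mixture-weighted distribution of the number of 13C atoms among the
#' requested positions.
#'
#' @param recipe a [tracer_recipe()].
#' @param atoms 1-based carbon positions of the EMU.
#' @param table an [isotope_table()].
#' @return MID vector of length `length(atoms) + 1`.
#' @export
tracer_substrate_mids <- function(recipe, atoms, table = isotope_table()) {
  if (any(atoms < 1 | atoms > recipe$n_carbons))
    stop("EMU atoms outside the substrate carbon range")
  p13 <- table$C[2]
  out <- numeric(length(atoms) + 1L)
  for (cmp in recipe$components) {
    mid <- 1
    for (a in atoms) {
      pa <- if (a %in% cmp$positions) cmp$purity else p13
      mid <- convolve_mid(mid, c(1 - pa, pa))
    }
    out <- out + cmp$fraction * mid
  }
  out
}

#' Measured-fragment specification
#'
#' Describes a GC-MS fragment ion: which backbone carbons of the parent
#' metabolite it retains and the elemental composition of everything else in
#' the ion (derivatization groups, heteroatoms, non-backbone carbons), which
#' determines its natural-isotope envelope.
#'
#' @param fragment_id identifier of the measured ion.
#' @param metabolite_id parent metabolite id.
#' @param backbone_atoms strictly increasing 1-based carbon positions.
#' @param extra_formula named counts of additional atoms among C, H, N, O,
#'   Si, S (e.g. `c(C = 8, H = 26, N = 1, O = 2, Si = 2)` for a TBDMS ion).
#' @return object of class `fragment_spec`.
#' @export
fragment_spec <- function(fragment_id, metabolite_id, backbone_atoms,
                          extra_formula = c()) {
  backbone_atoms <- as.integer(backbone_atoms)
  if (!length(backbone_atoms) || is.unsorted(backbone_atoms, strictly = TRUE))
    stop("backbone_atoms must be non-empty and strictly increasing")
  ef <- c(C = 0, H = 0, N = 0, O = 0, Si = 0, S = 0)
  if (length(extra_formula)) {
    bad <- setdiff(names(extra_formula), names(ef))
    if (length(bad)) stop("unsupported elements in extra_formula: ",
                          paste(bad, collapse = ", "))
    if (any(extra_formula < 0)) stop("extra_formula counts must be >= 0")
    ef[names(extra_formula)] <- extra_formula
  }
  structure(list(fragment_id = fragment_id, metabolite_id = metabolite_id,
                 backbone_atoms = backbone_atoms, extra_formula = ef),
            class = "fragment_spec")
}

#' Natural-isotope correction matrix of a fragment
#'
#' Column `m` (0-based) is the theoretical mass-shift distribution of the
#' fragment ion when exactly `m` backbone carbons are 13C: a point mass
#' shifted by `m`, convolved with the natural-isotope envelope of the
#' `extra_formula` atoms and with natural 13C on the remaining unlabeled
#' backbone carbons, truncated to `n_rows` mass channels.
#'
#' @param frag a [fragment_spec()].
#' @param table an [isotope_table()].
#' @param n_rows number of measured mass channels (>= backbone size + 1).
#' @return `n_rows` x `(n_backbone + 1)` matrix.
#' @export
correction_matrix <- function(frag, table = isotope_table(),
                              n_rows = length(frag$backbone_atoms) + 1L) {
  nb <- length(frag$backbone_atoms)
  if (n_rows < nb + 1L) stop("n_rows must be at least n_backbone + 1")
  extra <- 1
  for (el in names(frag$extra_formula)) {
    cnt <- frag$extra_formula[[el]]
    if (cnt > 0) extra <- convolve_mid(extra, element_shift_dist(table[[el]], cnt))
  }
  C <- matrix(0, n_rows, nb + 1L)
  for (m in 0:nb) {
    nat <- natural_mid(nb - m, table)      # unlabeled backbone carbons
    env <- convolve_mid(extra, nat)
    col <- c(numeric(m), env)              # shift by m labeled carbons
    len <- min(length(col), n_rows)
    C[seq_len(len), m + 1L] <- col[seq_len(len)]
  }
  C
}

#' Correct raw MS intensities to a backbone MID
#'
#' Deconvolves natural-isotope background (derivatization atoms, heteroatoms,
#' natural 13C of the unlabeled backbone positions) from raw fragment
#' intensities by non-negative least squares against the fragment's
#' [correction_matrix()], then renormalizes. Non-negativity keeps noisy data
#' from producing negative mass-isotopomer fractions.
#'
#' @param raw non-negative intensity vector over consecutive mass channels
#'   starting at the unshifted fragment mass; length >= backbone size + 1.
#' @param frag a [fragment_spec()].
#' @param table an [isotope_table()].
#' @return corrected MID vector of length `n_backbone + 1`.
#' @export
correct_raw_ms <- function(raw, frag, table = isotope_table()) {
  if (all(raw == 0)) stop("degenerate input: all-zero raw intensities")
  if (any(raw < 0)) stop("raw intensities must be non-negative")
  C <- correction_matrix(frag, table, n_rows = length(raw))
  if (kappa(crossprod(C)) > 1e20)
    warning("ill-conditioned correction matrix for fragment ", frag$fragment_id)
  x <- pracma::lsqnonneg(C, raw / sum(raw))$x
  if (sum(x) <= 0) stop("correction produced an empty MID for ", frag$fragment_id)
  x / sum(x)
}

#' Remove unlabeled inoculum biomass from a corrected MID
#'
#' A fraction `ratio` of the analyzed biomass stems from the unlabeled
#' inoculum and therefore shows the natural-abundance pattern of the backbone;
#' this inverts the mixing, clips small negatives and renormalizes.
#'
#' @param mid corrected MID vector.
#' @param ratio fraction of unlabeled inoculum biomass in `[0, 1)`; the
#'   default 0 leaves the MID unchanged.
#' @param table an [isotope_table()].
#' @return corrected MID of the labeled population.
#' @export
inoculum_correct <- function(mid, ratio = 0, table = isotope_table()) {
  if (ratio < 0 || ratio >= 1) stop("inoculum ratio must lie in [0, 1)")
  if (ratio == 0) return(mid)
  nat <- natural_mid(length(mid) - 1L, table)
  x <- (mid - ratio * nat) / (1 - ratio)
  if (min(x) < -1e-3)
    warning("inoculum correction produced fractions below -1e-3; ",
            "ratio or data may be inconsistent")
  x <- pmax(x, 0)
  x / sum(x)
}

#' Packaged registry of TBDMS amino-acid fragments
#'
#' Representative TBDMS-derivatized proteinogenic amino-acid fragments with
#' their backbone carbons and non-backbone elemental formulas: per amino acid
#' the `[M-57]` ion (full backbone, loss of a tert-butyl group) and the
#' `[M-159]` ion (loss of carbon 1 with its TBDMS-carboxyl). The registry is a
#' plain CSV that users can copy and edit for their own instruments.
#'
#' @return data.frame with columns `fragment_id`, `metabolite`,
#'   `backbone_atoms`, `extra_formula`.
#' @export
tbdms_fragments <- function() {
  path <- system.file("extdata", "tbdms_fragments.csv", package = "emuflux")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# parse "C8H26NO2Si2"-style formula strings into named counts
parse_formula <- function(s) {
  out <- c(C = 0, H = 0, N = 0, O = 0, Si = 0, S = 0)
  if (is.na(s) || !nzchar(s)) return(out)
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  for (tok in toks) {
    el <- gsub("[0-9]", "", tok)
    cnt <- gsub("[^0-9]", "", tok)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!el %in% names(out)) stop("unsupported element in formula: ", el)
    out[el] <- out[el] + cnt
  }
  out
}
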