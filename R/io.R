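
# ---- file formats ------------------------------------------------------------
#
# Tracer CSV:      substrate, n_carbons, labeled_positions, molar_fraction,
#                  atom_purity   (positions "1 3" space-separated, "U", or "")
# Measurement CSV: fragment_id, metabolite, backbone_atoms, extra_formula,
#                  kind (raw|corrected|flux), m0..mK, sd0..sdK (NA-padded).
#                  kind == "flux" rows carry a measured rate in m0/sd0 and the
#                  reaction id in the metabolite column.
# Isotope JSON:    named lists of abundance vectors.

#' Write a tracer recipe CSV
#' @param recipe a [tracer_recipe()] or named list of recipes.
#' @param path output path.
#' @export
write_tracers <- function(recipe, path) {
  recipes <- if (inherits(recipe, "tracer_recipe"))
    stats::setNames(list(recipe), recipe$substrate) else recipe
  rows <- list()
  for (rc in recipes) {
    for (cmp in rc$components) {
      pos <- if (length(cmp$positions) == rc$n_carbons &&
                 all(cmp$positions == seq_len(rc$n_carbons))) "U"
             else paste(cmp$positions, collapse = " ")
      rows[[length(rows) + 1L]] <- data.frame(
        substrate = rc$substrate, n_carbons = rc$n_carbons,
        labeled_positions = pos, molar_fraction = cmp$fraction,
        atom_purity = cmp$purity, stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read a tracer recipe CSV
#' @param path tracer CSV path.
#' @return named list of [tracer_recipe()] per substrate.
#' @export
read_tracers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(labeled_positions = "character"))
  out <- list()
  for (sub in unique(df$substrate)) {
    d <- df[df$substrate == sub, ]
    comps <- data.frame(
      positions = vapply(d$labeled_positions, function(p) {
        p <- trimws(p)
        if (toupper(p) == "U") "U" else gsub("\\s+", ",", p)
      }, character(1)),
      fraction = d$molar_fraction, purity = d$atom_purity)
    out[[sub]] <- tracer_recipe(sub, comps, d$n_carbons[1])
  }
  out
}

#' Write measurements (raw intensities and/or corrected MIDs) to CSV
#' @param exp a `synthetic_experiment`, or a list with elements
#'   `measurements` ([measurement_set()]), optional `raw` (named intensity
#'   vectors) and `fragments`.
#' @param path output path.
#' @param kinds which kinds to write.
#' @export
write_measurements <- function(exp, path, kinds = c("corrected", "raw", "flux")) {
  frags <- exp$fragments
  fmt_formula <- function(ef) {
    nz <- ef[ef > 0]
    paste0(names(nz), ifelse(nz == 1, "", nz), collapse = "")
  }
  width <- 0L
  rows <- list()
  add <- function(frag, kind, vals, sds) {
    width <<- max(width, length(vals))
    rows[[length(rows) + 1L]] <<- list(
      fragment_id = frag$fragment_id, metabolite = frag$metabolite_id,
      backbone_atoms = paste(frag$backbone_atoms, collapse = " "),
      extra_formula = fmt_formula(frag$extra_formula),
      kind = kind, vals = vals, sds = sds)
  }
  if ("corrected" %in% kinds) {
    for (m in exp$measurements$mid_measurements)
      add(m$fragment, "corrected", m$mid, m$sd)
  }
  if ("raw" %in% kinds && length(exp$raw)) {
    for (fr in frags)
      if (!is.null(exp$raw[[fr$fragment_id]]))
        add(fr, "raw", exp$raw[[fr$fragment_id]], NULL)
  }
  if ("flux" %in% kinds) {
    fm <- exp$measurements$flux_measurements
    for (i in seq_len(NROW(fm)))
      rows[[length(rows) + 1L]] <- list(
        fragment_id = paste0("flux_", fm$reaction_id[i]),
        metabolite = fm$reaction_id[i], backbone_atoms = "",
        extra_formula = "", kind = "flux",
        vals = fm$value[i], sds = fm$sd[i])
  }
  pad <- function(x, n) c(x, rep(NA_real_, n - length(x)))
  df <- do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(fragment_id = r$fragment_id, metabolite = r$metabolite,
                      backbone_atoms = r$backbone_atoms,
                      extra_formula = r$extra_formula, kind = r$kind,
                      stringsAsFactors = FALSE)
    v <- pad(r$vals, width); s <- pad(if (is.null(r$sds)) numeric(0) else r$sds, width)
    names(v) <- paste0("m", seq_len(width) - 1L)
    names(s) <- paste0("sd", seq_len(width) - 1L)
    cbind(out, as.data.frame(as.list(v)), as.data.frame(as.list(s)))
  }))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Read a measurement CSV into a measurement set
#'
#' Rows of kind `raw` are corrected with [correct_raw_ms()] (then inoculum
#' corrected); rows of kind `corrected` pass through; `flux` rows become
#' measured rates.
#'
#' @param path measurement CSV path.
#' @param table an [isotope_table()].
#' @param inoculum_ratio unlabeled-inoculum fraction handed to
#'   [inoculum_correct()].
#' @param default_sd sd assigned to corrected-from-raw rows lacking one.
#' @param excluded_fragments fragment ids to drop.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path, table = isotope_table(),
                              inoculum_ratio = 0, default_sd = 0.004,
                              excluded_fragments = character(0),
                              prefer = c("corrected", "raw")) {
  prefer <- match.arg(prefer)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(backbone_atoms = "character",
                                       extra_formula = "character"))
  # a file may carry the same fragment as both raw and corrected rows;
  # keep one kind per fragment, preferring `prefer`
  has_pref <- df$fragment_id %in% df$fragment_id[df$kind == prefer]
  drop <- df$kind %in% c("raw", "corrected") & has_pref & df$kind != prefer
  df <- df[!drop, , drop = FALSE]
  mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
  scols <- grep("^sd[0-9]+$", names(df), value = TRUE)
  mids <- list(); fluxes <- list()
  for (i in seq_len(nrow(df))) {
    vals <- as.numeric(df[i, mcols]); vals <- vals[!is.na(vals)]
    sds <- as.numeric(df[i, scols]); sds <- sds[!is.na(sds)]
    if (df$kind[i] == "flux") {
      fluxes[[length(fluxes) + 1L]] <- data.frame(
        reaction_id = df$metabolite[i], value = vals[1], sd = sds[1])
      next
    }
    atoms <- as.integer(strsplit(trimws(df$backbone_atoms[i]), "[^0-9]+")[[1]])
    frag <- fragment_spec(df$fragment_id[i], df$metabolite[i], atoms,
                          parse_formula(df$extra_formula[i]))
    nb <- length(atoms)
    if (df$kind[i] == "raw") {
      mid <- correct_raw_ms(vals, frag, table)
      mid <- inoculum_correct(mid, inoculum_ratio, table)
      sd <- rep(default_sd, nb + 1L)
    } else {
      mid <- vals[seq_len(nb + 1L)]
      mid <- inoculum_correct(check_mid(mid, tol = 1e-3), inoculum_ratio, table)
      sd <- if (length(sds) >= nb + 1L) sds[seq_len(nb + 1L)] else rep(default_sd, nb + 1L)
    }
    mids[[length(mids) + 1L]] <- list(fragment = frag, mid = mid, sd = sd)
  }
  measurement_set(mids,
                  if (length(fluxes)) do.call(rbind, fluxes) else NULL,
                  excluded_fragments = excluded_fragments)
}

#' Write an isotope table to JSON
#' @param table an [isotope_table()].
#' @param path output path.
#' @export
write_isotopes <- function(table, path) {
  jsonlite::write_json(unclass(table), path, auto_unbox = FALSE, digits = NA)
}

#' Read an isotope table from JSON
#' @param path JSON path.
#' @return an [isotope_table()].
#' @export
read_isotopes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  isotope_table(overrides = raw)
}

#' Write fitted fluxes and intervals to a results CSV
#'
#' One row per reaction (`id, net, exchange, ci_lower, ci_upper`) followed by
#' a fit-summary block (SSR, degrees of freedom, chi-squared critical values
#' and verdict) as comment lines.
#'
#' @param fit a [fit_fluxes()] result.
#' @param net the `mfa_network`.
#' @param path output path.
#' @param ci optional [monte_carlo_ci()] result.
#' @param alpha significance level of the reported chi-squared verdict.
#' @export
write_results <- function(fit, net, path, ci = NULL, alpha = 0.05) {
  ids <- reaction_ids(net)
  ex <- stats::setNames(numeric(length(ids)), ids)
  ex[names(fit$best_flux$exchange)] <- fit$best_flux$exchange
  df <- data.frame(id = ids, net = as.numeric(fit$best_flux$net[ids]),
                   exchange = as.numeric(ex),
                   ci_lower = NA_real_, ci_upper = NA_real_)
  if (!is.null(ci)) {
    i <- match(df$id, ci$intervals$reaction_id)
    df$ci_lower <- ci$intervals$lower[i]
    df$ci_upper <- ci$intervals$upper[i]
  }
  ct <- chi2_test(fit$ssr, fit$dof, alpha)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# ssr,%.10g", fit$ssr),
    sprintf("# dof,%d", fit$dof),
    sprintf("# chi2_lower_critical,%.6g", ct$lower_critical),
    sprintf("# chi2_upper_critical,%.6g", ct$upper_critical),
    sprintf("# chi2_pass,%s", ct$pass)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a results CSV written by [write_results()]
#' @param path results CSV path.
#' @return data.frame of fluxes with the summary in `attr(, "summary")`.
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  com <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"))
  kv <- do.call(rbind, strsplit(sub("^#\\s*", "", com), ","))
  attr(df, "summary") <- stats::setNames(as.list(kv[, 2]), kv[, 1])
  df
}
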