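# Pathway-definition file dialect (JSON or TSV) and the parameter-table
# loader that merges user-supplied thermodynamic/kinetic values onto the
# shipped pathway topologies.

#' Parse a reaction equation string
#'
#' Equations look like `"1 glc + 1 atp -> 1 g6p + 1 adp"`; coefficients
#' default to 1, `<->`/`<=>` mark reversibility (informational; the
#' `reversible` flag on the reaction governs).
#'
#' @param eq equation string.
#' @return named numeric stoichiometry vector, substrates negative.
#' @export
parse_equation <- function(eq) {
  sides <- strsplit(eq, "<->|<=>|->", perl = TRUE)[[1]]
  if (length(sides) == 1 && grepl("(<->|<=>|->)\\s*$", eq)) {
    sides <- c(sides, "")  # sink reaction: empty right-hand side
  }
  if (length(sides) != 2) {
    stop_zf(sprintf("cannot parse equation '%s'", eq), "zf_parse_error")
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "" || side == "0") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(side, "\\+")[[1]])
    st <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.]+\\s+)?(\\S+)$", tm))[[1]]
      if (length(m) != 3) {
        stop_zf(sprintf("cannot parse term '%s'", tm), "zf_parse_error")
      }
      coef <- if (m[2] == "") 1 else as.numeric(trimws(m[2]))
      cur <- if (m[3] %in% names(st)) st[[m[3]]] else 0
      st[m[3]] <- cur + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  out <- lhs
  for (nm in names(rhs)) out[nm] <- (if (nm %in% names(out)) out[nm] else 0) + rhs[nm]
  out[out != 0]
}

format_equation <- function(stoich) {
  fmt <- function(v) {
    paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  }
  paste(fmt(stoich[stoich < 0]), "->", fmt(stoich[stoich > 0]))
}

parse_km_entries <- function(s, where = "km") {
  if (is.na(s) || !nzchar(trimws(s))) return(stats::setNames(numeric(0), character(0)))
  parts <- trimws(strsplit(s, "[;,]")[[1]])
  km <- numeric(0)
  for (p in parts) {
    kv <- trimws(strsplit(p, ":")[[1]])
    val <- suppressWarnings(as.numeric(kv[2]))
    if (length(kv) != 2 || is.na(val)) {
      stop_zf(sprintf("malformed %s entry '%s' (expect 'met:mM')", where, p),
              "zf_parse_error")
    }
    km[kv[1]] <- val
  }
  km
}

#' Write a pathway to the JSON pathway-definition dialect
#'
#' One record per reaction: `id`, `equation`, `dg0_prime_kj_mol`,
#' `reversible`, `rel_flux`, `kcat_s`, `km` (map metabolite -> mM),
#' `mw_g_mol`; plus pathway-level `fixed_conc_mM`, bounds and temperature.
#'
#' @param pathway a [pathway_model()].
#' @param path output file.
#' @export
write_pathway_json <- function(pathway, path) {
  recs <- lapply(pathway$reactions, function(r) {
    k <- r$kinetics
    list(id = r$id, equation = format_equation(r$stoich),
         dg0_prime_kj_mol = r$dg0_prime, reversible = r$reversible,
         rel_flux = unname(pathway$rel_flux[[r$id]]),
         kcat_s = if (is.null(k)) NA else k$kcat_fwd,
         km = if (is.null(k) || !length(k$km)) NULL else as.list(k$km),
         mw_g_mol = if (is.null(k)) NA else k$mw)
  })
  obj <- list(reactions = unname(recs),
              fixed_conc_mM = as.list(pathway$fixed_conc),
              conc_lb_mM = pathway$conc_lb, conc_ub_mM = pathway$conc_ub,
              boundary = pathway$boundary, temperature_K = pathway$temperature)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pathway from the JSON pathway-definition dialect
#'
#' @param path file written by [write_pathway_json()] (or hand-authored in
#'   the same dialect).
#' @return a [pathway_model()].
#' @export
read_pathway_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rxns <- lapply(obj$reactions, function(rec) {
    km <- if (!is.null(rec$km)) unlist(rec$km) else numeric(0)
    kin <- NULL
    if (!is.null(rec$kcat_s) && !is.na(rec$kcat_s)) {
      kin <- enzyme_kinetics(rec$kcat_s, km, rec$mw_g_mol,
                             irreversible = !isTRUE(rec$reversible))
    }
    thermo_reaction(rec$id, parse_equation(rec$equation),
                    dg0_prime = rec$dg0_prime_kj_mol %||% NA_real_,
                    reversible = isTRUE(rec$reversible), kinetics = kin)
  })
  rel <- vapply(obj$reactions, function(rec) rec$rel_flux, numeric(1))
  names(rel) <- vapply(obj$reactions, function(rec) rec$id, character(1))
  pathway_model(rxns, rel_flux = rel,
                fixed_conc = unlist(obj$fixed_conc_mM) %||% numeric(),
                conc_lb = obj$conc_lb_mM %||% .CONC_LB_MM,
                conc_ub = obj$conc_ub_mM %||% .CONC_UB_MM,
                boundary = unlist(obj$boundary) %||% character(),
                temperature = obj$temperature_K %||% 298.15)
}

#' Load a thermodynamic/kinetic parameter table
#'
#' TSV/CSV with columns `reaction_id`, `dg0_prime_kj_mol`, `kcat_s`,
#' `km_entries` (semicolon-separated `met:mM` pairs), `mw_g_mol`.
#' Duplicate rows for a reaction are merged: geometric mean for the kinetic
#' parameters (the convention used when a database offers several
#' measurements), arithmetic mean for standard Gibbs energies; a warning
#' reports every merge.
#'
#' @param path parameter file (separator inferred from the extension:
#'   `.csv` comma, otherwise tab).
#' @return data frame with one row per reaction and a `km` list-column of
#'   named mM vectors.
#' @export
load_parameter_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("reaction_id", "dg0_prime_kj_mol", "kcat_s", "km_entries",
            "mw_g_mol")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_zf(paste("parameter table lacks column(s):",
                  paste(miss, collapse = ", ")), "zf_bad_table")
  }
  for (col in c("dg0_prime_kj_mol", "kcat_s", "mw_g_mol")) {
    if (!is.numeric(raw[[col]])) {
      bad <- raw[[col]][!is.na(raw[[col]]) &
                          is.na(suppressWarnings(as.numeric(raw[[col]])))]
      if (length(bad)) {
        stop_zf(sprintf("non-numeric value '%s' in column %s (check units suffixes)",
                        bad[1], col), "zf_bad_table")
      }
      raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
    }
  }
  raw$km <- lapply(ifelse(is.na(raw$km_entries), "", raw$km_entries),
                   parse_km_entries)
  out <- list()
  for (id in unique(raw$reaction_id)) {
    rows <- raw[raw$reaction_id == id, , drop = FALSE]
    if (nrow(rows) > 1) {
      warning(sprintf("merging %d parameter rows for '%s' (geometric mean of kinetics)",
                      nrow(rows), id))
    }
    gmean <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else exp(mean(log(v)))
    }
    kms <- rows$km[vapply(rows$km, length, integer(1)) > 0]
    km <- if (length(kms)) {
      nms <- unique(unlist(lapply(kms, names)))
      stats::setNames(vapply(nms, function(nm) {
        gmean(vapply(kms, function(k) k[nm] %||% NA_real_, numeric(1)))
      }, numeric(1)), nms)
    } else numeric(0)
    dg <- rows$dg0_prime_kj_mol[!is.na(rows$dg0_prime_kj_mol)]
    out[[id]] <- list(reaction_id = id,
                      dg0_prime_kj_mol = if (length(dg)) mean(dg) else NA_real_,
                      kcat_s = gmean(rows$kcat_s),
                      km = km,
                      mw_g_mol = gmean(rows$mw_g_mol))
  }
  structure(out, class = "parameter_table")
}

#' Merge a parameter table onto a pathway
#'
#' Fills `dg0_prime` and kinetics fields of matching reactions; entries the
#' table does not cover are reported in the `missing` attribute as a
#' checklist (the merge never fails on gaps).
#'
#' @param pathway a [pathway_model()].
#' @param params a [load_parameter_table()] result.
#' @return the updated pathway; `attr(, "missing")` is a data frame listing
#'   reaction ids and the fields still absent.
#' @export
merge_parameters <- function(pathway, params) {
  checklist <- list()
  for (id in names(pathway$reactions)) {
    r <- pathway$reactions[[id]]
    p <- params[[id]]
    if (!is.null(p)) {
      if (!is.na(p$dg0_prime_kj_mol)) r$dg0_prime <- p$dg0_prime_kj_mol
      if (!is.na(p$kcat_s) && !is.na(p$mw_g_mol)) {
        irr <- if (!is.null(r$kinetics)) r$kinetics$irreversible else !r$reversible
        r$kinetics <- enzyme_kinetics(p$kcat_s, p$km, p$mw_g_mol,
                                      irreversible = irr)
      }
    }
    gaps <- character(0)
    if (is.na(r$dg0_prime)) gaps <- c(gaps, "dg0_prime")
    if (is.null(r$kinetics)) gaps <- c(gaps, "kinetics")
    if (length(gaps)) checklist[[id]] <- gaps
    pathway$reactions[[id]] <- r
  }
  miss <- data.frame(
    reaction_id = names(checklist),
    missing = vapply(checklist, paste, character(1), collapse = ","),
    row.names = NULL
  )
  attr(pathway, "missing") <- miss
  pathway
}
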