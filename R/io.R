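# File formats: scenario CSV/JSON, factor-set JSON, numeric formatting.

#' Format numbers in scientific notation
#'
#' @param x numeric vector.
#' @param digits significant digits (default 3, matching the published
#'   tables); must be >= 2.
#' @return Character vector like `"5.75E+00"`; `NA` stays `"NA"`.
#' @export
format_sci <- function(x, digits = 3) {
  if (digits < 2) stop_validation("digits must be >= 2")
  out <- toupper(formatC(x, format = "e", digits = digits - 1))
  out[is.na(x)] <- "NA"
  out
}

scenario_to_rows <- function(scen) {
  if (is.null(scen$footprint)) return(NULL)
  data.frame(scenario = scen$name, aop = aop_keys(),
             value = as.numeric(scen$footprint),
             unit = unname(aop_units()), stringsAsFactors = FALSE)
}

scenario_to_handprint_row <- function(scen) {
  if (is.null(scen$handprint)) return(NULL)
  data.frame(scenario = scen$name,
             handprint_base = scen$handprint$base,
             handprint_min = scen$handprint$min,
             handprint_max = scen$handprint$max, stringsAsFactors = FALSE)
}

#' Write scenarios to CSV
#'
#' Footprints go to `path` as long-format rows `scenario,aop,value,unit`
#' (missing entries as literal `NA`); handprints, if any scenario carries
#' one, to a sibling file `<stem>_handprint.csv` with columns
#' `scenario,handprint_base,handprint_min,handprint_max`.
#'
#' @param scenarios a list of [scenario()] objects.
#' @param path CSV path for the footprint table.
#' @return Invisibly, the paths written.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  fp <- do.call(rbind, lapply(scenarios, scenario_to_rows))
  hp <- do.call(rbind, lapply(scenarios, scenario_to_handprint_row))
  utils::write.csv(fp, path, row.names = FALSE, na = "NA")
  paths <- path
  if (!is.null(hp)) {
    hp_path <- handprint_sibling(path)
    utils::write.csv(hp, hp_path, row.names = FALSE)
    paths <- c(paths, hp_path)
  }
  invisible(paths)
}

handprint_sibling <- function(path) {
  sub("(\\.[^.]*)?$", "_handprint\\1", path)
}

#' Read scenarios from CSV
#'
#' Expects the format written by [write_scenarios()].  Unit strings must
#' match the canonical Area-of-Protection units exactly (`DALY`,
#' `species.yr`, `USD`); values may be literal `NA` for burdens that were
#' not assessed.  Duplicate scenario/AoP rows, unknown units and negative
#' values are rejected with the offending row named.
#'
#' @param path CSV path of the footprint table.
#' @param handprint_path optional CSV of handprint bounds; defaults to the
#'   `<stem>_handprint.csv` sibling when that file exists.
#' @return List of validated [scenario()] objects.
#' @export
read_scenarios <- function(path, handprint_path = NULL) {
  if (!file.exists(path)) stop_validation("no such scenario file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(scenario = "character",
                                       aop = "character", value = "numeric",
                                       unit = "character"))
  required <- c("scenario", "aop", "value", "unit")
  if (!all(required %in% names(df))) {
    stop_validation("scenario CSV needs columns scenario,aop,value,unit")
  }
  units <- aop_units()
  for (i in seq_len(nrow(df))) {
    if (!df$aop[i] %in% aop_keys()) {
      stop_validation(sprintf("row %d: unknown AoP '%s'", i, df$aop[i]))
    }
    if (!identical(df$unit[i], unname(units[[df$aop[i]]]))) {
      stop_validation(sprintf("row %d: unit '%s' does not match canonical '%s' for %s",
                              i, df$unit[i], units[[df$aop[i]]], df$aop[i]))
    }
    if (!is.na(df$value[i]) && df$value[i] < 0) {
      stop_validation(sprintf("row %d: negative burden %g", i, df$value[i]))
    }
  }
  dup <- duplicated(df[c("scenario", "aop")])
  if (any(dup)) {
    stop_validation(sprintf("row %d: duplicate scenario/AoP entry", which(dup)[1]))
  }

  if (is.null(handprint_path)) {
    sib <- handprint_sibling(path)
    if (file.exists(sib)) handprint_path <- sib
  }
  hp <- NULL
  if (!is.null(handprint_path)) {
    hp <- utils::read.csv(handprint_path, stringsAsFactors = FALSE)
    if (!all(c("scenario", "handprint_base", "handprint_min",
               "handprint_max") %in% names(hp))) {
      stop_validation("handprint CSV needs scenario,handprint_base,handprint_min,handprint_max")
    }
  }

  names_all <- unique(c(df$scenario, hp$scenario))
  lapply(names_all, function(nm) {
    rows <- df[df$scenario == nm, ]
    fp <- NULL
    if (nrow(rows) > 0) {
      v <- stats::setNames(rep(NA_real_, 3), aop_keys())
      v[rows$aop] <- rows$value
      fp <- impact_vector(v[["HUMAN_HEALTH"]], v[["ECOSYSTEMS"]],
                          v[["RESOURCES"]])
    }
    hrow <- if (is.null(hp)) NULL else hp[hp$scenario == nm, ]
    hpe <- NULL
    if (!is.null(hrow) && nrow(hrow) == 1) {
      hpe <- handprint_estimate(hrow$handprint_base, hrow$handprint_min,
                                hrow$handprint_max)
    }
    scenario(nm, footprint = fp, handprint = hpe)
  })
}

#' Read and write scenarios as JSON
#'
#' JSON mirror of the CSV interchange format: an array of objects with
#' `name`, optional `footprint` (object keyed by AoP, `null` for missing)
#' and optional `handprint` (`base`/`min`/`max`).
#'
#' @param scenarios list of [scenario()] objects.
#' @param path JSON file path.
#' @return `read_scenarios_json()` returns a list of validated scenarios.
#' @export
write_scenarios_json <- function(scenarios, path) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  recs <- lapply(scenarios, function(s) {
    rec <- list(name = s$name)
    if (!is.null(s$footprint)) {
      rec$footprint <- lapply(as.list(unclass(s$footprint)),
                              function(v) if (is.na(v)) NULL else v)
    }
    if (!is.null(s$handprint)) rec$handprint <- unclass(s$handprint)
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenarios_json
#' @export
read_scenarios_json <- function(path) {
  if (!file.exists(path)) stop_validation("no such scenario file: ", path)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(recs, function(rec) {
    fp <- NULL
    if (!is.null(rec$footprint)) {
      g <- function(k) {
        v <- rec$footprint[[k]]
        if (is.null(v)) NA_real_ else as.numeric(v)
      }
      fp <- impact_vector(g("HUMAN_HEALTH"), g("ECOSYSTEMS"), g("RESOURCES"))
    }
    hp <- NULL
    if (!is.null(rec$handprint)) {
      hp <- handprint_estimate(rec$handprint$base, rec$handprint$min,
                               rec$handprint$max)
    }
    scenario(rec$name, footprint = fp, handprint = hp)
  })
}

#' Read and write value-choice pools as JSON
#'
#' The pool file carries `footprint_nfs` (array of id/source/year/factors
#' records), `handprint_nfs` (id/year/factor), `weighting_sets` (object
#' keyed by main-set label, arrays of id/weights records), `variants` and a
#' `synthetic` flag.  Factor units are the canonical Area-of-Protection
#' units per year.
#'
#' @param pools a [factor_pools()].
#' @param path JSON file path.
#' @return `read_factor_pools()` returns a validated [factor_pools()].
#' @export
write_factor_pools <- function(pools, path) {
  if (!inherits(pools, "factor_pools")) {
    stop_validation("pools must be a factor_pools object")
  }
  x <- list(
    footprint_nfs = lapply(pools$footprint_nfs, function(nf) {
      list(id = nf$id, source = nf$source, year = nf$year,
           factors = as.list(nf$factors))
    }),
    handprint_nfs = lapply(pools$handprint_nfs, function(nf) {
      list(id = nf$id, year = nf$year, factor = nf$factor)
    }),
    weighting_sets = lapply(pools$weighting_sets, function(grp) {
      lapply(grp, function(wf) list(id = wf$id, weights = as.list(wf$weights)))
    }),
    variants = pools$variants,
    synthetic = pools$synthetic)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factor_pools
#' @export
read_factor_pools <- function(path) {
  if (!file.exists(path)) stop_validation("no such pools file: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  fps <- lapply(x$footprint_nfs, function(r) {
    normalization_set(r$id, r$source, r$year, r$factors$HUMAN_HEALTH,
                      r$factors$ECOSYSTEMS, r$factors$RESOURCES)
  })
  hps <- lapply(x$handprint_nfs, function(r) {
    handprint_normalization_set(r$id, r$year, r$factor)
  })
  wfs <- lapply(names(x$weighting_sets), function(lbl) {
    lapply(x$weighting_sets[[lbl]], function(r) {
      weighting_set(r$id, lbl, r$weights$HUMAN_HEALTH, r$weights$ECOSYSTEMS,
                    r$weights$RESOURCES)
    })
  })
  names(wfs) <- names(x$weighting_sets)
  factor_pools(fps, hps, wfs,
               variants = as.character(unlist(x$variants)),
               synthetic = isTRUE(x$synthetic))
}

#' Export all built-in data for inspection
#'
#' Writes the built-in case studies (CSV + JSON), their derived reference
#' factors, and a synthetic pool file to a directory.
#'
#' @param dest destination directory (created if absent).
#' @param seed seed for the synthetic pool values.
#' @return Invisibly, the files written.
#' @export
export_fixtures <- function(dest, seed = 0) {
  dir.create(dest, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (nm in builtin_case_names()) {
    case <- builtin_case(nm)
    scen <- list(case$comparator, case$treatment)
    p <- file.path(dest, paste0(nm, ".csv"))
    written <- c(written, write_scenarios(scen, p))
    pj <- file.path(dest, paste0(nm, ".json"))
    write_scenarios_json(scen, pj)
    written <- c(written, pj)
    f <- reference_factors(nm)
    pools1 <- factor_pools(list(f$nf), list(f$hnf),
                           stats::setNames(list(list(f$wf)), f$wf$main_set))
    pf <- file.path(dest, paste0(nm, "_reference_factors.json"))
    write_factor_pools(pools1, pf)
    written <- c(written, pf)
  }
  pp <- file.path(dest, "synthetic_pools.json")
  write_factor_pools(synthetic_pools(seed), pp)
  invisible(c(written, pp))
}
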