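#' Write an isotherm as delimited text
#'
#' Plain tab-delimited format with a `#`-prefixed sidecar block carrying the
#' schedule (units fixed in the keys), followed by the columns
#' `injection_index`, `injection_volume_uL`, `heat_ucal`,
#' `normalized_heat_kcal_per_mol`, `molar_ratio`.
#'
#' @param isotherm An `itc_isotherm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(isotherm, path) {
  stopifnot(inherits(isotherm, "itc_isotherm"))
  sch <- isotherm$schedule
  hdr <- c("# itcbridge isotherm v1",
           sprintf("# cell_volume_mL: %.10g", sch$cell_volume * 1e3),
           sprintf("# cell_conc_uM: %.10g", sch$cell_conc0 * 1e6),
           sprintf("# syringe_conc_uM: %.10g", sch$syringe_conc * 1e6),
           sprintf("# temperature_K: %.10g", sch$temperature))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(as.data.frame(isotherm), digits = 17,
                            scientific = TRUE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isotherm from delimited text
#'
#' Parses the format written by [write_isotherm()]: the sidecar block
#' reconstructs the [injection_schedule()], the required columns are
#' validated, the molar-ratio axis must be strictly increasing, and unknown
#' extra columns are accepted with a warning.
#'
#' @param path Input file path.
#' @return An `itc_isotherm`.
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+):\\s*(\\S+)", hdr))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  meta <- stats::setNames(vapply(kv, function(m) as.numeric(m[3]), numeric(1)),
                          vapply(kv, function(m) m[2], character(1)))
  need_meta <- c("cell_volume_mL", "cell_conc_uM", "syringe_conc_uM",
                 "temperature_K")
  if (!all(need_meta %in% names(meta)))
    stop("isotherm sidecar block is missing: ",
         paste(setdiff(need_meta, names(meta)), collapse = ", "))
  df <- utils::read.table(text = ln[!startsWith(ln, "#")], header = TRUE,
                          sep = "\t")
  need <- c("injection_index", "injection_volume_uL", "heat_ucal",
            "normalized_heat_kcal_per_mol", "molar_ratio")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("isotherm file is missing required columns: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  if (any(diff(df$molar_ratio) <= 0)) {
    bad <- which(diff(df$molar_ratio) <= 0)[1] + 1
    stop(sprintf("molar_ratio must be strictly increasing (violated at row %d)",
                 bad))
  }
  sch <- injection_schedule(meta[["cell_volume_mL"]] * 1e-3,
                            meta[["cell_conc_uM"]] * 1e-6,
                            meta[["syringe_conc_uM"]] * 1e-6,
                            df$injection_volume_uL * 1e-6,
                            meta[["temperature_K"]])
  structure(list(schedule = sch,
                 raw_heats = df$heat_ucal,
                 normalized_heats = df$normalized_heat_kcal_per_mol,
                 molar_ratios = df$molar_ratio,
                 displacement_correction = TRUE,
                 dilution_offset = 0,
                 model = NULL),
            class = "itc_isotherm")
}

#' Expected-mass table for trimer and bridged complexes
#'
#' The full expected-mass bookkeeping for a set of intact-site counts: for
#' each q, the trimer complex (1 trimer : q LC8 dimers) and the fully
#' occupied bridged complex (2 trimers : 3q LC8 dimers), plus the free
#' trimer.  With the default mass table this reproduces, for q = 3/2/1,
#' the expected complex masses 292.8/114.6, 229.2/93.4 and 165.6/72.2 kDa
#' and the 51.0 kDa free trimer.
#'
#' @param q Vector of intact QT site counts (subset of 1:3; default all).
#' @param masses A [mass_table()].
#' @return Data frame with one row per q: bridged and trimer-complex
#'   stoichiometry ratios and expected masses, and the free-trimer mass.
#' @examples
#' masses_table()
#' @export
masses_table <- function(q = 3:1, masses = mass_table()) {
  stopifnot(all(q %in% 1:3))
  rows <- lapply(q, function(qi) {
    occ <- max_occupancy(qi)
    bridged <- complex_mass(species_composition(2, occ[["bridged_max"]], qi),
                            masses)
    trimer <- complex_mass(species_composition(1, occ[["trimer_max"]], qi),
                           masses)
    data.frame(q = qi,
               bridged_ratio = sprintf("2:%d", occ[["bridged_max"]]),
               bridged_mass_kDa = bridged,
               trimer_ratio = sprintf("1:%d", occ[["trimer_max"]]),
               trimer_complex_mass_kDa = trimer,
               free_trimer_mass_kDa = 3 * masses$lbd_od_monomer)
  })
  do.call(rbind, rows)
}

#' Run a simulate / fit / aggregate / speciate pipeline
#'
#' Drives the package end to end from a single configuration list:
#' generates a synthetic replicate set (from a named preset or explicit
#' generating model), fits every replicate with the chosen model, derives
#' dG and -TdS per replicate, aggregates each quantity across replicates by
#' inverse-variance weighting, and optionally computes a speciation table.
#' Reruns with an identical config give an identical report (the `timestamp`
#' field aside).
#'
#' @param config List with elements:
#'   \describe{
#'     \item{preset}{Preset name for [itc_preset()], or instead}
#'     \item{generating_model}{explicit [thermo_params()] /
#'       [sequential_model()];}
#'     \item{model}{`"oss"` (default) or `"sequential"`;}
#'     \item{n_replicates}{default 3;}
#'     \item{noise_sigma}{ucal, default 0.1;}
#'     \item{seed}{default 1;}
#'     \item{schedule}{optional [injection_schedule()], default
#'       [make_schedule()];}
#'     \item{exclude_first}{default FALSE;}
#'     \item{speciation}{optional list(total_trimer, total_lc8_dimer, q,
#'       kd_intra, kd_bridge).}
#'   }
#' @return A list of class `itcbridge_report`: the echoed config, the
#'   per-replicate fits, the aggregated thermodynamics table and any
#'   speciation output.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  model_type <- config$model %||% "oss"
  if (!model_type %in% c("oss", "sequential"))
    stop("configuration error: model must be 'oss' or 'sequential'")
  if (model_type == "sequential" && is.null(config$constraints))
    config$constraints <- constraint_spec()
  gen <- config$generating_model
  if (is.null(gen)) {
    if (is.null(config$preset))
      stop("configuration error: provide a preset name or a generating_model")
    pre <- itc_preset(config$preset)
    gen <- if (model_type == "sequential") {
      if (is.null(pre$sequential))
        stop("configuration error: preset '", config$preset,
             "' has no sequential parameter set")
      pre$sequential
    } else pre$oss
  }
  sch <- config$schedule %||% make_schedule()
  spec <- synthetic_spec(gen, sch,
                         noise_sigma = config$noise_sigma %||% 0.1,
                         n_replicates = config$n_replicates %||% 3,
                         seed = config$seed %||% 1)
  reps <- gen_replicates(spec)
  fits <- lapply(reps, function(iso) {
    if (model_type == "oss")
      fit_oss(iso, exclude_first = isTRUE(config$exclude_first))
    else
      fit_sequential_constrained(iso, constraints = config$constraints,
                                 exclude_first = isTRUE(config$exclude_first))
  })

  # aggregate each reported quantity across replicates, per event
  ev0 <- fits[[1]]$events
  agg <- do.call(rbind, lapply(seq_len(nrow(ev0)), function(e) {
    one <- function(col, se_col) {
      y <- vapply(fits, function(f) f$events[[col]][e], numeric(1))
      s <- vapply(fits, function(f) f$events[[se_col]][e], numeric(1))
      s[!is.finite(s) | s <= 0] <- max(abs(y)) * 1e-6 + 1e-12
      aggregate_inverse_variance(y, s)
    }
    kd <- one("kd", "kd_se"); dh <- one("dh", "dh_se")
    dg <- one("dg", "dg_se"); ts <- one("neg_t_ds", "ntds_se")
    data.frame(event = ev0$event[e],
               kd = kd$aggregate, kd_err = kd$aggregate_error,
               dh = dh$aggregate, dh_err = dh$aggregate_error,
               dg = dg$aggregate, dg_err = dg$aggregate_error,
               neg_t_ds = ts$aggregate, neg_t_ds_err = ts$aggregate_error)
  }))

  report <- list(config = config,
                 package_version = as.character(utils::packageVersion("itcbridge")),
                 seed = spec$seed,
                 replicate_fits = fits,
                 aggregated = agg)
  if (!is.null(config$speciation)) {
    sc <- config$speciation
    lm <- ladder_model(sc$q, sc$kd_intra, sc$kd_bridge)
    st <- speciate(sc$total_trimer, sc$total_lc8_dimer, lm)
    mp <- mass_profile(st, config$masses %||% mass_table())
    report$speciation <- list(state = st, mass_profile = mp)
  }
  report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  class(report) <- "itcbridge_report"
  report
}

#' @export
print.itcbridge_report <- function(x, ...) {
  cat("itcbridge pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  %d replicate fit(s), model %s\n", length(x$replicate_fits),
              x$replicate_fits[[1]]$model_type))
  cat("  aggregated thermodynamics:\n")
  a <- x$aggregated
  for (i in seq_len(nrow(a)))
    cat(sprintf(
      "    %-12s Kd = %.3g uM, dH = %.3g, dG = %.3g, -TdS = %.3g kcal/mol\n",
      a$event[i], a$kd[i] * 1e6, a$dh[i], a$dg[i], a$neg_t_ds[i]))
  if (!is.null(x$speciation))
    cat(sprintf("  speciation: weight-average mass %.1f kDa\n",
                x$speciation$mass_profile$weight_average_mass))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Machine-readable form of a pipeline report (fits reduced to their
#' parameter/SE tables).  Two runs with identical configs serialize
#' identically apart from the timestamp.
#'
#' @param report An `itcbridge_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "itcbridge_report"))
  x <- list(package_version = report$package_version,
            seed = report$seed,
            timestamp = report$timestamp,
            aggregated = report$aggregated,
            replicates = lapply(report$replicate_fits, function(f)
              list(model = f$model_type, converged = f$converged,
                   residual_rms = f$residual_rms, events = f$events)))
  if (!is.null(report$speciation)) {
    x$speciation <- list(
      species = report$speciation$state$species,
      free_trimer = report$speciation$state$free_trimer,
      free_lc8 = report$speciation$state$free_lc8,
      weight_average_mass = report$speciation$mass_profile$weight_average_mass)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
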