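# CSV dialect: comma-separated UTF-8 with header
#   condition,replicate,time,time_unit,value,kind,dose
# time_unit in {s, min, h, day}; kind in {fraction, amount}; dose required
# (same unit as value) when kind = amount. Parsing is strict: malformed
# rows are errors with their row number, never silently skipped.

.time_unit_seconds <- c(s = 1, min = 60, h = 3600, day = 86400)

#' Read release curves from CSV
#'
#' Reads the package's release-table dialect (see Details) and returns the
#' curves grouped by condition. Times are converted to seconds internally;
#' amounts are normalised to fractions according to `normalization_mode`.
#'
#' @details Required columns: `condition`, `replicate`, `time`,
#' `time_unit` (one of s, min, h, day), `value`, `kind` (`fraction` or
#' `amount`) and `dose` (required when `kind = "amount"`). Each
#' (condition, replicate, time) triple must be unique, and `time_unit` and
#' `kind` must be uniform within a condition. Any malformed cell is an
#' error naming the offending data row.
#'
#' @param path CSV file path.
#' @param normalization_mode How amounts become fractions:
#'   `"final_observed"` divides by the final cumulative amount of the
#'   replicate (the model's M_inf definition); `"loaded_dose"` divides by
#'   the dose column.
#' @return Named list (by condition) of lists of [release_curve()] objects.
#' @seealso [write_release_csv()]
#' @export
read_release_csv <- function(path,
                             normalization_mode = c("final_observed",
                                                    "loaded_dose")) {
  normalization_mode <- match.arg(normalization_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  need <- c("condition", "replicate", "time", "time_unit", "value", "kind")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("no data rows in ", path)
  if (!("dose" %in% names(df))) df$dose <- ""

  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(trimws(x)) | !nzchar(trimws(x)))
    if (length(bad))
      stop(sprintf("non-numeric '%s' in data row %d: '%s'",
                   col, bad[1], x[bad[1]]))
    v
  }
  df$time_num <- num(df$time, "time")
  df$value_num <- num(df$value, "value")
  bad_unit <- which(!(df$time_unit %in% names(.time_unit_seconds)))
  if (length(bad_unit))
    stop(sprintf("unknown time unit in data row %d: '%s'",
                 bad_unit[1], df$time_unit[bad_unit[1]]))
  bad_kind <- which(!(df$kind %in% c("fraction", "amount")))
  if (length(bad_kind))
    stop(sprintf("unknown measurement kind in data row %d: '%s'",
                 bad_kind[1], df$kind[bad_kind[1]]))
  key <- paste(df$condition, df$replicate, df$time, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate (condition, replicate, time) in data row %d",
                 which(duplicated(key))[1]))

  out <- list()
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, , drop = FALSE]
    if (length(unique(sub$time_unit)) > 1L)
      stop(sprintf("condition '%s' mixes time units", cond))
    if (length(unique(sub$kind)) > 1L)
      stop(sprintf("condition '%s' mixes measurement kinds", cond))
    kind <- sub$kind[1]
    if (kind == "amount") {
      dose <- suppressWarnings(as.numeric(sub$dose))
      if (any(is.na(dose) | dose <= 0))
        stop(sprintf(
          "condition '%s': a positive dose is required for amount data",
          cond))
    }
    curves <- lapply(unique(sub$replicate), function(rep) {
      rs <- sub[sub$replicate == rep, , drop = FALSE]
      ord <- order(rs$time_num)
      rs <- rs[ord, , drop = FALSE]
      secs <- rs$time_num * .time_unit_seconds[[rs$time_unit[1]]]
      if (kind == "fraction") {
        frac <- rs$value_num
        mode <- normalization_mode
      } else if (normalization_mode == "loaded_dose") {
        frac <- rs$value_num / as.numeric(rs$dose)
        mode <- "loaded_dose"
      } else {
        last <- rs$value_num[length(rs$value_num)]
        if (last <= 0)
          stop(sprintf(
            "condition '%s' replicate '%s': final amount must be positive",
            cond, rep))
        frac <- rs$value_num / last
        mode <- "final_observed"
      }
      release_curve(secs, frac, replicate_id = rep,
                    normalization_mode = mode)
    })
    out[[cond]] <- curves
  }
  out
}

#' Write release curves to CSV
#'
#' Inverse of [read_release_csv()] for fraction data: writes one row per
#' observation in the package's release-table dialect.
#'
#' @param curves A single [release_curve()] or a list of them.
#' @param path Output CSV path.
#' @param condition Condition label for all curves.
#' @param time_unit Unit to express times in (`s`, `min`, `h`, `day`).
#' @return `path`, invisibly.
#' @export
write_release_csv <- function(curves, path, condition = "condition1",
                              time_unit = "s") {
  if (inherits(curves, "release_curve")) curves <- list(curves)
  stopifnot(time_unit %in% names(.time_unit_seconds))
  div <- .time_unit_seconds[[time_unit]]
  rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(condition = condition,
               replicate = cv$replicate_id,
               time = cv$times / div,
               time_unit = time_unit,
               value = cv$fractions,
               kind = "fraction",
               dose = "",
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fit settings from a YAML config file
#'
#' Recognised keys mirror the arguments of [fit_config()], plus `radius`
#' (m) and `normalization_mode`. Unknown keys are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return List with elements `config` (a [fit_config()]), `radius`, and
#'   `normalization_mode` (the latter two `NULL` when absent).
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c(names(formals(fit_config)), "radius", "normalization_mode")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg_args <- raw[intersect(names(raw), names(formals(fit_config)))]
  list(config = do.call(fit_config, cfg_args),
       radius = raw$radius,
       normalization_mode = raw$normalization_mode)
}

#' Fit every condition in a release CSV and write a report
#'
#' The programmatic core of the command-line `fit` subcommand: reads a
#' release table, fits each condition's replicates with
#' [fit_replicates()], and optionally writes a machine-readable JSON
#' report plus a human-readable text summary. The report header records
#' seed, bounds, model variant, radius and package version, so a report is
#' self-describing and reproducible.
#'
#' @param input Release CSV path.
#' @param radius Sphere radius, m (overrides any config value).
#' @param config A [fit_config()], a YAML path, or `NULL` for defaults.
#' @param seed Overrides the config seed when non-`NULL`.
#' @param out Output stem: writes `<out>.json` and `<out>.txt` when
#'   non-`NULL`.
#' @param quiet Suppress progress messages.
#' @return An object of class `fit_report` (invisibly): list with
#'   `header` and per-condition `results` ([fit_replicates()] summaries).
#' @export
run_fit_command <- function(input, radius = NULL, config = NULL,
                            seed = NULL, out = NULL, quiet = FALSE) {
  normalization_mode <- "final_observed"
  if (is.character(config)) {
    cf <- read_fit_config(config)
    if (is.null(radius)) radius <- cf$radius
    if (!is.null(cf$normalization_mode))
      normalization_mode <- cf$normalization_mode
    config <- cf$config
  }
  if (is.null(config)) config <- fit_config()
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(radius)) radius <- default_radius()

  conditions <- read_release_csv(input, normalization_mode)
  results <- list()
  failures <- character()
  for (cond in names(conditions)) {
    if (!quiet) message("fitting condition '", cond, "' (",
                        length(conditions[[cond]]), " replicate(s))")
    res <- tryCatch(
      fit_replicates(conditions[[cond]], radius = radius, config = config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cond, conditionMessage(res)))
    } else {
      results[[cond]] <- res
    }
  }
  if (length(failures))
    stop("unfittable condition(s):\n  ", paste(failures, collapse = "\n  "))

  header <- list(
    package = "microrelease",
    version = as.character(utils::packageVersion("microrelease")),
    input = input,
    radius_m = radius,
    seed = config$seed,
    model_variant = config$model_variant,
    log10_d_eff_bounds = config$log10_d_eff_bounds,
    log10_h_bounds = config$log10_h_bounds,
    normalization_mode = normalization_mode,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  report <- structure(list(header = header, results = results),
                      class = "fit_report")
  if (!is.null(out)) {
    json <- list(header = header,
                 results = lapply(results, function(r) list(
                   n_replicates = r$n_replicates,
                   excluded = r$excluded,
                   d_eff_mean = unname(r$d_eff["mean"]),
                   d_eff_sd = unname(r$d_eff["sd"]),
                   h_mean = unname(r$h["mean"]),
                   h_sd = unname(r$h["sd"]),
                   r_squared_mean = unname(r$r_squared["mean"]),
                   r_squared_sd = unname(r$r_squared["sd"]),
                   h_weak_fraction = r$h_weak_fraction)))
    jsonlite::write_json(json, paste0(out, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    txt <- utils::capture.output(print(report))
    writeLines(txt, paste0(out, ".txt"))
  }
  invisible(report)
}

#' @export
print.fit_report <- function(x, ...) {
  h <- x$header
  cat(sprintf("microrelease %s fit report\n", h$version))
  cat(sprintf("  input: %s   radius: %.4g m   seed: %d   variant: %s\n",
              h$input, h$radius_m, h$seed, h$model_variant))
  cat(sprintf("  bounds: log10 D_eff [%g, %g], log10 h [%g, %g]   norm: %s\n",
              h$log10_d_eff_bounds[1], h$log10_d_eff_bounds[2],
              h$log10_h_bounds[1], h$log10_h_bounds[2],
              h$normalization_mode))
  cat(sprintf("%-16s %-22s %-22s %-12s\n",
              "condition", "D_eff (m^2/s)", "h (m/s)", "R^2 (%)"))
  for (cond in names(x$results)) {
    r <- x$results[[cond]]
    pm <- function(v, d = 3) {
      if (is.na(v["sd"])) sprintf("%.*g", d, v["mean"])
      else sprintf("%.*g +/- %.2g", d, v["mean"], v["sd"])
    }
    cat(sprintf("%-16s %-22s %-22s %-12s\n", cond,
                pm(r$d_eff), pm(r$h), pm(r$r_squared, 4)))
  }
  invisible(x)
}
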