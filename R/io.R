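# Plain-text serialization: traces, observables tables, model configs.
# Every output file embeds the seed (when known) and a short config hash so
# that a result can be traced back to the exact inputs that produced it.

# Polynomial rolling hash over the serialized object (mod 2^31 - 1, so the
# arithmetic stays exact in doubles); provenance tagging, not cryptography.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write / read a current trace
#'
#' Two-column delimited text (`time_s`, `current`), UTF-8, one header line,
#' preceded by `#`-comment provenance lines (config hash, seed, application
#' window, channel count).
#'
#' @param trace A `current_trace`.
#' @param path File path.
#' @param sidecar If `TRUE` and the trace carries a `"ground_truth"`
#'   attribute (synthetic traces do), a structured-text record of the
#'   generating truth and recording config is written next to the trace as
#'   `<path>.truth.json`.
#' @return `write_trace()`: the path, invisibly. `read_trace()`: a
#'   `current_trace`.
#' @export
write_trace <- function(trace, path, sidecar = FALSE) {
  stopifnot(inherits(trace, "current_trace"))
  cfg <- attr(trace, "config")
  seed <- if (!is.null(cfg)) cfg$seed else NA
  app <- attr(trace, "application")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gabadesens trace; config_hash=%s; seed=%s",
            config_hash(list(cfg, attr(trace, "n_channels"),
                             attr(trace, "unitary_current"))),
            as.character(seed)),
    sprintf("# application_s=%g,%g; n_channels=%s; unitary_current=%s",
            app[1], app[2], attr(trace, "n_channels"),
            attr(trace, "unitary_current")),
    "time_s\tcurrent"), con)
  utils::write.table(data.frame(time_s = trace$time,
                                current = trace$current),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  gt <- attr(trace, "ground_truth")
  if (isTRUE(sidecar) && !is.null(gt)) {
    gt_rec <- lapply(gt, function(x) {
      if (inherits(x, "rate_parameters") ||
          inherits(x, "mutation_profile")) unclass(x) else x
    })
    jsonlite::write_json(
      list(ground_truth = gt_rec,
           config = unclass(cfg),
           config_hash = config_hash(list(cfg, gt_rec))),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^#", lines, value = TRUE)
  app <- c(NA_real_, NA_real_)
  n_channels <- NA; unitary <- NA
  m <- regmatches(meta, regexec(
    "application_s=([0-9.eE+-]+),([0-9.eE+-]+); n_channels=([^;]+); unitary_current=(.*)$",
    meta))
  for (g in m) {
    if (length(g) == 5) {
      app <- as.numeric(g[2:3])
      n_channels <- suppressWarnings(as.numeric(g[4]))
      unitary <- suppressWarnings(as.numeric(g[5]))
    }
  }
  d <- utils::read.delim(path, comment.char = "#", header = TRUE)
  if (!all(c("time_s", "current") %in% names(d))) {
    stop("not a trace file (need time_s and current columns): ", path,
         call. = FALSE)
  }
  new_current_trace(d$time_s, d$current, n_channels = n_channels,
                    unitary_current = unitary,
                    application = if (all(is.finite(app))) app else NULL)
}

#' Write an observables table
#'
#' One delimited row per construct: `construct`, `tau_fast_s`, `tau_slow_s`,
#' `pct_A_fast`, `pct_I_res`, `tau_w_s`.
#'
#' @param observables Named list of `desens_observables` (names = construct
#'   labels) or a data frame already in the output layout.
#' @param path File path.
#' @param seed Optional seed recorded in the provenance comment.
#' @return The path, invisibly.
#' @export
write_observables <- function(observables, path, seed = NA) {
  if (!is.data.frame(observables)) {
    observables <- do.call(rbind, lapply(names(observables), function(cc) {
      o <- observables[[cc]]
      data.frame(construct = cc, tau_fast_s = o$tau_fast,
                 tau_slow_s = o$tau_slow, pct_A_fast = o$pct_A_fast,
                 pct_I_res = o$pct_I_res, tau_w_s = o$tau_w,
                 stringsAsFactors = FALSE)
    }))
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gabadesens observables; config_hash=%s; seed=%s",
                     config_hash(observables), as.character(seed)), con)
  suppressWarnings(utils::write.table(observables, con, sep = "\t",
                                      row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Write / read a model definition config
#'
#' Round-trippable YAML description of a scheme build: variant, rate
#' parameters, mutation profile and agonist concentration.
#'
#' @param variant,params,profile,agonist_conc As for [build_scheme()].
#' @param path File path.
#' @return `write_model_config()`: the path, invisibly.
#'   `read_model_config()`: list with `variant`, `params`, `profile`,
#'   `agonist_conc` ready to splice into [build_scheme()].
#' @export
write_model_config <- function(variant, params, profile = mutation_profile(),
                               agonist_conc = 0.01, path) {
  cfg <- list(
    variant = variant,
    agonist_conc = agonist_conc,
    rate_parameters = unclass(params),
    mutation_profile = list(
      mutated = as.list(profile$mutated),
      multipliers = unclass(profile)[c("c3_plus", "c3_minus", "c4_plus",
                                       "c4_minus", "c5_plus", "c5_minus",
                                       "c34_plus", "c34_minus")],
      concerted_factors = lapply(profile$concerted_factors, as.list)))
  cfg$config_hash <- config_hash(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- do.call(rate_parameters, cfg$rate_parameters)
  mp <- cfg$mutation_profile
  prof <- do.call(mutation_profile, c(
    list(mutated = unlist(mp$mutated) %||% character()),
    mp$multipliers,
    list(concerted_factors = lapply(mp$concerted_factors, unlist))))
  list(variant = cfg$variant, params = p, profile = prof,
       agonist_conc = cfg$agonist_conc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calibration / comparison report
#'
#' Structured-text (JSON) dump of parameters, losses and per-construct
#' predictions, with the config hash and seed embedded.
#'
#' @param report A list (e.g. assembled around [calibrate_wt()] /
#'   [model_comparison_report()] outputs).
#' @param path File path.
#' @param seed Optional seed to record.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, seed = NA) {
  report$provenance <- list(config_hash = config_hash(report),
                            seed = seed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
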