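# Configuration files, table output, provenance, and example fixtures.
#
# Configs are YAML with a versioned schema.  Every rate field carries
# explicit units which are validated at the boundary (the model mixes
# per-volume and per-concentration conventions, so silent unit mistakes
# are the main user hazard); unknown keys are rejected with the offending
# field path.  Outputs are delimited tables (TSV by default) with 12
# significant digits and no timestamps, so a fixed config + seed gives
# byte-identical files.

CONFIG_SCHEMA_VERSION <- 1L

COMMANDS <- c("stationary", "moments", "ode", "bifurcation", "deviation",
              "surface", "ssa", "validate")

# expected units per rate field
UNIT_MAP <- c(alpha = "uM/ms", alpha0 = "uM/ms", alpha1 = "uM/ms",
              kappa = "uM", k_plus = "uM^-2 ms^-1", k_minus = "ms^-1",
              gamma_plus = "ms^-1", gamma_minus = "ms^-1",
              delta_plus = "ms^-1", delta_minus = "ms^-1",
              v = "L", beta = "ms^-1", c_inf = "uM")

config_error <- function(path, msg) {
  stop(sprintf("config field `%s`: %s", path, msg), call. = FALSE)
}

check_keys <- function(block, allowed, path) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    config_error(paste0(path, ".", extra[1]), "unknown key")
}

# a rate entry is {value: <num>, units: "<exact unit string>"}
get_rate <- function(block, name, path, required = TRUE) {
  entry <- block[[name]]
  fp <- paste0(path, ".", name)
  if (is.null(entry)) {
    if (required) config_error(fp, "missing")
    return(NULL)
  }
  if (!is.list(entry) || !all(c("value", "units") %in% names(entry)))
    config_error(fp, "must be a {value, units} pair")
  check_keys(entry, c("value", "units"), fp)
  if (!is.numeric(entry$value) || length(entry$value) != 1 ||
      !is.finite(entry$value))
    config_error(paste0(fp, ".value"), "must be a finite number")
  expect <- UNIT_MAP[[name]]
  if (!identical(entry$units, expect))
    config_error(paste0(fp, ".units"),
                 sprintf("must be \"%s\" (got \"%s\")", expect,
                         as.character(entry$units)))
  entry$value
}

#' Read, validate and write run configurations
#'
#' `read_run_config()` parses a YAML run configuration and validates it;
#' `validate_run_config()` checks an in-memory list and returns the
#' resolved configuration (scheme, parameters, numerics); and
#' `write_run_config()` serializes a configuration list back to YAML so
#' that configs round-trip losslessly.
#'
#' @param path File path of the YAML configuration.
#' @param config A configuration list (as returned by [yaml::read_yaml()]
#'   or built in code).
#' @return `read_run_config()`/`validate_run_config()`: an object of
#'   class `"run_config"` with fields `command`, `scheme`, `params`,
#'   `numerics`, `scan`, `ssa`, `output` and `raw` (the input list).
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  if (inherits(config, "run_config")) config <- config$raw
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("configuration must be a list")
  check_keys(config, c("schema_version", "command", "model", "environment",
                       "numerics", "scan", "ssa", "output"), "<top>")
  if (is.null(config$schema_version) ||
      config$schema_version != CONFIG_SCHEMA_VERSION)
    config_error("schema_version",
                 sprintf("must be %d", CONFIG_SCHEMA_VERSION))
  if (is.null(config$command) || !config$command %in% COMMANDS)
    config_error("command",
                 paste("must be one of:", paste(COMMANDS, collapse = ", ")))

  # environment -> subspace_params
  env <- config$environment
  if (is.null(env)) config_error("environment", "missing")
  check_keys(env, c("v", "beta", "c_inf"), "environment")
  params <- subspace_params(v = get_rate(env, "v", "environment"),
                            beta = get_rate(env, "beta", "environment"),
                            c_inf = get_rate(env, "c_inf", "environment"))

  # model -> channel_scheme
  mdl <- config$model
  if (is.null(mdl)) config_error("model", "missing")
  check_keys(mdl, c("kind", "variant", "rates", "b_t"), "model")
  if (is.null(mdl$kind) ||
      !mdl$kind %in% c("unregulated", "single_regulated", "multi_channel",
                       "calmodulin"))
    config_error("model.kind", "unknown scheme kind")
  rates <- mdl$rates
  if (is.null(rates)) config_error("model.rates", "missing")
  rate_names <- c("alpha", "alpha0", "alpha1", "kappa", "k_plus", "k_minus",
                  "gamma_plus", "gamma_minus", "delta_plus", "delta_minus")
  check_keys(rates, rate_names, "model.rates")
  rv <- list()
  for (nm in rate_names)
    rv[[nm]] <- get_rate(rates, nm, "model.rates", required = FALSE)
  scheme <- do.call(make_scheme, c(
    list(kind = mdl$kind),
    if (!is.null(mdl$variant)) list(variant = mdl$variant),
    if (!is.null(mdl$b_t)) list(b_t = mdl$b_t),
    rv))

  # numerics
  num <- config$numerics
  if (is.null(num)) num <- list()
  check_keys(num, c("n_max", "tail_tol", "ref_multiplier", "seed"),
             "numerics")
  numerics <- list(
    n_max = if (is.null(num$n_max)) "auto" else num$n_max,
    tail_tol = if (is.null(num$tail_tol)) 1e-10 else num$tail_tol,
    ref_multiplier = if (is.null(num$ref_multiplier)) 10L
                     else as.integer(num$ref_multiplier),
    seed = if (is.null(num$seed)) 1L else as.integer(num$seed))

  # command-specific blocks
  scan <- config$scan
  if (!is.null(scan))
    check_keys(scan, c("mode", "v0_grid", "c_star_grid", "c_star",
                       "c_star_grid_n", "kappa_grid"), "scan")
  ssa <- config$ssa
  if (!is.null(ssa))
    check_keys(ssa, c("t_end", "burn_in", "max_events", "n_batches"), "ssa")
  out <- config$output
  if (!is.null(out)) check_keys(out, c("format", "prefix"), "output")
  fmt <- if (is.null(out$format)) "tsv" else out$format
  if (!fmt %in% c("tsv", "csv")) config_error("output.format",
                                              "must be tsv or csv")

  structure(list(command = config$command, scheme = scheme,
                 params = params, numerics = numerics, scan = scan,
                 ssa = ssa,
                 output = list(format = fmt,
                               prefix = if (is.null(out$prefix))
                                 config$command else out$prefix),
                 raw = config),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run configuration: command `%s`, scheme `%s`\n",
              x$command, x$scheme$kind))
  invisible(x)
}

format_cell <- function(x) {
  if (is.numeric(x)) sprintf("%.12g", x) else as.character(x)
}

write_delim_table <- function(df, path, format = "tsv") {
  sep <- if (format == "csv") "," else "\t"
  out <- vapply(df, function(col) vapply(col, format_cell, character(1)),
                character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1,
                                    dimnames = list(NULL, names(df)))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  invisible(path)
}

provenance_record <- function(cfg, certificates = list()) {
  list(package = "dyadCME",
       package_version = as.character(utils::packageVersion("dyadCME")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       schema_version = CONFIG_SCHEMA_VERSION,
       seed = cfg$numerics$seed,
       resolved_config = cfg$raw,
       certificates = certificates)
}

#' Execute a run configuration
#'
#' Dispatches on `config$command`, writes the requested delimited tables
#' plus a machine-readable provenance record (resolved configuration,
#' package and R versions, seed, truncation certificates) into `out_dir`,
#' and returns the result object invisibly.  The `ok` field of the return
#' value is `TRUE` iff all convergence certificates passed; the command-
#' line wrapper maps it to the exit status.
#'
#' @param config A `"run_config"` from [read_run_config()].
#' @param out_dir Writable output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `ok`, `files` (paths written), and the
#'   command-specific `result` object.
#' @export
run_config <- function(config, out_dir = ".", quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt <- config$output$format
  prefix <- file.path(out_dir, config$output$prefix)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- character(0)
  certificates <- list()
  ok <- TRUE
  result <- NULL
  num <- config$numerics
  scheme <- config$scheme
  params <- config$params
  cmd <- config$command

  emit <- function(df, suffix) {
    path <- sprintf("%s_%s.%s", prefix, suffix, fmt)
    write_delim_table(df, path, fmt)
    files <<- c(files, path)
    path
  }

  if (cmd %in% c("stationary", "moments")) {
    sdist <- solve_cme(scheme, params, n_max = num$n_max,
                       tail_tol = num$tail_tol)
    ms <- summarize_moments(sdist)
    certificates <- list(n_max = sdist$space$n_max,
                         tail_mass = sdist$tail_mass,
                         residual = sdist$residual)
    if (cmd == "stationary") emit(as.data.frame(sdist), "distribution")
    emit(as.data.frame(ms), "moments")
    say("E[C] = %.6g uM, p_open = %.4g (n_max = %d, tail %.2g)",
        ms$E_C, ms$p_open, sdist$space$n_max, sdist$tail_mass)
    result <- ms
  } else if (cmd == "ode") {
    kind <- if (identical(scheme$variant, "inactivated")) "inactivated"
            else "activated"
    eq <- ode_steady_states(kind,
                            alpha0 = scheme$alpha[1],
                            alpha1 = scheme$alpha[length(scheme$alpha)],
                            beta = params$beta, c_inf = params$c_inf,
                            kappa = scheme$kappa)
    emit(cbind(data.frame(kappa_uM = scheme$kappa), eq$equilibria,
               classification = eq$classification), "equilibria")
    result <- eq
  } else if (cmd == "bifurcation") {
    kg <- config$scan$kappa_grid
    if (is.null(kg)) config_error("scan.kappa_grid",
                                  "required for the bifurcation command")
    kind <- if (identical(scheme$variant, "inactivated")) "inactivated"
            else "activated"
    bt <- bifurcation_scan(kind, kappa_grid = as.numeric(kg),
                           alpha0 = scheme$alpha[1],
                           alpha1 = scheme$alpha[length(scheme$alpha)],
                           beta = params$beta, c_inf = params$c_inf)
    emit(bt[, c("kappa_uM", "c_uM", "stability")], "bifurcation")
    iv <- attr(bt, "bistable_interval")
    say("bistable kappa interval: %s",
        if (is.null(iv)) "none" else sprintf("[%g, %g] uM", iv[1], iv[2]))
    result <- bt
  } else if (cmd %in% c("deviation", "surface")) {
    sc <- config$scan
    if (is.null(sc$mode)) config_error("scan.mode",
                                       "required (single_channel or multi_channel)")
    kind <- if (identical(scheme$variant, "inactivated")) "inactivated"
            else "activated"
    if (cmd == "deviation") {
      if (is.null(sc$c_star)) config_error("scan.c_star", "required")
      res <- small_system_deviation(
        kind, v0 = params$v, c_star = sc$c_star, kappa = scheme$kappa,
        k_plus = scheme$k_plus, mode = sc$mode, beta = params$beta,
        c_inf = params$c_inf, ref_multiplier = num$ref_multiplier,
        tail_tol = num$tail_tol)
      emit(data.frame(v0_liters = params$v, c_star_uM = sc$c_star,
                      delta_percent = res$delta_percent,
                      e_c_small_uM = res$E_C_small,
                      e_c_large_uM = res$E_C_large,
                      tail_mass_small = res$tail_mass_small,
                      tail_mass_large = res$tail_mass_large), "deviation")
      certificates <- list(tail_mass_small = res$tail_mass_small,
                           tail_mass_large = res$tail_mass_large)
      say("Delta = %.2f%%", res$delta_percent)
      result <- res
    } else {
      surf <- deviation_surface(
        kind, mode = sc$mode,
        v0_grid = if (is.null(sc$v0_grid))
          10^seq(-17, -15, length.out = 5) else as.numeric(sc$v0_grid),
        c_star_grid = if (is.null(sc$c_star_grid))
          seq(1, 20, length.out = 5) else as.numeric(sc$c_star_grid),
        kappa = scheme$kappa, k_plus = scheme$k_plus, beta = params$beta,
        c_inf = params$c_inf, ref_multiplier = num$ref_multiplier,
        tail_tol = num$tail_tol)
      emit(surf$table, "surface")
      ok <- ok && !any(surf$table$failed)
      say("max suppression %.1f%%", surf$max_suppression_percent)
      result <- surf
    }
  } else if (cmd %in% c("ssa", "validate")) {
    sb <- config$ssa
    if (is.null(sb$t_end)) config_error("ssa.t_end", "required")
    cfg <- ssa_config(scheme, params, t_end = sb$t_end,
                      burn_in = if (is.null(sb$burn_in)) 0 else sb$burn_in,
                      seed = num$seed,
                      max_events = if (is.null(sb$max_events)) 1e8
                                   else sb$max_events,
                      n_batches = if (is.null(sb$n_batches)) 20L
                                  else sb$n_batches)
    sim <- ssa_simulate(cfg)
    ok <- ok && !sim$truncated
    emit(as.data.frame(sim), "ssa")
    result <- sim
    if (cmd == "validate") {
      sdist <- solve_cme(scheme, params, n_max = num$n_max,
                         tail_tol = num$tail_tol)
      cmp <- compare_to_cme(sim, sdist)
      certificates <- list(n_max = sdist$space$n_max,
                           tail_mass = sdist$tail_mass,
                           residual = sdist$residual)
      emit(data.frame(z_E_count = cmp$z_E_count,
                      max_abs_z_state = max(abs(cmp$z_state)),
                      tv_distance = cmp$tv_distance, pass = cmp$pass),
           "validate")
      ok <- ok && cmp$pass
      say("CME-vs-SSA: %s (|z| max %.2f, TV %.3g)",
          if (cmp$pass) "pass" else "FAIL",
          max(abs(c(cmp$z_E_count, cmp$z_state))), cmp$tv_distance)
      result <- cmp
    }
  }

  prov_path <- sprintf("%s_provenance.json", prefix)
  jsonlite::write_json(provenance_record(config, certificates), prov_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, prov_path)
  invisible(list(ok = ok, files = files, result = result))
}

rate_entry <- function(name, value) {
  list(value = value, units = unname(UNIT_MAP[[name]]))
}

base_environment_block <- function(v = 1e-17, beta = 0.01, c_inf = 0.1) {
  list(v = rate_entry("v", v), beta = rate_entry("beta", beta),
       c_inf = rate_entry("c_inf", c_inf))
}

#' Write ready-to-run example configurations
#'
#' Emits a set of validated YAML configs covering the canonical study
#' conditions: the unregulated subspace, the single calcium-activated
#' channel at its reference parameters, single-channel deviation sweeps
#' (activated and inactivated), monostable and bistable multi-channel
#' volume series, multi-channel deviation surfaces, and a calmodulin
#' template whose rate values are left blank for user parameters.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  put <- function(name, cfg) {
    p <- file.path(dir, paste0(name, ".yaml"))
    yaml::write_yaml(cfg, p)
    paths <<- c(paths, p)
  }
  base <- function(command, model, ...)
    c(list(schema_version = CONFIG_SCHEMA_VERSION, command = command,
           model = model, environment = base_environment_block()),
      list(...))

  put("unregulated_basic", base(
    "stationary",
    list(kind = "unregulated",
         rates = list(alpha = rate_entry("alpha", 0.049)))))

  act_model <- list(kind = "single_regulated", variant = "activated",
                    rates = list(alpha1 = rate_entry("alpha1", 0.049),
                                 kappa = rate_entry("kappa", 2),
                                 k_plus = rate_entry("k_plus", 0.05)))
  put("single_activated", base("stationary", act_model))

  sweep_act <- base(
    "surface",
    list(kind = "single_regulated", variant = "activated",
         rates = list(alpha1 = rate_entry("alpha1", 0.049),
                      kappa = rate_entry("kappa", 2),
                      k_plus = rate_entry("k_plus", 0.005))),
    scan = list(mode = "single_channel"))
  put("single_activated_sweep", sweep_act)

  put("single_inactivated_sweep", base(
    "surface",
    list(kind = "single_regulated", variant = "inactivated",
         rates = list(alpha0 = rate_entry("alpha0", 0.049),
                      kappa = rate_entry("kappa", 0.63),
                      k_plus = rate_entry("k_plus", 0.05))),
    scan = list(mode = "single_channel")))

  put("multi_monostable", base(
    "stationary",
    list(kind = "multi_channel", variant = "activated", b_t = 4L,
         rates = list(alpha1 = rate_entry("alpha1", 0.049),
                      kappa = rate_entry("kappa", 0.45),
                      k_plus = rate_entry("k_plus", 5e-4)))))

  put("multi_bistable", base(
    "stationary",
    list(kind = "multi_channel", variant = "activated", b_t = 4L,
         rates = list(alpha1 = rate_entry("alpha1", 0.049),
                      kappa = rate_entry("kappa", 2),
                      k_plus = rate_entry("k_plus", 0.005)))))

  put("multi_inactivated", base(
    "stationary",
    list(kind = "multi_channel", variant = "inactivated", b_t = 4L,
         rates = list(alpha0 = rate_entry("alpha0", 0.049),
                      kappa = rate_entry("kappa", 0.63),
                      k_plus = rate_entry("k_plus", 0.005)))))

  put("surface_activated", base(
    "surface",
    list(kind = "multi_channel", variant = "activated",
         rates = list(alpha1 = rate_entry("alpha1", 0.049),
                      kappa = rate_entry("kappa", 0.45),
                      k_plus = rate_entry("k_plus", 0.005))),
    scan = list(mode = "multi_channel")))

  put("surface_inactivated", base(
    "surface",
    list(kind = "multi_channel", variant = "inactivated",
         rates = list(alpha0 = rate_entry("alpha0", 0.049),
                      kappa = rate_entry("kappa", 0.63),
                      k_plus = rate_entry("k_plus", 0.05))),
    scan = list(mode = "multi_channel")))

  # calmodulin scheme template: the lobe-specific rate values are user
  # parameters (they come from the channel-regulation literature, not
  # from this package); the zeros below are placeholders to replace.
  cal <- base(
    "stationary",
    list(kind = "calmodulin", variant = "activated",
         rates = list(alpha0 = rate_entry("alpha0", 0),
                      alpha1 = rate_entry("alpha1", 0.049),
                      kappa = rate_entry("kappa", 0),
                      k_plus = rate_entry("k_plus", 0),
                      gamma_plus = rate_entry("gamma_plus", 0),
                      gamma_minus = rate_entry("gamma_minus", 0),
                      delta_plus = rate_entry("delta_plus", 0),
                      delta_minus = rate_entry("delta_minus", 0))))
  put("calmodulin_template", cal)

  invisible(paths)
}
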