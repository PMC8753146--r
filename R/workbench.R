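#' Load and validate a run configuration
#'
#' Reads a JSON or YAML configuration (chosen by file extension), checks it
#' against the schema of its subcommand, fails fast on unknown keys, and
#' fills documented defaults. Every validation failure names the offending
#' key and the violated constraint.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return Object of class \code{"run_config"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # YAML 1.1 would read the key "n" as a boolean; keep y/n/yes/no literal
    # and accept only true/false as booleans
    keep_literal <- function(x)
      if (tolower(x) %in% c("true", "false")) tolower(x) == "true" else x
    yaml::read_yaml(path, handlers = list("bool#yes" = keep_literal,
                                          "bool#no" = keep_literal))
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_config(cfg)
}

config_commands <- function() {
  c("simulate-abm", "meanfield-phase", "macro-run", "indices-ensemble",
    "fit-changepoint", "fit-pcr", "gen-synthetic")
}

#' @rdname load_config
#' @param cfg A configuration list (as parsed from JSON/YAML).
#' @export
validate_config <- function(cfg) {
  if (is.null(cfg$command))
    stop("config key 'command' is required (one of ",
         paste(config_commands(), collapse = ", "), ")")
  if (!cfg$command %in% config_commands())
    stop("unknown command '", cfg$command, "'; must be one of ",
         paste(config_commands(), collapse = ", "))
  top_allowed <- c("command", "seed", "out_dir", "log_level", "params")
  unknown <- setdiff(names(cfg), top_allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(top_allowed, collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("'seed' must be an integer, got ", cfg$seed)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  if (!cfg$log_level %in% c("quiet", "info", "debug"))
    stop("'log_level' must be one of quiet, info, debug")
  if (is.null(cfg$params)) cfg$params <- list()
  check_probability <- function(key) {
    v <- cfg$params[[key]]
    if (!is.null(v) && (!is.numeric(v) || any(v < 0) || any(v > 1)))
      stop("'", key, "' must lie in [0,1], got ", paste(v, collapse = ", "))
  }
  for (key in c("p", "r", "pa", "pv", "f0", "p_star", "r_star", "f",
                "epsilon", "zeta_a", "zeta_v"))
    check_probability(key)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run config: command =", x$command, ", seed =", x$seed,
      ", out_dir =", x$out_dir, "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname load_config
#' @param file Destination path (JSON or YAML by extension).
#' @export
write_config <- function(cfg, file) {
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE))
    yaml::write_yaml(x, file)
  else jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(file)
}

# degree-distribution sub-config: {type: delta|poisson|table, ...}
parse_degree_config <- function(dc) {
  if (is.null(dc)) return(degree_distribution(c(2, 10), c(0.2, 0.8)))
  if (inherits(dc, "degree_distribution")) return(dc)
  if (!is.null(dc$type)) {
    if (dc$type == "delta") return(delta_degree(dc$k))
    if (dc$type == "poisson") return(poisson_degree(dc$mean))
  }
  if (!is.null(dc$support)) return(degree_distribution(dc$support, dc$mass))
  stop("degree distribution config needs 'type' (delta/poisson) or ",
       "'support'/'mass'")
}

wb_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[demotip] ", ...)
}

#' Execute a configured run
#'
#' Dispatches a validated configuration to the corresponding analysis,
#' writes its CSV/JSON artifacts into \code{out_dir}, and records a
#' \code{manifest.json} (config copy, seed, package and R versions, input
#' checksums, output list, wall time) so that any artifact can be
#' regenerated from its manifest alone.
#'
#' @param config A \code{run_config} (or path to one).
#' @return Invisibly, the manifest list; on error the condition propagates
#'   (the command-line wrapper converts it to a nonzero exit status).
#' @export
run_command <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pr <- config$params
  outputs <- character(0)
  inputs <- character(0)
  emit_csv <- function(df, name) {
    fp <- file.path(config$out_dir, name)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     fp, row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, fp)
    fp
  }
  emit_json <- function(x, name) {
    fp <- file.path(config$out_dir, name)
    jsonlite::write_json(x, fp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, fp)
    fp
  }

  switch(config$command,
    "simulate-abm" = {
      sp <- do.call(society_params,
                    pr[intersect(names(pr), names(formals(society_params)))])
      horizon <- if (is.null(pr$horizon)) 100L else as.integer(pr$horizon)
      traj <- run_abm(sp, horizon, config$seed)
      emit_csv(as.data.frame(traj), "trajectory.csv")
      g <- attr(traj, "graph")
      fp <- file.path(config$out_dir, "edges.txt")
      utils::write.table(g$edges, fp, row.names = FALSE, col.names = FALSE)
      outputs <- c(outputs, fp)
      wb_log(config, "ABM run: ", horizon, " steps, final z = ",
             round(traj$z[nrow(traj)], 4))
    },
    "meanfield-phase" = {
      dd <- parse_degree_config(pr$degree)
      grid <- phase_diagram(pr$p_star_grid, pr$r_star_grid, pr$f, pr$mu, dd,
                            convention = pr$convention %||% "printed")
      emit_csv(grid, "phase_diagram.csv")
      wb_log(config, "phase diagram: ", nrow(grid), " grid points")
    },
    "macro-run" = {
      dd <- parse_degree_config(pr$degree)
      mp <- pr
      mp$degree_dist <- dd
      traj <- run_macro(list(f = pr$f0 %||% 0.1, p = pr$p %||% 0.005,
                             pa = pr$pa %||% 0, pv = pr$pv %||% 0.02),
                        mp, pr$horizon %||% 600)
      emit_csv(as.data.frame(traj), "macro_trajectory.csv")
      wb_log(config, "macro run: final z = ", round(traj$z[nrow(traj)], 4))
    },
    "indices-ensemble" = {
      dd <- parse_degree_config(pr$degree)
      shared <- pr[intersect(names(pr), c("tau1", "tau2", "T", "epsilon",
                                          "zeta_a", "zeta_v", "mu",
                                          "convention", "enthusiasm_form"))]
      shared$degree_dist <- dd
      ens <- simulate_ensemble(pr$n %||% 200, ranges = pr$ranges,
                               horizon = pr$horizon %||% 600,
                               seed = config$seed, params = shared)
      emit_csv(as.data.frame(ens), "index_ensemble.csv")
      wb_log(config, "ensemble: ", sum(ens$reformed), "/", nrow(ens),
             " societies reformed")
    },
    "fit-changepoint" = {
      inputs <- pr$input
      df <- utils::read.csv(pr$input)
      x <- df[[pr$x_col %||% "x"]]
      y <- df[[pr$y_col %||% "y"]]
      fit <- fit_piecewise(x, y, ci = pr$ci %||% "wald")
      emit_json(list(coefficients = as.list(coef(fit)),
                     ci95 = apply(fit$ci95, 1, as.list),
                     sigma2 = fit$sigma2, n = fit$n), "changepoint_fit.json")
      emit_csv(data.frame(term = names(coef(fit)), estimate = coef(fit),
                          lower = fit$ci95[, 1], upper = fit$ci95[, 2]),
               "changepoint_fit.csv")
      wb_log(config, "changepoint at ", round(coef(fit)["xc"], 3))
    },
    "fit-pcr" = {
      inputs <- pr$input
      df <- utils::read.csv(pr$input)
      preds <- pr$predictors %||%
        c("cpi", "democracy_index", "gdp_pc", "eu_member", "population")
      y <- df[[pr$y_col %||% "turnout_avg"]]
      keep <- stats::complete.cases(df[, preds]) & !is.na(y)
      if (sum(!keep)) wb_log(config, "listwise deletion: ", sum(!keep),
                             " incomplete rows dropped")
      fit <- pcr_select(df[keep, preds], y[keep])
      emit_json(list(selected_k = fit$selected_k,
                     adj_r2 = as.list(fit$adj_r2_profile),
                     beta = as.list(fit$beta)), "pcr_fit.json")
      wb_log(config, "PCR selected k = ", fit$selected_k)
    },
    "gen-synthetic" = {
      tab <- gen_synthetic_country_table(pr$n %||% 50, seed = config$seed)
      emit_csv(tab, pr$output %||% "synthetic_country_table.csv")
      wb_log(config, "synthetic country table: ", nrow(tab), " rows")
    })

  manifest <- list(
    command = config$command,
    seed = config$seed,
    config = unclass(config),
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    outputs = as.list(stats::setNames(tools::md5sum(outputs), outputs)),
    package_version = as.character(utils::packageVersion("demotip")),
    r_version = R.version.string,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
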