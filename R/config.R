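#' Run configurations: read, write, execute
#'
#' A run configuration bundles a scenario specification (one
#' `{family, center, spread}` block per fuzzy input) with the run
#' settings `grid_size`, `n_steps`, `mode`, `tolerance` and `seed`.
#' Configurations round-trip through JSON (always available) or YAML
#' (when the `yaml` package is installed), selected by file extension.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param config A run-configuration list (as from [default_run_config()]).
#' @return `read_run_config()` and `default_run_config()` return the
#'   configuration list; `write_run_config()` returns `path` invisibly.
#' @name run-config
NULL

#' @rdname run-config
#' @param scenario An [fbqp_scenario()] to encode (members must be
#'   parabolic or crisp).
#' @param n_steps,mode,tolerance,seed Run settings.
#' @export
default_run_config <- function(scenario = fbqp_example_scenario(),
                               n_steps = 100L, mode = "auto",
                               tolerance = 1e-6, seed = 1L) {
  spec <- lapply(scenario, function(m) {
    fam <- attr(m, "family")
    if (fam == "parabolic")
      list(family = "parabolic", center = attr(m, "center"),
           spread = attr(m, "spread"))
    else if (fam == "crisp")
      list(family = "crisp", center = attr(m, "center"))
    else stop("only parabolic/crisp members can be encoded in a config")
  })
  list(scenario = spec,
       grid_size = length(scenario$A$alpha),
       n_steps = as.integer(n_steps), mode = mode,
       tolerance = tolerance, seed = as.integer(seed))
}

#' @rdname run-config
#' @export
write_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required for YAML configs")
    yaml::write_yaml(config, path)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

#' @rdname run-config
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the `yaml` package is required for YAML configs")
    yaml::read_yaml(path)
  } else stop("unsupported config extension: ", ext)
}

# Rebuild the scenario encoded in a config.
config_scenario <- function(config) {
  grid <- alpha_grid(config$grid_size)
  mk <- function(sp) {
    if (sp$family == "parabolic")
      parabolic_fuzzy_number(sp$center, sp$spread, grid)
    else crisp_fuzzy_number(sp$center, grid)
  }
  fbqp_scenario(A = mk(config$scenario$A), B = mk(config$scenario$B),
                x_m2 = mk(config$scenario$x_m2),
                x_m1 = mk(config$scenario$x_m1),
                x_0 = mk(config$scenario$x_0))
}

# Small stable polynomial string hash for provenance headers (hex).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 17
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(config) {
  c(sprintf("# fbqpop config_hash=%s seed=%d grid=%d mode=%s",
            config_hash(config), config$seed, config$grid_size, config$mode))
}

#' Execute a run configuration and write its outputs
#'
#' Rebuilds the configured scenario, simulates it, and writes
#' `trajectory.csv` (long format, [as.data.frame.fbqp_trajectory()]) and
#' `equilibrium.csv` (columns `alpha`, `x_left`, `x_right`) into
#' `out_dir`, each preceded by a provenance comment header (config hash,
#' seed, grid size). Identical configurations produce byte-identical
#' outputs.
#'
#' @param config A run-configuration list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the trajectory, the equilibrium and the
#'   output paths.
#' @export
run_from_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- config_scenario(config)
  tr <- fbqp_simulate(sc, config$n_steps, mode = config$mode)
  eq <- if (identical(config$mode, "case2"))
    fuzzy_equilibrium_case2(sc$A, sc$B) else fuzzy_equilibrium_case1(sc$A, sc$B)
  hdr <- provenance_header(config)
  traj_path <- file.path(out_dir, "trajectory.csv")
  eq_path <- file.path(out_dir, "equilibrium.csv")
  write_csv_with_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_csv_with_header(as.data.frame(tr), traj_path)
  write_csv_with_header(
    data.frame(alpha = eq$value$alpha, x_left = eq$value$left,
               x_right = eq$value$right), eq_path)
  invisible(list(trajectory = tr, equilibrium = eq,
                 paths = c(trajectory = traj_path, equilibrium = eq_path)))
}
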