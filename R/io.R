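run_config_defaults <- function() {
  list(sites = site_archetypes(),
       fishing_levels = c("none", "moderate", "high"),
       bleaching_levels = c("none", "once-per-decade", "twice-per-decade"),
       water_levels = c("regulated", "unregulated"),
       n_replicates = 20L,
       horizon_years = 40L,
       master_seed = 1L,
       snapshot_years = c(5L, 10L, 20L, 40L),
       n_perm = 4999L,
       tolerance = 0,
       jitter = 0,
       output_dir = "reefcast-output",
       verbosity = 1L)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration and fills defaults for anything omitted:
#' 20 replicates, a 40-year horizon, snapshot years 5/10/20/40, 4999
#' permutations, the full 18-scenario factorial and all four site
#' archetypes. Unknown keys are rejected; invalid values raise distinct
#' diagnostics.
#'
#' @param path path to a YAML file (or a list already in memory).
#' @return A validated list of class `"run_config"`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    out <- tryCatch(yaml::read_yaml(path),
                    error = function(e) stop("config parse error: ",
                                             conditionMessage(e)))
    if (!is.list(out)) stop("config parse error: not a mapping")
    out
  }
  defaults <- run_config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]

  bad <- setdiff(cfg$sites, site_archetypes())
  if (length(bad))
    stop("invalid value: unknown site archetype(s) ",
         paste(bad, collapse = ", "))
  for (nm in c("n_replicates", "horizon_years", "master_seed", "n_perm")) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop("invalid value: ", nm, " must be a positive integer")
    cfg[[nm]] <- as.integer(v)
  }
  if (any(cfg$snapshot_years < 0) ||
      any(cfg$snapshot_years > cfg$horizon_years))
    stop("invalid value: snapshot_years must lie within the horizon")
  if (cfg$jitter < 0 || cfg$jitter > 0.5)
    stop("invalid value: jitter must be in [0, 0.5]")
  if (cfg$tolerance < 0) stop("invalid value: tolerance must be >= 0")
  cfg <- cfg[names(defaults)]
  class(cfg) <- "run_config"
  cfg
}

#' Write a run configuration to YAML
#'
#' Round-trips through [load_run_config()] to an equal configuration.
#'
#' @param config a `run_config` (or plain list accepted by
#'   [load_run_config()]).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(load_run_config(config))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write site parameters as flat key-value text
#'
#' One parameter per line in `name = value` form, with a comment header
#' giving the units convention. Round-trips bit-exactly through
#' [read_site_params()] (values printed at full precision).
#'
#' @param params a [site_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_params <- function(params, path) {
  validate_site_params(params)
  lines <- c("# reef site parameters; annual rates (yr-1),",
             "# grazing in m2 g-1 yr-1, recruitment fluxes in g m-2 yr-1")
  for (nm in names(params)) {
    v <- params[[nm]]
    lines <- c(lines, sprintf("%s = %s", nm,
                              if (is.logical(v)) as.character(v) else
                                format(v, digits = 17)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read site parameters from flat key-value text
#'
#' @param path file written by [write_site_params()].
#' @return A [site_params()] list.
#' @export
read_site_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2)) stop("malformed parameter line")
  vals <- lapply(kv, function(x)
    if (x[2] %in% c("TRUE", "FALSE")) as.logical(x[2]) else
      as.numeric(x[2]))
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(site_params, vals)
}

#' Write run outputs with a content-digest manifest
#'
#' Writes each element of `outputs` (data frames / matrices as
#' tab-separated text with headers) into `directory` under its element
#' name, then writes `MANIFEST.txt` listing every file with its MD5 content
#' digest. The layout is deterministic: identical outputs give identical
#' digests, and any single-byte corruption changes the digest.
#'
#' @param outputs named list of data frames or matrices (may be empty).
#' @param directory output directory (created if needed).
#' @return Data frame manifest (`file`, `md5`), invisibly.
#' @export
write_results <- function(outputs, directory) {
  if (length(outputs) && is.null(names(outputs)))
    stop("outputs must be named")
  ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("unwritable directory: ", directory)
  files <- character(0)
  for (nm in names(outputs)) {
    f <- file.path(directory, paste0(nm, ".tsv"))
    x <- outputs[[nm]]
    if (is.matrix(x)) x <- as.data.frame(x)
    write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(directory, "MANIFEST.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Verify a results directory against its manifest
#'
#' @param directory directory written by [write_results()].
#' @return Logical: `TRUE` if every listed file matches its digest;
#'   otherwise `FALSE` (with a warning naming mismatches).
#' @export
verify_results <- function(directory) {
  mf <- file.path(directory, "MANIFEST.txt")
  if (!file.exists(mf)) stop("no MANIFEST.txt in ", directory)
  manifest <- read.table(mf, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) return(TRUE)
  cur <- unname(tools::md5sum(file.path(directory, manifest$file)))
  bad <- manifest$file[is.na(cur) | cur != manifest$md5]
  if (length(bad)) {
    warning("digest mismatch: ", paste(bad, collapse = ", "))
    return(FALSE)
  }
  TRUE
}

#' Run the full pipeline from a configuration
#'
#' End-to-end driver: builds the scenario grid and site fixtures, runs the
#' Monte-Carlo ensembles, extracts snapshot community matrices, and writes
#' scenario grid, snapshot matrices and forcing audit tables (plus a
#' digest manifest) into the configured output directory. All randomness
#' flows from `master_seed`, so one configuration yields a byte-identical
#' output tree on rerun.
#'
#' @param config a `run_config`, list, or YAML path.
#' @param directory output directory (default from the config).
#' @return The manifest data frame, invisibly.
#' @export
run_pipeline <- function(config, directory = NULL) {
  cfg <- load_run_config(config)
  if (is.null(directory)) directory <- cfg$output_dir
  grid <- scenario_grid(cfg$fishing_levels, cfg$bleaching_levels,
                        cfg$water_levels)
  outputs <- list(scenario_grid = grid)
  for (site_lab in cfg$sites) {
    site <- make_site(site_lab, seed = cfg$master_seed, jitter = cfg$jitter)
    ens <- lapply(seq_len(nrow(grid)), function(i)
      run_ensemble(grid[i, ], site, n_replicates = cfg$n_replicates,
                   master_seed = cfg$master_seed,
                   horizon_years = cfg$horizon_years, scenario_index = i))
    audits <- do.call(rbind, lapply(seq_along(ens), function(i) {
      a <- forcing_audit(ens[[i]])
      cbind(scenario = grid$label[i], a, stringsAsFactors = FALSE)
    }))
    outputs[[paste0("forcings_", site_lab)]] <- audits
    for (y in cfg$snapshot_years) {
      cm <- snapshot_matrix(ens, y)
      outputs[[sprintf("snapshot_%s_year%02d", site_lab, y)]] <-
        as.data.frame(cm)
    }
  }
  write_results(outputs, directory)
}
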