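## Run configuration and file outputs ------------------------------------------

#' Assemble a run configuration
#'
#' A run configuration bundles everything needed to regenerate an analysis:
#' parameter profile (or overrides), heterogeneity specification, treatment
#' protocol fields, fate thresholds and bifurcation grids.  It serializes
#' losslessly to YAML.
#'
#' @param profile parameter profile name (see [fk_profile()]).
#' @param params named list of parameter overrides applied on top of the
#'   profile.
#' @param population named list overriding [heterogeneity_spec()] fields.
#' @param protocol named list of [fk_protocol()] fields.
#' @param death_threshold,activation_threshold fate thresholds; `NULL`
#'   means the profile values.
#' @param ciap_grid cIAP grid for threshold curves.
#' @param p53_range scanned p53 range.
#' @return A `fk_config` list.
#' @export
fk_config <- function(profile = "table1_basal", params = list(),
                      population = list(), protocol = list(),
                      death_threshold = NULL, activation_threshold = NULL,
                      ciap_grid = seq(0, 1, by = 0.1),
                      p53_range = c(0, 2)) {
  structure(list(profile = profile, params = params,
                 population = population, protocol = protocol,
                 death_threshold = death_threshold,
                 activation_threshold = activation_threshold,
                 ciap_grid = ciap_grid, p53_range = p53_range),
            class = "fk_config")
}

#' Read / write a run configuration
#'
#' @param path YAML file.
#' @return [read_run_config()] returns an `fk_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- fk_config()
  bad <- setdiff(names(y), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(y))
    if (!is.null(y[[nm]])) cfg[[nm]] <- y[[nm]]
  cfg
}

#' @rdname read_run_config
#' @param config an `fk_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}

## materialize the pieces of a config
.fk_config_realize <- function(cfg) {
  prof <- fk_profile(cfg$profile)
  p <- prof$params
  if (length(cfg$params)) p <- do.call(fk_params, c(cfg$params))
  spec <- do.call(heterogeneity_spec, cfg$population)
  proto <- do.call(fk_protocol, cfg$protocol)
  list(params = p, spec = spec, protocol = proto,
       death_threshold = cfg$death_threshold %||% prof$death_threshold,
       activation_threshold =
         cfg$activation_threshold %||% prof$activation_threshold,
       ciap_grid = cfg$ciap_grid, p53_range = cfg$p53_range)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## FNV-1a hash of the serialized config: stable, dependency-free tag that
## every output file carries so a result can be traced to its config
.fk_config_hash <- function(config) {
  bytes <- utf8ToInt(paste(yaml::as.yaml(unclass(config)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor on the low byte (b < 256), then multiply mod 2^32 in two
    ## 16-bit halves to stay within exact double arithmetic
    x <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    lo <- x %% 65536
    hi <- x %/% 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

## write a data.frame as CSV with a config-hash comment header
.fk_write_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory or population result to tidy CSV
#'
#' @param x an `fk_trajectory` or `fk_population`.
#' @param path output file.
#' @param cell_id id column value for a single trajectory.
#' @param config optional `fk_config` whose hash is stamped in the header.
#' @return `path`, invisibly.
#' @export
export_csv <- function(x, path, cell_id = 1L, config = NULL) {
  hash <- if (is.null(config)) "none" else .fk_config_hash(config)
  if (inherits(x, "fk_trajectory")) {
    df <- cbind(cell_id = cell_id, as.data.frame(x))
  } else if (inherits(x, "fk_population")) {
    df <- x$fates
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x)
  } else stop("cannot export objects of class ", class(x)[1L], call. = FALSE)
  .fk_write_csv(df, path, hash)
}
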