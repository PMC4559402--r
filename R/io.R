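TRAJ_FORMAT_VERSION <- 1L
TRAJ_COLS <- c("step", "pup", "x", "y", "theta", "tb", "eta")

#' Load a simulation configuration from YAML
#'
#' The file mirrors [sim_config()] field names one-to-one; unspecified
#' fields take the standard defaults, unknown keys are rejected, and values
#' are range-checked. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config must be a YAML mapping", call. = FALSE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vals$variant) &&
      !vals$variant %in% c("endothermic", "ectothermic",
                           "homeothermotaxic")) {
    stop("unknown variant '", vals$variant, "'; valid variants are ",
         "'endothermic', 'ectothermic', 'homeothermotaxic'", call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Write a configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a trajectory to CSV with a JSON sidecar
#'
#' The trajectory is written as a plain CSV (columns `step`, `pup`, `x`,
#' `y`, `theta`, `tb`, `eta`) headed by a single comment line recording the
#' format version and seed; the configuration, seed and package version go
#' to a JSON sidecar next to it (`<path>.json` with the `.csv` extension
#' replaced). The round trip is lossless to full double precision.
#'
#' @param sim A `"huddle_sim"` (or a trajectory tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  traj <- as_trajectory(sim)
  cfg <- if (inherits(sim, "huddle_sim")) sim$config else attr(traj, "config")
  seed <- if (inherits(sim, "huddle_sim")) sim$seed else NULL
  header <- sprintf("# huddlesim-trajectory v%d seed=%s",
                    TRAJ_FORMAT_VERSION,
                    if (is.null(seed)) "NA" else seed)
  readr::write_lines(header, path)
  readr::write_csv(traj[TRAJ_COLS], path, append = TRUE, col_names = TRUE)
  meta <- list(
    format = "huddlesim-trajectory",
    format_version = TRAJ_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("huddlesim")),
    seed = seed,
    config = if (!is.null(cfg)) unclass(cfg) else NULL
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the trajectory tibble and, when the JSON sidecar is present, the
#' configuration and seed. If the seed recorded in the CSV header disagrees
#' with the sidecar, a warning is issued and the sidecar wins.
#'
#' @param path CSV path.
#' @return A `"huddle_sim"` object (with `engine = "file"`).
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  first <- readr::read_lines(path, n_max = 1)
  if (!grepl("^# huddlesim-trajectory v", first)) {
    stop("malformed header: not a huddlesim trajectory file", call. = FALSE)
  }
  ver <- as.integer(sub("^# huddlesim-trajectory v(\\d+).*$", "\\1", first))
  if (is.na(ver) || ver > TRAJ_FORMAT_VERSION) {
    stop("trajectory format version mismatch (file v", ver, ", reader v",
         TRAJ_FORMAT_VERSION, ")", call. = FALSE)
  }
  header_seed <- suppressWarnings(
    as.integer(sub("^.*seed=([-0-9NA]+).*$", "\\1", first))
  )
  traj <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(TRAJ_COLS, names(traj))
  if (length(missing) > 0) {
    stop("trajectory format error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(traj[TRAJ_COLS])) {
    stop("trajectory format error: truncated or non-numeric rows",
         call. = FALSE)
  }

  cfg <- NULL
  seed <- header_seed
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$seed)) {
      if (!is.na(header_seed) && header_seed != meta$seed) {
        warning("seed mismatch between CSV header (", header_seed,
                ") and sidecar (", meta$seed, "); using the sidecar")
      }
      seed <- meta$seed
    }
    if (!is.null(meta$config)) {
      cfg <- do.call(sim_config, meta$config)
    }
  }
  traj <- tibble::as_tibble(traj)
  attr(traj, "config") <- cfg
  structure(list(trajectory = traj, config = cfg,
                 seed = if (is.na(seed)) NULL else seed,
                 engine = "file"),
            class = "huddle_sim")
}
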