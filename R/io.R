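#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' The trajectory is written in long format (one row per segment per
#' recorded step) as `<prefix>_trajectory.csv` with columns `time_hr`,
#' `segment_id` (0-based), `n`, `q_m3s`, `dp_Pa`, `tau_Pa`, plus
#' `<prefix>_probs.csv` for BR5 runs and `<prefix>_meta.json` describing
#' rule, alpha, seed, geometry, boundary conditions, duration and loss.
#'
#' @param trajectory A full-record `"ec_trajectory"`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default `"run"`).
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(trajectory, dir, prefix = "run") {
  stopifnot(inherits(trajectory, "ec_trajectory"))
  if (is.null(trajectory$n))
    stop("trajectory was not recorded in full", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_seg <- ncol(trajectory$n)
  long <- data.frame(
    time_hr = rep(trajectory$time_hr, each = n_seg),
    segment_id = rep(seq_len(n_seg) - 1L, length(trajectory$time_hr)),
    n = as.vector(t(trajectory$n)),
    q_m3s = as.vector(t(trajectory$q)),
    dp_Pa = as.vector(t(trajectory$dp)),
    tau_Pa = as.vector(t(trajectory$tau)))
  paths <- file.path(dir, paste0(prefix, "_trajectory.csv"))
  utils::write.csv(long, paths, row.names = FALSE)
  if (!is.null(trajectory$probs)) {
    p <- file.path(dir, paste0(prefix, "_probs.csv"))
    utils::write.csv(trajectory$probs, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- trajectory$meta
  meta$loss <- unclass(trajectory$loss)
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(paths, mp))
}

#' Write a sweep summary to CSV with a JSON sidecar
#'
#' @param sweep A `"sweep_result"`.
#' @param dir Output directory.
#' @param prefix File name prefix (default `"sweep"`).
#' @return Invisibly, the paths written.
#' @export
write_sweep <- function(sweep, dir, prefix = "sweep") {
  stopifnot(inherits(sweep, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(as.data.frame(sweep), p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_surface.csv"))
  utils::write.csv(loss_surface(sweep), p2, row.names = FALSE)
  meta <- list(dt = attr(sweep, "dt"), steps = attr(sweep, "steps"),
               branch_names = attr(sweep, "branch_names"),
               alphas = sort(unique(sweep$alpha)),
               m = length(unique(sweep$seed)))
  p3 <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(p1, p2, p3))
}

#' Read a simulation configuration file
#'
#' Accepts YAML or JSON with keys mirroring [model_params()] fields plus a
#' `geometry` block: `type` (`"a_branch"` or `"y_branch"`) and
#' `distal_multiplier` or `inlet_flow_ratio`. Missing keys take the
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `params` (an `"ec_params"`) and `network`
#'   (a built `"vessel_network"`).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  geo <- cfg$geometry %||% list(type = "a_branch")
  cfg$geometry <- NULL
  par_args <- cfg[names(cfg) %in% names(formals(model_params))]
  params <- do.call(model_params, par_args)
  network <- if (identical(geo$type, "y_branch")) {
    build_y_branch(params, inlet_flow_ratio = geo$inlet_flow_ratio %||% 1)
  } else {
    build_a_branch(params, distal_multiplier = geo$distal_multiplier %||% 2L)
  }
  list(params = params, network = network)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a network edge list to CSV
#'
#' @param network A `"vessel_network"`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(network, path) {
  utils::write.csv(network_edgelist(network), path, row.names = FALSE)
  invisible(path)
}
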