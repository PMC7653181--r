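#' Construct a metric trajectory
#'
#' A metric trajectory holds the per-frame structural metrics of one
#' simulation trajectory (e.g. backbone dihedral angles in radians, or
#' particle coordinates) together with the recorded total potential energy
#' of every frame and the fixed recording interval.
#'
#' @param metrics Numeric matrix, frames x metric count.  Column names give
#'   the metric names.
#' @param energy Numeric vector of per-frame total potential energy; length
#'   must equal `nrow(metrics)`.
#' @param dt Recording interval between consecutive frames (time units),
#'   a single positive number.
#' @param id Character identifier for the trajectory.
#'
#' @return An object of class `metric_trajectory` with fields `id`,
#'   `metrics`, `energy` and `dt`.
#' @export
#' @examples
#' tr <- metric_trajectory(cbind(x = runif(10), y = runif(10)),
#'                         energy = rnorm(10), dt = 0.1)
#' n_frames(tr)
metric_trajectory <- function(metrics, energy, dt, id = "traj") {
  metrics <- as.matrix(metrics)
  storage.mode(metrics) <- "double"
  energy <- as.numeric(energy)
  if (nrow(metrics) < 1L)
    stop("trajectory must contain at least one frame")
  if (length(energy) != nrow(metrics))
    stop(sprintf("energy length (%d) does not match frame count (%d)",
                 length(energy), nrow(metrics)))
  if (!all(is.finite(metrics)) || !all(is.finite(energy)))
    stop("metrics and energy must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number")
  if (is.null(colnames(metrics)))
    colnames(metrics) <- paste0("m", seq_len(ncol(metrics)))
  structure(list(id = as.character(id), metrics = metrics,
                 energy = energy, dt = dt),
            class = "metric_trajectory")
}

#' @rdname metric_trajectory
#' @param x A `metric_trajectory`.
#' @export
n_frames <- function(x) nrow(x$metrics)

#' @export
print.metric_trajectory <- function(x, ...) {
  cat(sprintf("<metric_trajectory '%s': %d frames x %d metrics, dt = %g>\n",
              x$id, n_frames(x), ncol(x$metrics), x$dt))
  invisible(x)
}

# Check that a set of trajectories forms a consistent dataset: equal frame
# counts and equal dt, so that all share one frequency grid.
validate_dataset <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  lens <- vapply(trajs, n_frames, integer(1))
  dts <- vapply(trajs, function(t) t$dt, numeric(1))
  ncols <- vapply(trajs, function(t) ncol(t$metrics), integer(1))
  if (length(unique(lens)) != 1L)
    stop(sprintf(
      "dataset inconsistency: trajectories differ in length (%s); all must share one frequency grid",
      paste(unique(lens), collapse = ", ")))
  if (diff(range(dts)) > 1e-12 * max(dts))
    stop("dataset inconsistency: trajectories differ in recording interval dt")
  if (length(unique(ncols)) != 1L)
    stop("dataset inconsistency: trajectories differ in metric count")
  invisible(trajs)
}

#' Read metric trajectories from delimited text files
#'
#' Each file holds one trajectory: a header row naming the metric columns,
#' one row per frame, and one column named `energy` with the total
#' potential energy.  All files of a dataset must have the same frame
#' count (the low-pass filter maps every trajectory onto one shared
#' frequency grid).
#'
#' @param paths Character vector of file paths (CSV or TSV; the delimiter
#'   is sniffed).
#' @param dt Recording interval shared by all trajectories.
#' @param metric_cols Optional character vector selecting/ordering the
#'   metric columns; default: every column except `energy`, in file order.
#' @param degrees If `TRUE`, metric columns are interpreted as angles in
#'   degrees and converted to radians on read.
#' @param ids Trajectory identifiers; defaults to the file base names.
#'
#' @return List of [metric_trajectory()] objects in input order.
#' @export
read_trajectories <- function(paths, dt, metric_cols = NULL,
                              degrees = FALSE, ids = NULL) {
  if (length(paths) < 1L) stop("no trajectory files given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("trajectory file(s) not found: ", paste(missing, collapse = ", "))
  if (is.null(ids))
    ids <- tools::file_path_sans_ext(basename(paths))
  trajs <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    d <- data.table::fread(paths[i], header = TRUE, data.table = FALSE)
    if (!"energy" %in% names(d))
      stop(sprintf("schema error in '%s': required column 'energy' missing",
                   paths[i]))
    mc <- metric_cols %||% setdiff(names(d), "energy")
    absent <- setdiff(mc, names(d))
    if (length(absent))
      stop(sprintf("schema error in '%s': metric column(s) %s missing",
                   paths[i], paste(absent, collapse = ", ")))
    metrics <- as.matrix(d[, mc, drop = FALSE])
    if (degrees) metrics <- metrics * pi / 180
    trajs[[i]] <- metric_trajectory(metrics, d$energy, dt = dt, id = ids[i])
  }
  validate_dataset(trajs)
}

#' Write a metric trajectory to a delimited text file
#'
#' Inverse of [read_trajectories()]: emits the metric columns followed by
#' an `energy` column, full double precision, one row per frame.
#'
#' @param traj A [metric_trajectory()].
#' @param path Output file path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "metric_trajectory"))
  write_numeric_csv(cbind(traj$metrics, energy = traj$energy), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Collects and validates every tunable of the analysis pipeline.  Each
#' field can also be supplied in a YAML file read with [read_config()].
#'
#' @param max_n Largest integer multiplier of the sine/cosine basis
#'   (basis size = 2 x metrics x `max_n`).
#' @param k_min,k_max Bounds of the low-pass cutoff scan (frequency indices
#'   on the even-extended grid).  `k_max = NULL` defaults to one tenth of
#'   the trajectory length.
#' @param variance_fraction Fraction of total variance the retained
#'   principal components must reach, in (0, 1]; default 0.90.
#' @param segment_length Segment length in frames (>= 2); `NULL` (the
#'   default) uses one hundredth of the trajectory length.
#' @param lag Lag in segments at which transitions are counted (>= 1).
#' @param n_states Optional override of the automatic state count.
#' @param degrees Whether metric columns are angles in degrees.
#' @param project_raw If `TRUE`, project unweighted features instead of
#'   weighted ones (for comparison with the weighted default).
#' @param gap_on_raw If `TRUE`, take the state-count eigen-gap on the raw
#'   similarity matrix instead of its row-stochastic normalization.
#' @param seed Random seed controlling every stochastic component.
#' @param out_dir Output directory for result files.
#'
#' @return A validated list of class `espctm_config`.
#' @export
espctm_config <- function(max_n = 10L, k_min = 1L, k_max = NULL,
                          variance_fraction = 0.90, segment_length = NULL,
                          lag = 1L, n_states = NULL, degrees = FALSE,
                          project_raw = FALSE, gap_on_raw = FALSE,
                          seed = 1L, out_dir = NULL) {
  cfg <- list(max_n = as.integer(max_n), k_min = as.integer(k_min),
              k_max = if (!is.null(k_max)) as.integer(k_max),
              variance_fraction = variance_fraction,
              segment_length = if (!is.null(segment_length))
                as.integer(segment_length),
              lag = as.integer(lag),
              n_states = if (!is.null(n_states)) as.integer(n_states),
              degrees = isTRUE(degrees), project_raw = isTRUE(project_raw),
              gap_on_raw = isTRUE(gap_on_raw),
              seed = as.integer(seed), out_dir = out_dir)
  if (cfg$max_n < 1L) stop("max_n must be >= 1")
  if (cfg$variance_fraction <= 0 || cfg$variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  if (!is.null(cfg$segment_length) && cfg$segment_length < 2L)
    stop("segment_length must be >= 2")
  if (cfg$lag < 1L) stop("lag must be >= 1")
  if (cfg$k_min < 1L) stop("k_min must be >= 1")
  if (!is.null(cfg$k_max) && cfg$k_max < cfg$k_min)
    stop("k_max must be >= k_min")
  if (!is.null(cfg$n_states) && cfg$n_states < 2L)
    stop("n_states override must be >= 2")
  class(cfg) <- "espctm_config"
  cfg
}

#' Read pipeline configuration from a YAML file
#'
#' Fields mirror the arguments of [espctm_config()]; unknown fields are an
#' error, absent fields take their defaults.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file contents.
#' @return An `espctm_config`.
#' @export
read_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(espctm_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(espctm_config, modifyList(raw, list(...)))
}

# Format a numeric matrix/vector as full-precision delimited text.
write_numeric_csv <- function(x, path, col_names = NULL) {
  x <- as.matrix(x)
  d <- as.data.frame(format(x, digits = 17, trim = TRUE, scientific = TRUE),
                     stringsAsFactors = FALSE)
  if (!is.null(col_names)) names(d) <- col_names
  data.table::fwrite(d, path, quote = FALSE)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Serializes the kinetic model and the state assignment as delimited text
#' (full double precision) plus one machine-readable JSON summary, and
#' returns a manifest listing every file written.
#'
#' @param model A `markov_model` as returned by [build_markov()].
#' @param assignment A `state_assignment` as returned by [assign_states()].
#' @param dir Output directory (created if absent).
#' @param extra Optional named list merged into `summary.json` (e.g. chosen
#'   cutoff, eigenvalue spectra).
#'
#' @return Character vector of files written (the manifest), invisibly
#'   also saved as `manifest.txt`.
#' @export
write_results <- function(model, assignment, dir, extra = list()) {
  stopifnot(inherits(model, "markov_model"),
            inherits(assignment, "state_assignment"))
  if (length(assignment$labels) == 0L)
    stop("empty state assignment")
  if (nrow(model$P) != assignment$n_states)
    stop(sprintf("model has %d states but assignment has %d",
                 nrow(model$P), assignment$n_states))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  put <- function(x, name, col_names = NULL) {
    p <- file.path(dir, name)
    write_numeric_csv(x, p, col_names)
    files <<- c(files, p)
  }
  ns <- assignment$n_states
  put(model$P, "transition_matrix.csv", paste0("S", seq_len(ns) - 1L))
  put(matrix(model$stationary, ncol = 1), "stationary.csv", "pi")
  put(matrix(model$lifetimes, ncol = 1), "lifetimes.csv", "lifetime")
  lab <- data.frame(trajectory = assignment$provenance$trajectory,
                    start_frame = assignment$provenance$start_frame,
                    state = assignment$labels)
  p <- file.path(dir, "labels.csv")
  data.table::fwrite(lab, p)
  files <- c(files, p)
  put(assignment$memberships, "memberships.csv",
      paste0("S", seq_len(ns) - 1L))
  put(matrix(assignment$eigenvalues, ncol = 1),
      "eigenvalues_similarity.csv", "eigenvalue")
  if (!is.null(extra$eigenvalues_pca))
    put(cbind(index = seq_along(extra$eigenvalues_pca),
              eigenvalue = extra$eigenvalues_pca,
              cumulative_fraction = cumsum(extra$eigenvalues_pca) /
                sum(extra$eigenvalues_pca)),
        "eigenvalues_pca.csv",
        c("index", "eigenvalue", "cumulative_fraction"))
  if (!is.null(extra$r_curve))
    put(extra$r_curve, "r_of_K.csv", colnames(extra$r_curve))
  summ <- c(list(n_states = ns, lag_segments = model$lag,
                 lag_time = model$lag_time,
                 stationary = model$stationary,
                 lifetimes = model$lifetimes),
            extra[setdiff(names(extra), c("eigenvalues_pca", "r_curve"))])
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, p)
  writeLines(basename(files), file.path(dir, "manifest.txt"))
  esp_log("write", "wrote %d files to %s", length(files), dir)
  invisible(files)
}

#' Bundled reference transition matrices
#'
#' Returns one of the reference kinetic models shipped with the package:
#' published row-stochastic transition matrices for a Brownian particle on
#' the three-well landscape (`"toy"`, 3 states, lag unit = 100 recording
#' intervals) and for the alanine dodecapeptide Ala12 (`"ala12"`, 6 states,
#' lag = 1 ns), used to validate the Markov layer.
#'
#' @param which `"toy"` or `"ala12"`.
#' @return List with `P` (transition matrix), `stationary` (published
#'   stationary distribution), `lifetimes` (published lifetimes) and
#'   `lag_time` (in the published unit).
#' @export
reference_model <- function(which = c("toy", "ala12")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_reference_model.csv"),
                      package = "espctm")
  d <- data.table::fread(path, data.table = FALSE)
  ns <- nrow(d)
  P <- as.matrix(d[, seq_len(ns)])
  dimnames(P) <- list(d$state, names(d)[seq_len(ns)])
  list(P = P, stationary = d$stationary, lifetimes = d$lifetime,
       lag_time = 1)
}
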