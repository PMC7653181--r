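#' Run the full metastable-state pipeline
#'
#' Executes the five analysis steps on a set of metric trajectories:
#' 1. featurize each trajectory in the sine/cosine basis and normalize
#'    every dimension over the pooled dataset;
#' 2. scan low-pass cutoffs of the recorded energy and select the
#'    effective-energy regression model maximizing `r(K)`;
#' 3. rescale features by the regression weights and fit the E-space
#'    (PCA with the variance-retention rule), then project every
#'    trajectory;
#' 4. average projections over isometric segments, build the
#'    segment-similarity matrix, choose the state count from its
#'    eigenvalue gap and assign metastable states by PCCA+;
#' 5. estimate the lagged Markov transition matrix, stationary
#'    distribution and state lifetimes.
#'
#' Any step failure aborts with the step name attached.
#'
#' @param trajs List of [metric_trajectory()] objects (a consistent
#'   dataset: equal lengths and dt).
#' @param config An [espctm_config()].
#' @return An `espctm_result` with elements `basis`, `features`
#'   (`feature_set`), `energy_model`, `espace`, `projections`,
#'   `segments`, `assignment`, `markov`, `frame_labels` (per-frame state
#'   labels inherited from segments), `config`.  If `config$out_dir` is
#'   set, results are also written there via [write_results()].
#' @export
run_espctm <- function(trajs, config = espctm_config()) {
  stopifnot(inherits(config, "espctm_config"))
  validate_dataset(trajs)
  set.seed(config$seed)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline step '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  ids <- vapply(trajs, function(t) t$id, character(1))
  dt <- trajs[[1]]$dt

  basis <- step("featurize",
                make_basis(ncol(trajs[[1]]$metrics), config$max_n))
  fset <- step("featurize", {
    raw <- lapply(trajs, featurize, basis = basis)
    normalize_features(raw)
  })

  emod <- step("effective_energy", {
    n <- n_frames(trajs[[1]])
    kmax <- config$k_max %||% max(1L, n %/% 10L)
    select_cutoff(fset, lapply(trajs, function(t) t$energy),
                  k_range = seq(config$k_min, max(config$k_min, kmax)),
                  dt = dt)
  })

  esp <- step("espace",
              fit_espace(fset, emod$coef, config$variance_fraction))
  proj <- step("espace",
               lapply(fset$features, project_espace, espace = esp,
                      raw = config$project_raw))

  L <- config$segment_length %||%
    max(2L, n_frames(trajs[[1]]) %/% 100L)
  segs <- step("discretize", segment_average(proj, L, ids = ids))
  S <- step("discretize", similarity_matrix(segs))
  ns <- step("discretize",
             select_n_states(S, override = config$n_states,
                             gap_on_raw = config$gap_on_raw))
  assign <- step("discretize",
                 assign_states(S, max(2L, as.integer(ns)),
                               provenance = segs$provenance))

  mkv <- step("markov", {
    lab_by_traj <- split(assign$labels,
                         rep(seq_along(trajs), segs$n_segments))
    build_markov(lab_by_traj, lag = config$lag,
                 n_states = assign$n_states,
                 lag_time = config$lag * segs$L * dt)
  })

  frame_labels <- lapply(seq_along(trajs), function(j) {
    sl <- assign$labels[rep(seq_along(trajs), segs$n_segments) == j]
    lab <- rep(sl, each = segs$L)
    length(lab) <- n_frames(trajs[[j]]) # trailing frames -> NA
    lab
  })

  res <- structure(list(basis = basis, features = fset,
                        energy_model = emod, espace = esp,
                        projections = proj, segments = segs,
                        similarity = S, assignment = assign,
                        markov = mkv, frame_labels = frame_labels,
                        config = config),
                   class = "espctm_result")
  if (!is.null(config$out_dir)) {
    write_results(mkv, assign, config$out_dir, extra = list(
      eigenvalues_pca = esp$eigenvalues,
      r_curve = as.matrix(emod$r_curve),
      k_star = emod$k_star, r = emod$r, n_c = esp$n_c,
      seed = config$seed))
  }
  res
}

#' @export
print.espctm_result <- function(x, ...) {
  cat(sprintf(
    "<espctm_result: %d trajectories, K* = %d, N_c = %d, N_s = %d>\n",
    length(x$projections), x$energy_model$k_star, x$espace$n_c,
    x$assignment$n_states))
  print(x$markov)
  invisible(x)
}

#' Simulate the three-well toy system and validate the pipeline on it
#'
#' Simulates Langevin trajectories on the three-well landscape, runs the
#' full pipeline, and compares the recovered model against ground truth:
#' the number of metastable states against the three wells, the state
#' assignment against the watershed basin of each segment's mean
#' position, and the stationary distribution against the Boltzmann
#' quadrature weights at the simulation temperature.
#'
#' @param seed Random seed.
#' @param n_traj,n_frames Simulation size (defaults: 10 trajectories of
#'   10000 frames).
#' @param kT Simulation temperature (default: the calibrated value 60).
#' @param eps Landscape scale.
#' @param config Pipeline configuration; the seed is overridden by
#'   `seed`.
#' @param ... Further arguments to [simulate_brownian()].
#' @return A list report: `result` (the `espctm_result`), `n_states`,
#'   `stationary` (ordered by basin), `boltzmann` (oracle weights),
#'   `max_stationary_error`, `state_to_basin` (mapping), `purity`
#'   (fraction of segments whose state matches the basin of their mean
#'   position), `lifetimes`.
#' @export
reproduce_toy <- function(seed = 1L, n_traj = 10L, n_frames = 10000L,
                          kT = 60, eps = 40,
                          config = espctm_config(), ...) {
  config$seed <- as.integer(seed)
  # toy segments must sit well below the basin dwell time (~30 recorded
  # frames): 20 frames = 2 time units
  config$segment_length <- config$segment_length %||% 20L
  trajs <- simulate_brownian(n_traj = n_traj, n_frames = n_frames,
                             eps = eps, kT = kT, seed = seed, ...)
  res <- run_espctm(trajs, config)
  ns <- res$assignment$n_states

  # basin of each segment's mean (wrapped circular mean) position
  segpos <- segment_mean_positions(trajs, res$segments)
  basins <- assign_basins(segpos[, 1], segpos[, 2], eps)
  map <- state_basin_map(res$assignment$labels, basins, ns)
  purity <- mean(map$mapped[res$assignment$labels] == basins)

  bw <- boltzmann_basin_weights(eps, kT)
  pi_by_basin <- rep(NA_real_, 3)
  for (s in seq_len(ns)) {
    b <- map$mapped[s]
    pi_by_basin[b] <- sum(pi_by_basin[b], res$markov$stationary[s],
                          na.rm = TRUE)
  }
  err <- max(abs(pi_by_basin - bw), na.rm = TRUE)
  esp_log("toy", "N_s = %d, purity = %.3f, max |pi - Boltzmann| = %.3f",
          ns, purity, err)
  list(result = res, n_states = ns,
       stationary = pi_by_basin, boltzmann = bw,
       max_stationary_error = err,
       state_to_basin = map$mapped, purity = purity,
       lifetimes = res$markov$lifetimes)
}

# Circular-mean positions of segments on the torus.
segment_mean_positions <- function(trajs, segs) {
  out <- matrix(NA_real_, nrow(segs$averages), 2)
  row <- 0L
  for (j in seq_along(trajs)) {
    m <- trajs[[j]]$metrics
    for (s in seq_len(segs$n_segments[j])) {
      idx <- ((s - 1L) * segs$L + 1L):(s * segs$L)
      row <- row + 1L
      out[row, ] <- c(atan2(mean(sin(m[idx, 1])), mean(cos(m[idx, 1]))),
                      atan2(mean(sin(m[idx, 2])), mean(cos(m[idx, 2]))))
    }
  }
  out
}

# Majority-vote mapping from pipeline states to landscape basins.
state_basin_map <- function(labels, basins, n_states) {
  mapped <- integer(n_states)
  for (s in seq_len(n_states)) {
    tb <- tabulate(basins[labels == s], 3)
    mapped[s] <- if (sum(tb) > 0) which.max(tb) else NA_integer_
  }
  list(mapped = mapped)
}
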