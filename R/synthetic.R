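#' Generate a synthetic single-cell measurement data set
#'
#' Emulates measured PRC1 trajectory tables: the branching model is simulated
#' past a burn-in, each post-burn-in cell's trajectory is sampled at constant
#' intervals, every sample is corrupted by multiplicative lognormal
#' measurement noise (unit median, coefficient of variation
#' `measurement_cv`), and a fraction `outlier_fraction` of trajectories is
#' replaced by corrupted ones whose end/start fold change is drawn uniformly
#' from `outlier_ratio_range` — mimicking mis-identified cycle boundaries,
#' which in real data produced fold changes up to fifty.
#'
#' Outlier corruption rescales the accumulation segment smoothly (factor
#' growing geometrically from 1 at the minimum to the required value at the
#' end), so corrupted trajectories keep a valid two-phase shape but an
#' implausible X2/X0 ratio.
#'
#' @param params A validated [prc1_params] object.
#' @param n_cells Number of cells to emit (>= 10).
#' @param dt Sampling interval (default 0.25 time units).
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   measurement noise, in `[0, 0.5)` (default 0.05).
#' @param outlier_fraction Fraction of trajectories corrupted, in `[0, 0.5)`
#'   (default 0.1). Exactly `round(outlier_fraction * n_cells)` cells are
#'   corrupted.
#' @param outlier_ratio_range Range `c(low, high)` of the corrupted end/start
#'   ratio (default `c(10, 50)`).
#' @param burn_in Generations discarded before collecting cells (default 5).
#' @param seed Optional integer seed.
#' @return A list of class `prc1_dataset`: `trajectories` (tibble `cell_id,
#'   parent_id, time, value`) and `truth` (per-cell cycle record with an
#'   `outlier` flag; kinetic columns describe the uncorrupted cell).
#' @examples
#' d <- generate_dataset(prc1_params(1), n_cells = 50, seed = 1)
#' dplyr::count(d$truth, outlier)
#' @export
generate_dataset <- function(params, n_cells, dt = 0.25,
                             measurement_cv = 0.05, outlier_fraction = 0.1,
                             outlier_ratio_range = c(10, 50),
                             burn_in = 5, seed = NULL) {
  params <- validate_params(params)
  if (n_cells < 10) abort("`n_cells` must be at least 10.")
  stopifnot(measurement_cv >= 0, measurement_cv < 0.5,
            outlier_fraction >= 0, outlier_fraction < 0.5,
            length(outlier_ratio_range) == 2,
            outlier_ratio_range[1] > 0,
            outlier_ratio_range[1] <= outlier_ratio_range[2],
            dt > 0)
  if (!is.null(seed)) set.seed(seed)

  cells <- simulate_post_burnin(params, n_cells, burn_in = burn_in)
  traj <- pedigree_to_trajectories(cells, dt)

  n_out <- round(outlier_fraction * n_cells)
  outlier_ids <- if (n_out > 0) sample(cells$cell_id, n_out) else integer(0)

  if (n_out > 0) {
    ratio_target <- stats::runif(n_out, outlier_ratio_range[1],
                                 outlier_ratio_range[2])
    for (i in seq_len(n_out)) {
      id <- outlier_ids[i]
      cell <- cells[cells$cell_id == id, ]
      sel <- which(traj$cell_id == id)
      age <- traj$time[sel] - cell$birth_time
      f_end <- ratio_target[i] / (cell$X2 / cell$X0)
      up <- age > cell$T1
      frac <- (age[up] - cell$T1) / cell$T2
      traj$value[sel][up] <- traj$value[sel][up] * f_end^frac
    }
  }

  if (measurement_cv > 0) {
    sigma <- sqrt(log(1 + measurement_cv^2))
    traj$value <- traj$value * exp(rnorm(nrow(traj), 0, sigma))
  }

  truth <- dplyr::mutate(
    dplyr::select(as_tibble(cells), "cell_id", "parent_id", "generation",
                  "X0", "X1", "X2", "T1", "T2", "a", "b"),
    outlier = .data$cell_id %in% outlier_ids
  )
  structure(list(trajectories = traj, truth = truth), class = "prc1_dataset")
}

# simulate a capped pedigree until at least n_target cells exist in
# generations > burn_in; returns those cells (first n_target in id order)
simulate_post_burnin <- function(params, n_target, burn_in = 5, cap = NULL,
                                 ancestor_x0 = NULL) {
  cap <- cap %||% (2 * min(max(64, ceiling(n_target / 4)), 4096))
  sizes <- 1
  g <- 0
  post <- 0
  while (post < n_target) {
    g <- g + 1
    sizes <- c(sizes, min(2 * sizes[g], 2 * floor(cap / 2)))
    if (g > burn_in) post <- post + sizes[g + 1]
    if (g > 200) abort("Burn-in target not reachable; increase `cap`.")
  }
  ped <- simulate_pedigree(params, n_generations = g, cap = cap,
                           ancestor_x0 = ancestor_x0)
  cells <- ped[ped$generation > burn_in, , drop = FALSE]
  head(cells, n_target)
}

#' @export
print.prc1_dataset <- function(x, ...) {
  cat(sprintf("<prc1_dataset> %d cells (%d outliers), %d samples\n",
              nrow(x$truth), sum(x$truth$outlier), nrow(x$trajectories)))
  invisible(x)
}

#' Write the ground-truth table of a synthetic data set
#'
#' @param truth The `truth` component of a [generate_dataset()] result.
#' @param path File path (TSV).
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(as_tibble(truth), path, progress = FALSE)
  invisible(path)
}
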