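#' Draw per-cell cycle records from the stochastic two-phase model
#'
#' Given birth amounts `x0`, draws one cell cycle per element: the four
#' regression equations are evaluated in the order ln(a), T1, ln(b), T2, each
#' with an independent Gaussian noise draw, and the phase amounts follow the
#' piecewise-exponential kinetics X1 = X0 exp(-a T1), X2 = X1 exp(b T2).
#'
#' A draw that would make a kinetic parameter non-positive (possible for the
#' identity-scale T1 equation and for T2) is rejected and its noise term
#' redrawn, i.e. the noise is Gaussian conditional on positivity. More than
#' `max_redraws` consecutive rejections for one equation signals pathological
#' parameters and fails, naming the equation.
#'
#' @param x0 Numeric vector of birth amounts (a.u., > 0). One record per element.
#' @param params A validated [prc1_params] object.
#' @param cell_id Optional identifiers (defaults to `seq_along(x0)`).
#' @param seed Optional integer; when given, seeds the RNG for this call.
#' @param max_redraws Rejection budget per equation (default 1000).
#' @return A tibble with columns `cell_id, X0, X1, X2, T1, T2, a, b`.
#' @examples
#' p <- prc1_params(1)
#' sample_cycle(1e5, p, seed = 1)
#' @export
sample_cycle <- function(x0, params, cell_id = NULL, seed = NULL,
                         max_redraws = 1000) {
  params <- validate_params(params)
  stopifnot(is.numeric(x0), all(is.finite(x0)), all(x0 > 0))
  if (!is.null(seed)) set.seed(seed)
  cell_id <- cell_id %||% seq_along(x0)
  rec <- draw_cycle(x0, params$regression, max_redraws)
  tibble(cell_id = cell_id, X0 = x0, X1 = rec$X1, X2 = rec$X2,
         T1 = rec$T1, T2 = rec$T2, a = rec$a, b = rec$b)
}

# vectorised single-cycle draw; noise order per cell: ln(a), T1, ln(b), T2
draw_cycle <- function(x0, reg, max_redraws = 1000) {
  n <- length(x0)
  s <- noise_sd(reg)

  lna <- reg$b1 + reg$b10 * x0 + rnorm(n, 0, s[["a"]])
  a <- exp(lna)

  t1_mean <- reg$b2 + reg$b21 * lna
  if (identical(reg$t1_link, "log")) {
    T1 <- exp(t1_mean + rnorm(n, 0, s[["T1"]]))
  } else {
    T1 <- redraw_positive(t1_mean, s[["T1"]], max_redraws, "T1")
  }

  X1 <- x0 * exp(-a * T1)
  lnb <- reg$b4 + reg$b41 * lna + reg$b43 * X1 + rnorm(n, 0, s[["b"]])
  b <- exp(lnb)

  T2 <- redraw_positive(reg$b5 + reg$b52 * T1, s[["T2"]], max_redraws, "T2")
  X2 <- X1 * exp(b * T2)

  list(X1 = X1, X2 = X2, T1 = T1, T2 = T2, a = a, b = b)
}

# additive Gaussian noise conditional on a positive result
redraw_positive <- function(mean, sd, max_redraws, equation) {
  out <- mean + rnorm(length(mean), 0, sd)
  if (sd == 0) {
    if (any(out <= 0)) {
      abort(sprintf(
        "Equation %s yields non-positive values with zero dispersion (pathological parameters).",
        equation))
    }
    return(out)
  }
  tries <- 0L
  repeat {
    bad <- which(out <= 0)
    if (length(bad) == 0) return(out)
    tries <- tries + 1L
    if (tries > max_redraws) {
      abort(sprintf(
        "Equation %s: more than %d consecutive rejected redraws (pathological parameters).",
        equation, max_redraws))
    }
    out[bad] <- mean[bad] + rnorm(length(bad), 0, sd)
  }
}

#' Split a dividing cell's protein between two daughters
#'
#' Draws the inherited fraction U from the symmetric Beta(alpha, alpha) law
#' and allocates `X0_left = U * X2`, `X0_right = X2 - X0_left`, so the two
#' daughters' birth amounts sum to the parent's division amount exactly (to
#' the last bit of the floating-point representation).
#'
#' @param x2 Numeric vector of division amounts (> 0).
#' @param division A `prc1_division` component (or a `prc1_params` object).
#' @param seed Optional integer seed.
#' @return A tibble with columns `U, X0_left, X0_right`.
#' @export
divide_protein <- function(x2, division, seed = NULL) {
  if (inherits(division, "prc1_params")) division <- division$division
  stopifnot(is.numeric(x2), all(x2 > 0), division$alpha > 0)
  if (!is.null(seed)) set.seed(seed)
  U <- rbeta(length(x2), division$alpha, division$alpha)
  # right = x2 - U x2, then left recomputed as x2 - right: makes
  # left + right == x2 exact in floating point (Sterbenz), not just close
  right <- x2 - U * x2
  left <- x2 - right
  tibble(U = U, X0_left = left, X0_right = right)
}

#' Simulate a multi-generation branching pedigree
#'
#' Starts from a single ancestor and grows a binary tree of cell cycles:
#' each cell's kinetics are drawn with [sample_cycle()], and at division the
#' protein is split between the two daughters with [divide_protein()]. Birth
#' and division times accumulate along lineages (the ancestor is born at time
#' 0). Generations are simulated breadth-first with vectorised draws, so a
#' fixed `seed` reproduces the pedigree exactly.
#'
#' With `cap` set, at most `cap` cells are propagated per generation: when a
#' generation would exceed the cap, `floor(cap / 2)` parents are chosen
#' uniformly at random and both daughters of each chosen parent are kept, so
#' retained sibling pairs stay intact and lineage links exact. Without a cap
#' the tree is full binary and the projected node count must stay below
#' `max_nodes`.
#'
#' @param params A validated [prc1_params] object.
#' @param n_generations Number of generations beyond the ancestor (>= 1).
#' @param ancestor_x0 Birth amount of the ancestor. Default `NULL` starts at
#'   the deterministic symmetric-division equilibrium of the parameter set
#'   (see [find_equilibria()]); if no equilibrium is found, 1e5 a.u. is used.
#' @param cap Optional per-generation cell cap (even number recommended).
#' @param seed Optional integer seed.
#' @param max_nodes Hard limit on the projected uncapped node count.
#' @return A tibble of class `prc1_pedigree` with columns `cell_id,
#'   parent_id, generation, birth_time, division_time, U, X0, X1, X2, T1, T2,
#'   a, b`. `U` is the split fraction the cell received at birth (`NA` for
#'   the ancestor).
#' @examples
#' p <- prc1_params(1)
#' ped <- simulate_pedigree(p, n_generations = 3, seed = 1)
#' nrow(ped) # 1 + 2 + 4 + 8
#' @export
simulate_pedigree <- function(params, n_generations, ancestor_x0 = NULL,
                              cap = NULL, seed = NULL, max_nodes = 2^21) {
  params <- validate_params(params)
  stopifnot(length(n_generations) == 1, n_generations >= 1,
            n_generations == as.integer(n_generations))
  if (is.null(cap)) {
    projected <- 2^(n_generations + 1) - 1
    if (projected > max_nodes) {
      abort(sprintf(
        "Uncapped pedigree would hold %.3g nodes (> max_nodes = %.3g); set `cap`.",
        projected, max_nodes))
    }
  } else {
    stopifnot(cap >= 2)
  }
  if (!is.null(seed)) set.seed(seed)
  ancestor_x0 <- ancestor_x0 %||% default_ancestor_x0(params)
  stopifnot(ancestor_x0 > 0)

  gens <- vector("list", n_generations + 1)
  next_id <- 1L
  x0 <- ancestor_x0
  parent_id <- NA_integer_
  birth_time <- 0
  U <- NA_real_

  for (g in 0:n_generations) {
    n <- length(x0)
    ids <- seq.int(next_id, length.out = n)
    next_id <- next_id + n
    rec <- draw_cycle(x0, params$regression)
    gens[[g + 1]] <- tibble(
      cell_id = ids, parent_id = parent_id, generation = g,
      birth_time = birth_time,
      division_time = birth_time + rec$T1 + rec$T2,
      U = U, X0 = x0, X1 = rec$X1, X2 = rec$X2,
      T1 = rec$T1, T2 = rec$T2, a = rec$a, b = rec$b
    )
    if (g == n_generations) break

    keep <- seq_len(n)
    if (!is.null(cap) && 2 * n > cap) {
      keep <- sort(sample.int(n, floor(cap / 2)))
    }
    split <- divide_protein(rec$X2[keep], params$division)
    # interleave daughters so siblings are adjacent: left, right, left, right
    x0 <- as.vector(rbind(split$X0_left, split$X0_right))
    U <- as.vector(rbind(split$U, 1 - split$U))
    parent_id <- rep(ids[keep], each = 2)
    birth_time <- rep(gens[[g + 1]]$division_time[keep], each = 2)
  }
  out <- dplyr::bind_rows(gens)
  class(out) <- c("prc1_pedigree", class(out))
  attr(out, "data_set") <- params$data_set
  attr(out, "ancestor_x0") <- ancestor_x0
  out
}

default_ancestor_x0 <- function(params) {
  eq <- tryCatch(find_equilibria(params), error = function(e) NULL)
  if (!is.null(eq) && nrow(eq) > 0) {
    if (any(eq$stable)) eq$X0_star[which(eq$stable)[1]] else eq$X0_star[1]
  } else {
    1e5
  }
}

#' Sample each cell's trajectory on a regular time grid
#'
#' Converts a pedigree into long-format protein trajectories: each cell is
#' sampled at ages 0, dt, 2 dt, ... up to the last grid point at or before its
#' division time, following the piecewise-exponential kinetics
#' X(t) = X0 exp(-a t) for t <= T1 and X(t) = X1 exp(b (t - T1)) afterwards.
#' The first sample is the birth amount exactly; when the grid lands on the
#' division time the last sample is the division amount exactly.
#'
#' Cells whose whole cycle is shorter than `dt` are emitted with the single
#' birth sample and listed in the `short_cycle` attribute of the result.
#'
#' @param pedigree A `prc1_pedigree` tibble (or any tibble with columns
#'   `cell_id, parent_id, birth_time, X0, X1, T1, T2, a, b`).
#' @param dt Sampling interval (time units, > 0).
#' @return A tibble with columns `cell_id, parent_id, time, value`, `time`
#'   being absolute time on the per-cell grid of spacing `dt`.
#' @export
pedigree_to_trajectories <- function(pedigree, dt) {
  stopifnot(dt > 0, nrow(pedigree) > 0)
  T_tot <- pedigree$T1 + pedigree$T2
  # tolerance so a grid point landing on the division time is kept
  n_samp <- pmax(1L, floor(T_tot / dt + 1e-9) + 1L)
  idx <- rep.int(seq_len(nrow(pedigree)), n_samp)
  k <- sequence(n_samp) - 1L
  age <- k * dt
  X0 <- pedigree$X0[idx]; X1 <- pedigree$X1[idx]
  a <- pedigree$a[idx]; b <- pedigree$b[idx]; T1 <- pedigree$T1[idx]
  value <- ifelse(age <= T1, X0 * exp(-a * age), X1 * exp(b * (age - T1)))
  at_division <- abs(age - T_tot[idx]) <= 1e-9 * pmax(1, T_tot[idx])
  value[at_division] <- pedigree$X2[idx][at_division]
  out <- tibble(
    cell_id = pedigree$cell_id[idx],
    parent_id = pedigree$parent_id[idx],
    time = pedigree$birth_time[idx] + age,
    value = value
  )
  short <- pedigree$cell_id[n_samp == 1L]
  if (length(short) > 0) {
    warn(sprintf("%d cell(s) have a cycle shorter than dt; emitted with one sample.",
                 length(short)))
  }
  attr(out, "dt") <- dt
  attr(out, "short_cycle") <- short
  out
}

#' Follow one random lineage from the ancestor to a leaf
#'
#' Chooses, at every division, one of the two daughters by an unbiased coin
#' flip and reports the birth and division amounts along the resulting
#' root-to-leaf path.
#'
#' @param pedigree A `prc1_pedigree` tibble.
#' @param seed Optional integer seed (fixed seed, identical path).
#' @return A tibble with columns `generation, cell_id, X0, X2`.
#' @export
lineage_series <- function(pedigree, seed = NULL) {
  stopifnot(nrow(pedigree) > 0)
  if (!is.null(seed)) set.seed(seed)
  root <- pedigree$cell_id[is.na(pedigree$parent_id)]
  stopifnot(length(root) == 1)
  children <- split(pedigree$cell_id, factor(pedigree$parent_id,
                                             levels = pedigree$cell_id))
  path <- root
  current <- root
  repeat {
    kids <- children[[as.character(current)]]
    if (is.null(kids) || length(kids) == 0) break
    current <- if (length(kids) == 1) kids else kids[sample.int(length(kids), 1)]
    path <- c(path, current)
  }
  i <- match(path, pedigree$cell_id)
  tibble(generation = pedigree$generation[i], cell_id = path,
         X0 = pedigree$X0[i], X2 = pedigree$X2[i])
}

#' Export a pedigree as a Newick tree
#'
#' Branch lengths are the cell-cycle durations T1 + T2; tip and node labels
#' are the cell ids.
#'
#' @param pedigree A `prc1_pedigree` tibble.
#' @return A single Newick string (terminated by `;`).
#' @export
pedigree_to_newick <- function(pedigree) {
  stopifnot(nrow(pedigree) > 0)
  len <- pedigree$T1 + pedigree$T2
  kids <- split(seq_len(nrow(pedigree)),
                factor(pedigree$parent_id, levels = pedigree$cell_id))
  build <- function(i) {
    ch <- kids[[i]]
    lab <- sprintf("%s:%.10g", pedigree$cell_id[i], len[i])
    if (is.null(ch) || length(ch) == 0) return(lab)
    paste0("(", paste(vapply(ch, build, character(1)), collapse = ","), ")", lab)
  }
  root <- which(is.na(pedigree$parent_id))
  stopifnot(length(root) == 1)
  paste0(build(root), ";")
}

#' Write pedigree / trajectory tables to disk
#'
#' Fixed CSV dialect: comma (or tab) separated, `.` decimal mark, UTF-8,
#' mandatory header, ASCII minus signs — so identical inputs give
#' byte-identical files.
#'
#' @param pedigree,trajectories Tables as produced by [simulate_pedigree()] /
#'   [pedigree_to_trajectories()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree_tsv <- function(pedigree, path) {
  readr::write_tsv(as_tibble(pedigree), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_tsv
#' @export
write_trajectories_csv <- function(trajectories, path) {
  readr::write_csv(as_tibble(trajectories), path, progress = FALSE)
  invisible(path)
}

#' Read a long-format trajectory table
#'
#' Expects columns `cell_id, parent_id, time, value` (the format written by
#' [write_trajectories_csv()]).
#'
#' @param path CSV file path.
#' @return A tibble ordered by cell and time.
#' @export
read_trajectories_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "time", "value")
  missing <- setdiff(need, names(out))
  if (length(missing) > 0) {
    abort(sprintf("Trajectory file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dplyr::arrange(out, .data$cell_id, .data$time)
}
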