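#' Simulation-based correlation table
#'
#' Runs the branching simulator from the default ancestor until at least
#' `n_cells_target` cells exist in generations beyond `burn_in`, then
#' computes the pairwise correlation table of the cycle variables over those
#' post-burn-in cells — the simulation counterpart of a data-derived
#' correlation table.
#'
#' @param params A validated [prc1_params] object.
#' @param n_cells_target Minimum number of post-burn-in cells (>= 1000).
#' @param burn_in Generations discarded (default 5).
#' @param cap Per-generation cell cap (default 4096).
#' @param seed Optional integer seed.
#' @param ancestor_x0 Optional ancestor override (default: deterministic
#'   equilibrium).
#' @return A `prc1_corr` matrix; the record count used is in attribute
#'   `n_cells`.
#' @export
simulated_correlation_table <- function(params, n_cells_target = 10000,
                                        burn_in = 5, cap = 4096, seed = NULL,
                                        ancestor_x0 = NULL) {
  params <- validate_params(params)
  if (n_cells_target < 1000) abort("`n_cells_target` must be at least 1000.")
  if (!is.null(seed)) set.seed(seed)
  cells <- simulate_post_burnin(params, n_cells_target, burn_in = burn_in,
                                cap = cap, ancestor_x0 = ancestor_x0)
  out <- correlation_table(cells)
  attr(out, "n_cells") <- nrow(cells)
  out
}

#' Parent-progeny and sibling time-point correlations
#'
#' For each pair of cycle-percentage grid points (p, q), interpolates every
#' cell's protein level at fraction p (resp. q) of its own cycle span
#' (linear interpolation on the log-value scale between adjacent samples) and
#' correlates the values across related cell pairs: parent vs daughter, or
#' sibling vs sibling. The sibling matrix uses both orderings of each pair
#' and is therefore exactly symmetric.
#'
#' @param trajectories Long-format tibble with `cell_id, parent_id, time,
#'   value` and lineage links (as from [pedigree_to_trajectories()]).
#' @param relation `"parent-progeny"` or `"sib-sib"`.
#' @param grid Cycle percentages (default 0 to 100 by 5).
#' @param pairing For parent-progeny, `"both"` daughters (default, two pairs
#'   per parent) or one `"single"` random daughter.
#' @param min_pairs Entries backed by fewer pairs are reported NA
#'   (default 50).
#' @param seed Optional seed (used by `pairing = "single"`).
#' @return A square matrix over the grid of class `prc1_timepoint`, with the
#'   pair count in attribute `n_pairs` and the relation in `relation`.
#' @export
timepoint_correlations <- function(trajectories,
                                   relation = c("parent-progeny", "sib-sib"),
                                   grid = seq(0, 100, by = 5),
                                   pairing = c("both", "single"),
                                   min_pairs = 50, seed = NULL) {
  relation <- match.arg(relation)
  pairing <- match.arg(pairing)
  stopifnot(all(grid >= 0), all(grid <= 100), !is.unsorted(grid))
  if (!is.null(seed)) set.seed(seed)

  trajectories <- dplyr::arrange(trajectories, .data$cell_id, .data$time)
  per_cell <- split(seq_len(nrow(trajectories)), trajectories$cell_id)
  ids <- as.vector(vapply(per_cell, function(i) trajectories$cell_id[i[1]],
                          trajectories$cell_id[1]))
  frac <- grid / 100

  vals <- matrix(NA_real_, length(per_cell), length(grid))
  keep <- logical(length(per_cell))
  for (j in seq_along(per_cell)) {
    i <- per_cell[[j]]
    if (length(i) < 2) next
    tt <- trajectories$time[i]
    vv <- trajectories$value[i]
    if (any(vv <= 0)) next
    span <- tt[length(tt)] - tt[1]
    if (span <= 0) next
    vals[j, ] <- exp(approx((tt - tt[1]) / span, log(vv), xout = frac,
                            rule = 2, ties = "ordered")$y)
    keep[j] <- TRUE
  }
  ids <- ids[keep]
  vals <- vals[keep, , drop = FALSE]
  parent_of <- trajectories$parent_id[!duplicated(trajectories$cell_id)]
  names(parent_of) <- trajectories$cell_id[!duplicated(trajectories$cell_id)]
  parent <- unname(parent_of[as.character(ids)])

  if (relation == "parent-progeny") {
    child_row <- which(!is.na(parent) & parent %in% ids)
    if (pairing == "single" && length(child_row) > 0) {
      fam <- split(child_row, parent[child_row])
      child_row <- vapply(fam, function(r) {
        if (length(r) == 1) r else r[sample.int(length(r), 1)]
      }, integer(1))
    }
    row1 <- match(parent[child_row], ids)   # parent side (axis 1)
    row2 <- child_row                       # progeny side (axis 2)
  } else {
    fam <- split(seq_along(ids), parent)
    fam <- fam[vapply(fam, length, integer(1)) == 2]
    s1 <- vapply(fam, `[`, integer(1), 1)
    s2 <- vapply(fam, `[`, integer(1), 2)
    # both orderings: makes the matrix exactly symmetric
    row1 <- c(s1, s2)
    row2 <- c(s2, s1)
  }
  n_pairs <- length(row1)
  if (n_pairs < min_pairs) {
    abort(sprintf("Only %d related pairs available (< %d).", n_pairs, min_pairs))
  }

  A <- vals[row1, , drop = FALSE]
  B <- vals[row2, , drop = FALSE]
  cc <- suppressWarnings(cor(A, B))
  sd_a <- apply(A, 2, sd); sd_b <- apply(B, 2, sd)
  cc[sd_a == 0, ] <- NA_real_
  cc[, sd_b == 0] <- NA_real_
  dimnames(cc) <- list(grid, grid)
  structure(cc, class = c("prc1_timepoint", class(cc)),
            relation = relation, n_pairs = n_pairs)
}

#' Per-variable summary statistics of cycle records
#'
#' Mean, sample standard deviation (n - 1 denominator) and coefficient of
#' variation cv = sd / mean for each cycle variable, including the total
#' duration T1 + T2. Variables with non-positive mean get an undefined cv.
#'
#' @param features Cycle-record tibble (>= 2 rows).
#' @return A tibble with columns `variable, mean, sd, cv`.
#' @export
cv_summary <- function(features) {
  if (nrow(features) < 2) abort("Need at least 2 records.")
  vars <- intersect(c("X0", "X1", "X2", "T1", "T2", "a", "b"), names(features))
  d <- features[vars]
  if (all(c("T1", "T2") %in% vars)) d[["T1+T2"]] <- features$T1 + features$T2
  purrr::map_dfr(names(d), function(nm) {
    m <- mean(d[[nm]]); s <- sd(d[[nm]])
    tibble(variable = nm, mean = m, sd = s,
           cv = if (m > 0) s / m else NA_real_)
  })
}

#' Write a time-point correlation matrix as TSV
#'
#' @param mat A `prc1_timepoint` matrix.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timepoint_tsv <- function(mat, path) {
  df <- as_tibble(unclass(mat), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(pct = rownames(mat)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
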