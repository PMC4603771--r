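#' Fit the four-equation regression structure to cycle records
#'
#' Ordinary least squares on the exact model forms:
#' `ln(a) ~ X0`, `ln(T1) ~ ln(a)` (or `T1 ~ ln(a)` when
#' `t1_link = "identity"`), `ln(b) ~ ln(a) + X1` and `T2 ~ T1`. The noise
#' dispersion of each equation is the unbiased residual standard deviation
#' (denominator n - p); both the standard-deviation and variance readings are
#' reported.
#'
#' @param features Cycle-record tibble with columns `X0, X1, X2, T1, T2, a, b`
#'   (>= 30 rows, all positive).
#' @param t1_link `"log"` (default) or `"identity"` scale for the T1 response.
#' @return An object of class `prc1_fit`: the four `lm` fits, the implied
#'   regression coefficients, and dispersions. Use [tidy()] / [glance()] for
#'   broom-style summaries and [fitted_params()] to turn the fit into a
#'   simulable parameter object.
#' @examples
#' p <- prc1_params(1)
#' feats <- simulate_pedigree(p, 8, cap = 256, seed = 1)
#' fit <- fit_regressions(feats)
#' tidy(fit)
#' @export
fit_regressions <- function(features, t1_link = c("log", "identity")) {
  t1_link <- match.arg(t1_link)
  need <- c("X0", "X1", "T1", "T2", "a", "b")
  missing <- setdiff(need, names(features))
  if (length(missing) > 0) {
    abort(sprintf("`features` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(features) < 30) abort("Need at least 30 records to fit.")
  for (nm in need) {
    if (any(!is.finite(features[[nm]])) || any(features[[nm]] <= 0)) {
      abort(sprintf("Column `%s` must be finite and positive.", nm))
    }
  }
  d <- tibble(X0 = features$X0, X1 = features$X1, T1 = features$T1,
              T2 = features$T2, lna = log(features$a), lnb = log(features$b),
              lnT1 = log(features$T1))

  fits <- list(
    lna = lm(lna ~ X0, data = d),
    T1 = if (t1_link == "log") lm(lnT1 ~ lna, data = d) else lm(T1 ~ lna, data = d),
    lnb = lm(lnb ~ lna + X1, data = d),
    T2 = lm(T2 ~ T1, data = d)
  )
  for (nm in names(fits)) {
    if (any(is.na(coef(fits[[nm]])))) {
      abort(sprintf("Rank-deficient design in the %s equation.",
                    c(lna = "ln(a)", T1 = "T1", lnb = "ln(b)", T2 = "T2")[nm]))
    }
  }
  cf <- lapply(fits, coef)
  sig <- vapply(fits, sigma, numeric(1))
  regression <- list(
    b1 = unname(cf$lna[1]), b10 = unname(cf$lna[2]),
    b2 = unname(cf$T1[1]), b21 = unname(cf$T1[2]),
    b4 = unname(cf$lnb[1]), b41 = unname(cf$lnb[2]), b43 = unname(cf$lnb[3]),
    b5 = unname(cf$T2[1]), b52 = unname(cf$T2[2]),
    s_a = unname(sig["lna"]), s_T1 = unname(sig["T1"]),
    s_b = unname(sig["lnb"]), s_T2 = unname(sig["T2"]),
    t1_link = t1_link, noise_convention = "sd"
  )
  structure(
    list(fits = fits, regression = regression, t1_link = t1_link,
         n = nrow(features),
         dispersion_sd = setNames(unname(sig), c("s_a", "s_T1", "s_b", "s_T2")),
         dispersion_var = setNames(unname(sig^2), c("s_a", "s_T1", "s_b", "s_T2"))),
    class = "prc1_fit"
  )
}

#' @export
print.prc1_fit <- function(x, ...) {
  cat(sprintf("<prc1_fit> four-equation cycle regression on %d records (T1 %s scale)\n",
              x$n, x$t1_link))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @method tidy prc1_fit
#' @export
tidy.prc1_fit <- function(x, ...) {
  eq_names <- c(lna = "ln(a)",
                T1 = if (x$t1_link == "log") "ln(T1)" else "T1",
                lnb = "ln(b)", T2 = "T2")
  purrr::map_dfr(names(x$fits), function(nm) {
    s <- summary(x$fits[[nm]])$coefficients
    term <- rownames(s)
    term[term == "lna"] <- "ln(a)"
    tibble(equation = eq_names[[nm]], term = term,
           estimate = s[, 1], std.error = s[, 2],
           statistic = s[, 3], p.value = s[, 4])
  })
}

#' @method glance prc1_fit
#' @export
glance.prc1_fit <- function(x, ...) {
  tibble(
    n = x$n, t1_link = x$t1_link,
    s_a = x$dispersion_sd[["s_a"]], s_T1 = x$dispersion_sd[["s_T1"]],
    s_b = x$dispersion_sd[["s_b"]], s_T2 = x$dispersion_sd[["s_T2"]],
    r2_a = summary(x$fits$lna)$r.squared,
    r2_T1 = summary(x$fits$T1)$r.squared,
    r2_b = summary(x$fits$lnb)$r.squared,
    r2_T2 = summary(x$fits$T2)$r.squared
  )
}

#' Assemble a simulable parameter object from fitted components
#'
#' @param fit A `prc1_fit` from [fit_regressions()].
#' @param division A `prc1_division` (e.g. from
#'   [estimate_division_asymmetry()]) or a single `alpha` value.
#' @param data_set Optional integer label.
#' @param noise_convention `"sd"` (default) or `"var"` for how the stored
#'   dispersions are to be read.
#' @return A validated [prc1_params] object.
#' @export
fitted_params <- function(fit, division, data_set = NA_integer_,
                          noise_convention = c("sd", "var")) {
  noise_convention <- match.arg(noise_convention)
  stopifnot(inherits(fit, "prc1_fit"))
  alpha <- if (is.numeric(division)) division else division$alpha
  reg <- fit$regression
  if (noise_convention == "var") {
    reg[c("s_a", "s_T1", "s_b", "s_T2")] <- as.list(fit$dispersion_var)
    reg$noise_convention <- "var"
  }
  validate_params(new_prc1_params(data_set, reg, list(alpha = alpha)))
}

#' Estimate the division-asymmetry Beta parameter
#'
#' Under balanced exponential growth the birth amount is X0 = U X2 with U
#' independent of X2, which ties the coefficients of variation together as
#' \deqn{cv_U^2 = (cv_{X_0}^2 - cv_{X_2}^2) / (cv_{X_2}^2 + 1).}
#' With E(U) = 1/2 this gives V(U) = cv_U^2 / 4, and inverting
#' V(U) = 1/(8 alpha + 4) yields the Beta shape
#' alpha = (1 / V(U) - 4) / 8.
#'
#' @param features Cycle-record tibble with `X0` and `X2` (>= 30 rows).
#' @return A `prc1_division` object carrying `alpha` plus the intermediate
#'   `cv_X0`, `cv_X2`, `cv_U2` and `V_U`.
#' @export
estimate_division_asymmetry <- function(features) {
  stopifnot(all(c("X0", "X2") %in% names(features)))
  if (nrow(features) < 30) abort("Need at least 30 records.")
  cv0 <- sd(features$X0) / mean(features$X0)
  cv2 <- sd(features$X2) / mean(features$X2)
  cv_u2 <- (cv0^2 - cv2^2) / (cv2^2 + 1)
  if (cv_u2 <= 0) {
    abort(sprintf(
      "Division asymmetry unidentifiable: cv(X0) = %.4f <= cv(X2) = %.4f gives a non-positive cv_U^2.",
      cv0, cv2))
  }
  v_u <- cv_u2 / 4
  structure(
    list(alpha = (1 / v_u - 4) / 8, cv_X0 = cv0, cv_X2 = cv2,
         cv_U2 = cv_u2, V_U = v_u, n = nrow(features)),
    class = "prc1_division"
  )
}

#' @export
print.prc1_division <- function(x, ...) {
  cat(sprintf("<prc1_division> U ~ Beta(%.4g, %.4g), V(U) = %.5g\n",
              x$alpha, x$alpha, beta_split_variance(x$alpha)))
  if (!is.null(x$cv_X0)) {
    cat(sprintf("  estimated from cv(X0) = %.4f, cv(X2) = %.4f (n = %d)\n",
                x$cv_X0, x$cv_X2, x$n))
  }
  invisible(x)
}

#' @method tidy prc1_division
#' @export
tidy.prc1_division <- function(x, ...) {
  tibble(alpha = x$alpha, V_U = beta_split_variance(x$alpha),
         cv_X0 = x$cv_X0 %||% NA_real_, cv_X2 = x$cv_X2 %||% NA_real_,
         n = x$n %||% NA_integer_)
}

corr_variables <- c("X0", "X1", "X2", "T1", "T2", "T1+T2",
                    "a", "ln(a)", "b", "ln(b)")

#' Pairwise correlation table of the cycle variables
#'
#' Pearson correlations over the ten variables X0, X1, X2, T1, T2, T1+T2, a,
#' ln(a), b, ln(b), computed on the same record set. Zero-variance variables
#' give undefined (NA) entries, never 0.
#'
#' @param features Cycle-record tibble (>= 3 rows, positive `a` and `b`).
#' @return A 10 x 10 correlation matrix of class `prc1_corr`. `tidy()` gives
#'   the lower triangle in long form.
#' @export
correlation_table <- function(features) {
  if (nrow(features) < 3) abort("Need at least 3 records.")
  if (any(features$a <= 0) || any(features$b <= 0)) {
    abort("`a` and `b` must be positive for the logged variables.")
  }
  m <- cbind(X0 = features$X0, X1 = features$X1, X2 = features$X2,
             T1 = features$T1, T2 = features$T2,
             `T1+T2` = features$T1 + features$T2,
             a = features$a, `ln(a)` = log(features$a),
             b = features$b, `ln(b)` = log(features$b))
  sds <- apply(m, 2, sd)
  cc <- suppressWarnings(cor(m))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- ifelse(sds == 0, NA_real_, 1)
  structure(cc, class = c("prc1_corr", class(cc)))
}

#' @export
print.prc1_corr <- function(x, digits = 2, ...) {
  cat("<prc1_corr> pairwise Pearson correlations (lower triangle)\n")
  m <- unclass(x)
  m[upper.tri(m, diag = TRUE)] <- NA
  out <- format(round(m, digits))
  out[is.na(m)] <- ""
  print(out[-1, -ncol(m), drop = FALSE], quote = FALSE)
  invisible(x)
}

#' @method tidy prc1_corr
#' @export
tidy.prc1_corr <- function(x, ...) {
  m <- unclass(x)
  lower <- which(lower.tri(m), arr.ind = TRUE)
  tibble(var1 = rownames(m)[lower[, 1]], var2 = colnames(m)[lower[, 2]],
         r = m[lower])
}

#' Write / read a correlation table as lower-triangular TSV
#'
#' The layout mirrors the printed correlation tables: one row per variable
#' from X1 down, one column per variable from X0 up, upper entries empty.
#'
#' @param corr A `prc1_corr` matrix.
#' @param path File path.
#' @return `path` invisibly (writer); a `prc1_corr` matrix (reader).
#' @export
write_correlation_tsv <- function(corr, path) {
  m <- unclass(corr)
  m[upper.tri(m, diag = TRUE)] <- NA
  df <- as_tibble(m[-1, -ncol(m), drop = FALSE])
  df <- dplyr::bind_cols(tibble(variable = rownames(m)[-1]), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_correlation_tsv
#' @export
read_correlation_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  vars <- c(names(df)[2], df$variable)
  m <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_len(nrow(df))) {
    for (j in seq(2, ncol(df))) {
      m[df$variable[i], names(df)[j]] <- as.numeric(df[[j]][i])
    }
  }
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 1
  structure(m, class = c("prc1_corr", class(m)))
}
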