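# Dissociation-constant estimation from titration band intensities.
#
# The model is the one-site Hill isotherm
#   f(c) = f0 + A * c^n / (Kd^n + c^n),  n = 1 by default,
# fitted by least squares to per-site band intensities normalized to
# fraction-modulated. For fixed n = 1 the problem is separable: at any Kd the
# baseline f0 and amplitude A solve a linear least-squares problem, so the
# fit profiles the residual sum of squares over log(Kd) (variable
# projection) and optimizes that one-dimensional profile — deterministic,
# scale-equivariant, and free of nonlinear-solver tuning. The standard error
# of Kd comes from the Jacobian-based parameter covariance at the optimum
# ("goodness of fit to a sigmoidal curve"). Freeing the Hill exponent falls
# back to Levenberg-Marquardt.

#' Normalize titration band intensities to fraction modulated
#'
#' Per site, maps intensities to `(I - I_min) / (I_max - I_min)`, inverting
#' decreasing sites so that 1 always corresponds to the fully ligand-bound
#' state. Constant sites (no dynamic range) are dropped with a warning.
#'
#' @param series Tibble with columns `concentration_M`, `site_id`,
#'   `intensity`, `direction` (`"increase"` or `"decrease"`).
#' @return The series with a `fraction_modulated` column, constant sites
#'   removed.
#' @export
normalize_sites <- function(series) {
  stopifnot(all(c("concentration_M", "site_id", "intensity", "direction")
                %in% names(series)))
  out <- series %>%
    group_by(.data$site_id) %>%
    mutate(
      .range = max(.data$intensity) - min(.data$intensity),
      fraction_modulated = ifelse(
        .data$.range == 0, NA_real_,
        (.data$intensity - min(.data$intensity)) / .data$.range
      )
    ) %>%
    ungroup()
  out <- out %>%
    mutate(fraction_modulated = ifelse(.data$direction == "decrease",
                                       1 - .data$fraction_modulated,
                                       .data$fraction_modulated))
  dropped <- unique(out$site_id[out$.range == 0])
  if (length(dropped) > 0) {
    warn(sprintf("dropped constant site(s): %s",
                 paste(dropped, collapse = ", ")))
    out <- out[!out$site_id %in% dropped, ]
  }
  select(out, -".range")
}

#' Fit a dissociation constant to titration data
#'
#' Fits `f(c) = f0 + A * c^n / (Kd^n + c^n)` (n = 1 unless `free_hill`) to
#' fraction-modulated band intensities by nonlinear least squares
#' (Levenberg-Marquardt, with bounded restarts from perturbed starting
#' values). By default all sites' normalized points are pooled into one fit.
#' Concentrations are rescaled internally by their geometric mean, so the fit
#' is scale-equivariant; `kd` and `kd_se` are reported on the input (molar)
#' scale. Initialization: Kd at the geometric mean of the non-zero tested
#' concentrations, `f0` at the minimum, amplitude at the range.
#'
#' @param series Tibble as in [normalize_sites()] (raw intensities), or one
#'   already carrying a `fraction_modulated` column.
#' @param pool_sites Pool all sites into a single fit (default). With
#'   `FALSE`, each site is fitted separately and a list of fits is returned.
#' @param free_hill Also estimate the Hill exponent `n`.
#' @return A `binding_fit` object with elements `kd`, `kd_se`, `f0`,
#'   `amplitude`, `hill`, `rss`, `n_points`, `flags`, `data`, `fit`.
#' @export
#' @examples
#' conc <- 3.44e-7 * 10^seq(-2, 2, length.out = 8)
#' ser <- synth_titration(kd = 3.44e-7, concentrations = conc, noise_sd = 0)
#' fit_kd(ser)
fit_kd <- function(series, pool_sites = TRUE, free_hill = FALSE) {
  if (!"fraction_modulated" %in% names(series)) {
    series <- normalize_sites(series)
  }
  series <- series[!is.na(series$fraction_modulated), ]
  if (nrow(series) == 0) {
    abort("no usable sites after normalization", class = "selexr_fit_error")
  }
  if (!pool_sites) {
    fits <- lapply(split(series, series$site_id), fit_kd,
                   pool_sites = TRUE, free_hill = free_hill)
    return(fits)
  }
  conc <- series$concentration_M
  y <- series$fraction_modulated
  nz <- conc[conc > 0]
  if (length(unique(nz)) < 4) {
    abort("need >= 4 distinct non-zero concentrations",
          class = "selexr_argument_error")
  }
  g <- exp(mean(log(nz)))        # geometric mean: internal concentration unit
  cs <- conc / g
  est <- if (free_hill) {
    fit_hill_lm(cs, y)
  } else {
    fit_varpro_n1(cs, y)
  }
  kd <- est$kd * g
  kd_se <- est$kd_se * g
  flags <- character()
  rng <- range(nz)
  if (kd > 100 * rng[2] || kd < rng[1] / 100) {
    flags <- c(flags, "poorly_constrained")
    warn(sprintf(
      "fitted Kd (%.3g M) lies > 100x outside the tested range [%.3g, %.3g]",
      kd, rng[1], rng[2]
    ))
  }
  if (abs(est$A) < 1e-8) flags <- c(flags, "zero_amplitude")
  params <- tibble(
    term = c("kd", "f0", "A", if (free_hill) "n"),
    estimate = c(kd, est$f0, est$A, if (free_hill) est$n),
    std.error = c(kd_se, est$f0_se, est$A_se, if (free_hill) est$n_se)
  )
  structure(
    list(
      kd = kd,
      kd_se = kd_se,
      f0 = est$f0,
      amplitude = est$A,
      hill = if (free_hill) est$n else 1,
      rss = est$rss,
      n_points = length(y),
      flags = flags,
      params = params,
      data = as_tibble(series)
    ),
    class = "binding_fit"
  )
}

# variable-projection fit of y = f0 + A*c/(kd + c) on the rescaled
# concentration axis: profile the RSS over log(kd), where f0 and A are the
# exact linear least-squares solution at each kd
fit_varpro_n1 <- function(cs, y) {
  profile_rss <- function(lk) {
    th <- cs / (exp(lk) + cs)
    sum(stats::lm.fit(cbind(1, th), y)$residuals^2)
  }
  nz <- cs[cs > 0]
  lo <- log(min(nz)) - log(1e6)
  hi <- log(max(nz)) + log(1e6)
  grid <- seq(lo, hi, length.out = 240)
  rssg <- vapply(grid, profile_rss, 0)
  i <- which.min(rssg)
  opt <- stats::optimize(profile_rss,
                         c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                         tol = 1e-11)
  kd <- exp(opt$minimum)
  th <- cs / (kd + cs)
  lin <- stats::lm.fit(cbind(1, th), y)
  f0 <- unname(lin$coefficients[1])
  A <- unname(lin$coefficients[2])
  rss <- sum(lin$residuals^2)
  # Jacobian-based covariance at the optimum; parameters (f0, A, kd)
  J <- cbind(1, th, -A * cs / (kd + cs)^2)
  dof <- max(1L, length(y) - 3L)
  cov <- tryCatch(rss / dof * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, 3) else sqrt(pmax(0, diag(cov)))
  list(kd = kd, kd_se = se[3], f0 = f0, f0_se = se[1], A = A, A_se = se[2],
       rss = rss)
}

# free-Hill fallback: Levenberg-Marquardt with bounded restarts
fit_hill_lm <- function(cs, y) {
  df <- data.frame(cs = cs, y = y)
  fit <- NULL
  errs <- character()
  for (kd0 in c(1, 0.1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ f0 + A * cs^n / (kd^n + cs^n), data = df,
        start = list(kd = kd0, f0 = min(y), A = max(y) - min(y), n = 1),
        lower = c(kd = 1e-12, f0 = -Inf, A = -Inf, n = 0.1),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                             ptol = 1e-13)
      ),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("Kd fit did not converge after restarts: ",
                 paste(unique(errs), collapse = "; ")),
          class = "selexr_fit_error")
  }
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    setNames(rep(NA_real_, 4), names(est)))
  list(kd = unname(est["kd"]), kd_se = unname(se["kd"]),
       f0 = unname(est["f0"]), f0_se = unname(se["f0"]),
       A = unname(est["A"]), A_se = unname(se["A"]),
       n = unname(est["n"]), n_se = unname(se["n"]),
       rss = deviance(fit))
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g +/- %.3g M (n = %g, %d points)\n",
              x$kd, x$kd_se, x$hill, x$n_points))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a binding fit into a parameter table
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.binding_fit <- function(x, ...) {
  x$params
}

#' One-row summary of a binding fit
#'
#' @param x A `binding_fit`.
#' @param ... Unused.
#' @return One-row tibble: `kd`, `kd_se`, `f0`, `amplitude`, `hill`, `rss`,
#'   `n_points`, `flags`.
#' @export
glance.binding_fit <- function(x, ...) {
  tibble(
    kd = x$kd, kd_se = x$kd_se, f0 = x$f0, amplitude = x$amplitude,
    hill = x$hill, rss = x$rss, n_points = x$n_points,
    flags = paste(x$flags, collapse = ";")
  )
}
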