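#' Continuous piecewise-linear (breakpoint) regression
#'
#' Fits `y = b0 + b1 * x + sum_j d_j * (x - psi_j)_+` with one or two
#' breakpoints by exhaustive profile-RSS grid search over the breakpoint
#' bounds, followed by local golden-section/Brent polishing of each
#' breakpoint.  For the small designs typical of stepped-temperature
#' metabolic trials (8 test temperatures) the grid search guarantees the
#' global profile optimum, which iterative linearization cannot.
#'
#' Slope standard errors come from the linear fit at the optimal
#' breakpoints; breakpoint standard errors use the segmented-regression
#' delta method `SE(psi_j) = SE(gamma_j) / |d_j|`, where `gamma_j` is the
#' coefficient of the gap covariate `-1(x > psi_j)` added to the final
#' fit.
#'
#' @param x predictor (ambient temperature, degrees C).
#' @param y response (a metabolic or water-loss rate).
#' @param n_breakpoints 1 or 2.
#' @param bounds numeric vector `c(lo, hi)` for one breakpoint, or a list
#'   of two such vectors for two breakpoints.  Must lie inside the range
#'   of `x`; for two breakpoints the intervals must not overlap.
#' @param grid_step grid resolution, same units as `x`.
#' @param polish refine the grid optimum by bounded 1-D minimization
#'   (coordinate-wise for two breakpoints).
#' @return object of class `piecewise_fit`: list with `psi`, `psi_se`,
#'   `coefficients` (b0, b1, gap coefficients d), `slopes` (per-segment
#'   slopes) with `slope_se`, `rss`, `n`, `n_breakpoints`, `converged`,
#'   `method`, `fitted`, plus the inputs.
#' @export
fit_piecewise <- function(x, y, n_breakpoints = 1, bounds,
                          grid_step = 0.05, polish = TRUE) {
  stopifnot(length(x) == length(y))
  ord <- order(x)
  x <- as.numeric(x[ord])
  y <- as.numeric(y[ord])
  n <- length(x)
  if (n < 2 * n_breakpoints + 3) {
    stop("too few points to identify the breakpoints", call. = FALSE)
  }
  if (n_breakpoints == 1 && is.numeric(bounds)) bounds <- list(bounds)
  if (length(bounds) != n_breakpoints) {
    stop("one bounds interval per breakpoint required", call. = FALSE)
  }
  rng <- range(x)
  for (b in bounds) {
    if (b[1] >= b[2] || b[1] < rng[1] || b[2] > rng[2]) {
      stop("breakpoint bounds must be ordered and inside the x-range",
           call. = FALSE)
    }
  }
  if (n_breakpoints == 2 && bounds[[1]][2] > bounds[[2]][1]) {
    stop("breakpoint bounds must not overlap", call. = FALSE)
  }

  if (n_breakpoints == 1) {
    grid <- seq(bounds[[1]][1], bounds[[1]][2], by = grid_step)
    rss <- rss_profile_1bp(x, y, grid)
    psi <- grid[pick_grid_min(rss, grid, mean(bounds[[1]]))]
  } else {
    g1 <- seq(bounds[[1]][1], bounds[[1]][2], by = grid_step)
    g2 <- seq(bounds[[2]][1], bounds[[2]][2], by = grid_step)
    rssm <- rss_profile_2bp(x, y, g1, g2)
    best <- pick_grid_min_2d(rssm, g1, g2,
                             c(mean(bounds[[1]]), mean(bounds[[2]])))
    psi <- c(g1[best[1]], g2[best[2]])
  }

  if (polish) psi <- polish_psi(x, y, psi, bounds, grid_step)
  finalize_piecewise(x, y, psi, bounds, grid_step, method = "grid")
}

# index of the grid minimum; ties (within 1e-12) broken toward the
# midpoint of the bounds, then earliest.
pick_grid_min <- function(rss, grid, mid) {
  cand <- which(rss <= min(rss) + 1e-12)
  cand[which.min(abs(grid[cand] - mid))]
}

pick_grid_min_2d <- function(rssm, g1, g2, mids) {
  m <- min(rssm)
  cand <- which(rssm <= m + 1e-12, arr.ind = TRUE)
  d <- abs(g1[cand[, 1]] - mids[1]) + abs(g2[cand[, 2]] - mids[2])
  cand[which.min(d), ]
}

polish_psi <- function(x, y, psi, bounds, grid_step) {
  for (rep in 1:2) {
    for (j in seq_along(psi)) {
      lo <- max(bounds[[j]][1], psi[j] - grid_step)
      hi <- min(bounds[[j]][2], psi[j] + grid_step)
      if (length(psi) == 2) {
        if (j == 1) hi <- min(hi, psi[2] - 1e-6)
        if (j == 2) lo <- max(lo, psi[1] + 1e-6)
      }
      f <- function(p) {
        q <- psi
        q[j] <- p
        rss_at_psi(x, y, q)
      }
      opt <- optimize(f, c(lo, hi), tol = 1e-7)
      if (opt$objective <= rss_at_psi(x, y, psi)) psi[j] <- opt$minimum
    }
    if (length(psi) == 1) break
  }
  psi
}

design_hinge <- function(x, psi) {
  X <- cbind(1, x)
  for (p in psi) X <- cbind(X, pmax(x - p, 0))
  X
}

finalize_piecewise <- function(x, y, psi, bounds, grid_step, method,
                               iterations = NA_integer_,
                               converged_hint = TRUE) {
  n <- length(x)
  nbp <- length(psi)
  X <- design_hinge(x, psi)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  p <- ncol(X)
  sigma2 <- rss / max(n - p, 1)
  xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  beta_se <- if (is.null(xtx_inv)) rep(NA_real_, p) else
    sqrt(pmax(diag(xtx_inv), 0) * sigma2)

  deltas <- beta[-(1:2)]
  yscale <- max(sd(y), 1e-6 * max(abs(y)), 1e-12)
  counts <- segment_counts(x, psi)
  converged <- converged_hint &&
    all(counts >= 2) &&
    all(abs(deltas) > 1e-8 * yscale) &&
    is.finite(rss)

  # delta-method SE of each breakpoint via the gap covariate -1(x > psi)
  psi_se <- rep(NA_real_, nbp)
  if (converged && n > p + nbp) {
    Xg <- X
    for (p_j in psi) Xg <- cbind(Xg, -(x > p_j))
    gfit <- lm.fit(Xg, y)
    g_rss <- sum(gfit$residuals^2)
    g_sigma2 <- g_rss / max(n - ncol(Xg), 1)
    g_inv <- tryCatch(solve(crossprod(Xg)), error = function(e) NULL)
    if (!is.null(g_inv)) {
      g_se <- sqrt(pmax(diag(g_inv), 0) * g_sigma2)
      psi_se <- g_se[p + seq_len(nbp)] / abs(deltas)
    }
  }

  slopes <- cumsum(c(beta[2], deltas))
  slope_se <- vapply(seq_len(nbp + 1), function(k) {
    a <- c(0, 1, rep(1, k - 1), rep(0, nbp - k + 1))[seq_len(p)]
    if (is.null(xtx_inv)) NA_real_ else
      sqrt(max(drop(t(a) %*% xtx_inv %*% a), 0) * sigma2)
  }, numeric(1))

  structure(list(
    psi = unname(psi), psi_se = unname(psi_se),
    coefficients = setNames(unname(beta),
                            c("intercept", "x",
                              paste0("gap", seq_len(nbp)))),
    coef_se = unname(beta_se),
    slopes = unname(slopes), slope_se = slope_se,
    intercept = unname(beta[1]),
    rss = rss, n = n, n_breakpoints = nbp,
    converged = converged, method = method, iterations = iterations,
    bounds = bounds, grid_step = grid_step,
    x = x, y = y, fitted = drop(X %*% beta)
  ), class = "piecewise_fit")
}

segment_counts <- function(x, psi) {
  brk <- c(-Inf, sort(psi), Inf)
  as.vector(table(cut(x, brk)))
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Continuous piecewise-linear fit (%d breakpoint%s, %s)\n",
              x$n_breakpoints, if (x$n_breakpoints > 1) "s" else "",
              x$method))
  cat(sprintf("  psi: %s\n",
              paste(sprintf("%.3f (SE %.3f)", x$psi, x$psi_se),
                    collapse = ", ")))
  cat(sprintf("  slopes: %s\n",
              paste(sprintf("%.4f", x$slopes), collapse = ", ")))
  cat(sprintf("  RSS %.6g on n = %d; converged: %s\n",
              x$rss, x$n, x$converged))
  invisible(x)
}

#' Iterative linearization refit of breakpoints
#'
#' The classic segmented-regression iteration: at the current breakpoints
#' fit the linear model with hinge covariates `(x - psi)_+` and gap
#' covariates `-1(x > psi)`, then update `psi <- psi + gamma / d` until
#' the update is below `tol` or `max_iter` is reached.  Faster than the
#' grid for large n but can diverge on small or flat data, in which case
#' the fit is flagged non-converged and the caller should fall back to
#' [fit_piecewise()].
#'
#' @param x,y data.
#' @param psi_init starting breakpoint(s), inside the range of `x`.
#' @param tol convergence tolerance on the breakpoint update (degrees C).
#' @param max_iter iteration cap.
#' @return a `piecewise_fit` (method `"iterative"`).
#' @export
iterative_refit <- function(x, y, psi_init, tol = 1e-4, max_iter = 50) {
  ord <- order(x)
  x <- as.numeric(x[ord])
  y <- as.numeric(y[ord])
  rng <- range(x)
  if (any(psi_init <= rng[1] | psi_init >= rng[2])) {
    stop("psi_init must lie strictly inside the x-range", call. = FALSE)
  }
  psi <- sort(as.numeric(psi_init))
  nbp <- length(psi)
  ok <- FALSE
  it <- 0L
  yscale <- max(sd(y), 1e-6 * max(abs(y)), 1e-12)
  for (it in seq_len(max_iter)) {
    X <- design_hinge(x, psi)
    for (p_j in psi) X <- cbind(X, -(x > p_j))
    fit <- tryCatch(lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta <- fit$coefficients
    deltas <- beta[2 + seq_len(nbp)]
    gammas <- beta[2 + nbp + seq_len(nbp)]
    if (any(abs(deltas) < 1e-8 * yscale)) break
    step <- gammas / deltas
    psi_new <- psi + step
    if (any(psi_new <= rng[1] | psi_new >= rng[2]) ||
        (nbp == 2 && diff(psi_new) <= 0)) {
      break
    }
    psi <- psi_new
    if (max(abs(step)) < tol) {
      ok <- TRUE
      break
    }
  }
  bounds <- lapply(psi, function(p) rng)
  finalize_piecewise(x, y, psi, bounds, grid_step = NA_real_,
                     method = "iterative", iterations = it,
                     converged_hint = ok)
}

#' Thermoneutral zone estimate from a two-breakpoint fit
#'
#' `Tlc` and `Tuc` are the lower and upper breakpoints of the VO2 fit,
#' breadth is their difference, and BMR is the mean of the observed VO2
#' at test temperatures lying inside the fitted zone (falling back to the
#' fitted plateau value, flagged, if no observation lands inside).
#'
#' @param fit a converged two-breakpoint `piecewise_fit` on VO2 vs Ta.
#' @param profile data frame with columns `Ta` and `VO2` for the same
#'   individual.
#' @param id identifier copied into the output.
#' @return one-row data frame: `id`, `Tlc`, `Tuc`, `breadth`, `BMR`,
#'   `Tlc_se`, `Tuc_se`, `bmr_from_plateau`, `converged`.
#' @export
tnz_from_fit <- function(fit, profile, id = NA_character_) {
  stopifnot(inherits(fit, "piecewise_fit"))
  if (fit$n_breakpoints != 2) {
    stop("a two-breakpoint fit is required", call. = FALSE)
  }
  tlc <- fit$psi[1]
  tuc <- fit$psi[2]
  inside <- profile$Ta >= tlc & profile$Ta <= tuc
  from_plateau <- !any(inside)
  bmr <- if (from_plateau) {
    mid <- mean(c(tlc, tuc))
    fit$intercept + fit$coefficients["x"] * mid +
      fit$coefficients["gap1"] * max(mid - tlc, 0)
  } else {
    mean(profile$VO2[inside])
  }
  data.frame(id = id, Tlc = tlc, Tuc = tuc, breadth = tuc - tlc,
             BMR = unname(bmr),
             Tlc_se = fit$psi_se[1], Tuc_se = fit$psi_se[2],
             bmr_from_plateau = from_plateau,
             converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Evaporative water loss inflection point
#'
#' @param fit a one-breakpoint `piecewise_fit` on EWL vs Ta.
#' @return list with `inflection` (degrees C), `se` and `converged`;
#'   `inflection` is `NA` when the fit did not converge (e.g. flat EWL).
#' @export
ewl_inflection <- function(fit) {
  stopifnot(inherits(fit, "piecewise_fit"))
  if (fit$n_breakpoints != 1) {
    stop("a one-breakpoint fit is required", call. = FALSE)
  }
  if (!fit$converged) {
    return(list(inflection = NA_real_, se = NA_real_, converged = FALSE))
  }
  list(inflection = fit$psi[1], se = fit$psi_se[1], converged = TRUE)
}

#' Per-individual TNZ and EWL-inflection fits for a population
#'
#' Runs the two-breakpoint VO2 fit and the one-breakpoint EWL fit for
#' every individual in a long profile table.
#'
#' @param profiles data frame with columns `id`, `Ta`, `VO2`, `EWL`.
#' @param vo2_bounds list of two bounds intervals for `Tlc` and `Tuc`.
#' @param ewl_bounds bounds interval for the EWL inflection.
#' @param grid_step grid resolution, degrees C.
#' @return data frame, one row per individual: the [tnz_from_fit()]
#'   columns plus `ewl_infl`, `ewl_infl_se`, `ewl_converged`.
#' @export
fit_population <- function(profiles,
                           vo2_bounds = list(c(12, 28), c(28, 38)),
                           ewl_bounds = c(28, 38),
                           grid_step = 0.05) {
  out <- lapply(split(profiles, profiles$id), function(pr) {
    f2 <- fit_piecewise(pr$Ta, pr$VO2, 2, vo2_bounds, grid_step)
    tnz <- tnz_from_fit(f2, pr, id = pr$id[1])
    f1 <- fit_piecewise(pr$Ta, pr$EWL, 1, ewl_bounds, grid_step)
    infl <- ewl_inflection(f1)
    tnz$ewl_infl <- infl$inflection
    tnz$ewl_infl_se <- infl$se
    tnz$ewl_converged <- infl$converged
    tnz
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population summary of per-individual estimates
#'
#' Arithmetic mean and standard error (SD / sqrt(n)) of each numeric
#' estimate over the individuals whose fit converged.
#'
#' @param estimates output of [fit_population()] (or any data frame with
#'   a logical `converged` column and numeric estimate columns).
#' @param columns which columns to summarize.
#' @return data frame with `quantity`, `mean`, `se`, `n`, `n_excluded`.
#' @export
population_summary <- function(estimates,
                               columns = c("Tlc", "Tuc", "breadth", "BMR",
                                           "ewl_infl")) {
  conv <- if ("converged" %in% names(estimates)) estimates$converged else
    rep(TRUE, nrow(estimates))
  if (sum(conv) < 2) {
    stop("fewer than 2 converged individuals", call. = FALSE)
  }
  columns <- intersect(columns, names(estimates))
  rows <- lapply(columns, function(cl) {
    v <- estimates[[cl]][conv]
    v <- v[is.finite(v)]
    data.frame(quantity = cl, mean = mean(v),
               se = sd(v) / sqrt(length(v)),
               n = length(v), n_excluded = nrow(estimates) - length(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
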