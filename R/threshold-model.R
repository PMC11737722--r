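# Piecewise linear threshold (hinge) dose-response model and its
# grid-search estimation machinery.
#
# The model: the expected change dy is zero while both the rotation
# amplitude Theta (degrees) and the peak angular velocity Phi
# (degrees/s) remain below their respective thresholds, and grows
# linearly in each supra-threshold excess:
#
#   E[dy] = c1 * (Theta - Theta0)_+  +  c2 * (Phi - Phi0)_+
#
# For a postulated threshold pair the model is linear in (c1, c2), so
# each grid cell is an ordinary least-squares fit through the origin;
# significance against the null dy == 0 comes from inverting the F
# distribution, and the threshold estimate is the "lowest" significant,
# adequately supported pair on the grid.

#' Piecewise linear threshold model mean
#'
#' Evaluates the four-branch hinge mean exactly: 0 below both
#' thresholds, `c1 (Theta - Theta0)` when only the amplitude threshold
#' is met, `c2 (Phi - Phi0)` when only the velocity threshold is met,
#' and the sum when both are.  The boundary `Theta == Theta0` (and
#' likewise for Phi) belongs to the supra-threshold branch, where the
#' excess is zero, so the mean is continuous everywhere.
#'
#' @param theta rotation amplitude(s), degrees.
#' @param phi peak angular velocity(ies), degrees/s.
#' @param theta0,phi0 thresholds.
#' @param c1,c2 slopes per degree and per degree/s.
#' @param fit optionally, a `threshold_fit` whose parameters are used
#'   instead of the scalar arguments.
#' @return Numeric vector of model means.
#' @export
eq1_mean <- function(theta, phi, theta0, phi0, c1, c2 = 0, fit = NULL) {
  if (!is.null(fit)) {
    theta0 <- fit$theta0; phi0 <- fit$phi0
    c1 <- if (is.na(fit$c1)) 0 else fit$c1
    c2 <- if (is.na(fit$c2)) 0 else fit$c2
  }
  c1 * pmax(theta - theta0, 0) + c2 * pmax(phi - phi0, 0)
}

#' Build the hinge design matrix for one postulated threshold pair
#'
#' Regressors are the supra-threshold excesses `(Theta - theta0)_+` and
#' `(Phi - phi0)_+` with no intercept (the sub-threshold mean is fixed
#' at zero by the model).  Columns that are identically zero (no
#' supra-threshold observations) are dropped; near-collinear column
#' pairs (correlation above `collinear_tol`, as happens when the dose
#' design couples velocity proportionally to amplitude) collapse to the
#' amplitude hinge alone and the fit is flagged non-identifiable.
#'
#' @param records dose-response data frame with columns `theta_deg`,
#'   `phi_deg_s` (or `theta`, `phi`).
#' @param theta0,phi0 postulated thresholds.
#' @param collinear_tol correlation above which the two hinges are
#'   treated as one.
#' @return List: `X` (n x q matrix, possibly zero columns), `cols`
#'   (which of c("theta","phi") were retained), `n_supra_theta`,
#'   `n_supra_phi`, `identifiable`.
#' @export
build_design <- function(records, theta0, phi0, collinear_tol = 0.99) {
  th <- records$theta_deg %||% records$theta
  ph <- records$phi_deg_s %||% records$phi
  if (is.null(th) || is.null(ph) || length(th) == 0L)
    stop("build_design: records need theta/phi dose columns")
  x1 <- pmax(th - theta0, 0)
  x2 <- pmax(ph - phi0, 0)
  n_supra_theta <- sum(x1 > 0)
  n_supra_phi <- sum(x2 > 0)
  have1 <- any(x1 > 0); have2 <- any(x2 > 0)
  identifiable <- TRUE
  if (have1 && have2) {
    r <- suppressWarnings(stats::cor(x1, x2))
    if (!is.na(r) && abs(r) > collinear_tol) {
      # proportional dosing: the two hinges carry the same information;
      # refit on the amplitude hinge alone
      X <- cbind(theta = x1)
      identifiable <- FALSE
    } else X <- cbind(theta = x1, phi = x2)
  } else if (have1) X <- cbind(theta = x1)
  else if (have2) X <- cbind(phi = x2)
  else X <- matrix(numeric(0), nrow = length(x1), ncol = 0)
  list(X = X, cols = colnames(X),
       n_supra_theta = n_supra_theta, n_supra_phi = n_supra_phi,
       identifiable = identifiable)
}

#' Fit the threshold model at one postulated (theta0, phi0) pair
#'
#' Ordinary least squares of the outcome on the retained hinge columns
#' (no intercept), tested against the null model `dy == 0` with
#' \deqn{F = \frac{(RSS_0 - RSS_1)/q}{RSS_1/(n-q)},\qquad RSS_0=\sum dy^2,}
#' and `p` from the upper tail of `F(q, n - q)`.  Cells with no
#' supra-threshold observations, or without a residual degree of
#' freedom, report `p = 1` and are flagged unsupported.
#'
#' @inheritParams build_design
#' @param outcome `"amplitude"` or `"latency"` (selects `dy_amplitude`
#'   / `dy_latency`), or a numeric vector of responses.
#' @return A `threshold_fit` list: `theta0`, `phi0`, `c1`, `c2`, `rss`,
#'   `df_model`, `df_resid`, `f_stat`, `p_value`, `n_supra_theta`,
#'   `n_supra_phi`, `identifiable`, `supported`.
#' @export
fit_cell <- function(records, theta0, phi0,
                     outcome = c("amplitude", "latency"),
                     collinear_tol = 0.99) {
  y <- outcome_vector(records, outcome)
  keep <- is.finite(y)
  y <- y[keep]
  records <- records[keep, , drop = FALSE]
  if (length(y) == 0L) stop("fit_cell: no finite responses")
  d <- build_design(records, theta0, phi0, collinear_tol)
  n <- length(y)
  rss0 <- sum(y^2)
  fit <- list(theta0 = theta0, phi0 = phi0,
              c1 = NA_real_, c2 = NA_real_,
              rss = rss0, df_model = 0L, df_resid = n,
              f_stat = NA_real_, p_value = 1,
              n_supra_theta = d$n_supra_theta,
              n_supra_phi = d$n_supra_phi,
              identifiable = d$identifiable, supported = FALSE)
  class(fit) <- "threshold_fit"
  q <- ncol(d$X)
  if (q == 0L) return(fit)
  XtX <- crossprod(d$X)
  # guard against numerically singular two-hinge systems
  if (q == 2L) {
    det2 <- XtX[1, 1] * XtX[2, 2] - XtX[1, 2]^2
    if (det2 <= 1e-12 * XtX[1, 1] * XtX[2, 2]) {
      d$X <- d$X[, 1, drop = FALSE]; d$cols <- colnames(d$X)
      d$identifiable <- FALSE
      fit$identifiable <- FALSE
      XtX <- crossprod(d$X); q <- 1L
    }
  }
  beta <- solve(XtX, crossprod(d$X, y))
  rss1 <- max(rss0 - sum(beta * crossprod(d$X, y)), 0)
  if ("theta" %in% d$cols) fit$c1 <- beta[match("theta", d$cols)]
  if ("phi" %in% d$cols) fit$c2 <- beta[match("phi", d$cols)]
  fit$rss <- rss1
  fit$df_model <- q
  fit$df_resid <- n - q
  if (fit$df_resid < 1L) {
    fit$p_value <- 1
    return(fit)
  }
  fit$supported <- TRUE
  if (rss1 <= 1e-12 * rss0) {
    fit$f_stat <- Inf
    fit$p_value <- if (rss0 > 0) 0 else 1
  } else {
    fit$f_stat <- ((rss0 - rss1) / q) / (rss1 / (n - q))
    fit$p_value <- stats::pf(fit$f_stat, q, n - q, lower.tail = FALSE)
  }
  fit
}

outcome_vector <- function(records, outcome) {
  if (is.numeric(outcome)) return(outcome)
  outcome <- match.arg(outcome, c("amplitude", "latency"))
  col <- if (outcome == "amplitude") "dy_amplitude" else "dy_latency"
  y <- records[[col]] %||% records[[outcome]]
  if (is.null(y)) stop("records lack the '", col, "' column")
  y
}

#' Specify the threshold search grid
#'
#' @param theta_max,phi_max upper bounds of the postulated threshold
#'   ranges (degrees, degrees/s); the search always starts at 0.
#' @param theta_step,phi_step grid resolution.
#' @return A `grid_spec` list with the two axes.
#' @export
grid_spec <- function(theta_max = 45, phi_max = 3500,
                      theta_step = 0.5, phi_step = 25) {
  stopifnot(theta_max > 0, phi_max > 0, theta_step > 0, phi_step > 0)
  structure(list(theta = seq(0, theta_max, by = theta_step),
                 phi = seq(0, phi_max, by = phi_step),
                 theta_max = theta_max, phi_max = phi_max),
            class = "grid_spec")
}

#' Scan the full grid of postulated threshold pairs
#'
#' Evaluates [fit_cell()] at every `(theta0, phi0)` pair on the grid
#' and assembles the p-value and coefficient surfaces.  The
#' computation is vectorised over the grid via the normal-equation
#' cross-products, and agrees cell-for-cell with [fit_cell()].
#'
#' @param records dose-response data frame.
#' @param grid a [grid_spec()].
#' @param outcome `"amplitude"` or `"latency"`.
#' @param collinear_tol hinge-collinearity cutoff, see
#'   [build_design()].
#' @return A `grid_scan` object: `theta_grid`, `phi_grid`, surfaces
#'   `p` (matrix theta x phi), `c1`, `c2`, `rss`, `f`, `supra`
#'   (supra-threshold support counts), `identifiable` (logical
#'   matrix), plus `outcome`, `n`, and the input `grid`.
#' @export
grid_scan <- function(records, grid = grid_spec(),
                      outcome = c("amplitude", "latency"),
                      collinear_tol = 0.99) {
  outcome <- match.arg(outcome)
  y <- outcome_vector(records, outcome)
  keep <- is.finite(y)
  y <- y[keep]
  records <- records[keep, , drop = FALSE]
  if (length(y) == 0L) stop("grid_scan: no finite responses")
  th <- records$theta_deg %||% records$theta
  ph <- records$phi_deg_s %||% records$phi
  n <- length(y)
  tg <- grid$theta; pg <- grid$phi
  gt <- length(tg); gp <- length(pg)

  # hinge matrices: n x gt and n x gp
  T <- pmax(outer(th, tg, "-"), 0)
  P <- pmax(outer(ph, pg, "-"), 0)

  S11 <- colSums(T^2)                 # gt
  S22 <- colSums(P^2)                 # gp
  S1y <- drop(crossprod(T, y))        # gt
  S2y <- drop(crossprod(P, y))        # gp
  S12 <- crossprod(T, P)              # gt x gp
  m1 <- colMeans(T); m2 <- colMeans(P)
  v1 <- S11 - n * m1^2; v2 <- S22 - n * m2^2
  denom <- sqrt(outer(v1, v2))
  corTP <- (S12 - n * outer(m1, m2)) / ifelse(denom > 0, denom, NA)

  have1 <- matrix(S11 > 0, gt, gp)
  have2 <- matrix(S22 > 0, gt, gp, byrow = TRUE)
  rss0 <- sum(y^2)

  # two-hinge solution (normal equations), masked where invalid
  det2 <- outer(S11, S22) - S12^2
  singular <- det2 <= 1e-12 * outer(S11, S22)
  collinear <- (!is.na(corTP) & abs(corTP) > collinear_tol) | singular
  S1yM <- matrix(S1y, gt, gp); S2yM <- matrix(S2y, gt, gp, byrow = TRUE)
  S11M <- matrix(S11, gt, gp); S22M <- matrix(S22, gt, gp, byrow = TRUE)
  both <- have1 & have2 & !collinear
  c1s <- c2s <- rss <- matrix(NA_real_, gt, gp)
  qs <- matrix(0L, gt, gp)
  ident <- matrix(TRUE, gt, gp)

  idx <- both
  c1s[idx] <- (S1yM[idx] * S22M[idx] - S12[idx] * S2yM[idx]) / det2[idx]
  c2s[idx] <- (S2yM[idx] * S11M[idx] - S12[idx] * S1yM[idx]) / det2[idx]
  rss[idx] <- rss0 - (c1s[idx] * S1yM[idx] + c2s[idx] * S2yM[idx])
  qs[idx] <- 2L

  # theta hinge alone: collinear collapse, or no supra-phi data
  idx <- have1 & (!have2 | (have2 & collinear))
  c1s[idx] <- S1yM[idx] / S11M[idx]
  rss[idx] <- rss0 - S1yM[idx]^2 / S11M[idx]
  qs[idx] <- 1L
  ident[have1 & have2 & collinear] <- FALSE

  # phi hinge alone
  idx <- !have1 & have2
  c2s[idx] <- S2yM[idx] / S22M[idx]
  rss[idx] <- rss0 - S2yM[idx]^2 / S22M[idx]
  qs[idx] <- 1L

  rss[qs == 0L] <- rss0
  rss <- pmax(rss, 0)

  df_resid <- n - qs
  f <- ((rss0 - rss) / pmax(qs, 1L)) / (rss / pmax(df_resid, 1L))
  exact <- rss <= 1e-12 * rss0
  f[exact] <- Inf
  p <- matrix(1, gt, gp)
  ok <- qs > 0L & df_resid >= 1L
  p[ok] <- stats::pf(f[ok], qs[ok], df_resid[ok], lower.tail = FALSE)
  p[ok & exact] <- if (rss0 > 0) 0 else 1

  n_supra_theta <- colSums(outer(th, tg, ">"))
  n_supra_phi <- colSums(outer(ph, pg, ">"))

  structure(list(theta_grid = tg, phi_grid = pg,
                 p = p, c1 = c1s, c2 = c2s, rss = rss, f = f,
                 q = qs, supported = ok,
                 n_supra_theta = n_supra_theta,
                 n_supra_phi = n_supra_phi,
                 supra = outer(n_supra_theta, rep(1, gp)) +
                   matrix(n_supra_phi, gt, gp, byrow = TRUE),
                 identifiable = ident,
                 outcome = outcome, n = n, grid = grid,
                 rss0 = rss0),
            class = "grid_scan")
}

#' @export
print.grid_scan <- function(x, ...) {
  cat(sprintf("<grid_scan> %s, %d x %d cells, n = %d, min p = %.3g\n",
              x$outcome, length(x$theta_grid), length(x$phi_grid), x$n,
              min(x$p)))
  invisible(x)
}

#' Select the lowest significant, adequately supported threshold pair
#'
#' A cell is eligible when (i) its fit is significant against the null
#' of no change, `p <= alpha`; (ii) it has at least `support_min`
#' supra-threshold observations (amplitude and velocity counts
#' combined); and (iii) it fits the data as well as the best cell on
#' the grid: a cell whose residual sum of squares is significantly
#' worse than the grid minimum (an F comparison with 2 numerator
#' degrees of freedom for the two postulated thresholds, at the same
#' `alpha`) cannot be the threshold pair that produced the data, so it
#' is excluded.  This is the standard grid-search change-point
#' confidence-region construction; without it, any strong
#' dose-response signal would make even grossly misplaced threshold
#' pairs "significant" and the lowest-pair rule would collapse to the
#' origin.  Among eligible cells the "lowest" pair under the scaled
#' order `theta0/theta_max + phi0/phi_max` is returned (ties broken by
#' the smaller `theta0`).  Returns `NULL` when no cell qualifies.
#'
#' @param scan a [grid_scan()].
#' @param alpha significance level (or vector of levels; default the
#'   conventional 0.05 / 0.01 / 0.001 trio).
#' @param support_min minimum combined supra-threshold count.
#' @param bonferroni apply a Bonferroni correction across the grid
#'   before thresholding the p-values.
#' @param adequacy apply eligibility rule (iii); disable to reproduce
#'   the bare lowest-significant-pair reading.
#' @return For a single `alpha`, a list `(theta0, phi0, p_value,
#'   n_supra, identifiable)` or `NULL`; for several, a named list per
#'   alpha.
#' @export
select_thresholds <- function(scan, alpha = c(0.05, 0.01, 0.001),
                              support_min = 3, bonferroni = FALSE,
                              adequacy = TRUE) {
  stopifnot(inherits(scan, "grid_scan"))
  if (length(alpha) > 1L) {
    out <- lapply(alpha, select_thresholds, scan = scan,
                  support_min = support_min, bonferroni = bonferroni,
                  adequacy = adequacy)
    names(out) <- paste0("alpha_", alpha)
    return(out)
  }
  p <- scan$p
  if (bonferroni) p <- pmin(p * length(p), 1)
  ok <- p <= alpha & scan$supra >= support_min
  if (adequacy && any(ok)) {
    cand <- scan$supported & scan$supra >= support_min
    rss_min <- min(scan$rss[cand])
    i_min <- which(cand & scan$rss <= rss_min + 1e-12 * scan$rss0,
                   arr.ind = FALSE)[1L]
    df_den <- scan$n - scan$q[i_min] - 2L
    if (df_den >= 1L) {
      if (rss_min <= 1e-12 * scan$rss0) {
        adequate <- scan$rss <= 1e-12 * scan$rss0
      } else {
        f_adeq <- ((scan$rss - rss_min) / 2) / (rss_min / df_den)
        adequate <- stats::pf(f_adeq, 2, df_den, lower.tail = FALSE) > alpha
      }
      ok <- ok & adequate
    }
  }
  elig <- which(ok, arr.ind = TRUE)
  if (nrow(elig) == 0L) return(NULL)
  t0 <- scan$theta_grid[elig[, 1]]
  p0 <- scan$phi_grid[elig[, 2]]
  score <- t0 / scan$grid$theta_max + p0 / scan$grid$phi_max
  ord <- order(score, t0)
  i <- elig[ord[1L], 1]; j <- elig[ord[1L], 2]
  list(theta0 = scan$theta_grid[i], phi0 = scan$phi_grid[j],
       p_value = scan$p[i, j], n_supra = scan$supra[i, j],
       identifiable = scan$identifiable[i, j],
       bonferroni = bonferroni)
}

#' Point estimate of the threshold pair from a grid scan
#'
#' The cell with the smallest F-test p-value (the "deepest" cell of
#' the probability surface).  Minimising p rather than raw RSS keeps
#' one- and two-hinge cells comparable: a two-hinge corner cell can
#' always shave some RSS by overfitting noise, but pays for the extra
#' parameter in the F test.  Ties (e.g. exact fits) resolve to the
#' lowest scaled pair for determinism.  This is the point estimator;
#' the decision rule lives in [select_thresholds()].
#'
#' @param scan a [grid_scan()].
#' @param support_min minimum combined supra-threshold count.
#' @return List `(theta0, phi0, rss, p_value)`.
#' @export
estimate_thresholds <- function(scan, support_min = 3) {
  stopifnot(inherits(scan, "grid_scan"))
  cand <- scan$supported & scan$supra >= support_min
  if (!any(cand)) return(NULL)
  p <- ifelse(cand, scan$p, Inf)
  ij <- which(p == min(p), arr.ind = TRUE)
  sc <- scan$theta_grid[ij[, 1]] / scan$grid$theta_max +
    scan$phi_grid[ij[, 2]] / scan$grid$phi_max
  k <- order(scan$rss[ij], sc, scan$theta_grid[ij[, 1]])[1L]
  i <- ij[k, 1]; j <- ij[k, 2]
  list(theta0 = scan$theta_grid[i], phi0 = scan$phi_grid[j],
       rss = scan$rss[i, j], p_value = scan$p[i, j])
}

#' Iso-probability contours of the p-value surface
#'
#' Lines of constant probability over the postulated-threshold plane.
#'
#' @param scan a [grid_scan()].
#' @param levels probability levels to contour.
#' @return Data frame with columns `level`, `piece`, `theta0`, `phi0`
#'   (empty when the surface is constant or never crosses a level).
#' @export
contour_surface <- function(scan, levels = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(scan, "grid_scan"))
  if (diff(range(scan$p)) == 0)
    return(data.frame(level = numeric(0), piece = integer(0),
                      theta0 = numeric(0), phi0 = numeric(0)))
  cl <- grDevices::contourLines(x = scan$theta_grid, y = scan$phi_grid,
                                z = scan$p, levels = levels)
  if (length(cl) == 0L)
    return(data.frame(level = numeric(0), piece = integer(0),
                      theta0 = numeric(0), phi0 = numeric(0)))
  do.call(rbind, lapply(seq_along(cl), function(k) {
    data.frame(level = cl[[k]]$level, piece = k,
               theta0 = cl[[k]]$x, phi0 = cl[[k]]$y)
  }))
}

#' One-sided test for increased supra-threshold variance
#'
#' Tests `Var(supra) > Var(sub)` between the sub- and supra-threshold
#' response samples.  The default is the one-sided variance-ratio
#' (F) test; `"brown-forsythe"` uses a one-sided Welch t-test on
#' absolute deviations from the group medians, robust to
#' non-normality.
#'
#' @param sub,supra numeric response samples (each with >= 2
#'   observations; `sub` must have positive variance).
#' @param method `"ratio"` or `"brown-forsythe"`.
#' @return List with `statistic`, `p_value`, `method`, and the group
#'   variances.
#' @export
variance_change_test <- function(sub, supra,
                                 method = c("ratio", "brown-forsythe")) {
  method <- match.arg(method)
  sub <- sub[is.finite(sub)]; supra <- supra[is.finite(supra)]
  if (length(sub) < 2L || length(supra) < 2L)
    stop("variance_change_test: need >= 2 observations per group")
  v_sub <- stats::var(sub); v_supra <- stats::var(supra)
  if (v_sub == 0)
    stop("variance_change_test: sub-threshold group has zero variance")
  if (method == "ratio") {
    stat <- v_supra / v_sub
    p <- stats::pf(stat, length(supra) - 1L, length(sub) - 1L,
                   lower.tail = FALSE)
  } else {
    d_sub <- abs(sub - stats::median(sub))
    d_supra <- abs(supra - stats::median(supra))
    tt <- stats::t.test(d_supra, d_sub, alternative = "greater")
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(statistic = stat, p_value = p, method = method,
       var_sub = v_sub, var_supra = v_supra)
}
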