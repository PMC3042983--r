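logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log1p(exp(-abs(a - b))))
}

gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  gl_cache[[key]]
}

#' Log scale density of the ICP diffusion
#'
#' The scale density `s(p)` of a one-dimensional diffusion is
#' `exp(-int^p 2 drift(xi)/diffusion(xi)^2 dxi)`. For the ICP model the
#' inner integral is elementary, giving (up to an arbitrary additive
#' constant that cancels in all hitting probabilities)
#'
#' \deqn{\log s(p) = -\frac{2}{\sigma^2 E}\left[(I + p_b/R)\log p - p/R\right].}
#'
#' `log s` attains its minimum exactly at the deterministic equilibrium
#' `R*I + p_b`. The magnitude of `log s` reaches several hundreds at typical
#' parameter values, which is why all downstream arithmetic stays in log
#' space.
#'
#' @param params A [csf_params()] object with `sigma > 0`.
#' @param p Pressure(s), mmHg; must be > 0.
#' @return `log s(p)` (dimensionless; defined up to an additive constant).
#' @export
scale_log_density <- function(params, p) {
  params <- validate_csf_params(params)
  if (params$sigma == 0) {
    stop("scale density requires sigma > 0 (deterministic model has no ",
         "diffusion)", call. = FALSE)
  }
  if (any(p <= 0)) stop("scale density is defined for p > 0", call. = FALSE)
  A <- 2 / (params$sigma^2 * params$E)
  -A * ((params$I + params$p_b / params$R) * log(p) - p / params$R)
}

#' Log of the scale-function increment
#'
#' Computes `log int_{p_lo}^{p_hi} s(eta) d eta`, the increment of the scale
#' function `S`, by fixed-order Gauss-Legendre quadrature per panel with
#' panel doubling until the log-result changes by less than `tol`. The
#' quadrature is assembled with log-sum-exp, so it remains finite although
#' the linear-space integrand can span hundreds of orders of magnitude at
#' clinically typical noise intensities.
#'
#' @inheritParams scale_log_density
#' @param p_lo,p_hi Integration limits, mmHg, `0 < p_lo < p_hi`.
#' @param n_nodes Gauss-Legendre nodes per panel (>= 2, default 16).
#' @param tol Convergence tolerance on the log value (default 1e-8).
#' @return `log S(p_hi) - S(p_lo)` as a single number (same arbitrary
#'   constant convention as [scale_log_density()]).
#' @export
log_scale_increment <- function(params, p_lo, p_hi, n_nodes = 16L,
                                tol = 1e-8) {
  params <- validate_csf_params(params)
  if (!(p_lo > 0) || !(p_hi > p_lo)) {
    stop("require 0 < p_lo < p_hi", call. = FALSE)
  }
  stopifnot(n_nodes >= 2L)
  rule <- gl_rule(as.integer(n_nodes))
  panels <- 4L
  prev <- NA_real_
  repeat {
    edges <- seq(p_lo, p_hi, length.out = panels + 1L)
    widths <- diff(edges)
    # nodes/weights for all panels at once
    xs <- rep(edges[-length(edges)], each = n_nodes) +
      rep(widths, each = n_nodes) * rep(rule$x, panels)
    lw <- log(rep(widths, each = n_nodes) * rep(rule$w, panels))
    val <- logsumexp(lw + scale_log_density(params, xs))
    if (!is.na(prev) && abs(val - prev) < tol) return(val)
    prev <- val
    panels <- panels * 2L
    if (panels > 2^15) {
      warning("panel doubling reached its cap before the requested tolerance")
      return(val)
    }
  }
}

#' Probability of reaching a critical ICP level before a lower level
#'
#' Two-barrier first-passage probability of the ICP diffusion: starting from
#' `x`, the probability `u(x)` of reaching the critical upper level `b`
#' before falling to the lower absorbing level `a`,
#'
#' \deqn{u(x) = \frac{S(x) - S(a)}{S(b) - S(a)},}
#'
#' where `S` is the scale function. Computed entirely in log space via
#' [log_scale_increment()] and a stable logistic ratio, so it is finite and
#' in \[0, 1\] even when the scale integrand spans hundreds of orders of
#' magnitude.
#'
#' The literal lower barrier at 0 is degenerate: whenever the stationary
#' distribution exists, 0 is an entrance boundary (the scale integral
#' diverges there) and the probability of reaching `b` before 0 is
#' identically 1. A positive clinically meaningful lower level `a` (default
#' 30 mmHg for the standard critical-event scenario with `b = 40`,
#' `x = 35`) keeps the question well-posed; see
#' [bvp_hitting_probability()] for the boundary-value replication mode.
#'
#' @param params A [csf_params()] object with `sigma > 0` (for `sigma = 0`
#'   an error points to the deterministic limit).
#' @param x Current ICP, mmHg, with `a <= x <= b`.
#' @param a Lower absorbing level, mmHg (> 0), default 30.
#' @param b Critical upper level, mmHg, default 40.
#' @return Probability in \[0, 1\].
#' @examples
#' hitting_probability(csf_params(sigma = 1.2), x = 35, a = 30, b = 40)
#' @export
hitting_probability <- function(params, x, a = 30, b = 40) {
  params <- validate_csf_params(params)
  if (!(a > 0 && a <= x && x <= b)) {
    stop("require 0 < a <= x <= b (got a=", a, ", x=", x, ", b=", b, ")",
         call. = FALSE)
  }
  if (params$sigma == 0) {
    stop("sigma = 0: hitting probability is the deterministic limit (1 if ",
         "the deterministic flow from x reaches b before a, else 0); the ",
         "scale function is undefined", call. = FALSE)
  }
  if (x == a) return(0)
  if (x == b) return(1)
  log_lo <- log_scale_increment(params, a, x)
  log_hi <- log_scale_increment(params, x, b)
  # u = I(a,x) / (I(a,x) + I(x,b))
  stats::plogis(log_lo - log_hi)
}

#' Hitting probability by the two-point boundary-value route
#'
#' Replicates the boundary-value formulation of the critical-event
#' probability: `u` satisfies the singular ODE
#' `(sigma^2 E^2 x^2 / 2) u'' + (E I x - E x (x - p_b)/R) u' = 0` with
#' `u(b) = 1` and the lower condition imposed at a small `epsilon > 0`
#' (`u(epsilon) = 0`). The ODE is solved by central finite differences on a
#' uniform grid over `[epsilon, b]` (tridiagonal solve); the result is
#' equivalent to [hitting_probability()] with `a = epsilon`.
#'
#' The ODE is singular at 0, and when the stationary distribution exists the
#' exact limit `epsilon -> 0` is `u == 1` for every `x > 0` (0 is an
#' entrance boundary), so `epsilon` must be strictly positive.
#'
#' @param params A [csf_params()] object with `sigma > 0`.
#' @param x Current ICP, mmHg, `epsilon < x < b`.
#' @param b Critical upper level, mmHg, default 40.
#' @param epsilon Lower boundary location, mmHg (> 0).
#' @param n_grid Number of grid intervals (default 10000).
#' @return Probability in \[0, 1\] (linear interpolation between grid
#'   points at `x`).
#' @export
bvp_hitting_probability <- function(params, x, b = 40, epsilon, n_grid = 1e4) {
  params <- validate_csf_params(params)
  if (missing(epsilon)) stop("'epsilon' (lower boundary > 0) is required", call. = FALSE)
  if (!(epsilon > 0)) {
    stop("epsilon must be > 0: the ODE is singular at 0 and the exact ",
         "epsilon -> 0 limit is u == 1 whenever the stationary ",
         "distribution exists", call. = FALSE)
  }
  if (!(epsilon < x && x < b)) stop("require epsilon < x < b", call. = FALSE)
  if (params$sigma == 0) stop("sigma = 0: use the deterministic limit", call. = FALSE)
  n_grid <- as.integer(n_grid)
  stopifnot(n_grid >= 10L)
  h <- (b - epsilon) / n_grid
  xg <- epsilon + h * seq_len(n_grid - 1L)        # interior nodes
  # divide the ODE by sigma^2 E^2 x^2 / 2:  u'' + c(x) u' = 0
  cx <- (2 / (params$sigma^2 * params$E)) *
    ((params$I + params$p_b / params$R) / xg - 1 / params$R)
  lower <- 1 / h^2 - cx / (2 * h)
  diagn <- rep(-2 / h^2, n_grid - 1L)
  upper <- 1 / h^2 + cx / (2 * h)
  rhs <- numeric(n_grid - 1L)
  rhs[n_grid - 1L] <- -upper[n_grid - 1L]          # u(b) = 1; u(epsilon) = 0
  u <- thomas_solve(lower, diagn, upper, rhs)
  grid <- c(epsilon, xg, b)
  uu <- pmin(pmax(c(0, u, 1), 0), 1)
  stats::approx(grid, uu, xout = x)$y
}

thomas_solve <- function(lower, diagn, upper, rhs) {
  n <- length(diagn)
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- upper[1] / diagn[1]
  dp[1] <- rhs[1] / diagn[1]
  for (i in 2:n) {
    denom <- diagn[i] - lower[i] * cp[i - 1]
    cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Monte-Carlo estimate of the hitting probability
#'
#' Independent validation of [hitting_probability()]: simulates log-Euler
#' paths from `x` and reports the fraction that cross the upper level `b`
#' before the lower level `a` within the horizon `t_max`. Crossings are
#' detected by level comparison between steps (no Brownian-bridge
#' correction), so comparisons against the analytic value carry a small
#' discretization allowance at the default `dt`.
#'
#' @inheritParams hitting_probability
#' @param n_paths Number of Monte-Carlo paths (>= 100).
#' @param dt Step size, min (default 5e-4).
#' @param t_max Horizon, min (default 60). An error is signaled if more than
#'   1% of paths are censored (neither barrier reached by `t_max`).
#' @param seed Integer seed, or `NULL`.
#' @return A one-row tibble of class `mc_estimate` with columns `estimate`,
#'   `se` (binomial standard error), `n_paths`, `dt`, `t_max`, `n_hit_b`,
#'   `n_hit_a`, `censored_frac`.
#' @examples
#' mc_hitting_probability(csf_params(sigma = 1.2), x = 35,
#'                        n_paths = 1000, seed = 1)
#' @export
mc_hitting_probability <- function(params, x, a = 30, b = 40,
                                   n_paths = 20000, dt = 5e-4, t_max = 60,
                                   seed = NULL) {
  params <- validate_csf_params(params)
  if (!(a > 0 && a <= x && x <= b)) stop("require 0 < a <= x <= b", call. = FALSE)
  stopifnot(n_paths >= 100, dt > 0, t_max > dt)
  co <- csf_coefficients(params)
  if (!is.null(seed)) set.seed(seed)
  counts <- mc_first_passage_cpp(co$alpha, co$beta, co$noise_amp,
                                 x, a, b, as.integer(n_paths), dt, t_max)
  censored_frac <- counts[3] / n_paths
  if (censored_frac > 0.01) {
    stop("censored fraction ", signif(censored_frac, 3),
         " exceeds 1%: horizon t_max too short for a valid two-barrier ",
         "probability", call. = FALSE)
  }
  est <- counts[1] / n_paths
  out <- tibble::tibble(
    estimate = est,
    se = sqrt(est * (1 - est) / n_paths),
    n_paths = as.integer(n_paths), dt = dt, t_max = t_max,
    n_hit_b = counts[1], n_hit_a = counts[2],
    censored_frac = censored_frac
  )
  attr(out, "params") <- params
  attr(out, "problem") <- c(x = x, a = a, b = b)
  class(out) <- c("mc_estimate", class(out))
  out
}

#' Risk curve over noise intensity or outflow resistance
#'
#' Evaluates the critical-event probability [hitting_probability()] along a
#' grid of one parameter — the noise intensity `sigma` (standard grid 0.4 to
#' 1.3 mL/min) or the outflow resistance `R` (standard grid 4 to 12
#' mmHg.mL^-1.min at `sigma = 0.8`) — holding all other parameters fixed.
#' For an upper level above the deterministic equilibrium the curve is
#' expected nondecreasing in `sigma`; a violation is reported as a warning,
#' never silently dropped.
#'
#' @param params A [csf_params()] object (the varied field is overridden by
#'   the grid).
#' @param axis Which parameter to vary: `"sigma"` or `"R"`.
#' @param grid Strictly increasing grid of parameter values (defaults:
#'   `seq(0.4, 1.3, by = 0.05)` for sigma, `seq(4, 12, by = 0.5)` for R).
#' @param x,a,b Hitting problem as in [hitting_probability()] (defaults
#'   35, 30, 40 mmHg).
#' @return A tibble of class `csf_risk_curve` with the grid column
#'   (`sigma` or `R`) and `probability`; attributes `axis`, `x`, `a`, `b`,
#'   `params`.
#' @examples
#' rc <- risk_curve(csf_params(), axis = "sigma",
#'                  grid = seq(0.8, 1.3, by = 0.1))
#' rc
#' @export
risk_curve <- function(params, axis = c("sigma", "R"), grid = NULL,
                       x = 35, a = 30, b = 40) {
  params <- validate_csf_params(params)
  axis <- match.arg(axis)
  if (is.null(grid)) {
    grid <- if (axis == "sigma") seq(0.4, 1.3, by = 0.05) else seq(4, 12, by = 0.5)
  }
  if (any(diff(grid) <= 0) || any(grid <= 0)) {
    stop("grid must be strictly increasing and positive", call. = FALSE)
  }
  prob <- purrr::map_dbl(seq_along(grid), function(i) {
    pp <- params
    pp[[axis]] <- grid[i]
    tryCatch(hitting_probability(pp, x = x, a = a, b = b),
             error = function(e) {
               stop("risk curve point ", i, " (", axis, " = ", grid[i], "): ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  if (axis == "sigma" && b > equilibrium_icp(params) &&
      any(diff(prob) < -1e-12)) {
    warning("risk curve not nondecreasing in sigma (numerical check failed)")
  }
  out <- tibble::tibble(value = grid, probability = prob)
  names(out)[1] <- axis
  attr(out, "axis") <- axis
  attr(out, "x") <- x
  attr(out, "a") <- a
  attr(out, "b") <- b
  attr(out, "params") <- params
  class(out) <- c("csf_risk_curve", class(out))
  out
}

#' Risk surface over outflow resistance and noise intensity
#'
#' The critical-event probability on the full (R, sigma) grid. Each entry is
#' an independent [hitting_probability()] evaluation, so any row or column
#' equals the corresponding [risk_curve()].
#'
#' @inheritParams risk_curve
#' @param R_grid,sigma_grid Strictly increasing positive grids (defaults
#'   as in [risk_curve()]).
#' @return A tibble of class `csf_risk_surface` in long format with columns
#'   `R`, `sigma`, `probability`; attributes `x`, `a`, `b`, `params`. Use
#'   [as.matrix()] for the probability matrix (rows = R, columns = sigma).
#' @export
risk_surface <- function(params, R_grid = seq(4, 12, by = 0.5),
                         sigma_grid = seq(0.4, 1.3, by = 0.05),
                         x = 35, a = 30, b = 40) {
  params <- validate_csf_params(params)
  for (g in list(R_grid, sigma_grid)) {
    if (any(diff(g) <= 0) || any(g <= 0)) {
      stop("grids must be strictly increasing and positive", call. = FALSE)
    }
  }
  cells <- expand.grid(sigma = sigma_grid, R = R_grid)   # R varies slowest
  prob <- purrr::map_dbl(seq_len(nrow(cells)), function(i) {
    pp <- params
    pp$R <- cells$R[i]
    pp$sigma <- cells$sigma[i]
    tryCatch(hitting_probability(pp, x = x, a = a, b = b),
             error = function(e) {
               stop("risk surface cell (R = ", cells$R[i], ", sigma = ",
                    cells$sigma[i], "): ", conditionMessage(e), call. = FALSE)
             })
  })
  out <- tibble::tibble(R = cells$R, sigma = cells$sigma, probability = prob)
  attr(out, "x") <- x
  attr(out, "a") <- a
  attr(out, "b") <- b
  attr(out, "params") <- params
  class(out) <- c("csf_risk_surface", class(out))
  out
}

#' @export
as.matrix.csf_risk_surface <- function(x, ...) {
  Rg <- sort(unique(x$R))
  sg <- sort(unique(x$sigma))
  m <- matrix(NA_real_, length(Rg), length(sg),
              dimnames = list(R = format(Rg, trim = TRUE),
                              sigma = format(sg, trim = TRUE)))
  m[cbind(match(x$R, Rg), match(x$sigma, sg))] <- x$probability
  m
}
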