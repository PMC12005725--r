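## Pre-steady-state stopped-flow fitting.
##
## Transients are fit with a single exponential  y = A exp(-kobs t) + C
## or, when a steady-state phase follows the burst, with the burst equation
## y = A exp(-kobs t) + kss t + C.  Observed rates plotted against ligand
## concentration in the low-concentration linear regime follow
## kobs = k+1 [S] + k-1, so a line fit yields the second-order on-rate
## (slope) and the off-rate (intercept).

#' Average replicate stopped-flow traces
#'
#' Traces must share the trace kind and ligand concentration.  When time
#' grids differ, all traces are linearly interpolated onto the grid of the
#' densest trace, restricted to the overlap of all time ranges, and averaged
#' pointwise.
#'
#' @param traces list of [sf_trace()] objects.
#' @return An [sf_trace()] of the pointwise mean.
#' @export
average_traces <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L ||
      !all(vapply(traces, inherits, logical(1), "sf_trace")))
    stop_user("'traces' must be a non-empty list of sf_trace objects")
  kinds <- vapply(traces, attr, character(1), "kind")
  concs <- vapply(traces, function(x) as.numeric(attr(x, "ligand_conc")),
                  numeric(1))
  if (length(unique(kinds)) != 1L)
    stop_user("trace kinds differ: ", paste(unique(kinds), collapse = ", "))
  if (!all(is.na(concs)) &&
      (any(is.na(concs)) || diff(range(concs)) > 1e-9 * max(abs(concs), 1)))
    stop_user("ligand concentrations differ across traces")
  dens <- which.max(vapply(traces, nrow, integer(1)))
  grid <- traces[[dens]]$t
  lo <- max(vapply(traces, function(x) min(x$t), numeric(1)))
  hi <- min(vapply(traces, function(x) max(x$t), numeric(1)))
  grid <- grid[grid >= lo & grid <= hi]
  if (length(grid) < 2L) stop_user("trace time ranges do not overlap")
  ys <- vapply(traces, function(x) approx(x$t, x$y, xout = grid)$y,
               numeric(length(grid)))
  sf_trace(grid, rowMeans(ys), kind = kinds[1L], ligand_conc = concs[1L])
}

## deterministic initial values for y = A exp(-k t) + C
init_single_exp <- function(t, y) {
  n <- length(y)
  tail_n <- max(3L, ceiling(n * 0.1))
  C0 <- mean(y[(n - tail_n + 1L):n])
  A0 <- y[1L] - C0
  r <- (y - C0) * sign(A0)
  ok <- which(r > 0 & t > t[1L] - 1)
  k0 <- NA_real_
  if (length(ok) >= 3L) {
    sl <- coef(lm(log(r[ok]) ~ t[ok]))[[2L]]
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 3 / max(diff(range(t)), 1e-12)
  list(A = A0, k = k0, C = C0)
}

#' Fit a single-exponential transient
#'
#' Nonlinear least-squares fit of `y = A * exp(-k_obs * t) + C` with
#' deterministic initialization: the offset from the trace tail, the
#' amplitude from the first point, and the rate from a log-linearized
#' regression of the residuals.  A warning is issued when the trace covers
#' less than `3 / k_obs` of the relaxation.
#'
#' @param trace an [sf_trace()] (or data frame with `t` and `y`).
#' @return An object of class `exp_fit`: `A`, `k_obs`, `C`, standard errors
#'   `se` (named), `residual_norm`, and the `nls` fit object.
#' @examples
#' tr <- sf_trace(seq(0, 1, by = 0.01), 2 * exp(-5 * seq(0, 1, by = 0.01)) + 1)
#' fit_single_exponential(tr)$k_obs
#' @export
fit_single_exponential <- function(trace) {
  t <- trace$t; y <- trace$y
  if (length(t) < 10L) stop_user("need >= 10 points")
  if (sd(y) < 1e-12 * (abs(mean(y)) + 1e-12))
    stop("degenerate input: trace is constant, no exponential to fit")
  ini <- init_single_exp(t, y)
  fit <- NULL
  for (fac in c(1, 0.3, 3)) {
    st <- list(A = ini$A, k = ini$k * fac, C = ini$C)
    fit <- tryCatch(
      nls(y ~ A * exp(-k * t) + C, data = data.frame(t = t, y = y),
          start = st, algorithm = "port",
          lower = c(A = -Inf, k = 1e-12, C = -Inf)),
      error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        nls(y ~ A * exp(-k * t) + C, data = data.frame(t = t, y = y),
            start = st),
        error = function(e) NULL)
    if (!is.null(fit) && coef(fit)[["k"]] <= 0) fit <- NULL
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("single-exponential fit did not converge (start: A=",
         signif(ini$A, 4), ", k=", signif(ini$k, 4), ", C=",
         signif(ini$C, 4), "; bounds: k > 0)")
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3),
                                              c("A", "k", "C")))
  if (max(t) < 3 / co[["k"]])
    warning(sprintf(
      "trace covers only %.2g relaxation times (< 3/k_obs); k_obs unreliable",
      max(t) * co[["k"]]))
  structure(list(A = co[["A"]], k_obs = co[["k"]], C = co[["C"]],
                 se = c(A = unname(se["A"]), k_obs = unname(se["k"]),
                        C = unname(se["C"])),
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fit = fit),
            class = "exp_fit")
}

#' Fit a burst (exponential-plus-line) transient
#'
#' Least-squares fit of `y = A * exp(-k_obs * t) + k_ss * t + C`, the model
#' for turbidity transients in which a fast dissociation burst is followed
#' by steady-state turnover.  For turbidity decays the burst-phase `k_obs`
#' is reported as the microtubule-dissociation rate `k2`.  An exactly linear
#' trace returns `A = 0` with `k_obs = NA` (the exponential rate is then
#' unidentifiable).
#'
#' @param trace an [sf_trace()] (or data frame with `t` and `y`).
#' @return An object of class `burst_fit`: `A`, `k_obs`, `k_ss`, `C`,
#'   standard errors, `residual_norm`, and the `nls` fit object.
#' @export
fit_burst <- function(trace) {
  t <- trace$t; y <- trace$y
  if (length(t) < 10L) stop_user("need >= 10 points")
  n <- length(t)
  ## tail line for the steady-state phase
  tail_i <- seq.int(max(1L, ceiling(n * 0.6)), n)
  lf <- lm(y[tail_i] ~ t[tail_i])
  ss0 <- coef(lf)[[2L]]; C0 <- coef(lf)[[1L]]
  ## exactly linear trace: exponential amplitude is zero
  full_line <- lm(y ~ t)
  scale <- max(abs(y), 1e-300)
  if (sqrt(mean(residuals(full_line)^2)) < 1e-10 * scale) {
    co <- coef(full_line)
    sfl <- suppressWarnings(summary(full_line))
    return(structure(list(A = 0, k_obs = NA_real_, k_ss = co[[2L]],
                          C = co[[1L]],
                          se = c(A = 0, k_obs = NA_real_,
                                 k_ss = sfl$coefficients[2L, 2L],
                                 C = sfl$coefficients[1L, 2L]),
                          residual_norm = sqrt(sum(residuals(full_line)^2)),
                          fit = full_line, pure_line = TRUE),
                     class = "burst_fit"))
  }
  r <- y - (ss0 * t + C0)
  A0 <- r[1L]
  ok <- which(r * sign(A0) > 0)
  k0 <- NA_real_
  if (length(ok) >= 3L) {
    sl <- coef(lm(log(r[ok] * sign(A0)) ~ t[ok]))[[2L]]
    if (is.finite(sl) && sl < 0) k0 <- -sl
  }
  if (!is.finite(k0) || k0 <= 0) k0 <- 3 / max(diff(range(t)), 1e-12)
  fit <- NULL
  starts <- list()
  for (fac in c(1, 0.3, 3))
    for (ssi in c(ss0, 0))
      starts <- c(starts, list(list(A = A0, k = k0 * fac, ss = ssi,
                                    C = C0)))
  for (st in starts) {
    fit <- tryCatch(
      nls(y ~ A * exp(-k * t) + ss * t + C, data = data.frame(t = t, y = y),
          start = st, algorithm = "port",
          lower = c(A = -Inf, k = 1e-12, ss = -Inf, C = -Inf)),
      error = function(e) NULL)
    if (is.null(fit))   # unbounded Gauss-Newton is sturdier near flat spots
      fit <- tryCatch(
        nls(y ~ A * exp(-k * t) + ss * t + C,
            data = data.frame(t = t, y = y), start = st),
        error = function(e) NULL)
    if (!is.null(fit) && coef(fit)[["k"]] <= 0) fit <- NULL
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("burst fit did not converge (start: A=", signif(A0, 4), ", k=",
         signif(k0, 4), ", ss=", signif(ss0, 4), ", C=", signif(C0, 4), ")")
  co <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4),
                                              c("A", "k", "ss", "C")))
  structure(list(A = co[["A"]], k_obs = co[["k"]], k_ss = co[["ss"]],
                 C = co[["C"]],
                 se = c(A = unname(se["A"]), k_obs = unname(se["k"]),
                        k_ss = unname(se["ss"]), C = unname(se["C"])),
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 fit = fit, pure_line = FALSE),
            class = "burst_fit")
}

#' Extract k+1 and k-1 from a kobs-vs-concentration series
#'
#' Weighted least-squares line `k_obs = k_plus1 * [S] + k_minus1` over the
#' low-concentration linear regime; the slope is the second-order on-rate
#' and the intercept the off-rate.  Weights are inverse-variance from the
#' per-concentration fit standard errors when available, else the fit is
#' unweighted.  A negative intercept is reported as-is with its standard
#' error (small off-rates fit through noisy points can legitimately come out
#' slightly negative).
#'
#' @param series data frame with columns `conc` (uM), `kobs` (s^-1) and
#'   optionally `se`.
#' @param max_conc optional upper concentration bound enforcing the linear
#'   regime; points above it are dropped.
#' @return List of class `kobs_fit`: `k_plus1` (uM^-1 s^-1), `k_minus1`
#'   (s^-1), `se` (named), `n`, and the `lm` object.
#' @export
fit_kobs_linear <- function(series, max_conc = Inf) {
  need <- c("conc", "kobs")
  if (!all(need %in% names(series)))
    stop_user("'series' needs columns: ", paste(need, collapse = ", "))
  s <- series[series$conc <= max_conc, , drop = FALSE]
  if (length(unique(s$conc)) < 3L)
    stop_user("need >= 3 distinct concentrations for the line fit, got ",
              length(unique(s$conc)))
  w <- NULL
  if (!is.null(s$se) && all(is.finite(s$se)) && all(s$se > 0))
    w <- 1 / s$se^2
  fit <- lm(kobs ~ conc, data = s, weights = w)
  co <- coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  structure(list(k_plus1 = co[["conc"]], k_minus1 = co[["(Intercept)"]],
                 se = c(k_plus1 = unname(se["conc"]),
                        k_minus1 = unname(se["(Intercept)"])),
                 n = nrow(s), fit = fit),
            class = "kobs_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit: y = A exp(-k t) + C\n  A = %.6g, k_obs = %.6g s^-1, C = %.6g\n",
              x$A, x$k_obs, x$C))
  invisible(x)
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("burst fit: y = A exp(-k t) + kss t + C\n  A = %.6g, k_obs = %.6g s^-1, k_ss = %.6g s^-1, C = %.6g\n",
              x$A, x$k_obs, x$k_ss, x$C))
  invisible(x)
}

#' @export
print.kobs_fit <- function(x, ...) {
  cat(sprintf("kobs line fit over %d points:\n  k+1 = %.4g +/- %.2g uM^-1 s^-1, k-1 = %.4g +/- %.2g s^-1\n",
              x$n, x$k_plus1, x$se[["k_plus1"]], x$k_minus1,
              x$se[["k_minus1"]]))
  invisible(x)
}
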