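## Shared statistical layer: Michaelis--Menten fitting, exponential dwell
## fitting with truncation/censoring, and derived rate-constant arithmetic.

#' Fit the Michaelis--Menten equation
#'
#' Least-squares fit of `y = kcat * x / (Km + x)` to rates versus substrate
#' concentration (microtubules for ATPase data, ATP for dwell-rate data).
#' Initialization uses a Lineweaver--Burk linearization; standard errors
#' come from the Jacobian.  A warning is issued when the concentrations do
#' not bracket the fitted Km.
#'
#' @param x concentrations (uM).
#' @param y rates (s^-1).
#' @return An object of class `mm_fit`: `kcat`, `Km`, `se` (named),
#'   `residual_norm`, and the `nls` fit.
#' @examples
#' x <- c(5, 10, 20, 50, 100, 300, 1000)
#' fit_michaelis_menten(x, 6.3 * x / (43 + x))
#' @export
fit_michaelis_menten <- function(x, y) {
  if (length(x) != length(y)) stop_user("'x' and 'y' lengths differ")
  if (length(unique(x)) < 3L)
    stop_user("need >= 3 distinct concentrations")
  if (any(x < 0)) stop_user("concentrations must be non-negative")
  ok <- x > 0 & y > 0
  kcat0 <- max(y) * 1.2
  Km0 <- median(x)
  if (sum(ok) >= 3L) {
    lb <- lm(I(1 / y[ok]) ~ I(1 / x[ok]))
    v0 <- 1 / coef(lb)[[1L]]
    K0 <- coef(lb)[[2L]] * v0
    if (is.finite(v0) && v0 > 0 && is.finite(K0) && K0 > 0) {
      kcat0 <- v0; Km0 <- K0
    }
  }
  fit <- tryCatch(
    nls(y ~ kcat * x / (Km + x), data = data.frame(x = x, y = y),
        start = list(kcat = kcat0, Km = Km0), algorithm = "port",
        lower = c(kcat = 1e-12, Km = 1e-12)),
    error = function(e)
      stop("Michaelis-Menten fit did not converge: ", conditionMessage(e)))
  co <- coef(fit)
  if (co[["kcat"]] <= 0 || co[["Km"]] <= 0)
    stop("Michaelis-Menten fit returned non-positive parameters")
  if (min(x[x > 0]) > co[["Km"]] || max(x) < co[["Km"]])
    warning("concentrations do not span the fitted Km; estimates poorly ",
            "constrained")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, Km = NA_real_))
  structure(list(kcat = co[["kcat"]], Km = co[["Km"]],
                 se = c(kcat = unname(se["kcat"]), Km = unname(se["Km"])),
                 residual_norm = sqrt(sum(residuals(fit)^2)), fit = fit),
            class = "mm_fit")
}

#' Fit an exponential rate to dwell-time data
#'
#' Three estimators for the exit rate of (approximately) exponential dwells:
#' \describe{
#'   \item{`mle_censored`}{maximum likelihood for an exponential
#'     left-truncated at `min_dwell`; right-censored dwells contribute
#'     survival terms.  Closed form: `rate = n_uncensored / sum(d -
#'     min_dwell)` over all retained dwells.  The default: unbiased under
#'     truncation by the memorylessness of the exponential.  When
#'     `frame_interval` is supplied and the dwells are ceiling-discretized
#'     frame counts, the exact discrete (geometric) MLE is used instead:
#'     `rate = -log(1 - p) / h` with `p` the per-frame exit probability,
#'     which removes the `O(rate * h)` bias of the continuous estimator at
#'     coarse frame times.}
#'   \item{`histogram_ls`}{least-squares fit of `a * exp(-rate * t)` to the
#'     binned dwell histogram, the estimator conventionally used for dwell
#'     histograms; bin width `max(frame_interval, range/30)`.}
#'   \item{`inverse_mean`}{`1 / mean(d)` over retained uncensored dwells; no
#'     truncation correction (the `k2_SMF` convention).}
#' }
#'
#' @param dwells numeric vector of dwell durations (s), or a data frame with
#'   `duration_s` (and optionally `censored`) columns.
#' @param min_dwell left-truncation point (s): only dwells strictly longer
#'   than this are observable.  The more-than-two-frames inclusion rule for
#'   frame-discretized data is `min_dwell = 2 * frame_interval`: a spot
#'   visible in exactly two frames (duration `2 * frame_interval` after
#'   ceiling discretization) is excluded, and in continuous time a dwell is
#'   seen in more than two frames exactly when it exceeds `2 *
#'   frame_interval`.
#' @param method estimator; see Details.
#' @param censored logical vector of right-censoring flags.
#' @param frame_interval camera frame interval (s), used for the histogram
#'   bin floor.
#' @param n_bins target bin count for `histogram_ls`.
#' @return An object of class `dwell_rate_result`: `rate` (s^-1), `se`,
#'   `method`, `n_used`, `min_dwell`.
#' @export
fit_dwell_exponential <- function(dwells, min_dwell = 0,
                                  method = c("mle_censored", "histogram_ls",
                                             "inverse_mean"),
                                  censored = NULL, frame_interval = NULL,
                                  n_bins = 30L) {
  method <- match.arg(method)
  if (is.data.frame(dwells)) {
    censored <- censored %||% dwells$censored %||% rep(FALSE, nrow(dwells))
    dwells <- dwells$duration_s
  }
  censored <- censored %||% rep(FALSE, length(dwells))
  check_scalar(min_dwell, "min_dwell", min = 0)
  keep <- if (min_dwell > 0) dwells > min_dwell else dwells > 0
  d <- dwells[keep]
  cn <- censored[keep]
  n_u <- sum(!cn)
  if (n_u < 20L)
    stop_user("need >= 20 uncensored dwells >= min_dwell, got ", n_u)

  if (method == "mle_censored") {
    h <- frame_interval
    on_lattice <- !is.null(h) &&
      all(abs(d / h - round(d / h)) < 1e-6) &&
      abs(min_dwell / h - round(min_dwell / h)) < 1e-6
    if (on_lattice) {
      ## geometric MLE for ceiling-discretized dwells truncated at m frames:
      ## shifted counts n_i = N_i - m are geometric(p) on {1, 2, ...}
      m <- round(min_dwell / h)
      ni <- round(d / h) - m
      p <- n_u / (sum(ni[!cn]) + sum(ni[cn]))
      rate <- -log(1 - p) / h
      se <- rate / sqrt(n_u)
    } else {
      rate <- n_u / sum(d - min_dwell)
      se <- rate / sqrt(n_u)
    }
  } else if (method == "inverse_mean") {
    rate <- 1 / mean(d[!cn])
    se <- rate / sqrt(n_u)
  } else {
    du <- d[!cn]
    rng <- diff(range(du))
    if (rng == 0) stop_user("all dwells identical: histogram fit undefined")
    binw <- max(frame_interval %||% 0, rng / n_bins)
    ## anchor the breaks at the truncation point: retained dwells are
    ## strictly greater, so frame-lattice durations never sit on the first
    ## edge, and right-closed bins assign lattice points uniquely
    brks <- seq(min_dwell, max(du) + binw, by = binw)
    h <- graphics::hist(du, breaks = brks, plot = FALSE)
    cnt <- h$counts; mids <- h$mids
    pos <- cnt > 0
    sl <- coef(lm(log(cnt[pos]) ~ mids[pos]))
    st <- list(a = exp(sl[[1L]]), rate = max(-sl[[2L]], 1e-6))
    fit <- tryCatch(
      nls(cnt ~ a * exp(-rate * mids),
          data = data.frame(cnt = cnt, mids = mids),
          start = st, algorithm = "port",
          lower = c(a = 1e-12, rate = 1e-12)),
      error = function(e)
        stop("histogram exponential fit did not converge: ",
             conditionMessage(e)))
    rate <- coef(fit)[["rate"]]
    se <- tryCatch(summary(fit)$coefficients["rate", "Std. Error"],
                   error = function(e) NA_real_)
  }
  structure(list(rate = rate, se = se, method = method, n_used = n_u,
                 min_dwell = min_dwell),
            class = "dwell_rate_result")
}

#' Dissociation constant from on/off rates
#'
#' `Kd = k_minus1 / k_plus1` (uM).
#'
#' @param k_minus1 off-rate (s^-1).
#' @param k_plus1 second-order on-rate (uM^-1 s^-1), > 0.
#' @return Kd in uM.
#' @examples
#' derive_kd(92, 5.3)     # ~17.4 uM, front head
#' derive_kd(0.015, 4.4)  # ~0.0034 uM (3.4 nM), rear head
#' @export
derive_kd <- function(k_minus1, k_plus1) {
  check_scalar(k_minus1, "k_minus1", min = 0)
  if (!is_scalar_number(k_plus1) || k_plus1 <= 0)
    stop_user("'k_plus1' must be > 0")
  k_minus1 / k_plus1
}

#' Fold change between two rates
#'
#' @param a,b rates; `b > 0`.
#' @param sig_figs significant figures for the reported ratio.
#' @return `signif(a / b, sig_figs)`.
#' @examples
#' fold_change(91, 0.65)   # 140
#' fold_change(42.1, 2.3)  # 18
#' @export
fold_change <- function(a, b, sig_figs = 2L) {
  check_scalar(a, "a")
  if (!is_scalar_number(b) || b <= 0) stop_user("'b' must be > 0")
  signif(a / b, sig_figs)
}

#' Assemble a per-construct rate table
#'
#' Collects `RateSet` rows (per construct and redox condition) into a table
#' with columns `construct`, `condition`, `kcat`, `Km`, `k_plus1`,
#' `k_minus1`, `k2`, `k2_SMF`, `Kd`.  A missing `Kd` is derived from its
#' components; a stored `Kd` inconsistent with `k_minus1 / k_plus1` by more
#' than 5% relative is flagged in `kd_inconsistent`.
#'
#' @param rate_sets list of named lists; each needs `construct` and
#'   `condition` (`"reduced"`, `"oxidized"` or `"n/a"`), other fields
#'   optional.
#' @return A data frame of class `rate_table`.
#' @export
build_rate_table <- function(rate_sets) {
  cols <- c("kcat", "Km", "k_plus1", "k_minus1", "k2", "k2_SMF", "Kd")
  if (length(rate_sets) == 0L) {
    out <- data.frame(construct = character(0), condition = character(0))
    for (cl in cols) out[[cl]] <- numeric(0)
    out$kd_inconsistent <- logical(0)
    class(out) <- c("rate_table", "data.frame")
    return(out)
  }
  rows <- lapply(rate_sets, function(rs) {
    if (is.null(rs$construct) || is.null(rs$condition))
      stop_user("each rate set needs 'construct' and 'condition'")
    row <- data.frame(construct = rs$construct, condition = rs$condition)
    for (cl in cols) row[[cl]] <- as.numeric(rs[[cl]] %||% NA_real_)
    row
  })
  out <- do.call(rbind, rows)
  key <- paste(out$construct, out$condition, sep = "\r")
  if (anyDuplicated(key))
    stop_user("duplicate (construct, condition) keys: ",
              paste(unique(out$construct[duplicated(key)]), collapse = ", "))
  derived <- ifelse(is.finite(out$k_minus1) & is.finite(out$k_plus1) &
                      out$k_plus1 > 0, out$k_minus1 / out$k_plus1, NA_real_)
  out$kd_inconsistent <- is.finite(out$Kd) & is.finite(derived) &
    abs(out$Kd - derived) > 0.05 * derived
  out$Kd <- ifelse(is.na(out$Kd), derived, out$Kd)
  class(out) <- c("rate_table", "data.frame")
  out
}
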