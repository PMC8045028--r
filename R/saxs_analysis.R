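#' Construct a SAXS curve
#'
#' @param q scattering vector, 1/Angstrom; strictly positive. Rows are
#'   sorted ascending; duplicate q are kept.
#' @param intensity intensities (arbitrary units), finite
#' @param sigma optional per-point uncertainties (> 0)
#' @param label sample label
#' @param concentration optional protein concentration, mg/mL
#' @return object of class `saxs_curve` (data frame with columns `q`,
#'   `intensity` and optionally `sigma`)
#' @export
saxs_curve <- function(q, intensity, sigma = NULL, label = "",
                       concentration = NA_real_) {
  stopifnot(length(q) == length(intensity))
  if (!is.null(sigma)) stopifnot(length(sigma) == length(q), all(sigma > 0))
  if (any(q <= 0)) stop("q must be strictly positive")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  o <- order(q)
  df <- data.frame(q = q[o], intensity = intensity[o])
  if (!is.null(sigma)) df$sigma <- sigma[o]
  attr(df, "label") <- label
  attr(df, "concentration") <- concentration
  class(df) <- c("saxs_curve", "data.frame")
  df
}

#' Read a 2-3 column SAXS .dat file
#'
#' Whitespace- or comma-separated numeric text with columns q, I and
#' optionally sigma; `#` comment lines are ignored. Rows with
#' non-positive q or non-finite intensity are dropped (with a message)
#' and the remainder sorted ascending in q.
#'
#' @param path file path
#' @param label sample label (default: file name)
#' @param concentration optional mg/mL
#' @return a [saxs_curve()]
#' @export
read_dat <- function(path, label = basename(path), concentration = NA_real_) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(gsub(",", " ", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no data rows in ", path)
  m <- utils::read.table(text = lines, header = FALSE)
  if (ncol(m) < 2) stop("need at least 2 numeric columns in ", path)
  q <- as.numeric(m[[1]])
  I <- as.numeric(m[[2]])
  s <- if (ncol(m) >= 3) as.numeric(m[[3]]) else NULL
  ok <- is.finite(q) & q > 0 & is.finite(I)
  if (!is.null(s)) ok <- ok & is.finite(s) & s > 0
  if (sum(!ok) > 0)
    message("read_dat: dropped ", sum(!ok), " unusable row(s)")
  if (sum(ok) == 0) stop("no usable rows in ", path)
  saxs_curve(q[ok], I[ok], if (!is.null(s)) s[ok], label = label,
             concentration = concentration)
}

#' Write a SAXS curve as 3-column text
#'
#' @param curve a [saxs_curve()]
#' @param path output file
#' @export
write_dat <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", attr(curve, "label") %||% ""), con)
  if (is.null(curve$sigma))
    writeLines(sprintf("%.8e %.8e", curve$q, curve$intensity), con)
  else
    writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$intensity,
                       curve$sigma), con)
  invisible(path)
}

#' Guinier analysis of a SAXS curve
#'
#' Weighted linear regression of ln I against q^2 on the largest low-q
#' window satisfying q*Rg < `qrg_max`. The window depends on the fitted
#' Rg and is resolved by fixed-point iteration starting from the first
#' 10 points; a two-window cycle is broken toward the larger window.
#' When a `sigma` column is present, weights are 1/sigma_lnI^2 with
#' sigma_lnI = sigma/I; otherwise the fit is unweighted.
#'
#' A residual sign-runs diagnostic on the final window flags a low-q
#' trend (upturn from aggregation or downturn from repulsive structure
#' factor) in the `aggregation_flag` field; it is a warning, not a
#' rejection.
#'
#' @param curve a [saxs_curve()]
#' @param qrg_max Guinier window limit (default 0.8)
#' @param max_iter maximum fixed-point iterations
#' @return object of class `guinier_result` with fields `rg`, `i0`,
#'   `rg_err`, `i0_err`, `q_window`, `n_points`, `r_squared`,
#'   `aggregation_flag`
#' @examples
#' q <- seq(0.01, 0.3, by = 0.005)
#' cv <- saxs_curve(q, 7.3 * exp(-q^2 * 13^2 / 3))
#' guinier_fit(cv)  # Rg = 13, I0 = 7.3
#' @export
guinier_fit <- function(curve, qrg_max = 0.8, max_iter = 50L) {
  stopifnot(inherits(curve, "saxs_curve"), qrg_max > 0)
  use <- curve$intensity > 0
  if (sum(use) < 3) stop("fewer than 3 points with positive intensity")
  q <- curve$q[use]
  I <- curve$intensity[use]
  s <- curve$sigma[use]
  wts <- if (!is.null(s)) (I / s)^2 else NULL

  fit_window <- function(nw) {
    q2 <- q[1:nw]^2
    df <- data.frame(lnI = log(I[1:nw]), q2 = q2)
    stats::lm(lnI ~ q2, data = df, weights = wts[1:nw])
  }
  rg_of <- function(fit) {
    sl <- stats::coef(fit)[["q2"]]
    if (sl >= 0)
      stop("Guinier fit failed: non-negative slope of ln I vs q^2 ",
           "(no Gaussian decay at low q)")
    sqrt(-3 * sl)
  }
  window_for <- function(rg) {
    # ties broken toward the larger window
    nw <- sum(q <= qrg_max / rg * (1 + 1e-9))
    max(nw, 3L)
  }

  nw <- min(10L, length(q))
  seen <- integer(0)
  for (it in seq_len(max_iter)) {
    fit <- fit_window(nw)
    rg <- rg_of(fit)
    nw_new <- min(window_for(rg), length(q))
    if (nw_new == nw) break
    if (nw_new %in% seen) {         # cycle: take the larger window
      nw <- max(nw_new, nw)
      fit <- fit_window(nw)
      rg <- rg_of(fit)
      break
    }
    seen <- c(seen, nw)
    nw <- nw_new
    if (it == max_iter)
      stop("Guinier window iteration did not converge")
  }
  # enforce the window rule against the final rg
  while (nw > 3 && q[nw] * rg > qrg_max * (1 + 1e-6)) {
    nw <- nw - 1L
    fit <- fit_window(nw)
    rg <- rg_of(fit)
  }

  sm <- suppressWarnings(summary(fit))   # noiseless curves fit exactly
  co <- sm$coefficients
  i0 <- exp(co["(Intercept)", "Estimate"])
  res <- list(
    rg = rg,
    i0 = i0,
    rg_err = 3 * co["q2", "Std. Error"] / (2 * rg),
    i0_err = i0 * co["(Intercept)", "Std. Error"],
    q_window = c(q[1], q[nw]),
    n_points = nw,
    r_squared = sm$r.squared,
    aggregation_flag = .runs_trend_flag(stats::residuals(fit))
  )
  class(res) <- "guinier_result"
  res
}

# Wald-Wolfowitz-style runs test on residual signs: too few runs means a
# systematic low-q trend in the Guinier residuals
.runs_trend_flag <- function(resid) {
  sg <- sign(resid)
  sg <- sg[sg != 0]
  n1 <- sum(sg > 0); n2 <- sum(sg < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0 || n < 8) return(FALSE)
  runs <- 1 + sum(diff(sg) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  z < stats::qnorm(0.05)   # one-sided: fewer runs than random
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("<guinier_result> Rg = %.2f +/- %.2f A, I0 = %.4g +/- %.2g\n",
              x$rg, x$rg_err, x$i0, x$i0_err))
  cat(sprintf("  window q in [%.4g, %.4g] (%d points, qmax*Rg = %.3f), R^2 = %.4f\n",
              x$q_window[1], x$q_window[2], x$n_points,
              x$q_window[2] * x$rg, x$r_squared))
  if (isTRUE(x$aggregation_flag))
    cat("  warning: systematic low-q residual trend (possible aggregation)\n")
  invisible(x)
}

#' Association number from calibrated forward scattering
#'
#' \deqn{N_{ass} = \frac{I_0^{sample}/c_{sample}}{I_0^{ref}/c_{ref}}
#'   \cdot \frac{M_{ref}}{M_{monomer}}}
#' with a reference standard of known molecular mass (e.g. BSA).
#'
#' @param i0_sample,i0_ref forward scattering intensities
#' @param c_sample,c_ref mass concentrations, mg/mL
#' @param mw_ref reference molecular weight, Da
#' @param mw_monomer monomer molecular weight of the sample, Da
#' @return the association number (1 = monomer)
#' @export
association_number <- function(i0_sample, c_sample, i0_ref, c_ref,
                               mw_ref, mw_monomer) {
  vals <- c(i0_sample, c_sample, i0_ref, c_ref, mw_ref, mw_monomer)
  if (any(vals <= 0)) stop("all inputs must be > 0")
  (i0_sample / c_sample) / (i0_ref / c_ref) * mw_ref / mw_monomer
}

#' Kratky transform
#'
#' Returns the points (q, q^2 I(q)) without dimensionless rescaling.
#'
#' @param curve a [saxs_curve()]
#' @return data frame with columns `q` and `q2I`
#' @export
kratky <- function(curve) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (nrow(curve) == 0) {
    warning("empty SAXS curve: Kratky transform has no points")
    return(data.frame(q = numeric(0), q2I = numeric(0)))
  }
  data.frame(q = curve$q, q2I = curve$q^2 * curve$intensity)
}
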