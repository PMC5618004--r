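#' @include foodwebCore.R
NULL

#' Fit the piecewise carbon-demand law to (ciliate, BCD) observations
#'
#' Least-squares estimation of the quadratic coefficient `k` and the
#' DOC-supply plateau `psi` of the regime law `BCD = min(k * C^2, psi)`.
#' The functional form itself enforces continuity at the implied crossover
#' `sqrt(psi/k)`.  Optimisation is Nelder-Mead on `(log k, log psi)` from a
#' data-driven start (quadratic fit of the low-C half for `k`, mean of the
#' top observations for `psi`), polished by a second restart.
#'
#' Identifiability: if the fitted crossover lies at or beyond the largest
#' observed `C`, no observation constrains the plateau and `psi` is flagged
#' unidentifiable (estimate set to `NA`); symmetrically for `k` when the
#' crossover lies at or below the smallest positive `C`.
#'
#' @param C ciliate biomasses (>= 0), at least 4 values.
#' @param bcdObs observed carbon demands, same length, non-negative.
#' @param init optional named vector `c(k =, psi =)` of starting values.
#' @param tol relative convergence tolerance of the optimiser.
#' @return a list with `k`, `psi`, `crossover`, logical `identifiable`
#'   (named `k`, `psi`), `sse` and `converged`.
#' @examples
#' C <- seq(1, 60, length.out = 20)
#' y <- pmin(1.1e-3 * C^2, 1)
#' fitBcdCurve(C, y)
#' @export
fitBcdCurve <- function(C, bcdObs, init = NULL, tol = 1e-12) {
  if (length(C) != length(bcdObs))
    stop("'C' and 'bcdObs' must have equal length")
  if (length(C) < 4)
    stop("need at least 4 (C, BCD) pairs spanning both regimes")
  if (any(!is.finite(C)) || any(!is.finite(bcdObs)) ||
      any(C < 0) || any(bcdObs < 0))
    stop("observations must be finite and non-negative")
  if (all(bcdObs == 0)) stop("all observed carbon demands are zero")

  keep <- C > 0 & bcdObs > 0
  if (sum(keep) < 4)
    stop("need at least 4 pairs with positive C and BCD")
  Cp <- C[keep]; yp <- bcdObs[keep]

  if (is.null(init)) {
    ord <- order(Cp)
    lowHalf <- ord[seq_len(max(2, floor(length(ord) / 2)))]
    k0 <- sum(yp[lowHalf] * Cp[lowHalf]^2) / sum(Cp[lowHalf]^4)
    psi0 <- mean(sort(yp, decreasing = TRUE)[seq_len(max(2, ceiling(length(yp) / 4)))])
    init <- c(k = max(k0, .Machine$double.xmin), psi = max(psi0, min(yp)))
  }
  sse <- function(par) {
    pred <- pmin(exp(par[1]) * Cp^2, exp(par[2]))
    sum((pred - yp)^2)
  }
  fit <- stats::optim(log(init), sse, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = 5000))
  fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = 5000))
  k <- exp(fit$par[[1]]); psi <- exp(fit$par[[2]])
  crossover <- sqrt(psi / k)
  identifiable <- c(k = crossover > min(Cp), psi = crossover < max(Cp))
  out <- list(k = if (identifiable[["k"]]) k else NA_real_,
              psi = if (identifiable[["psi"]]) psi else NA_real_,
              crossover = if (all(identifiable)) crossover else NA_real_,
              identifiable = identifiable,
              sse = fit$value, converged = fit$convergence == 0)
  if (!all(identifiable))
    warning("parameter(s) not identifiable from these observations: ",
            paste(names(identifiable)[!identifiable], collapse = ", "),
            " (all data on one side of the crossover)")
  out
}
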