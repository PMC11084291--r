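#' Observed order of accuracy from three grid solutions
#'
#' Richardson-extrapolation order estimation from a fine/medium/coarse
#' solution triplet. For equal refinement ratios
#' `p = ln(eps32/eps21) / ln(r)` with `eps21 = f2 - f1`,
#' `eps32 = f3 - f2`; for unequal ratios the standard fixed-point form is
#' iterated. The sign of `eps32/eps21` is preserved: a negative ratio
#' (medium value outside the fine/coarse bracket) means oscillatory
#' convergence and is flagged rather than silently absorbed, and a ratio
#' below one yields a negative effective order (flagged non-convergent).
#'
#' @param f1,f2,f3 Solution values on the fine, medium and coarse grids.
#' @param r21 Refinement ratio medium/fine (> 1).
#' @param r32 Refinement ratio coarse/medium (> 1); defaults to `r21`.
#' @return List with `p` (observed order), `monotone` (logical),
#'   `convergent` (logical, `p > 0`), and the error increments `eps21`,
#'   `eps32`.
#' @export
#' @examples
#' # second-order data: f = 1 + h^2 at h = 1, 2, 4
#' observed_order(2, 5, 17, r21 = 2)$p # 2
observed_order <- function(f1, f2, f3, r21, r32 = r21) {
  if (r21 <= 1 || r32 <= 1) stop("refinement ratios must exceed 1")
  eps21 <- f2 - f1
  eps32 <- f3 - f2
  if (eps21 == 0 || eps32 == 0) {
    stop("degenerate convergence: identical solutions on adjacent grids")
  }
  ratio <- eps32 / eps21
  monotone <- ratio > 0
  if (abs(r21 - r32) < 1e-12) {
    p <- log(abs(ratio)) / log(r21)
  } else {
    # for f = f* + C h^p: eps32/eps21 = r21^p (r32^p - 1)/(r21^p - 1),
    # which is continuous and increasing in p (limit log(r32)/log(r21) at 0)
    ratio_fun <- function(p) {
      if (abs(p) < 1e-12) return(log(r32) / log(r21))
      r21^p * expm1(p * log(r32)) / expm1(p * log(r21))
    }
    g <- function(p) log(ratio_fun(p)) - log(abs(ratio))
    p <- tryCatch(
      stats::uniroot(g, lower = -60, upper = 60, tol = 1e-13)$root,
      error = function(e) log(abs(ratio)) / log(sqrt(r21 * r32)))
  }
  if (!monotone) {
    warning("non-monotone (oscillatory) grid convergence; order estimate unreliable")
  }
  list(p = p, monotone = monotone, convergent = is.finite(p) && p > 0,
       eps21 = eps21, eps32 = eps32)
}

#' Grid convergence index
#'
#' `GCI = fs * |(f_coarse - f_fine)/f_fine| / (r^p - 1) * 100` in percent.
#'
#' @param f_fine,f_coarse Solutions on the finer and coarser grids.
#' @param r Refinement ratio (> 1).
#' @param p Observed (or assumed) order of accuracy.
#' @param fs Safety factor; 1.25 is standard for three-grid studies.
#' @return GCI in percent (non-negative).
#' @export
#' @examples
#' gci(1, 1.01, r = 2, p = 2) # 0.4167
gci <- function(f_fine, f_coarse, r, p, fs = 1.25) {
  if (r <= 1) stop("'r' must exceed 1")
  if (!is.finite(p)) stop("'p' must be finite")
  denom <- r^p - 1
  if (abs(denom) < 1e-300) stop("r^p = 1: GCI undefined")
  if (f_fine == 0) stop("relative error undefined for f_fine = 0")
  fs * abs((f_coarse - f_fine) / f_fine) / denom * 100
}

#' Asymptotic-range check
#'
#' Returns `gci32 / (r21^p * gci21)`; values near 1 indicate both GCI
#' estimates sit in the asymptotic range of convergence.
#'
#' @param gci21,gci32 Fine-medium and medium-coarse GCI values (%).
#' @param r21 Fine-medium refinement ratio.
#' @param p Observed order.
#' @return The asymptotic ratio (dimensionless).
#' @export
asymptotic_check <- function(gci21, gci32, r21, p) {
  if (gci21 == 0) stop("'gci21' must be non-zero")
  gci32 / (r21^p * gci21)
}

#' Three-grid convergence study
#'
#' Convenience wrapper combining [observed_order()], [gci()], Richardson
#' extrapolation and the asymptotic check for a fine-to-coarse solution
#' triplet.
#'
#' @param h Representative cell sizes, strictly increasing (fine first),
#'   length 3.
#' @param f Corresponding solution values, length 3.
#' @param fs Safety factor for the GCI (default 1.25).
#' @return Object of class `gci_result` with `p`, `f_ext` (extrapolated
#'   value), `E` (relative errors e21, e32), `gci` (gci21, gci32, %),
#'   `asymptotic_ratio`, `monotone`.
#' @export
#' @examples
#' h <- c(1, 2, 4)
#' grid_convergence(h, 3 + 0.1 * h^2)
grid_convergence <- function(h, f, fs = 1.25) {
  if (length(h) != 3L || length(f) != 3L) stop("need exactly three grids")
  if (any(diff(h) <= 0)) stop("'h' must be strictly increasing (fine first)")
  r21 <- h[2] / h[1]
  r32 <- h[3] / h[2]
  oo <- observed_order(f[1], f[2], f[3], r21, r32)
  p <- oo$p
  res <- list(p = p, monotone = oo$monotone)
  if (oo$convergent) {
    res$f_ext <- f[1] + (f[1] - f[2]) / (r21^p - 1)
    res$gci <- c(gci21 = gci(f[1], f[2], r21, p, fs),
                 gci32 = gci(f[2], f[3], r32, p, fs))
    res$asymptotic_ratio <- asymptotic_check(res$gci["gci21"],
                                             res$gci["gci32"], r21, p)
  } else {
    res$f_ext <- NA_real_
    res$gci <- c(gci21 = NA_real_, gci32 = NA_real_)
    res$asymptotic_ratio <- NA_real_
  }
  res$E <- c(e21 = (f[2] - f[1]) / f[1], e32 = (f[3] - f[2]) / f[2])
  res$h <- h
  res$f <- f
  class(res) <- "gci_result"
  res
}

#' @export
print.gci_result <- function(x, ...) {
  cat(sprintf("Grid refinement study (p = %.3f%s)\n", x$p,
              if (!x$monotone) ", OSCILLATORY" else ""))
  cat(sprintf("  %-18s E = %10.3e   GCI = %6.3f%%\n", "fine-medium:",
              x$E["e21"], x$gci["gci21"]))
  cat(sprintf("  %-18s E = %10.3e   GCI = %6.3f%%\n", "medium-coarse:",
              x$E["e32"], x$gci["gci32"]))
  if (is.finite(x$asymptotic_ratio)) {
    cat(sprintf("  extrapolated value %.6g; asymptotic ratio %.3f\n",
                x$f_ext, x$asymptotic_ratio))
  }
  invisible(x)
}
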