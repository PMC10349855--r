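## SAXS: Debye curves from bead models, Guinier fits, p(r) analysis,
## chi-square model-vs-data fitting.

#' Read / write a three-column scattering curve
#'
#' Whitespace-delimited `q I sigma` columns (the common beamline/SASBDB
#' .dat layout); leading header or comment lines that do not parse as
#' three numbers are skipped.
#'
#' @param path File path.
#' @return A [ScatteringCurve-class].
#' @export
readScatteringCurve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(lines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    if (length(v) >= 2 && !anyNA(v[1:2])) v else NULL
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no numeric data rows in ", path)
  q <- vapply(rows, `[`, 1.0, 1)
  I <- vapply(rows, `[`, 1.0, 2)
  s <- vapply(rows, function(v) if (length(v) >= 3) v[3] else NA_real_, 1.0)
  scatteringCurve(q, I, s)
}

#' @rdname readScatteringCurve
#' @param curve A [ScatteringCurve-class].
#' @export
writeScatteringCurve <- function(curve, path) {
  df <- as.data.frame(curve)
  writeLines(c("# q(A^-1) I(a.u.) sigma",
               sprintf("%.6g %.8g %.8g", df$q, df$I, df$sigma)), path)
  invisible(path)
}

# effective per-residue scattering weights (relative electron counts);
# one bead per residue at the heavy-atom centroid
.RESIDUE_WEIGHTS <- c(GLY = 30, ALA = 38, SER = 46, CYS = 54, THR = 54,
                      VAL = 54, PRO = 52, ILE = 62, LEU = 62, ASN = 60,
                      ASP = 59, GLN = 68, GLU = 67, MET = 70, HIS = 72,
                      LYS = 71, ARG = 85, PHE = 78, TYR = 86, TRP = 98,
                      A = 159, G = 167, C = 135, U = 136,
                      RA = 159, RG = 167, RC = 135, RU = 136)

.beadModel <- function(conformer, weights = c("residue", "uniform")) {
  weights <- match.arg(weights)
  a <- atoms(conformer)
  key <- paste(a$chain_id, a$residue_number)
  uk <- unique(key)
  n <- length(uk)
  X <- matrix(0, n, 3)
  f <- numeric(n)
  rn <- character(n)
  for (i in seq_len(n)) {
    sel <- key == uk[i]
    X[i, ] <- c(mean(a$x[sel]), mean(a$y[sel]), mean(a$z[sel]))
    rn[i] <- a$residue_name[sel][1]
  }
  if (weights == "uniform") {
    f[] <- 1
  } else {
    f <- unname(.RESIDUE_WEIGHTS[rn])
    f[is.na(f)] <- 55  # generic protein residue
  }
  list(X = X, f = f)
}

.sinc <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)

#' Model scattering curve by the Debye formula
#'
#' One bead per residue (heavy-atom centroid) with effective per-residue
#' scattering weights;
#' \deqn{I(q) = \sum_i\sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' so that \eqn{I(0) = (\sum_i f_i)^2}.
#'
#' @param conformer A [Conformer-class] (>= 1 residue).
#' @param q_grid Scattering vector grid, 1/Angstrom.
#' @param weights `"residue"` (effective electron counts per residue
#'   type) or `"uniform"`.
#' @return A [ScatteringCurve-class] (sigma = NA).
#' @export
debyeCurve <- function(conformer, q_grid, weights = "residue") {
  stopifnot(length(conformer) >= 1)
  bm <- .beadModel(conformer, weights)
  n <- nrow(bm$X)
  I0 <- sum(bm$f)^2
  if (n == 1) return(scatteringCurve(q_grid, rep(I0, length(q_grid))))
  D <- as.matrix(stats::dist(bm$X))
  iu <- which(upper.tri(D))
  dij <- D[iu]
  fij <- (bm$f %o% bm$f)[iu]
  I <- vapply(q_grid, function(q)
    sum(bm$f^2) + 2 * sum(fij * .sinc(q * dij)), 1.0)
  scatteringCurve(q_grid, I)
}

#' Guinier fit for the radius of gyration
#'
#' Weighted linear fit of \eqn{\ln I} versus \eqn{q^2} over the low-q
#' regime, iteratively shrinking the range until
#' \eqn{q_{max} R_g < } `qrg_max` (the classical validity rule).
#'
#' @param curve A [ScatteringCurve-class].
#' @param qrg_max Validity limit for q*Rg (default 1.3).
#' @param min_points Minimum points in the fitted range (default 5).
#' @return List: `rg` (Angstrom), `i0`, `fit_range` (indices used),
#'   `qrg` (q_max*Rg of the final fit), `n_points`.
#' @export
guinierRg <- function(curve, qrg_max = 1.3, min_points = 5) {
  q <- curve@q; I <- curve@I; s <- curve@sigma
  ok <- I > 0 & q > 0
  q <- q[ok]; I <- I[ok]; s <- s[ok]
  m <- length(q)
  if (m < min_points) stop("Guinier failure: too few positive-I points")
  w <- if (all(is.finite(s)) && all(s > 0)) (I / s)^2 else rep(1, m)
  fit_once <- function(mm) {
    cf <- stats::coef(stats::lm(log(I[1:mm]) ~ I(q[1:mm]^2),
                                weights = w[1:mm]))
    slope <- cf[[2]]
    if (slope >= 0) return(NULL)
    list(rg = sqrt(-3 * slope), i0 = exp(cf[[1]]))
  }
  mm <- m
  repeat {
    f <- fit_once(mm)
    if (is.null(f)) {
      mm <- mm - 1
      if (mm < min_points) stop("Guinier failure: no linear low-q regime")
      next
    }
    if (q[mm] * f$rg <= qrg_max)
      return(list(rg = f$rg, i0 = f$i0, fit_range = 1:mm,
                  qrg = q[mm] * f$rg, n_points = mm))
    mm <- mm - 1
    if (mm < min_points)
      stop("Guinier failure: qRg rule violated by all candidate ranges")
  }
}

#' Pair-distance distribution from a model
#'
#' Weighted histogram of all bead pair distances. `Dmax` is the exact
#' maximum pairwise distance; `Rg` is computed from the unbinned pair
#' distances (\eqn{R_g^2 = \sum f_i f_j r_{ij}^2 / (2 (\sum f_i)^2)}, the
#' exact second moment of p(r)).
#'
#' @param conformer A [Conformer-class] (>= 2 residues).
#' @param bin Histogram bin width in Angstrom (default 0.5).
#' @param weights Bead weighting as in [debyeCurve()].
#' @return A [PairDistribution-class].
#' @export
pofrFromModel <- function(conformer, bin = 0.5, weights = "residue") {
  bm <- .beadModel(conformer, weights)
  if (nrow(bm$X) < 2) stop("need >= 2 scattering centers")
  D <- as.matrix(stats::dist(bm$X))
  iu <- which(upper.tri(D))
  dij <- D[iu]
  fij <- (bm$f %o% bm$f)[iu]
  dmax <- max(dij)
  nb <- max(1, ceiling(dmax / bin))
  edges <- seq(0, nb * bin, by = bin)
  idx <- pmin(nb, findInterval(dij, edges, rightmost.closed = TRUE))
  p <- vapply(seq_len(nb), function(k) sum(fij[idx == k]), 1.0)
  r <- edges[-1] - bin / 2
  rg <- sqrt(sum(fij * dij^2) / sum(bm$f)^2)
  new("PairDistribution", r = r, p = p, dmax = dmax, rg = rg)
}

#' Indirect transform: p(r) from an experimental curve
#'
#' Regularized inversion of \eqn{I(q) = \sum_k p_k\,\mathrm{sinc}(q r_k)
#' \Delta r} on an r-grid up to `dmax_trial`, with a second-difference
#' smoothness penalty and non-negativity enforced by non-negative least
#' squares (`pracma::lsqnonneg`). Reports fit quality so a grossly wrong
#' `dmax_trial` is visible (analyst-in-the-loop Dmax selection, as in
#' practice).
#'
#' @param curve A [ScatteringCurve-class] with positive errors.
#' @param dmax_trial Trial maximum dimension, Angstrom (> 0).
#' @param n_bins Number of r bins (default 60).
#' @param lambda Smoothness penalty weight relative to the data term
#'   (default 0.05).
#' @return A [PairDistribution-class] with attributes `"chi2"` (reduced
#'   chi-square of the reconstruction against the curve) and
#'   `"large_misfit"` (logical; TRUE flags a poor reconstruction, e.g.
#'   `dmax_trial` far too small).
#' @export
pofrFromCurve <- function(curve, dmax_trial, n_bins = 60, lambda = 0.05) {
  stopifnot(dmax_trial > 0)
  q <- curve@q; I <- curve@I; s <- curve@sigma
  if (!all(is.finite(s)) || any(s <= 0)) s <- pmax(abs(I), 1e-12) * 0.01
  dr <- dmax_trial / n_bins
  r <- seq(dr / 2, dmax_trial - dr / 2, length.out = n_bins)
  A <- outer(q, r, function(qq, rr) .sinc(qq * rr)) * dr
  W <- 1 / s
  Aw <- A * W
  yw <- I * W
  # second-difference penalty, scaled to the data term
  D2 <- diag(n_bins)
  D2 <- diff(diff(D2))
  scale <- sqrt(sum(Aw^2) / max(sum(D2^2), 1))
  Astack <- rbind(Aw, lambda * scale * D2)
  ystack <- c(yw, rep(0, nrow(D2)))
  sol <- pracma::lsqnonneg(Astack, ystack)
  p <- sol$x
  fitI <- as.vector(A %*% p)
  chi2 <- sum(((fitI - I) / s)^2) / max(length(q) - 1, 1)
  # Dmax: last bin with appreciable mass
  nz <- which(p > 1e-3 * max(p))
  dmax_eff <- if (length(nz)) r[max(nz)] + dr / 2 else dmax_trial
  rg <- if (sum(p) > 0) sqrt(sum(r^2 * p) / (2 * sum(p))) else NA_real_
  out <- new("PairDistribution", r = r, p = p, dmax = dmax_eff, rg = rg)
  attr(out, "chi2") <- chi2
  attr(out, "large_misfit") <- chi2 > 10
  out
}

#' Reduced chi-square fit of a model curve to an experimental curve
#'
#' The model is linearly interpolated onto the experimental q grid and
#' scaled as \eqn{c I_{model} + b} with `(c, b)` from weighted least
#' squares (set `fit_offset = FALSE` to force b = 0), then
#' \deqn{\chi^2 = \frac{1}{N-1}\sum\left(\frac{c I_{model}+b-I_{exp}}
#' {\sigma_{exp}}\right)^2.}
#'
#' @param model,experiment [ScatteringCurve-class] objects; the
#'   experimental curve needs positive errors.
#' @param fit_offset Fit an additive constant (default TRUE).
#' @return List: `chi2`, `scale`, `offset`, `n` (overlapping points).
#' @export
fitChi2 <- function(model, experiment, fit_offset = TRUE) {
  qe <- experiment@q; Ie <- experiment@I; se <- experiment@sigma
  inb <- qe >= min(model@q) & qe <= max(model@q)
  if (sum(inb) < 2) stop("overlap error: <2 overlapping q points")
  qe <- qe[inb]; Ie <- Ie[inb]; se <- se[inb]
  if (!all(is.finite(se)) || any(se <= 0)) se <- rep(1, length(qe))
  Im <- stats::approx(model@q, model@I, xout = qe)$y
  w <- 1 / se^2
  if (fit_offset) {
    Sw <- sum(w); Sx <- sum(w * Im); Sy <- sum(w * Ie)
    Sxx <- sum(w * Im^2); Sxy <- sum(w * Im * Ie)
    den <- Sw * Sxx - Sx^2
    cc <- (Sw * Sxy - Sx * Sy) / den
    b <- (Sy - cc * Sx) / Sw
  } else {
    cc <- sum(w * Im * Ie) / sum(w * Im^2)
    b <- 0
  }
  chi2 <- sum(w * (cc * Im + b - Ie)^2) / (length(qe) - 1)
  list(chi2 = chi2, scale = cc, offset = b, n = length(qe))
}

#' @describeIn scatteringCurve plot a scattering curve (log I vs q)
#' @param x A [ScatteringCurve-class].
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "ScatteringCurve", y = "missing"),
          function(x, y, ...) {
  graphics::plot(x@q, x@I, log = "y", xlab = expression(q ~ (ring(A)^-1)),
                 ylab = "I(q)", type = "l", ...)
})
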