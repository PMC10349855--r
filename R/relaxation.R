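## 15N relaxation: decay fitting, offset correction, tumbling analysis.

#' Read a relaxation decay table
#'
#' Delimited text with header columns `residue_number`, `delay_s`,
#' `intensity` and optionally `replicate_id` (to mark duplicate delays).
#'
#' @param path File path.
#' @return data.frame.
#' @export
readDecayTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  need <- c("residue_number", "delay_s", "intensity")
  if (!all(need %in% names(tab)))
    stop("decay table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Fit a mono-exponential relaxation decay
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R t}} to one residue's decay
#' series. When duplicate delays are present, the intensity uncertainty is
#' estimated as the root-mean-square of half the absolute difference within
#' each duplicate pair; this sets the fit weights, so the covariance-based
#' standard error of the rate carries the duplicate scatter.
#'
#' @param delays Delay times in seconds (duplicates allowed).
#' @param intensities Peak intensities (arbitrary units).
#' @return List with `rate` (1/s), `error` (1/s), `amplitude`, `sigma_I`
#'   (intensity uncertainty used; NA if no duplicates), and `flag`
#'   (`"ok"`, `"non-decaying"` or `"non-convergent"`). Flagged records
#'   should be excluded downstream.
#' @examples
#' t <- c(0.0216, 0.0864, 0.162, 0.2484, 0.3456, 0.5184, 0.6696, 0.8856,
#'        1.1448, 1.3824)
#' fitDecay(t, 100 * exp(-2 * t))$rate  # 2
#' @export
fitDecay <- function(delays, intensities) {
  stopifnot(length(delays) == length(intensities))
  keep <- is.finite(delays) & is.finite(intensities)
  t <- delays[keep]; I <- intensities[keep]
  if (length(unique(t)) < 4)
    stop("need >= 4 distinct delays for a decay fit")
  # duplicate-based intensity uncertainty
  sig <- NA_real_
  dup <- split(I, t)
  half <- unlist(lapply(dup[vapply(dup, length, 1L) > 1],
                        function(v) abs(diff(v)) / 2))
  if (length(half) > 0) sig <- sqrt(mean(half^2))
  if (stats::sd(I) < 1e-12 * max(abs(I), 1))
    return(list(rate = 0, error = 0, amplitude = mean(I), sigma_I = sig,
                flag = "non-decaying"))
  w <- if (is.finite(sig) && sig > 0) rep(1 / sig^2, length(I))
       else rep(1, length(I))
  # log-linear start (positive intensities only)
  pos <- I > 0
  start <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(I[pos]) ~ t[pos]))
    list(I0 = exp(cf[[1]]), R = max(-cf[[2]], 1e-6))
  } else list(I0 = max(I), R = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ I0 * exp(-R * t), start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(rate = NA_real_, error = NA_real_, amplitude = NA_real_,
                sigma_I = sig, flag = "non-convergent"))
  cf <- summary(fit)$coefficients
  list(rate = cf["R", "Estimate"], error = cf["R", "Std. Error"],
       amplitude = cf["I0", "Estimate"], sigma_I = sig, flag = "ok")
}

#' Fit relaxation rates for every residue of a decay table
#'
#' @param table data.frame as from [readDecayTable()].
#' @return data.frame with one row per residue: `residue_number`, `rate`,
#'   `error`, `amplitude`, `flag`.
#' @export
fitRates <- function(table) {
  res <- sort(unique(table$residue_number))
  out <- do.call(rbind, lapply(res, function(r) {
    d <- table[table$residue_number == r, ]
    f <- tryCatch(fitDecay(d$delay_s, d$intensity),
                  error = function(e) list(rate = NA, error = NA,
                                           amplitude = NA, flag = "error"))
    data.frame(residue_number = r, rate = f$rate, error = f$error,
               amplitude = f$amplitude, flag = f$flag)
  }))
  rownames(out) <- NULL
  out
}

#' Correct R1rho to R2 for resonance offset
#'
#' \deqn{R_{1\rho} = R_1 \cos^2\theta + R_2 \sin^2\theta,\qquad
#'   \theta = \arctan(\nu_1/\Delta\nu)}
#' solved for \eqn{R_2}. On resonance (`delta_nu = 0`, theta = 90 deg)
#' R2 equals R1rho.
#'
#' @param r1rho,r1 Rates in 1/s (vectorized).
#' @param nu1 Spin-lock field strength, Hz (> 0).
#' @param delta_nu Resonance offset, Hz.
#' @param sin2_floor Minimum \eqn{\sin^2\theta} considered reliable
#'   (default 0.25); smaller values are returned with attribute
#'   `"unreliable"` set.
#' @return R2 in 1/s, with logical attribute `"unreliable"` marking
#'   far-off-resonance corrections.
#' @export
offsetCorrectR2 <- function(r1rho, r1, nu1, delta_nu, sin2_floor = 0.25) {
  stopifnot(all(nu1 > 0))
  theta <- atan2(nu1, delta_nu)
  s2 <- sin(theta)^2
  r2 <- (r1rho - r1 * cos(theta)^2) / s2
  attr(r2, "unreliable") <- s2 < sin2_floor
  r2
}

# 15N/1H Larmor frequency ratio (gamma_N/gamma_H magnitudes)
.NH_FREQ_RATIO <- 0.1013291

#' Rotational correlation time from R2/R1
#'
#' The standard isotropic estimator
#' \deqn{\tau_c = \frac{1}{4\pi\nu_N}\sqrt{6 R_2/R_1 - 7}}
#' with \eqn{\nu_N} the 15N Larmor frequency at the given 1H field.
#' Valid only for \eqn{R_2/R_1 > 7/6} (slow-tumbling regime).
#'
#' @param r2_over_r1 Dimensionless ratio (vectorized).
#' @param field_1H 1H spectrometer frequency, MHz.
#' @return tau_c in nanoseconds.
#' @examples
#' tumblingTime(8.03, 600)  # ~8.4 ns
#' @export
tumblingTime <- function(r2_over_r1, field_1H) {
  if (any(6 * r2_over_r1 - 7 <= 0))
    stop("out of regime: R2/R1 must exceed 7/6 for the tauc estimator")
  nuN <- field_1H * 1e6 * .NH_FREQ_RATIO
  1e9 / (4 * pi * nuN) * sqrt(6 * r2_over_r1 - 7)
}

#' Theoretical tumbling time from molecular weight
#'
#' Empirical rule of thumb for a globular protein in water at 25 C:
#' \eqn{\tau_c \approx 0.6\ \mathrm{ns/kDa} \times MW}. Reported to one
#' decimal place (e.g. 14 kDa -> 8.4 ns, 10.9 kDa -> 6.5 ns,
#' 3.2 kDa -> 1.9 ns).
#'
#' @param mw Molecular weight in kDa (> 0).
#' @return tau_c in ns, rounded to 1 decimal.
#' @export
theoreticalTauc <- function(mw) {
  stopifnot(all(mw > 0))
  round(0.6 * mw, 1)
}

#' Domain-averaged tumbling times
#'
#' Arithmetic mean and sample SD of per-residue tau_c over each segment of
#' a partition. Segments with fewer than 2 valid residues are skipped with
#' a warning.
#'
#' @param tauc data.frame with columns `residue_number`, `tauc` (ns) and
#'   optionally `chain_id` (default "A") and `valid` (logical).
#' @param partition A [DomainPartition-class].
#' @return data.frame with `segment`, `n`, `mean_tauc`, `sd_tauc`.
#' @export
domainAverageTauc <- function(tauc, partition) {
  if (is.null(tauc$chain_id)) tauc$chain_id <- "A"
  if (is.null(tauc$valid)) tauc$valid <- TRUE
  tauc <- tauc[tauc$valid & is.finite(tauc$tauc), , drop = FALSE]
  s <- domainSegments(partition)
  rows <- list()
  for (i in seq_len(nrow(s))) {
    v <- tauc$tauc[tauc$chain_id == s$chain_id[i] &
                     tauc$residue_number >= s$start[i] &
                     tauc$residue_number <= s$end[i]]
    if (length(v) < 2) {
      warning(sprintf("segment %s skipped: <2 valid residues", s$name[i]))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      segment = s$name[i], n = length(v),
      mean_tauc = mean(v), sd_tauc = stats::sd(v))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(segment = character(), n = integer(),
                      mean_tauc = numeric(), sd_tauc = numeric())
  rownames(out) <- NULL
  out
}
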