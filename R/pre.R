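## PRE: intensity ratios -> Gamma2 -> distances -> flat-bottom restraints,
## and back-calculation of PRE profiles from coordinates.

#' Read / write a PRE profile
#'
#' Delimited text with header columns `residue_number`, `ratio` and
#' optionally `error`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
readPreProfile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!all(c("residue_number", "ratio") %in% names(tab)))
    stop("PRE profile must have columns residue_number, ratio")
  tab
}

#' @rdname readPreProfile
#' @param profile data.frame with `residue_number`, `ratio`, optional
#'   `error`.
#' @export
writePreProfile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Paramagnetic/diamagnetic intensity ratios
#'
#' Element-wise I_para/I_dia over residues shared between the two peak
#' tables. Residues with non-positive diamagnetic intensity are skipped
#' with a warning. Ratios above 1.2 are flagged anomalous. If both tables
#' carry an `intensity_error` column the ratio error is propagated in
#' quadrature.
#'
#' @param para,dia Peak tables (data.frames with `residue_number` and
#'   `intensity`).
#' @return data.frame with `residue_number`, `ratio`, `error` (NA when not
#'   propagated) and logical `anomalous`.
#' @export
intensityRatio <- function(para, dia) {
  shared <- intersect(para$residue_number, dia$residue_number)
  if (length(shared) == 0) stop("no shared residues between tables")
  pi_ <- match(shared, para$residue_number)
  di <- match(shared, dia$residue_number)
  Ip <- para$intensity[pi_]; Id <- dia$intensity[di]
  bad <- Id <= 0
  if (any(bad)) {
    warning(sprintf("%d residue(s) skipped: non-positive diamagnetic intensity",
                    sum(bad)))
    shared <- shared[!bad]; Ip <- Ip[!bad]; Id <- Id[!bad]
    pi_ <- pi_[!bad]; di <- di[!bad]
  }
  ratio <- Ip / Id
  err <- rep(NA_real_, length(ratio))
  if (!is.null(para$intensity_error) && !is.null(dia$intensity_error)) {
    err <- ratio * sqrt((para$intensity_error[pi_] / Ip)^2 +
                          (dia$intensity_error[di] / Id)^2)
  }
  out <- data.frame(residue_number = shared, ratio = ratio, error = err,
                    anomalous = ratio > 1.2)
  out[order(out$residue_number), , drop = FALSE]
}

#' Convert an intensity ratio to the PRE rate Gamma2
#'
#' Inverts
#' \deqn{I_{para}/I_{dia} = \frac{R_2 e^{-\Gamma_2 t}}{R_2 + \Gamma_2}}
#' for \eqn{\Gamma_2}, where \eqn{R_2} is the diamagnetic transverse rate
#' and \eqn{t} the total transverse evolution time of the HSQC. The right
#' side is strictly decreasing in Gamma2 so the root is unique; it is
#' found by bisection (uniroot) to 1e-8 relative tolerance.
#'
#' @param ratio Intensity ratio(s) in (0, 1]; vectorized.
#' @param r2_dia Diamagnetic R2, 1/s.
#' @param t_evol Transverse evolution time, seconds.
#' @return Gamma2 in 1/s. Ratios >= 1 return 0 (flag `"no-effect"`);
#'   ratios <= 0 return Inf (flag `"lower-bound-only"`: the amide is
#'   broadened beyond detection so Gamma2 is only bounded from below).
#'   Flags are in the character attribute `"flag"`.
#' @examples
#' g <- ratioToGamma2(0.3509, r2_dia = 15, t_evol = 0.01)  # ~20
#' @export
ratioToGamma2 <- function(ratio, r2_dia, t_evol) {
  stopifnot(r2_dia > 0, t_evol > 0)
  fwd <- function(g) r2_dia * exp(-g * t_evol) / (r2_dia + g)
  one <- function(rt) {
    if (rt >= 1) return(0)
    if (rt <= 0) return(Inf)
    hi <- 10
    while (fwd(hi) > rt) hi <- hi * 2
    stats::uniroot(function(g) fwd(g) - rt, c(0, hi), tol = 1e-8)$root
  }
  out <- vapply(ratio, one, 1.0)
  flag <- rep("ok", length(ratio))
  flag[ratio >= 1] <- "no-effect"
  flag[ratio <= 0] <- "lower-bound-only"
  attr(out, "flag") <- flag
  out
}

#' @rdname ratioToGamma2
#' @param gamma2 PRE rate(s), 1/s.
#' @return `gamma2ToRatio`: the forward intensity ratio.
#' @export
gamma2ToRatio <- function(gamma2, r2_dia, t_evol) {
  r2_dia * exp(-gamma2 * t_evol) / (r2_dia + gamma2)
}

# Solomon-Bloembergen prefactor for a nitroxide radical / amide 1H pair,
# cm^6 s^-2 (dipolar constant times S(S+1)/... folded into one constant).
.SB_K <- 1.23e-32

.sbSpectral <- function(tauc_s, field_1H) {
  omegaH <- 2 * pi * field_1H * 1e6
  4 * tauc_s + 3 * tauc_s / (1 + (omegaH * tauc_s)^2)
}

#' Electron-amide distance from the PRE rate (Solomon-Bloembergen)
#'
#' \deqn{r = \left[\frac{K}{\Gamma_2}\left(4\tau_c +
#'   \frac{3\tau_c}{1+\omega_H^2\tau_c^2}\right)\right]^{1/6}}
#' with \eqn{K = 1.23\times10^{-32}\,\mathrm{cm^6 s^{-2}}} and
#' \eqn{\omega_H} the 1H Larmor angular frequency. Monotone decreasing in
#' Gamma2.
#'
#' @param gamma2 PRE rate(s), 1/s (> 0).
#' @param tauc Effective correlation time, ns.
#' @param field_1H 1H frequency, MHz.
#' @return Distance in Angstrom.
#' @examples
#' gamma2ToDistance(50, tauc = 8.4, field_1H = 600.13)  # ~14.2 A
#' @export
gamma2ToDistance <- function(gamma2, tauc, field_1H) {
  if (any(gamma2 <= 0)) stop("undefined distance: gamma2 must be > 0")
  stopifnot(tauc > 0)
  r_cm6 <- .SB_K / gamma2 * .sbSpectral(tauc * 1e-9, field_1H)
  (r_cm6)^(1 / 6) * 1e8
}

#' @rdname gamma2ToDistance
#' @param r Distance(s), Angstrom.
#' @return `distanceToGamma2`: Gamma2 in 1/s.
#' @export
distanceToGamma2 <- function(r, tauc, field_1H) {
  stopifnot(all(r > 0), tauc > 0)
  .SB_K * .sbSpectral(tauc * 1e-9, field_1H) / (r * 1e-8)^6
}

#' Describe a spin-label site
#'
#' The effective unpaired-electron position is modeled as a fixed-length
#' offset from the attachment residue's CA along the CA->CB direction
#' (side-chain direction proxy); residues without CB use the CA position.
#'
#' @param residue_number Attachment residue.
#' @param chain_id Chain of the attachment residue (default "A").
#' @param label Label name (default "PROXYL").
#' @param offset Offset length in Angstrom (default 6).
#' @return A list of class `"SpinLabelSite"`.
#' @export
spinLabelSite <- function(residue_number, chain_id = "A",
                          label = "PROXYL", offset = 6) {
  structure(list(residue_number = as.integer(residue_number),
                 chain_id = chain_id, label = label, offset = offset),
            class = "SpinLabelSite")
}

#' @export
print.SpinLabelSite <- function(x, ...) {
  cat(sprintf("SpinLabelSite: %s at %s:%d (offset %.1f A)\n",
              x$label, x$chain_id, x$residue_number, x$offset))
  invisible(x)
}

.labelPosition <- function(conformer, site) {
  a <- atoms(conformer)
  ica <- .atomIndex(a, site$chain_id, site$residue_number, "CA")
  if (length(ica) != 1)
    stop(sprintf("attachment residue %s:%d not found in conformer",
                 site$chain_id, site$residue_number))
  ca <- as.numeric(c(a$x[ica], a$y[ica], a$z[ica]))
  icb <- .atomIndex(a, site$chain_id, site$residue_number, "CB")
  if (length(icb) != 1) return(ca)
  cb <- as.numeric(c(a$x[icb], a$y[icb], a$z[icb]))
  u <- cb - ca
  ca + site$offset * u / sqrt(sum(u^2))
}

.amideProxyIndices <- function(a, chain_id, residues = NULL) {
  # amide proton proxy: backbone N position (pseudo-atomic resolution)
  sel <- a$chain_id == chain_id & a$atom_name == "N"
  if (!is.null(residues)) sel <- sel & a$residue_number %in% residues
  which(sel)
}

#' Back-calculate a PRE profile from coordinates
#'
#' For each residue of a chain the electron-amide distance (backbone N as
#' amide proxy) to the effective label position is converted to Gamma2 via
#' the Solomon-Bloembergen relation and to an intensity ratio via
#' [gamma2ToRatio()].
#'
#' @param conformer A [Conformer-class].
#' @param site A [spinLabelSite()].
#' @param tauc Effective correlation time, ns.
#' @param field_1H 1H frequency, MHz.
#' @param t_evol Transverse evolution time, seconds.
#' @param r2_dia Diamagnetic R2, 1/s.
#' @param chain_id Chain to profile (default the site's chain).
#' @param residues Optional residue subset.
#' @return data.frame with `residue_number`, `distance` (A), `gamma2`
#'   (1/s), `ratio`.
#' @export
backcalculatePre <- function(conformer, site, tauc, field_1H, t_evol,
                             r2_dia, chain_id = site$chain_id,
                             residues = NULL) {
  a <- atoms(conformer)
  idx <- .amideProxyIndices(a, chain_id, residues)
  if (length(idx) == 0) stop("no amide proxy atoms (N) found in chain")
  lab <- .labelPosition(conformer, site)
  X <- cbind(a$x[idx], a$y[idx], a$z[idx])
  d <- sqrt(rowSums(sweep(X, 2, lab)^2))
  g <- distanceToGamma2(d, tauc, field_1H)
  data.frame(residue_number = a$residue_number[idx], distance = d,
             gamma2 = g, ratio = gamma2ToRatio(g, r2_dia, t_evol))
}

#' Classify PRE ratios and build flat-bottom distance restraints
#'
#' Ratios below `low_cut` give upper-bound-only restraints (the amide is
#' close to the label; only r(low_cut) bounds it from above); ratios
#' between the cuts give quantitative restraints with target from the full
#' ratio -> Gamma2 -> distance conversion and bounds target +/- `tol`;
#' ratios above `high_cut` give lower-bound-only restraints. One restraint
#' per residue, from the backbone amide proxy to the effective label
#' position. The three classes are exhaustive and mutually exclusive.
#' When the profile carries an `error` column, a ratio whose error
#' interval crosses a cut is assigned the less informative class
#' (conservative handling of borderline peaks); without errors the cuts
#' apply to the ratio directly.
#'
#' @param profile PRE profile data.frame (`residue_number`, `ratio`).
#' @param site A [spinLabelSite()].
#' @param tauc,field_1H,t_evol,r2_dia Conversion parameters (tauc ns,
#'   field MHz, t_evol s, r2_dia 1/s). All required.
#' @param low_cut,high_cut Ratio thresholds (defaults 0.15 and 0.85).
#' @param tol Quantitative-class bound half-width, Angstrom (default 4).
#' @param weight Restraint weight (default 1).
#' @return data.frame with one row per residue: `residue_number`,
#'   `chain_id`, `site_residue`, `site_chain`, `site_offset`, `class`
#'   (`upper`/`quantitative`/`lower`), `target`, `lower`, `upper`,
#'   `weight`, `type = "pre"`. `Inf` upper bounds mark lower-bound-only
#'   restraints.
#' @export
buildPreRestraints <- function(profile, site, tauc, field_1H, t_evol,
                               r2_dia, low_cut = 0.15, high_cut = 0.85,
                               tol = 4, weight = 1) {
  if (missing(tauc) || missing(field_1H) || missing(t_evol) ||
      missing(r2_dia))
    stop("configuration error: tauc, field_1H, t_evol and r2_dia required")
  stopifnot(nrow(profile) > 0, low_cut < high_cut)
  rUpper <- gamma2ToDistance(
    ratioToGamma2(low_cut, r2_dia, t_evol), tauc, field_1H)
  rLower <- gamma2ToDistance(
    ratioToGamma2(high_cut, r2_dia, t_evol), tauc, field_1H)
  n <- nrow(profile)
  err <- if (!is.null(profile$error)) abs(profile$error) else rep(0, n)
  # classification on the error-widened interval: a ratio whose interval
  # crosses a cut takes the less informative class, so noisy ratios near
  # 1 never become spurious quantitative targets
  cls <- ifelse(profile$ratio < low_cut, "upper",
                ifelse(profile$ratio + err > high_cut, "lower",
                       "quantitative"))
  cls[cls == "quantitative" & profile$ratio - err < low_cut] <- "upper"
  target <- lower <- upper <- numeric(n)
  for (i in seq_len(n)) {
    if (cls[i] == "upper") {
      target[i] <- rUpper; lower[i] <- 0; upper[i] <- rUpper
    } else if (cls[i] == "lower") {
      target[i] <- rLower; lower[i] <- rLower; upper[i] <- Inf
    } else {
      g <- ratioToGamma2(profile$ratio[i], r2_dia, t_evol)
      target[i] <- gamma2ToDistance(g, tauc, field_1H)
      lower[i] <- max(0, target[i] - tol); upper[i] <- target[i] + tol
    }
  }
  data.frame(residue_number = profile$residue_number,
             chain_id = if (!is.null(profile$chain_id)) profile$chain_id
                        else site$chain_id,
             site_residue = site$residue_number, site_chain = site$chain_id,
             site_offset = site$offset, class = cls,
             target = target, lower = lower, upper = upper,
             weight = weight, type = "pre", stringsAsFactors = FALSE)
}

#' Write restraints to a delimited table or assign-style text
#'
#' @param restraints Restraint data.frame ([buildPreRestraints()] or
#'   [buildAmbiguousRestraints()] output).
#' @param path Output path.
#' @param format `"table"` (tab-delimited with header) or `"assign"`
#'   (one `assign (resid i) (resid j...) target minus plus` line per
#'   restraint, for external refinement programs).
#' @return Invisibly, `path`.
#' @export
writeRestraints <- function(restraints, path, format = c("table", "assign")) {
  format <- match.arg(format)
  if (format == "table") {
    utils::write.table(restraints, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    lines <- vapply(seq_len(nrow(restraints)), function(i) {
      r <- restraints[i, ]
      partner <- if (identical(r$type, "pre"))
        sprintf("(resid %d and name LABEL)", r$site_residue)
      else sprintf("(resid %s)", gsub(",", " or resid ", r$rna_positions))
      lo <- if (is.finite(r$lower)) r$target - r$lower else r$target
      hi <- if (is.finite(r$upper)) r$upper - r$target else 999
      sprintf("assign (resid %d) %s %.2f %.2f %.2f",
              r$residue_number, partner, r$target, lo, hi)
    }, "")
    writeLines(lines, path)
  }
  invisible(path)
}
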