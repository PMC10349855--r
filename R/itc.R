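## ITC: one-site isotherm simulation, nonlinear fitting, thermodynamics.

# gas constant in kcal / (mol K)
.R_KCAL <- 1.987e-3

# Cell concentrations after each injection under the exact stepwise
# displacement model: every injection of volume v dilutes the cell content
# by (1 - v/V0) and adds v*Ls/V0 of titrant.
.itcConcentrations <- function(iso) {
  v <- iso@injVolumes
  n <- length(v)
  Mt <- Lt <- numeric(n)
  M <- iso@cellConc; L <- 0
  for (i in seq_len(n)) {
    f <- 1 - v[i] / iso@cellVolume
    M <- M * f
    L <- L * f + iso@syringeConc * v[i] / iso@cellVolume
    Mt[i] <- M; Lt[i] <- L
  }
  list(Mt = Mt, Lt = Lt)
}

# bound ligand concentration for the one-site model (quadratic root)
.boundLigand <- function(Mt, Lt, kd, n) {
  sites <- n * Mt
  b <- sites + Lt + kd
  (b - sqrt(pmax(b^2 - 4 * sites * Lt, 0))) / 2
}

.predictHeats <- function(iso, kd, dh, n) {
  conc <- .itcConcentrations(iso)
  LB <- .boundLigand(conc$Mt, conc$Lt, kd, n)
  Q <- iso@cellVolume * LB * dh          # kcal of heat content in the cell
  Qprev <- c(0, Q[-length(Q)])
  dv <- iso@injVolumes / iso@cellVolume
  # displaced-volume correction: each injection expels cell liquid carrying
  # the average heat content of the step (Origin/Wiseman convention)
  Q - Qprev + dv * (Q + Qprev) / 2
}

#' Simulate a one-site ITC isotherm
#'
#' Heats per injection are differences of the cumulative bound-ligand heat
#' content between injections, with the stepwise displaced-volume dilution
#' correction, plus optional Gaussian noise. Mass conservation is
#' respected at every injection. A c-value (`n * [cell] / KD`) outside the
#' fittable 1-1000 window triggers a warning.
#'
#' @param kd Dissociation constant, mol/L.
#' @param dh Binding enthalpy, kcal/mol.
#' @param n Stoichiometry (sites per macromolecule).
#' @param protocol An [Isotherm-class] carrying the protocol (heats
#'   ignored); e.g. `isotherm(200e-6, 10e-6, 130e-6, rep(1.5e-6, 26))`.
#' @param noise Gaussian noise SD on each heat, kcal (default 0).
#' @return The protocol [Isotherm-class] with simulated `heats` filled in.
#' @export
simulateIsotherm <- function(kd, dh, n, protocol, noise = 0) {
  stopifnot(kd > 0, n > 0)
  cval <- n * protocol@cellConc / kd
  if (cval < 1 || cval > 1000)
    warning(sprintf("c-value %.3g outside the fittable 1-1000 window", cval))
  q <- .predictHeats(protocol, kd, dh, n)
  if (noise > 0) q <- q + stats::rnorm(length(q), 0, noise)
  new("Isotherm", cellVolume = protocol@cellVolume,
      cellConc = protocol@cellConc, syringeConc = protocol@syringeConc,
      injVolumes = protocol@injVolumes, heats = q,
      temperature = protocol@temperature)
}

#' Fit the one-site binding model to an isotherm
#'
#' Nonlinear least squares over (KD, dH, N) on the injection heats
#' (Levenberg-Marquardt, log-parametrized KD, multi-start over a KD
#' grid). `fix_n` fixes the stoichiometry (e.g. `fix_n = 1` for
#' low-c-value data where N is not identifiable).
#'
#' @param iso An [Isotherm-class] with heats.
#' @param fix_n Optional fixed stoichiometry.
#' @param skip_first Drop the first injection before fitting (common
#'   practice for the small pre-diffusion artifact; default FALSE).
#' @return List of class `"BindingFit"`: `kd`, `kd_se`, `dh`, `dh_se`,
#'   `n`, `n_se` (NA when fixed), `residuals`, `rss`, `converged`.
#' @export
fitOneSite <- function(iso, fix_n = NULL, skip_first = FALSE) {
  q <- iso@heats
  use <- seq_along(q)
  if (skip_first) use <- use[-1]
  if (length(use) < 10) stop("need >= 10 informative injections")
  qobs <- q[use]
  dh0 <- sum(qobs) / (iso@cellVolume * iso@cellConc *
                        if (is.null(fix_n)) 1 else fix_n)
  resid_fun <- function(lkd, dh, nn) {
    .predictHeats(iso, exp(lkd), dh, nn)[use] - qobs
  }
  best <- NULL
  for (lkd0 in log(10^seq(-9, -3, by = 1))) {
    fit <- tryCatch({
      if (is.null(fix_n)) {
        minpack.lm::nls.lm(
          par = list(lkd = lkd0, dh = dh0, nn = 1),
          fn = function(par) resid_fun(par$lkd, par$dh, par$nn),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        minpack.lm::nls.lm(
          par = list(lkd = lkd0, dh = dh0),
          fn = function(par) resid_fun(par$lkd, par$dh, fix_n),
          control = minpack.lm::nls.lm.control(maxiter = 500))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("fit error: one-site model did not converge")
  fit <- best$fit
  par <- fit$par
  # standard errors from the parameter covariance
  se <- tryCatch({
    covm <- tryCatch(solve(fit$hessian) * 2 *
                       best$rss / max(length(use) - length(par), 1),
                     error = function(e) matrix(NA, length(par), length(par)))
    sqrt(abs(diag(covm)))
  }, error = function(e) rep(NA_real_, length(par)))
  kd <- exp(par$lkd)
  kd_se <- kd * se[1]  # delta method for the log parametrization
  nn <- if (is.null(fix_n)) par$nn else fix_n
  structure(list(kd = kd, kd_se = kd_se, dh = par$dh, dh_se = se[2],
                 n = nn, n_se = if (is.null(fix_n)) se[3] else NA_real_,
                 residuals = fit$fvec, rss = best$rss,
                 converged = fit$info %in% 1:4),
            class = "BindingFit")
}

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf("One-site binding fit: KD = %.3g M, dH = %.3g kcal/mol, N = %.3g\n",
              x$kd, x$dh, x$n))
  invisible(x)
}

#' Binding thermodynamics from KD and dH
#'
#' \deqn{\Delta G = RT\ln K_D,\qquad -T\Delta S = \Delta G - \Delta H}
#' with R = 1.987e-3 kcal/(mol K). The closure
#' \eqn{\Delta G = \Delta H + (-T\Delta S)} holds exactly.
#'
#' @param kd Dissociation constant, mol/L (> 0).
#' @param dh Binding enthalpy, kcal/mol.
#' @param temperature Kelvin (default 298.15).
#' @return List: `dG` and `minus_TdS`, kcal/mol.
#' @examples
#' bindingThermodynamics(0.127e-6, -19.1)$minus_TdS  # ~9.68
#' @export
bindingThermodynamics <- function(kd, dh, temperature = 298.15) {
  stopifnot(all(kd > 0))
  dG <- .R_KCAL * temperature * log(kd)
  list(dG = dG, minus_TdS = dG - dh)
}

#' Reference ITC thermodynamics for the RBM5 RNA-binding constructs
#'
#' Duplicate one-site ITC measurements (KD, binding enthalpy, entropic
#' term and stoichiometry at 25 C) for the RBM5 RRM and zinc-finger
#' construct series binding short single-stranded RNAs, used as the
#' input for the package's thermodynamic consistency checks
#' ([bindingThermodynamics()] closure). `n_fixed` marks fits with the
#' stoichiometry fixed to 1 (weak binders). For the RRM1-ZnF1 wt / CU_9
#' replicate 2 entry the tabulated entropic term is sign-inconsistent
#' with the closure from its own (KD, dH) pair; `sign_inconsistent`
#' flags it, and consistency checks compare magnitudes there.
#'
#' @return data.frame with columns `protein`, `rna`, `replicate`,
#'   `kd_uM`, `dh_kcal`, `minus_tds_kcal`, `n`, `n_fixed`,
#'   `sign_inconsistent`.
#' @export
itcReferenceTable <- function() {
  tab <- rbind(
    c("RRM1", "CU_9", 1, 13.2, -7.3, 0.61, 1.04, 0, 0),
    c("RRM1", "CU_9", 2, 26.2, -10.0, 3.76, 1, 1, 0),
    c("RRM1", "GGCU_12", 1, 0.93, -11.7, 3.49, 0.97, 0, 0),
    c("RRM1", "GGCU_12", 2, 2.83, -10.6, 3.06, 1.01, 0, 0),
    c("RRM2", "GGCU_12", 1, 171, -24.5, 19.2, 1, 1, 0),
    c("RRM2", "GGCU_12", 2, 174, -25.8, 20.6, 1, 1, 0),
    c("RRM1-ZnF1 wt", "CU_9", 1, 8.39, -11.8, 4.88, 1.02, 0, 0),
    c("RRM1-ZnF1 wt", "CU_9", 2, 2.73, -6.23, 1.36, 0.94, 0, 1),
    c("RRM1-ZnF1 wt", "GGCU_12", 1, 0.084, -16.2, 6.57, 1.02, 0, 0),
    c("RRM1-ZnF1 wt", "GGCU_12", 2, 0.222, -14.1, 4.99, 0.81, 0, 0),
    c("RRM1-ZnF1 F142/144A", "GGCU_12", 1, 0.469, -12.7, 4.05, 0.7, 0, 0),
    c("RRM1-ZnF1 F142/144A", "GGCU_12", 2, 0.427, -12.0, 3.31, 0.97, 0, 0),
    c("RRM1-ZnF1 F202A", "GGCU_12", 1, 0.368, -9.58, 0.80, 1.03, 0, 0),
    c("RRM1-ZnF1 F202A", "GGCU_12", 2, 0.390, -9.74, 1.00, 1.01, 0, 0),
    c("RRM1-ZnF1 R198E", "GGCU_12", 1, 2.69, -10.7, 3.08, 1.05, 0, 0),
    c("RRM1-ZnF1 R198E", "GGCU_12", 2, 2.63, -8.37, 0.75, 1.11, 0, 0),
    c("RRM1-ZnF1_S", "GGCU_12", 1, 0.273, -10.5, 1.56, 1.08, 0, 0),
    c("RRM1-ZnF1_S", "GGCU_12", 2, 0.253, -10.9, 1.94, 1.06, 0, 0),
    c("RRM1-ZnF1_Se", "GGCU_12", 1, 0.766, -15.2, 6.90, 0.63, 0, 0),
    c("RRM1-ZnF1_Se", "GGCU_12", 2, 0.516, -14.2, 5.66, 0.60, 0, 0),
    c("RRM1-ZnF1_S-RRM2", "GGCU_12", 1, 0.127, -19.1, 9.68, 0.98, 0, 0),
    c("RRM1-ZnF1_S-RRM2", "GGCU_12", 2, 0.138, -18.1, 8.70, 1.01, 0, 0))
  data.frame(protein = tab[, 1], rna = tab[, 2],
             replicate = as.integer(tab[, 3]),
             kd_uM = as.numeric(tab[, 4]), dh_kcal = as.numeric(tab[, 5]),
             minus_tds_kcal = as.numeric(tab[, 6]),
             n = as.numeric(tab[, 7]),
             n_fixed = as.numeric(tab[, 8]) == 1,
             sign_inconsistent = as.numeric(tab[, 9]) == 1,
             stringsAsFactors = FALSE)
}

#' Read / write an isotherm file
#'
#' Delimited text with a small config header in comment lines
#' (`# cell_volume_ul`, `# cell_conc_uM`, `# syringe_conc_uM`,
#' `# temperature_K`) followed by a header row and columns
#' `injection_index`, `volume_ul`, `heat_ucal`.
#'
#' @param path File path.
#' @return An [Isotherm-class] (heats in kcal).
#' @export
readIsotherm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    ln <- grep(paste0("#\\s*", key), hdr, value = TRUE)
    if (length(ln) == 0) stop("isotherm file missing config key: ", key)
    as.numeric(sub(".*\\s", "", trimws(ln[1])))
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  isotherm(cellVolume = getval("cell_volume_ul") * 1e-6,
           cellConc = getval("cell_conc_uM") * 1e-6,
           syringeConc = getval("syringe_conc_uM") * 1e-6,
           injVolumes = tab$volume_ul * 1e-6,
           heats = tab$heat_ucal * 1e-9,
           temperature = getval("temperature_K"))
}

#' @rdname readIsotherm
#' @param iso An [Isotherm-class].
#' @export
writeIsotherm <- function(iso, path) {
  hdr <- c(sprintf("# cell_volume_ul %.6g", iso@cellVolume * 1e6),
           sprintf("# cell_conc_uM %.6g", iso@cellConc * 1e6),
           sprintf("# syringe_conc_uM %.6g", iso@syringeConc * 1e6),
           sprintf("# temperature_K %.6g", iso@temperature))
  q <- if (length(iso@heats)) iso@heats else rep(NA_real_,
                                                 length(iso@injVolumes))
  tab <- sprintf("%d %.6g %.8g", seq_along(iso@injVolumes),
                 iso@injVolumes * 1e6, q * 1e9)
  writeLines(c(hdr, "injection_index volume_ul heat_ucal", tab), path)
  invisible(path)
}

#' @describeIn isotherm plot heats per mole injectant vs molar ratio
#' @param x An [Isotherm-class].
#' @param y Ignored.
#' @param ... Passed to [graphics::plot()].
#' @export
setMethod("plot", signature(x = "Isotherm", y = "missing"),
          function(x, y, ...) {
  molinj <- x@syringeConc * x@injVolumes
  graphics::plot(molarRatio(x), x@heats / molinj,
                 xlab = "molar ratio", ylab = "kcal/mol of injectant", ...)
})
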