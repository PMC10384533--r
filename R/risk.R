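# Benzo[a]pyrene toxic-equivalent concentrations and incremental lifetime
# cancer risk (ILCR) by the USEPA ingestion and dermal-contact pathways,
# with the three-band classification.

#' Toxic equivalency factors of the 16 priority PAHs
#'
#' Potency of each congener relative to benzo\[a\]pyrene (BaP = 1).
#'
#' @return Named numeric vector over the 16 congener abbreviations.
#' @export
default_tef <- function() {
  c(NAP = 0.001, ANY = 0.001, ANA = 0.001, FLU = 0.001,
    PHE = 0.001, ANT = 0.01, FLT = 0.001, PYR = 0.001,
    BaA = 0.1, CHR = 0.001, BbF = 0.1, BkF = 0.1,
    BaP = 1, IcdP = 0.1, DBA = 1, BPE = 0.01)
}

#' BaP toxic-equivalent concentration
#'
#' `TEQ = sum(C_i * TEF_i)` over the named congeners.
#'
#' @param conc named numeric vector (or list) of congener concentrations
#'   (ng/g), all non-negative.
#' @param tef TEF table (named vector), default [default_tef()].
#' @return TEQ (ng/g).
#' @export
toxic_equivalent <- function(conc, tef = default_tef()) {
  conc <- unlist(conc)
  if (any(conc < 0)) .stopf("concentrations must be non-negative")
  unknown <- setdiff(names(conc), names(tef))
  if (length(unknown) > 0) {
    .stopf("unknown PAH name(s): %s", paste(unknown, collapse = ", "))
  }
  sum(conc * tef[names(conc)])
}

#' Exposure parameters of the ILCR model
#'
#' @param EF exposure frequency (d/y); @param ED exposure duration (y);
#' @param IR sediment ingestion rate (mg/d); @param SA dermal exposure area
#'   (cm^2/d); @param AF dermal adherence factor (mg/cm^2); @param ABS
#'   dermal absorption fraction, in (0, 1]; @param AT averaging time (d);
#' @param BW body weight (kg); @param CSF_ing,CSF_derm carcinogenic slope
#'   factors for the two pathways ((mg/(kg d))^-1); @param PEF particle
#'   emission factor (m^3/kg), carried for completeness but unused (no
#'   inhalation pathway is modelled).
#' @return `ilcr_params` list.
#' @export
ilcr_params <- function(EF = 350, ED = 40, IR = 100, SA = 5700,
                        AF = 0.07, ABS = 0.13, AT = 70 * 365, BW = 70,
                        CSF_ing = 7.3, CSF_derm = 3.85, PEF = 1.36e9) {
  p <- as.list(environment())
  if (any(unlist(p) <= 0)) .stopf("all ILCR parameters must be positive")
  if (ABS > 1) .stopf("ABS must lie in (0, 1]")
  class(p) <- "ilcr_params"
  p
}

#' ILCR by sediment ingestion
#'
#' `CS * CSF_ing * (BW/70)^(1/3) * IR * EF * ED / (BW * AT * 1e6)`.
#'
#' @param CS sediment TEQ concentration (ng/g), >= 0 (vectorized).
#' @param p an [ilcr_params()].
#' @return Dimensionless lifetime risk increment.
#' @export
ilcr_ingestion <- function(CS, p = ilcr_params()) {
  if (any(CS < 0)) .stopf("CS must be non-negative")
  CS * p$CSF_ing * (p$BW / 70)^(1 / 3) * p$IR * p$EF * p$ED / (p$BW * p$AT * 1e6)
}

#' ILCR by dermal contact
#'
#' `CS * CSF_derm * (BW/70)^(1/3) * SA * AF * ABS * EF * ED / (BW * AT * 1e6)`.
#'
#' @inheritParams ilcr_ingestion
#' @export
ilcr_dermal <- function(CS, p = ilcr_params()) {
  if (any(CS < 0)) .stopf("CS must be non-negative")
  CS * p$CSF_derm * (p$BW / 70)^(1 / 3) * p$SA * p$AF * p$ABS * p$EF * p$ED /
    (p$BW * p$AT * 1e6)
}

#' Classify a total ILCR value
#'
#' `negligible` below 1e-6, `potential` in `[1e-6, 1e-4]`, `high` above
#' 1e-4 (the boundary values belong to the potential band).
#'
#' @param ilcr_total total ILCR, >= 0 (vectorized).
#' @return Character vector of bands.
#' @export
classify_risk <- function(ilcr_total) {
  if (any(ilcr_total < 0)) .stopf("ILCR must be non-negative")
  ifelse(ilcr_total < 1e-6, "negligible",
         ifelse(ilcr_total > 1e-4, "high", "potential"))
}

#' Sediment TEQ from a total-PAH bed field
#'
#' The transport model tracks the congener sum; speciation enters only here,
#' through a fixed congener composition profile.  `TEQ = C_total *
#' sum(profile * TEF)` with the profile fractions summing to 1 (uniform over
#' the 16 congeners by default).
#'
#' @param C_sed total-PAH bed concentration(s), ng/g (matrix or vector).
#' @param profile named fractions over the congeners, summing to 1.
#' @param tef TEF table.
#' @return TEQ field, same shape as `C_sed`.
#' @export
sediment_teq <- function(C_sed, profile = NULL, tef = default_tef()) {
  if (is.null(profile)) {
    profile <- setNames(rep(1 / length(tef), length(tef)), names(tef))
  }
  if (abs(sum(profile) - 1) > 1e-9) .stopf("profile fractions must sum to 1")
  unknown <- setdiff(names(profile), names(tef))
  if (length(unknown) > 0) {
    .stopf("unknown PAH name(s): %s", paste(unknown, collapse = ", "))
  }
  w <- sum(profile * tef[names(profile)])
  C_sed * w
}

#' Per-cell cancer-risk map from a sediment TEQ field
#'
#' Applies the ingestion and dermal ILCR equations and the band
#' classification to every sea cell.
#'
#' @param teq matrix of sediment TEQ (ng/g) on the grid, or a numeric
#'   vector.
#' @param p an [ilcr_params()].
#' @param grid optional [bay_grid()]; when given, only sea cells are mapped.
#' @return `risk_map` data frame with columns `i`, `j`, `teq`, `ilcr_ing`,
#'   `ilcr_derm`, `ilcr_total`, `band`; attribute `"summary"` holds the
#'   min/max of the total ILCR.
#' @export
risk_map <- function(teq, p = ilcr_params(), grid = NULL) {
  if (is.matrix(teq)) {
    keep <- if (is.null(grid)) matrix(TRUE, nrow(teq), ncol(teq)) else sea_cells(grid)
    idx <- which(keep, arr.ind = TRUE)
    vals <- teq[keep]
  } else {
    idx <- cbind(seq_along(teq), rep(1L, length(teq)))
    vals <- as.numeric(teq)
  }
  bad <- which(vals < 0 | !is.finite(vals))
  if (length(bad) > 0) {
    .stopf("invalid TEQ at cell (%d, %d)", idx[bad[1], 1], idx[bad[1], 2])
  }
  ing <- ilcr_ingestion(vals, p)
  der <- ilcr_dermal(vals, p)
  tot <- ing + der
  out <- data.frame(i = idx[, 1], j = idx[, 2], teq = vals,
                    ilcr_ing = ing, ilcr_derm = der, ilcr_total = tot,
                    band = classify_risk(tot), stringsAsFactors = FALSE)
  attr(out, "summary") <- c(min = min(tot), max = max(tot))
  class(out) <- c("risk_map", "data.frame")
  out
}
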