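#' DPPH assay plate
#'
#' Concentration series of sample absorbances (OD at 517 nm unless stated
#' otherwise) against a control absorbance, the raw material for scavenging
#' percentages and EC50 estimation.
#'
#' @param concentration Numeric vector, microgram mL^-1 (> 0).
#' @param od_sample Numeric vector of sample absorbances (>= 0), same length.
#' @param od_control Control absorbance(s) (> 0); several control readings are
#'   averaged.
#' @param replicate Replicate identifiers (default all 1).
#' @param compound Compound name (metadata).
#' @param molar_mass Optional molar mass, g mol^-1, for molar conversions.
#' @param wavelength Detection wavelength, nm (metadata, default 517).
#' @param censor_at Reporting cap for censored EC50 labels, microgram mL^-1.
#'   Default NULL: censor at the largest tested concentration. Assays often
#'   validate a narrower reporting range than they test (e.g. because the
#'   vehicle interferes at the top dose); setting this reproduces such
#'   conventions.
#' @return An object of class \code{assay_plate}.
#' @export
assay_plate <- function(concentration, od_sample, od_control,
                        replicate = NULL, compound = "sample",
                        molar_mass = NULL, wavelength = 517,
                        censor_at = NULL) {
  concentration <- as.numeric(concentration)
  od_sample <- as.numeric(od_sample)
  if (length(concentration) != length(od_sample)) {
    stop("concentration and od_sample must have the same length")
  }
  if (any(concentration <= 0)) stop("concentrations must be > 0")
  if (any(od_sample < 0)) stop("OD readings must be >= 0")
  if (length(od_control) < 1 || any(od_control <= 0)) {
    stop("at least one positive control reading is required")
  }
  if (is.null(replicate)) replicate <- rep(1L, length(concentration))
  structure(
    list(data = data.frame(concentration = concentration,
                           od_sample = od_sample,
                           replicate = replicate,
                           stringsAsFactors = FALSE),
         od_control = mean(od_control),
         compound = compound, molar_mass = molar_mass,
         wavelength = wavelength, censor_at = censor_at),
    class = "assay_plate"
  )
}

#' @export
print.assay_plate <- function(x, ...) {
  cat("<assay_plate> ", x$compound, ": ",
      length(unique(x$data$concentration)), " concentration(s), ",
      nrow(x$data), " well(s), OD_0 = ", format(x$od_control),
      " @ ", x$wavelength, " nm\n", sep = "")
  invisible(x)
}

#' Read a plate CSV
#'
#' Columns \code{compound, concentration_ug_ml, od_sample, replicate};
#' control wells are rows with \code{compound == "CONTROL"} (their
#' \code{concentration_ug_ml} is ignored).
#'
#' @param path CSV path.
#' @param compound Which compound to extract; required when the file holds
#'   several.
#' @param molar_mass Optional molar mass passed through to the plate object.
#' @param censor_at Optional reporting cap passed through to the plate object.
#' @return An \code{assay_plate}.
#' @export
read_plate <- function(path, compound = NULL, molar_mass = NULL,
                       censor_at = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("compound", "concentration_ug_ml", "od_sample", "replicate")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("plate CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  ctrl <- raw[raw$compound == "CONTROL", , drop = FALSE]
  if (nrow(ctrl) == 0) stop("plate CSV has no CONTROL rows")
  smp <- raw[raw$compound != "CONTROL", , drop = FALSE]
  cmp <- unique(smp$compound)
  if (is.null(compound)) {
    if (length(cmp) != 1) {
      stop("plate holds several compounds (", paste(cmp, collapse = ", "),
           "); pick one with the 'compound' argument")
    }
    compound <- cmp
  }
  smp <- smp[smp$compound == compound, , drop = FALSE]
  if (nrow(smp) == 0) stop("no rows for compound '", compound, "'")
  assay_plate(concentration = smp$concentration_ug_ml,
              od_sample = smp$od_sample,
              od_control = ctrl$od_sample,
              replicate = smp$replicate,
              compound = compound, molar_mass = molar_mass,
              censor_at = censor_at)
}

#' Scavenging percentage
#'
#' SP(%) = 100 (OD_0 - OD_1) / OD_0. Negative values (pro-oxidant readings)
#' are returned as-is; clamp only when reporting.
#'
#' @param od_control Control absorbance OD_0 (> 0).
#' @param od_sample Sample absorbance OD_1 (>= 0). Vectorized.
#' @return Percent scavenging.
#' @examples
#' sp_percent(0.50, 0.35)  # 30
#' @export
sp_percent <- function(od_control, od_sample) {
  if (any(od_control <= 0)) stop("od_control must be > 0")
  if (any(od_sample < 0)) stop("od_sample must be >= 0")
  100 * (od_control - od_sample) / od_control
}

#' Four-parameter logistic with fixed bottom
#' @keywords internal
.fpl <- function(conc, top, ec50, hill) {
  top / (1 + (ec50 / conc)^hill)
}

#' Dose-response fit with censoring
#'
#' Aggregates replicate scavenging percentages to mean +/- sd per
#' concentration, then either (a) reports a censored EC50 "> C_max" when the
#' largest mean SP stays below 50% (the concentration ladder never reaches
#' half-scavenging, so no numeric estimate is defensible), or (b) fits a
#' four-parameter logistic with bottom fixed at 0 and top bounded by 100 by
#' least squares on the concentration means:
#' SP(c) = top / (1 + (EC50 / c)^hill).
#'
#' @param plate An \code{assay_plate} with at least 3 distinct concentrations.
#' @return An object of class \code{dose_response_fit} with fields
#'   \code{ec50} (numeric, NA when censored), \code{censored},
#'   \code{c_max}, \code{label} (e.g. ">128" or the estimate), \code{hill},
#'   \code{top}, \code{bottom} (0), \code{sp_by_conc} (concentration, mean,
#'   sd, n) and \code{monotone} (diagnostic: means non-increasing with
#'   dilution).
#' @examples
#' pl <- simulate_plate(true_ec50 = 20, seed = 1)
#' fit_dose_response(pl)
#' @export
fit_dose_response <- function(plate) {
  stopifnot(inherits(plate, "assay_plate"))
  d <- plate$data
  d$sp <- sp_percent(plate$od_control, d$od_sample)
  agg <- do.call(rbind, lapply(split(d, d$concentration), function(g) {
    data.frame(concentration = g$concentration[1], mean_sp = mean(g$sp),
               sd_sp = stats::sd(g$sp), n = nrow(g))
  }))
  agg <- agg[order(agg$concentration), , drop = FALSE]
  rownames(agg) <- NULL
  if (nrow(agg) < 3) {
    stop("dose-response fitting needs at least 3 distinct concentrations")
  }
  c_max <- max(agg$concentration)
  monotone <- !is.unsorted(agg$mean_sp)
  res <- list(c_max = c_max, sp_by_conc = agg, bottom = 0,
              monotone = monotone, compound = plate$compound)
  if (max(agg$mean_sp) < 50) {
    cap <- if (!is.null(plate$censor_at)) plate$censor_at else c_max
    res$censored <- TRUE
    res$ec50 <- NA_real_
    res$hill <- NA_real_
    res$top <- NA_real_
    res$label <- paste0(">", format(cap, trim = TRUE))
  } else {
    top0 <- min(100, max(agg$mean_sp))
    half <- top0 / 2
    above <- agg$concentration[agg$mean_sp >= half]
    ec0 <- if (length(above) > 0) min(above) else stats::median(agg$concentration)
    fit <- minpack.lm::nlsLM(
      mean_sp ~ top / (1 + (ec50 / concentration)^hill),
      data = agg,
      start = list(top = top0, ec50 = ec0, hill = 1),
      lower = c(top = 0, ec50 = 1e-12, hill = 1e-6),
      upper = c(top = 100, ec50 = Inf, hill = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
    cf <- stats::coef(fit)
    res$censored <- FALSE
    res$ec50 <- unname(cf["ec50"])
    res$hill <- unname(cf["hill"])
    res$top <- unname(cf["top"])
    res$label <- format(res$ec50, digits = 4)
  }
  class(res) <- "dose_response_fit"
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> ", x$compound, ": EC50 ",
      if (x$censored) paste(x$label, "(censored)") else
        paste0(format(x$ec50, digits = 4), " ug/mL (hill ",
               format(x$hill, digits = 3), ", top ",
               format(x$top, digits = 4), "%)"),
      "\n", sep = "")
  invisible(x)
}

#' Mass concentration to molarity
#'
#' microgram mL^-1 divided by g mol^-1 gives mmol L^-1 exactly.
#'
#' @param concentration Mass concentration, microgram mL^-1 (> 0).
#' @param molar_mass Molar mass, g mol^-1 (> 0).
#' @return Molar concentration, mM.
#' @examples
#' mass_to_molar(9.97, 302.24)  # 0.033 mM (quercetin EC50)
#' @export
mass_to_molar <- function(concentration, molar_mass) {
  if (any(concentration <= 0)) stop("concentration must be > 0")
  if (any(molar_mass <= 0)) stop("molar_mass must be > 0")
  concentration / molar_mass
}
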