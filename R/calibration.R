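#' Calibration model mapping a variant-effect predictor to P(neutral)
#'
#' A logistic map from a predictor output to the probability that a single
#' amino-acid substitution is functionally neutral. Two channels exist:
#' `"sift"` maps a SIFT deleteriousness probability through
#' `1 / (1 + exp(-(slope * log(sift_p + pseudocount) + intercept)))`
#' (natural log), and `"foldx"` maps a FoldX stability change (kcal/mol)
#' through `1 / (1 + exp(-(sign * slope * ddg + intercept)))`.
#'
#' The shipped default coefficients are the published calibrations:
#' SIFT slope 0.625, pseudocount 1.527e-4, intercept 1.971; FoldX slope
#' 1.465, intercept 1.201. The FoldX `sign` flag (default `+1`, as
#' published) flips the orientation of the stability axis: with `+1`,
#' destabilizing (positive) ddG values map to *higher* neutrality, which
#' contradicts the biophysical expectation, so `-1` is available without
#' touching the coefficients. No silent choice is made; the flag is part
#' of the model object.
#'
#' @param channel `"sift"` or `"foldx"`.
#' @param slope,intercept Logistic coefficients.
#' @param pseudocount Positive offset added to the SIFT probability before
#'   taking the log (SIFT channel only).
#' @param sign Either `+1` or `-1`; orientation of the FoldX axis
#'   (FoldX channel only).
#' @return An object of class `calibration_model`.
#' @seealso [default_calibrations()], [fit_calibration()]
#' @export
calibration_model <- function(channel = c("sift", "foldx"),
                              slope, intercept,
                              pseudocount = NULL, sign = 1L) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (channel == "sift") {
    if (is.null(pseudocount) || !is.numeric(pseudocount) ||
        length(pseudocount) != 1L || !is.finite(pseudocount) || pseudocount <= 0)
      stop("'pseudocount' must be a single positive number for the sift channel")
    sign <- NULL
  } else {
    if (!sign %in% c(-1L, 1L, -1, 1))
      stop("'sign' must be +1 or -1")
    pseudocount <- NULL
  }
  structure(
    list(channel = channel, slope = slope, intercept = intercept,
         pseudocount = pseudocount, sign = if (!is.null(sign)) as.integer(sign)),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  if (x$channel == "sift") {
    cat(sprintf(
      "P(neutral) calibration [sift]: 1/(1+exp(-(%.4g*ln(p + %.4g) + %.4g)))\n",
      x$slope, x$pseudocount, x$intercept))
  } else {
    cat(sprintf(
      "P(neutral) calibration [foldx]: 1/(1+exp(-(%+d*%.4g*ddG + %.4g)))\n",
      x$sign, x$slope, x$intercept))
  }
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Published default calibrations
#'
#' @param foldx_sign Orientation flag for the FoldX channel, `+1`
#'   (as published) or `-1`.
#' @return A list with components `sift` and `foldx`, each a
#'   [calibration_model()].
#' @export
default_calibrations <- function(foldx_sign = 1L) {
  list(
    sift  = calibration_model("sift",  slope = 0.625, intercept = 1.971,
                              pseudocount = 1.527e-4),
    foldx = calibration_model("foldx", slope = 1.465, intercept = 1.201,
                              sign = foldx_sign)
  )
}

#' P(neutral) from a SIFT probability
#'
#' @param sift_p SIFT deleteriousness probability/ies in \[0, 1\].
#' @param model A `"sift"` [calibration_model()].
#' @return Neutrality probabilities, strictly inside (0, 1), strictly
#'   increasing in `sift_p`.
#' @examples
#' p_neutral_sift(c(0, 0.05, 1))
#' @export
p_neutral_sift <- function(sift_p, model = default_calibrations()$sift) {
  stopifnot(inherits(model, "calibration_model"), model$channel == "sift")
  if (!is.numeric(sift_p) || anyNA(sift_p) ||
      any(sift_p < 0 | sift_p > 1))
    stop("'sift_p' must be numeric in [0, 1]")
  stats::plogis(model$slope * log(sift_p + model$pseudocount) + model$intercept)
}

#' P(neutral) from a FoldX stability change
#'
#' @param ddg FoldX ddG value(s), kcal/mol.
#' @param model A `"foldx"` [calibration_model()].
#' @return Neutrality probabilities, strictly inside (0, 1), monotone in
#'   `ddg` with direction set by the model's `sign` flag.
#' @examples
#' p_neutral_foldx(0)
#' @export
p_neutral_foldx <- function(ddg, model = default_calibrations()$foldx) {
  stopifnot(inherits(model, "calibration_model"), model$channel == "foldx")
  if (!is.numeric(ddg) || anyNA(ddg) || any(!is.finite(ddg)))
    stop("'ddg' must be finite numeric")
  stats::plogis(model$sign * model$slope * ddg + model$intercept)
}

# Constants for the variant-class heuristics: a premature stop in the last
# 16 residues is considered harmless (0.99); earlier stops, start/stop
# losses and gene absences are considered disruptive (0.01).
P_NEUTRAL_LATE_STOP <- 0.99
P_NEUTRAL_DISRUPTED <- 0.01
LATE_STOP_RESIDUES  <- 16L

#' P(neutral) for termination-affecting variant classes
#'
#' Heuristic assignments for variants that do not have a continuous
#' predictor score: a nonsense substitution landing within the last 16
#' residues of the protein gets P(neutral) 0.99 (the truncation is too
#' short to disrupt function); earlier nonsense substitutions and the loss
#' of a start or stop codon get 0.01.
#'
#' @param class Variant class, one of `"nonsense"`, `"start_loss"`,
#'   `"stop_loss"` (vectorized).
#' @param position 1-based residue index of the new stop (nonsense only).
#' @param length Protein length in residues (nonsense only).
#' @return Neutrality probabilities (0.99 or 0.01).
#' @examples
#' p_neutral_termination("nonsense", position = 90, length = 100)  # 0.99
#' p_neutral_termination("nonsense", position = 50, length = 100)  # 0.01
#' @export
p_neutral_termination <- function(class, position = NA_real_, length = NA_real_) {
  n <- base::length(class)
  position <- rep_len(position, n)
  length   <- rep_len(length, n)
  if (any(!class %in% c("nonsense", "start_loss", "stop_loss")))
    stop("termination heuristic applies only to nonsense/start_loss/stop_loss")
  ns <- class == "nonsense"
  if (any(ns & (is.na(position) | is.na(length))))
    stop("nonsense records need 'position' and 'length'")
  if (any(ns & position > length))
    stop("'position' exceeds protein 'length'")
  out <- rep(P_NEUTRAL_DISRUPTED, n)
  out[ns & position > length - LATE_STOP_RESIDUES] <- P_NEUTRAL_LATE_STOP
  out
}

#' P(neutral) for annotated variant records
#'
#' Dispatches each record to the appropriate channel: termination classes
#' go through [p_neutral_termination()]; missense records use the SIFT
#' channel whenever a SIFT probability is present (even if a FoldX value
#' is also available), and fall back to the FoldX channel otherwise.
#'
#' @param variants A data frame with columns `class`, `position`, `length`,
#'   `sift_p`, `foldx_ddg` (NA marks an absent value); see
#'   [read_variants()] for the on-disk layout.
#' @param models A list with `sift` and `foldx` [calibration_model()]s.
#' @return One neutrality probability per row.
#' @export
p_neutral_variant <- function(variants, models = default_calibrations()) {
  stopifnot(is.data.frame(variants),
            all(c("class", "sift_p", "foldx_ddg") %in% names(variants)))
  cls <- as.character(variants$class)
  bad <- !cls %in% c("missense", "nonsense", "start_loss", "stop_loss")
  if (any(bad))
    stop("unknown variant class: ", paste(unique(cls[bad]), collapse = ", "))
  pos <- if ("position" %in% names(variants)) variants$position else NA_real_
  len <- if ("length" %in% names(variants)) variants$length else NA_real_
  pos <- rep_len(pos, nrow(variants)); len <- rep_len(len, nrow(variants))
  out <- numeric(nrow(variants))
  term <- cls != "missense"
  if (any(term))
    out[term] <- p_neutral_termination(cls[term], pos[term], len[term])
  mis <- which(!term)
  if (base::length(mis)) {
    has_sift <- !is.na(variants$sift_p[mis])
    has_fx   <- !is.na(variants$foldx_ddg[mis])
    if (any(!has_sift & !has_fx))
      stop("missense record without sift_p or foldx_ddg")
    si <- mis[has_sift]
    fx <- mis[!has_sift]
    if (base::length(si)) out[si] <- p_neutral_sift(variants$sift_p[si], models$sift)
    if (base::length(fx)) out[fx] <- p_neutral_foldx(variants$foldx_ddg[fx], models$foldx)
  }
  out
}

#' Refit a predictor-to-neutrality calibration from labeled mutations
#'
#' Reproduces the calibration-fit procedure: the predictor axis (negative
#' natural log of the SIFT probability plus a pseudocount equal to the
#' smallest observed nonzero value, or the raw ddG for FoldX) is split
#' into equal-count bins; the proportion of tolerated mutations per bin is
#' computed; and a logistic curve is fitted to the binned proportions by
#' least squares on the logit scale (proportions clipped to
#' \[0.01, 0.99\]).
#'
#' The returned slope/intercept are in the convention of
#' [p_neutral_sift()] / [p_neutral_foldx()]: the logit of P(neutral) is
#' `slope * log(value + pseudocount) + intercept` (SIFT) or
#' `slope * ddg + intercept` (FoldX, sign folded into the slope).
#'
#' @param values Predictor outputs (SIFT probabilities or ddG values).
#' @param labels Logical (or 0/1): `TRUE` when the mutation is tolerated.
#' @param n_bins Number of equal-count bins (default 20).
#' @param channel `"sift"` or `"foldx"`.
#' @return An object of class `calibration_fit` (also a
#'   `calibration_model`) with extra components `bins` (midpoint,
#'   proportion, count per bin) and `residual` (root-mean-square logit
#'   residual of the fit).
#' @export
fit_calibration <- function(values, labels, n_bins = 20L,
                            channel = c("sift", "foldx")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(values), base::length(values) == base::length(labels))
  labels <- as.logical(labels)
  if (anyNA(values) || anyNA(labels)) stop("NA in 'values' or 'labels'")
  if (all(labels) || all(!labels))
    stop("cannot fit a calibration when all labels are one class")
  if (channel == "sift") {
    nz <- values[values > 0]
    if (!base::length(nz)) stop("all SIFT values are zero")
    pseudocount <- min(nz)
    axis <- -log(values + pseudocount)
  } else {
    pseudocount <- NULL
    axis <- values
  }
  # equal-count bins; duplicated quantile edges collapse (empty bins skipped)
  edges <- unique(stats::quantile(axis, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE))
  if (base::length(edges) < 3L) stop("fewer than 2 non-empty bins on the predictor axis")
  bin <- cut(axis, edges, include.lowest = TRUE)
  mid  <- tapply(axis, bin, mean)
  prop <- tapply(labels, bin, mean)
  cnt  <- tapply(labels, bin, base::length)
  keep <- !is.na(mid)
  mid <- mid[keep]; prop <- prop[keep]; cnt <- cnt[keep]
  if (base::length(mid) < 2L) stop("fewer than 2 non-empty bins survive")
  if (all(prop %in% c(0, 1)))
    stop("labels are perfectly separated along the predictor axis; ",
         "logistic fit is divergent")
  propc <- pmin(pmax(prop, 0.01), 0.99)
  y <- stats::qlogis(propc)
  x <- if (channel == "sift") -mid else mid  # back to log(value+pc) / ddg scale
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  model <- calibration_model(channel, slope = unname(cf[2]),
                             intercept = unname(cf[1]),
                             pseudocount = pseudocount, sign = 1L)
  model$bins <- data.frame(midpoint = as.numeric(mid),
                           proportion = as.numeric(prop),
                           count = as.integer(cnt), row.names = NULL)
  model$residual <- sqrt(mean(stats::residuals(fit)^2))
  class(model) <- c("calibration_fit", class(model))
  model
}

#' @export
print.calibration_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("fitted on %d bins, rms logit residual %.3f\n",
              nrow(x$bins), x$residual))
  invisible(x)
}

#' @param object,newdata A `calibration_fit` and new predictor values.
#' @rdname fit_calibration
#' @param ... unused.
#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  if (object$channel == "sift") p_neutral_sift(newdata, object)
  else p_neutral_foldx(newdata, object)
}
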