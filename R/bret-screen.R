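#' BRET ratio of a well
#'
#' BRET is the acceptor-channel emission (600 nm long-pass) divided by
#' the donor-channel emission (450 nm).
#'
#' @param acceptor_em,donor_em Emission counts (vectorized).
#' @return Numeric BRET ratio(s).
#' @export
bret_ratio <- function(acceptor_em, donor_em) {
  if (any(donor_em <= 0)) stop("donor emission must be > 0", call. = FALSE)
  if (any(acceptor_em < 0)) stop("acceptor emission must be >= 0", call. = FALSE)
  acceptor_em / donor_em
}

#' Fold response and positivity call
#'
#' Fold response is BRET from tracer-alone wells divided by BRET from
#' paired tracer-plus-competitor (control) wells; an interaction is
#' called positive at or above the 1.5-fold threshold (inclusive).
#'
#' @param bret_tracer,bret_control BRET ratios (vectorized).
#' @param threshold Positivity threshold (default 1.5).
#' @return Data.frame with `fold_response` and logical `positive`.
#' @export
fold_response <- function(bret_tracer, bret_control, threshold = 1.5) {
  if (any(bret_control <= 0)) stop("control BRET must be > 0", call. = FALSE)
  fold <- bret_tracer / bret_control
  # inclusive >= with a relative epsilon so ratios that are exactly at the
  # boundary in decimal (e.g. 0.15/0.10) are not lost to binary rounding
  data.frame(fold_response = fold,
             positive = fold >= threshold * (1 - 1e-12))
}

#' Signal-to-noise of a tracer measurement
#'
#' Computed as (BRET_tracer - mean(controls)) / SD(controls) with the
#' sample (n-1) standard deviation.
#'
#' @param bret_tracer Single tracer-alone BRET value (or replicate mean).
#' @param control_replicates Numeric vector (>= 2) of control-well BRET
#'   replicates.
#' @return Signal-to-noise ratio; `NA` with a warning if the control
#'   replicates have zero spread.
#' @export
signal_noise <- function(bret_tracer, control_replicates) {
  if (length(control_replicates) < 2) {
    stop("need >= 2 control replicates", call. = FALSE)
  }
  s <- stats::sd(control_replicates)
  if (s == 0) {
    warning("zero spread among control replicates; signal/noise undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (bret_tracer - mean(control_replicates)) / s
}

#' Summarise a competitive NanoBRET screen plate table
#'
#' Replicate wells are averaged per (construct, tracer, concentration,
#' condition) before the fold response is formed.  Signal-to-noise is
#' reported where at least two control replicates are present.
#' Constructs missing either paired condition are skipped with a
#' warning.
#'
#' @param plate Plate table in the schema of [generate_bret_plate()].
#' @param fold_threshold Positivity threshold (default 1.5).
#' @return A `screen_result` data.frame with one row per (construct,
#'   tracer, concentration): `bret_tracer`, `bret_control`,
#'   `fold_response`, `signal_noise`, `positive`.  The attribute
#'   `profile` lists constructs positive at each concentration and those
#'   retained (positive at the lowest tested concentration).
#' @export
screen_summary <- function(plate, fold_threshold = 1.5) {
  require_columns(plate, c("construct", "tracer", "concentration_nM",
                           "condition", "donor_em", "acceptor_em"),
                  "plate table")
  plate$bret <- bret_ratio(plate$acceptor_em, plate$donor_em)
  keyvars <- c("construct", "tracer", "concentration_nM")
  groups <- split(plate, plate[keyvars], drop = TRUE)
  rows <- lapply(groups, function(g) {
    tr <- g$bret[g$condition == "tracer_alone"]
    ct <- g$bret[g$condition == "tracer_plus_competitor"]
    if (length(tr) == 0 || length(ct) == 0) {
      warning(sprintf("construct %s / tracer %s at %g nM lacks a paired condition; skipped",
                      g$construct[1], g$tracer[1], g$concentration_nM[1]),
              call. = FALSE)
      return(NULL)
    }
    fr <- fold_response(mean(tr), mean(ct), fold_threshold)
    s2n <- if (length(ct) >= 2 && stats::sd(ct) > 0) {
      signal_noise(mean(tr), ct)
    } else {
      NA_real_
    }
    data.frame(construct = g$construct[1], tracer = g$tracer[1],
               concentration_nM = g$concentration_nM[1],
               bret_tracer = mean(tr), bret_control = mean(ct),
               fold_response = fr$fold_response,
               signal_noise = s2n, positive = fr$positive,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  concs <- sort(unique(out$concentration_nM))
  profile <- lapply(concs, function(cc) {
    sort(unique(out$construct[out$concentration_nM == cc & out$positive]))
  })
  names(profile) <- as.character(concs)
  attr(out, "profile") <- list(positive_at = profile,
                               retained = profile[[1]],
                               fold_threshold = fold_threshold)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Fit a one-site saturation-binding hyperbola to a dose series
#'
#' BRET at each tracer concentration is background-corrected by
#' subtracting the paired competitor-blocked measurement; the corrected
#' specific signal is fit by least squares to `bmax * c / (ec50 + c)`.
#' Non-convergence yields a result with `converged = FALSE`, never an
#' error.
#'
#' @param series Plate-format table from [generate_saturation_series()]
#'   (both conditions present at each of >= 4 concentrations).
#' @return A `saturation_fit`: `bmax`, `ec50` (nM), `converged`,
#'   `residuals`, and the per-concentration `corrected` data.frame.
#' @export
fit_saturation <- function(series) {
  require_columns(series, c("concentration_nM", "condition", "donor_em",
                            "acceptor_em"), "saturation series")
  series$bret <- bret_ratio(series$acceptor_em, series$donor_em)
  concs <- sort(unique(series$concentration_nM))
  if (length(concs) < 4) {
    config_error("saturation fit needs >= 4 concentrations")
  }
  corrected <- do.call(rbind, lapply(concs, function(cc) {
    g <- series[series$concentration_nM == cc, ]
    tr <- g$bret[g$condition == "tracer_alone"]
    bg <- g$bret[g$condition == "tracer_plus_competitor"]
    if (length(tr) == 0 || length(bg) == 0) {
      schema_error(sprintf("concentration %g nM lacks paired background wells", cc))
    }
    data.frame(concentration_nM = cc, corrected_bret = mean(tr) - mean(bg))
  }))
  y <- corrected$corrected_bret
  conc <- corrected$concentration_nM
  bmax0 <- max(y)
  if (bmax0 <= 0) {
    return(structure(list(bmax = NA_real_, ec50 = NA_real_,
                          converged = FALSE, residuals = NULL,
                          corrected = corrected),
                     class = "saturation_fit"))
  }
  half <- bmax0 / 2
  ec0 <- conc[which.min(abs(y - half))]
  fit <- tryCatch(
    stats::nls(y ~ bmax * conc / (ec50 + conc),
               start = list(bmax = bmax0, ec50 = max(ec0, min(conc))),
               algorithm = "port",
               lower = c(bmax = 1e-12, ec50 = 1e-9),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(bmax = NA_real_, ec50 = NA_real_,
                          converged = FALSE, residuals = NULL,
                          corrected = corrected),
                     class = "saturation_fit"))
  }
  est <- stats::coef(fit)
  structure(list(bmax = unname(est["bmax"]), ec50 = unname(est["ec50"]),
                 converged = TRUE, residuals = stats::resid(fit),
                 corrected = corrected),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<saturation_fit> bmax=%.4g BRET, ec50=%.4g nM (RSS %.3g)\n",
                x$bmax, x$ec50, sum(x$residuals^2)))
  } else {
    cat("<saturation_fit> did not converge\n")
  }
  invisible(x)
}
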