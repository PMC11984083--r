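#' Block-based amplitude response of one block
#'
#' Mean Hilbert envelope over the stimulation-on epoch minus the mean over
#' the preceding off-epoch (`ARC_b = a_on_bar - a_off_bar`).
#'
#' @param ab an [analytic()] result
#' @param off_interval,on_interval numeric length-2 `(start, end)` in
#'   seconds; the off epoch must precede the on epoch
#' @return amplitude change (envelope units)
#' @export
block_arc <- function(ab, off_interval, on_interval) {
  eo <- epoch_values(ab$envelope, ab$fs, off_interval)
  en <- epoch_values(ab$envelope, ab$fs, on_interval)
  mean(en) - mean(eo)
}

#' Block-based phase response of one block
#'
#' Fits an ordinary-least-squares line to the unwrapped phase over the
#' off-epoch, extrapolates it to the end of the on-epoch to obtain the
#' expected no-stimulation phase `psi_hat`, and returns
#' `(psi_hat - psi_actual) / n_pulses`.  Sign convention as printed in the
#' defining formula: positive values mean stimulation *delayed* the phase
#' (actual phase behind the extrapolation); a pulse train that *advances*
#' the phase by `delta` per pulse yields `-delta`.
#'
#' @param ab an [analytic()] result (`phase_unwrapped` is used)
#' @param off_interval,on_interval epoch bounds (s)
#' @param n_pulses number of pulses in the on-epoch, `> 0`
#' @return phase change per pulse (rad)
#' @export
block_prc <- function(ab, off_interval, on_interval, n_pulses) {
  if (n_pulses <= 0) stop("n_pulses must be > 0")
  t <- (seq_along(ab$phase_unwrapped) - 1) / ab$fs
  sel <- t >= off_interval[1] & t <= off_interval[2]
  if (sum(sel) < 2) stop("off-epoch too short")
  fit <- stats::lm.fit(cbind(1, t[sel]), ab$phase_unwrapped[sel])
  t_end <- on_interval[2]
  i_end <- min(length(t), round(t_end * ab$fs) + 1)
  psi_hat <- fit$coefficients[1] + fit$coefficients[2] * t[i_end]
  psi_actual <- ab$phase_unwrapped[i_end]
  unname((psi_hat - psi_actual) / n_pulses)
}

epoch_values <- function(x, fs, interval) {
  t <- (seq_along(x) - 1) / fs
  v <- x[t >= interval[1] & t <= interval[2]]
  if (length(v) == 0) stop("empty epoch")
  v
}

#' Pulse-based amplitude response
#'
#' For each pulse, the mean envelope in the `window_ms` before the pulse
#' (`pre_amp`) and the change to the mean in the `window_ms` after
#' (`delta_amp`).  Consecutive pulses closer than `window_ms` produce
#' overlapping windows; both are kept and flagged.
#'
#' @param ab an [analytic()] result
#' @param pulse_times pulse times (s); defaults to the annotation carried
#'   by `ab`
#' @param window_ms window length (ms), default 10
#' @return data.frame with columns `pulse_time`, `pre_amp`, `delta_amp`,
#'   `overlap`
#' @export
pulse_arc <- function(ab, pulse_times = NULL, window_ms = 10) {
  if (is.null(pulse_times)) pulse_times <- ab$pulse_times
  w <- window_ms / 1000
  t <- (seq_along(ab$envelope) - 1) / ab$fs
  dur <- t[length(t)]
  keep <- pulse_times >= w & pulse_times <= dur - w
  pulse_times <- pulse_times[keep]
  pre <- post <- numeric(length(pulse_times))
  for (k in seq_along(pulse_times)) {
    tp <- pulse_times[k]
    pre[k] <- mean(ab$envelope[t >= tp - w & t < tp])
    post[k] <- mean(ab$envelope[t >= tp & t < tp + w])
  }
  overlap <- c(FALSE, diff(pulse_times) < w)
  data.frame(pulse_time = pulse_times, pre_amp = pre,
             delta_amp = post - pre, overlap = overlap)
}

#' Central-difference derivative of a circular response curve
#'
#' For a curve sampled on an equally spaced circular phase grid,
#' `dPRC/dphi_k = (PRC_{k+1} - PRC_{k-1}) / (2 dphi)` with wraparound at
#' the ends.
#'
#' @param values curve values on the circular grid (length `>= 3`)
#' @param dphi grid spacing (rad); default `2 * pi / length(values)`
#' @return numeric vector, same length
#' @export
prc_derivative <- function(values, dphi = 2 * pi / length(values)) {
  n <- length(values)
  if (n < 3) stop("need at least 3 points")
  (values[c(2:n, 1)] - values[c(n, 1:(n - 1))]) / (2 * dphi)
}

#' Set of response curves over the eight target phases
#'
#' @param phases target phases (rad), equally spaced over 2*pi
#' @param arc,prc per-phase means; `arc_sem`, `prc_sem` standard errors
#' @param blocks per-block table (one row per block)
#' @return object of class `response_curve_set` with the per-phase curves,
#'   the central-difference PRC derivative, and `alignment_offset = 0`
#' @export
response_curve_set <- function(phases, arc, prc, arc_sem = NULL,
                               prc_sem = NULL, blocks = NULL) {
  n <- length(phases)
  dphi <- 2 * pi / n
  gaps <- wrap_phase(diff(c(phases, phases[1] + 2 * pi)))
  if (max(abs(gaps - dphi)) > 1e-6) stop("phases must be equally spaced over 2*pi")
  stopifnot(length(arc) == n, length(prc) == n)
  structure(list(phases = phases, arc = arc, prc = prc,
                 arc_sem = arc_sem, prc_sem = prc_sem,
                 prc_derivative = prc_derivative(prc, dphi),
                 alignment_offset = 0, blocks = blocks),
            class = "response_curve_set")
}

#' @export
print.response_curve_set <- function(x, ...) {
  cat(sprintf(
    "Response curves over %d phases; ARC range [%.3g, %.3g], PRC range [%.3g, %.3g]\n",
    length(x$phases), min(x$arc), max(x$arc), min(x$prc), max(x$prc)))
  if (x$alignment_offset != 0)
    cat(sprintf("  aligned: offset %.3g rad\n", x$alignment_offset))
  invisible(x)
}

#' Align a curve set on its most suppressive phase
#'
#' Circularly rotates the curves so the ARC minimum sits in the first
#' slot; ties go to the smallest phase index.  The applied rotation is
#' recorded in `alignment_offset` (rad).
#'
#' @param curves a [response_curve_set()]
#' @param reference_slot index where the minimum should land, default 1
#' @return rotated `response_curve_set`
#' @export
align_most_suppressive <- function(curves, reference_slot = 1) {
  n <- length(curves$phases)
  imin <- which.min(curves$arc)  # which.min takes the first of ties
  shift <- (imin - reference_slot) %% n
  idx <- ((seq_len(n) - 1 + shift) %% n) + 1
  out <- curves
  out$arc <- curves$arc[idx]
  out$prc <- curves$prc[idx]
  if (!is.null(curves$arc_sem)) out$arc_sem <- curves$arc_sem[idx]
  if (!is.null(curves$prc_sem)) out$prc_sem <- curves$prc_sem[idx]
  out$prc_derivative <- curves$prc_derivative[idx]
  out$alignment_offset <- shift * 2 * pi / n
  out
}

#' One-way ANOVA for phase dependence
#'
#' Standard one-way analysis of variance of per-block responses grouped by
#' target phase; returns the F-test p-value.  Errors when fewer than two
#' groups have two or more blocks, or when the within-group variance is
#' zero (F undefined).
#'
#' @param values per-block response values
#' @param phases grouping factor (target phase per block)
#' @export
phase_dependence_anova <- function(values, phases) {
  g <- factor(phases)
  tab <- table(g)
  if (sum(tab >= 2) < 2) stop("need >= 2 groups with >= 2 blocks")
  fit <- stats::lm(values ~ g)
  an <- suppressWarnings(stats::anova(fit))  # degenerate fits error below
  p <- an[["Pr(>F)"]][1]
  if (!is.finite(p)) stop("F statistic undefined (zero within-group variance)")
  p
}

#' Pearson correlation between ARC and PRC-derivative values
#'
#' @param arc,deriv matched vectors (pooled across phases and subjects),
#'   length `>= 3`
#' @return list with `R` (Pearson estimate) and `p`
#' @export
arc_prc_correlation <- function(arc, deriv) {
  if (length(arc) != length(deriv) || length(arc) < 3)
    stop("need matched vectors of length >= 3")
  if (stats::sd(arc) == 0 || stats::sd(deriv) == 0) stop("zero variance")
  ct <- stats::cor.test(arc, deriv, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlation between per-subject R and ANOVA p-values
#'
#' @param r_values per-subject Pearson correlations
#' @param p_values per-subject ANOVA p-values
#' @return list with `rs` (Spearman estimate) and `p`
#' @export
spearman_link <- function(r_values, p_values) {
  if (length(r_values) != length(p_values) || length(r_values) < 3)
    stop("need matched vectors of length >= 3")
  ct <- suppressWarnings(
    stats::cor.test(r_values, p_values, method = "spearman"))
  list(rs = unname(ct$estimate), p = ct$p.value)
}

#' Amplitude change versus pre-stimulation amplitude, by condition
#'
#' Regresses block amplitude change on the pre-epoch mean envelope
#' separately for each condition (`reference` = no stimulation,
#' `suppressive`, `amplifying`), and reports reference-subtracted slopes:
#' each stimulated block's change minus the reference line's prediction at
#' its pre-amplitude, regressed on pre-amplitude.
#'
#' @param blocks data.frame with columns `pre_amp`, `arc_value`,
#'   `condition`
#' @return list with `fits` (per-condition intercept/slope/p/n) and
#'   `reference_subtracted` (per non-reference condition slope/p)
#' @export
block_amplitude_dependence <- function(blocks) {
  stopifnot(all(c("pre_amp", "arc_value", "condition") %in% names(blocks)))
  conds <- unique(blocks$condition)
  fits <- list()
  for (cn in conds) {
    d <- blocks[blocks$condition == cn, ]
    if (nrow(d) == 0) {
      warning(sprintf("no blocks in condition '%s'", cn))
      next
    }
    if (nrow(d) < 5) warning(sprintf("fewer than 5 blocks in condition '%s'", cn))
    if (nrow(d) < 3 || stats::sd(d$pre_amp) == 0) {
      fits[[cn]] <- list(intercept = NA_real_, slope = NA_real_,
                         p = NA_real_, n = nrow(d))
      next
    }
    fit <- stats::lm(arc_value ~ pre_amp, data = d)
    sm <- summary(fit)$coefficients
    fits[[cn]] <- list(intercept = sm[1, 1], slope = sm[2, 1],
                       p = sm[2, 4], n = nrow(d))
  }
  rs <- list()
  if ("reference" %in% names(fits) && is.finite(fits$reference$slope)) {
    rf <- fits$reference
    for (cn in setdiff(names(fits), "reference")) {
      if (fits[[cn]]$n < 3) next
      d <- blocks[blocks$condition == cn, ]
      resid <- d$arc_value - (rf$intercept + rf$slope * d$pre_amp)
      fit <- stats::lm(resid ~ d$pre_amp)
      sm <- summary(fit)$coefficients
      rs[[cn]] <- list(slope = sm[2, 1], p = sm[2, 4],
                       mean_effect = mean(resid))
    }
  }
  list(fits = fits, reference_subtracted = rs)
}

#' Estimate block-based response curves from a set of trials
#'
#' End-to-end estimator: each trial (one target phase) is band-passed,
#' Hilbert-transformed, and reduced to per-block ARC and PRC values via
#' [block_arc()] and [block_prc()]; per-phase means and SEMs are
#' assembled into a [response_curve_set()].  Blocks whose on-epoch
#' received no pulses contribute to the ARC only.
#'
#' @param trials list of [recording()]s, each with `"on"`/`"off"` epochs
#'   carrying a `target_phase` column and pulse annotations
#' @param band analysis band (Hz), default `c(20, 35)`
#' @param edge_trim seconds excluded at the record edges
#' @return a [response_curve_set()]; the per-block table is in `$blocks`
#' @export
estimate_response_curves <- function(trials, band = c(20, 35),
                                     edge_trim = 0.5) {
  rows <- list()
  for (tr in trials) {
    ab <- analytic(bandpass(tr, band))
    ep <- tr$epochs
    on_rows <- which(ep$label == "on")
    dur <- (length(tr$samples) - 1) / tr$fs
    for (i in on_rows) {
      if (i == 1 || ep$label[i - 1] != "off") next
      off_iv <- c(max(ep$start[i - 1], edge_trim), ep$end[i - 1])
      on_iv <- c(ep$start[i], min(ep$end[i], dur - edge_trim))
      if (diff(off_iv) < 1 || diff(on_iv) < 1) next
      npls <- sum(tr$pulse_times > ep$start[i] & tr$pulse_times <= ep$end[i])
      arc <- block_arc(ab, off_iv, on_iv)
      prc <- if (npls > 0) block_prc(ab, off_iv, on_iv, npls) else NA_real_
      pre <- mean(epoch_values(ab$envelope, ab$fs, off_iv))
      rows[[length(rows) + 1]] <-
        data.frame(target_phase = ep$target_phase[i], arc_value = arc,
                   prc_value = prc, n_pulses = npls, pre_stim_amp = pre)
    }
  }
  blocks <- do.call(rbind, rows)
  phases <- sort(unique(blocks$target_phase))
  agg <- function(v) {
    m <- tapply(v, factor(blocks$target_phase, levels = phases), mean,
                na.rm = TRUE)
    s <- tapply(v, factor(blocks$target_phase, levels = phases),
                function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
    list(mean = as.numeric(m), sem = as.numeric(s))
  }
  a <- agg(blocks$arc_value)
  p <- agg(blocks$prc_value)
  response_curve_set(phases, a$mean, p$mean, a$sem, p$sem, blocks)
}
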