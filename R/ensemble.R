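#' Normalized nanoparticle-count order parameter
#'
#' \eqn{n^*_{NPs}}: per frame, the number of NPs containing at least one
#' RNA chain divided by the number of RNA chains.  Free polycation
#' clusters are excluded, so the order parameter runs from
#' \eqn{1/N_{RNA}} (everything in one aggregate) to 1 (one RNA per NP).
#'
#' @param np_lists list of per-frame NP lists (from
#'   \code{\link{find_nanoparticles}}), or a data.frame from
#'   \code{\link{np_metrics_table}}.
#' @param n_rna_chains number of RNA chains in the system.
#' @param steps optional per-frame step numbers.
#' @param replicate replicate id label.
#' @param alpha_np charge-ratio label carried in the output.
#' @return data.frame with \code{frame}, \code{step}, \code{n_nps_star},
#'   \code{replicate}, \code{alpha_np}.
#' @export
n_nps_star_series <- function(np_lists, n_rna_chains, steps = NULL,
                              replicate = 1L, alpha_np = NA_real_) {
  if (n_rna_chains <= 0)
    stop("n_nps_star_series: need at least one RNA chain")
  if (is.data.frame(np_lists)) {
    tab <- np_lists
    counts <- tapply(tab$n_rna_chains > 0, tab$frame, sum)
    frames <- as.integer(names(counts))
    stp <- tapply(tab$step, tab$frame, function(x) x[1])
    return(data.frame(frame = frames, step = as.integer(stp),
                      n_nps_star = as.numeric(counts) / n_rna_chains,
                      replicate = replicate, alpha_np = alpha_np))
  }
  counts <- vapply(np_lists, function(nps)
    sum(vapply(nps, function(np) np$n_rna_chains > 0, logical(1))),
    numeric(1))
  if (is.null(steps)) steps <- seq_along(np_lists)
  data.frame(frame = seq_along(np_lists), step = as.integer(steps),
             n_nps_star = counts / n_rna_chains,
             replicate = replicate, alpha_np = alpha_np)
}

#' Free-energy profile over the cluster-count order parameter
#'
#' Histograms the \eqn{n^*_{NPs}} series in bins of width
#' \eqn{1/N_{RNA}}, converts occupancies to a free energy
#' \eqn{F(n) = -k_BT \ln \hat P(n)} (shifted so the minimum is 0; empty
#' bins carry no value), and fits a quadratic over the bins within
#' \code{fit_window} \eqn{k_BT} of the minimum.  The parabola's vertex is
#' the reported minimum location; with a single occupied bin the fit is
#' unavailable and the minimum is that bin.
#'
#' @param series data.frame from \code{\link{n_nps_star_series}} (or a
#'   numeric vector of \eqn{n^*_{NPs}} values).
#' @param n_rna_chains number of RNA chains (bin width \eqn{1/N_{RNA}}).
#' @param temperature \eqn{k_BT} in \eqn{\epsilon}.
#' @param fit_window include bins with \eqn{F \le F_{min} +} this many
#'   \eqn{k_BT} in the fit.
#' @return object of class \code{free_energy_profile}: \code{bin_centers},
#'   \code{F}, \code{counts}, \code{fit} (quadratic coefficients or NULL),
#'   \code{minimum} (vertex location), \code{curvature}.
#' @export
free_energy_profile <- function(series, n_rna_chains, temperature = 1,
                                fit_window = 2) {
  x <- if (is.data.frame(series)) series$n_nps_star else as.numeric(series)
  if (length(x) == 0) stop("free_energy_profile: empty series")
  w <- 1 / n_rna_chains
  bin <- round(x / w)
  tab <- table(bin)
  centers <- as.numeric(names(tab)) * w
  p <- as.numeric(tab) / sum(tab)
  FF <- -temperature * log(p)
  FF <- FF - min(FF)
  fit <- NULL; minimum <- centers[which.min(FF)]; curvature <- NA_real_
  sel <- FF <= min(FF) + fit_window * temperature
  if (sum(sel) >= 3) {
    co <- stats::coef(stats::lm(FF[sel] ~ poly(centers[sel], 2, raw = TRUE)))
    a <- co[[3]]; b <- co[[2]]
    if (is.finite(a) && a > 0) {
      minimum <- -b / (2 * a)
      curvature <- 2 * a
      fit <- c(intercept = co[[1]], linear = b, quadratic = a)
    }
  }
  out <- list(bin_centers = centers, F = FF, counts = as.numeric(tab),
              fit = fit, minimum = minimum, curvature = curvature,
              temperature = temperature)
  class(out) <- "free_energy_profile"
  out
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("free_energy_profile:", length(x$bin_centers),
      "occupied bins; minimum at n* =", format(x$minimum, digits = 4), "\n")
  invisible(x)
}

#' Excess charge-ratio scaling transform
#'
#' Rescales charge ratios measured at different RNA concentrations onto a
#' common excess-polycation axis:
#' \deqn{\alpha N/P^* = (\alpha N/P - 1)\,c_{RNA}/c_{ref,RNA} + 1}
#' \deqn{N/P^* = (N/P - N/P_{iso})\,c_{RNA}/c_{ref,RNA} + N/P_{iso}}
#' Above the isoelectric point the system is governed by the excess
#' polycation concentration \eqn{c^*_{PEI}}, so data taken at different
#' \eqn{c_{RNA}} collapse when plotted against these starred ratios.  In
#' the simulations \eqn{N/P_{iso} = 1/\alpha}; experimentally it is the
#' N/P where the zeta-potential changes sign.
#'
#' @param alpha_np charge ratio(s) \eqn{\alpha N/P}.
#' @param c_rna RNA monomer concentration (any unit shared with
#'   \code{c_ref_rna}).
#' @param c_ref_rna reference RNA concentration.
#' @param np_ratio optional chemists' N/P ratio(s) for the N/P* transform.
#' @param np_iso isoelectric N/P ratio (\eqn{1/\alpha}; 2 at 50\%
#'   protonation, 1.7 experimentally).
#' @return data.frame with \code{alpha_np_star} and (if \code{np_ratio}
#'   given) \code{np_star}.
#' @export
np_star_transform <- function(alpha_np, c_rna, c_ref_rna,
                              np_ratio = NULL, np_iso = 2) {
  if (any(c_ref_rna <= 0)) stop("np_star_transform: c_ref_rna must be > 0")
  out <- data.frame(alpha_np_star = (alpha_np - 1) * c_rna / c_ref_rna + 1)
  if (!is.null(np_ratio))
    out$np_star <- (np_ratio - np_iso) * c_rna / c_ref_rna + np_iso
  out
}

#' Condition-level summary across replicates
#'
#' For each condition (e.g. an \eqn{\alpha N/P} value) and replicate, the
#' per-NP metrics are averaged over the equilibrated window (by default
#' the second half of the frames, unweighted across NPs), then mean and
#' standard deviation are taken across replicates.  A single replicate
#' reports sd = 0 with \code{single_replicate = TRUE}.
#'
#' @param metrics data.frame: per-NP rows with at least
#'   \code{condition}, \code{replicate}, \code{frame} and the metric
#'   columns.
#' @param metric_cols columns to summarize.
#' @param equilibrated_fraction final fraction of frames used.
#' @param weight \code{"none"} (every NP equal) or \code{"rna"} (weight by
#'   RNA chains per NP); recorded in the output.
#' @return data.frame, one row per condition x metric, with \code{mean},
#'   \code{sd}, \code{n_replicates}, \code{single_replicate},
#'   \code{weight}.
#' @export
sweep_summary <- function(metrics,
                          metric_cols = c("r_h", "kappa2", "charge",
                                          "n_nps_star"),
                          equilibrated_fraction = 0.5,
                          weight = c("none", "rna")) {
  weight <- match.arg(weight)
  metric_cols <- intersect(metric_cols, names(metrics))
  split_cond <- split(metrics, metrics$condition)
  rows <- lapply(names(split_cond), function(cond) {
    mc <- split_cond[[cond]]
    reps <- split(mc, mc$replicate)
    per_rep <- lapply(reps, function(rp) {
      fmax <- max(rp$frame); fmin <- min(rp$frame)
      lo <- fmin + (1 - equilibrated_fraction) * (fmax - fmin)
      rp <- rp[rp$frame >= lo, , drop = FALSE]
      vapply(metric_cols, function(cl) {
        v <- rp[[cl]]
        w <- if (weight == "rna" && "n_rna_chains" %in% names(rp))
          rp$n_rna_chains else rep(1, length(v))
        ok <- is.finite(v)
        if (!any(ok)) return(NA_real_)
        sum(v[ok] * w[ok]) / sum(w[ok])
      }, numeric(1))
    })
    pr <- do.call(rbind, per_rep)
    nrep <- nrow(pr)
    do.call(rbind, lapply(metric_cols, function(cl) {
      data.frame(condition = cond, metric = cl,
                 mean = mean(pr[, cl], na.rm = TRUE),
                 sd = if (nrep > 1) stats::sd(pr[, cl], na.rm = TRUE) else 0,
                 n_replicates = nrep,
                 single_replicate = nrep == 1,
                 weight = weight)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
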