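#' Read per-cell flow events from CSV
#'
#' Columns `event_id`, `dna`, `fsc_a`, `ch_total`, `ch_phospho` (extra
#' columns are kept).
#'
#' @param path CSV path.
#' @return A `flow_events` data frame.
#' @export
read_flow_csv <- function(path) {
  if (!file.exists(path)) stop("flow CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "dna", "fsc_a", "ch_total", "ch_phospho")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0)
    stop("flow CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$dna)) || any(df$dna <= 0))
    stop("dna signal must be finite and positive")
  class(df) <- c("flow_events", "data.frame")
  df
}

#' Unit-median normalization of the antibody channels
#'
#' Divides each channel by its median over the (gated) population, a robust
#' scaling that makes the downstream per-cell subtraction invariant to
#' channel gains. The constants used are attached as an attribute.
#'
#' @param events a `flow_events` data frame.
#' @return Events with `ch_total_norm` and `ch_phospho_norm` columns.
#' @export
normalize_channels <- function(events) {
  if (nrow(events) < 100)
    warning("fewer than 100 events; normalization medians are unstable")
  med_t <- stats::median(events$ch_total)
  med_p <- stats::median(events$ch_phospho)
  if (!is.finite(med_t) || med_t <= 0 || !is.finite(med_p) || med_p <= 0)
    stop("channel median must be positive for unit-median scaling")
  events$ch_total_norm <- events$ch_total / med_t
  events$ch_phospho_norm <- events$ch_phospho / med_p
  attr(events, "normalization") <- c(ch_total = med_t, ch_phospho = med_p)
  events
}

#' Gate G2 cells on DNA content
#'
#' Locates the G1 peak mode of the DNA distribution by kernel density,
#' verifies a second (G2) peak near twice that mode, and gates cells with
#' DNA in `[lower, upper] * mode` (default 1.8-2.2x). Explicit bounds
#' override peak detection.
#'
#' @param events a `flow_events` data frame.
#' @param lower,upper gate bounds as multiples of the G1 mode.
#' @param manual_gate optional numeric `c(lo, hi)` absolute DNA bounds,
#'   bypassing peak detection.
#' @return The G2 subset, with the gate recorded in attribute `g2_gate`.
#' @export
gate_g2 <- function(events, lower = 1.8, upper = 2.2, manual_gate = NULL) {
  if (!is.null(manual_gate)) {
    stopifnot(length(manual_gate) == 2, manual_gate[1] < manual_gate[2])
    gate <- manual_gate
  } else {
    den <- stats::density(events$dna, n = 1024)
    peaks <- which(diff(sign(diff(den$y))) == -2) + 1L
    if (length(peaks) < 1) stop("no peak detectable in the DNA distribution")
    # G1 = strongest peak; prominence threshold filters density ripples
    main <- peaks[which.max(den$y[peaks])]
    m <- den$x[main]
    g2_region <- den$x[peaks] > 1.7 * m & den$x[peaks] < 2.3 * m &
      den$y[peaks] > 0.05 * den$y[main]
    if (!any(g2_region))
      stop("no G2 peak near twice the G1 mode; supply manual_gate bounds")
    gate <- c(lower * m, upper * m)
  }
  out <- events[events$dna >= gate[1] & events$dna <= gate[2], , drop = FALSE]
  attr(out, "g2_gate") <- gate
  attr(out, "normalization") <- attr(events, "normalization")
  out
}

#' Per-cell unphosphorylated signal
#'
#' `u = ch_total_norm - ch_phospho_norm`, computed for each cell
#' separately. Negative values are retained (truncation would bias
#' small-cell bins toward zero).
#'
#' @param events events with normalized channels
#'   (see [normalize_channels()]).
#' @return Events with an `unphospho` column.
#' @export
unphospho_per_cell <- function(events) {
  if (is.null(events$ch_total_norm) || is.null(events$ch_phospho_norm))
    stop("run normalize_channels() first")
  events$unphospho <- events$ch_total_norm - events$ch_phospho_norm
  events
}

#' Assign cells to size bins
#'
#' Quantile bins (default) hold near-equal cell counts; equal-width bins
#' split the FSC-A range between the 1st and 99th percentiles evenly.
#' Boundaries are half-open with the rightmost bin closed.
#'
#' @param events a `flow_events` data frame (typically the G2 gate).
#' @param n_bins number of bins (>= 3).
#' @param scheme `"quantile"` or `"equal_width"`.
#' @return Integer bin index per cell (1 = smallest), with the break
#'   vector as attribute `breaks`.
#' @export
bin_by_size <- function(events, n_bins = 12L,
                        scheme = c("quantile", "equal_width")) {
  scheme <- match.arg(scheme)
  if (n_bins < 3) stop("n_bins must be >= 3")
  x <- events$fsc_a
  if (length(x) < n_bins) stop("fewer cells than bins")
  breaks <- if (scheme == "quantile") {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           names = FALSE))
  } else {
    lim <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    seq(lim[1], lim[2], length.out = n_bins + 1)
  }
  if (length(breaks) < n_bins + 1)
    stop("too many tied FSC-A values for ", n_bins, " quantile bins")
  breaks[1] <- min(breaks[1], min(x))
  breaks[length(breaks)] <- max(breaks[length(breaks)], max(x))
  bins <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  attr(bins, "breaks") <- breaks
  bins
}

#' Bin summaries and Kolmogorov-Smirnov tests against a center bin
#'
#' For each size bin: cell count, mean and standard error of the per-cell
#' unphosphorylated signal, and the two-sample KS p value of the bin's
#' values against the center bin's (the center bin itself gets p = 1).
#' The exact small-sample KS distribution is used whenever the product of
#' the two bin sizes is below 10000 (the standard rule; the asymptotic
#' approximation is markedly conservative for bins of less than about 100
#' cells). Bins under `min_cells` are flagged unstable.
#'
#' @param events G2-gated events with an `unphospho` column.
#' @param bins bin assignment from [bin_by_size()].
#' @param center_bin 1-based index of the reference bin.
#' @param ks_alpha significance level for the per-bin flag (strict).
#' @param min_cells minimum cells per bin before the unstable flag.
#' @return A `g2_bin_profile` data frame: `bin`, `fsc_lo`, `fsc_hi`, `n`,
#'   `mean_u`, `se`, `ks_p`, `significant`, `unstable`.
#' @export
bin_summary_and_ks <- function(events, bins, center_bin = 7L,
                               ks_alpha = 0.01, min_cells = 20L) {
  n_bins <- max(bins)
  if (center_bin < 1 || center_bin > n_bins)
    stop("center_bin out of range")
  u <- events$unphospho
  if (is.null(u)) stop("run unphospho_per_cell() first")
  center <- u[bins == center_bin]
  if (length(center) == 0) stop("center bin is empty")
  breaks <- attr(bins, "breaks")
  rows <- lapply(seq_len(n_bins), function(b) {
    ub <- u[bins == b]
    lo <- if (!is.null(breaks)) breaks[b] else NA_real_
    hi <- if (!is.null(breaks)) breaks[b + 1] else NA_real_
    if (length(ub) == 0) {
      warning("bin ", b, " is empty")
      return(data.frame(bin = b, fsc_lo = lo, fsc_hi = hi, n = 0L,
                        mean_u = NA_real_, se = NA_real_, ks_p = NA_real_,
                        significant = NA, unstable = TRUE))
    }
    if (b == center_bin) {
      p <- 1
    } else {
      p <- suppressWarnings(
        stats::ks.test(ub, center, exact = NULL)$p.value)
    }
    data.frame(bin = b, fsc_lo = lo, fsc_hi = hi, n = length(ub),
               mean_u = mean(ub),
               se = stats::sd(ub) / sqrt(length(ub)),
               ks_p = p, significant = p < ks_alpha,
               unstable = length(ub) < min_cells)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("g2_bin_profile", "data.frame")
  out
}

#' Size-binned unphosphorylated-Cdk1 profile of G2 cells
#'
#' Full chain: G2 gating on DNA content, unit-median channel normalization
#' over the gated population, per-cell subtraction, size binning and
#' per-bin KS tests against the center bin. The chain is invariant to
#' positive rescaling of any raw channel.
#'
#' @param events a `flow_events` data frame.
#' @param config an [analysis_config()] (`n_size_bins`, `center_bin`,
#'   `ks_alpha`).
#' @param scheme binning scheme, see [bin_by_size()].
#' @param manual_gate optional absolute DNA gate bounds.
#' @return A `g2_bin_profile` data frame (see [bin_summary_and_ks()]).
#' @export
flow_size_profile <- function(events, config = analysis_config(),
                              scheme = "quantile", manual_gate = NULL) {
  g2 <- gate_g2(events, manual_gate = manual_gate)
  g2 <- normalize_channels(g2)
  g2 <- unphospho_per_cell(g2)
  bins <- bin_by_size(g2, n_bins = config$n_size_bins, scheme = scheme)
  bin_summary_and_ks(g2, bins, center_bin = config$center_bin,
                     ks_alpha = config$ks_alpha)
}
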