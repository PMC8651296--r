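#' Selection criteria for smFRET traces
#'
#' The five acceptance criteria applied to every molecule, in order:
#' (1) signal-to-noise ratio of the detection-balanced total intensity at
#' least `snr_min`; (2) a single-step acceptor bleach occurring before the
#' donor bleach; (3) the per-molecule gamma factor within `gamma_range`;
#' (4) spontaneous donor and acceptor fluctuations negatively correlated
#' (Pearson correlation below `correlation_max`); (5) if a donor bleach is
#' recorded, it occurs in a single step. A rejected molecule carries the
#' code of the first criterion it failed.
#'
#' @param snr_min Minimum signal-to-noise ratio (default 5).
#' @param gamma_range Acceptable gamma interval (default `c(0.5, 2.5)`).
#' @param correlation_max Donor/acceptor correlation must be below this
#'   (default -0.1; slightly below zero to guard against sign noise on
#'   short traces).
#' @param gamma_window Frames averaged on each side of the acceptor bleach
#'   when estimating gamma (default 10).
#' @param min_frames Minimum pre-bleach frames for a classifiable trace.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(snr_min = 5, gamma_range = c(0.5, 2.5),
                               correlation_max = -0.1, gamma_window = 10,
                               min_frames = 10) {
  stopifnot(snr_min > 0, length(gamma_range) == 2,
            gamma_range[1] < gamma_range[2], correlation_max < 0)
  structure(list(snr_min = snr_min, gamma_range = gamma_range,
                 correlation_max = correlation_max,
                 gamma_window = gamma_window, min_frames = min_frames),
            class = "selection_criteria")
}

#' Subtract donor-to-acceptor spectral leakage
#'
#' Removes the fixed fraction of the measured donor signal that bleeds into
#' the acceptor channel: `I_A <- I_A - leakage * I_D` per frame. Applied to
#' background-corrected traces before bleach detection and gamma
#' estimation.
#'
#' @param trace A list with numeric `donor` and `acceptor` series.
#' @param leakage Leakage fraction, in [0, 0.5] (default 0.07).
#' @return The trace with corrected `acceptor`.
#' @export
subtract_leakage <- function(trace, leakage = 0.07) {
  if (!is.numeric(leakage) || leakage < 0 || leakage > 0.5) {
    stop("leakage must be in [0, 0.5]")
  }
  trace$acceptor <- trace$acceptor - leakage * trace$donor
  trace
}

# Plateau fits with 0, 1 or 2 changepoints, compared by BIC.
# cp is the first index of the new plateau. Returns RSS-based BICs and the
# best single changepoint.
changepoint_scan <- function(y) {
  n <- length(y)
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  seg_rss <- function(i, j) { # vectorized over i or j
    len <- j - i + 1
    s <- s1[j] - ifelse(i > 1, s1[i - 1], 0)
    q <- s2[j] - ifelse(i > 1, s2[i - 1], 0)
    pmax(q - s^2 / len, 0)
  }
  rss0 <- seg_rss(1, n)
  cps <- 2:n
  rss1 <- seg_rss(1, cps - 1) + seg_rss(cps, n)
  best1 <- which.min(rss1)
  cp1 <- cps[best1]
  rss1_min <- rss1[best1]
  rss2_min <- Inf
  cp2 <- c(NA_integer_, NA_integer_)
  if (n >= 4) {
    for (c1 in 2:(n - 1)) {
      c2s <- (c1 + 1):n
      tot <- seg_rss(1, c1 - 1) + seg_rss(c1, c2s - 1) + seg_rss(c2s, n)
      b <- which.min(tot)
      if (tot[b] < rss2_min) {
        rss2_min <- tot[b]
        cp2 <- c(c1, c2s[b])
      }
    }
  }
  bic <- function(rss, k) n * log(pmax(rss, 1e-12) / n) + k * log(n)
  seg2 <- if (!is.na(cp2[1])) {
    c(first = mean(y[1:(cp2[1] - 1)]),
      mid = mean(y[cp2[1]:(cp2[2] - 1)]),
      post = mean(y[cp2[2]:n]), len_mid = cp2[2] - cp2[1])
  } else c(first = NA, mid = NA, post = NA, len_mid = NA)
  list(cp = cp1, cp2 = cp2, seg2 = seg2,
       bic0 = bic(rss0, 2), bic1 = bic(rss1_min, 4), bic2 = bic(rss2_min, 6),
       pre_mean = mean(y[1:(cp1 - 1)]), post_mean = mean(y[cp1:n]))
}

# Classify a series as having 0, 1 or 2 plateau changes. A two-change
# model is accepted as a genuine multi-step bleach only when its middle
# plateau is sustained (`min_plateau` samples) and sits at a distinctly
# reduced level -- the signature of losing one of several fluorophores --
# otherwise the extra changepoint is treated as a state excursion and the
# series is classified single-step.
step_class <- function(scan, min_plateau = 0, level_gate = 1) {
  if (scan$bic1 < scan$bic0 && scan$bic1 <= scan$bic2) return("single")
  if (scan$bic2 < scan$bic0) {
    s <- scan$seg2
    genuine <- !is.na(s["len_mid"]) &&
      s["len_mid"] >= min_plateau &&
      s["mid"] < level_gate * s["first"] &&
      s["mid"] > s["first"] * 0.15 &&
      s["mid"] > s["post"] + 0.05 * abs(s["first"] - s["post"])
    if (genuine || min_plateau == 0) "multi" else "single"
  } else "none"
}

# Running upper quantile; windows clipped at the edges.
running_quantile <- function(y, window = 15, q = 0.9) {
  n <- length(y)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    quantile(y[max(1, i - half):min(n, i + half)], q, names = FALSE)
  }, 1)
}

#' Detect photobleaching steps in a two-channel trace
#'
#' Acceptor bleach steps are classified on the running upper envelope
#' (90th percentile over a 25-frame window) of the acceptor signal:
#' genuine FRET state excursions are brief dips that leave the envelope
#' flat, while the loss of one of several acceptors scales the whole
#' envelope down for a sustained period, so plateau models with zero, one
#' and two changepoints (least squares over all changepoint positions,
#' compared by BIC, with the multi-step call additionally requiring a
#' sustained intermediate plateau at a reduced level) separate
#' single-step from multi-step bleaching. The bleach
#' frame is then refined by a local two-plateau fit on the raw series.
#' If a single acceptor step is found, the donor series after the
#' acceptor bleach (where FRET no longer modulates it) is scanned with
#' the same plateau models for the donor bleach; a donor bleach is
#' recorded only when the donor drops to near zero.
#'
#' @param trace A leakage-corrected trace (`donor`, `acceptor`).
#' @param min_frames Traces shorter than this are unclassifiable.
#' @return List with `acceptor_class` ("single", "multi", "none" or
#'   "too_short"), `acceptor_bleach_frame` (first dark frame),
#'   `donor_class`, `donor_bleach_frame` (or `NA`), `donor_delta` (donor
#'   level change across the acceptor bleach; positive for a proper
#'   acceptor-first bleach) and `acceptor_delta`.
#' @export
detect_bleach_steps <- function(trace, min_frames = 10) {
  n <- length(trace$acceptor)
  if (n < min_frames) {
    return(list(acceptor_class = "too_short", acceptor_bleach_frame = NA,
                donor_class = "too_short", donor_bleach_frame = NA,
                donor_delta = NA, acceptor_delta = NA))
  }
  w_env <- max(3, min(25, 2 * (n %/% 6) + 1))
  env <- running_quantile(trace$acceptor, w_env)
  sa <- changepoint_scan(env)
  acl <- step_class(sa, min_plateau = 25, level_gate = 0.8)
  ab <- if (acl %in% c("single", "multi")) {
    cp_env <- if (acl == "multi") sa$cp2[2] else sa$cp
    # refine: first frame near the envelope changepoint after which the
    # raw acceptor stays at background (a state excursion recovers, a
    # bleach does not)
    cand <- max(2, cp_env - w_env - 5):min(n, cp_env + w_env + 5)
    thr <- 0.3 * sa$pre_mean
    sust <- vapply(cand, function(f) {
      trace$acceptor[f] < thr &&
        quantile(trace$acceptor[f:min(n, f + 15)], 0.9, names = FALSE) < thr
    }, TRUE)
    if (any(sust)) {
      cand[which(sust)[1]]
    } else { # fall back to a local two-plateau fit on the raw series
      lo <- max(1, cp_env - w_env - 6)
      ref <- changepoint_scan(trace$acceptor[lo:min(n, cp_env + w_env + 5)])
      lo + ref$cp - 1L
    }
  } else NA_integer_
  dcl <- "none"; db <- NA_integer_; ddelta <- NA_real_
  if (!is.na(ab)) {
    pre_d <- mean(trace$donor[max(1, ab - 10):(ab - 1)])
    post_end <- min(n, ab + 10)
    post_d <- if (ab < n) mean(trace$donor[min(ab + 1, n):post_end]) else NA
    ddelta <- post_d - pre_d
    if (ab + 7 <= n) { # scan donor after the acceptor bleach
      start <- ab + 2L # skip the transition neighborhood
      seg <- trace$donor[start:n]
      if (length(seg) >= min_frames) {
        sd_ <- changepoint_scan(seg)
        dcl <- step_class(sd_, min_plateau = 25, level_gate = 0.8)
        if (dcl %in% c("single", "multi")) {
          db <- start + (if (dcl == "multi") sd_$cp2[2] else sd_$cp) - 1L
          # only a drop to ~zero counts as a bleach
          lvl <- mean(seg[(if (dcl == "multi") sd_$cp2[2] else sd_$cp):length(seg)])
          if (lvl > 0.25 * max(abs(sd_$pre_mean), 1)) {
            dcl <- "none"; db <- NA_integer_
          }
        }
      }
    }
  }
  list(acceptor_class = acl, acceptor_bleach_frame = ab,
       donor_class = dcl, donor_bleach_frame = db,
       donor_delta = ddelta,
       acceptor_delta = sa$pre_mean - sa$post_mean)
}

#' Estimate the per-molecule gamma factor at the acceptor bleach
#'
#' gamma is the ratio of the acceptor intensity drop to the donor intensity
#' rise across the acceptor photobleach, averaged over `window` frames on
#' each side (the changepoint frame itself is excluded):
#' `gamma = (mean I_A(pre) - mean I_A(post)) / (mean I_D(post) - mean I_D(pre))`.
#' Because both the drop and the rise scale with the average pre-bleach
#' FRET, the estimate is insensitive to state dynamics inside the windows.
#'
#' @param trace Leakage-corrected trace.
#' @param bleach Result of [detect_bleach_steps()] (or a list with
#'   `acceptor_bleach_frame` and optionally `donor_bleach_frame`).
#' @param window Frames per side (default 10).
#' @return List with `gamma` (or `NA`) and `reason` (`NA` on success,
#'   otherwise "no_bleach", "short_window" or "nonpositive_donor_rise").
#' @export
estimate_gamma <- function(trace, bleach, window = 10) {
  ab <- bleach$acceptor_bleach_frame
  n <- length(trace$donor)
  if (is.na(ab)) return(list(gamma = NA_real_, reason = "no_bleach"))
  db <- bleach$donor_bleach_frame
  post_last <- min(n, ab + window, if (!is.na(db)) db - 1L else n)
  pre <- seq(max(1, ab - window), ab - 1)
  post <- if (ab + 1 <= post_last) seq(ab + 1, post_last) else integer(0)
  if (length(pre) < 5 || length(post) < 5) {
    return(list(gamma = NA_real_, reason = "short_window"))
  }
  d_a <- mean(trace$acceptor[pre]) - mean(trace$acceptor[post])
  d_d <- mean(trace$donor[post]) - mean(trace$donor[pre])
  if (!is.finite(d_d) || d_d <= 0) {
    return(list(gamma = NA_real_, reason = "nonpositive_donor_rise"))
  }
  list(gamma = d_a / d_d, reason = NA_character_)
}

#' Compute the FRET efficiency series of a corrected trace
#'
#' `E = I_A / (I_A + gamma * I_D)` per frame, restricted to pre-acceptor-
#' bleach frames. Values outside the histogram range [-0.25, 1.25] are
#' retained; frames where the denominator is not positive are masked `NA`.
#'
#' @param trace Leakage-corrected trace.
#' @param gamma Per-molecule gamma (> 0).
#' @param acceptor_bleach_frame First dark acceptor frame; `Inf` or `NA`
#'   uses the full trace.
#' @return Numeric E series over frames `1:(acceptor_bleach_frame - 1)`.
#' @export
compute_fret <- function(trace, gamma, acceptor_bleach_frame = NA) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  ab <- acceptor_bleach_frame
  last <- if (is.na(ab) || !is.finite(ab)) length(trace$donor) else ab - 1
  idx <- seq_len(max(last, 0))
  denom <- trace$acceptor[idx] + gamma * trace$donor[idx]
  E <- trace$acceptor[idx] / denom
  E[denom <= 0] <- NA_real_
  E
}

# Robust noise SD from first differences.
diff_noise_sd <- function(x) mad(diff(x)) / sqrt(2)

#' Apply the five-point selection filter to a trace set
#'
#' Runs the full per-molecule correction chain (leakage subtraction, bleach
#' detection, gamma estimation, FRET computation) and the selection
#' criteria in the order stated in [selection_criteria()]. The
#' signal-to-noise ratio is the mean detection-balanced total intensity
#' `I_A + gamma * I_D` over pre-bleach frames divided by a robust noise SD
#' estimated from its first differences (insensitive to genuine state
#' transitions); the anticorrelation test uses the Pearson correlation of
#' the mean-subtracted pre-bleach donor and acceptor series.
#'
#' @param traces List of traces (`id`, `donor`, `acceptor`), e.g. from
#'   [read_traces()], or a `sim_traces` object.
#' @param criteria A [selection_criteria()].
#' @param leakage Leakage fraction subtracted before analysis.
#' @return An object of class `trace_selection`: list with `molecules`
#'   (each annotated with `gamma`, `E`, `bleach`, `snr`, `correlation`,
#'   `accepted`, `reason`) and `summary` (data.frame of per-molecule
#'   outcomes). Reason codes: "too_short", "snr", "no_acceptor_bleach",
#'   "acceptor_multistep", "bleach_order", "gamma_range", "correlation",
#'   "donor_multistep".
#' @export
apply_selection <- function(traces, criteria = selection_criteria(),
                            leakage = 0.07) {
  if (inherits(traces, "sim_traces")) traces <- traces$molecules
  mols <- lapply(traces, function(tr) {
    tr <- subtract_leakage(tr, leakage)
    bl <- detect_bleach_steps(tr, criteria$min_frames)
    gm <- estimate_gamma(tr, bl, criteria$gamma_window)
    ab <- bl$acceptor_bleach_frame
    pre <- if (!is.na(ab)) seq_len(max(ab - 2, 0)) else seq_along(tr$donor)
    g_snr <- if (is.finite(gm$gamma) && gm$gamma > 0) gm$gamma else 1
    total <- tr$acceptor[pre] + g_snr * tr$donor[pre]
    snr <- if (length(pre) >= criteria$min_frames) {
      ns <- diff_noise_sd(total)
      if (ns > 0) mean(total) / ns else Inf
    } else NA_real_
    corr <- if (length(pre) >= criteria$min_frames) {
      suppressWarnings(cor(tr$donor[pre] - mean(tr$donor[pre]),
                           tr$acceptor[pre] - mean(tr$acceptor[pre])))
    } else NA_real_
    reason <- NA_character_
    if (bl$acceptor_class == "too_short" || length(pre) < criteria$min_frames) {
      reason <- "too_short"
    } else if (!is.na(snr) && snr < criteria$snr_min) {
      reason <- "snr"
    } else if (bl$acceptor_class == "none") {
      reason <- "no_acceptor_bleach"
    } else if (bl$acceptor_class == "multi") {
      reason <- "acceptor_multistep"
    } else if (!is.finite(bl$donor_delta) || bl$donor_delta <= 0) {
      reason <- "bleach_order"
    } else if (!is.finite(gm$gamma) ||
               gm$gamma < criteria$gamma_range[1] ||
               gm$gamma > criteria$gamma_range[2]) {
      reason <- "gamma_range"
    } else if (is.na(corr) || corr >= criteria$correlation_max) {
      reason <- "correlation"
    } else if (bl$donor_class == "multi") {
      reason <- "donor_multistep"
    }
    accepted <- is.na(reason)
    tr$bleach <- bl
    tr$gamma <- gm$gamma
    tr$snr <- snr
    tr$correlation <- corr
    tr$accepted <- accepted
    tr$reason <- reason
    if (accepted) tr$E <- compute_fret(tr, gm$gamma, ab)
    tr
  })
  summary <- data.frame(
    molecule_id = vapply(mols, function(m) as.integer(m$id %||% NA), 1L),
    accepted = vapply(mols, function(m) m$accepted, TRUE),
    reason = vapply(mols, function(m) m$reason %||% NA_character_, ""),
    gamma = vapply(mols, function(m) m$gamma %||% NA_real_, 1),
    snr = vapply(mols, function(m) m$snr %||% NA_real_, 1),
    defect = vapply(mols, function(m) m$defect %||% NA_character_, ""),
    stringsAsFactors = FALSE
  )
  structure(list(molecules = mols, summary = summary),
            class = "trace_selection")
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' FRET histograms for accepted traces
#'
#' Bins each trace's FRET series into 30 bins over [-0.25, 1.25] (width
#' 0.05) and normalizes by the trace's number of FRET points, so every
#' per-trace histogram sums to one. The ensemble histogram is the sum of
#' the normalized per-trace histograms divided by the number of molecules,
#' so it also sums to one. E values beyond the range are clipped into the
#' end bins.
#'
#' @param selection A `trace_selection` (accepted molecules are used), or a
#'   list of numeric E series.
#' @return List with `breaks` (length 31), `mids`, `per_trace` (matrix,
#'   one row per molecule), `ensemble` (length-30 vector), `n_molecules`
#'   and `n_clipped`.
#' @export
build_histograms <- function(selection) {
  series <- if (inherits(selection, "trace_selection")) {
    lapply(Filter(function(m) isTRUE(m$accepted), selection$molecules),
           function(m) m$E)
  } else selection
  breaks <- seq(-0.25, 1.25, by = 0.05)
  series <- Filter(function(e) sum(is.finite(e)) > 0, series)
  if (length(series) == 0) {
    return(list(breaks = breaks, mids = breaks[-31] + 0.025,
                per_trace = matrix(0, 0, 30), ensemble = rep(0, 30),
                n_molecules = 0L, n_clipped = 0L))
  }
  clipped <- 0L
  per <- t(vapply(series, function(e) {
    e <- e[is.finite(e)]
    clipped <<- clipped + sum(e < -0.25 | e > 1.25)
    e <- pmin(pmax(e, -0.25), 1.25 - 1e-9)
    h <- tabulate(floor((e + 0.25) / 0.05 + 1e-9) + 1, nbins = 30)
    h / sum(h)
  }, numeric(30)))
  list(breaks = breaks, mids = breaks[-31] + 0.025, per_trace = per,
       ensemble = colSums(per) / nrow(per), n_molecules = nrow(per),
       n_clipped = clipped)
}
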