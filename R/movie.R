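# Side-by-side two-channel movie rendering and processing. A movie is a
# list(frames = array[h, 2w, T], h, w) where columns 1..w are the donor
# half and w+1..2w the acceptor half; spot coordinates are local to a
# half, x = column, y = row.

#' Affine channel-registration map
#'
#' Maps donor-half coordinates (x, y) to acceptor-half coordinates via
#' `c(x', y') = A %*% c(x, y) + t`.
#'
#' @param A 2 x 2 matrix.
#' @param t Length-2 translation (pixels).
#' @param rms Residual root-mean-square of the fit (pixels).
#' @return Object of class `registration_map`.
#' @export
registration_map <- function(A = diag(2), t = c(0, 0), rms = 0) {
  stopifnot(all(dim(A) == c(2, 2)), length(t) == 2)
  if (abs(det(A)) < 1e-8) stop("registration transform is not invertible")
  structure(list(A = A, t = t, rms = rms, warn = rms > 1),
            class = "registration_map")
}

apply_registration <- function(reg, xy) {
  xy <- matrix(xy, ncol = 2)
  sweep(xy %*% t(reg$A), 2, reg$t, "+")
}

gauss_psf_stamp <- function(h, w, x, y, sigma, radius = NULL) {
  if (is.null(radius)) radius <- ceiling(4 * sigma)
  cx <- round(x); cy <- round(y)
  xs <- max(1, cx - radius):min(w, cx + radius)
  ys <- max(1, cy - radius):min(h, cy + radius)
  if (!length(xs) || !length(ys)) return(NULL)
  gx <- exp(-(xs - x)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y)^2 / (2 * sigma^2))
  list(rows = ys, cols = xs, k = outer(gy, gx) / (2 * pi * sigma^2))
}

#' Render a synthetic two-channel TIRF movie
#'
#' Paints each molecule as a 2D Gaussian point-spread function at its
#' donor position in the left half and at its registered position in the
#' right half (offset by the configured affine misalignment), scaled so
#' the painted intensity integrates to the ideal trace value of that
#' frame. A constant background plus a linear gradient along x is added,
#' then per-pixel Poisson shot noise and Gaussian read noise.
#'
#' @param truth A `sim_truth` or `sim_traces` from the generator.
#' @param misalignment A [registration_map()] giving the planted
#'   donor-to-acceptor transform (default identity).
#' @param noise Apply pixel noise (default `TRUE`).
#' @return Object of class `fret_movie` with `frames` (h x 2w x T array),
#'   `h`, `w`, and the truth attached as attribute `truth`.
#' @export
render_movie <- function(truth, misalignment = registration_map(),
                         noise = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  h <- config$frame_size[1]; w <- config$frame_size[2]
  T_ <- config$n_frames
  set.seed(config$seed + 3L)
  base <- matrix(config$background_level, h, w) +
    matrix(rep((seq_len(w) - 1) * config$background_gradient, each = h), h, w)
  frames <- array(0, dim = c(h, 2 * w, T_))
  stamps <- lapply(truth$molecules, function(mol) {
    axy <- apply_registration(misalignment, mol$pos)
    list(d = gauss_psf_stamp(h, w, mol$pos["x"], mol$pos["y"], config$psf_sigma),
         a = gauss_psf_stamp(h, w, axy[1], axy[2], config$psf_sigma),
         ch = ideal_channels(mol, config))
  })
  for (t in seq_len(T_)) {
    fd <- base
    fa <- base
    for (s in stamps) {
      don <- s$ch$donor[t]
      acc <- s$ch$acceptor[t] + config$leakage * don
      if (!is.null(s$d) && don > 0) {
        fd[s$d$rows, s$d$cols] <- fd[s$d$rows, s$d$cols] + don * s$d$k
      }
      if (!is.null(s$a) && acc > 0) {
        fa[s$a$rows, s$a$cols] <- fa[s$a$rows, s$a$cols] + acc * s$a$k
      }
    }
    f <- cbind(fd, fa)
    if (noise) {
      f <- matrix(rpois(length(f), f), h, 2 * w) +
        matrix(rnorm(length(f), 0, config$read_noise_sd), h, 2 * w)
    }
    frames[, , t] <- f
  }
  structure(list(frames = frames, h = h, w = w), class = "fret_movie",
            truth = truth, misalignment = misalignment)
}

#' Render a registration bead image pair
#'
#' Beads are bright spots visible in both channels; the acceptor-half
#' image is the donor-half image displaced by the planted misalignment.
#'
#' @param n_beads Number of beads.
#' @param misalignment Planted [registration_map()].
#' @param frame_size `c(h, w)` of one half.
#' @param intensity Bead intensity (counts).
#' @param psf_sigma PSF width (pixels).
#' @param noise_sd Gaussian noise SD.
#' @param seed Integer seed.
#' @return List with matrices `donor`, `acceptor` and the bead positions.
#' @export
render_bead_pair <- function(n_beads = 12, misalignment = registration_map(),
                             frame_size = c(64, 64), intensity = 2000,
                             psf_sigma = 1.2, noise_sd = 2, seed = 1L) {
  set.seed(seed)
  h <- frame_size[1]; w <- frame_size[2]
  m <- ceiling(4 * psf_sigma) + 3
  pos <- cbind(x = runif(n_beads, m, w - m), y = runif(n_beads, m, h - m))
  donor <- matrix(0, h, w); acceptor <- matrix(0, h, w)
  for (i in seq_len(n_beads)) {
    sd_ <- gauss_psf_stamp(h, w, pos[i, 1], pos[i, 2], psf_sigma)
    axy <- apply_registration(misalignment, pos[i, ])
    sa <- gauss_psf_stamp(h, w, axy[1], axy[2], psf_sigma)
    if (!is.null(sd_)) donor[sd_$rows, sd_$cols] <-
        donor[sd_$rows, sd_$cols] + intensity * sd_$k
    if (!is.null(sa)) acceptor[sa$rows, sa$cols] <-
        acceptor[sa$rows, sa$cols] + intensity * sa$k
  }
  donor <- donor + matrix(rnorm(h * w, 0, noise_sd), h, w)
  acceptor <- acceptor + matrix(rnorm(h * w, 0, noise_sd), h, w)
  list(donor = donor, acceptor = acceptor, positions = pos)
}

#' Write / read a movie as multi-page 16-bit TIFF
#'
#' Counts are stored as 16-bit values (clipped to [0, 65535]).
#'
#' @param movie A `fret_movie` (or list of matrices for a bead pair).
#' @param path Output path.
#' @export
write_movie <- function(movie, path) {
  pages <- if (inherits(movie, "fret_movie")) {
    lapply(seq_len(dim(movie$frames)[3]), function(t) movie$frames[, , t])
  } else movie
  pages <- lapply(pages, function(m) round(pmin(pmax(m, 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie
#' @return `read_movie()` returns a `fret_movie` (counts restored).
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(m) m * 65535)
  h <- nrow(pages[[1]]); w2 <- ncol(pages[[1]])
  frames <- array(unlist(pages), dim = c(h, w2, length(pages)))
  structure(list(frames = frames, h = h, w = w2 %/% 2),
            class = "fret_movie")
}

#' Detect spots as strict local maxima in a five-pixel-diameter disk
#'
#' A pixel is a spot iff it exceeds `min_intensity` and is the strict
#' maximum within the disk of five-pixel diameter centered on it; exact
#' ties are broken in favor of the lexicographically lowest (row, col)
#' position. Adding a constant to the image and to `min_intensity` leaves
#' the result unchanged.
#'
#' @param image Numeric matrix.
#' @param min_intensity Detection threshold.
#' @return data.frame with `x` (col), `y` (row), `intensity`.
#' @export
detect_spots <- function(image, min_intensity) {
  h <- nrow(image); w <- ncol(image)
  offs <- expand.grid(dy = -2:2, dx = -2:2)
  offs <- offs[offs$dx^2 + offs$dy^2 <= 2.5^2 &
                 !(offs$dx == 0 & offs$dy == 0), ]
  is_max <- image > min_intensity
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    shifted <- matrix(-Inf, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    shifted[ys - dy, xs - dx] <- image[ys, xs]
    # neighbor is lexicographically later than the pixel iff dy > 0 or
    # (dy == 0 and dx > 0): the pixel keeps an exact tie with it
    cmp <- if (dy > 0 || (dy == 0 && dx > 0)) image >= shifted
           else image > shifted
    is_max <- is_max & cmp
  }
  idx <- which(is_max, arr.ind = TRUE)
  data.frame(x = idx[, 2], y = idx[, 1],
             intensity = image[idx])[order(idx[, 1], idx[, 2]), ]
}

# Mutual nearest-neighbor matching between two point sets (rows = points).
mutual_nn <- function(P, Q, max_dist) {
  if (nrow(P) == 0 || nrow(Q) == 0) return(cbind(i = integer(), j = integer()))
  D <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  D <- sqrt(pmax(D, 0))
  nnP <- apply(D, 1, which.min)
  nnQ <- apply(D, 2, which.min)
  i <- which(nnQ[nnP] == seq_len(nrow(P)))
  keep <- D[cbind(i, nnP[i])] <= max_dist
  cbind(i = i[keep], j = nnP[i][keep])
}

#' Estimate the channel registration from a bead image pair
#'
#' Detects bead maxima in both halves, matches them by mutual nearest
#' neighbor, and fits the affine donor-to-acceptor transform by least
#' squares, iterating the match once with the fitted transform. At least
#' three matched beads are required; a residual RMS above one pixel sets
#' the `warn` flag.
#'
#' @param bead_donor,bead_acceptor Matrices (one channel half each).
#' @param min_intensity Spot threshold (default: 10 robust SDs above the
#'   median).
#' @param max_dist Matching gate in pixels for the initial match.
#' @return A [registration_map()].
#' @export
estimate_registration <- function(bead_donor, bead_acceptor,
                                  min_intensity = NULL, max_dist = 8) {
  thr <- function(img) median(img) + 10 * mad(img)
  if (is.null(min_intensity)) min_intensity <- min(thr(bead_donor),
                                                   thr(bead_acceptor))
  sd_ <- detect_spots(bead_donor, min_intensity)
  sa <- detect_spots(bead_acceptor, min_intensity)
  sd_xy <- refine_centroids(bead_donor, sd_)
  sa_xy <- refine_centroids(bead_acceptor, sa)
  fit_once <- function(reg, gate) {
    mapped <- apply_registration(reg, sd_xy)
    mm <- mutual_nn(mapped, sa_xy, gate)
    if (nrow(mm) < 3) stop("fewer than 3 matched beads; cannot register")
    X <- cbind(sd_xy[mm[, 1], , drop = FALSE])
    Y <- sa_xy[mm[, 2], , drop = FALSE]
    fit <- lsfit(X, Y)
    A <- unname(t(fit$coefficients[-1, , drop = FALSE]))
    t_ <- unname(fit$coefficients[1, ])
    res <- Y - (X %*% t(A) + matrix(t_, nrow(X), 2, byrow = TRUE))
    registration_map(A, t_, sqrt(mean(res^2)))
  }
  reg <- fit_once(registration_map(), max_dist)
  fit_once(reg, 3)
}

# Sub-pixel spot centers by least-squares 2D Gaussian fit (center,
# amplitude, width, flat background) in a 9x9 window, initialized from
# the background-subtracted centroid.
refine_centroids <- function(image, spots, half = 4) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(NA_real_, nrow(spots), 2)
  for (i in seq_len(nrow(spots))) {
    xs <- max(1, spots$x[i] - half):min(w, spots$x[i] + half)
    ys <- max(1, spots$y[i] - half):min(h, spots$y[i] + half)
    win <- image[ys, xs, drop = FALSE]
    b0 <- quantile(win, 0.25, names = FALSE)
    sub <- pmax(win - b0, 0)
    s <- sum(sub)
    cx <- if (s > 0) sum(colSums(sub) * xs) / s else spots$x[i]
    cy <- if (s > 0) sum(rowSums(sub) * ys) / s else spots$y[i]
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
    z <- as.numeric(win)
    amp0 <- max(win) - b0
    fit <- optim(c(cx, cy, log(max(amp0, 1e-6)), log(1.2), b0),
                 function(p) {
                   mu <- exp(p[3]) * exp(-((gx - p[1])^2 + (gy - p[2])^2) /
                                           (2 * exp(p[4])^2)) + p[5]
                   sum((z - mu)^2)
                 }, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
    out[i, ] <- fit$par[1:2]
  }
  out
}

#' Match donor and acceptor spots across channels
#'
#' Maps donor-half spot coordinates into the acceptor half through the
#' registration, then keeps mutual nearest-neighbor pairs closer than
#' `max_dist`. Donor spots without an acceptor counterpart are discarded.
#'
#' @param donor_spots,acceptor_spots data.frames from [detect_spots()].
#' @param registration A [registration_map()].
#' @param max_dist Gate in pixels (default 2).
#' @return data.frame with donor coordinates (`xd`, `yd`) and matched
#'   acceptor coordinates (`xa`, `ya`).
#' @export
match_spots <- function(donor_spots, acceptor_spots, registration,
                        max_dist = 2) {
  P <- apply_registration(registration, cbind(donor_spots$x, donor_spots$y))
  Q <- cbind(acceptor_spots$x, acceptor_spots$y)
  mm <- mutual_nn(P, Q, max_dist)
  data.frame(xd = donor_spots$x[mm[, 1]], yd = donor_spots$y[mm[, 1]],
             xa = acceptor_spots$x[mm[, 2]], ya = acceptor_spots$y[mm[, 2]])
}

#' Average detection image of the first frames of a movie half
#'
#' @param movie A `fret_movie`.
#' @param channel "donor" or "acceptor".
#' @param n_frames Frames averaged (default 10).
#' @return Matrix of one channel half.
#' @export
detection_image <- function(movie, channel = c("donor", "acceptor"),
                            n_frames = 10) {
  channel <- match.arg(channel)
  cols <- if (channel == "donor") seq_len(movie$w)
          else movie$w + seq_len(movie$w)
  n <- min(n_frames, dim(movie$frames)[3])
  apply(movie$frames[, cols, seq_len(n), drop = FALSE], c(1, 2), mean)
}

#' Remove a smooth background plane from an image
#'
#' Fits a least-squares plane (constant plus linear terms in x and y) to
#' the image -- robust to sparse bright spots after one reweighting pass
#' that drops pixels far above the fit -- and subtracts it. Used before
#' spot detection so a constant offset or linear illumination gradient
#' does not distort a global threshold.
#'
#' @param image Numeric matrix.
#' @return The flattened image (same dimensions).
#' @export
flatten_background <- function(image) {
  h <- nrow(image); w <- ncol(image)
  X <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), w))
  y <- as.numeric(image)
  fit <- lsfit(X, y)
  r <- fit$residuals
  keep <- r < 3 * mad(r)
  fit <- lsfit(X[keep, , drop = FALSE], y[keep])
  pred <- cbind(1, X) %*% fit$coefficients
  matrix(y - pred, h, w)
}

aperture_cols <- function(center, half, limit) {
  lo <- round(center) - half; hi <- round(center) + half
  if (lo < 1 || hi > limit) NULL else lo:hi
}

#' Extract per-molecule intensity traces from a movie
#'
#' Sums pixel values within a fixed square aperture around each matched
#' spot in each channel, frame by frame. Molecules whose aperture falls
#' off the image are dropped (recorded in attribute `dropped`).
#'
#' @param movie A `fret_movie`.
#' @param pairs data.frame from [match_spots()].
#' @param aperture Aperture side in pixels (odd; default 5).
#' @return List of traces (`id`, `donor`, `acceptor`, `xd`, `yd`, `xa`,
#'   `ya`).
#' @export
extract_traces <- function(movie, pairs, aperture = 5) {
  half <- (aperture - 1) / 2
  T_ <- dim(movie$frames)[3]
  out <- list()
  dropped <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    cd <- aperture_cols(pairs$xd[i], half, movie$w)
    rd <- aperture_cols(pairs$yd[i], half, movie$h)
    ca <- aperture_cols(pairs$xa[i], half, movie$w)
    ra <- aperture_cols(pairs$ya[i], half, movie$h)
    if (is.null(cd) || is.null(rd) || is.null(ca) || is.null(ra)) {
      dropped <- c(dropped, i)
      next
    }
    donor <- apply(movie$frames[rd, cd, , drop = FALSE], 3, sum)
    acceptor <- apply(movie$frames[ra, movie$w + ca, , drop = FALSE], 3, sum)
    out[[length(out) + 1]] <- list(id = i, donor = donor, acceptor = acceptor,
                                   xd = pairs$xd[i], yd = pairs$yd[i],
                                   xa = pairs$xa[i], ya = pairs$ya[i])
  }
  attr(out, "dropped") <- dropped
  out
}

#' Background-correct extracted traces
#'
#' For each molecule, frame and channel, subtracts the median pixel value
#' within a circular 35-pixel-diameter region around the spot -- excluding
#' the summation aperture itself -- multiplied by the number of summed
#' aperture pixels. Regions extending beyond the image are clipped.
#'
#' @param traces Output of [extract_traces()].
#' @param movie The same `fret_movie`.
#' @param aperture Aperture side used during extraction.
#' @param diameter Background region diameter in pixels (default 35).
#' @return The traces with background-subtracted `donor` and `acceptor`.
#' @export
correct_background <- function(traces, movie, aperture = 5, diameter = 35) {
  half <- (aperture - 1) / 2
  rad <- diameter / 2
  T_ <- dim(movie$frames)[3]
  npix <- aperture^2
  annulus_median <- function(x0, y0, col_off) {
    xs <- max(1, round(x0) - ceiling(rad)):min(movie$w, round(x0) + ceiling(rad))
    ys <- max(1, round(y0) - ceiling(rad)):min(movie$h, round(y0) + ceiling(rad))
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, length(xs))
    in_disk <- (gx - x0)^2 + (gy - y0)^2 <= rad^2
    in_ap <- abs(gx - round(x0)) <= half & abs(gy - round(y0)) <= half
    sel <- in_disk & !in_ap
    px <- movie$frames[cbind(rep(gy[sel], T_), rep(gx[sel] + col_off, T_),
                             rep(seq_len(T_), each = sum(sel)))]
    px <- matrix(px, ncol = T_)
    apply(px, 2, median)
  }
  lapply(traces, function(tr) {
    tr$donor <- tr$donor - npix * annulus_median(tr$xd, tr$yd, 0)
    tr$acceptor <- tr$acceptor - npix * annulus_median(tr$xa, tr$ya, movie$w)
    tr
  })
}
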