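# Gaussian-emission hidden Markov modeling of FRET efficiency series.
# EM (Baum-Welch) with scaled forward-backward in compiled code; model
# order selected by BIC.

gauss_dens <- function(x, means, sds) {
  B <- vapply(seq_along(means), function(k) {
    stats::dnorm(x, means[k], sds[k])
  }, numeric(length(x)))
  matrix(pmax(B, 1e-300), nrow = length(x))
}

fit_hmm_k <- function(x, K, max_iter = 200, tol = 1e-6, init_jitter = 0) {
  T_ <- length(x)
  qs <- (seq_len(K) - 0.5) / K
  means <- as.numeric(quantile(x, qs, names = FALSE))
  if (init_jitter > 0) means <- means + rnorm(K, 0, init_jitter)
  means <- sort(means)
  sds <- rep(max(sd(x) / sqrt(K), 1e-3), K)
  A <- matrix(0.05 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  pi0 <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    B <- gauss_dens(x, means, sds)
    es <- hmm_estep(B, A, pi0)
    g <- es$gamma
    nk <- colSums(g)
    means <- colSums(g * x) / nk
    sds <- sqrt(colSums(g * (outer(x, means, "-"))^2) / nk)
    sds <- pmax(sds, 1e-6)
    if (K > 1) {
      A <- es$xi / pmax(rowSums(es$xi), 1e-300)
      A <- A / rowSums(A)
    }
    pi0 <- pmax(g[1, ], 1e-12)
    pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_old) && abs(es$loglik - ll_old) < tol) {
      converged <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  # order states by mean
  o <- order(means)
  means <- means[o]; sds <- sds[o]
  A <- A[o, o, drop = FALSE]; pi0 <- pi0[o]
  B <- gauss_dens(x, means, sds)
  ll <- hmm_estep(B, A, pi0)$loglik
  path <- hmm_viterbi(log(B), log(pmax(A, 1e-300)), log(pi0))
  list(n_states = K, means = means, sds = sds, transition = A, pi0 = pi0,
       loglik = ll, path = path, converged = converged)
}

#' Fit a Gaussian-emission HMM to a FRET series with BIC model selection
#'
#' For each candidate number of states `n = 1..max_states`, runs EM
#' (Baum-Welch) with quantile-based mean initialization and `n_restarts`
#' seeded jittered restarts, keeping the restart with the highest
#' likelihood. Model order is selected by the Bayesian information
#' criterion `BIC = -2 logL + p log T` with `p = n^2 + 2n - 1` free
#' parameters (transitions, initial distribution, means, SDs); ties go to
#' the smaller model. The most likely state path is obtained by global
#' (Viterbi) decoding.
#'
#' @param E Numeric FRET series (finite values are used; length >= 10).
#' @param max_states Largest model order tried (default 5).
#' @param n_restarts EM restarts per model order (default 5).
#' @param seed Integer seed for the restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An object of class `hmm_fit`: `n_states`, `means`, `sds`,
#'   `transition`, `path`, `loglik`, `bic`, `all_bic`, `converged`, `E`.
#' @export
fit_hmm_bic <- function(E, max_states = 5, n_restarts = 5, seed = 1L,
                        max_iter = 200, tol = 1e-6) {
  x <- E[is.finite(E)]
  if (length(x) < 10) stop("E series must have at least 10 finite values")
  set.seed(seed)
  fits <- vector("list", max_states)
  for (K in seq_len(max_states)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      jit <- if (r == 1) 0 else 0.25 * sd(x) / sqrt(K)
      f <- tryCatch(fit_hmm_k(x, K, max_iter, tol, init_jitter = jit),
                    error = function(e) NULL)
      if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) best <- f
    }
    fits[K] <- list(best)
  }
  T_ <- length(x)
  bics <- vapply(seq_len(max_states), function(K) {
    f <- fits[[K]]
    if (is.null(f)) return(Inf)
    p <- K^2 + 2 * K - 1
    -2 * f$loglik + p * log(T_)
  }, 1)
  sel <- which.min(bics) # which.min takes the first (smallest K) on ties
  fit <- fits[[sel]]
  fit$bic <- bics[sel]
  fit$all_bic <- bics
  fit$all_loglik <- vapply(fits, function(f) {
    if (is.null(f)) NA_real_ else f$loglik
  }, 1)
  fit$E <- x
  if (!fit$converged) warning("EM did not fully converge for the selected model")
  class(fit) <- "hmm_fit"
  fit
}

#' Cluster HMM states across an ensemble of molecules
#'
#' Pools the fitted state means of all molecules and clusters them in one
#' dimension with k-means (`n_init` seeded restarts, best inertia kept).
#' Clusters are relabeled in order of increasing center. Each cluster's
#' representative FRET level is the center of the modal 0.05-wide
#' histogram bin of all decoded E points assigned to its states; the
#' predominant cluster is the one holding the most E points.
#'
#' @param fits List of `hmm_fit` objects.
#' @param k Number of target clusters (chosen per dataset from the shape
#'   of the ensemble FRET histogram).
#' @param seed Integer seed for k-means restarts.
#' @param n_init k-means restarts.
#' @return An object of class `cluster_model`: `centers`, `assignments`
#'   (list; per molecule an integer vector mapping HMM state -> cluster),
#'   `representative` (per-cluster level), `point_counts`, `predominant`.
#' @export
cluster_states <- function(fits, k, seed = 1L, n_init = 10) {
  means <- unlist(lapply(fits, function(f) f$means))
  if (length(unique(means)) < k) {
    stop("only ", length(unique(means)), " distinct state means in the ",
         "ensemble; choose k <= that")
  }
  set.seed(seed)
  km <- kmeans(matrix(means, ncol = 1), centers = k, nstart = n_init)
  o <- order(km$centers)
  relabel <- match(seq_len(k), o)
  cl <- relabel[km$cluster]
  centers <- sort(as.numeric(km$centers))
  idx <- 0L
  assignments <- lapply(fits, function(f) {
    a <- cl[idx + seq_along(f$means)]
    idx <<- idx + length(f$means)
    a
  })
  breaks <- seq(-0.25, 1.25, by = 0.05)
  pts <- vector("list", k)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    clust_path <- assignments[[i]][f$path]
    for (c_ in seq_len(k)) pts[[c_]] <- c(pts[[c_]], f$E[clust_path == c_])
  }
  representative <- vapply(seq_len(k), function(c_) {
    e <- pts[[c_]]
    if (length(e) == 0) return(NA_real_)
    e <- pmin(pmax(e, -0.25), 1.25 - 1e-9)
    h <- tabulate(floor((e + 0.25) / 0.05 + 1e-9) + 1, nbins = 30)
    breaks[which.max(h)] + 0.025
  }, 1)
  counts <- vapply(pts, length, 1L)
  structure(list(k = k, centers = centers, assignments = assignments,
                 representative = representative, point_counts = counts,
                 predominant = which.max(counts)),
            class = "cluster_model")
}

#' Dwell-time analysis of clustered state paths
#'
#' Maps each molecule's decoded state path to clusters, measures the
#' durations of consecutive same-cluster runs, discards the first and last
#' period of every trace (their start or end was not observed), and
#' excludes traces with fewer than two transitions. Rates are exponential
#' maximum-likelihood estimates `1 / mean(dwell)` per ordered
#' (from, to) cluster pair, with chi-square confidence intervals.
#'
#' @param fits List of `hmm_fit` objects.
#' @param clusters A [cluster_states()] model for the same fits.
#' @param frame_interval Seconds per frame.
#' @param conf Confidence level for the rate CIs.
#' @return An object of class `dwell_set`: `dwells` (data.frame with
#'   `molecule`, `from`, `to`, `duration`), `rates` (data.frame with
#'   `from`, `to`, `n`, `mean_dwell`, `rate`, `rate_lo`, `rate_hi`).
#' @export
dwell_analysis <- function(fits, clusters, frame_interval = 0.1,
                           conf = 0.95) {
  rows <- list()
  for (i in seq_along(fits)) {
    cp <- clusters$assignments[[i]][fits[[i]]$path]
    r <- rle(cp)
    n_trans <- length(r$lengths) - 1
    if (n_trans < 2) next
    interior <- seq(2, length(r$lengths) - 1)
    rows[[length(rows) + 1]] <- data.frame(
      molecule = i,
      from = r$values[interior],
      to = r$values[interior + 1],
      duration = r$lengths[interior] * frame_interval
    )
  }
  dwells <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule = integer(), from = integer(), to = integer(),
               duration = numeric())
  rates <- NULL
  if (nrow(dwells)) {
    sp <- split(dwells, list(dwells$from, dwells$to), drop = TRUE)
    rates <- do.call(rbind, lapply(sp, function(d) {
      n <- nrow(d)
      m <- mean(d$duration)
      a <- (1 - conf) / 2
      data.frame(from = d$from[1], to = d$to[1], n = n, mean_dwell = m,
                 rate = 1 / m,
                 rate_lo = stats::qchisq(a, 2 * n) / (2 * n * m),
                 rate_hi = stats::qchisq(1 - a, 2 * n) / (2 * n * m))
    }))
    rownames(rates) <- NULL
  }
  structure(list(dwells = dwells, rates = rates), class = "dwell_set")
}

#' Transition density plot of an ensemble
#'
#' Each cluster-level transition contributes a point at (FRET before,
#' FRET after), taken by default from the fitted HMM state means flanking
#' the transition (set `coordinates = "cluster"` to use cluster
#' representative levels instead). To keep molecules with many transitions
#' from dominating, points are deduplicated to one per molecule per
#' ordered cluster pair (`dedup = "first"` keeps the first occurrence;
#' `"mean"` averages the occurrences). Points are binned on a 50 x 50 grid
#' over [-0.25, 1.25] squared and convolved with a normalized Gaussian
#' kernel of two grid cells SD, truncated at four SDs; each point
#' contributes unit mass, so the density integrates to the deduplicated
#' point count.
#'
#' @param fits List of `hmm_fit` objects.
#' @param clusters A [cluster_states()] model for the same fits.
#' @param coordinates "state_means" (default) or "cluster".
#' @param dedup "first" (default) or "mean".
#' @return An object of class `transition_density`: `grid` (50 x 50),
#'   `points` (data.frame `molecule`, `from`, `to`, `pre`, `post`),
#'   `axis` (bin centers).
#' @export
transition_density <- function(fits, clusters,
                               coordinates = c("state_means", "cluster"),
                               dedup = c("first", "mean")) {
  coordinates <- match.arg(coordinates)
  dedup <- match.arg(dedup)
  pts <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    asg <- clusters$assignments[[i]]
    cp <- asg[f$path]
    tr <- which(diff(cp) != 0)
    if (length(tr) == 0) next
    pre_state <- f$path[tr]
    post_state <- f$path[tr + 1]
    d <- data.frame(
      molecule = i, from = cp[tr], to = cp[tr + 1],
      pre = if (coordinates == "state_means") f$means[pre_state]
            else clusters$representative[cp[tr]],
      post = if (coordinates == "state_means") f$means[post_state]
             else clusters$representative[cp[tr + 1]]
    )
    sp <- split(d, paste(d$from, d$to))
    d <- do.call(rbind, lapply(sp, function(g) {
      if (dedup == "first") g[1, ]
      else data.frame(molecule = g$molecule[1], from = g$from[1],
                      to = g$to[1], pre = mean(g$pre), post = mean(g$post))
    }))
    pts[[length(pts) + 1]] <- d
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(molecule = integer(), from = integer(), to = integer(),
               pre = numeric(), post = numeric())
  rownames(points) <- NULL
  ngrid <- 50
  lo <- -0.25; hi <- 1.25
  width <- (hi - lo) / ngrid
  grid <- matrix(0, ngrid, ngrid)
  if (nrow(points)) {
    ksd <- 2; half <- 4 * ksd
    off <- -half:half
    kern <- outer(stats::dnorm(off, 0, ksd), stats::dnorm(off, 0, ksd))
    for (p in seq_len(nrow(points))) {
      ix <- min(max(floor((points$pre[p] - lo) / width + 1e-9) + 1, 1), ngrid)
      iy <- min(max(floor((points$post[p] - lo) / width + 1e-9) + 1, 1), ngrid)
      xs <- ix + off; ys <- iy + off
      okx <- xs >= 1 & xs <= ngrid; oky <- ys >= 1 & ys <= ngrid
      # renormalize the clipped stamp so each point contributes mass 1
      sub <- kern[okx, oky, drop = FALSE] / sum(kern[okx, oky])
      grid[xs[okx], ys[oky]] <- grid[xs[okx], ys[oky]] + sub
    }
  }
  structure(list(grid = grid, points = points,
                 axis = lo + (seq_len(ngrid) - 0.5) * width),
            class = "transition_density")
}
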