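# Exhaustive feasibility oracle for small lattice-restricted chain-growth
# instances. Independent of the builder: plain depth-first enumeration
# over the 26 lattice directions, applying the same contracts (bend angle,
# steric exclusion incl. the mirrored partner chain, distance constraints
# once both sites are placed).

enumerate_feasible <- function(anchor, n_nodes, constraints,
                               excl = 0.25, spacing = 0.38,
                               transform = list(R = diag(c(-1, -1, 1)),
                                                t = c(0, 0, 0))) {
  dirs <- lattice_dirs()
  mirror <- function(p) as.numeric(transform$R %*% p) + transform$t
  cons <- split(seq_len(nrow(constraints)),
                pmin(constraints$site_a_res, constraints$site_b_res))
  ok_node <- function(p, placed, prev_res) {
    pb <- mirror(p)
    if (sum((p - pb)^2) < excl^2) return(FALSE)
    for (r in names(placed)) {
      q <- placed[[r]]
      if (as.integer(r) != prev_res && sum((p - q)^2) < excl^2) return(FALSE)
      if (sum((p - mirror(q))^2) < excl^2) return(FALSE)
    }
    TRUE
  }
  ok_cons <- function(res, placed) {
    ks <- cons[[as.character(res)]]
    if (is.null(ks)) return(TRUE)
    for (k in ks) {
      a <- placed[[as.character(constraints$site_a_res[k])]]
      b <- placed[[as.character(constraints$site_b_res[k])]]
      if (is.null(a) || is.null(b)) next
      if (constraints$site_b_sub[k] == "B") b <- mirror(b)
      d <- sqrt(sum((a - b)^2))
      if (d < constraints$lb[k] - 1e-9 || d > constraints$ub[k] + 1e-9) {
        return(FALSE)
      }
    }
    TRUE
  }
  recurse <- function(res, pos, prev_dir, placed) {
    if (res == 0) return(TRUE)
    for (i in seq_len(nrow(dirs))) {
      d <- dirs[i, ]
      if (!is.null(prev_dir) && sum(d * prev_dir) < -1e-12) next
      p <- pos + spacing * d
      if (!ok_node(p, placed, res + 1)) next
      placed2 <- placed
      placed2[[as.character(res)]] <- p
      if (!ok_cons(res, placed2)) next
      if (recurse(res - 1, p, d, placed2)) return(TRUE)
    }
    FALSE
  }
  recurse(n_nodes, anchor, NULL, list())
}

# Random small instance: constraints forward-simulated from a random
# feasible lattice chain, optionally tightened into infeasibility.
random_lattice_instance <- function(n_nodes, seed, tighten = FALSE) {
  set.seed(seed)
  dirs <- lattice_dirs()
  anchor <- c(1, 0.5, 0)
  mirror <- function(p) c(-p[1], -p[2], p[3])
  repeat { # random reference chain obeying bend + sterics
    pos <- anchor
    prev <- NULL
    chain <- list()
    ok <- TRUE
    for (res in n_nodes:1) {
      good <- FALSE
      for (try in 1:40) {
        d <- dirs[sample.int(26, 1), ]
        if (!is.null(prev) && sum(d * prev) < 0) next
        p <- pos + 0.38 * d
        clash <- sum((p - mirror(p))^2) < 0.25^2
        nms <- names(chain)
        for (j in seq_along(chain)) {
          if (clash) break
          adjacent <- as.integer(nms[j]) == res + 1
          clash <- (!adjacent && sum((p - chain[[j]])^2) < 0.25^2) ||
            sum((p - mirror(chain[[j]]))^2) < 0.25^2
        }
        if (clash) next
        pos <- p; prev <- d; chain[[as.character(res)]] <- p
        good <- TRUE
        break
      }
      if (!good) { ok <- FALSE; break }
    }
    if (ok) break
  }
  npairs <- sample(1:2, 1)
  rows <- lapply(seq_len(npairs), function(i) {
    a <- sample(seq_len(n_nodes), 1)
    inter <- runif(1) < 0.5
    b <- if (inter) a else sample(seq_len(n_nodes), 1)
    pa <- chain[[as.character(a)]]
    pb <- chain[[as.character(b)]]
    if (inter) pb <- mirror(pb)
    d <- sqrt(sum((pa - pb)^2))
    data.frame(site_a_res = a, site_a_sub = "A", site_b_res = b,
               site_b_sub = if (inter) "B" else "A",
               pair_class = "cc1_cc1", E_peak = 0.5, E_uncertainty = 0.05,
               D_FRET = d,
               lb = max(0, d - runif(1, 0.1, 0.6)),
               ub = d + runif(1, 0.05, 0.6), n_relaxations = 0L)
  })
  tab <- do.call(rbind, rows)
  if (tighten) {
    k <- sample(nrow(tab), 1)
    tab$ub[k] <- max(0.01, tab$lb[k] * 0.5)
    tab$lb[k] <- 0
  }
  class(tab) <- c("constraint_table", "data.frame")
  tab
}
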