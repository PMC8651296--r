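# Constraint-satisfaction chain growth: coarse-grained CC1 chains (one
# dimensionless node per residue) grown around the CAD scaffold under
# spacing, bend-angle, steric and FRET-distance constraints, with
# resampling, backtracking and bound relaxation.

#' Builder configuration
#'
#' @param linker_spacing Node spacing in unstructured regions (nm).
#' @param helix_spacing Node spacing inside helices (nm); helices are
#'   placed as single rigid straight segments.
#' @param exclusion_radius No node center may come within this distance of
#'   any scaffold atom or non-adjacent node (nm).
#' @param min_bend_angle Minimum bend angle at a junction node in degrees;
#'   90 means the chain may not turn by more than 90 degrees per step.
#' @param helix_ranges Named list of `c(first, last)` helical residue
#'   ranges (defaults: CC1alpha1 246-271, CC1alpha2 275-305, CC1alpha3
#'   310-337).
#' @param start_residue,end_residue Growth runs from `start_residue` (at
#'   the scaffold N-terminus) down to `end_residue`.
#' @param n_solutions Ensemble size (default 50).
#' @param relaxation_increment Upper-bound increment when a constraint
#'   must be relaxed (nm, default 1).
#' @param max_node_trials,max_helix_trials Direction samples per node /
#'   helix placement before backtracking.
#' @param max_backtracks Total backtracking budget per build attempt.
#' @param max_relaxation_rounds Cap for [relax_and_build()].
#' @param direction_set "uniform" for isotropic directions, or an n x 3
#'   matrix of unit vectors to sample from (used by the lattice-restricted
#'   feasibility checks).
#' @param seed Integer seed.
#' @return Object of class `builder_config`.
#' @export
builder_config <- function(linker_spacing = 0.38, helix_spacing = 0.15,
                           exclusion_radius = 0.25, min_bend_angle = 90,
                           helix_ranges = list(cc1a1 = c(246, 271),
                                               cc1a2 = c(275, 305),
                                               cc1a3 = c(310, 337)),
                           start_residue = 344, end_residue = 233,
                           n_solutions = 50, relaxation_increment = 1,
                           max_node_trials = 256, max_helix_trials = 4096,
                           max_backtracks = 400, max_relaxation_rounds = 40,
                           direction_set = "uniform", seed = 1L) {
  stopifnot(linker_spacing > 0, helix_spacing > 0, exclusion_radius >= 0,
            start_residue > end_residue, n_solutions >= 1)
  for (r in helix_ranges) {
    stopifnot(r[1] < r[2], r[1] >= end_residue, r[2] <= start_residue)
  }
  structure(list(linker_spacing = linker_spacing,
                 helix_spacing = helix_spacing,
                 exclusion_radius = exclusion_radius,
                 min_bend_angle = min_bend_angle,
                 helix_ranges = helix_ranges,
                 start_residue = as.integer(start_residue),
                 end_residue = as.integer(end_residue),
                 n_solutions = as.integer(n_solutions),
                 relaxation_increment = relaxation_increment,
                 max_node_trials = as.integer(max_node_trials),
                 max_helix_trials = as.integer(max_helix_trials),
                 max_backtracks = as.integer(max_backtracks),
                 max_relaxation_rounds = as.integer(max_relaxation_rounds),
                 direction_set = direction_set, seed = as.integer(seed)),
            class = "builder_config")
}

#' Coarse-grained node chain
#'
#' One node per residue for each of the two subunits; subunit B is the
#' rigid symmetry copy of subunit A.
#'
#' @param A n x 3 matrix of subunit-A node coordinates (nm), rows ordered
#'   by `resno`.
#' @param resno Ascending residue numbers.
#' @param transform Rigid A-to-B transform (`list(R, t)`).
#' @param labels Per-residue segment labels (default from the residue
#'   numbers).
#' @param kind "solution" or "average" (averaged chains need not obey the
#'   spacing invariants).
#' @return Object of class `node_chain`.
#' @export
node_chain <- function(A, resno, transform, labels = NULL,
                       kind = "solution") {
  A <- as.matrix(A)
  stopifnot(nrow(A) == length(resno), ncol(A) == 3, !is.unsorted(resno))
  if (is.null(labels)) labels <- cc1_segment_labels(resno)
  rownames(A) <- resno
  B <- apply_rigid(A, transform)
  rownames(B) <- resno
  structure(list(A = A, B = B, resno = as.integer(resno), labels = labels,
                 transform = transform, kind = kind), class = "node_chain")
}

node_xyz <- function(chain, resno, sub = "A") {
  m <- if (sub == "A") chain$A else chain$B
  i <- match(resno, chain$resno)
  if (any(is.na(i))) stop("residue ", resno[is.na(i)][1], " not in chain")
  if (length(resno) == 1) as.numeric(m[i, ]) else m[i, , drop = FALSE]
}

#' Write a node-chain ensemble as a multi-model pseudo-atom PDB
#'
#' One CA pseudo-atom per node, chains A and B, one MODEL per solution.
#'
#' @param chains A `node_chain` or list of them.
#' @param path Output path.
#' @export
write_chain_pdb <- function(chains, path) {
  if (inherits(chains, "node_chain")) chains <- list(chains)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(chains)) {
    ch <- chains[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 0L
    for (sub in c("A", "B")) {
      xyz <- if (sub == "A") ch$A else ch$B
      for (i in seq_along(ch$resno)) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, sub, ch$resno[i], xyz[i, 1] * 10, xyz[i, 2] * 10,
          xyz[i, 3] * 10), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- internal geometry helpers -------------------------------------------

min_dist2_to <- function(pts, ref) {
  # per row of pts, squared distance to the nearest row of ref
  if (is.null(ref) || nrow(ref) == 0) return(rep(Inf, nrow(pts)))
  d2 <- outer(rowSums(pts^2), rowSums(ref^2), "+") - 2 * pts %*% t(ref)
  apply(d2, 1, min)
}

sample_dirs <- function(n, direction_set) {
  if (is.character(direction_set)) {
    d <- matrix(rnorm(3 * n), n, 3)
    d / sqrt(rowSums(d^2))
  } else {
    direction_set[sample.int(nrow(direction_set), n, replace = TRUE), ,
                  drop = FALSE]
  }
}

# Build the ordered placement units (single nodes and rigid helices).
placement_units <- function(config) {
  resno <- config$start_residue:config$end_residue
  labels <- cc1_segment_labels(resno, config$helix_ranges)
  spac <- bond_spacings(resno, labels, config$linker_spacing,
                        config$helix_spacing, config$helix_ranges)
  # helix residues grouped into one unit each, walked in growth order
  units <- list()
  i <- 1
  while (i <= length(resno)) {
    lab <- labels[i]
    if (lab == "linker") {
      units[[length(units) + 1]] <- list(residues = resno[i],
                                         spacings = spac[i], type = "node")
      i <- i + 1
    } else {
      j <- i
      while (j <= length(resno) && labels[j] == lab) j <- j + 1
      units[[length(units) + 1]] <- list(residues = resno[i:(j - 1)],
                                         spacings = spac[i:(j - 1)],
                                         type = "helix")
      i <- j
    }
  }
  units
}

# Index constraints by the CC1 residue at which they become checkable
# (the lower-numbered CC1 site, since growth runs downward).
constraint_index <- function(constraints, config) {
  by_res <- list()
  for (k in seq_len(nrow(constraints))) {
    cls <- constraints$pair_class[k]
    if (cls == "cc1_cad") {
      r <- constraints$site_a_res[k]
    } else if (cls == "cc1_cc1") {
      r <- min(constraints$site_a_res[k], constraints$site_b_res[k])
    } else {
      next # core-core constraints play no role in chain growth
    }
    key <- as.character(r)
    by_res[[key]] <- c(by_res[[key]], k)
  }
  by_res
}

# Evaluate the constraints attached to residue r for a batch of candidate
# positions. candA: batch x 3 positions of residue r on subunit A; candB
# its partner. posA/posB: placed node matrices (rownames resno). Returns
# list(ok = logical batch, rejected = integer counts per constraint row).
check_constraints_batch <- function(ks, r, candA, candB, posA, posB,
                                    constraints, cad) {
  nb <- nrow(candA)
  ok <- rep(TRUE, nb)
  rej <- integer(nrow(constraints))
  site_pos <- function(res, sub) {
    key <- as.character(res)
    m <- if (sub == "A") posA else posB
    if (!is.null(m) && key %in% rownames(m)) return(m[key, ])
    NULL
  }
  for (k in ks) {
    a_res <- constraints$site_a_res[k]; a_sub <- constraints$site_a_sub[k]
    b_res <- constraints$site_b_res[k]; b_sub <- constraints$site_b_sub[k]
    cls <- constraints$pair_class[k]
    # endpoint(s): batch matrix for the residue being placed, fixed
    # 3-vector for the other site; for cc1_cad rows the second site is
    # the dye pseudo-atom on the scaffold
    ends <- list()
    for (side_i in 1:2) {
      res <- if (side_i == 1) a_res else b_res
      sub <- if (side_i == 1) a_sub else b_sub
      if (cls == "cc1_cad" && side_i == 2 && !is.null(cad)) {
        ends[[side_i]] <- eff_center(cad, res, sub)
      } else if (res == r) {
        ends[[side_i]] <- if (sub == "A") candA else candB
      } else {
        p <- site_pos(res, sub)
        if (is.null(p)) { ends <- NULL; break } # other site not yet placed
        ends[[side_i]] <- p
      }
    }
    if (is.null(ends)) next
    e1 <- ends[[1]]; e2 <- ends[[2]]
    if (is.matrix(e1) && is.matrix(e2)) {
      d2 <- rowSums((e1 - e2)^2)
    } else if (is.matrix(e1)) {
      d2 <- rowSums(sweep(e1, 2, e2)^2)
    } else if (is.matrix(e2)) {
      d2 <- rowSums(sweep(e2, 2, e1)^2)
    } else {
      d2 <- rep(sum((e1 - e2)^2), nb)
    }
    bad <- d2 < constraints$lb[k]^2 | d2 > constraints$ub[k]^2
    rej[k] <- rej[k] + sum(bad & ok)
    ok <- ok & !bad
  }
  list(ok = ok, rejected = rej)
}

# Evaluate a batch of single-node candidates. Returns the first accepted
# placement (pts 1 x 3 with residue rowname, dir) or NULL, plus rejection
# counts.
eval_node_unit <- function(dirs, unit, prev_pos, transform, cad_xyz,
                           posA, posB, excl2, cons_idx, constraints, cad) {
  cand <- sweep(dirs * unit$spacings, 2, prev_pos, "+")
  candB <- apply_rigid(cand, transform)
  # distance constraints first (cheap), sterics only on the survivors
  rejected <- integer(nrow(constraints))
  ok <- rep(TRUE, nrow(cand))
  ks <- cons_idx[[as.character(unit$residues)]]
  if (!is.null(ks)) {
    cc <- check_constraints_batch(ks, unit$residues, cand, candB,
                                  posA, posB, constraints, cad)
    rejected <- cc$rejected
    ok <- cc$ok
  }
  steric_rejected <- 0L
  if (any(ok)) {
    s <- which(ok)
    sok <- min_dist2_to(cand[s, , drop = FALSE], cad_xyz) >= excl2
    sok <- sok & rowSums((cand[s, , drop = FALSE] -
                            candB[s, , drop = FALSE])^2) >= excl2
    if (!is.null(posA)) {
      # the chain-adjacent previous node sits exactly one bond away and
      # cannot violate the exclusion, so no exemption is needed here
      sok <- sok & min_dist2_to(cand[s, , drop = FALSE], posA) >= excl2
      sok <- sok & min_dist2_to(cand[s, , drop = FALSE], posB) >= excl2
    }
    steric_rejected <- sum(!sok)
    ok[s] <- sok
  }
  hit <- which(ok)
  if (length(hit)) {
    i <- hit[1]
    list(pts = matrix(cand[i, ], 1, 3, dimnames = list(unit$residues, NULL)),
         dir = dirs[i, ], steric_rejected = steric_rejected,
         rejected = rejected)
  } else {
    list(pts = NULL, dir = NULL, steric_rejected = steric_rejected,
         rejected = rejected)
  }
}

# Evaluate a batch of rigid-helix candidates (whole segment per sampled
# direction), fully vectorized over the direction batch.
eval_helix_unit <- function(dirs, offs, unit, prev_pos, transform, cad_xyz,
                            posA, posB, excl2, cons_idx, constraints, cad) {
  nb <- nrow(dirs)
  K <- length(offs)
  e <- dirs %*% t(transform$R)           # partner-rotated directions
  prevB <- as.numeric(transform$R %*% prev_pos) + transform$t
  # distance constraints first (cheap per-direction vectors), sterics
  # only on the surviving directions
  ok <- rep(TRUE, nb)
  rejected <- integer(nrow(constraints))
  helix_res <- unit$residues
  pos_of <- function(res, sub) { # batch endpoint position as nb x 3
    if (res %in% helix_res) {
      o <- offs[match(res, helix_res)]
      if (sub == "A") sweep(o * dirs, 2, prev_pos, "+")
      else sweep(o * e, 2, prevB, "+")
    } else {
      m <- if (sub == "A") posA else posB
      key <- as.character(res)
      if (is.null(m) || !key %in% rownames(m)) NULL
      else matrix(m[key, ], nb, 3, byrow = TRUE)
    }
  }
  for (r in helix_res) {
    ks <- cons_idx[[as.character(r)]]
    if (is.null(ks) || !any(ok)) next
    for (kcon in ks) {
      cls <- constraints$pair_class[kcon]
      p1 <- pos_of(constraints$site_a_res[kcon],
                   constraints$site_a_sub[kcon])
      p2 <- if (cls == "cc1_cad") {
        matrix(eff_center(cad, constraints$site_b_res[kcon],
                          constraints$site_b_sub[kcon]), nb, 3, byrow = TRUE)
      } else {
        pos_of(constraints$site_b_res[kcon], constraints$site_b_sub[kcon])
      }
      if (is.null(p1) || is.null(p2)) next
      d2 <- rowSums((p1 - p2)^2)
      bad <- d2 < constraints$lb[kcon]^2 | d2 > constraints$ub[kcon]^2
      rejected[kcon] <- rejected[kcon] + sum(bad & ok)
      ok <- ok & !bad
    }
  }
  steric_rejected <- 0L
  if (any(ok)) {
    s <- which(ok)
    ns <- length(s)
    ds <- dirs[s, , drop = FALSE]
    es <- e[s, , drop = FALSE]
    flat <- matrix(0, ns * K, 3)
    for (k in seq_len(K)) {
      flat[(k - 1) * ns + seq_len(ns), ] <-
        sweep(offs[k] * ds, 2, prev_pos, "+")
    }
    chk <- function(ref) {
      if (is.null(ref) || nrow(ref) == 0) return(rep(TRUE, ns))
      m <- matrix(min_dist2_to(flat, ref) >= excl2, ns, K)
      rowSums(!m) == 0
    }
    sok <- chk(cad_xyz) & chk(posA) & chk(posB)
    # candidate nodes against their own partner segment: node k1 on A vs
    # node k2 on B, |c0 + o1 d - o2 e|^2 with |d| = |e| = 1
    c0 <- prev_pos - prevB
    base2 <- sum(c0^2)
    dot_cd <- as.numeric(ds %*% c0)
    dot_ce <- as.numeric(es %*% c0)
    dot_de <- rowSums(ds * es)
    o1 <- rep(offs, each = K)
    o2 <- rep(offs, K)
    d2p <- matrix(base2 + o1^2 + o2^2, ns, K * K, byrow = TRUE) +
      2 * outer(dot_cd, o1) - 2 * outer(dot_ce, o2) -
      2 * outer(dot_de, o1 * o2)
    sok <- sok & (rowSums(d2p < excl2) == 0)
    steric_rejected <- sum(!sok)
    ok[s] <- sok
  }
  hit <- which(ok)
  if (length(hit)) {
    i <- hit[1]
    pts <- sweep(outer(offs, dirs[i, ]), 2, prev_pos, "+")
    rownames(pts) <- helix_res
    list(pts = pts, dir = dirs[i, ], steric_rejected = steric_rejected,
         rejected = rejected)
  } else {
    list(pts = NULL, dir = NULL, steric_rejected = steric_rejected,
         rejected = rejected)
  }
}

#' Grow one CC1 chain solution
#'
#' Nodes are placed from `start_residue` down to `end_residue`, anchored
#' at the scaffold's N-terminal C-alpha. Linker nodes step
#' `linker_spacing` in a uniformly random direction whose bend angle at
#' the junction is at least `min_bend_angle`; each helix is placed as one
#' rigid straight segment of `helix_spacing` steps whose direction is
#' sampled once. After every placement the mirrored partner node is placed
#' implicitly through the dimer symmetry transform, and both are checked
#' for steric exclusion (no center within `exclusion_radius` of any
#' scaffold atom or previously placed node, chain-adjacent neighbors
#' exempt) and for every distance constraint whose two sites are now
#' placed (node to effective dye center for `cc1_cad` pairs, node to node
#' for `cc1_cc1`). Failed placements are resampled up to the trial budget,
#' then the preceding placement is retried (backtracking).
#'
#' @param cad Scaffold `atomic_model` with effective centers for all
#'   `cc1_cad` sites and a symmetry `transform`; may be `NULL` for free
#'   growth (anchor at the origin, two-fold symmetry about z).
#' @param constraints A `constraint_table` with bounds set (may have zero
#'   rows).
#' @param config A [builder_config()].
#' @param seed Integer seed for this attempt.
#' @param anchor Anchor point overriding the scaffold C-alpha.
#' @return A `node_chain` on success, with attribute `stats` (trials,
#'   backtracks, per-constraint rejections); on failure an object of class
#'   `build_failure` with `deepest_residue` and the rejection statistics.
#' @export
build_chain_solution <- function(cad, constraints, config = builder_config(),
                                 seed = config$seed, anchor = NULL) {
  set.seed(seed)
  transform <- if (!is.null(cad)) cad$transform else
    rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  if (is.null(transform)) stop("scaffold has no symmetry transform")
  if (is.null(anchor)) {
    anchor <- if (!is.null(cad)) {
      as.numeric(coords(cad, "A", config$start_residue + 1))
    } else c(0, 0, 0)
  }
  cad_xyz <- if (!is.null(cad)) {
    as.matrix(cad$atoms[, c("x", "y", "z")])
  } else matrix(numeric(0), 0, 3)
  units <- placement_units(config)
  cons_idx <- constraint_index(constraints, config)
  n_units <- length(units)
  placedA <- vector("list", n_units)
  last_dir <- vector("list", n_units + 1)
  last_pos <- vector("list", n_units + 1)
  last_pos[[1]] <- anchor
  last_dir[1] <- list(NULL)
  excl2 <- config$exclusion_radius^2
  rej_total <- integer(nrow(constraints))
  steric_rej <- 0L
  trials_total <- 0L
  backtracks <- 0L
  u <- 1L
  deepest <- config$start_residue + 1L
  cos_bend <- cos(config$min_bend_angle * pi / 180) - 1e-12
  # trial counters persist while a unit stays on the search path, so
  # repeated failures above eventually exhaust it and backtracking
  # cascades deeper (depth-first search with per-placement budgets)
  used_vec <- integer(n_units)
  trials_by_unit <- integer(n_units)
  while (u <= n_units) {
    unit <- units[[u]]
    budget <- if (unit$type == "helix") config$max_helix_trials else
      config$max_node_trials
    batch <- if (unit$type == "helix") 512L else 128L
    prev_pos <- last_pos[[u]]
    prev_dir <- last_dir[[u]]
    posA <- if (u > 1) do.call(rbind, placedA[seq_len(u - 1)]) else NULL
    posB <- if (!is.null(posA)) {
      b <- apply_rigid(posA, transform); rownames(b) <- rownames(posA); b
    } else NULL
    found <- FALSE
    offs <- cumsum(unit$spacings)
    while (!found && used_vec[u] < budget) {
      nb <- min(batch, budget - used_vec[u])
      dirs <- sample_dirs(nb, config$direction_set)
      used_vec[u] <- used_vec[u] + nb
      trials_total <- trials_total + nb
      trials_by_unit[u] <- trials_by_unit[u] + nb
      if (!is.null(prev_dir)) {
        keep <- (dirs %*% prev_dir) >= cos_bend
        dirs <- dirs[keep[, 1], , drop = FALSE]
      }
      if (nrow(dirs) == 0) next
      res <- if (unit$type == "node") {
        eval_node_unit(dirs, unit, prev_pos, transform, cad_xyz, posA, posB,
                       excl2, cons_idx, constraints, cad)
      } else {
        eval_helix_unit(dirs, offs, unit, prev_pos, transform, cad_xyz,
                        posA, posB, excl2, cons_idx, constraints, cad)
      }
      steric_rej <- steric_rej + res$steric_rejected
      rej_total <- rej_total + res$rejected
      if (!is.null(res$pts)) {
        placedA[[u]] <- res$pts
        last_pos[[u + 1]] <- res$pts[nrow(res$pts), ]
        last_dir[[u + 1]] <- res$dir
        found <- TRUE
      }
    }
    if (found) {
      deepest <- min(deepest, min(unit$residues))
      u <- u + 1L
      if (u <= n_units) used_vec[u] <- 0L
    } else {
      if (u == 1L || backtracks >= config$max_backtracks) {
        return(structure(list(deepest_residue = deepest,
                              rejections = rej_total,
                              steric_rejections = steric_rej,
                              trials = trials_total,
                              backtracks = backtracks),
                         class = "build_failure"))
      }
      placedA[u - 1L] <- list(NULL)
      backtracks <- backtracks + 1L
      u <- u - 1L
    }
  }
  A <- do.call(rbind, placedA)
  o <- order(as.integer(rownames(A)))
  chain <- node_chain(A[o, , drop = FALSE], as.integer(rownames(A))[o],
                      transform,
                      labels = cc1_segment_labels(
                        as.integer(rownames(A))[o], config$helix_ranges))
  attr(chain, "stats") <- list(trials = trials_total, backtracks = backtracks,
                               rejections = rej_total,
                               steric_rejections = steric_rej, seed = seed,
                               trials_by_unit = trials_by_unit)
  chain
}

#' Relax constraint bounds until a solution can be built
#'
#' Repeated build attempts; while they fail, the single constraint most
#' often implicated in candidate rejections (ties broken toward the
#' deeper, lower-numbered residue) has its upper bound increased by
#' `relaxation_increment` (1 nm) and its `n_relaxations` count
#' incremented. Stops at the first successful build or after
#' `max_relaxation_rounds`.
#'
#' @inheritParams build_chain_solution
#' @param attempts_per_round Build attempts between relaxations.
#' @return List with `constraints` (possibly relaxed), `solution` (a
#'   `node_chain`) and `rounds`.
#' @export
relax_and_build <- function(cad, constraints, config = builder_config(),
                            seed = config$seed, attempts_per_round = 10,
                            anchor = NULL) {
  rounds <- 0L
  repeat {
    rej <- integer(nrow(constraints))
    for (a in seq_len(attempts_per_round)) {
      sol <- build_chain_solution(cad, constraints, config,
                                  seed = seed + 1000L * rounds + a,
                                  anchor = anchor)
      if (inherits(sol, "node_chain")) {
        return(list(constraints = constraints, solution = sol,
                    rounds = rounds))
      }
      rej <- rej + sol$rejections
    }
    rounds <- rounds + 1L
    if (rounds > config$max_relaxation_rounds) {
      stop("no solution after ", config$max_relaxation_rounds,
           " relaxation rounds; per-constraint rejections: ",
           paste(rej, collapse = ","))
    }
    if (all(rej == 0)) {
      stop("builds fail without constraint rejections; the scaffold ",
           "geometry itself is infeasible")
    }
    worst <- which(rej == max(rej))
    if (length(worst) > 1) { # tie: deepest (lowest-residue) constraint
      depth <- pmin(constraints$site_a_res[worst],
                    ifelse(constraints$pair_class[worst] == "cc1_cc1",
                           constraints$site_b_res[worst],
                           constraints$site_a_res[worst]))
      worst <- worst[which.min(depth)]
    }
    constraints$ub[worst] <- constraints$ub[worst] +
      config$relaxation_increment
    constraints$n_relaxations[worst] <- constraints$n_relaxations[worst] + 1L
  }
}

#' Build an ensemble of chain solutions
#'
#' Collects `n_solutions` independently seeded successful builds under a
#' fixed (already relaxed) constraint set, re-validates each against all
#' constraints and sterics with the independent validator, and classifies
#' each solution's topology.
#'
#' @inheritParams build_chain_solution
#' @param max_attempts Cap on total build attempts.
#' @return Object of class `solution_ensemble`: `solutions` (list of
#'   `node_chain`), `topology` (character vector), `stats` (attempts,
#'   failures), `constraints`.
#' @export
ensemble_build <- function(cad, constraints, config = builder_config(),
                           seed = config$seed,
                           max_attempts = 40L * config$n_solutions,
                           anchor = NULL) {
  sols <- list()
  topo <- character(0)
  attempts <- 0L
  while (length(sols) < config$n_solutions && attempts < max_attempts) {
    attempts <- attempts + 1L
    sol <- build_chain_solution(cad, constraints, config,
                                seed = seed + 7919L * attempts,
                                anchor = anchor)
    if (!inherits(sol, "node_chain")) next
    v <- validate_chain(sol, cad, constraints, config)
    if (!v$ok) {
      stop("builder produced an invalid solution: ",
           paste(v$problems, collapse = "; "))
    }
    sols[[length(sols) + 1]] <- sol
    topo <- c(topo, if (!is.null(config$helix_ranges$cc1a2) &&
                        !is.null(config$helix_ranges$cc1a3)) {
      classify_topology(sol, config)$label
    } else NA_character_)
  }
  if (length(sols) < config$n_solutions) {
    warning("only ", length(sols), " of ", config$n_solutions,
            " solutions obtained within the attempt budget")
  }
  structure(list(solutions = sols, topology = topo,
                 stats = list(attempts = attempts,
                              failures = attempts - length(sols)),
                 constraints = constraints),
            class = "solution_ensemble")
}

#' Independent validator for chain solutions
#'
#' Re-checks a finished chain against every contract with code that shares
#' nothing with the builder: exact bond spacings, helix collinearity,
#' bend angles, steric exclusions (scaffold and non-adjacent nodes, both
#' subunits), all distance constraints within their bounds, and exact
#' subunit symmetry.
#'
#' @param chain A `node_chain`.
#' @param cad Scaffold model (or `NULL`).
#' @param constraints A `constraint_table`.
#' @param config The [builder_config()] used.
#' @return List with `ok` and `problems` (character vector).
#' @export
validate_chain <- function(chain, cad, constraints,
                           config = builder_config()) {
  problems <- character(0)
  res <- chain$resno
  A <- chain$A
  tol <- 1e-9
  labels <- cc1_segment_labels(res, config$helix_ranges)
  spac <- bond_spacings(res, labels, config$linker_spacing,
                        config$helix_spacing, config$helix_ranges)
  # bond i connects residue res[i] to res[i]+1 (the next row up)
  for (i in seq_len(length(res) - 1)) {
    d <- sqrt(sum((A[i + 1, ] - A[i, ])^2))
    if (abs(d - spac[i]) > 1e-6) {
      problems <- c(problems, sprintf("bond %d-%d length %.4f != %.2f",
                                      res[i], res[i] + 1, d, spac[i]))
    }
  }
  for (nm in names(config$helix_ranges)) {
    r <- config$helix_ranges[[nm]]
    idx <- which(res >= r[1] & res <= r[2])
    if (length(idx) >= 3) {
      seg <- A[idx, , drop = FALSE]
      ax <- unit3(seg[length(idx), ] - seg[1, ])
      rel <- sweep(seg, 2, seg[1, ])
      perp <- rel - outer(as.numeric(rel %*% ax), ax)
      if (max(sqrt(rowSums(perp^2))) > 1e-6) {
        problems <- c(problems, paste("helix", nm, "not collinear"))
      }
    }
  }
  # bend angles: consecutive bond vectors in growth (descending) order
  Ad <- A[order(-res), , drop = FALSE]
  bonds <- diff(Ad)
  for (i in seq_len(nrow(bonds) - 1)) {
    u <- unit3(bonds[i, ]); v <- unit3(bonds[i + 1, ])
    turn <- acos(pmin(pmax(sum(u * v), -1), 1)) * 180 / pi
    if (turn > 180 - config$min_bend_angle + 1e-6) {
      problems <- c(problems, sprintf("bend angle %.1f too sharp after bond %d",
                                      180 - turn, i))
    }
  }
  # sterics
  all_nodes <- rbind(A, chain$B)
  n <- nrow(A)
  idx_res <- c(res, res)
  idx_sub <- rep(c("A", "B"), each = n)
  D <- as.matrix(stats::dist(all_nodes))
  adjacent <- abs(outer(idx_res, idx_res, "-")) == 1 &
    outer(idx_sub, idx_sub, "==")
  diag(D) <- Inf
  D[adjacent] <- Inf
  if (min(D) < config$exclusion_radius - 1e-9) {
    problems <- c(problems, sprintf("node-node distance %.3f below exclusion",
                                    min(D)))
  }
  if (!is.null(cad)) {
    cx <- as.matrix(cad$atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(all_nodes^2), rowSums(cx^2), "+") -
      2 * all_nodes %*% t(cx)
    if (min(d2) < config$exclusion_radius^2 - 1e-9) {
      problems <- c(problems, "node within exclusion radius of scaffold atom")
    }
  }
  # constraints
  if (nrow(constraints)) {
    for (k in seq_len(nrow(constraints))) {
      cls <- constraints$pair_class[k]
      if (!cls %in% c("cc1_cad", "cc1_cc1")) next
      pa <- node_xyz(chain, constraints$site_a_res[k],
                     constraints$site_a_sub[k])
      pb <- if (cls == "cc1_cad") {
        eff_center(cad, constraints$site_b_res[k], constraints$site_b_sub[k])
      } else {
        node_xyz(chain, constraints$site_b_res[k], constraints$site_b_sub[k])
      }
      d <- sqrt(sum((pa - pb)^2))
      if (d < constraints$lb[k] - 1e-9 || d > constraints$ub[k] + 1e-9) {
        problems <- c(problems, sprintf(
          "constraint %d (%d%s:%d%s) distance %.3f outside [%.3f, %.3f]",
          k, constraints$site_a_res[k], constraints$site_a_sub[k],
          constraints$site_b_res[k], constraints$site_b_sub[k], d,
          constraints$lb[k], constraints$ub[k]))
      }
    }
  }
  symm <- max(abs(apply_rigid(A, chain$transform) - chain$B))
  if (symm > 1e-9) problems <- c(problems, "subunit B breaks symmetry")
  list(ok = length(problems) == 0, problems = problems)
}

#' Average a solution ensemble into a mean model
#'
#' Per-residue arithmetic mean coordinates with the RMS spread about the
#' mean. Averaging mixes only solutions of one topology class unless
#' `force = TRUE`; the result is of kind "average" (it need not obey the
#' spacing invariants).
#'
#' @param ensemble A `solution_ensemble`.
#' @param class Topology class to average ("stacked" or "wedged";
#'   default: the majority class).
#' @param force Average across classes.
#' @return List with `chain` (average `node_chain`), `spread`
#'   (per-residue RMS, nm), `n`.
#' @export
average_model <- function(ensemble, class = NULL, force = FALSE) {
  stopifnot(inherits(ensemble, "solution_ensemble"))
  sel <- seq_along(ensemble$solutions)
  if (!force) {
    if (is.null(class)) {
      class <- names(which.max(table(ensemble$topology)))
    }
    sel <- which(ensemble$topology == class)
    if (length(sel) < 2) stop("fewer than 2 solutions in class ", class)
  }
  arrs <- lapply(ensemble$solutions[sel], function(s) s$A)
  n <- length(arrs)
  mean_a <- Reduce(`+`, arrs) / n
  spread <- sqrt(Reduce(`+`, lapply(arrs, function(a) {
    rowSums((a - mean_a)^2)
  })) / n)
  ref <- ensemble$solutions[[sel[1]]]
  ch <- node_chain(mean_a, ref$resno, ref$transform, labels = ref$labels,
                   kind = "average")
  list(chain = ch, spread = spread, n = n)
}

# Minimum distance between two finite 3D segments.
segment_distance <- function(p1, p2, q1, q2) {
  u <- p2 - p1; v <- q2 - q1; w0 <- p1 - q1
  a <- sum(u * u); b <- sum(u * v); c_ <- sum(v * v)
  d_ <- sum(u * w0); e_ <- sum(v * w0)
  den <- a * c_ - b^2
  if (den > 1e-12) {
    s <- (b * e_ - c_ * d_) / den
    t_ <- (a * e_ - b * d_) / den
  } else {
    s <- 0; t_ <- if (c_ > 0) e_ / c_ else 0
  }
  s <- min(max(s, 0), 1); t_ <- min(max(t_, 0), 1)
  # refine clamped solution
  t_ <- if (c_ > 0) min(max((b * s + e_) / c_, 0), 1) else 0
  s <- if (a > 0) min(max((b * t_ - d_) / a, 0), 1) else 0
  sqrt(sum((p1 + s * u - (q1 + t_ * v))^2))
}

#' Classify a solution's CC1alpha2/alpha3 packing topology
#'
#' Computes the helix axis of CC1alpha2 on subunit A and of CC1alpha3 on
#' subunit B (N-to-C direction between the helix end nodes). The solution
#' is "stacked" when the two axes pack antiparallel (angle above
#' `angle_min`) and closer than `dist_max` (minimal axis-to-axis
#' distance); otherwise "wedged".
#'
#' @param chain A `node_chain` containing both helices.
#' @param config A [builder_config()] (helix ranges).
#' @param angle_min Degrees (default 135).
#' @param dist_max nm (default 1.5).
#' @return List with `label`, `angle` (degrees) and `distance` (nm).
#' @export
classify_topology <- function(chain, config = builder_config(),
                              angle_min = 135, dist_max = 1.5) {
  r2 <- config$helix_ranges$cc1a2
  r3 <- config$helix_ranges$cc1a3
  if (is.null(r2) || is.null(r3)) stop("helix ranges cc1a2/cc1a3 required")
  a2_1 <- node_xyz(chain, r2[1], "A"); a2_2 <- node_xyz(chain, r2[2], "A")
  b3_1 <- node_xyz(chain, r3[1], "B"); b3_2 <- node_xyz(chain, r3[2], "B")
  u <- a2_2 - a2_1; v <- b3_2 - b3_1
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) stop("degenerate helix axis")
  ang <- acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
  d <- segment_distance(a2_1, a2_2, b3_1, b3_2)
  list(label = if (ang > angle_min && d < dist_max) "stacked" else "wedged",
       angle = ang, distance = d)
}
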