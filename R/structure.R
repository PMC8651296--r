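# Atomic models in nm. An `atomic_model` is a list with `atoms`
# (data.frame: chain, resno, elety, element, x, y, z), optional
# `eff_centers` (data.frame: chain, resno, x, y, z) and optional
# `transform` (the A -> B rigid symmetry transform, list(R, t)).

new_atomic_model <- function(atoms, eff_centers = NULL, transform = NULL) {
  stopifnot(all(c("chain", "resno", "elety", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch & atoms$elety == "CA"]
    if (anyDuplicated(r)) stop("duplicate residue numbers in chain ", ch)
  }
  structure(list(atoms = atoms, eff_centers = eff_centers,
                 transform = transform), class = "atomic_model")
}

#' Read / write an atomic model in PDB format
#'
#' Coordinates are converted between PDB angstroms and the internal nm.
#'
#' @param path PDB file path.
#' @return `read_structure()` returns an `atomic_model`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  new_atomic_model(data.frame(
    chain = a$chain, resno = a$resno, elety = a$elety,
    element = a$elesy, x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE
  ))
}

#' @rdname read_structure
#' @param model An `atomic_model` to write (nm converted to angstrom).
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  pdb <- bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]) * 10)),
    resno = a$resno, chain = a$chain, elety = a$elety,
    resid = rep("ALA", nrow(a))
  )
  invisible(path)
}

coords <- function(model, chain = NULL, resno = NULL, elety = "CA") {
  a <- model$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(resno)) sel <- sel & a$resno %in% resno
  if (!is.null(elety)) sel <- sel & a$elety %in% elety
  as.matrix(a[sel, c("x", "y", "z")])
}

#' Least-RMSD rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum |R p_i + t - q_i|^2` for paired points (rows of `P`, `Q`).
#'
#' @param P,Q n x 3 matrices of paired coordinates.
#' @return List with `R` (3 x 3), `t` (length 3) and `rmsd`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3, nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_ <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t_, "+")
  list(R = R, t = t_, rmsd = sqrt(mean(rowSums((fitted - Q)^2))))
}

apply_rigid <- function(xyz, tr) {
  sweep(matrix(xyz, ncol = 3) %*% t(tr$R), 2, tr$t, "+")
}

rigid_transform <- function(R, t) list(R = R, t = as.numeric(t))

compose_rigid <- function(tr2, tr1) { # tr2(tr1(x))
  rigid_transform(tr2$R %*% tr1$R, as.numeric(tr2$R %*% tr1$t) + tr2$t)
}

#' Symmetrize a dimer by replacing one subunit with a copy of the other
#'
#' Superposes chain A's C-alpha atoms over the alignment residue ranges
#' onto chain B's, replaces all of chain B by the transformed copy of
#' chain A, and returns the rigid A-to-B transform. The result is exactly
#' two-fold symmetric under that transform, which downstream steps use to
#' mirror nodes and dye centers onto the partner subunit.
#'
#' @param model An `atomic_model` with chains "A" and "B".
#' @param ranges List of `c(first, last)` residue ranges used for the
#'   superposition (default: the proximal CC2, aa 345-378, and CC3,
#'   aa 408-436).
#' @return The symmetrized `atomic_model`, with `transform` set.
#' @export
symmetrize_dimer <- function(model, ranges = list(c(345, 378), c(408, 436))) {
  res <- unlist(lapply(ranges, function(r) seq(r[1], r[2])))
  a <- model$atoms
  for (ch in c("A", "B")) {
    have <- a$resno[a$chain == ch & a$elety == "CA"]
    missing <- setdiff(res, have)
    if (length(missing)) {
      stop("chain ", ch, " is missing alignment residues: ",
           paste(missing, collapse = ", "))
    }
  }
  ca_a <- coords(model, "A", res)
  ca_b <- coords(model, "B", res)
  # order by resno for pairing
  ord <- function(ch) order(a$resno[a$chain == ch & a$elety == "CA" &
                                      a$resno %in% res])
  fit <- kabsch(ca_a[ord("A"), ], ca_b[ord("B"), ])
  tr <- rigid_transform(fit$R, fit$t)
  newb <- a[a$chain == "A", ]
  newb$chain <- "B"
  newb[, c("x", "y", "z")] <- apply_rigid(
    as.matrix(a[a$chain == "A", c("x", "y", "z")]), tr)
  atoms <- rbind(a[a$chain == "A", ], newb)
  new_atomic_model(atoms, eff_centers = NULL, transform = tr)
}

#' Dye parameters for accessible-volume sampling
#'
#' Tether lengths default to 1.35 nm (Cy3-like donor) and 1.50 nm
#' (Cy5-like acceptor): for unobstructed uniform-in-ball sampling the mean
#' protrusion of the dye center from the attachment C-alpha is 3L/4.
#'
#' @param dye "cy3" or "cy5".
#' @param L Tether length in nm (default by dye).
#' @param clash_radius Minimum distance from any protein atom (nm).
#' @param n_samples Accepted samples to draw (default 100).
#' @param seed Integer seed.
#' @return Object of class `dye_params`.
#' @export
dye_params <- function(dye = c("cy3", "cy5"), L = NULL, clash_radius = 0.3,
                       n_samples = 100, seed = 1L) {
  dye <- match.arg(dye)
  if (is.null(L)) L <- if (dye == "cy3") 1.35 else 1.50
  stopifnot(L > 0, n_samples >= 1, clash_radius >= 0)
  structure(list(dye = dye, L = L, clash_radius = clash_radius,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "dye_params")
}

#' Sample accessible-volume dye-center positions at a labeling site
#'
#' Draws positions uniformly from the ball of radius `L` around the
#' site's C-alpha, rejecting positions within `clash_radius` of any
#' protein atom (the attachment residue's own atoms excepted) or closer
#' than 0.2 nm to the C-alpha itself, until `n_samples` are accepted.
#' The mean of the accepted cloud is the dye-center estimate.
#'
#' @param model An `atomic_model`.
#' @param resno,chain Labeling site.
#' @param params A [dye_params()].
#' @return List with `mean` (length 3), `cloud` (n x 3), `protrusion`
#'   (mean C-alpha-to-center distance over the cloud, nm) and
#'   `acceptance`.
#' @export
sample_dye_centers <- function(model, resno, chain = "A",
                               params = dye_params()) {
  ca <- coords(model, chain, resno)
  if (nrow(ca) != 1) stop("site ", chain, ":", resno, " has no unique C-alpha")
  ca <- as.numeric(ca)
  a <- model$atoms
  other <- !(a$chain == chain & a$resno == resno)
  prot <- as.matrix(a[other, c("x", "y", "z")])
  set.seed(params$seed + resno)
  accepted <- matrix(0, 0, 3)
  drawn <- 0L
  while (nrow(accepted) < params$n_samples) {
    m <- 500L
    drawn <- drawn + m
    dir <- matrix(rnorm(3 * m), m, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    r <- params$L * runif(m)^(1 / 3)
    pts <- sweep(dir * r, 2, ca, "+")
    ok <- r >= 0.2
    if (nrow(prot) > 0 && any(ok)) {
      D2 <- outer(rowSums(pts^2), rowSums(prot^2), "+") -
        2 * pts %*% t(prot)
      ok <- ok & (apply(D2, 1, min) >= params$clash_radius^2)
    }
    accepted <- rbind(accepted, pts[ok, , drop = FALSE])
    if (drawn >= 100 * params$n_samples &&
        nrow(accepted) / drawn < 0.01) {
      stop("site ", chain, ":", resno, " is buried: dye acceptance below 1%")
    }
  }
  accepted <- accepted[seq_len(params$n_samples), , drop = FALSE]
  list(mean = colMeans(accepted), cloud = accepted,
       protrusion = mean(sqrt(rowSums(sweep(accepted, 2, ca)^2))),
       acceptance = nrow(accepted) / drawn, ca = ca)
}

#' Effective dye centers for labeling sites
#'
#' Because labeling is stochastic, either dye may occupy either site of a
#' pair; the donor-like and acceptor-like mean centers at each site are
#' therefore averaged into a single effective center (a pseudo-atom), and
#' model distances are measured center to center.
#'
#' @param model An `atomic_model` (symmetric dimer models use their
#'   `transform` to mirror chain A centers onto chain B).
#' @param sites Integer residue numbers (on chain A; chain B centers are
#'   mirrored when a symmetry transform is present, else sampled).
#' @param cy3,cy5 [dye_params()] for the two dyes.
#' @return The model with `eff_centers` filled (chains A and B), plus
#'   attribute `protrusions` (data.frame of per-site, per-dye mean
#'   C-alpha-to-center distances).
#' @export
effective_centers <- function(model, sites, cy3 = dye_params("cy3"),
                              cy5 = dye_params("cy5")) {
  rows <- list(); prot <- list()
  for (s in sites) {
    s3 <- sample_dye_centers(model, s, "A", cy3)
    s5 <- sample_dye_centers(model, s, "A", cy5)
    eff <- (s3$mean + s5$mean) / 2
    rows[[length(rows) + 1]] <- data.frame(chain = "A", resno = s,
                                           x = eff[1], y = eff[2], z = eff[3])
    prot[[length(prot) + 1]] <- data.frame(resno = s, cy3 = s3$protrusion,
                                           cy5 = s5$protrusion)
  }
  eff_a <- do.call(rbind, rows)
  if (!is.null(model$transform)) {
    eff_b <- eff_a
    eff_b$chain <- "B"
    eff_b[, c("x", "y", "z")] <- apply_rigid(
      as.matrix(eff_a[, c("x", "y", "z")]), model$transform)
  } else {
    eff_b <- do.call(rbind, lapply(sites, function(s) {
      s3 <- sample_dye_centers(model, s, "B", cy3)
      s5 <- sample_dye_centers(model, s, "B", cy5)
      eff <- (s3$mean + s5$mean) / 2
      data.frame(chain = "B", resno = s, x = eff[1], y = eff[2], z = eff[3])
    }))
  }
  model$eff_centers <- rbind(eff_a, eff_b)
  attr(model, "protrusions") <- do.call(rbind, prot)
  model
}

eff_center <- function(model, resno, chain) {
  ec <- model$eff_centers
  row <- ec[ec$resno == resno & ec$chain == chain, ]
  if (nrow(row) != 1) {
    stop("no effective center for site ", chain, ":", resno,
         "; run effective_centers() first")
  }
  as.numeric(row[, c("x", "y", "z")])
}

# Minimal rotation taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) { # pick any perpendicular axis
    axis <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- skew(w / sqrt(sum(w^2)))
  s_ <- sqrt(sum(w^2))
  diag(3) + s_ * K + (1 - c_) * K %*% K
}

skew <- function(a) matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0),
                           3, 3)

#' Optimize the flexible apex of a symmetric dimer against FRET distances
#'
#' Treats the distal CC2 helix (residues 379-391) as a rigid body pivoting
#' about the G379 C-alpha. The pivot motion is parameterized by the two
#' angles (polar, azimuth) that redirect the helix axis; the connecting
#' linker (392-407) follows with a displacement that tapers linearly to
#' zero at residue 407, and the identical motion is applied to the partner
#' subunit through the dimer symmetry transform, keeping the model
#' symmetric. The proximal CC2 and CC3 domains stay fixed. The objective
#' penalizes constraint distances outside their bound windows
#' (`sum(max(0, |d - D_FRET| - halfwidth)^2)`); it is minimized by a
#' coarse grid over the two angles followed by local refinement.
#' Orientations bringing moved atoms within 0.2 nm of fixed atoms are
#' rejected.
#'
#' @param model A symmetric `atomic_model` with `transform` and effective
#'   centers for all constrained sites (see [symmetrize_dimer()] and
#'   [effective_centers()]).
#' @param constraints A `constraint_table` whose classes are
#'   `cad_cad_inter` / `intra_subunit` (apex sites).
#' @param helix_range,linker_range,pivot_resno Apex definition.
#' @param grid_polar,grid_azimuth Coarse grid (degrees).
#' @return List with `model` (moved), `angles` (polar, azimuth, degrees),
#'   `rotation_angle` (net helix-axis reorientation, degrees),
#'   `residuals` (per-constraint distance minus target), `objective`,
#'   `satisfied`.
#' @export
optimize_apex <- function(model, constraints,
                          helix_range = c(379, 391),
                          linker_range = c(392, 407), pivot_resno = 379,
                          grid_polar = seq(0, 60, by = 5),
                          grid_azimuth = seq(0, 345, by = 15)) {
  if (is.null(model$transform)) {
    stop("model has no symmetry transform; run symmetrize_dimer() first")
  }
  a <- model$atoms
  ca_a <- coords(model, "A", elety = "CA")
  res_a <- a$resno[a$chain == "A" & a$elety == "CA"]
  pivot <- as.numeric(coords(model, "A", pivot_resno))
  tip <- as.numeric(coords(model, "A", helix_range[2]))
  d0 <- tip - pivot; d0 <- d0 / sqrt(sum(d0^2))
  # orthonormal frame around d0 for the azimuth
  e1 <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * d0) * d0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d0[2] * e1[3] - d0[3] * e1[2], d0[3] * e1[1] - d0[1] * e1[3],
          d0[1] * e1[2] - d0[2] * e1[1])
  new_dir <- function(polar, azim) {
    p <- polar * pi / 180; b <- azim * pi / 180
    cos(p) * d0 + sin(p) * (cos(b) * e1 + sin(b) * e2)
  }
  in_helix <- function(r) r >= helix_range[1] & r <= helix_range[2]
  in_linker <- function(r) r >= linker_range[1] & r <= linker_range[2]
  taper <- function(r) (linker_range[2] - r) /
    (linker_range[2] - helix_range[2])
  displace <- function(xyz, resno, R) {
    # rigid motion for helix residues, tapered for linker residues
    moved <- xyz
    rot <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
    w <- ifelse(in_helix(resno), 1, ifelse(in_linker(resno), taper(resno), 0))
    moved + (rot - moved) * w
  }
  ec <- model$eff_centers
  ec_a <- ec[ec$chain == "A", ]
  sites_used <- unique(c(constraints$site_a_res, constraints$site_b_res))
  miss <- setdiff(sites_used, ec_a$resno)
  if (length(miss)) stop("missing effective centers for sites: ",
                         paste(miss, collapse = ", "))
  half_w <- (constraints$ub - constraints$lb) / 2
  moved_rng <- range(helix_range, linker_range)
  fixed_sel <- !(in_helix(res_a) | in_linker(res_a)) &
    res_a != moved_rng[1] - 1 & res_a != moved_rng[2] + 1
  fixed_xyz <- rbind(ca_a[fixed_sel, , drop = FALSE],
                     apply_rigid(ca_a[fixed_sel, , drop = FALSE],
                                 model$transform))
  objective <- function(par, check_clash = TRUE) {
    R <- rotation_between(d0, new_dir(par[1], par[2]))
    eca <- displace(as.matrix(ec_a[, c("x", "y", "z")]), ec_a$resno, R)
    rownames(eca) <- ec_a$resno
    ecb <- apply_rigid(eca, model$transform)
    rownames(ecb) <- ec_a$resno
    get <- function(resno, sub) {
      m <- if (sub == "A") eca else ecb
      m[as.character(resno), ]
    }
    d <- vapply(seq_len(nrow(constraints)), function(i) {
      pa <- get(constraints$site_a_res[i], constraints$site_a_sub[i])
      pb <- get(constraints$site_b_res[i], constraints$site_b_sub[i])
      sqrt(sum((pa - pb)^2))
    }, 1)
    pen <- pmax(0, abs(d - constraints$D_FRET) - half_w)
    # tiny quadratic pull toward D_FRET breaks ties inside the bound
    # windows without overriding them
    obj <- sum(pen^2) + 1e-3 * sum((d - constraints$D_FRET)^2)
    if (check_clash) {
      mv_sel <- in_helix(res_a) | in_linker(res_a)
      mv <- displace(ca_a[mv_sel, , drop = FALSE], res_a[mv_sel], R)
      mv2 <- apply_rigid(mv, model$transform)
      D2 <- outer(rowSums(rbind(mv, mv2)^2), rowSums(fixed_xyz^2), "+") -
        2 * rbind(mv, mv2) %*% t(fixed_xyz)
      if (min(D2) < 0.2^2) obj <- obj + 1e3 + 1e3 * (0.2^2 - min(D2))
    }
    attr(obj, "dist") <- d
    obj
  }
  best <- NULL
  for (p in grid_polar) for (b in (if (p == 0) 0 else grid_azimuth)) {
    v <- as.numeric(objective(c(p, b)))
    if (is.null(best) || v < best$v) best <- list(v = v, par = c(p, b))
  }
  opt <- optim(best$par, function(par) as.numeric(objective(par)),
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  par <- opt$par
  R <- rotation_between(d0, new_dir(par[1], par[2]))
  sel_a <- a$chain == "A"
  moved_a <- displace(as.matrix(a[sel_a, c("x", "y", "z")]),
                      a$resno[sel_a], R)
  atoms <- a
  atoms[sel_a, c("x", "y", "z")] <- moved_a
  selb <- a$chain == "B"
  atoms[selb, c("x", "y", "z")] <- apply_rigid(moved_a, model$transform)
  out <- new_atomic_model(atoms, transform = model$transform)
  out$eff_centers <- ec
  out$eff_centers[ec$chain == "A", c("x", "y", "z")] <-
    displace(as.matrix(ec_a[, c("x", "y", "z")]), ec_a$resno, R)
  out$eff_centers[ec$chain == "B", c("x", "y", "z")] <- apply_rigid(
    as.matrix(out$eff_centers[ec$chain == "A", c("x", "y", "z")]),
    model$transform)
  final <- objective(par)
  dists <- attr(final, "dist")
  resid <- dists - constraints$D_FRET
  satisfied <- all(dists >= constraints$lb - 1e-9 &
                     dists <= constraints$ub + 1e-9)
  ang <- acos(pmin(pmax(sum(d0 * new_dir(par[1], par[2])), -1), 1)) * 180 / pi
  list(model = out, angles = par, rotation_angle = ang,
       residuals = resid, objective = as.numeric(final),
       satisfied = satisfied)
}
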