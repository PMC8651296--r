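# Synthetic structural ground truth: a CAD-like symmetric dimer scaffold
# and a planted resting-state CC1 node chain, from which constraint tables
# can be forward-simulated with known truth.

unit3 <- function(v) v / sqrt(sum(v^2))

# Spherical linear interpolation between two unit vectors, returning n
# intermediate directions (excluding d_from, including d_to).
slerp_dirs <- function(d_from, d_to, n) {
  d_from <- unit3(d_from); d_to <- unit3(d_to)
  ang <- acos(pmin(pmax(sum(d_from * d_to), -1), 1))
  if (ang < 1e-9) return(matrix(rep(d_to, n), n, 3, byrow = TRUE))
  perp <- unit3(d_to - sum(d_from * d_to) * d_from)
  t(vapply(seq_len(n) / n, function(f) {
    cos(f * ang) * d_from + sin(f * ang) * perp
  }, numeric(3)))
}

#' Synthetic CAD-like dimer scaffold
#'
#' Builds a coarse C-alpha-only stand-in for the V-shaped parallel CAD
#' dimer (residues 345-436 per subunit): a long CC2 helix rising from the
#' dimer base, an apex linker, and a CC3 helix folding back along CC2.
#' Chain B is chain A rotated by the exact two-fold symmetry about the z
#' axis, which is returned as the model's `transform`. This synthetic
#' scaffold reproduces the qualitative geometry the modeling pipeline
#' needs (compact symmetric base, apical linker region, CC3 running back
#' to the base); it is not a crystal structure.
#'
#' @return An `atomic_model` with chains "A" and "B" and `transform` set.
#' @export
make_synthetic_cad <- function() {
  u2 <- unit3(c(0.13, 0, 0.99))
  p_cc2 <- t(vapply(0:46, function(k) c(0.45, 0.25, 0.5) + 0.15 * k * u2,
                    numeric(3)))
  u3 <- unit3(c(-0.02, 0, -0.99))
  p_cc3 <- t(vapply(0:28, function(k) c(0.95, 0.55, 4.8) + 0.15 * k * u3,
                    numeric(3)))
  p391 <- p_cc2[47, ]; p408 <- p_cc3[1, ]
  p_link <- t(vapply(1:16, function(i) {
    p391 + (i / 17) * (p408 - p391)
  }, numeric(3)))
  xyz <- rbind(p_cc2, p_link, p_cc3)
  resno <- c(345:391, 392:407, 408:436)
  rot2 <- diag(c(-1, -1, 1)) # C2 about z
  atoms_a <- data.frame(chain = "A", resno = resno, elety = "CA",
                        element = "C", x = xyz[, 1], y = xyz[, 2],
                        z = xyz[, 3], stringsAsFactors = FALSE)
  xyz_b <- xyz %*% t(rot2)
  atoms_b <- atoms_a
  atoms_b$chain <- "B"
  atoms_b$x <- xyz_b[, 1]; atoms_b$y <- xyz_b[, 2]; atoms_b$z <- xyz_b[, 3]
  new_atomic_model(rbind(atoms_a, atoms_b),
                   transform = rigid_transform(rot2, c(0, 0, 0)))
}

# Per-residue segment labels for the CC1 chain.
cc1_segment_labels <- function(resno,
                               helix_ranges = list(cc1a1 = c(246, 271),
                                                   cc1a2 = c(275, 305),
                                                   cc1a3 = c(310, 337))) {
  lab <- rep("linker", length(resno))
  for (nm in names(helix_ranges)) {
    r <- helix_ranges[[nm]]
    lab[resno >= r[1] & resno <= r[2]] <- nm
  }
  lab
}

#' Planted resting-state CC1 node chain
#'
#' Constructs, with exact builder spacings (0.38 nm linker bonds, 0.15 nm
#' helix bonds) and bend angles of at least 90 degrees, a CC1 chain
#' (one node per residue, 233-344) in the resting topology: CC1alpha3
#' helices closely apposed near the symmetry axis and directed away from
#' the CAD base, CC1alpha2 packed antiparallel against the partner
#' CC1alpha3, and CC1alpha1 running parallel to the partner CC3. The
#' partner chain is the exact symmetry copy. Used as ground truth for
#' forward-simulated constraint tables and recovery tests.
#'
#' @param cad A synthetic CAD model from [make_synthetic_cad()] (supplies
#'   the anchor C-alpha at residue 345 and the symmetry transform).
#' @return A `node_chain` (see [node_chain()]).
#' @export
make_planted_chain <- function(cad = make_synthetic_cad()) {
  anchor <- as.numeric(coords(cad, "A", 345))
  v3 <- unit3(c(-0.07, -0.04, -0.995))     # CC1a3 growth axis (downward)
  mhat <- unit3(c(-0.81, -0.58, 0))        # U-turn lateral direction
  v2 <- unit3(c(-0.07, -0.04, 0.995))      # CC1a2 growth axis (upward)
  w1 <- unit3(c(-0.02, 0, 1))              # CC1a1 growth axis (upward)
  dirs <- list()
  # linker 344..338 (7 bonds), easing from down-and-out into the a3 axis
  dirs$seg1 <- slerp_dirs(c(0.25, 0.3, -0.92), v3, 7)
  # bond into 337 plus helix a3 337..310 (27 bonds), all along v3
  dirs$a3 <- matrix(rep(v3, 28), 28, 3, byrow = TRUE)
  # U-turn 309..305 (5 bonds): half-circle in the (mhat, z) plane with a
  # tangential swing keeping the path clear of the symmetry axis
  th <- c(-65, -25, 0, 25, 65) * pi / 180
  that <- unit3(c(-mhat[2], mhat[1], 0))
  bias <- c(-0.35, -0.35, 0, 0.35, 0.35)
  dirs$uturn <- t(vapply(seq_along(th), function(i) {
    unit3(cos(th[i]) * mhat + sin(th[i]) * c(0, 0, 1) + bias[i] * that)
  }, numeric(3)))
  # helix a2 305..275 (30 bonds) along v2
  dirs$a2 <- matrix(rep(v2, 30), 30, 3, byrow = TRUE)
  # linker 274..271 (4 bonds) rising toward the a1 start
  dirs$seg4 <- slerp_dirs(unit3(c(-0.35, -0.25, 0.9)), w1, 4)
  # helix a1 271..246 (25 bonds) along w1
  dirs$a1 <- matrix(rep(w1, 25), 25, 3, byrow = TRUE)
  # N-terminal linker 245..233 (13 bonds), splaying up and outward
  dirs$seg6 <- slerp_dirs(w1, unit3(c(-0.55, -0.35, 0.76)), 13)
  D <- do.call(rbind, dirs)
  resno <- 344:233
  stopifnot(nrow(D) == length(resno))
  labels <- cc1_segment_labels(resno)
  spac <- bond_spacings(resno, labels)
  pos <- matrix(NA_real_, length(resno), 3)
  cur <- anchor
  for (i in seq_along(resno)) {
    cur <- cur + spac[i] * D[i, ]
    pos[i, ] <- cur
  }
  o <- order(resno)
  node_chain(pos[o, , drop = FALSE], resno[o], transform = cad$transform)
}

# Spacing of the bond entering each residue (from resno + 1): helix
# spacing iff both endpoints lie in the same helix segment.
bond_spacings <- function(resno, labels, linker_spacing = 0.38,
                          helix_spacing = 0.15,
                          helix_ranges = list(cc1a1 = c(246, 271),
                                              cc1a2 = c(275, 305),
                                              cc1a3 = c(310, 337))) {
  prev_lab <- cc1_segment_labels(resno + 1, helix_ranges)
  ifelse(labels != "linker" & labels == prev_lab, helix_spacing,
         linker_spacing)
}

#' Default 36-pair constraint site list
#'
#' The site pairs used for the bundled forward-simulated constraint table:
#' inter-subunit CC1:CC1' pairs spanning all three helices and linkers,
#' intra-subunit CC1:CC1 pairs bracketing the helix segments, and
#' CC1:CAD pairs tying CC1alpha1 and the CC1alpha2/alpha3 unit to sites on
#' CC2/CC3 of both subunits. Pair identities follow the measurement sites
#' highlighted in the study of the CC1-CAD resting clamp; efficiencies are
#' forward-simulated from the planted chain rather than measured.
#'
#' @return data.frame with columns `site_a_res`, `site_a_sub`,
#'   `site_b_res`, `site_b_sub`, `pair_class`.
#' @export
default_constraint_sites <- function() {
  inter <- c(239, 242, 246, 254, 261, 268, 274, 278, 285, 291, 298, 305,
             309, 312, 320, 328, 337)
  intra <- list(c(239, 274), c(274, 307), c(307, 337), c(246, 271),
                c(275, 305))
  cad <- list( # cc1 residue, cad residue, cad subunit
    c(242, 400, "B"), c(242, 417, "B"), c(242, 431, "B"), c(242, 431, "A"),
    c(274, 431, "B"), c(274, 431, "A"), c(337, 363, "A"), c(298, 363, "A"),
    c(337, 345, "A"), c(312, 345, "A"), c(309, 345, "B"), c(261, 417, "B"),
    c(254, 431, "B"), c(268, 400, "B"))
  rbind(
    data.frame(site_a_res = inter, site_a_sub = "A", site_b_res = inter,
               site_b_sub = "B", pair_class = "cc1_cc1"),
    do.call(rbind, lapply(intra, function(p) {
      data.frame(site_a_res = p[1], site_a_sub = "A", site_b_res = p[2],
                 site_b_sub = "A", pair_class = "cc1_cc1")
    })),
    do.call(rbind, lapply(cad, function(p) {
      data.frame(site_a_res = as.integer(p[1]), site_a_sub = "A",
                 site_b_res = as.integer(p[2]), site_b_sub = p[3],
                 pair_class = "cc1_cad")
    }))
  )
}

#' Forward-simulate a constraint table from a planted chain
#'
#' For each listed site pair the true model distance is computed (node to
#' node for `cc1_cc1`, node to effective dye center for `cc1_cad`),
#' converted to a peak efficiency through the inverse Forster relation,
#' optionally jittered uniformly by `epsilon` in E, and assembled into a
#' [constraint_table()] with bounds set.
#'
#' @param chain A `node_chain` (e.g. [make_planted_chain()]).
#' @param cad A CAD model with effective centers for all `cc1_cad` sites.
#' @param sites Site list (default [default_constraint_sites()]).
#' @param forster A [forster_config()].
#' @param epsilon Half-width of uniform jitter added to E (0 = exact).
#' @param seed Seed for the jitter.
#' @return A `constraint_table`.
#' @export
make_planted_constraints <- function(chain, cad,
                                     sites = default_constraint_sites(),
                                     forster = forster_config(),
                                     epsilon = 0, seed = 1L) {
  d <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    pa <- node_xyz(chain, s$site_a_res, s$site_a_sub)
    pb <- if (s$pair_class == "cc1_cad") {
      eff_center(cad, s$site_b_res, s$site_b_sub)
    } else {
      node_xyz(chain, s$site_b_res, s$site_b_sub)
    }
    sqrt(sum((pa - pb)^2))
  }, 1)
  E <- distance_to_fret(d, forster)
  if (epsilon > 0) {
    set.seed(seed)
    E <- E + runif(length(E), -epsilon, epsilon)
  }
  E <- pmin(pmax(E, 1e-3), 1 - 1e-3)
  constraint_table(sites$site_a_res, sites$site_a_sub, sites$site_b_res,
                   sites$site_b_sub, sites$pair_class, E,
                   forster = forster)
}
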