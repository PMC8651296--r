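#' Forster configuration
#'
#' Holds the Forster radius \eqn{R_0}, the inter-fluorophore distance at
#' which FRET efficiency is 0.5. The default 5.1 nm is the theoretical
#' value for the Alexa Fluor 555/647 pair in water under the assumption of
#' fast isotropic dye re-orientation.
#'
#' @param R0 Forster radius in nm (> 0).
#' @return An object of class `forster_config`.
#' @export
forster_config <- function(R0 = 5.1) {
  stopifnot(is.numeric(R0), length(R0) == 1, is.finite(R0), R0 > 0)
  structure(list(R0 = R0), class = "forster_config")
}

#' Convert FRET efficiency to inter-dye distance
#'
#' Applies the Forster relation \eqn{R = R_0 (1/E - 1)^{1/6}}. Only defined
#' on the open interval \eqn{0 < E < 1}; measured peak efficiencies at the
#' extremes should be clipped into (0, 1) by the caller before conversion.
#'
#' @param E FRET efficiency (vectorized), each value in (0, 1).
#' @param forster A [forster_config()].
#' @return Distance(s) in nm.
#' @seealso [distance_to_fret()] for the inverse.
#' @export
fret_to_distance <- function(E, forster = forster_config()) {
  stopifnot(inherits(forster, "forster_config"), is.numeric(E))
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("fret_to_distance() requires 0 < E < 1; clip measured peaks into ",
         "(0, 1) (e.g. [1e-3, 1 - 1e-3]) before converting.")
  }
  forster$R0 * (1 / E - 1)^(1 / 6)
}

#' Convert inter-dye distance to FRET efficiency
#'
#' Inverse of [fret_to_distance()]: \eqn{E = 1 / (1 + (R/R_0)^6)}.
#'
#' @param R Distance(s) in nm, > 0.
#' @param forster A [forster_config()].
#' @return FRET efficiency in (0, 1).
#' @export
distance_to_fret <- function(R, forster = forster_config()) {
  stopifnot(inherits(forster, "forster_config"), is.numeric(R))
  if (any(!is.finite(R)) || any(R <= 0)) stop("distances must be positive and finite")
  1 / (1 + (R / forster$R0)^6)
}

#' Build a distance-constraint table from measured FRET peaks
#'
#' Each row pairs two labeled sites with the peak efficiency of its smFRET
#' histogram. `pair_class` records where the two dyes sit, which determines
#' how the model distance is measured and how the acceptance bounds are
#' offset (see [constraint_bounds()]):
#' \describe{
#'   \item{cc1_cad}{one site on a CC1 node, one on a dye simulated on the
#'     core structure; distance is node to effective dye center.}
#'   \item{cc1_cc1}{both sites on CC1 nodes (same or opposite subunit);
#'     distance is node to node.}
#'   \item{cad_cad_inter, intra_subunit}{both sites carry simulated dyes on
#'     the core structure; distance is effective center to effective
#'     center.}
#' }
#'
#' @param site_a_res,site_b_res Residue numbers.
#' @param site_a_sub,site_b_sub Subunit labels, "A" or "B".
#' @param pair_class Character, one of the classes above.
#' @param E_peak Measured peak FRET efficiency in (0, 1).
#' @param E_uncertainty Peak uncertainty in E units; defaults to 0.05, the
#'   bin width of the smFRET histograms.
#' @param forster A [forster_config()] used to fill `D_FRET`.
#' @return A `data.frame` of class `constraint_table` with columns
#'   `site_a_res`, `site_a_sub`, `site_b_res`, `site_b_sub`, `pair_class`,
#'   `E_peak`, `E_uncertainty`, `D_FRET`, `lb`, `ub`, `n_relaxations`.
#' @export
constraint_table <- function(site_a_res, site_a_sub, site_b_res, site_b_sub,
                             pair_class, E_peak, E_uncertainty = 0.05,
                             forster = forster_config()) {
  classes <- c("cc1_cad", "cc1_cc1", "cad_cad_inter", "intra_subunit")
  if (!all(pair_class %in% classes)) {
    stop("unknown pair_class: ", paste(setdiff(pair_class, classes), collapse = ", "))
  }
  stopifnot(all(site_a_sub %in% c("A", "B")), all(site_b_sub %in% c("A", "B")),
            all(E_peak > 0 & E_peak < 1))
  tab <- data.frame(
    site_a_res = as.integer(site_a_res), site_a_sub = site_a_sub,
    site_b_res = as.integer(site_b_res), site_b_sub = site_b_sub,
    pair_class = pair_class, E_peak = E_peak,
    E_uncertainty = rep_len(E_uncertainty, length(E_peak)),
    stringsAsFactors = FALSE
  )
  tab$D_FRET <- fret_to_distance(tab$E_peak, forster)
  tab$lb <- NA_real_
  tab$ub <- NA_real_
  tab$n_relaxations <- 0L
  class(tab) <- c("constraint_table", "data.frame")
  constraint_bounds(tab, forster)
}

#' Set acceptance distance bounds on a constraint table
#'
#' The peak efficiency is first broadened by `E_uncertainty` on both sides
#' and converted to distance. The lower bound is additionally offset
#' downward by 1 nm for `cc1_cad` pairs (the CC1-side dye may point away
#' from the core-side dye) or 2 nm for `cc1_cc1` pairs (both dyes may point
#' away from each other); the tether-free classes get no offset. The upper
#' bound is the distance at `E_peak - E_uncertainty`; bounds are floored at
#' zero. `n_relaxations` counts later 1-nm upper-bound relaxations and is
#' reset here.
#'
#' @param constraints A `constraint_table`.
#' @param forster A [forster_config()].
#' @param eps Clipping margin keeping broadened efficiencies inside (0, 1).
#' @return The table with `lb`/`ub` filled and `n_relaxations` zeroed.
#' @export
constraint_bounds <- function(constraints, forster = forster_config(),
                              eps = 1e-4) {
  stopifnot(inherits(constraints, "constraint_table"))
  offs <- c(cc1_cad = 1, cc1_cc1 = 2, cad_cad_inter = 0, intra_subunit = 0)
  off <- unname(offs[constraints$pair_class])
  if (any(is.na(off))) stop("unknown pair_class in constraint table")
  e_hi <- pmin(constraints$E_peak + constraints$E_uncertainty, 1 - eps)
  e_lo <- pmax(constraints$E_peak - constraints$E_uncertainty, eps)
  constraints$lb <- pmax(fret_to_distance(e_hi, forster) - off, 0)
  constraints$ub <- fret_to_distance(e_lo, forster)
  constraints$n_relaxations <- 0L
  constraints
}

#' Read / write a constraint table as TSV
#'
#' The on-disk dialect carries the measured columns (`site_a_res`,
#' `site_a_sub`, `site_b_res`, `site_b_sub`, `pair_class`, `E_peak`, and
#' optionally `E_uncertainty`); derived columns are recomputed on read.
#'
#' @param path File path.
#' @param forster A [forster_config()] used to recompute `D_FRET` and bounds.
#' @return `read_constraints()` returns a `constraint_table`.
#' @export
read_constraints <- function(path, forster = forster_config()) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  eu <- if ("E_uncertainty" %in% names(raw)) raw$E_uncertainty else 0.05
  constraint_table(raw$site_a_res, raw$site_a_sub, raw$site_b_res,
                   raw$site_b_sub, raw$pair_class, raw$E_peak,
                   E_uncertainty = eu, forster = forster)
}

#' @rdname read_constraints
#' @param constraints A `constraint_table` to write.
#' @export
write_constraints <- function(constraints, path) {
  keep <- c("site_a_res", "site_a_sub", "site_b_res", "site_b_sub",
            "pair_class", "E_peak", "E_uncertainty")
  write.table(as.data.frame(constraints)[, keep], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
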