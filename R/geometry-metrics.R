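.coords_of <- function(g, labels) {
  stopifnot(inherits(g, "molecule_geometry"))
  unknown <- setdiff(labels, g$labels)
  if (length(unknown) > 0) {
    stop("unknown atom label(s): ", paste(unknown, collapse = ", "))
  }
  g$coords[labels, , drop = FALSE]
}

.vnorm <- function(v) sqrt(sum(v^2))

#' Bond length
#'
#' Euclidean distance between two labeled atoms, angstroms.
#'
#' @param g A \code{molecule_geometry}.
#' @param a,b Atom labels.
#' @return Distance in angstroms.
#' @export
bond_length <- function(g, a, b) {
  p <- .coords_of(g, c(a, b))
  .vnorm(p[2, ] - p[1, ])
}

#' Bond angle
#'
#' Angle a-b-c at the central atom b, degrees in [0, 180].
#'
#' @param g A \code{molecule_geometry}.
#' @param a,b,c Atom labels, b central.
#' @return Angle in degrees.
#' @export
bond_angle <- function(g, a, b, c) {
  p <- .coords_of(g, c(a, b, c))
  v1 <- p[1, ] - p[2, ]
  v2 <- p[3, ] - p[2, ]
  n1 <- .vnorm(v1); n2 <- .vnorm(v2)
  if (n1 < 1e-12 || n2 < 1e-12) stop("coincident atoms give no angle")
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Dihedral angle
#'
#' Torsion a-b-c-d about the b-c axis, signed, degrees in (-180, 180].
#'
#' @param g A \code{molecule_geometry}.
#' @param a,b,c,d Atom labels.
#' @return Dihedral in degrees.
#' @export
dihedral <- function(g, a, b, c, d) {
  p <- .coords_of(g, c(a, b, c, d))
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("collinear atoms: dihedral undefined")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / .vnorm(b2)
  atan2(y, x) * 180 / pi
}

# least-squares plane through a label set: returns unit normal + centroid
.fit_plane <- function(g, labels) {
  if (length(labels) < 3) stop("a plane needs at least 3 atoms")
  p <- .coords_of(g, labels)
  ctr <- colMeans(p)
  x <- sweep(p, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("atoms are collinear: plane undefined")
  }
  list(normal = sv$v[, 3], centroid = ctr, singular = sv$d, centered = x)
}

#' Mean-plane r.m.s. deviation
#'
#' Root-mean-square perpendicular distance of a set of atoms from their
#' least-squares best-fit plane (the plane orthogonal to the smallest
#' principal component of the centered coordinates). Zero iff the set is
#' exactly coplanar. This is the planarity statistic crystallographers quote
#' for fused-ring systems.
#'
#' @param g A \code{molecule_geometry}.
#' @param labels At least 3 non-collinear atom labels.
#' @return r.m.s. deviation in angstroms.
#' @export
mean_plane_rmsd <- function(g, labels) {
  pl <- .fit_plane(g, labels)
  dist <- pl$centered %*% pl$normal
  sqrt(mean(dist^2))
}

#' Angle between two best-fit planes
#'
#' Acute angle between the least-squares plane normals of two label sets,
#' degrees in [0, 90] (crystallographic convention).
#'
#' @param g A \code{molecule_geometry}.
#' @param labels_1,labels_2 Label sets, each defining a plane.
#' @return Angle in degrees.
#' @export
plane_plane_angle <- function(g, labels_1, labels_2) {
  n1 <- .fit_plane(g, labels_1)$normal
  n2 <- .fit_plane(g, labels_2)$normal
  cosang <- abs(sum(n1 * n2))
  acos(pmin(1, cosang)) * 180 / pi
}

#' Hydrogen-bond geometry
#'
#' The three distances and the donor-H...acceptor angle of a D-H...A contact.
#'
#' @param g A \code{molecule_geometry}.
#' @param donor,h,acceptor Atom labels.
#' @return Named list: \code{d_dh}, \code{d_ha}, \code{d_da} (angstroms) and
#'   \code{angle_dha} (degrees at the H atom).
#' @export
hbond_geometry <- function(g, donor, h, acceptor) {
  list(
    d_dh = bond_length(g, donor, h),
    d_ha = bond_length(g, h, acceptor),
    d_da = bond_length(g, donor, acceptor),
    angle_dha = bond_angle(g, donor, h, acceptor)
  )
}

#' Compare two geometries over named internal coordinates
#'
#' Absolute and percent deviations of bond lengths and bond angles between a
#' reference structure (e.g. crystal) and a test structure (e.g. optimized).
#' Internal coordinates only: no superposition is performed, so the result is
#' invariant under independent rigid motions of either structure. Percent
#' deviations use the reference value as denominator.
#'
#' @param g_ref,g_test \code{molecule_geometry} objects.
#' @param bonds List of label pairs (each \code{c(a, b)}), or a 2-column
#'   matrix/data.frame of labels, referring to \code{g_ref}.
#' @param angles List of label triples (each \code{c(a, b, c)}), or a
#'   3-column matrix/data.frame. Optional.
#' @param mapping Named character vector mapping reference labels to test
#'   labels; default identity (same labels in both structures).
#' @return An object of class \code{geometry_comparison}: data.frames
#'   \code{bond_deviations} and \code{angle_deviations} plus
#'   \code{max_bond_dev} (angstrom) and \code{max_angle_dev} (degrees).
#' @export
compare_geometries <- function(g_ref, g_test, bonds, angles = list(),
                               mapping = NULL) {
  as_rows <- function(x, k) {
    if (is.data.frame(x) || is.matrix(x)) {
      x <- as.matrix(x)
      lapply(seq_len(nrow(x)), function(i) as.character(x[i, seq_len(k)]))
    } else {
      lapply(x, as.character)
    }
  }
  bonds <- as_rows(bonds, 2)
  angles <- as_rows(angles, 3)
  map_lab <- function(lab) {
    if (is.null(mapping)) return(lab)
    out <- unname(mapping[lab])
    if (any(is.na(out))) {
      stop("mapping does not cover label(s): ",
           paste(lab[is.na(out)], collapse = ", "))
    }
    out
  }
  bd <- do.call(rbind, lapply(bonds, function(pr) {
    r <- bond_length(g_ref, pr[1], pr[2])
    t <- bond_length(g_test, map_lab(pr[1]), map_lab(pr[2]))
    data.frame(pair = paste(pr, collapse = "-"), ref = r, test = t,
               dev = abs(t - r), dev_pct = 100 * abs(t - r) / r,
               stringsAsFactors = FALSE)
  }))
  ad <- if (length(angles) > 0) {
    do.call(rbind, lapply(angles, function(tr) {
      r <- bond_angle(g_ref, tr[1], tr[2], tr[3])
      t <- bond_angle(g_test, map_lab(tr[1]), map_lab(tr[2]), map_lab(tr[3]))
      data.frame(triple = paste(tr, collapse = "-"), ref = r, test = t,
                 dev = abs(t - r), dev_pct = 100 * abs(t - r) / r,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(triple = character(0), ref = numeric(0), test = numeric(0),
               dev = numeric(0), dev_pct = numeric(0))
  }
  structure(
    list(bond_deviations = bd, angle_deviations = ad,
         max_bond_dev = if (nrow(bd) > 0) max(bd$dev) else NA_real_,
         max_angle_dev = if (nrow(ad) > 0) max(ad$dev) else NA_real_),
    class = "geometry_comparison"
  )
}

#' @export
print.geometry_comparison <- function(x, ...) {
  cat("<geometry_comparison> ", nrow(x$bond_deviations), " bond(s), ",
      nrow(x$angle_deviations), " angle(s); max |dr| = ",
      format(x$max_bond_dev, digits = 3), " A, max |dtheta| = ",
      format(x$max_angle_dev, digits = 3), " deg\n", sep = "")
  invisible(x)
}
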