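#' Coordinate sets with repeat annotation
#'
#' A `coordinate_set` holds atom records (chain, residue number, atom name,
#' x/y/z in angstrom) together with an ordered, non-overlapping annotation of
#' repeat units as residue ranges. `read_structure` ingests a PDB-format file
#' through `bio3d`; insertion codes are rejected because residue ranges would
#' become ambiguous.
#'
#' @param atom Data frame with columns `chain`, `resno`, `elety`, `resid`,
#'   `x`, `y`, `z`.
#' @param repeats Data frame with columns `start`, `end` (residue numbers)
#'   and optionally `chain`.
#' @return An object of class `coordinate_set`.
#' @export
coordinate_set <- function(atom, repeats) {
  need <- c("chain", "resno", "elety", "resid", "x", "y", "z")
  stopifnot(all(need %in% names(atom)))
  repeats <- as.data.frame(repeats)
  stopifnot(all(c("start", "end") %in% names(repeats)))
  if (is.null(repeats$chain)) repeats$chain <- atom$chain[1L]
  if (nrow(repeats) < 1L) stop("at least one repeat range is required")
  if (any(repeats$end < repeats$start)) stop("repeat range with end < start")
  o <- order(repeats$start)
  repeats <- repeats[o, , drop = FALSE]
  if (nrow(repeats) > 1L &&
      any(repeats$start[-1L] <= repeats$end[-nrow(repeats)])) {
    stop("repeat annotation has overlapping ranges")
  }
  rownames(repeats) <- NULL
  structure(list(atom = atom, repeats = repeats), class = "coordinate_set")
}

#' @rdname coordinate_set
#' @param path PDB-format file path.
#' @param repeat_spec Repeat annotation: either a data frame of residue
#'   ranges (`start`, `end`, optional `chain`) or a list
#'   `list(first_residue, repeat_length, n_repeats, chain)` describing
#'   regularly spaced repeats (default repeat length 35 residues).
#' @param chain Chain identifier to read (default: first chain in the file).
#' @export
read_structure <- function(path, repeat_spec, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(a$insert) & a$insert != "")) {
    stop("insertion codes present; renumber the structure first")
  }
  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms on chain ", chain)
  if (is.list(repeat_spec) && !is.data.frame(repeat_spec)) {
    rl <- repeat_spec$repeat_length %||% 35L
    repeats <- data.frame(
      start = repeat_spec$first_residue + (seq_len(repeat_spec$n_repeats) - 1L) * rl,
      end = repeat_spec$first_residue + seq_len(repeat_spec$n_repeats) * rl - 1L,
      chain = chain
    )
  } else {
    repeats <- as.data.frame(repeat_spec)
    if (is.null(repeats$chain)) repeats$chain <- chain
  }
  for (i in seq_len(nrow(repeats))) {
    hit <- a$resno >= repeats$start[i] & a$resno <= repeats$end[i]
    if (!any(hit)) {
      stop(sprintf("repeat range %d-%d has no atoms on chain %s",
                   repeats$start[i], repeats$end[i], chain))
    }
  }
  coordinate_set(
    data.frame(chain = a$chain, resno = a$resno, elety = a$elety,
               resid = a$resid, x = a$x, y = a$y, z = a$z),
    repeats
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-repeat reference points: centroid of CA atoms when present, else of all
# atoms in the annotated range.
repeat_centroids <- function(coords) {
  a <- coords$atom
  reps <- coords$repeats
  use_ca <- any(a$elety == "CA")
  cent <- t(vapply(seq_len(nrow(reps)), function(i) {
    sel <- a$resno >= reps$start[i] & a$resno <= reps$end[i]
    if (use_ca && any(a$elety[sel] == "CA")) sel <- sel & a$elety == "CA"
    colMeans(as.matrix(a[sel, c("x", "y", "z")]))
  }, numeric(3L)))
  cent
}

#' Fit superhelical parameters of an alpha-solenoid
#'
#' Estimates radius, rise and twist of the superhelix traced by the
#' per-repeat reference points (CA centroids of the annotated repeats). The
#' helical axis direction is first obtained from cross products of second
#' differences of consecutive centroids (which lie in the plane normal to the
#' axis for a regular helix) and then refined by least squares; the axis
#' position is the least-squares circle center of the centroids projected
#' onto the normal plane. Twist is the mean angular increment between
#' consecutive centroids about the axis (right-handed, axis oriented from
#' repeat 1 to repeat N), rise the mean axial increment, and the derived
#' quantities follow `pitch = rise * 360 / twist` and
#' `repeats_per_turn = 360 / twist`.
#'
#' @param coords A `coordinate_set` with >= 4 annotated repeats.
#' @param refine Refine the axis direction/center numerically (default TRUE).
#' @return An object of class `solenoid_parameters`: list with `radius`,
#'   `rise`, `twist`, `pitch`, `repeats_per_turn`, `axis` (unit vector),
#'   `axis_point`, and `rms_radius` (spread of centroid radii).
#' @export
fit_superhelix <- function(coords, refine = TRUE) {
  cent <- if (inherits(coords, "coordinate_set")) repeat_centroids(coords)
          else as.matrix(coords)
  n <- nrow(cent)
  if (n < 4L) stop("superhelix fitting needs at least 4 repeat centroids")
  v <- diff(cent)                 # chord vectors
  w <- diff(v)                    # second differences, normal-plane vectors
  crosses <- vapply(seq_len(nrow(w) - 1L), function(i) {
    cross3(w[i, ], w[i + 1L, ])
  }, numeric(3L))
  norms <- sqrt(colSums(crosses^2))
  scale0 <- mean(sqrt(rowSums(w^2)))^2
  if (all(norms < 1e-9 * max(scale0, 1))) {
    stop("degenerate geometry: repeat centroids are collinear or coplanar")
  }
  u <- rowSums(sweep(crosses, 2L,
                     sign(colSums(crosses * crosses[, which.max(norms)])),
                     "*"))
  u <- u / sqrt(sum(u^2))
  # orient axis from first toward last repeat
  if (sum((cent[n, ] - cent[1L, ]) * u) < 0) u <- -u

  if (refine) {
    ang <- c(acos(u[3L]), atan2(u[2L], u[1L]))
    obj <- function(p) {
      ui <- c(sin(p[1L]) * cos(p[2L]), sin(p[1L]) * sin(p[2L]), cos(p[1L]))
      helix_residual(cent, ui)
    }
    fit <- optim(ang, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    u <- c(sin(fit$par[1L]) * cos(fit$par[2L]),
           sin(fit$par[1L]) * sin(fit$par[2L]), cos(fit$par[1L]))
    if (sum((cent[n, ] - cent[1L, ]) * u) < 0) u <- -u
  }

  geo <- helix_geometry(cent, u)
  if (geo$radius < 1e-6 * max(1, mean(abs(cent)))) {
    stop("degenerate geometry: zero superhelical radius")
  }
  twist <- geo$twist_deg
  structure(
    list(radius = geo$radius, rise = geo$rise, twist = twist,
         pitch = geo$rise * 360 / twist, repeats_per_turn = 360 / twist,
         axis = u, axis_point = geo$center3, rms_radius = geo$rms_radius),
    class = "solenoid_parameters"
  )
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# In-plane circle fit + axial statistics for a trial axis direction.
helix_geometry <- function(cent, u) {
  # orthonormal basis (e1, e2, u), right-handed
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  p1 <- cent %*% e1
  p2 <- cent %*% e2
  z <- cent %*% u
  # Kasa algebraic circle fit: minimize ||x||^2 - 2 c.x - r0 linear LS
  A <- cbind(2 * p1, 2 * p2, 1)
  b <- p1^2 + p2^2
  sol <- qr.solve(A, b)
  cx <- sol[1L]; cy <- sol[2L]
  r <- sqrt((p1 - cx)^2 + (p2 - cy)^2)
  phi <- atan2(p2 - cy, p1 - cx)
  dphi <- diff(phi)
  dphi <- (dphi + pi) %% (2 * pi) - pi   # unwrap to (-pi, pi]
  list(radius = mean(r),
       rms_radius = sd(r),
       rise = mean(diff(z)),
       twist_deg = mean(dphi) * 180 / pi,
       center3 = as.numeric(cx * e1 + cy * e2))
}

helix_residual <- function(cent, u) {
  g <- helix_geometry(cent, u)
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  p1 <- cent %*% e1 - sum(g$center3 * e1)
  p2 <- cent %*% e2 - sum(g$center3 * e2)
  r <- sqrt(p1^2 + p2^2)
  sum((r - mean(r))^2) + sum((diff(cent %*% u) - g$rise)^2)
}

# Least-squares rigid superposition (Kabsch): returns rotation R and
# translation t with  moving %*% t(R) + t  ~  fixed.
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), ncol(moving) == 3L)
  mc <- colMeans(moving)
  fc <- colMeans(fixed)
  H <- t(sweep(moving, 2L, mc)) %*% sweep(fixed, 2L, fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- fc - as.numeric(R %*% mc)
  list(R = R, t = t,
       rmsd = sqrt(mean(rowSums(
         (sweep(moving, 2L, mc) %*% t(R) - sweep(fixed, 2L, fc))^2))))
}

apply_rigid <- function(x, R, t) sweep(x %*% t(R), 2L, t, "+")

#' Screw decomposition of a rigid transform
#'
#' Represents the rigid motion `x -> R x + t` as a rotation by
#' `rotation_angle` degrees about an axis (unit vector `screw_axis` through
#' `axis_point`) plus a translation `axial_translation` along that axis.
#'
#' @param R 3x3 rotation matrix.
#' @param t Length-3 translation vector.
#' @return List with `rotation_angle` (degrees, in `[0, 180]`), `screw_axis`,
#'   `axial_translation` (angstrom) and `axis_point`.
#' @export
screw_decompose <- function(R, t) {
  tr <- sum(diag(R))
  cos_th <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cos_th)
  if (theta < 1e-9) {
    nt <- sqrt(sum(t^2))
    axis <- if (nt > 0) t / nt else c(0, 0, 1)
    return(list(rotation_angle = 0, screw_axis = axis,
                axial_translation = nt, axis_point = c(0, 0, 0)))
  }
  if (abs(theta - pi) < 1e-6) {
    # axis from the symmetric part: R + I has rank 1 with columns || axis
    M <- R + diag(3L)
    axis <- M[, which.max(colSums(M^2))]
  } else {
    axis <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L],
              R[2L, 1L] - R[1L, 2L]) / (2 * sin(theta))
  }
  axis <- axis / sqrt(sum(axis^2))
  d <- sum(t * axis)
  # point on axis: solve (I - R) p = t_perp
  t_perp <- t - d * axis
  A <- diag(3L) - R
  p <- tryCatch(qr.solve(A + tcrossprod(axis), t_perp),
                error = function(e) rep(NA_real_, 3L))
  list(rotation_angle = theta * 180 / pi, screw_axis = axis,
       axial_translation = d, axis_point = as.numeric(p))
}

#' Reconstruct a rigid transform from its screw parameters
#'
#' Inverse of [screw_decompose]; used to verify that the decomposition
#' composes back to the original motion.
#'
#' @param screw List as returned by [screw_decompose].
#' @return List with `R` and `t`.
#' @export
screw_compose <- function(screw) {
  u <- screw$screw_axis
  th <- screw$rotation_angle * pi / 180
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  p <- screw$axis_point
  if (any(is.na(p))) p <- c(0, 0, 0)
  t <- p - as.numeric(R %*% p) + screw$axial_translation * u
  list(R = R, t = t)
}

#' Inter-repeat rigid-body (hinge) transforms between two conformations
#'
#' For each adjacent repeat pair (i, i+1): repeat i of conformation A is
#' least-squares superposed onto repeat i of conformation B; the residual
#' rigid transform carrying the superposed repeat i+1 of A onto repeat i+1 of
#' B is then extracted as a screw (hinge rotation angle, screw axis, axial
#' translation). Atom correspondence between A and B is by residue number and
#' atom name within each annotated repeat.
#'
#' @param coords_a,coords_b `coordinate_set` objects with matching repeat
#'   annotations (same number of repeats) and a one-to-one atom
#'   correspondence per repeat.
#' @param atoms Atom names used for superposition (default `"CA"`; `NULL`
#'   uses all matched atoms).
#' @return Data frame with one row per adjacent pair: `pair`,
#'   `rotation_angle` (degrees), `axis_x/y/z`, `axial_translation`,
#'   `superposition_rmsd`, `residual_rmsd`; screw details in attribute
#'   `screws`.
#' @export
inter_repeat_transforms <- function(coords_a, coords_b, atoms = "CA") {
  stopifnot(inherits(coords_a, "coordinate_set"),
            inherits(coords_b, "coordinate_set"))
  ra <- coords_a$repeats
  rb <- coords_b$repeats
  if (nrow(ra) != nrow(rb)) stop("repeat annotations differ in length")
  n <- nrow(ra)
  get_rep <- function(coords, reps, i) {
    a <- coords$atom
    sel <- a$resno >= reps$start[i] & a$resno <= reps$end[i]
    if (!is.null(atoms)) sel <- sel & a$elety %in% atoms
    a[sel, , drop = FALSE]
  }
  match_pair <- function(ai, bi, label) {
    key_a <- paste(ai$resno - min(ai$resno), ai$elety)
    key_b <- paste(bi$resno - min(bi$resno), bi$elety)
    common <- intersect(key_a, key_b)
    un <- c(setdiff(key_a, key_b), setdiff(key_b, key_a))
    if (length(un) > 0) {
      stop("atom correspondence mismatch in ", label, ": ",
           paste(head(un, 10L), collapse = ", "))
    }
    list(a = as.matrix(ai[match(common, key_a), c("x", "y", "z")]),
         b = as.matrix(bi[match(common, key_b), c("x", "y", "z")]))
  }
  out <- vector("list", n - 1L)
  screws <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    mi <- match_pair(get_rep(coords_a, ra, i), get_rep(coords_b, rb, i),
                     sprintf("repeat %d", i))
    mj <- match_pair(get_rep(coords_a, ra, i + 1L),
                     get_rep(coords_b, rb, i + 1L),
                     sprintf("repeat %d", i + 1L))
    fit_i <- kabsch(mi$a, mi$b)
    a_next <- apply_rigid(mj$a, fit_i$R, fit_i$t)
    fit_j <- kabsch(a_next, mj$b)
    sc <- screw_decompose(fit_j$R, fit_j$t)
    screws[[i]] <- sc
    out[[i]] <- data.frame(
      pair = sprintf("%d-%d", i, i + 1L),
      rotation_angle = sc$rotation_angle,
      axis_x = sc$screw_axis[1L], axis_y = sc$screw_axis[2L],
      axis_z = sc$screw_axis[3L],
      axial_translation = sc$axial_translation,
      superposition_rmsd = fit_i$rmsd,
      residual_rmsd = fit_j$rmsd
    )
  }
  res <- do.call(rbind, out)
  attr(res, "screws") <- screws
  res
}

#' Residue-pair distances in two conformations
#'
#' Euclidean distances (angstrom) between named atoms of residue pairs in
#' each of two conformations. Missing atoms yield an NA entry for that pair
#' while the remaining pairs are still computed.
#'
#' @param coords_a,coords_b `coordinate_set` objects.
#' @param pairs Data frame with columns `resno1`, `resno2`.
#' @param atom_name Atom name (default `"CA"`; e.g. `"NZ"` for lysine
#'   side-chain amines).
#' @return Data frame `resno1, resno2, r_a, r_b, note`.
#' @export
pair_distances <- function(coords_a, coords_b, pairs, atom_name = "CA") {
  one <- function(coords, resno) {
    a <- coords$atom
    sel <- a$resno == resno & a$elety == atom_name
    if (sum(sel) != 1L) return(NULL)
    as.numeric(a[sel, c("x", "y", "z")])
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    p1 <- pairs$resno1[i]; p2 <- pairs$resno2[i]
    xa1 <- one(coords_a, p1); xa2 <- one(coords_a, p2)
    xb1 <- one(coords_b, p1); xb2 <- one(coords_b, p2)
    note <- ""
    r_a <- r_b <- NA_real_
    if (is.null(xa1) || is.null(xa2)) note <- "missing atom in A"
    else r_a <- sqrt(sum((xa1 - xa2)^2))
    if (is.null(xb1) || is.null(xb2)) {
      note <- paste0(note, if (nzchar(note)) "; ", "missing atom in B")
    } else r_b <- sqrt(sum((xb1 - xb2)^2))
    data.frame(resno1 = p1, resno2 = p2, r_a = r_a, r_b = r_b, note = note)
  })
  do.call(rbind, res)
}

#' FRET efficiency from inter-dye distance
#'
#' `E = 1 / (1 + (r / R0)^6)` with Forster radius `R0` (54 angstrom for the
#' Cy3/AF647 pair).
#'
#' @param r Inter-dye distance (angstrom, >= 0).
#' @param r0 Forster radius (angstrom, > 0).
#' @return FRET efficiency in `(0, 1]`.
#' @export
predict_fret_from_distance <- function(r, r0 = 54) {
  if (any(r < 0)) stop("distance must be non-negative")
  if (r0 <= 0) stop("Forster radius must be positive")
  1 / (1 + (r / r0)^6)
}

#' Screen residue pairs for FRET-sensitive labeling sites
#'
#' Evaluates, for every residue pair separated by `separation` repeats (same
#' relative position within each repeat), the inter-residue distance in the
#' apo and bound conformations and the corresponding Forster-predicted FRET
#' efficiencies. Pairs whose apo distance exceeds `r0` while their bound
#' distance falls below it (i.e. pairs straddling the Forster radius) are
#' retained and ranked by the magnitude of the FRET change.
#'
#' @param coords_apo,coords_bound `coordinate_set` objects with matching
#'   repeat annotations.
#' @param r0 Forster radius (angstrom).
#' @param separation Repeat separation between the two residues.
#' @param atom_name Atom used for the distance (default `"CA"`).
#' @return Data frame ranked by descending `abs(e_bound - e_apo)` with
#'   columns `resno1, resno2, repeat1, repeat2, offset, r_apo, r_bound,
#'   e_apo, e_bound`.
#' @export
screen_fret_pairs <- function(coords_apo, coords_bound, r0 = 54,
                              separation = 8, atom_name = "CA") {
  ra <- coords_apo$repeats
  rb <- coords_bound$repeats
  if (nrow(ra) != nrow(rb)) stop("repeat annotations differ in length")
  n <- nrow(ra)
  if (separation >= n) return(empty_screen())
  rows <- list()
  a_apo <- coords_apo$atom
  a_bnd <- coords_bound$atom
  for (i in seq_len(n - separation)) {
    j <- i + separation
    len <- min(ra$end[i] - ra$start[i], ra$end[j] - ra$start[j])
    for (off in 0:len) {
      r1 <- ra$start[i] + off
      r2 <- ra$start[j] + off
      xa1 <- atom_xyz(a_apo, r1, atom_name)
      xa2 <- atom_xyz(a_apo, r2, atom_name)
      xb1 <- atom_xyz(a_bnd, rb$start[i] + off, atom_name)
      xb2 <- atom_xyz(a_bnd, rb$start[j] + off, atom_name)
      if (is.null(xa1) || is.null(xa2) || is.null(xb1) || is.null(xb2)) next
      r_apo <- sqrt(sum((xa1 - xa2)^2))
      r_bound <- sqrt(sum((xb1 - xb2)^2))
      if (r_apo > r0 && r_bound < r0) {
        rows[[length(rows) + 1L]] <- data.frame(
          resno1 = r1, resno2 = r2, repeat1 = i, repeat2 = j, offset = off,
          r_apo = r_apo, r_bound = r_bound,
          e_apo = predict_fret_from_distance(r_apo, r0),
          e_bound = predict_fret_from_distance(r_bound, r0)
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_screen())
  res <- do.call(rbind, rows)
  res[order(-abs(res$e_bound - res$e_apo)), , drop = FALSE]
}

atom_xyz <- function(atom, resno, atom_name) {
  sel <- atom$resno == resno & atom$elety == atom_name
  if (sum(sel) != 1L) return(NULL)
  as.numeric(atom[sel, c("x", "y", "z")])
}

empty_screen <- function() {
  data.frame(resno1 = integer(), resno2 = integer(), repeat1 = integer(),
             repeat2 = integer(), offset = integer(), r_apo = numeric(),
             r_bound = numeric(), e_apo = numeric(), e_bound = numeric())
}
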