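#' Generate an ideal alpha-solenoid coordinate set
#'
#' Places one reference point per repeat on a regular superhelix: repeat `k`
#' (0-based) sits at `(radius * cos(k * twist), radius * sin(k * twist),
#' k * rise)` with `twist` in degrees (right-handed about +z). Optionally each
#' repeat is decorated with a small rigid pseudo-atom cloud carried by the
#' same rotation + translation, which makes the per-repeat centroid equal the
#' reference point and gives the inter-repeat transform analysis something to
#' superpose.
#'
#' @param spec A [solenoid_spec].
#' @param atoms_per_repeat 1 for bare reference points, or >= 4 for a
#'   decorated rigid cloud per repeat.
#' @param cloud_size Half-extent of the decoration cloud (angstrom).
#' @return A `coordinate_set` (see [read_structure]).
#' @export
generate_ideal_solenoid <- function(spec, atoms_per_repeat = 1L,
                                    cloud_size = 2) {
  stopifnot(inherits(spec, "solenoid_spec"))
  if (spec$radius <= 0) stop("radius must be positive")
  m <- as.integer(atoms_per_repeat)
  stopifnot(m >= 1L)
  # rigid local cloud, centered on the origin so centroid = reference point
  local <- if (m == 1L) {
    matrix(0, 1L, 3L)
  } else {
    pts <- matrix(c(1, 1, 1, 1, -1, -1, -1, 1, -1, -1, -1, 1),
                  4L, 3L, byrow = TRUE)
    while (nrow(pts) < m) {
      extra <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, -1, 0, 0),
                      4L, 3L, byrow = TRUE)
      pts <- rbind(pts, extra[seq_len(min(4L, m - nrow(pts))), , drop = FALSE])
    }
    pts <- pts[seq_len(m), , drop = FALSE]
    pts <- sweep(pts, 2L, colMeans(pts))
    pts * cloud_size
  }
  theta <- (seq_len(spec$n_repeats) - 1L) * spec$twist * pi / 180
  coords <- do.call(rbind, lapply(seq_len(spec$n_repeats), function(k) {
    th <- theta[k]
    rot <- matrix(c(cos(th), -sin(th), 0,
                    sin(th),  cos(th), 0,
                    0, 0, 1), 3L, 3L, byrow = TRUE)
    center <- c(spec$radius * cos(th), spec$radius * sin(th),
                (k - 1L) * spec$rise)
    sweep(local %*% t(rot), 2L, center, "+")
  }))
  n_atoms <- nrow(coords)
  atom <- data.frame(
    chain = "A",
    resno = rep(seq_len(spec$n_repeats * m)),
    elety = "CA",
    resid = "ALA",
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L]
  )
  repeats <- data.frame(
    start = (seq_len(spec$n_repeats) - 1L) * m + 1L,
    end = seq_len(spec$n_repeats) * m,
    chain = "A"
  )
  coordinate_set(atom, repeats)
}

#' Write a coordinate set as a PDB file
#'
#' Standard ATOM records in angstrom, written through `bio3d`.
#'
#' @param coords A `coordinate_set`.
#' @param file Output PDB path.
#' @export
write_structure <- function(coords, file) {
  stopifnot(inherits(coords, "coordinate_set"))
  a <- coords$atom
  bio3d::write.pdb(
    file = file,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno,
    resid = a$resid,
    chain = a$chain,
    elety = a$elety
  )
  invisible(file)
}
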