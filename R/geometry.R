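#' Construct a 2-D point
#'
#' Points are length-2 numeric vectors `c(x, y)` in 0-based pixel-centre
#' image coordinates (x = column, rightward; y = row, downward).
#'
#' @param x,y finite numeric scalars, in pixels.
#' @return numeric vector `c(x, y)`.
#' @export
point2d <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != 1L || length(y) != 1L ||
      !is.finite(x) || !is.finite(y)) {
    stop("point2d: x and y must be finite numeric scalars")
  }
  c(x = as.numeric(x), y = as.numeric(y))
}

mandatory_roles <- c(
  "femoral_shaft_pair_proximal", "femoral_shaft_pair_distal",
  "femoral_notch_pair",
  "tibial_shaft_pair_proximal", "tibial_shaft_pair_distal",
  "plateau_corner_left", "plateau_corner_right"
)

#' Landmark schema: semantic roles over point indices
#'
#' A schema names which point indices play which anatomical role. Mandatory
#' roles are the femoral shaft pairs (proximal/distal), the femoral notch
#' pair, the tibial shaft pairs (proximal/distal) and the two tibial plateau
#' corners. Pair roles map to two indices, corner roles to one. Indices are
#' 1-based. `curves` optionally lists, per bone, the ordered indices of an
#' open outline polyline (used by point-to-curve distances).
#'
#' @param n_points total number of landmarks.
#' @param roles named list; each element an integer vector of length 1
#'   (corner roles) or 2 (pair roles).
#' @param curves optional named list of integer vectors (ordered outline
#'   indices per bone).
#' @return object of class `landmark_schema`.
#' @export
landmark_schema <- function(n_points, roles, curves = NULL) {
  n_points <- as.integer(n_points)
  stopifnot(n_points >= 1L)
  missing_roles <- setdiff(mandatory_roles, names(roles))
  if (length(missing_roles)) {
    stop("landmark_schema: missing mandatory roles: ",
         paste(missing_roles, collapse = ", "))
  }
  roles <- lapply(roles, as.integer)
  pair_roles <- grep("_pair", names(roles), value = TRUE)
  for (r in names(roles)) {
    idx <- roles[[r]]
    want <- if (r %in% pair_roles) 2L else 1L
    if (length(idx) != want) {
      stop(sprintf("landmark_schema: role '%s' needs %d index(es)", r, want))
    }
    if (any(idx < 1L | idx > n_points)) {
      stop(sprintf("landmark_schema: role '%s' has indices outside 1..%d",
                   r, n_points))
    }
  }
  idx_all <- unlist(roles[mandatory_roles], use.names = FALSE)
  if (anyDuplicated(idx_all)) {
    stop("landmark_schema: mandatory role indices must be unique")
  }
  if (!is.null(curves)) {
    curves <- lapply(curves, as.integer)
    for (cv in curves) {
      if (any(cv < 1L | cv > n_points)) stop("landmark_schema: curve index out of range")
    }
  }
  structure(list(n_points = n_points, roles = roles, curves = curves),
            class = "landmark_schema")
}

#' Ordered landmark set with a role schema
#'
#' @param points n x 2 numeric matrix of (x, y) image coordinates.
#' @param schema a [landmark_schema()].
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(points, schema) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("landmark_set: points must be an n x 2 matrix")
  if (!inherits(schema, "landmark_schema")) stop("landmark_set: schema required")
  if (nrow(points) != schema$n_points) {
    stop(sprintf("landmark_set: %d points but schema declares %d",
                 nrow(points), schema$n_points))
  }
  if (!all(is.finite(points))) stop("landmark_set: non-finite coordinates")
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, schema = schema), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set: %d points, roles: %s>\n", nrow(x$points),
              paste(names(x$schema$roles), collapse = ", ")))
  invisible(x)
}

#' Extract the points of a role
#'
#' @param l a [landmark_set()].
#' @param role role name present in the schema.
#' @return 1 x 2 or 2 x 2 matrix of coordinates.
#' @export
role_points <- function(l, role) {
  idx <- l$schema$roles[[role]]
  if (is.null(idx)) stop(sprintf("role '%s' not present in schema", role))
  l$points[idx, , drop = FALSE]
}

#' Midpoint of a pair of points
#'
#' @param pair 2 x 2 matrix (rows = points) or list of two points.
#' @return numeric `c(x, y)`.
#' @export
midpoint <- function(pair) {
  if (is.list(pair)) pair <- rbind(pair[[1]], pair[[2]])
  m <- colMeans(pair[, 1:2, drop = FALSE])
  c(x = unname(m[1]), y = unname(m[2]))
}

#' Similarity transform (rotation + isotropic scale + translation)
#'
#' Maps a point p to `scale * R(rotation) %*% p + translation`, with
#' `R(theta) = [[cos, -sin], [sin, cos]]`. In the y-down image frame a
#' positive angle appears as a clockwise rotation on screen. No reflection
#' component is representable (scale > 0).
#'
#' @param scale positive scalar.
#' @param rotation radians.
#' @param translation point `c(x, y)`.
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0,
                                 translation = c(0, 0)) {
  stopifnot(is.finite(scale), scale > 0, is.finite(rotation),
            all(is.finite(translation)), length(translation) == 2L)
  structure(list(scale = as.numeric(scale), rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform scale=%.6g rot=%.6g rad t=(%.6g, %.6g)>\n",
              x$scale, x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param t a [similarity_transform()].
#' @param p point `c(x, y)` or n x 2 matrix.
#' @return transformed point(s), same shape as the input.
#' @export
transform_apply <- function(t, p) {
  a <- t$scale * cos(t$rotation)
  b <- t$scale * sin(t$rotation)
  if (is.matrix(p)) {
    out <- cbind(a * p[, 1] - b * p[, 2] + t$translation[1],
                 b * p[, 1] + a * p[, 2] + t$translation[2])
    dimnames(out) <- list(NULL, c("x", "y"))
    return(out)
  }
  c(x = a * p[1] - b * p[2] + t$translation[1],
    y = b * p[1] + a * p[2] + t$translation[2])
}

#' Unique similarity transform mapping one point pair onto another
#'
#' Solves for the (reflection-free) similarity sending `src_a -> dst_a` and
#' `src_b -> dst_b` exactly. Solved in complex form: with points as
#' z = x + iy, the map is z' = A z + c where A = (dst_b - dst_a) /
#' (src_b - src_a).
#'
#' @param src_a,src_b,dst_a,dst_b points `c(x, y)`; the two source points and
#'   the two destination points must each be distinct.
#' @return a [similarity_transform()].
#' @export
transform_between_point_pairs <- function(src_a, src_b, dst_a, dst_b) {
  zs <- complex(real = c(src_a[1], src_b[1]), imaginary = c(src_a[2], src_b[2]))
  zd <- complex(real = c(dst_a[1], dst_b[1]), imaginary = c(dst_a[2], dst_b[2]))
  if (zs[1] == zs[2]) stop("transform_between_point_pairs: coincident source points (degenerate geometry)")
  if (zd[1] == zd[2]) stop("transform_between_point_pairs: coincident destination points (degenerate geometry)")
  A <- (zd[2] - zd[1]) / (zs[2] - zs[1])
  cc <- zd[1] - A * zs[1]
  similarity_transform(scale = Mod(A), rotation = Arg(A),
                       translation = c(Re(cc), Im(cc)))
}

#' Invert a similarity transform
#'
#' @param t a [similarity_transform()].
#' @return the inverse [similarity_transform()].
#' @export
transform_invert <- function(t) {
  A <- complex(modulus = t$scale, argument = t$rotation)
  Ainv <- 1 / A
  cinv <- -Ainv * complex(real = t$translation[1], imaginary = t$translation[2])
  similarity_transform(scale = Mod(Ainv), rotation = Arg(Ainv),
                       translation = c(Re(cinv), Im(cinv)))
}

#' Compose two similarity transforms
#'
#' `transform_apply(transform_compose(t2, t1), p)` equals
#' `transform_apply(t2, transform_apply(t1, p))`.
#'
#' @param t2,t1 similarity transforms (t1 applied first).
#' @return a [similarity_transform()].
#' @export
transform_compose <- function(t2, t1) {
  A1 <- complex(modulus = t1$scale, argument = t1$rotation)
  A2 <- complex(modulus = t2$scale, argument = t2$rotation)
  A <- A2 * A1
  c1 <- complex(real = t1$translation[1], imaginary = t1$translation[2])
  c2 <- complex(real = t2$translation[1], imaginary = t2$translation[2])
  cc <- A2 * c1 + c2
  similarity_transform(scale = Mod(A), rotation = Arg(A),
                       translation = c(Re(cc), Im(cc)))
}
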