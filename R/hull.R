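# Quickhull in 3D and half-space membership tests.
#
# The trace point cloud is triangulated into tetrahedra by a Delaunay
# triangulation whose union is exactly the convex hull of the points, so
# "voxel center inside the tetrahedral mesh" is equivalent to "voxel center
# inside the convex hull". The hull is represented by its facet half-spaces
# A x <= b, which makes the voxel test a single matrix product.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Convex hull of a 3D point cloud (quickhull). Returns list(normals, offsets,
# vertices) with unit outward normals: x inside  <=>  normals %*% x <= offsets.
convex_hull_3d <- function(pts, tol = NULL) {
  pts <- unique(round(as.matrix(pts), 12))
  if (ncol(pts) != 3) stop("points must be n x 3")
  n <- nrow(pts)
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 1e-12)
  if (is.null(tol)) tol <- 1e-9 * scale

  if (n < 4) stop("need at least 4 non-coplanar points to form a volume", call. = FALSE)

  # initial simplex: two extremes, farthest from their line, farthest from plane
  ext_ax <- which.max(apply(pts, 2, function(v) diff(range(v))))
  i1 <- which.min(pts[, ext_ax]); i2 <- which.max(pts[, ext_ax])
  d12 <- pts[i2, ] - pts[i1, ]
  if (sqrt(sum(d12^2)) < tol) stop("degenerate point cloud (all points coincide)", call. = FALSE)
  rel <- sweep(pts, 2, pts[i1, ])
  crossm <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
                  rel[, 3] * d12[1] - rel[, 1] * d12[3],
                  rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dline <- sqrt(rowSums(crossm^2)) / sqrt(sum(d12^2))
  i3 <- which.max(dline)
  if (dline[i3] < tol) stop("degenerate point cloud (collinear points)", call. = FALSE)
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- abs(rel %*% nrm)
  i4 <- which.max(dplane)
  if (dplane[i4] < tol) {
    stop("degenerate trace: all points are coplanar (zero enclosed volume)", call. = FALSE)
  }
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  mk_face <- function(a, b, c) {
    nv <- cross3(pts[b, ] - pts[a, ], pts[c, ] - pts[a, ])
    ln <- sqrt(sum(nv^2))
    if (ln < 1e-300) return(NULL)
    nv <- nv / ln
    off <- sum(nv * pts[a, ])
    if (sum(nv * interior) > off) { nv <- -nv; off <- -off }
    list(v = c(a, b, c), n = nv, o = off)
  }
  faces <- list(mk_face(i1, i2, i3), mk_face(i1, i2, i4),
                mk_face(i1, i3, i4), mk_face(i2, i3, i4))

  # assign outside points to faces
  above <- function(face, idx) {
    if (length(idx) == 0) return(integer(0))
    s <- pts[idx, , drop = FALSE] %*% face$n - face$o
    idx[s > tol]
  }
  all_idx <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  outside <- lapply(faces, above, idx = all_idx)

  repeat {
    pending <- which(lengths(outside) > 0)
    if (length(pending) == 0) break
    fi <- pending[1]
    face <- faces[[fi]]
    cand <- outside[[fi]]
    s <- pts[cand, , drop = FALSE] %*% face$n - face$o
    p <- cand[which.max(s)]

    vis <- vapply(faces, function(f) sum(f$n * pts[p, ]) - f$o > tol, logical(1))
    # horizon: edges of visible faces shared with exactly one visible face
    edges <- do.call(rbind, lapply(which(vis), function(i) {
      v <- faces[[i]]$v
      rbind(sort(c(v[1], v[2])), sort(c(v[1], v[3])), sort(c(v[2], v[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]

    pool <- unique(unlist(outside[vis]))
    pool <- setdiff(pool, p)
    faces <- faces[!vis]
    outside <- outside[!vis]
    for (e in seq_len(nrow(horizon))) {
      nf <- mk_face(horizon[e, 1], horizon[e, 2], p)
      if (is.null(nf)) next
      faces[[length(faces) + 1L]] <- nf
      outside[[length(outside) + 1L]] <- above(nf, pool)
    }
  }

  normals <- do.call(rbind, lapply(faces, `[[`, "n"))
  offsets <- vapply(faces, `[[`, numeric(1), "o")
  list(normals = normals, offsets = offsets,
       vertices = sort(unique(unlist(lapply(faces, `[[`, "v")))),
       points = pts, tol = tol)
}

# Membership test: rows of `x` inside the hull (boundary counts as inside;
# ties broken toward inclusion via the hull tolerance).
in_convex_hull <- function(x, hull) {
  x <- as.matrix(x)
  s <- hull$normals %*% t(x) - hull$offsets
  colSums(s > hull$tol) == 0
}
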