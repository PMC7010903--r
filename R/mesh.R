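# Triangle-mesh handling: ASCII OBJ/PLY I/O, watertightness validation,
# divergence-theorem volumes, area-weighted surface sampling and ray-casting
# point containment. Meshes represent one closed compartment surface each
# (cytoplasm = outer cell surface, nucleus, Golgi), vertices in micrometres.

#' Read / write triangle meshes
#'
#' Minimal ASCII OBJ and PLY readers and writers. Polygonal OBJ faces are
#' fan-triangulated. Returns a `tri_mesh` (list with `vertices` n x 3 and
#' `faces` m x 3 of vertex indices).
#'
#' @param path file path; format chosen by extension (`.obj` / `.ply`).
#' @return a `tri_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext, obj = .read_obj(path), ply = .read_ply(path),
              stopf("unsupported mesh format '.%s' (use OBJ or PLY)", ext))
  structure(m, class = "tri_mesh")
}

.read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) stopf("no vertices/faces in OBJ '%s'", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  faces <- list()
  for (f in strsplit(trimws(fl), "\\s+")) {
    idx <- as.integer(vapply(strsplit(f[-1], "/"), `[`, "", 1))
    for (k in seq_len(length(idx) - 2))            # fan triangulation
      faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

.read_ply <- function(path) {
  ln <- readLines(path)
  if (!grepl("^ply", ln[1])) stopf("not a PLY file: %s", path)
  if (!any(grepl("format ascii", ln))) stopf("only ASCII PLY supported")
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       grep("element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       grep("element face", ln, value = TRUE)[1]))
  hdr <- which(ln == "end_header")[1]
  v <- do.call(rbind, lapply(strsplit(trimws(ln[hdr + seq_len(nv)]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- list()
  for (x in strsplit(trimws(ln[hdr + nv + seq_len(nf)]), "\\s+")) {
    n <- as.integer(x[1]); idx <- as.integer(x[1 + seq_len(n)]) + 1L
    for (k in seq_len(n - 2))
      faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

#' @rdname read_mesh
#' @param mesh a `tri_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else stopf("unsupported mesh format '.%s'", ext)
  invisible(path)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d triangles, volume %.4g um^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Mesh validity and measures
#'
#' `mesh_is_watertight()` checks that every edge is shared by exactly two
#' faces with opposite orientation (a closed, consistently oriented
#' 2-manifold). `mesh_volume()` is the signed divergence-theorem volume
#' (positive for outward orientation); `mesh_orient()` flips the face
#' orientation if the signed volume is negative. `mesh_areas()` returns the
#' per-triangle areas.
#'
#' @param mesh a `tri_mesh`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  half <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(half[, 1], half[, 2]), pmax(half[, 1], half[, 2]))
  tab <- table(key)
  if (any(tab != 2)) return(FALSE)
  # opposite orientation: each directed edge must appear exactly once
  dkey <- paste(half[, 1], half[, 2])
  !any(duplicated(dkey))
}

#' @rdname mesh_is_watertight
#' @param signed return the signed volume (default takes `abs`)?
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
             a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  if (signed) vol else abs(vol)
}

#' @rdname mesh_is_watertight
#' @export
mesh_orient <- function(mesh) {
  if (mesh_volume(mesh, signed = TRUE) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' @rdname mesh_is_watertight
#' @export
mesh_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Uniform points on a mesh surface
#'
#' Area-weighted triangle choice followed by uniform barycentric sampling.
#'
#' @param mesh a `tri_mesh`.
#' @param n number of points.
#' @param seed optional seed.
#' @return n x 3 matrix.
#' @export
sample_on_mesh <- function(mesh, n, seed = NULL) {
  with_seed(seed, {
    tri <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = mesh_areas(mesh))
    v <- mesh$vertices; f <- mesh$faces[tri, , drop = FALSE]
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
    v[f[, 1], , drop = FALSE] * w1 + v[f[, 2], , drop = FALSE] * w2 +
      v[f[, 3], , drop = FALSE] * w3
  })
}

# Ray-triangle intersections of many rays against all triangles of a mesh.
# origins/dirs: n x 3. Returns list(ray = i, t = distance, sgn = +1 entering /
# -1 exiting) for hits with t > tol. Chunked over rays to bound memory.
.ray_mesh_hits <- function(origins, dirs, mesh, tol = 1e-9) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(origins)
  out_ray <- list(); out_t <- list(); out_s <- list(); kk <- 0L
  chunk <- max(1L, floor(4e6 / nrow(f)))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(n, lo + chunk - 1L)
    o <- origins[lo:hi, , drop = FALSE]; d <- dirs[lo:hi, , drop = FALSE]
    m <- hi - lo + 1L
    for (j in seq_len(nrow(f))) {
      p0 <- v[f[j, 1], ]; e1 <- v[f[j, 2], ] - p0; e2 <- v[f[j, 3], ] - p0
      # Moller-Trumbore, vectorised over rays
      hx <- d[, 2] * e2[3] - d[, 3] * e2[2]
      hy <- d[, 3] * e2[1] - d[, 1] * e2[3]
      hz <- d[, 1] * e2[2] - d[, 2] * e2[1]
      det <- e1[1] * hx + e1[2] * hy + e1[3] * hz
      ok <- abs(det) > 1e-14
      if (!any(ok)) next
      sx <- o[, 1] - p0[1]; sy <- o[, 2] - p0[2]; sz <- o[, 3] - p0[3]
      u <- (sx * hx + sy * hy + sz * hz) / det
      qx <- sy * e1[3] - sz * e1[2]
      qy <- sz * e1[1] - sx * e1[3]
      qz <- sx * e1[2] - sy * e1[1]
      vv <- (d[, 1] * qx + d[, 2] * qy + d[, 3] * qz) / det
      tt <- (e2[1] * qx + e2[2] * qy + e2[3] * qz) / det
      hit <- ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > tol
      if (any(hit)) {
        kk <- kk + 1L
        out_ray[[kk]] <- (lo:hi)[hit]
        out_t[[kk]] <- tt[hit]
        # det = e1.(d x e2) = -d.(e1 x e2): det > 0 <=> d against the outward
        # normal <=> entering
        out_s[[kk]] <- ifelse(det[hit] > 0, 1, -1)
      }
    }
  }
  list(ray = unlist(out_ray), t = unlist(out_t), sgn = unlist(out_s))
}

#' Point-in-mesh test
#'
#' Ray-casting parity test against a watertight mesh (a fixed oblique ray
#' direction avoids grazing lattice-aligned triangles).
#'
#' @param pts n x 3 matrix of points.
#' @param mesh a `tri_mesh` (closed).
#' @return logical vector.
#' @export
points_in_mesh <- function(pts, mesh) {
  pts <- rbind(pts)
  n <- nrow(pts)
  dir <- c(0.1234567, 0.6789012, 0.7234567)
  dir <- dir / sqrt(sum(dir^2))
  dirs <- matrix(dir, n, 3, byrow = TRUE)
  hits <- .ray_mesh_hits(pts, dirs, mesh)
  if (!length(hits$ray)) return(rep(FALSE, n))
  cnt <- tabulate(hits$ray, nbins = n)
  cnt %% 2 == 1
}

#' Assemble a cell model from compartment meshes
#'
#' Builds a `cell_model` from watertight triangle meshes of the cytoplasm
#' (outer cell surface), nucleus and optionally Golgi. Volumes come from the
#' divergence theorem; the nucleus (and Golgi) must lie strictly inside the
#' cell surface, verified by point-in-mesh tests of their vertices. The
#' membrane is the outward cytoplasm surface (zero-thickness surface
#' source).
#'
#' @param cytoplasm_mesh,nucleus_mesh,golgi_mesh `tri_mesh` objects or file
#'   paths (OBJ/PLY, um units); `golgi_mesh` may be `NULL`.
#' @return a `cell_model` with `shape = "mesh"`.
#' @export
load_mesh_cell <- function(cytoplasm_mesh, nucleus_mesh, golgi_mesh = NULL) {
  as_mesh <- function(m, label) {
    if (is.character(m)) m <- read_mesh(m)
    if (!mesh_is_watertight(m))
      stopf("mesh for %s is not watertight", label)
    mesh_orient(structure(m, class = "tri_mesh"))
  }
  cy <- as_mesh(cytoplasm_mesh, "cytoplasm")
  nu <- as_mesh(nucleus_mesh, "nucleus")
  go <- if (!is.null(golgi_mesh)) as_mesh(golgi_mesh, "golgi")
  if (!all(points_in_mesh(nu$vertices, cy)))
    stopf("geometry error: nucleus mesh not fully inside the cell surface")
  if (!is.null(go)) {
    if (!all(points_in_mesh(go$vertices, cy)))
      stopf("geometry error: Golgi mesh not inside the cell surface")
    if (any(points_in_mesh(go$vertices, nu)))
      stopf("geometry error: Golgi mesh intersects the nucleus")
  }
  vols <- list(cell = mesh_volume(cy), nucleus = mesh_volume(nu),
               golgi = if (is.null(go)) 0 else mesh_volume(go))
  vols$cytoplasm <- vols$cell - vols$nucleus - vols$golgi
  xy <- cy$vertices[, 1:2]
  structure(list(
    shape = "mesh",
    meshes = list(cytoplasm = cy, nucleus = nu, golgi = go),
    nucleus = list(type = "mesh", centre = colMeans(nu$vertices)),
    golgi = if (is.null(go)) NULL else list(mesh = TRUE),
    volumes = vols,
    footprint_diameter = max(apply(xy, 2, function(u) diff(range(u)))),
    height_um = diff(range(cy$vertices[, 3]))),
    class = "cell_model")
}
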