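#' Closed triangulated surface
#'
#' A watertight, consistently oriented triangle mesh (outward normals) used
#' as an acoustic interface. Vertices are in metres.
#'
#' @param vertices numeric matrix, n x 3.
#' @param triangles integer matrix, m x 3 of 1-based vertex indices.
#' @param label region label carried through the pipeline.
#' @param check validate watertightness, orientation and triangle areas
#'   (default TRUE).
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, label = "region",
                         check = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)),
                      ncol = 3, dimnames = NULL)
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  storage.mode(vertices) <- "double"
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         label = label), class = "surface_mesh")
  if (check) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> '%s': %d vertices, %d triangles, area %.4g m^2\n",
              x$label, nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Validate a surface mesh
#'
#' Checks that every edge is shared by exactly two triangles with opposite
#' traversal direction (watertight, consistently oriented), that no triangle
#' has (near-)zero area, and that the orientation is outward (positive
#' enclosed volume).
#'
#' @param mesh a `surface_mesh`.
#' @return Invisibly `TRUE`; stops with a diagnostic otherwise.
#' @export
validate_mesh <- function(mesh) {
  tri <- mesh$triangles
  nv <- nrow(mesh$vertices)
  if (any(tri < 1L) || any(tri > nv)) stop("triangle index out of range")
  # directed edges: each undirected edge must appear once per direction
  de <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key_fwd <- paste(de[, 1], de[, 2])
  key_rev <- paste(de[, 2], de[, 1])
  if (anyDuplicated(key_fwd))
    stop("mesh not consistently oriented: repeated directed edge")
  if (!all(key_fwd %in% key_rev))
    stop("mesh not watertight: boundary edge found")
  a <- triangle_areas(mesh)
  if (any(a <= 1e-14 * max(a)))
    stop("mesh contains (near-)zero-area triangles")
  if (mesh_volume(mesh) <= 0)
    stop("mesh oriented inward: enclosed volume is non-positive")
  invisible(TRUE)
}

triangle_corners <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  list(a = v[t[, 1], , drop = FALSE], b = v[t[, 2], , drop = FALSE],
       c = v[t[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-triangle areas
#' @param mesh a `surface_mesh`.
#' @return Numeric vector of triangle areas, m^2.
#' @export
triangle_areas <- function(mesh) {
  co <- triangle_corners(mesh)
  cr <- cross3(co$b - co$a, co$c - co$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area
#' @param mesh a `surface_mesh`.
#' @return Total area in m^2.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Enclosed volume (signed; positive for outward orientation)
#' @param mesh a `surface_mesh`.
#' @return Volume in m^3 via the divergence theorem.
#' @export
mesh_volume <- function(mesh) {
  co <- triangle_corners(mesh)
  sum(rowSums(co$a * cross3(co$b, co$c))) / 6
}

#' Barycentre of the enclosed solid
#'
#' Centroid of the volume bounded by a watertight, outward-oriented mesh,
#' computed exactly by the divergence theorem over signed tetrahedra
#' (independent of mesh grading, unlike a vertex average).
#'
#' @param mesh a `surface_mesh`.
#' @return Length-3 numeric point, metres.
#' @export
volume_centroid <- function(mesh) {
  validate_mesh(mesh)
  co <- triangle_corners(mesh)
  w <- rowSums(co$a * cross3(co$b, co$c)) / 6    # signed tet volumes
  cen <- (co$a + co$b + co$c) / 4                # tet centroid (4th vtx = 0)
  as.numeric(colSums(cen * w) / sum(w))
}

#' Mean edge length of a mesh
#' @param mesh a `surface_mesh`.
#' @return Mean undirected edge length in metres.
#' @export
mean_edge_length <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  e <- rbind(t[, 1:2], t[, 2:3], t[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  mean(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                     v[e[, 2], , drop = FALSE])^2)))
}

enclosing_radius <- function(mesh) {
  cen <- volume_centroid(mesh)
  max(sqrt(rowSums(sweep(mesh$vertices, 2, cen)^2)))
}

#' Icosphere generator
#'
#' Subdivided icosahedron projected onto the sphere: `20 * 4^subdivisions`
#' triangles, watertight and outward-oriented by construction.
#'
#' @param radius sphere radius, metres (> 0).
#' @param subdivisions number of 4-to-1 refinements (>= 0).
#' @param center sphere centre (length-3).
#' @param label region label.
#' @return A `surface_mesh`.
#' @examples
#' m <- icosphere(0.25, 2)
#' nrow(m$triangles)  # 320
#' @export
icosphere <- function(radius, subdivisions = 0, center = c(0, 0, 0),
                      label = "sphere") {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    vlist <- list(v)
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      edge_mid[[key]] <- nv
      nv
    }
    for (t in seq_len(nrow(f))) {
      i1 <- f[t, 1]; i2 <- f[t, 2]; i3 <- f[t, 3]
      a <- midpoint(i1, i2); b <- midpoint(i2, i3); c <- midpoint(i3, i1)
      nf[4 * t - 3, ] <- c(i1, a, c)
      nf[4 * t - 2, ] <- c(i2, b, a)
      nf[4 * t - 1, ] <- c(i3, c, b)
      nf[4 * t, ] <- c(a, b, c)
    }
    v <- do.call(rbind, c(list(v), vlist[-1]))
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  surface_mesh(v, f, label = label)
}

## ---- mesh I/O -------------------------------------------------------------

#' Read a triangulated surface from Gmsh (.msh) or STL
#'
#' Supports Gmsh MSH ASCII versions 2.2 and 4.1 and both ASCII and binary
#' STL. STL files (which duplicate vertices per facet) are welded back to a
#' shared-vertex mesh within a tolerance relative to the model size. Region
#' labels are taken from Gmsh physical names / the STL solid name when
#' present.
#'
#' @param path input file; format inferred from the extension
#'   (`.msh` / `.stl`).
#' @param label region label override.
#' @param check run [validate_mesh()] on the result.
#' @return A `surface_mesh`.
#' @export
read_mesh <- function(path, label = NULL, check = TRUE) {
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    msh = read_msh(path),
    stl = read_stl(path),
    stop("unsupported mesh format '.", ext, "' (use .msh or .stl)"))
  if (!is.null(label)) mesh$label <- label
  if (check) validate_mesh(mesh)
  mesh
}

#' Write a surface mesh to Gmsh (.msh, ASCII v2.2) or STL (ASCII)
#'
#' @param mesh a `surface_mesh`.
#' @param path output file; format inferred from the extension.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    msh = write_msh(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format '.", ext, "' (use .msh or .stl)"))
  invisible(path)
}

read_msh <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) return(NULL)
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- sect("MeshFormat")
  if (is.null(fmt)) stop("not a Gmsh MSH file: ", path)
  ver <- as.numeric(strsplit(trimws(fmt[1]), "\\s+")[[1]][1])
  label <- NULL
  pn <- sect("PhysicalNames")
  if (!is.null(pn) && length(pn) > 1) {
    first <- strsplit(trimws(pn[2]), "\\s+")[[1]]
    label <- gsub('"', "", paste(first[-(1:2)], collapse = " "))
  }
  if (ver < 3) {
    nod <- sect("Nodes")
    nn <- as.integer(nod[1])
    ntab <- matrix(as.numeric(unlist(strsplit(trimws(nod[1 + seq_len(nn)]),
                                              "\\s+"))), ncol = 4,
                   byrow = TRUE)
    ids <- as.integer(ntab[, 1])
    verts <- ntab[, 2:4, drop = FALSE]
    el <- sect("Elements")
    ne <- as.integer(el[1])
    tris <- list()
    for (ln in el[1 + seq_len(ne)]) {
      w <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
      if (w[2] == 2L) {                      # 3-node triangle
        ntags <- w[3]
        tris[[length(tris) + 1L]] <- w[(4 + ntags):(6 + ntags)]
      } else if (w[2] == 3L) {
        stop("quadrilateral elements are not supported: triangulations only")
      }
    }
    if (!length(tris)) stop("no triangles found in ", path)
    tri <- do.call(rbind, tris)
  } else {
    nod <- sect("Nodes")
    hdr <- as.numeric(strsplit(trimws(nod[1]), "\\s+")[[1]])
    nblocks <- hdr[1]
    i <- 2L
    ids <- integer(0); verts <- NULL
    for (b in seq_len(nblocks)) {
      bh <- as.numeric(strsplit(trimws(nod[i]), "\\s+")[[1]])
      nin <- bh[4]
      if (nin > 0) {
        bid <- as.integer(nod[i + seq_len(nin)])
        coords <- matrix(as.numeric(unlist(strsplit(
          trimws(nod[i + nin + seq_len(nin)]), "\\s+"))), ncol = 3,
          byrow = TRUE)
        ids <- c(ids, bid)
        verts <- rbind(verts, coords)
      }
      i <- i + 1L + 2L * nin
    }
    el <- sect("Elements")
    hdr <- as.numeric(strsplit(trimws(el[1]), "\\s+")[[1]])
    nblocks <- hdr[1]
    i <- 2L
    tris <- list()
    for (b in seq_len(nblocks)) {
      bh <- as.numeric(strsplit(trimws(el[i]), "\\s+")[[1]])
      etype <- bh[3]; nin <- bh[4]
      if (nin > 0 && etype == 2) {
        m <- matrix(as.integer(unlist(strsplit(trimws(el[i + seq_len(nin)]),
                                               "\\s+"))), ncol = 4,
                    byrow = TRUE)
        tris[[length(tris) + 1L]] <- m[, 2:4, drop = FALSE]
      } else if (etype == 3) {
        stop("quadrilateral elements are not supported: triangulations only")
      }
      i <- i + 1L + nin
    }
    if (!length(tris)) stop("no triangles found in ", path)
    tri <- do.call(rbind, tris)
  }
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  tri <- matrix(remap[tri], ncol = 3)
  surface_mesh(verts, tri, label = if (is.null(label)) "region" else label,
               check = FALSE)
}

write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; t <- mesh$triangles
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "1",
               sprintf('2 1 "%s"', mesh$label), "$EndPhysicalNames",
               "$Nodes", as.character(nrow(v))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(v)),
                     v[, 1], v[, 2], v[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(t))), con)
  writeLines(sprintf("%d 2 2 1 1 %d %d %d", seq_len(nrow(t)),
                     t[, 1], t[, 2], t[, 3]), con)
  writeLines("$EndElements", con)
}

read_stl <- function(path) {
  # sniff: binary STL has an 80-byte header then uint32 facet count
  hdr <- readBin(path, "raw", n = 80)
  txt <- rawToChar(hdr[hdr != as.raw(0)])
  is_ascii <- grepl("^\\s*solid", txt)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    if (!length(vl)) is_ascii <- FALSE else {
      nums <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vl), "\\s+"),
                                              `[`, 2:4))), ncol = 3,
                     byrow = TRUE)
      name <- sub("^\\s*solid\\s*", "", lines[1])
      return(weld_stl(nums, if (nzchar(name)) name else "region"))
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(nf) || nf <= 0) stop("unreadable STL file: ", path)
  buf <- readBin(con, "raw", n = nf * 50)
  if (length(buf) < nf * 50) stop("truncated binary STL: ", path)
  m <- matrix(buf, nrow = 50)
  vraw <- m[13:48, , drop = FALSE]       # 9 floats of vertex data per facet
  vals <- readBin(as.vector(vraw), "numeric", n = 9L * nf, size = 4,
                  endian = "little")
  nums <- matrix(vals, ncol = 3, byrow = TRUE)
  weld_stl(nums, "region")
}

weld_stl <- function(tri_vertices, label) {
  if (nrow(tri_vertices) %% 3 != 0) stop("STL vertex count not divisible by 3")
  scale <- max(apply(tri_vertices, 2, function(x) diff(range(x))))
  tol <- scale * 1e-8
  key <- apply(round(tri_vertices / tol), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  verts <- tri_vertices[!duplicated(key), , drop = FALSE]
  tri <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, tri, label = label, check = FALSE)
}

write_stl <- function(mesh, path) {
  co <- triangle_corners(mesh)
  nrm <- cross3(co$b - co$a, co$c - co$a)
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$label), con)
  body <- sprintf(paste0(
    " facet normal %.9g %.9g %.9g\n  outer loop\n",
    "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
    "   vertex %.9g %.9g %.9g\n  endloop\n endfacet"),
    nrm[, 1], nrm[, 2], nrm[, 3],
    co$a[, 1], co$a[, 2], co$a[, 3],
    co$b[, 1], co$b[, 2], co$b[, 3],
    co$c[, 1], co$c[, 2], co$c[, 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", mesh$label), con)
}
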