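# Warp meshes: grids mapping output-screen positions to source-image
# texture coordinates (with intensity weights), used to pre-distort the
# fisheye view for a specific mirror/dome combination.

#' Warp mesh
#'
#' A regular `nx` by `ny` grid of nodes. Each node has a screen position
#' (`x`, `y`, normalized to [-1, 1] with y up), a texture coordinate
#' (`u`, `v` in [0, 1]) into the source image, and an intensity weight.
#' Nodes with texture coordinates outside [0, 1]^2 are invalid: output
#' pixels falling in cells that touch them are rendered transparent
#' (black), the convention of externally produced warp files which mark
#' unused regions with negative texture coordinates.
#'
#' @param x,y,u,v,intensity `ny` x `nx` matrices (rows bottom-to-top).
#' @param type integer projection-type tag carried in the file header
#'   (2 for fisheye in the original ecosystem; not interpreted here).
#' @return object of class `warp_mesh`.
#' @export
warp_mesh <- function(x, y, u, v, intensity, type = 2L) {
  dims <- dim(x)
  if (is.null(dims) || any(dims < 2L))
    stop("mesh needs at least 2 x 2 nodes")
  for (m in list(y, u, v, intensity))
    if (!identical(dim(m), dims)) stop("all node matrices must match")
  structure(list(x = x, y = y, u = u, v = v, intensity = intensity,
                 nx = dims[2], ny = dims[1], type = as.integer(type)),
            class = "warp_mesh")
}

#' @export
print.warp_mesh <- function(x, ...) {
  cat(sprintf("<warp_mesh> %d x %d nodes (type %d)\n", x$nx, x$ny, x$type))
  invisible(x)
}

#' Identity warp mesh
#'
#' Maps the screen straight onto the texture (`u = (x+1)/2`,
#' `v = (y+1)/2`, intensity 1); applying it leaves an image unchanged.
#'
#' @param nx,ny grid dimensions (>= 2).
#' @return a [warp_mesh()].
#' @export
identity_warp_mesh <- function(nx = 9L, ny = 9L) {
  xs <- matrix(seq(-1, 1, length.out = nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq(-1, 1, length.out = ny), ny, nx)
  warp_mesh(xs, ys, (xs + 1) / 2, (ys + 1) / 2,
            matrix(1, ny, nx))
}

#' Read / write a warp-mesh text file
#'
#' Text format: line 1 the projection-type integer; line 2 `nx ny`; then
#' `nx * ny` node lines `x y u v intensity`, x varying fastest, rows from
#' bottom to top.
#'
#' @param path file path.
#' @return [read_warp_mesh()]: a [warp_mesh()].
#' @export
read_warp_mesh <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  type <- as.integer(trimws(lines[1]))
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nx <- dims[1]; ny <- dims[2]
  vals <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nx * ny * 5)
    stop("warp mesh file has ", length(vals) / 5, " nodes; expected ",
         nx * ny)
  m <- matrix(vals, ncol = 5, byrow = TRUE)
  shape <- function(col) matrix(m[, col], ny, nx, byrow = TRUE)
  warp_mesh(shape(1), shape(2), shape(3), shape(4), shape(5), type)
}

#' @rdname read_warp_mesh
#' @param mesh a [warp_mesh()].
#' @export
write_warp_mesh <- function(mesh, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("%d", mesh$type),
               sprintf("%d %d", mesh$nx, mesh$ny)), con)
  for (i in seq_len(mesh$ny))
    writeLines(sprintf("%.8g %.8g %.8g %.8g %.8g", mesh$x[i, ],
                       mesh$y[i, ], mesh$u[i, ], mesh$v[i, ],
                       mesh$intensity[i, ]), con)
  invisible(path)
}

# bilinear sample of an image matrix at continuous pixel coordinates
# (cx, cy in units of pixels, pixel centers at 0.5 .. n - 0.5), clamped
.bilinear_sample <- function(img, cx, cy) {
  h <- nrow(img); w <- ncol(img)
  fx <- pmin(pmax(cx - 0.5, 0), w - 1)
  fy <- pmin(pmax(cy - 0.5, 0), h - 1)
  x0 <- pmin(floor(fx), w - 2); y0 <- pmin(floor(fy), h - 2)
  tx <- fx - x0; ty <- fy - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x0 + 2)]
  i10 <- img[cbind(y0 + 2, x0 + 1)]
  i11 <- img[cbind(y0 + 2, x0 + 2)]
  (1 - ty) * ((1 - tx) * i00 + tx * i01) + ty * ((1 - tx) * i10 + tx * i11)
}

#' Apply a warp mesh to an image
#'
#' Resamples the input image through the mesh: each output pixel's screen
#' position is located in the mesh grid, the texture coordinate and
#' intensity are bilinearly interpolated across the containing cell, and the
#' input image is sampled bilinearly at that texture coordinate and scaled
#' by the intensity. Output pixels in cells with any invalid node
#' (texture coordinates outside [0, 1]^2) are transparent (0).
#'
#' Image convention: a numeric matrix (grayscale, values in [0, 1]) or an
#' `height x width x channels` array; row 1 is the top of the image, and the
#' mesh's y axis points up.
#'
#' @param image matrix or 3-d array.
#' @param mesh a [warp_mesh()].
#' @return warped image, same dimensions as the input.
#' @export
apply_warp_mesh <- function(image, mesh) {
  if (length(dim(image)) == 3L) {
    out <- image
    for (ch in seq_len(dim(image)[3]))
      out[, , ch] <- apply_warp_mesh(image[, , ch], mesh)
    return(out)
  }
  if (!is.matrix(image) || !nrow(image) || !ncol(image))
    stop("image must be a non-empty matrix or 3-d array")
  h <- nrow(image); w <- ncol(image)
  # output pixel centers in mesh screen coordinates ([-1,1], y up)
  sx <- -1 + 2 * (seq_len(w) - 0.5) / w
  sy <- 1 - 2 * (seq_len(h) - 0.5) / h
  # the mesh is a regular tensor grid: row/column coordinates
  gx <- mesh$x[1, ]; gy <- mesh$y[, 1]
  valid_node <- mesh$u >= 0 & mesh$u <= 1 & mesh$v >= 0 & mesh$v <= 1
  out <- matrix(0, h, w)
  jx <- pmin(pmax(findInterval(sx, gx), 1L), mesh$nx - 1L)
  tx <- (sx - gx[jx]) / (gx[jx + 1L] - gx[jx])
  for (i in seq_len(h)) {
    jy <- min(max(findInterval(sy[i], gy), 1L), mesh$ny - 1L)
    ty <- (sy[i] - gy[jy]) / (gy[jy + 1L] - gy[jy])
    if (ty < -1e-9 || ty > 1 + 1e-9) next  # outside the mesh vertically
    inx <- tx >= -1e-9 & tx <= 1 + 1e-9
    ok <- inx & valid_node[cbind(jy, jx)] & valid_node[cbind(jy, jx + 1L)] &
      valid_node[cbind(jy + 1L, jx)] & valid_node[cbind(jy + 1L, jx + 1L)]
    if (!any(ok)) next
    bl <- function(m) {
      (1 - ty) * ((1 - tx[ok]) * m[cbind(jy, jx[ok])] +
                    tx[ok] * m[cbind(jy, jx[ok] + 1L)]) +
        ty * ((1 - tx[ok]) * m[cbind(jy + 1L, jx[ok])] +
                tx[ok] * m[cbind(jy + 1L, jx[ok] + 1L)])
    }
    u <- bl(mesh$u); v <- bl(mesh$v); w8 <- bl(mesh$intensity)
    cx <- u * w
    cy <- (1 - v) * h   # v points up, image rows run top-down
    out[i, ok] <- pmax(0, w8) * .bilinear_sample(image, cx, cy)
  }
  out
}

#' Render a labeled fisheye test pattern
#'
#' A quick visual check of the projection chain: concentric rings every 15
#' degrees of polar angle, meridians every 30 degrees of image azimuth, and
#' a brighter wedge marking the up direction.
#'
#' @param size output image size in pixels (square).
#' @param theta_max fisheye rim polar angle (degrees).
#' @return a `size` x `size` matrix in [0, 1].
#' @export
fisheye_test_pattern <- function(size = 512L, theta_max = DOME_MAX_POLAR_DEG) {
  px <- (seq_len(size) - 0.5) / size
  u <- matrix(px, size, size, byrow = TRUE)
  v <- matrix(rev(px), size, size)   # row 1 = top = v near 1
  du <- u - 0.5; dv <- v - 0.5
  rad <- sqrt(du^2 + dv^2)
  theta <- rad / 0.5 * theta_max
  psi <- atan2(dv, du) * 180 / pi
  img <- matrix(0.15, size, size)
  img[theta <= theta_max] <- 0.35
  rings <- abs((theta %% 15) - 0) < 1.2 | abs((theta %% 15) - 15) < 1.2
  merid <- abs(((psi + 360) %% 30)) < 1.5 | abs(((psi + 360) %% 30) - 30) < 1.5
  img[rings & theta <= theta_max] <- 0.9
  img[merid & theta <= theta_max & theta > 2] <- 0.7
  img[abs(psi - 90) < 8 & theta < 20] <- 1.0  # up marker
  img
}
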