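# Camera model and rotation utilities shared by the renderer, SfM and MVS.
# Convention: pinhole, zero distortion, x = K [R | t] X; depth is the
# z-coordinate in the camera frame; pixel coordinates are 0-based with pixel
# centers at integer coordinates.

#' Pinhole camera intrinsics
#' @param fx,fy focal lengths in pixels
#' @param cx,cy principal point in pixels (0-based)
#' @param height,width image size in pixels
#' @return object of class `camera_intrinsics`
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, height, width) {
  stopifnot(fx > 0, fy > 0, cx >= 0, cx < width, cy >= 0, cy < height)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 height = as.integer(height), width = as.integer(width)),
            class = "camera_intrinsics")
}

#' Intrinsics as a 3x3 matrix K
#' @param intr a [camera_intrinsics()]
#' @return 3x3 matrix
#' @export
intrinsics_matrix <- function(intr) {
  matrix(c(intr$fx, 0, 0,
           0, intr$fy, 0,
           intr$cx, intr$cy, 1), 3, 3)
}

#' Rigid world-to-camera pose
#' @param R 3x3 rotation (world to camera), det +1
#' @param t length-3 translation; camera center is -t(R) %*% t
#' @return object of class `camera_pose`
#' @export
camera_pose <- function(R, t) {
  stopifnot(all(dim(R) == c(3, 3)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("R must be a proper rotation (orthonormal, det +1)")
  structure(list(R = R, t = as.numeric(t)), class = "camera_pose")
}

pose_center <- function(pose) as.numeric(-crossprod(pose$R, pose$t))

#' Compose a look-at pose from a camera center and target point
#' @param center,target length-3 world points
#' @param up world up vector
#' @return `camera_pose` (z axis points from center toward target)
#' @export
pose_lookat <- function(center, target, up = c(0, 1, 0)) {
  z <- target - center
  nz <- sqrt(sum(z^2))
  if (nz < 1e-12) stop("look-at target coincides with camera center")
  z <- z / nz
  x <- cross3(up, z)
  if (sqrt(sum(x^2)) < 1e-8) x <- cross3(c(1, 0, 0), z)
  x <- x / sqrt(sum(x^2))
  y <- cross3(z, x)
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  camera_pose(R, -as.numeric(R %*% center))
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Project world points into pixel coordinates
#' @param X Nx3 matrix of world points
#' @param pose `camera_pose`; @param intr `camera_intrinsics`
#' @param intr camera intrinsics
#' @return list with `uv` (Nx2, 0-based pixels) and `depth` (length N)
#' @export
project_points <- function(X, pose, intr) {
  X <- matrix(X, ncol = 3)
  Xc <- t(pose$R %*% t(X) + pose$t)
  z <- Xc[, 3]
  uv <- cbind(intr$fx * Xc[, 1] / z + intr$cx,
              intr$fy * Xc[, 2] / z + intr$cy)
  list(uv = uv, depth = z)
}

#' Back-project pixels at given depths into world points
#' @param uv Nx2 matrix of 0-based pixel coordinates
#' @param depth length-N depths (camera-frame z)
#' @param pose `camera_pose`; @param intr `camera_intrinsics`
#' @param intr camera intrinsics
#' @return Nx3 matrix of world points
#' @export
backproject_pixels <- function(uv, depth, pose, intr) {
  uv <- matrix(uv, ncol = 2)
  xc <- (uv[, 1] - intr$cx) / intr$fx * depth
  yc <- (uv[, 2] - intr$cy) / intr$fy * depth
  Xc <- cbind(xc, yc, depth)
  t(crossprod(pose$R, t(Xc) - 0) + pose_center(pose))
}

# ---- quaternions (w, x, y, z), unit, representing world->camera R ---------

rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# angle-axis (length-3) to rotation matrix, and its application to the
# left of an existing rotation (optimisation increments)
aa_to_rot <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3) + skew3(v))
  k <- v / th
  K <- skew3(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew3 <- function(v) matrix(c(0, v[3], -v[2],
                              -v[3], 0, v[1],
                              v[2], -v[1], 0), 3, 3)

#' Angle in degrees between two rotations
#' @param Ra,Rb 3x3 rotation matrices
#' @return rotation angle of `Ra %*% t(Rb)` in degrees
#' @export
rotation_angle_deg <- function(Ra, Rb) {
  Rrel <- Ra %*% t(Rb)
  c_ang <- (sum(diag(Rrel)) - 1) / 2
  acos(pmin(1, pmax(-1, c_ang))) * 180 / pi
}

#' Closed-form similarity alignment (rotation, translation, scale)
#'
#' Finds s, R, t minimising mean squared ||s R x + t - y||^2 between paired
#' point sets (Umeyama-style via SVD of the cross-covariance).
#'
#' @param X,Y Nx3 matrices of corresponding points (align X onto Y)
#' @return list with `s`, `R`, `t` and the aligned points `Xa`
#' @export
align_similarity <- function(X, Y) {
  X <- matrix(X, ncol = 3); Y <- matrix(Y, ncol = 3)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(Xc^2))
  s <- sum(diag(diag(sv$d) %*% D)) / varx
  t <- my - s * as.numeric(R %*% mx)
  list(s = s, R = R, t = t, Xa = t(s * R %*% t(X) + t))
}
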