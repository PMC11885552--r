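#' Mirror a landmark configuration
#'
#' Reflects a single configuration across the stated axis (negating the x or
#' y coordinate), leaving landmark order unchanged. Used to convert right
#' maxillae to left before digitization-consistent analysis; reflection is
#' never applied implicitly during alignment.
#'
#' @param config k x 2 matrix.
#' @param axis `"x"` (negate x) or `"y"` (negate y).
#' @return k x 2 matrix.
#' @export
mirror_config <- function(config, axis = c("x", "y")) {
  axis <- match.arg(axis)
  config <- as.matrix(config)
  if (axis == "x") config[, 1] <- -config[, 1] else config[, 2] <- -config[, 2]
  config
}

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid; the standard geometric-morphometrics size measure and the
#' allometry proxy used in the PGLS models.
#'
#' @param config k x 2 matrix without missing points.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (anyNA(config)) stop("centroid_size: configuration has missing points")
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2, ctr)^2))
  if (cs < .Machine$double.eps^0.5)
    stop("degenerate configuration: all landmarks coincide")
  cs
}

# --- thin-plate spline machinery ------------------------------------------

# U(r) = r^2 log r  (value at r = 0 is 0); constant factors are irrelevant
# for both interpolation and bending-energy minimization.
tps_kernel <- function(d) {
  u <- d^2 * log(d)
  u[d == 0] <- 0
  u
}

# Solve the 2D TPS interpolation mapping src -> dst. Returns a closure
# evaluating the map at new points, plus the affine/warp coefficients.
tps_fit <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  k <- nrow(src)
  if (k < 3L) stop("TPS requires at least 3 points")
  K <- tps_kernel(as.matrix(stats::dist(src)))
  Q <- cbind(1, src)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (collinear or coincident points)"))
  W <- sol[1:k, , drop = FALSE]
  A <- sol[(k + 1):(k + 3), , drop = FALSE]
  list(
    predict = function(pts) {
      pts <- as.matrix(pts)
      D <- sqrt(outer(rowSums(pts^2), rowSums(src^2), "+") -
                  2 * tcrossprod(pts, src))
      D[D < 0 | is.na(D)] <- 0
      U <- tps_kernel(D)
      cbind(1, pts) %*% A + U %*% W
    },
    warp = W, affine = A
  )
}

# Bending-energy matrix of a reference configuration: upper-left k x k block
# of the inverse of the TPS system matrix.
bending_energy_matrix <- function(ref) {
  ref <- as.matrix(ref)
  k <- nrow(ref)
  K <- tps_kernel(as.matrix(stats::dist(ref)))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular bending-energy system for reference configuration"))
  B <- Li[1:k, 1:k, drop = FALSE]
  (B + t(B)) / 2
}

# Total bending energy of deforming ref into config.
bending_energy <- function(config, ref) {
  B <- bending_energy_matrix(ref)
  d <- as.matrix(config) - as.matrix(ref)
  sum(d[, 1] %*% B %*% d[, 1] + d[, 2] %*% B %*% d[, 2])
}

#' Estimate missing landmarks by thin-plate-spline interpolation
#'
#' For each incomplete specimen, a TPS map is fitted from the reference
#' configuration to the specimen over their shared (present) landmarks, and
#' the missing coordinates are filled in as the images of the reference's
#' corresponding points. The TPS interpolant reproduces the generating map
#' exactly when the specimen is an affine image of the reference.
#'
#' @param landmarks a [landmark_set()] with at least one complete specimen.
#' @param reference k x 2 matrix used as interpolation source, or `NULL` to
#'   use the mean of the complete specimens after a preliminary Procrustes
#'   alignment of the complete specimens only.
#' @return a `landmark_set` with all points present and an attribute
#'   `estimated` naming the completed specimens.
#' @export
estimate_missing_tps <- function(landmarks, reference = NULL) {
  miss <- landmarks$missing
  if (!any(miss)) return(landmarks)
  complete <- which(rowSums(miss) == 0)
  incomplete <- which(rowSums(miss) > 0)
  if (is.null(reference)) {
    if (!length(complete))
      stop("no complete specimen available to build a TPS reference")
    if (length(complete) == 1L) {
      reference <- landmarks$coords[complete, , ]
    } else {
      sub <- landmark_set(landmarks$coords[complete, , , drop = FALSE],
                          landmarks$specimen_ids[complete],
                          curves = landmarks$curves)
      ref_gpa <- gpa_align(sub, slide_semilandmarks = FALSE)
      reference <- ref_gpa$consensus
    }
  }
  out <- landmarks
  for (i in incomplete) {
    shared <- which(!miss[i, ])
    if (length(shared) < 3L)
      stop("specimen ", landmarks$specimen_ids[i],
           " has fewer than 3 observed landmarks")
    fit <- tryCatch(
      tps_fit(reference[shared, , drop = FALSE],
              landmarks$coords[i, shared, , drop = TRUE]),
      error = function(e) stop("TPS estimation failed for specimen ",
                               landmarks$specimen_ids[i], ": ",
                               conditionMessage(e)))
    gap <- which(miss[i, ])
    out$coords[i, gap, ] <- fit$predict(reference[gap, , drop = FALSE])
    out$missing[i, gap] <- FALSE
  }
  attr(out, "estimated") <- landmarks$specimen_ids[incomplete]
  out
}

# Optimal rotation (no reflection) aligning X onto M; both centered.
opa_rotate <- function(X, M) {
  s <- svd(crossprod(X, M))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  X %*% R
}

#' Procrustes distance between two configurations
#'
#' Centers and scales both configurations to unit centroid size, optimally
#' rotates the first onto the second (reflection disallowed), and returns
#' the root summed squared difference.
#'
#' @param a,b k x 2 matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  pa <- scale(as.matrix(a), scale = FALSE); pa <- pa / sqrt(sum(pa^2))
  pb <- scale(as.matrix(b), scale = FALSE); pb <- pb / sqrt(sum(pb^2))
  sqrt(sum((opa_rotate(pa, pb) - pb)^2))
}

# Slide semilandmarks of one aligned configuration against the reference.
# sliders: 3-column matrix (before, slide, after).  criterion "bending"
# minimizes the TPS bending energy of the deviation from the reference
# (Gunz-style), "procrustes" projects the deviation onto the tangent.
slide_one <- function(X, M, sliders, criterion, B = NULL) {
  k <- nrow(X)
  tang <- X[sliders[, "after"], , drop = FALSE] -
    X[sliders[, "before"], , drop = FALSE]
  tang <- tang / sqrt(rowSums(tang^2))
  s_idx <- sliders[, "slide"]
  if (criterion == "procrustes") {
    tshift <- rowSums(tang * (M[s_idx, , drop = FALSE] -
                                X[s_idx, , drop = FALSE]))
    X[s_idx, ] <- X[s_idx, , drop = FALSE] + tang * tshift
    return(X)
  }
  if (is.null(B)) B <- bending_energy_matrix(M)
  S <- length(s_idx)
  U <- matrix(0, 2 * k, S)
  U[cbind(s_idx, seq_len(S))] <- tang[, 1]
  U[cbind(k + s_idx, seq_len(S))] <- tang[, 2]
  d0 <- c(X[, 1] - M[, 1], X[, 2] - M[, 2])
  E <- rbind(cbind(B, matrix(0, k, k)), cbind(matrix(0, k, k), B))
  G <- crossprod(U, E %*% U)
  diag(G) <- diag(G) + 1e-12
  tshift <- -solve(G, crossprod(U, E %*% d0))
  X[s_idx, ] <- X[s_idx, , drop = FALSE] + tang * as.vector(tshift)
  X
}

#' Generalized Procrustes Analysis with sliding semilandmarks
#'
#' Iteratively removes translation, scale and rotation from a set of
#' landmark configurations: each configuration is centered, scaled to unit
#' centroid size and rotated (reflection disallowed) onto the running
#' consensus, which is then re-estimated, until the consensus stabilizes.
#' Semilandmarks optionally slide along their curve tangents each outer
#' iteration, by default minimizing thin-plate-spline bending energy against
#' the consensus. Final shape coordinates are orthogonally projected onto
#' the tangent space at the consensus.
#'
#' @param landmarks a [landmark_set()] without missing points.
#' @param slide_semilandmarks logical; slide curve points?
#' @param sliders 3-column (before, slide, after) matrix from
#'   [sliders_from_curves()]; defaults to sliders derived from the set's
#'   curves (curve endpoints fixed).
#' @param slide_criterion `"bending"` (default) or `"procrustes"`.
#' @param tol consensus root-mean-square change declaring convergence.
#' @param max_iter maximum outer iterations.
#' @param project project final coordinates to the tangent space?
#' @return object of class `gpa_shape` with elements `aligned` (n x k x 2
#'   Procrustes coordinates), `consensus` (k x 2), `centroid_sizes` (raw
#'   sizes before scaling), `specimen_ids`, and convergence diagnostics
#'   (`iterations`, `deltas`, `ss_history`).
#' @export
gpa_align <- function(landmarks, slide_semilandmarks = length(landmarks$curves) > 0,
                      sliders = NULL, slide_criterion = c("bending", "procrustes"),
                      tol = 1e-8, max_iter = 100, project = TRUE) {
  slide_criterion <- match.arg(slide_criterion)
  if (any(landmarks$missing))
    stop("landmark set has missing points; run estimate_missing_tps() first")
  n <- dim(landmarks$coords)[1]; k <- dim(landmarks$coords)[2]
  if (slide_semilandmarks && is.null(sliders))
    sliders <- sliders_from_curves(landmarks$curves)
  if (slide_semilandmarks && (is.null(sliders) || nrow(sliders) == 0))
    slide_semilandmarks <- FALSE

  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- landmarks$coords[i, , ]
    cs[i] <- centroid_size(cfg)
    cfg <- sweep(cfg, 2, colMeans(cfg))
    X[[i]] <- cfg / cs[i]
  }

  deltas <- numeric(0)
  ss_hist <- numeric(0)
  # one pass of plain iterative superimposition, run to convergence
  superimpose <- function(X, M) {
    for (it in seq_len(max_iter)) {
      X <- lapply(X, opa_rotate, M = M)
      ss_hist <<- c(ss_hist, sum(vapply(X, function(x) sum((x - M)^2),
                                        numeric(1))))
      M_new <- Reduce(`+`, X) / n
      M_new <- sweep(M_new, 2, colMeans(M_new))
      M_new <- M_new / sqrt(sum(M_new^2))
      delta <- sqrt(mean((M_new - M)^2))
      deltas <<- c(deltas, delta)
      M <- M_new
      if (delta < tol) return(list(X = X, M = M, converged = TRUE))
    }
    list(X = X, M = M, converged = FALSE)
  }

  fit <- superimpose(X, X[[1]])
  if (!fit$converged)
    stop("GPA did not converge after ", max_iter,
         " iterations; last consensus RMS change = ",
         format(deltas[length(deltas)]))
  slide_iters <- 0L
  if (slide_semilandmarks) {
    # sliding phase: slide against the current consensus, re-superimpose,
    # and keep going only while the Procrustes sum of squares decreases
    # (the joint slide/consensus problem is degenerate along common curve
    # reparameterizations, so descent is monitored explicitly)
    ss_of <- function(f) sum(vapply(f$X, function(x) sum((x - f$M)^2),
                                    numeric(1)))
    cur_ss <- ss_of(fit)
    for (sit in seq_len(20L)) {
      B <- if (slide_criterion == "bending") bending_energy_matrix(fit$M)
           else NULL
      Xs <- lapply(fit$X, function(x) {
        x2 <- slide_one(x, fit$M, sliders, slide_criterion, B)
        x2 <- sweep(x2, 2, colMeans(x2))
        x2 / sqrt(sum(x2^2))
      })
      cand <- superimpose(Xs, fit$M)
      if (!cand$converged) break
      new_ss <- ss_of(cand)
      if (new_ss > cur_ss - 1e-10) break
      fit <- cand
      cur_ss <- new_ss
      slide_iters <- sit
    }
  }
  M <- fit$M
  X <- lapply(fit$X, opa_rotate, M = M)

  aligned <- array(NA_real_, c(n, k, 2),
                   dimnames = list(landmarks$specimen_ids, NULL, c("x", "y")))
  cvec <- c(M[, 1], M[, 2])
  for (i in seq_len(n)) {
    xi <- X[[i]]
    if (project) {
      v <- c(xi[, 1], xi[, 2])
      v <- v - cvec * (sum(cvec * v) - 1)
      xi <- cbind(v[1:k], v[(k + 1):(2 * k)])
    }
    aligned[i, , ] <- xi
  }
  structure(list(aligned = aligned, consensus = M, centroid_sizes = cs,
                 specimen_ids = landmarks$specimen_ids,
                 curves = landmarks$curves, sliders = sliders,
                 slid = slide_semilandmarks, criterion = slide_criterion,
                 iterations = length(deltas), slide_iterations = slide_iters,
                 deltas = deltas,
                 ss_history = ss_hist, projected = project),
            class = "gpa_shape")
}

#' @export
print.gpa_shape <- function(x, ...) {
  cat("Generalized Procrustes Analysis\n")
  cat("  specimens:", length(x$specimen_ids),
      " landmarks:", nrow(x$consensus), "\n")
  cat("  semilandmark sliding:",
      if (x$slid) paste0("yes (", x$criterion, " criterion)") else "no", "\n")
  cat("  converged in", x$iterations, "iterations; final consensus change",
      format(x$deltas[x$iterations], digits = 3), "\n")
  invisible(x)
}

#' Flatten aligned shapes to a specimen x variable matrix
#'
#' Landmark-major order (x1, y1, x2, y2, ...).
#' @param shape a `gpa_shape` (or any n x k x 2 array).
#' @return n x 2k numeric matrix with specimen row names.
#' @export
flatten_shapes <- function(shape) {
  arr <- if (inherits(shape, "gpa_shape")) shape$aligned else shape
  n <- dim(arr)[1]; k <- dim(arr)[2]
  out <- matrix(NA_real_, n, 2 * k)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[i, , ]))
  rownames(out) <- dimnames(arr)[[1]]
  colnames(out) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  out
}
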