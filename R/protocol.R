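#' Multi-shell diffusion acquisition protocol
#'
#' Groups measurements into b=0 and diffusion-weighted shells with a
#' b-value tolerance, and normalizes gradient directions.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per measurement.
#' @param bvecs N x 3 matrix of gradient directions (unit vectors for b>0;
#'   arbitrary, typically zero, for b=0).
#' @param b0_threshold b-values at or below this count as b=0 (default 50).
#' @param shell_tolerance measurements whose b-values differ by at most this
#'   amount belong to the same shell (default 100).
#' @return object of class `diffusion_protocol`: `bvals`, `bvecs`
#'   (unit rows for b>0), `b0` logical, `shells` named list mapping nominal
#'   shell b-value to measurement indices (b=0 shell named `"0"`).
#' @export
diffusion_protocol <- function(bvals, bvecs, b0_threshold = 50,
                               shell_tolerance = 100) {
  bvals <- as.numeric(bvals)
  bvecs <- matrix(as.numeric(bvecs), ncol = 3L)
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs disagree in length")
  b0 <- bvals <= b0_threshold
  if (!any(b0)) stop("protocol must contain at least one b=0 measurement")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(!b0 & nrm < 1e-8))
    stop("zero gradient direction on a diffusion-weighted measurement")
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  # cluster weighted b-values into shells
  shells <- list(`0` = which(b0))
  bw <- sort(unique(bvals[!b0]))
  while (length(bw)) {
    grp <- bw[bw <= bw[1L] + shell_tolerance]
    nominal <- round(mean(grp))
    shells[[as.character(nominal)]] <-
      which(!b0 & abs(bvals - mean(grp)) <= shell_tolerance)
    bw <- bw[bw > bw[1L] + shell_tolerance]
  }
  if (any(vapply(shells, length, 1L) == 0L)) stop("empty shell after grouping")
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0, shells = shells),
            class = "diffusion_protocol")
}

#' @export
print.diffusion_protocol <- function(x, ...) {
  cat(sprintf("diffusion_protocol: %d measurements; shells: %s\n",
              length(x$bvals),
              paste(sprintf("b=%s (n=%d)", names(x$shells),
                            vapply(x$shells, length, 1L)), collapse = ", ")))
  invisible(x)
}

#' Read an FSL-dialect bval/bvec pair
#'
#' Whitespace-separated files: one row of b-values, and three rows (x, y, z)
#' of gradient components.
#'
#' @param bval_path,bvec_path file paths.
#' @param ... passed to [diffusion_protocol()].
#' @return a `diffusion_protocol`.
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path, ...) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- scan(bvec_path, quiet = TRUE)
  if (length(bv) != 3L * length(bvals))
    stop("bvec file does not contain 3 rows matching the bval count")
  bvecs <- t(matrix(bv, nrow = 3L, byrow = TRUE))
  diffusion_protocol(bvals, bvecs, ...)
}

#' Write an FSL-dialect bval/bvec pair
#'
#' @param protocol a `diffusion_protocol`.
#' @param bval_path,bvec_path output paths.
#' @export
write_bvals_bvecs <- function(protocol, bval_path, bvec_path) {
  writeLines(paste(protocol$bvals, collapse = " "), bval_path)
  writeLines(apply(t(protocol$bvecs), 1L, paste, collapse = " "), bvec_path)
  invisible(NULL)
}

#' Deterministic multi-shell protocol
#'
#' HCP-style acquisition: three shells at b = 1000, 2000, 3000 s/mm^2 with
#' quasi-uniform Fibonacci-sphere directions, plus interleaved b=0 volumes.
#'
#' @param n_dirs directions per shell (length-3 integer, default 30 each).
#' @param n_b0 number of b=0 measurements (default 6).
#' @param shells nominal shell b-values (s/mm^2).
#' @return a `diffusion_protocol`.
#' @export
multishell_protocol <- function(n_dirs = c(30L, 30L, 30L), n_b0 = 6L,
                                shells = c(1000, 2000, 3000)) {
  stopifnot(length(n_dirs) == length(shells), n_b0 >= 1L)
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, n_b0, 3L)
  for (s in seq_along(shells)) {
    dirs <- fibonacci_directions(n_dirs[s], rotate = s - 1L)
    bvals <- c(bvals, rep(shells[s], n_dirs[s]))
    bvecs <- rbind(bvecs, dirs)
  }
  diffusion_protocol(bvals, bvecs)
}

#' Quasi-uniform unit directions on the sphere (Fibonacci lattice)
#'
#' @param n number of directions.
#' @param rotate integer; rotates the azimuthal origin so successive shells
#'   do not share directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n, rotate = 0L) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5)) + rotate * 0.7
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
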