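#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive n reproducible child seeds (< 2^31) from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (radians) to (-pi, pi].
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Circular mean of a sample of angles
#'
#' Direction of the vector sum of unit phasors, the standard circular mean.
#'
#' @param deg angles in degrees.
#' @return circular mean in degrees, in (-180, 180].
#' @examples
#' circ_mean_deg(c(350, 10)) # 0
#' @export
circ_mean_deg <- function(deg) {
  if (length(deg) == 0L || !all(is.finite(deg)))
    stop_invalid("circ_mean_deg needs a non-empty finite sample")
  rad2deg(Arg(mean(exp(1i * deg2rad(deg)))))
}

# Mean resultant length of angles given in degrees.
circ_r <- function(deg) Mod(mean(exp(1i * deg2rad(deg))))

# Absolute circular distance between two angles in degrees, in [0, 180].
circ_dist_deg <- function(a, b) {
  d <- abs(((a - b + 180) %% 360) - 180)
  d
}

# Tiny FNV-1a hash of a character scalar, for provenance records.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
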