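# Small 3-vector helpers shared across the package. All angles are degrees,
# all lengths meters, camera frame: x right, y down, z away from the sensor.

.DEG <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Unit vector, or NULL when the norm is below tol (caller decides whether that
# is an error or an undefined angle).
.vunit <- function(v, tol = 1e-8) {
  n <- .vnorm(v)
  if (!is.finite(n) || n < tol) return(NULL)
  v / n
}

.is_pos3 <- function(x) is.numeric(x) && length(x) == 3L && all(is.finite(x))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Deterministic child seeds derived from a base seed; kept inside 32-bit range.
.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

# Format doubles for text output so files are byte-stable across sessions.
.fmt_num <- function(x) sprintf("%.17g", x)
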