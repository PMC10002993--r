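# Small numeric helpers shared across modules. All coordinates are plain
# numeric length-3 vectors (mm); matrices are n x 3 with one point per row.

vnorm <- function(v) sqrt(sum(v * v))

normalize <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

as_point3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || !all(is.finite(p))) {
    stop(sprintf("%s must be a finite numeric vector of length 3", what),
         call. = FALSE)
  }
  p
}

#' Euclidean distance between two points
#'
#' @param a,b numeric length-3 points (mm).
#' @return distance in mm.
#' @export
point_distance <- function(a, b) {
  vnorm(as_point3(a, "a") - as_point3(b, "b"))
}

# Deterministic substream seed derivation: one base seed plus a path of small
# integer ids (stage, patient, replicate ...). Uses a 31-bit LCG-style mix so
# adding patients or replicates never perturbs earlier substreams.
substream_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed %% 2147483647)
  for (id in ids) {
    s <- (s * 48271 + as.double(id) + 1) %% 2147483647
  }
  as.integer(s)
}

with_substream <- function(seed, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, ...))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
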