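#' @importFrom stats median quantile rnorm runif sd
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_facesim <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "facesim_error")))
}

as_matrix3 <- function(x, what = "coordinates") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop_facesim(what, " must have 3 columns", class = "facesim_input_error")
  }
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

# Row-wise Euclidean norms.
row_norms <- function(x) sqrt(rowSums(x * x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rotation about the x (left-right) axis by `deg` degrees.
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(
    1, 0, 0,
    0, cos(a), -sin(a),
    0, sin(a), cos(a)
  ), 3, 3, byrow = TRUE)
}
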