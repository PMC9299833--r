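## Internal helpers shared across modules.

#' @keywords internal
#' @import stats
#' @import graphics
#' @importFrom utils read.csv write.csv packageVersion
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validation helper: stop with the offending field name.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Lognormal parameterized by arithmetic mean and coefficient of variation.
# cv = 0 degenerates to a point mass at the mean.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Shoelace area of a closed polygon given as an n x 2 matrix (not repeated
# at the end).
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  i <- seq_len(nrow(poly)); j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x[i] * y[j] - x[j] * y[i])) / 2
}

as_polygon_matrix <- function(polygon) {
  m <- as.matrix(polygon)
  check_that(ncol(m) == 2 && nrow(m) >= 3 && all(is.finite(m)),
             "polygon must be an n x 2 matrix of finite vertices, n >= 3")
  storage.mode(m) <- "double"
  unname(m)
}
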