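#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix Diagonal colSums rowSums rowMeans t readMM writeMM
#' @importFrom stats prcomp quantile rnbinom rnorm rlnorm runif wilcox.test
#'   p.adjust loess predict var sd as.dist dist ecdf setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Tukey trimean
#'
#' Robust location summary `(Q1 + 2 * median + Q3) / 4`, with
#' linear-interpolation quartiles (`stats::quantile()` type 7).
#'
#' @param x Numeric vector.
#' @return A single number.
#' @examples
#' trimean(0:8) # 4
#' @export
trimean <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  (q[1] + 2 * q[2] + q[3]) / 4
}
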