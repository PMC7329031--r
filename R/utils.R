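#' @keywords internal
"_PACKAGE"

## Calendar conventions: internal grids are in cal BP (before 1950 CE) at
## annual resolution; the CE convention appears only at the SPDSeries
## boundary and in user-facing tables.

#' Convert between cal BP and CE calendar conventions
#'
#' Calendar years "before present" are counted back from 1950 CE, so
#' `year_ce = 1950 - cal_bp`.
#'
#' @param cal_bp,year_ce Numeric vectors of calendar years.
#' @return Numeric vector in the other convention.
#' @export
bp_to_ce <- function(cal_bp) 1950 - cal_bp

#' @rdname bp_to_ce
#' @export
ce_to_bp <- function(year_ce) 1950 - year_ce

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG state is untouched. `seed = NULL` runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Derive a stream-specific child seed from a base seed, keeping the result
## a valid 32-bit integer.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + stream) %% .Machine$integer.max)
}

stopifnot_named <- function(x, what) {
  if (is.null(x)) stop(sprintf("'%s' is required", what), call. = FALSE)
  x
}
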