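## small shared helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's random stream.
#' @keywords internal
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## sub-seed derivation: one master seed fans out to named streams so data
## generation, splitting, initialization and augmentation draw independently.
## Offsets are fixed constants; results stay below 2^31.
sub_seed <- function(seed, stream) {
  offs <- c(data = 1001L, split = 2003L, init = 3007L, augment = 4001L,
            batch = 5003L, scene = 6007L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  as.integer(((as.numeric(seed) %% 1e6) * 2011 + offs[[stream]]) %% 100000003)
}

## clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
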